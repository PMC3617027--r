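#' Distance between two neurons on the ring
#'
#' Pyramidal neurons are arranged on a ring of `n` sites; the distance
#' between indices `i` and `j` is the shorter arc,
#' `min(|i - j|, n - |i - j|)`. Vectorized over `i` and `j`.
#'
#' @param i,j 0-based neuron indices.
#' @param n ring size.
#' @return integer distances in `[0, n/2]`.
#' @export
ring_distance <- function(i, j, n) {
  if (any(i < 0 | i >= n | j < 0 | j >= n))
    stop("neuron indices must lie in [0, n)")
  d <- abs(i - j)
  pmin(d, n - d)
}

#' Pyramidal-to-pyramidal synaptic weight
#'
#' The weight between pyramidal neurons `i` and `j` is a Gaussian function
#' of their ring distance, `W+ * exp(-d^2 / (2 sigma^2))`, mirroring the
#' monotone fall-off of lateral contact probability between pyramidal cells
#' in superficial and deep cortical layers.
#'
#' @param i,j 0-based neuron indices (vectorized).
#' @param connectivity the `connectivity` section of a network config (needs
#'   `gaussian_amplitude` and `gaussian_width`).
#' @param n ring size.
#' @return numeric weights.
#' @export
pyramidal_weight <- function(i, j, connectivity, n) {
  if (connectivity$gaussian_width <= 0)
    stop("gaussian_width must be positive")
  d <- ring_distance(i, j, n)
  connectivity$gaussian_amplitude *
    exp(-d^2 / (2 * connectivity$gaussian_width^2))
}

#' Voltage-dependent magnesium block of NMDA receptors
#'
#' The fraction of NMDA conductance available at membrane potential `v`,
#' `1 / (1 + [Mg] exp(-0.062 v) / 3.57)` with `[Mg]` in mM and `v` in mV.
#' Strictly increasing in `v`; equal to 1 for all `v` when magnesium is
#' absent.
#'
#' @param v membrane potential (mV), vectorized.
#' @param magnesium_mM extracellular magnesium concentration (mM).
#' @return factors in (0, 1].
#' @export
mg_block_factor <- function(v, magnesium_mM = 1) {
  if (magnesium_mM < 0) stop("magnesium concentration must be >= 0")
  1 / (1 + magnesium_mM * exp(-0.062 * v) / 3.57)
}

#' Build a local-circuit network
#'
#' Assembles the pyramidal-to-pyramidal weight matrix (Gaussian in ring
#' distance; all other connection blocks are uniform with weight 1) and
#' bundles it with the configuration. The returned object is what
#' [simulate_network()] integrates.
#'
#' @param cfg a [default_network_config()]-style configuration.
#' @return an object of class `circuit_network` with elements `config` and
#'   `W` (the `n_pyramidal` x `n_pyramidal` weight matrix).
#' @export
build_network <- function(cfg = default_network_config()) {
  validate_network_config(cfg)
  n <- cfg$populations$pyramidal$n
  idx <- seq_len(n) - 1L
  d <- outer(idx, idx, function(a, b) pmin(abs(a - b), n - abs(a - b)))
  W <- cfg$connectivity$gaussian_amplitude *
    exp(-d^2 / (2 * cfg$connectivity$gaussian_width^2))
  structure(list(config = cfg, W = W), class = "circuit_network")
}

#' @export
print.circuit_network <- function(x, ...) {
  cat("circuit_network:",
      x$config$populations$pyramidal$n, "pyramidal /",
      x$config$populations$interneuron$n, "interneurons, rho =",
      x$config$connectivity$rho, "\n")
  invisible(x)
}

#' Simulate a local circuit
#'
#' Integrates the network with the forward Euler method at the configured
#' timestep. The protocol list may contain:
#' \describe{
#'   \item{`i_inject_pyramidal`, `i_inject_interneuron`}{constant injected
#'     current (pA) per neuron.}
#'   \item{`pulses`}{a data.frame/matrix with columns `population`
#'     (`"pyramidal"` or `"interneuron"`), `onset`, `offset` (ms) and
#'     `factor`: during the pulse the population's mean excitatory noise
#'     conductance is set to `factor` times the reference excitatory
#'     conductance.}
#'   \item{`stimulus_rate`}{per-pyramidal-neuron extrinsic Poisson rate
#'     (Hz), with `g_ext_ampa` and `g_ext_nmda` conductance strengths (nS).}
#' }
#' When `sdf_populations` (a list of 0-based pyramidal index vectors) is
#' given, population spike-density functions are computed online with the
#' rise-and-decay kernel and sampled every millisecond; a positive
#' `stop_threshold` (Hz) ends the trial at the first crossing.
#'
#' @param network a [build_network()] object.
#' @param duration trial length (ms).
#' @param protocol list of time-varying inputs (see Details).
#' @param seed integer seed; every source of randomness in the simulation
#'   derives from it.
#' @param sdf_populations optional list of 0-based pyramidal index sets.
#' @param sdf_kernel [sdf_params()] used for online population SDFs.
#' @param stop_threshold Hz; 0 disables early stopping.
#' @return a `spike_raster` (see [spike_raster()]) with attributes `sdf`
#'   (samples x populations matrix), `crossed_pop` and `crossed_t` when SDF
#'   tracking is enabled.
#' @export
simulate_network <- function(network, duration, protocol = list(),
                             seed = NULL, sdf_populations = list(),
                             sdf_kernel = sdf_params(),
                             stop_threshold = 0) {
  stopifnot(inherits(network, "circuit_network"))
  if (!is.null(seed)) set.seed(seed)
  proto <- compile_protocol(protocol, network$config)
  res <- cpp_simulate_network(unclass(network$config), network$W, duration,
                              proto, lapply(sdf_populations, as.integer),
                              sdf_kernel$rise, sdf_kernel$decay,
                              stop_threshold)
  raster <- spike_raster(res$neuron, res$time, res$duration,
                         res$n_pyramidal, res$n_interneuron)
  if (length(sdf_populations) > 0) {
    attr(raster, "sdf") <- res$sdf[seq_len(res$n_samples), , drop = FALSE]
    attr(raster, "crossed_pop") <-
      if (res$crossed_pop > 0) res$crossed_pop else NA_integer_
    attr(raster, "crossed_t") <- res$crossed_t
  }
  raster
}

# Translate a user protocol into the flat list the C++ core expects.
compile_protocol <- function(protocol, cfg) {
  out <- list()
  if (!is.null(protocol$i_inject_pyramidal))
    out$i_inject_pyramidal <- protocol$i_inject_pyramidal
  if (!is.null(protocol$i_inject_interneuron))
    out$i_inject_interneuron <- protocol$i_inject_interneuron
  if (!is.null(protocol$pulses)) {
    p <- protocol$pulses
    if (is.data.frame(p)) {
      pop <- match(p$population, c("pyramidal", "interneuron")) - 1L
      if (anyNA(pop)) stop("pulse population must be pyramidal/interneuron")
      if (any(p$offset <= p$onset)) stop("pulse offset must exceed onset")
      if (any(p$factor < 0)) stop("pulse factor must be >= 0")
      out$pulses <- cbind(pop, p$onset, p$offset, p$factor)
    } else out$pulses <- as.matrix(p)
  }
  if (!is.null(protocol$stimulus_rate)) {
    n <- cfg$populations$pyramidal$n
    if (length(protocol$stimulus_rate) != n)
      stop("stimulus_rate must have one rate per pyramidal neuron")
    out$stimulus_rate <- protocol$stimulus_rate / 1000  # Hz -> spikes/ms
    out$g_ext_ampa <- protocol$g_ext_ampa %||% 0
    out$g_ext_nmda <- protocol$g_ext_nmda %||% 0
    out$stimulus_onset <- protocol$stimulus_onset %||% 0
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spike raster container
#'
#' An ordered set of (neuron, time) spike events from one simulation.
#' Neuron ids are 0-based with the pyramidal block first (ids
#' `0 .. n_pyramidal-1`), then interneurons.
#'
#' @param neuron integer neuron ids (0-based).
#' @param time spike times (ms).
#' @param duration trial length (ms).
#' @param n_pyramidal,n_interneuron population sizes.
#' @return a `spike_raster` data.frame with attributes.
#' @export
spike_raster <- function(neuron, time, duration, n_pyramidal,
                         n_interneuron) {
  o <- order(time, neuron)
  r <- data.frame(neuron_id = as.integer(neuron[o]), time_ms = time[o])
  if (nrow(r) > 0) {
    stopifnot(all(r$time_ms >= 0), all(r$time_ms <= duration + 1e-9),
              all(r$neuron_id >= 0),
              all(r$neuron_id < n_pyramidal + n_interneuron))
  }
  structure(r, duration = duration, n_pyramidal = n_pyramidal,
            n_interneuron = n_interneuron,
            class = c("spike_raster", "data.frame"))
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("spike_raster: %d spikes, %d+%d neurons, %.0f ms\n",
              nrow(x), attr(x, "n_pyramidal"), attr(x, "n_interneuron"),
              attr(x, "duration")))
  invisible(x)
}

#' @export
plot.spike_raster <- function(x, ...) {
  plot(x$time_ms, x$neuron_id + 1, pch = ".", xlab = "time (ms)",
       ylab = "neuron", ...)
  abline(h = attr(x, "n_pyramidal") + 0.5, col = "grey")
  invisible(x)
}

#' Read / write a spike raster as CSV
#'
#' Plain CSV with header `neuron_id,time_ms`, 0-based ids, pyramidal block
#' first. Metadata (duration and population sizes) is carried in `#`
#' comment lines at the top of the file so the round trip is lossless.
#'
#' @param raster a `spike_raster`.
#' @param path file path.
#' @return `read_raster_csv` returns a `spike_raster`; `write_raster_csv`
#'   returns `path` invisibly.
#' @export
write_raster_csv <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# duration_ms=%.6f n_pyramidal=%d n_interneuron=%d",
                     attr(raster, "duration"), attr(raster, "n_pyramidal"),
                     attr(raster, "n_interneuron")), con)
  utils::write.csv(as.data.frame(raster), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
read_raster_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, gregexpr("[0-9.]+", hdr))[[1]]
  d <- utils::read.csv(path, comment.char = "#")
  spike_raster(d$neuron_id, d$time_ms, as.numeric(m[1]),
               as.integer(m[2]), as.integer(m[3]))
}

#' Per-neuron spike trains from a raster
#'
#' @param raster a `spike_raster`.
#' @param population `"pyramidal"`, `"interneuron"` or `"all"`.
#' @return a list of numeric spike-time vectors, one per neuron
#'   (0-based order within the chosen population).
#' @export
spike_trains <- function(raster, population = c("pyramidal", "interneuron",
                                                "all")) {
  population <- match.arg(population)
  nE <- attr(raster, "n_pyramidal")
  nI <- attr(raster, "n_interneuron")
  keep <- switch(population,
                 pyramidal = raster$neuron_id < nE,
                 interneuron = raster$neuron_id >= nE,
                 all = rep(TRUE, nrow(raster)))
  ids <- raster$neuron_id[keep]
  if (population == "interneuron") ids <- ids - nE
  n <- switch(population, pyramidal = nE, interneuron = nI, all = nE + nI)
  out <- split(raster$time_ms[keep], factor(ids, levels = 0:(n - 1)))
  names(out) <- NULL
  out
}

#' Synaptic currents at a given membrane state
#'
#' Evaluates the recurrent and background currents of one pyramidal
#' neuron from explicit state values: AMPA, NMDA (with magnesium block and
#' the NMDA scale factor) and GABA recurrent currents plus the
#' point-conductance background current. Sign convention: positive values
#' are outward, so excitatory currents are negative below the excitatory
#' reversal potential. Negative noise conductances are clamped to zero at
#' use, matching the simulator.
#'
#' @param v membrane potential (mV).
#' @param cfg a `network_config`.
#' @param ampa_drive,nmda_drive,gaba_drive weighted sums of presynaptic
#'   gating variables (weight x gating, summed over presynaptic neurons).
#' @param g_e,g_i background noise conductances (nS).
#' @param target `"pyramidal"` or `"interneuron"` (selects receptor
#'   parameters).
#' @return named list of currents in pA: `ampa`, `nmda`, `gaba`,
#'   `background`, `total`.
#' @export
total_current <- function(v, cfg, ampa_drive = 0, nmda_drive = 0,
                          gaba_drive = 0, g_e = 0, g_i = 0,
                          target = c("pyramidal", "interneuron")) {
  target <- match.arg(target)
  syn <- cfg$synapses
  rec <- if (target == "pyramidal") syn$onto_pyramidal
         else syn$onto_interneuron
  B <- mg_block_factor(v, syn$magnesium_mM)
  i_ampa <- rec$g_ampa * ampa_drive * (v - syn$excitatory_reversal)
  i_nmda <- cfg$connectivity$rho * rec$g_nmda * B * nmda_drive *
    (v - syn$excitatory_reversal)
  i_gaba <- rec$g_gaba * gaba_drive * (v - syn$inhibitory_reversal)
  i_bg <- max(g_e, 0) * (v - syn$excitatory_reversal) +
    max(g_i, 0) * (v - syn$inhibitory_reversal)
  list(ampa = i_ampa, nmda = i_nmda, gaba = i_gaba, background = i_bg,
       total = i_ampa + i_nmda + i_gaba + i_bg)
}
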