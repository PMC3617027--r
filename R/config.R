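#' Default network configuration
#'
#' Returns the full parameter set for one local circuit: leaky
#' integrate-and-fire membrane parameters for the pyramidal and interneuron
#' populations, AMPA/NMDA/GABA synaptic kinetics and conductance strengths
#' per target population, ring connectivity, point-conductance background
#' noise, and the integration step.
#'
#' Units throughout: conductance nS, capacitance pF, potential mV, time ms,
#' current pA (nS x mV = pA, pF/nS = ms), diffusion nS^2/ms. Membrane parameters follow
#' the classic working-memory ring-model lineage (pyramidal: Cm 500 pF, gL
#' 25 nS; interneuron: Cm 200 pF, gL 20 nS; VL -70, Vth -50, Vreset -60 mV;
#' refractory 2/1 ms). Background noise parameters follow the standard
#' point-conductance model of in vivo-like synaptic bombardment (tau_e
#' 2.728 ms, tau_i 10.49 ms, sd_e 3.0 nS, sd_i 6.6 nS, mean excitatory
#' conductance 12.1 nS onto pyramidal cells). The mean excitatory noise
#' conductance for interneurons and the mean inhibitory noise conductance
#' for both populations are zero: recurrent connectivity itself supplies
#' inhibitory background onto pyramidal cells and both backgrounds onto
#' interneurons.
#'
#' Recurrent conductance strengths are expressed per unit synaptic weight
#' per presynaptic neuron at the reference size (1000 pyramidal / 250
#' interneurons); [scale_network_config()] rescales them when the network is
#' shrunk so that total recurrent drive is preserved.
#'
#' @param n_pyramidal number of pyramidal neurons (ring size).
#' @param n_interneuron number of interneurons.
#' @return A nested list of class `network_config`.
#' @export
default_network_config <- function(n_pyramidal = 1000L,
                                   n_interneuron = 250L) {
  cfg <- list(
    populations = list(
      pyramidal = list(
        n = as.integer(n_pyramidal),
        membrane_capacitance = 500,   # pF
        leak_conductance = 25,        # nS
        leak_reversal = -70,          # mV
        spike_threshold = -50,        # mV
        reset_potential = -60,        # mV
        refractory_period = 2         # ms
      ),
      interneuron = list(
        n = as.integer(n_interneuron),
        membrane_capacitance = 200,
        leak_conductance = 20,
        leak_reversal = -70,
        spike_threshold = -50,
        reset_potential = -60,
        refractory_period = 1
      )
    ),
    synapses = list(
      excitatory_reversal = 0,     # mV, AMPA and NMDA
      inhibitory_reversal = -70,   # mV, GABA
      magnesium_mM = 1,            # extracellular [Mg2+]
      nmda_saturation_rate = 0.5,  # alpha, 1/ms
      nmda_rise_time_constant = 2, # tau_x, ms
      # Conductance strengths (nS per unit weight per presynaptic neuron at
      # reference size) and decay time constants (ms) by target population.
      # AMPA is stronger and faster onto interneurons; NMDA is stronger and
      # slower onto pyramidal cells; GABA is several times stronger than the
      # excitatory conductances and stronger onto pyramidal cells.
      onto_pyramidal = list(
        g_ampa = 0.10, tau_ampa = 2,
        g_nmda = 0.24, tau_nmda = 100,
        g_gaba = 2.80, tau_gaba = 10
      ),
      onto_interneuron = list(
        g_ampa = 0.45, tau_ampa = 1,
        g_nmda = 0.12, tau_nmda = 50,
        g_gaba = 0.50, tau_gaba = 10
      )
    ),
    connectivity = list(
      gaussian_amplitude = 1.0,   # W+ of the pyramidal-to-pyramidal Gaussian
      gaussian_width = 60,        # sigma, in ring units at reference size
      rho = 1.0                   # NMDA conductance scale factor
    ),
    noise = list(
      pyramidal = list(
        mean_exc_conductance = 12.1,  # g_e0, nS
        mean_inh_conductance = 0,     # g_i0, nS (recurrent GABA suffices)
        exc_time_constant = 2.728,    # tau_e, ms
        inh_time_constant = 10.49,    # tau_i, ms
        exc_diffusion = 2 * 3.0^2 / 2.728,  # D_e = 2 sd_e^2 / tau_e
        inh_diffusion = 2 * 6.6^2 / 10.49   # D_i
      ),
      interneuron = list(
        mean_exc_conductance = 0,
        mean_inh_conductance = 0,
        exc_time_constant = 2.728,
        inh_time_constant = 10.49,
        exc_diffusion = 2 * 3.0^2 / 2.728,
        inh_diffusion = 2 * 6.6^2 / 10.49
      ),
      # Reference mean excitatory conductance used by control pulses: a pulse
      # with scale factor f sets the target population's g_e0 to
      # f * reference during the pulse window, so pulses are well defined
      # even for a population whose resting g_e0 is zero.
      reference_exc_conductance = 12.1
    ),
    integration = list(
      dt = 0.02,            # ms, forward Euler
      reference_n_pyramidal = 1000L
    )
  )
  class(cfg) <- "network_config"
  validate_network_config(cfg)
  cfg
}

#' Validate a network configuration
#'
#' Checks the structural invariants of a [default_network_config()]-style
#' list: positive capacitances, conductances and time constants, reset below
#' threshold, non-negative diffusion coefficients, positive Gaussian width
#' and NMDA scale factor. A pyramidal/interneuron ratio different from 4:1
#' raises a warning, not an error.
#'
#' @param cfg a `network_config` list.
#' @return `cfg`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_network_config <- function(cfg) {
  for (pop in c("pyramidal", "interneuron")) {
    p <- cfg$populations[[pop]]
    stopifnot(p$n >= 1,
              p$membrane_capacitance > 0,
              p$leak_conductance > 0,
              p$reset_potential < p$spike_threshold,
              p$refractory_period >= 0)
  }
  syn <- cfg$synapses
  for (tgt in c("onto_pyramidal", "onto_interneuron")) {
    s <- syn[[tgt]]
    stopifnot(s$tau_ampa > 0, s$tau_nmda > 0, s$tau_gaba > 0,
              s$g_ampa >= 0, s$g_nmda >= 0, s$g_gaba >= 0)
    if (s$tau_nmda <= s$tau_ampa)
      stop("NMDA decay must be slower than AMPA decay (", tgt, ")")
  }
  if (syn$magnesium_mM < 0) stop("magnesium concentration must be >= 0")
  stopifnot(syn$nmda_rise_time_constant > 0, syn$nmda_saturation_rate > 0)
  con <- cfg$connectivity
  if (con$gaussian_width <= 0) stop("gaussian_width must be > 0")
  if (con$rho < 0) stop("rho must be >= 0")
  for (pop in c("pyramidal", "interneuron")) {
    nz <- cfg$noise[[pop]]
    stopifnot(nz$exc_time_constant > 0, nz$inh_time_constant > 0,
              nz$exc_diffusion >= 0, nz$inh_diffusion >= 0)
  }
  stopifnot(cfg$integration$dt > 0)
  ratio <- cfg$populations$pyramidal$n / cfg$populations$interneuron$n
  if (abs(ratio - 4) > 1e-9)
    warning("pyramidal/interneuron ratio is ", signif(ratio, 3),
            ", not the default 4:1", call. = FALSE)
  invisible(cfg)
}

#' Rescale a configuration to a smaller network
#'
#' Produces a configuration for a network of `n_pyramidal` pyramidal cells
#' (and proportionally many interneurons) whose population-level dynamics
#' approximate the reference-size network: per-synapse recurrent conductance
#' strengths are multiplied by `reference_n / n_pyramidal` so summed
#' recurrent drive is preserved, and the Gaussian footprint is scaled to the
#' same fraction of the ring. Background noise parameters are per neuron and
#' are left unchanged.
#'
#' @param cfg a `network_config`.
#' @param n_pyramidal new ring size.
#' @param dt optional new integration step (ms).
#' @return a rescaled `network_config`.
#' @export
scale_network_config <- function(cfg, n_pyramidal, dt = NULL) {
  n_ref <- cfg$integration$reference_n_pyramidal
  f <- n_ref / n_pyramidal
  n_int <- max(1L, as.integer(round(n_pyramidal / 4)))
  cfg$populations$pyramidal$n <- as.integer(n_pyramidal)
  cfg$populations$interneuron$n <- n_int
  for (tgt in c("onto_pyramidal", "onto_interneuron")) {
    for (g in c("g_ampa", "g_nmda", "g_gaba"))
      cfg$synapses[[tgt]][[g]] <- cfg$synapses[[tgt]][[g]] * f
  }
  cfg$connectivity$gaussian_width <- cfg$connectivity$gaussian_width / f
  if (!is.null(dt)) cfg$integration$dt <- dt
  suppressWarnings(validate_network_config(cfg))
  cfg
}

#' Read / write a configuration as JSON
#'
#' The configuration is serialized as plain JSON so simulation protocols can
#' be versioned alongside analysis code.
#'
#' @param cfg a `network_config`.
#' @param path file path.
#' @return `read_network_config` returns a `network_config`;
#'   `write_network_config` returns `path` invisibly.
#' @export
write_network_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_network_config
#' @export
read_network_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$populations$pyramidal$n <- as.integer(cfg$populations$pyramidal$n)
  cfg$populations$interneuron$n <- as.integer(cfg$populations$interneuron$n)
  cfg$integration$reference_n_pyramidal <-
    as.integer(cfg$integration$reference_n_pyramidal)
  class(cfg) <- "network_config"
  validate_network_config(cfg)
  cfg
}

#' @export
print.network_config <- function(x, ...) {
  cat("Local-circuit network configuration\n")
  cat(sprintf("  populations : %d pyramidal / %d interneurons\n",
              x$populations$pyramidal$n, x$populations$interneuron$n))
  cat(sprintf("  connectivity: W+ = %.3g, sigma = %.3g, rho = %.3g\n",
              x$connectivity$gaussian_amplitude,
              x$connectivity$gaussian_width, x$connectivity$rho))
  cat(sprintf("  integration : dt = %.3g ms\n", x$integration$dt))
  invisible(x)
}

#' Reduced-size network for exploratory and test runs
#'
#' Convenience constructor: the default configuration rescaled with
#' [scale_network_config()] to a smaller ring and a coarser integration
#' step. Population-level dynamics approximate the reference network;
#' finite-size fluctuations are correspondingly larger, so estimate
#' distributions are wider than at reference size.
#'
#' @param n_pyramidal ring size.
#' @param dt integration step (ms).
#' @return a `circuit_network` (see [build_network()]).
#' @export
small_network <- function(n_pyramidal = 250, dt = 0.1) {
  cfg <- suppressWarnings(
    scale_network_config(default_network_config(), n_pyramidal, dt = dt))
  suppressWarnings(build_network(cfg))
}
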