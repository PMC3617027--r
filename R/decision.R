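#' Gaussian response-field stimulus configuration
#'
#' Two noisy stimuli drive the decision network: a target and a distractor,
#' each a set of independent homogeneous Poisson spike trains whose
#' per-neuron rates follow a Gaussian response field around the stimulus
#' centre. The response-field width equals the width of the recurrent
#' pyramidal interaction structure. On each trial one population-level rate
#' is drawn per stimulus from a normal distribution (truncated at zero);
#' the distractor's mean is the target's mean multiplied by the task
#' difficulty (target-distractor similarity in `[0, 1]`: 0 silences the
#' distractor, 1 makes the stimuli indistinguishable on average).
#'
#' The default mean rate represents a pool of upstream stimulus-selective
#' neurons (200 neurons firing at 8 Hz each) feeding every response-field
#' neuron through relatively weak extrinsic conductances, trading spatial
#' for temporal summation.
#'
#' @param n_pyramidal ring size of the decision network.
#' @param target_centre,distractor_centre 0-based response-field centres;
#'   default quarter and three-quarter points of the ring.
#' @param mean_rate mean summed input rate at the field centre (Hz).
#' @param rate_sd per-trial standard deviation of the rate draw (Hz).
#' @param width response-field width (ring units).
#' @param g_ext_ampa,g_ext_nmda extrinsic conductance strengths (nS).
#' @return a list of class `stimulus_config`.
#' @export
stimulus_config <- function(n_pyramidal = 1000L,
                            target_centre = round(n_pyramidal / 4),
                            distractor_centre = round(3 * n_pyramidal / 4),
                            mean_rate = 3000,
                            rate_sd = 300,
                            width = 60 * n_pyramidal / 1000,
                            g_ext_ampa = 0.25,
                            g_ext_nmda = 0.025) {
  stopifnot(target_centre != distractor_centre, mean_rate >= 0,
            rate_sd >= 0, width > 0)
  structure(list(n_pyramidal = as.integer(n_pyramidal),
                 target_centre = as.integer(target_centre),
                 distractor_centre = as.integer(distractor_centre),
                 mean_rate = mean_rate, rate_sd = rate_sd, width = width,
                 g_ext_ampa = g_ext_ampa, g_ext_nmda = g_ext_nmda),
            class = "stimulus_config")
}

#' Timing-to-decision coupling configuration
#'
#' The decision network is identical to the timing network except for its
#' NMDA scale factor, set to one quarter of the timing baseline so that its
#' intrinsic processing alone cannot reach decisions, and for the presence
#' of stimulus selectivity. Every pyramidal neuron in the decision network
#' receives AMPA-only input from all pyramidal neurons of the timing
#' network at one fifth of the extrinsic AMPA strength; climbing activity
#' upstream thereby gain-modulates decision processing.
#'
#' @param rho_baseline timing-network baseline NMDA scale factor.
#' @param decision_rho decision-network NMDA scale factor.
#' @param g_ext_ampa extrinsic AMPA strength the coupling is derived from.
#' @param n_timing_pyramidal timing-network ring size; the per-synapse
#'   coupling conductance is scaled by `reference / n` so the summed
#'   non-selective drive matches the reference-size network.
#' @param g_couple coupling AMPA conductance (nS per timing pyramidal
#'   neuron).
#' @param timing_rho_speed,timing_rho_accuracy timing-network scale factors
#'   imposing a tight and a loose temporal constraint.
#' @return a list of class `coupling_config`.
#' @export
coupling_config <- function(rho_baseline = 1.7,
                            decision_rho = rho_baseline / 4,
                            g_ext_ampa = stimulus_config()$g_ext_ampa,
                            n_timing_pyramidal = 1000,
                            g_couple = (g_ext_ampa / 5) *
                              (1000 / n_timing_pyramidal),
                            timing_rho_speed = 2.0,
                            timing_rho_accuracy = 1.4) {
  stopifnot(g_couple >= 0, decision_rho >= 0)
  structure(list(rho_baseline = rho_baseline, decision_rho = decision_rho,
                 g_couple = g_couple,
                 timing_rho_speed = timing_rho_speed,
                 timing_rho_accuracy = timing_rho_accuracy),
            class = "coupling_config")
}

#' Per-neuron stimulus rate profile
#'
#' `rate(i) = mean_rate * exp(-d(i, centre)^2 / (2 width^2))` with ring
#' distance `d`.
#'
#' @param centre 0-based centre index.
#' @param mean_rate rate at the centre (Hz).
#' @param width Gaussian width (ring units).
#' @param n ring size.
#' @return numeric rate vector (Hz), length `n`.
#' @export
stimulus_rate_profile <- function(centre, mean_rate, width, n) {
  d <- ring_distance(seq_len(n) - 1L, rep(centre, n), n)
  mean_rate * exp(-d^2 / (2 * width^2))
}

#' Generate homogeneous Poisson spike trains
#'
#' Independent homogeneous Poisson trains, one per entry of `rate`.
#' (The network simulator draws its extrinsic Poisson input internally with
#' per-step Bernoulli thinning; this generator provides trains for
#' analyses and for checking Poisson statistics.)
#'
#' @param rate per-train rate vector (Hz).
#' @param duration train length (ms).
#' @return list of sorted spike-time vectors (ms).
#' @export
generate_poisson_inputs <- function(rate, duration) {
  lapply(rate, function(r) {
    n <- stats::rpois(1, r * duration / 1000)
    sort(stats::runif(n, 0, duration))
  })
}

# Decision populations: response-field centre +/- halfwidth (0-based sets).
decision_populations <- function(stimulus, halfwidth) {
  n <- stimulus$n_pyramidal
  list(target = sort((stimulus$target_centre +
                        seq(-halfwidth, halfwidth)) %% n),
       distractor = sort((stimulus$distractor_centre +
                            seq(-halfwidth, halfwidth)) %% n))
}

#' Run one coupled-circuit decision trial
#'
#' Simulates the timing and decision circuits concurrently. The timing
#' network climbs under `timing_rho`; its pyramidal spikes drive a
#' spatially non-selective AMPA conductance onto every decision pyramidal
#' neuron. The decision network receives the two Poisson stimuli; the
#' first of the target/distractor populations whose mean SDF reaches the
#' rate threshold determines the outcome (simultaneous same-sample
#' crossings are broken by the higher SDF, then by coin flip), and the
#' crossing time is the decision time. If neither population crosses
#' within the trial the outcome is `"none"`.
#'
#' @param timing_network,decision_network [build_network()] objects with
#'   identical parameters (rho is overridden per role).
#' @param coupling a [coupling_config()].
#' @param stimulus a [stimulus_config()].
#' @param difficulty distractor multiplier in `[0, 1]`.
#' @param timing_rho timing-network NMDA scale factor for this trial.
#' @param duration maximum trial length (ms), measured from stimulus onset.
#' @param stimulus_onset time (ms) at which the stimuli switch on; the
#'   preceding window lets both circuits settle into their background
#'   states, and decision times are measured from stimulus onset.
#' @param threshold decision threshold (Hz).
#' @param halfwidth neurons averaged on either side of each RF centre.
#' @param seed integer seed.
#' @param keep_rasters return both rasters.
#' @param early_stop end the trial at the first crossing.
#' @return list of class `decision_result`: outcome
#'   (`"correct"`/`"error"`/`"none"`), decision_time (ms or NA),
#'   difficulty, rates drawn, and optionally the rasters and SDF traces.
#' @export
run_decision_trial <- function(timing_network, decision_network, coupling,
                               stimulus, difficulty, timing_rho,
                               duration = 1500, stimulus_onset = 300,
                               threshold = 20,
                               halfwidth = 25, seed = NULL,
                               keep_rasters = FALSE, early_stop = TRUE) {
  stopifnot(difficulty >= 0, difficulty <= 1)
  if (!is.null(seed)) set.seed(seed)
  timing_network$config$connectivity$rho <- timing_rho
  decision_network$config$connectivity$rho <- coupling$decision_rho

  mu_t <- max(0, stats::rnorm(1, stimulus$mean_rate, stimulus$rate_sd))
  mu_d <- max(0, stats::rnorm(1, difficulty * stimulus$mean_rate,
                              stimulus$rate_sd))
  n <- stimulus$n_pyramidal
  rate <- stimulus_rate_profile(stimulus$target_centre, mu_t,
                                stimulus$width, n) +
          stimulus_rate_profile(stimulus$distractor_centre, mu_d,
                                stimulus$width, n)
  pops <- decision_populations(stimulus, halfwidth)
  proto_d <- compile_protocol(list(stimulus_rate = rate,
                                   g_ext_ampa = stimulus$g_ext_ampa,
                                   g_ext_nmda = stimulus$g_ext_nmda,
                                   stimulus_onset = stimulus_onset),
                              decision_network$config)
  sp <- sdf_params()
  res <- cpp_simulate_coupled(unclass(timing_network$config),
                              timing_network$W,
                              unclass(decision_network$config),
                              decision_network$W,
                              stimulus_onset + duration, list(), proto_d,
                              coupling$g_couple,
                              lapply(pops, as.integer), list(),
                              sp$rise, sp$decay,
                              if (early_stop) threshold else 0,
                              stimulus_onset)
  ns <- res$n_samples
  sdf <- res$decision$sdf[seq_len(ns), , drop = FALSE]
  crossed <- res$crossed_pop
  dt_ms <- res$crossed_t
  if (!early_stop) {
    # read the crossing off the recorded traces (from stimulus onset)
    ct <- apply(sdf, 2, function(v) {
      i <- which(v >= threshold & seq_along(v) - 1 >= stimulus_onset)
      if (length(i)) i[1] - 1 else NA_real_
    })
    if (all(is.na(ct))) { crossed <- 0 } else {
      crossed <- which.min(ct)
      dt_ms <- ct[crossed]
    }
  }
  outcome <- if (crossed == 0) "none" else if (crossed == 1) "correct"
             else "error"
  out <- list(outcome = outcome,
              decision_time = if (crossed == 0) NA_real_
                              else dt_ms - stimulus_onset,
              difficulty = difficulty, timing_rho = timing_rho,
              target_rate = mu_t, distractor_rate = mu_d, sdf = sdf)
  if (keep_rasters) {
    out$timing_raster <- with(res$timing, spike_raster(
      neuron, time, duration, n_pyramidal, n_interneuron))
    out$decision_raster <- with(res$decision, spike_raster(
      neuron, time, duration, n_pyramidal, n_interneuron))
  }
  class(out) <- "decision_result"
  out
}

#' @export
print.decision_result <- function(x, ...) {
  cat(sprintf("decision_result: %s at %s ms (difficulty %.2f)\n", x$outcome,
              format(x$decision_time), x$difficulty))
  invisible(x)
}

#' Run a speed/accuracy block of decision trials
#'
#' Runs `n_trials` per (condition, difficulty) cell. The speed condition
#' runs the timing network with the scale factor learned for a short
#' interval (tight temporal constraint, strong gain modulation early); the
#' accuracy condition uses the factor for a long interval. Outcome-"none"
#' trials are excluded from accuracy and decision-time statistics and
#' reported separately.
#'
#' @param timing_network,decision_network [build_network()] objects.
#' @param coupling a [coupling_config()].
#' @param stimulus a [stimulus_config()].
#' @param difficulties numeric difficulties in `[0, 1]`.
#' @param n_trials trials per cell.
#' @param seed base seed.
#' @param ... passed to [run_decision_trial()].
#' @return a list of class `sat_summary`: `trials` (per-trial data.frame)
#'   and `summary` (per-cell accuracy with 95% binomial CI, mean decision
#'   time with standard error, counts).
#' @export
run_sat_block <- function(timing_network, decision_network, coupling,
                          stimulus, difficulties = c(0, 0.5, 1),
                          n_trials = 100, seed = 1, ...) {
  conds <- c(speed = coupling$timing_rho_speed,
             accuracy = coupling$timing_rho_accuracy)
  rows <- list()
  cell <- 0L
  for (ci in seq_along(conds)) {
    for (di in seq_along(difficulties)) {
      cell <- cell + 1L
      for (k in seq_len(n_trials)) {
        tr <- run_decision_trial(timing_network, decision_network, coupling,
                                 stimulus, difficulties[di], conds[ci],
                                 seed = seed + 100000L * cell + k, ...)
        rows[[length(rows) + 1]] <- data.frame(
          trial = k, condition = names(conds)[ci],
          difficulty = difficulties[di], outcome = tr$outcome,
          decision_time_ms = if (is.na(tr$decision_time)) NA_real_
                             else tr$decision_time)
      }
    }
  }
  trials <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(
    split(trials, list(trials$condition, trials$difficulty)), function(g) {
      dec <- g[g$outcome != "none", ]
      nc <- sum(dec$outcome == "correct")
      ci <- if (nrow(dec) > 0)
        stats::binom.test(nc, nrow(dec))$conf.int else c(NA, NA)
      data.frame(condition = g$condition[1], difficulty = g$difficulty[1],
                 n = nrow(g), n_decided = nrow(dec),
                 accuracy = if (nrow(dec)) nc / nrow(dec) else NA_real_,
                 acc_lo = ci[1], acc_hi = ci[2],
                 mean_dt = mean(dec$decision_time_ms),
                 se_dt = stats::sd(dec$decision_time_ms) /
                   sqrt(max(1, nrow(dec))))
    }))
  rownames(summary) <- NULL
  structure(list(trials = trials, summary = summary), class = "sat_summary")
}

#' @export
print.sat_summary <- function(x, ...) {
  print(x$summary, digits = 3)
  invisible(x)
}

#' Gain-modulation probe of the decision network
#'
#' Runs one coupled trial with a single stimulus (the distractor silenced)
#' and compares the spatial profile of the decision network's response in
#' an early and a late window. As climbing activity evolves upstream, the
#' response amplitude should grow without a change in tuning width:
#' spatially non-selective input produces gain modulation, not a change of
#' selectivity. Gaussian fits quantify amplitude, centre and width per
#' window.
#'
#' @param timing_network,decision_network [build_network()] objects.
#' @param coupling a [coupling_config()].
#' @param stimulus a [stimulus_config()].
#' @param timing_rho timing-network scale factor.
#' @param duration trial length (ms).
#' @param window window length (ms) at the start and end of the trial.
#' @param n_trials trials whose spatial profiles are averaged before
#'   fitting.
#' @param seed integer seed (trial `k` uses `seed + k - 1`).
#' @return list of class `gain_probe`: `early_fit`, `late_fit`
#'   ([gaussian_profile_fit()] results), `early_profile`, `late_profile`.
#' @export
gain_modulation_probe <- function(timing_network, decision_network,
                                  coupling, stimulus, timing_rho = 1.8,
                                  duration = 1000, window = 250,
                                  stimulus_onset = 300, n_trials = 1,
                                  seed = 1) {
  early <- late <- 0
  for (k in seq_len(n_trials)) {
    tr <- run_decision_trial(timing_network, decision_network, coupling,
                             stimulus, difficulty = 0,
                             timing_rho = timing_rho, duration = duration,
                             stimulus_onset = stimulus_onset,
                             seed = seed + k - 1, keep_rasters = TRUE,
                             early_stop = FALSE)
    sdfm <- compute_sdf_matrix(tr$decision_raster)
    tg <- attr(sdfm, "time")
    early <- early + colMeans(sdfm[tg >= stimulus_onset &
                                     tg <= stimulus_onset + window, ,
                                   drop = FALSE]) / n_trials
    late <- late + colMeans(sdfm[tg >= stimulus_onset + duration - window, ,
                                 drop = FALSE]) / n_trials
  }
  structure(list(early_fit = gaussian_profile_fit(early),
                 late_fit = gaussian_profile_fit(late),
                 early_profile = early, late_profile = late),
            class = "gain_probe")
}

#' @export
print.gain_probe <- function(x, ...) {
  cat(sprintf("gain probe: amplitude %.2f -> %.2f Hz, width %.1f -> %.1f\n",
              x$early_fit$amplitude, x$late_fit$amplitude,
              x$early_fit$width, x$late_fit$width))
  invisible(x)
}

#' Quantile analysis of decision-time distributions
#'
#' For each difficulty, the normalized cumulative distribution of
#' correct-trial decision times is evaluated and the times at which it
#' crosses the requested quantiles are read off; straight lines are then
#' fitted to crossing time against difficulty. A steeper slope for the
#' upper quantile than the lower one means the tail of the distribution
#' grows faster than its leading edge as the task hardens. Per-difficulty
#' skewness and correct-versus-error mean decision times are also
#' reported.
#'
#' @param trials per-trial data.frame (columns `difficulty`, `outcome`,
#'   `decision_time_ms`), e.g. one condition of `run_sat_block()$trials`.
#' @param quantiles probabilities of interest.
#' @return a list of class `quantile_slopes`: `crossings` (difficulty x
#'   quantile), `slopes` (one per quantile), `skewness` per difficulty,
#'   `mean_dt_correct`, `mean_dt_error`.
#' @export
quantile_slope_analysis <- function(trials, quantiles = c(0.1, 0.9)) {
  sp <- split(trials, trials$difficulty)
  cross <- do.call(rbind, lapply(sp, function(g) {
    dts <- g$decision_time_ms[g$outcome == "correct"]
    q <- stats::quantile(dts, quantiles, na.rm = TRUE, type = 6)
    data.frame(difficulty = g$difficulty[1], t(as.numeric(q)))
  }))
  names(cross)[-1] <- paste0("q", quantiles)
  rownames(cross) <- NULL
  slopes <- vapply(seq_along(quantiles), function(j) {
    unname(stats::coef(stats::lm(cross[[j + 1]] ~ cross$difficulty))[2])
  }, numeric(1))
  names(slopes) <- paste0("q", quantiles)
  skew <- vapply(sp, function(g)
    sample_skewness(g$decision_time_ms[g$outcome == "correct"]), numeric(1))
  structure(list(crossings = cross, slopes = slopes, skewness = skew,
                 mean_dt_correct = mean(
                   trials$decision_time_ms[trials$outcome == "correct"],
                   na.rm = TRUE),
                 mean_dt_error = mean(
                   trials$decision_time_ms[trials$outcome == "error"],
                   na.rm = TRUE)),
            class = "quantile_slopes")
}

#' @export
print.quantile_slopes <- function(x, ...) {
  print(x$crossings, digits = 4)
  cat("slopes:", paste(sprintf("%s = %.3g", names(x$slopes), x$slopes),
                       collapse = ", "), "\n")
  invisible(x)
}
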