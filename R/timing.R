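#' Interval-estimation protocol
#'
#' Bundles the knobs of the interval-estimation task: the NMDA scale
#' factors to probe, trial length, the firing-rate threshold whose crossing
#' by the bump population's mean SDF defines the interval estimate, and the
#' number of flanking neurons averaged on either side of the bump centre.
#'
#' The default `rho` grid spans the climbing regime of the default
#' configuration; the trial must be long enough that the slowest `rho`
#' crosses threshold on most trials.
#'
#' @param rho numeric vector of NMDA scale factors.
#' @param trial_duration trial length (ms).
#' @param rate_threshold Hz; crossing time = interval estimate.
#' @param bump_halfwidth neurons averaged on either side of the centre.
#' @param n_trials trials per `rho`.
#' @return a list of class `timing_protocol`.
#' @export
timing_protocol <- function(rho = seq(1.3, 2, by = 0.1),
                            trial_duration = 2500,
                            rate_threshold = 20,
                            bump_halfwidth = 100,
                            n_trials = 500) {
  stopifnot(rate_threshold > 0, trial_duration > 0, bump_halfwidth >= 0,
            n_trials >= 1, all(rho > 0))
  structure(list(rho = rho, trial_duration = trial_duration,
                 rate_threshold = rate_threshold,
                 bump_halfwidth = bump_halfwidth, n_trials = n_trials),
            class = "timing_protocol")
}

#' Identify the bump population from per-neuron SDFs
#'
#' The neuron with the highest trial-mean SDF is the bump centre; the bump
#' population is the centre plus `halfwidth` neurons on either side with
#' ring wrap-around. Ties are broken toward the lowest index. If every
#' SDF is identically zero there is no bump.
#'
#' @param sdf_matrix samples x neurons matrix ([compute_sdf_matrix()]).
#' @param halfwidth flanking neurons on each side.
#' @return list with `centre` (0-based index or NA), `members` (0-based
#'   indices) and `no_bump` flag.
#' @export
identify_bump <- function(sdf_matrix, halfwidth) {
  mu <- colMeans(sdf_matrix)
  if (all(mu == 0))
    return(list(centre = NA_integer_, members = integer(0), no_bump = TRUE))
  centre <- which.max(mu) - 1L            # which.max takes the first max
  n <- ncol(sdf_matrix)
  members <- sort(unique((centre + seq(-halfwidth, halfwidth)) %% n))
  list(centre = centre, members = members, no_bump = FALSE)
}

#' First threshold crossing of a rate trace
#'
#' Earliest sample at which the trace is at or above `threshold`;
#' `NA` if it never crosses.
#'
#' @param mean_sdf an `sdf_trace` (or numeric vector with a `time`
#'   attribute).
#' @param threshold Hz.
#' @return crossing time (ms) or `NA`.
#' @export
detect_threshold_crossing <- function(mean_sdf, threshold) {
  i <- which(as.numeric(mean_sdf) >= threshold)
  if (length(i) == 0) return(NA_real_)
  attr(mean_sdf, "time")[i[1]]
}

#' Run one interval-estimation trial
#'
#' Simulates the timing network at NMDA scale `rho`, builds per-neuron
#' SDFs, identifies the bump population, and reads the interval estimate
#' from the first crossing of the rate threshold by the bump population's
#' mean SDF.
#'
#' @param network a [build_network()] object (its `rho` is overridden).
#' @param rho NMDA conductance scale factor for this trial.
#' @param protocol a [timing_protocol()].
#' @param seed integer seed.
#' @param keep_raster return the raster alongside the estimate.
#' @param extra_protocol additional simulation protocol entries (e.g.
#'   control pulses) merged into the trial.
#' @return list: `estimate` (ms or NA), `bump_centre` (0-based or NA),
#'   `rho`, `mean_sdf`, and optionally `raster`.
#' @export
run_interval_trial <- function(network, rho, protocol = timing_protocol(),
                               seed = NULL, keep_raster = FALSE,
                               extra_protocol = list()) {
  network$config$connectivity$rho <- rho
  raster <- simulate_network(network, protocol$trial_duration,
                             protocol = extra_protocol, seed = seed)
  sdfm <- compute_sdf_matrix(raster)
  bump <- identify_bump(sdfm, protocol$bump_halfwidth)
  if (bump$no_bump) {
    out <- list(estimate = NA_real_, bump_centre = NA_integer_, rho = rho,
                mean_sdf = NULL)
  } else {
    ms <- population_mean_sdf(sdfm, bump$members + 1L)
    out <- list(estimate = detect_threshold_crossing(ms,
                                                     protocol$rate_threshold),
                bump_centre = bump$centre, rho = rho, mean_sdf = ms)
  }
  if (keep_raster) out$raster <- raster
  out
}

#' Run the interval-estimation experiment over a rho grid
#'
#' @param network a [build_network()] object.
#' @param protocol a [timing_protocol()].
#' @param seed base seed; trial `k` of `rho[i]` uses
#'   `seed + 1000 * i + k`.
#' @return data.frame with columns trial, rho, estimate_ms, bump_centre.
#' @export
run_timing_experiment <- function(network, protocol = timing_protocol(),
                                  seed = 1) {
  rows <- list()
  for (i in seq_along(protocol$rho)) {
    for (k in seq_len(protocol$n_trials)) {
      tr <- run_interval_trial(network, protocol$rho[i], protocol,
                               seed = seed + 1000L * i + k)
      rows[[length(rows) + 1]] <-
        data.frame(trial = k, rho = protocol$rho[i],
                   estimate_ms = tr$estimate,
                   bump_centre = if (is.na(tr$bump_centre)) NA_integer_
                                 else tr$bump_centre)
    }
  }
  do.call(rbind, rows)
}

#' Scalar-property summary of interval estimates
#'
#' Groups estimates by `rho`, computes mean, SD, CV (with a bootstrap CI)
#' per group excluding no-estimate trials (reported as a separate count),
#' fits SD against mean by least squares, and fits a horizontal line to the
#' CV. An approximately linear SD-vs-mean relation with constant CV is the
#' scalar property (Weber's law) of interval timing.
#'
#' @param estimates data.frame from [run_timing_experiment()] (columns
#'   `rho`, `estimate_ms`), or any data.frame with those columns.
#' @param n_boot bootstrap resamples for the CV confidence intervals.
#' @return a list of class `scalar_property`: `table` (per-rho summary),
#'   `slope`, `intercept`, `r_squared` of the SD-on-mean fit, `cv_mean`
#'   (horizontal CV fit), and `cv_range`.
#' @export
scalar_property_summary <- function(estimates, n_boot = 1000) {
  groups <- split(estimates, estimates$rho)
  tab <- do.call(rbind, lapply(groups, function(g) {
    ok <- is.finite(g$estimate_ms)
    s <- summary_statistics(g$estimate_ms[ok], n_boot = n_boot)
    data.frame(rho = g$rho[1], n = sum(ok), n_missed = sum(!ok),
               mean = s$mean, sd = s$sd, cv = s$cv,
               cv_lo = s$cv_ci[1], cv_hi = s$cv_ci[2])
  }))
  rownames(tab) <- NULL
  fit <- stats::lm(sd ~ mean, data = tab)
  structure(list(table = tab,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 cv_mean = mean(tab$cv),
                 cv_range = diff(range(tab$cv))),
            class = "scalar_property")
}

#' @export
print.scalar_property <- function(x, ...) {
  print(x$table, digits = 4)
  cat(sprintf("SD ~ mean: slope %.4f, R^2 %.3f; CV %.3f (range %.3f)\n",
              x$slope, x$r_squared, x$cv_mean, x$cv_range))
  invisible(x)
}

#' Learn an interval by trial-to-trial adjustment of rho
#'
#' Starting from `rho0`, after each trial the NMDA scale factor moves in
#' the direction that reduces the timing error:
#' `rho[n+1] = rho[n] + eta * (T[n] - T_desired)`,
#' exploiting the monotone decrease of the estimate with `rho` (an estimate
#' that is too long calls for stronger NMDA conductance and hence faster
#' climbing). Trials without an estimate leave `rho` unchanged and are
#' logged. `rho` is floored at `rho_min`.
#'
#' @param network a [build_network()] object.
#' @param t_desired target interval (ms).
#' @param eta learning rate (1/ms).
#' @param n_trials number of trials.
#' @param protocol a [timing_protocol()] (its `rho` grid is ignored).
#' @param seed base seed; trial `k` uses `seed + k`.
#' @param rho0 starting scale factor.
#' @param rho_min lower floor for `rho`.
#' @param estimator optional function `(rho, seed) -> estimate` replacing
#'   the spiking trial (used for fixed-point analysis of the rule).
#' @return data.frame of class `learning_trace`: trial, rho, estimate_ms,
#'   updated (logical); attributes `t_desired`, `eta`.
#' @export
learn_interval <- function(network, t_desired, eta, n_trials,
                           protocol = timing_protocol(), seed = 1,
                           rho0 = 1.7, rho_min = 0.1,
                           estimator = NULL) {
  stopifnot(eta > 0, t_desired > 0)
  rho <- rho0
  rows <- list()
  for (k in seq_len(n_trials)) {
    est <- if (is.null(estimator)) {
      run_interval_trial(network, rho, protocol, seed = seed + k)$estimate
    } else estimator(rho, seed + k)
    updated <- is.finite(est)
    rows[[k]] <- data.frame(trial = k, rho = rho, estimate_ms = est,
                            updated = updated)
    if (updated) rho <- max(rho_min, rho + eta * (est - t_desired))
  }
  out <- do.call(rbind, rows)
  attr(out, "t_desired") <- t_desired
  attr(out, "eta") <- eta
  class(out) <- c("learning_trace", "data.frame")
  out
}

#' Control pulses for starting and stopping an estimate
#'
#' Builds the pulse table understood by [simulate_network()]. Two
#' mechanisms are supported. `"nonselective_excitation_pyramidal"` raises
#' the mean excitatory noise conductance of every pyramidal neuron; a brief
#' pulse recruits blanket feedback inhibition and resets the network
#' regardless of its state, so the same pulse both starts and stops an
#' estimate. `"excitation_interneurons"` raises the mean excitatory noise
#' conductance of the interneurons, stopping the estimate through
#' disynaptic inhibition.
#'
#' @param mechanism one of the two mechanisms above.
#' @param onset pulse onset (ms).
#' @param duration pulse length (ms).
#' @param factor scale factor applied to the reference excitatory noise
#'   conductance during the pulse (>= 1).
#' @return one-row data.frame usable as (part of) `protocol$pulses`.
#' @export
control_pulse <- function(mechanism = c("nonselective_excitation_pyramidal",
                                        "excitation_interneurons"),
                          onset, duration, factor) {
  mechanism <- match.arg(mechanism)
  stopifnot(duration > 0, factor >= 0)
  data.frame(population = if (mechanism == "excitation_interneurons")
               "interneuron" else "pyramidal",
             onset = onset, offset = onset + duration, factor = factor)
}
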