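#' Spike-density-function parameters
#'
#' Parameters of the causal rise-and-decay kernel
#' `k(u) = (1 - exp(-u/rise)) * exp(-u/decay)` for `u >= 0`, used to turn
#' spike trains into continuous firing-rate estimates. The kernel is used
#' unnormalized and the trace is then scaled by `1000 / integral(k)` so
#' that a sustained Poisson train of rate `r` Hz produces a plateau of
#' about `r` Hz, letting thresholds be expressed in Hz.
#'
#' @param rise rise time constant (ms).
#' @param decay decay time constant (ms); must exceed `rise`.
#' @param resolution sample resolution (ms).
#' @return a list of class `sdf_params`.
#' @export
sdf_params <- function(rise = 1, decay = 20, resolution = 1) {
  stopifnot(rise > 0, decay > rise, resolution > 0)
  structure(list(rise = rise, decay = decay, resolution = resolution),
            class = "sdf_params")
}

# kernel integral in ms: tau_d^2 / (tau_g + tau_d)
sdf_kernel_integral <- function(params) {
  params$decay^2 / (params$rise + params$decay)
}

#' Spike-density function of one spike train
#'
#' Convolves a spike train with the causal rise-and-decay kernel and samples
#' the result on a regular grid. Each spike contributes only after its own
#' time.
#'
#' @param spike_times numeric spike times (ms).
#' @param duration trial length (ms).
#' @param params an [sdf_params()] object.
#' @return an `sdf_trace`: numeric rate vector (Hz) with attribute `time`
#'   (ms).
#' @export
compute_sdf <- function(spike_times, duration, params = sdf_params()) {
  tg <- seq(0, duration, by = params$resolution)
  out <- numeric(length(tg))
  K <- sdf_kernel_integral(params)
  for (ts in spike_times) {
    live <- tg >= ts
    u <- tg[live] - ts
    out[live] <- out[live] +
      (1 - exp(-u / params$rise)) * exp(-u / params$decay)
  }
  structure(1000 * out / K, time = tg, class = "sdf_trace")
}

#' Spike-density functions for every neuron of a population
#'
#' @param raster a `spike_raster`.
#' @param params an [sdf_params()].
#' @param population which block of the raster to use.
#' @return a samples x neurons matrix of rates (Hz), with attribute `time`.
#' @export
compute_sdf_matrix <- function(raster, params = sdf_params(),
                               population = "pyramidal") {
  trains <- spike_trains(raster, population)
  duration <- attr(raster, "duration")
  tg <- seq(0, duration, by = params$resolution)
  m <- matrix(0, length(tg), length(trains))
  for (j in seq_along(trains))
    m[, j] <- as.numeric(compute_sdf(trains[[j]], duration, params))
  attr(m, "time") <- tg
  m
}

#' Mean SDF over an index set
#'
#' Pointwise arithmetic mean of the SDF traces of the neurons in
#' `index_set`.
#'
#' @param sdf_matrix samples x neurons matrix from [compute_sdf_matrix()].
#' @param index_set 1-based column indices.
#' @return an `sdf_trace`.
#' @export
population_mean_sdf <- function(sdf_matrix, index_set) {
  stopifnot(length(index_set) >= 1)
  structure(rowMeans(sdf_matrix[, index_set, drop = FALSE]),
            time = attr(sdf_matrix, "time"), class = "sdf_trace")
}

#' @export
plot.sdf_trace <- function(x, ...) {
  plot(attr(x, "time"), as.numeric(x), type = "l", xlab = "time (ms)",
       ylab = "rate (Hz)", ...)
  invisible(x)
}

#' Gaussian fit to a spatial activity profile on the ring
#'
#' Fits `baseline + amplitude * exp(-d^2 / (2 width^2))` to a profile over
#' ring positions by nonlinear least squares, where `d` is ring distance to
#' the fitted centre. The profile is first rotated so its maximum sits at
#' the ring midpoint (the deterministic initialization rule), the Gaussian
#' is fitted in rotated coordinates and the centre is mapped back, making
#' the fit invariant to shifts across the ring seam.
#'
#' @param profile numeric vector over ring positions `0 .. n-1`.
#' @param n ring size (defaults to `length(profile)`).
#' @return a `gaussian_fit` list: amplitude, centre (0-based, real-valued),
#'   width, baseline, residual_norm.
#' @export
gaussian_profile_fit <- function(profile, n = length(profile)) {
  stopifnot(length(profile) == n, n >= 8)
  shift <- which.max(profile) - 1L          # 0-based argmax
  mid <- floor(n / 2)
  rot <- ((seq_len(n) - 1L) - shift + mid) %% n  # argmax now at mid
  y <- numeric(n)
  y[rot + 1L] <- profile
  u <- (seq_len(n) - 1L) - mid
  if (diff(range(y)) < 1e-9) {
    # flat profile: degenerate fit rather than a solver failure
    return(structure(list(amplitude = 0, centre = shift %% n, width = n / 10,
                          baseline = mean(y), residual_norm = 0),
                     class = "gaussian_fit"))
  }
  d0 <- data.frame(u = u, y = y)
  obj <- function(par) {
    sum((y - (par[3] + par[1] * exp(-(u - par[4])^2 / (2 * par[2]^2))))^2)
  }
  cf2 <- tryCatch({
    fit <- minpack.lm::nlsLM(y ~ b + A * exp(-u^2 / (2 * w^2)), data = d0,
                             start = list(A = max(y) - min(y), w = n / 10,
                                          b = min(y)),
                             lower = c(A = 0, w = 1e-3, b = -Inf),
                             control = minpack.lm::nls.lm.control(
                               maxiter = 200))
    cf <- stats::coef(fit)
    fit2 <- minpack.lm::nlsLM(y ~ b + A * exp(-(u - c0)^2 / (2 * w^2)),
                              data = d0,
                              start = list(A = cf[["A"]], w = cf[["w"]],
                                           b = cf[["b"]], c0 = 0),
                              lower = c(A = 0, w = 1e-3, b = -Inf,
                                        c0 = -n / 2),
                              upper = c(A = Inf, w = Inf, b = Inf,
                                        c0 = n / 2),
                              control = minpack.lm::nls.lm.control(
                                maxiter = 200))
    stats::coef(fit2)
  }, error = function(e) {
    # derivative-free fallback for ill-conditioned profiles
    o <- stats::optim(c(max(y) - min(y), n / 10, min(y), 0), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000))
    c(A = max(o$par[1], 0), w = abs(o$par[2]), b = o$par[3], c0 = o$par[4])
  })
  structure(list(amplitude = unname(cf2[["A"]]),
                 centre = (shift + cf2[["c0"]]) %% n,
                 width = abs(unname(cf2[["w"]])),
                 baseline = unname(cf2[["b"]]),
                 residual_norm = sqrt(obj(c(cf2[["A"]], cf2[["w"]],
                                            cf2[["b"]], cf2[["c0"]])))),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf(
    "gaussian_fit: amplitude %.3g, centre %.2f, width %.3g, baseline %.3g\n",
    x$amplitude, x$centre, x$width, x$baseline))
  invisible(x)
}

#' Dip statistic for unimodality
#'
#' Hartigan-style dip statistic: half the sup-norm distance from the
#' empirical CDF to the nearest unimodal CDF, computed by scanning
#' candidate modes and measuring, for each, the distance of the ECDF to its
#' greatest convex minorant left of the mode and to its least concave
#' majorant right of the mode. P-values are calibrated by Monte Carlo
#' against the uniform null (the least favourable unimodal distribution).
#'
#' @param x numeric sample.
#' @param n_boot Monte Carlo replicates for the p-value (0 skips it).
#' @param n_modes maximum number of candidate modes scanned (all points are
#'   used when the sample is smaller).
#' @return a list of class `dip_test`: statistic, p_value, n, degenerate
#'   (TRUE when the sample has fewer than 4 distinct values).
#' @export
dip_test <- function(x, n_boot = 200, n_modes = 500) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (length(unique(x)) < 4) {
    return(structure(list(statistic = 0, p_value = NA_real_, n = n,
                          degenerate = TRUE), class = "dip_test"))
  }
  stat <- dip_stat(x, n_modes)
  p <- NA_real_
  if (n_boot > 0) {
    null <- vapply(seq_len(n_boot),
                   function(i) dip_stat(sort(stats::runif(n)), n_modes),
                   numeric(1))
    p <- (1 + sum(null >= stat)) / (n_boot + 1)
  }
  structure(list(statistic = stat, p_value = p, n = n, degenerate = FALSE),
            class = "dip_test")
}

#' @export
print.dip_test <- function(x, ...) {
  cat(sprintf("dip test: D = %.4f, p = %s, n = %d%s\n", x$statistic,
              format(x$p_value), x$n,
              if (x$degenerate) " (degenerate sample)" else ""))
  invisible(x)
}

# Max deviation of the ECDF above its greatest convex minorant over x[1..m].
# Uses upper ECDF values i/n on the convex side and lower values (i-1)/n on
# the concave side, reflecting the step corners of the empirical CDF.
gcm_deviation <- function(x, Fv) {
  m <- length(x)
  hull <- c(1L)                 # indices of convex minorant vertices
  for (i in 2:m) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1]; b <- hull[length(hull)]
      # drop b if it lies above segment a -> i
      if ((Fv[b] - Fv[a]) * (x[i] - x[a]) >=
          (Fv[i] - Fv[a]) * (x[b] - x[a])) hull <- hull[-length(hull)]
      else break
    }
    hull <- c(hull, i)
  }
  dev <- 0
  for (k in seq_len(length(hull) - 1)) {
    a <- hull[k]; b <- hull[k + 1]
    if (x[b] > x[a]) {
      idx <- a:b
      interp <- Fv[a] + (Fv[b] - Fv[a]) * (x[idx] - x[a]) / (x[b] - x[a])
      dev <- max(dev, max(Fv[idx] - interp))
    }
  }
  dev
}

dip_stat <- function(x, n_modes) {
  n <- length(x)
  Fu <- seq_len(n) / n          # upper corner values
  Fl <- (seq_len(n) - 1) / n    # lower corner values
  cand <- if (n <= n_modes) seq_len(n)
          else unique(round(seq(1, n, length.out = n_modes)))
  best <- Inf
  for (m in cand) {
    left <- if (m >= 3) gcm_deviation(x[1:m], Fu[1:m]) else 0
    right <- if (m <= n - 2)
      gcm_deviation(rev(-x[m:n]), rev(1 - Fl[m:n])) else 0
    best <- min(best, max(left, right))
  }
  best / 2
}

#' Interspike-interval analysis of climbing activity
#'
#' Pools the interspike intervals of a set of spike trains inside an epoch
#' and summarizes them: the least-squares slope of ISI against the time of
#' the earlier spike of each pair (a negative slope indicates a genuine
#' firing-rate gradient), sample skewness, and the dip test for
#' unimodality. Climbing activity carried by a true rate gradient shows a
#' negative trend and a positively skewed, unimodal ISI distribution,
#' distinguishing it from averaged binary up/down switching.
#'
#' @param trains list of spike-time vectors (ms).
#' @param epoch numeric length-2 window (ms).
#' @param n_boot Monte Carlo replicates for the dip p-value.
#' @return a list of class `isi_analysis`: trend_slope (ms ISI per ms),
#'   skewness, dip (a `dip_test`), n_isi, mean_isi.
#' @export
isi_analysis <- function(trains, epoch, n_boot = 200) {
  isis <- list(); onsets <- list()
  for (tr in trains) {
    tr <- sort(tr[tr >= epoch[1] & tr <= epoch[2]])
    if (length(tr) >= 2) {
      isis[[length(isis) + 1]] <- diff(tr)
      onsets[[length(onsets) + 1]] <- tr[-length(tr)]
    }
  }
  isi <- unlist(isis); onset <- unlist(onsets)
  if (length(isi) < 4) {
    return(structure(list(trend_slope = NA_real_, skewness = NA_real_,
                          dip = NULL, n_isi = length(isi),
                          mean_isi = mean(isi)), class = "isi_analysis"))
  }
  slope <- unname(stats::coef(stats::lm(isi ~ onset))[2])
  structure(list(trend_slope = slope,
                 skewness = sample_skewness(isi),
                 dip = dip_test(isi, n_boot = n_boot),
                 n_isi = length(isi),
                 mean_isi = mean(isi)),
            class = "isi_analysis")
}

#' @export
print.isi_analysis <- function(x, ...) {
  cat(sprintf("ISI analysis: n = %d, mean %.1f ms, trend %.4g, skew %.3g\n",
              x$n_isi, x$mean_isi, x$trend_slope, x$skewness))
  if (!is.null(x$dip)) print(x$dip)
  invisible(x)
}

sample_skewness <- function(x) {
  m <- mean(x); s <- stats::sd(x)
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

#' Summary statistics with a bootstrap CI for the CV
#'
#' Mean, sample standard deviation, coefficient of variation with a
#' percentile bootstrap confidence interval (fixed number of resamples,
#' reproducible given the RNG state), skewness and quantiles.
#'
#' @param x numeric sample.
#' @param n_boot bootstrap resamples for the CV interval.
#' @param conf confidence level.
#' @return a list: n, mean, sd, cv, cv_ci (length 2), skewness, quantiles.
#' @export
summary_statistics <- function(x, n_boot = 2000, conf = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  m <- mean(x); s <- stats::sd(x)
  cv <- if (m != 0) s / m else NA_real_
  ci <- c(NA_real_, NA_real_)
  if (n >= 3 && n_boot > 0 && m != 0) {
    bs <- vapply(seq_len(n_boot), function(i) {
      xi <- x[sample.int(n, n, replace = TRUE)]
      stats::sd(xi) / mean(xi)
    }, numeric(1))
    a <- (1 - conf) / 2
    ci <- unname(stats::quantile(bs, c(a, 1 - a), na.rm = TRUE))
  }
  list(n = n, mean = m, sd = s, cv = cv, cv_ci = ci,
       skewness = if (n >= 3) sample_skewness(x) else NA_real_,
       quantiles = stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9)))
}

#' Write an SDF trace as CSV
#'
#' Two columns, `t_ms,rate_hz`.
#'
#' @param trace an `sdf_trace`.
#' @param path file path.
#' @export
write_sdf_csv <- function(trace, path) {
  utils::write.csv(data.frame(t_ms = attr(trace, "time"),
                              rate_hz = as.numeric(trace)),
                   path, row.names = FALSE)
  invisible(path)
}
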