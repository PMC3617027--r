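#' Parameters of the unstable Ornstein-Uhlenbeck growth process
#'
#' Near the unstable flat steady state the reduced system expands along
#' the leading eigenvector, and the amplitude `z` of that mode follows a
#' one-dimensional OU process with positive drift,
#' `dz = lambda z dt + sigma dW`, started at `z0 > 0`. The interval
#' estimate is the first passage of `z` through the NMDA-activation
#' threshold `theta_z`.
#'
#' @param lambda drift eigenvalue (1/ms), positive because the flat state
#'   is unstable.
#' @param sigma noise amplitude (state units per sqrt ms).
#' @param z0 initial amplitude (state units).
#' @param theta_z threshold (state units), greater than `z0`.
#' @return a list of class `ou_params`.
#' @export
ou_params <- function(lambda, sigma, z0, theta_z) {
  stopifnot(lambda > 0, sigma >= 0, z0 > 0, theta_z > z0)
  structure(list(lambda = lambda, sigma = sigma, z0 = z0,
                 theta_z = theta_z), class = "ou_params")
}

#' Transition density of the growth process
#'
#' At time `t` the process is Gaussian with mean `z0 exp(lambda t)` —
#' the deterministic exponential growth curve — and standard deviation
#' `sigma sqrt((exp(2 lambda t) - 1) / (2 lambda))`.
#'
#' @param z state values.
#' @param t time (ms, scalar).
#' @param params an [ou_params()].
#' @return density values.
#' @export
ou_transition_density <- function(z, t, params) {
  m <- params$z0 * exp(params$lambda * t)
  s <- sqrt(params$sigma^2 * (exp(2 * params$lambda * t) - 1) /
              (2 * params$lambda))
  if (s == 0) return(ifelse(z == m, Inf, 0))
  stats::dnorm(z, m, s)
}

#' Mean growth curve of the process
#'
#' @param t time (ms).
#' @param params an [ou_params()].
#' @return `z0 exp(lambda t)`.
#' @export
ou_mean_trajectory <- function(t, params) {
  params$z0 * exp(params$lambda * t)
}

#' First-passage-time distribution of the growth process
#'
#' For positive drift the accumulated noise saturates:
#' `z(t) = exp(lambda t) (z0 + eta(t))` with
#' `eta(t) -> N(0, s^2)`, `s^2 = sigma^2 / (2 lambda)`. The passage time of
#' `theta_z` is therefore `T = ln(theta_z / (z0 + eta)) / lambda`, with
#' density
#' `f(T) = lambda theta_z exp(-lambda T) *
#'         dnorm(theta_z exp(-lambda T); z0, s)`.
#' The reported moments are the exact mean and variance of this
#' distribution (Gaussian quadrature over the saturated noise variable);
#' to leading order in `s/z0` they reduce to
#' `mean ~ (ln(theta_z/z0) + s^2/(2 z0^2)) / lambda` and
#' `variance ~ s^2 / (lambda^2 z0^2)`.
#' Shorter estimates (larger `lambda`, smaller threshold) come with
#' proportionally smaller spread, which is the scalar property.
#'
#' @param params an [ou_params()].
#' @param t optional time grid (ms); defaults to an adaptive grid reaching
#'   `mean + 8 SD`, which captures essentially all probability mass.
#' @return a list of class `fpt_distribution`: `t`, `density`, `mean`,
#'   `variance`, `sd`, `params`.
#' @export
fpt_density <- function(params, t = NULL) {
  s <- params$sigma / sqrt(2 * params$lambda)
  mo <- fpt_moments(params)
  m <- mo[["mean"]]; v <- mo[["variance"]]
  if (is.null(t))
    t <- seq(max(0, m - 10 * sqrt(v)), m + 8 * sqrt(v), length.out = 2048)
  u <- params$theta_z * exp(-params$lambda * t)
  dens <- params$lambda * u * stats::dnorm(u, params$z0, s)
  structure(list(t = t, density = dens, mean = m, variance = v,
                 sd = sqrt(v), params = params),
            class = "fpt_distribution")
}

# Exact moments of T = ln(theta/(z0+eta))/lambda, eta ~ N(0, s^2),
# integrated over the admissible branch eta > -z0 (the excluded mass is
# negligible whenever z0 exceeds a few multiples of s).
fpt_moments <- function(params) {
  s <- params$sigma / sqrt(2 * params$lambda)
  if (s == 0) {
    m <- log(params$theta_z / params$z0) / params$lambda
    return(c(mean = m, variance = 0))
  }
  Tof <- function(eta) log(params$theta_z / (params$z0 + eta)) /
    params$lambda
  lo <- max(-params$z0 * (1 - 1e-12), -8 * s)
  hi <- 8 * s
  m1 <- stats::integrate(function(e) Tof(e) * stats::dnorm(e, 0, s),
                         lo, hi, rel.tol = 1e-10)$value
  m2 <- stats::integrate(function(e) Tof(e)^2 * stats::dnorm(e, 0, s),
                         lo, hi, rel.tol = 1e-10)$value
  c(mean = m1, variance = m2 - m1^2)
}

#' @export
print.fpt_distribution <- function(x, ...) {
  cat(sprintf("first-passage distribution: mean %.1f ms, sd %.2f ms\n",
              x$mean, x$sd))
  invisible(x)
}

#' @export
plot.fpt_distribution <- function(x, ...) {
  plot(x$t, x$density, type = "l", xlab = "time (ms)", ylab = "density",
       ...)
  invisible(x)
}

#' Monte-Carlo first-passage times
#'
#' Euler-Maruyama paths of `dz = lambda z dt + sigma dW` from `z0` until
#' the first crossing of `theta_z`. Paths that have not crossed by the
#' horizon are counted and excluded (with a warning if they exceed 0.1% of
#' paths).
#'
#' @param params an [ou_params()].
#' @param n_paths number of simulated paths.
#' @param dt Euler step (ms).
#' @param seed integer seed.
#' @param horizon maximum path length (ms); defaults to closed-form mean
#'   plus 12 SD.
#' @return list: `times` (crossing times of crossed paths), `n_uncrossed`.
#' @export
simulate_ou_first_passage <- function(params, n_paths = 10000, dt = 0.1,
                                      seed = NULL, horizon = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cf <- fpt_density(params)
  if (is.null(horizon)) horizon <- cf$mean + 12 * cf$sd
  if (params$sigma == 0) {
    # deterministic growth: single crossing time for every path
    tm <- log(params$theta_z / params$z0) / params$lambda
    return(list(times = rep(tm, n_paths), n_uncrossed = 0L))
  }
  tt <- cpp_ou_first_passage(n_paths, params$z0, params$theta_z,
                             params$lambda, params$sigma, dt, horizon)
  n_un <- sum(is.na(tt))
  if (n_un > 0.001 * n_paths)
    warning(sprintf("%d of %d paths did not cross within the horizon",
                    n_un, n_paths), call. = FALSE)
  list(times = tt[!is.na(tt)], n_uncrossed = n_un)
}

#' Map a firing-rate threshold to an NMDA-activation threshold
#'
#' The state variable of the reduced system is NMDA activation, not firing
#' rate. The fixed firing-rate threshold of the timing network is carried
#' over by scaling with the ratio of the maxima of the two quantities at
#' the stable bump state: `theta_z = rate_threshold * max_activation /
#' max_rate`.
#'
#' @param rate_threshold firing-rate threshold (Hz).
#' @param max_rate peak firing rate of the stable bump state (Hz).
#' @param max_activation peak NMDA activation of the stable bump state.
#' @return threshold in activation units.
#' @export
nmda_threshold_from_rate <- function(rate_threshold, max_rate,
                                     max_activation) {
  stopifnot(rate_threshold > 0, max_rate > 0, max_activation > 0)
  rate_threshold * max_activation / max_rate
}

#' Derive OU parameters from the reduced model over a rho grid
#'
#' For each NMDA scale factor in the climbing regime: the unstable flat
#' state supplies the positive eigenvalue `lambda`; the stable bump state
#' supplies the threshold via [nmda_threshold_from_rate()], expressed as a
#' deviation from the flat state. The initial amplitude of the unstable
#' mode is the scale the background noise itself establishes before
#' exponential growth takes over, a fixed multiple `kappa` of the
#' stationary linear-mode scale `sigma / sqrt(2 lambda)`. The noise
#' amplitude is held constant across the family, consistent with constant
#' background-noise parameters across `rho` in the spiking network.
#'
#' @param params a [reduced_params()].
#' @param rho_grid scale factors, all in the climbing regime (regime 3).
#' @param sigma common noise amplitude (state units per sqrt ms).
#' @param kappa initial amplitude in units of the stationary mode scale:
#'   `z0 = kappa * sigma / sqrt(2 lambda)`.
#' @return data.frame of class `ou_family` with columns rho, z0, theta_z,
#'   lambda, sigma, plus peak rate/activation of the bump state.
#' @export
ou_params_from_reduced <- function(params, rho_grid, sigma = 1e-3,
                                   kappa = 5) {
  rows <- lapply(rho_grid, function(r) {
    params$rho <- r
    cls <- classify_regime(params)
    if (cls$regime != 3)
      stop("rho = ", r, " is not in the climbing regime (regime ",
           cls$regime, ")")
    states <- cls$states
    shapes <- vapply(states, function(s) s$shape, character(1))
    stable <- vapply(states, function(s) s$stable, logical(1))
    flat <- states[[which(shapes == "flat" & !stable)[1]]]
    bump <- states[[which(shapes == "bump" & stable)[1]]]
    s_flat <- flat$S[1]
    lam <- flat$max_eigenvalue
    z0 <- kappa * sigma / sqrt(2 * lam)
    theta_abs <- nmda_threshold_from_rate(params$rate_threshold,
                                          bump$peak_rate, bump$peak_S)
    data.frame(rho = r, z0 = z0, theta_z = theta_abs - s_flat,
               lambda = lam, sigma = sigma,
               bump_peak_rate = bump$peak_rate,
               bump_peak_activation = bump$peak_S, s_flat = s_flat)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ou_family", "data.frame")
  out
}

#' Scalar-property curve of a first-passage family
#'
#' Closed-form mean and SD of the first-passage time for each parameter
#' set, with the least-squares fit of SD on mean. An approximately linear
#' relation with near-constant coefficient of variation is the scalar
#' property.
#'
#' @param family an `ou_family` data.frame (or any data.frame with columns
#'   lambda, sigma, z0, theta_z).
#' @return list of class `scalar_property`: `table` (mean, sd, cv per
#'   row), `slope`, `intercept`, `r_squared`, `cv_mean`, `cv_range`.
#' @export
scalar_property_curve <- function(family) {
  tab <- do.call(rbind, lapply(seq_len(nrow(family)), function(i) {
    p <- ou_params(family$lambda[i], family$sigma[i], family$z0[i],
                   family$theta_z[i])
    f <- fpt_density(p)
    data.frame(rho = if ("rho" %in% names(family)) family$rho[i] else NA,
               mean = f$mean, sd = f$sd, cv = f$sd / f$mean)
  }))
  fit <- stats::lm(sd ~ mean, data = tab)
  structure(list(table = tab,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 cv_mean = mean(tab$cv),
                 cv_range = diff(range(tab$cv))),
            class = "scalar_property")
}
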