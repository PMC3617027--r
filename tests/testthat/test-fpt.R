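test_that("the transition density grows along the exponential curve", {
  p <- ou_params(lambda = 0.004, sigma = 3e-4, z0 = 0.04, theta_z = 0.3)
  for (t in c(50, 200, 600))
    expect_equal(ou_mean_trajectory(t, p), 0.04 * exp(0.004 * t))
  # variance increases in time
  sd_at <- function(t) sqrt(p$sigma^2 * (exp(2 * p$lambda * t) - 1) /
                              (2 * p$lambda))
  expect_true(all(diff(sd_at(c(10, 100, 400, 800))) > 0))
  # at small t the density concentrates at the (barely moved) mean
  d <- ou_transition_density(seq(0, 0.1, by = 1e-4), 1, p)
  expect_equal(seq(0, 0.1, by = 1e-4)[which.max(d)],
               ou_mean_trajectory(1, p), tolerance = 1e-2)
  # sigma = 0: delta at the deterministic trajectory
  p0 <- ou_params(0.004, 0, 0.04, 0.3)
  expect_equal(ou_transition_density(0.04 * exp(0.004 * 10), 10, p0), Inf)
  expect_equal(ou_transition_density(0.2, 10, p0), 0)
})

test_that("the first-passage density integrates to one and matches its
           own moments", {
  p <- ou_params(lambda = 0.004, sigma = 3e-4, z0 = 0.04, theta_z = 0.3)
  f <- fpt_density(p)
  dt <- diff(f$t[1:2])
  mass <- sum(f$density) * dt
  expect_equal(mass, 1, tolerance = 1e-3)
  m_num <- sum(f$t * f$density) * dt
  v_num <- sum((f$t - m_num)^2 * f$density) * dt
  expect_equal(m_num, f$mean, tolerance = 0.01 * f$mean)
  expect_equal(v_num, f$variance, tolerance = 0.01 * f$variance)
  # leading-order analytic forms agree in the small-noise regime
  s2 <- p$sigma^2 / (2 * p$lambda)
  expect_equal(f$mean, (log(p$theta_z / p$z0) + s2 / (2 * p$z0^2)) /
                 p$lambda, tolerance = 0.01 * f$mean)
  expect_equal(f$variance, s2 / (p$lambda^2 * p$z0^2),
               tolerance = 0.05 * f$variance)
})

test_that("degenerate and limiting cases of the first-passage time", {
  # threshold just above z0: mean goes to zero
  p <- ou_params(lambda = 0.004, sigma = 1e-6, z0 = 0.04,
                 theta_z = 0.04 * (1 + 1e-9))
  expect_lt(fpt_density(p)$mean, 1e-3)
  # sigma = 0: deterministic crossing at the closed-form limit
  p0 <- ou_params(0.004, 0, 0.04, 0.3)
  mc <- simulate_ou_first_passage(p0, 100)
  expect_equal(unique(mc$times), log(0.3 / 0.04) / 0.004)
  # mean decreases in lambda at fixed (z0, theta, sigma)
  means <- vapply(c(0.002, 0.004, 0.008), function(l)
    fpt_density(ou_params(l, 3e-4, 0.04, 0.3))$mean, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("Monte-Carlo first passage matches the closed form", {
  p <- ou_params(lambda = 0.005, sigma = 4e-4, z0 = 0.05, theta_z = 0.32)
  f <- fpt_density(p)
  mc <- simulate_ou_first_passage(p, n_paths = 20000, dt = 0.05, seed = 17)
  expect_equal(mean(mc$times), f$mean, tolerance = 0.02 * f$mean)
  expect_equal(var(mc$times), f$variance, tolerance = 0.06 * f$variance)
  expect_lt(mc$n_uncrossed, 5)
  # halving dt barely changes the empirical mean
  mc2 <- simulate_ou_first_passage(p, n_paths = 20000, dt = 0.025,
                                   seed = 18)
  expect_equal(mean(mc2$times), mean(mc$times),
               tolerance = 0.01 * mean(mc$times))
})

test_that("rate-to-activation threshold mapping is proportional", {
  expect_equal(nmda_threshold_from_rate(20, 20, 0.6), 0.6)
  expect_equal(nmda_threshold_from_rate(20, 40, 0.6),
               nmda_threshold_from_rate(20, 20, 0.6) / 2)
  expect_error(nmda_threshold_from_rate(20, -1, 0.5))
})

test_that("a constructed SD = c * mean family is recovered and the
           noise-independence constraint matters", {
  # family built so that the closed-form SD is exactly 0.1 * mean:
  # choose constant theta/z0 ratio and sigma ~ sqrt(lambda) * z0 * c * ln
  lam <- seq(0.002, 0.008, by = 0.001)
  ratio <- 8
  z0 <- 0.04
  cv <- 0.05
  fam <- data.frame(lambda = lam,
                    sigma = cv * log(ratio) * z0 * sqrt(2 * lam),
                    z0 = z0, theta_z = z0 * ratio)
  sp <- scalar_property_curve(fam)
  expect_equal(sp$slope, cv, tolerance = 0.03)
  expect_gt(sp$r_squared, 0.999)
  expect_lt(sp$cv_range / sp$cv_mean, 0.05)

  # negative control: making sigma proportional to lambda (violating the
  # excitation-independent-noise constraint) breaks CV constancy
  fam2 <- fam
  fam2$sigma <- 2e-1 * fam2$lambda
  sp2 <- scalar_property_curve(fam2)
  expect_gt(sp2$cv_range / sp2$cv_mean, 0.25)
})
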