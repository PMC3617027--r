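test_that("SDF construction matches the rise-and-decay kernel", {
  p <- sdf_params()
  # empty train: all-zero trace
  z <- compute_sdf(numeric(0), 200, p)
  expect_true(all(as.numeric(z) == 0))

  # single spike: trace equals the (calibrated) kernel itself
  s <- compute_sdf(50, 300, p)
  tg <- attr(s, "time")
  u <- pmax(tg - 50, 0)
  K <- p$decay^2 / (p$rise + p$decay)
  ref <- ifelse(tg >= 50, 1000 * (1 - exp(-u / p$rise)) *
                  exp(-u / p$decay) / K, 0)
  expect_equal(as.numeric(s), ref)
  # causal: nothing before the spike
  expect_true(all(as.numeric(s)[tg < 50] == 0))
  # peak where the kernel's derivative vanishes:
  # u* = rise * log(1 + decay/rise)
  u_star <- p$rise * log(1 + p$decay / p$rise)
  expect_equal(tg[which.max(as.numeric(s))] - 50, round(u_star),
               tolerance = 1)

  # superposition: SDF of merged trains = sum of individual SDFs
  a <- c(10, 40, 90); b <- c(20, 95)
  expect_equal(as.numeric(compute_sdf(c(a, b), 200, p)),
               as.numeric(compute_sdf(a, 200, p)) +
                 as.numeric(compute_sdf(b, 200, p)))
})

test_that("SDF conserves spike count and calibrates to rate in Hz", {
  p <- sdf_params()
  spikes <- sort(runif(60, 0, 800))
  s <- compute_sdf(spikes, 1200, p)   # long tail captured
  # integral over time (Hz * ms) = 1000 * spike count
  expect_equal(sum(as.numeric(s)) * p$resolution, 1000 * length(spikes),
               tolerance = 0.01)
  # a sustained regular train at r Hz plateaus near r
  train <- seq(0, 2000, by = 20)      # 50 Hz
  s2 <- as.numeric(compute_sdf(train, 2000, p))
  expect_equal(mean(s2[500:1800]), 50, tolerance = 0.02)
})

test_that("population mean SDF averages pointwise", {
  m <- cbind(rep(10, 5), rep(30, 5), rep(50, 5))
  attr(m, "time") <- 0:4
  expect_equal(as.numeric(population_mean_sdf(m, c(1, 2))), rep(20, 5))
  expect_equal(as.numeric(population_mean_sdf(m, 2)), rep(30, 5))
})

test_that("gaussian profile fit recovers parameters across the ring seam", {
  n <- 200
  x <- 0:(n - 1)
  d <- pmin(abs(x - 60), n - abs(x - 60))
  y <- 2 + 12 * exp(-d^2 / (2 * 9^2))
  f <- gaussian_profile_fit(y)
  expect_equal(f$amplitude, 12, tolerance = 1e-5)
  expect_equal(f$centre, 60, tolerance = 1e-4)
  expect_equal(f$width, 9, tolerance = 1e-5)
  expect_equal(f$baseline, 2, tolerance = 1e-5)

  # shifted across the seam: same shape, shifted centre
  d2 <- pmin(abs(x - 195), n - abs(x - 195))
  f2 <- gaussian_profile_fit(2 + 12 * exp(-d2^2 / (2 * 9^2)))
  expect_equal(f2$centre, 195, tolerance = 1e-4)
  expect_equal(f2$width, 9, tolerance = 1e-5)

  # noisy profile: parameters recovered within tolerance over repetitions
  set.seed(8)
  errs <- replicate(20, {
    f3 <- gaussian_profile_fit(y + rnorm(n, 0, 0.5))
    c(f3$amplitude - 12, f3$centre - 60, f3$width - 9)
  })
  expect_lt(max(abs(rowMeans(errs))), 0.5)
})

test_that("dip test separates unimodal from well-separated bimodal data", {
  set.seed(11)
  uni <- rnorm(400)
  bi <- c(rnorm(200, -4), rnorm(200, 4))
  d_uni <- dip_test(uni, n_boot = 200)
  d_bi <- dip_test(bi, n_boot = 200)
  expect_gt(d_uni$p_value, 0.05)
  expect_lt(d_bi$p_value, 0.05)
  expect_gt(d_bi$statistic, d_uni$statistic)
  # location/scale invariance of the statistic
  expect_equal(dip_test(uni * 3 + 7, n_boot = 0)$statistic,
               d_uni$statistic)
  # degenerate sample flagged
  expect_true(dip_test(rep(3, 50))$degenerate)
})

test_that("ISI analysis detects rate gradients and bimodal ISI mixtures", {
  # perfectly periodic train: zero trend, degenerate distribution
  per <- isi_analysis(list(seq(0, 1000, by = 25)), c(0, 1000))
  expect_equal(per$trend_slope, 0, tolerance = 1e-10)
  expect_true(per$dip$degenerate)

  # linearly increasing rate: ISIs shrink over time (negative trend)
  set.seed(12)
  trains <- lapply(1:20, function(i) {
    t <- 0; out <- c()
    while (t < 1000) {
      rate <- 5 + 45 * t / 1000                  # 5 -> 50 Hz
      t <- t + rexp(1, rate / 1000)
      out <- c(out, t)
    }
    out[out < 1000]
  })
  a <- isi_analysis(trains, c(0, 1000), n_boot = 100)
  expect_lt(a$trend_slope, 0)
  expect_gt(a$skewness, 0)
  expect_gt(a$dip$p_value, 0.05)

  # bimodal synthetic ISI mixture rejects unimodality
  bim <- cumsum(sample(c(rnorm(300, 10, 0.5), rnorm(300, 60, 2))))
  b <- isi_analysis(list(bim), c(0, max(bim)), n_boot = 100)
  expect_lt(b$dip$p_value, 0.05)
})

test_that("summary statistics match hand-computed values", {
  s <- summary_statistics(c(1, 2, 3), n_boot = 0)
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$cv, 0.5)
  z <- summary_statistics(rep(4, 10), n_boot = 0)
  expect_equal(z$sd, 0)
  expect_equal(z$cv, 0)
})

test_that("bootstrap CV interval approximately covers the truth", {
  set.seed(13)
  true_cv <- 0.2
  cover <- replicate(60, {
    x <- rnorm(80, 100, 20)
    s <- summary_statistics(x, n_boot = 300)
    s$cv_ci[1] <= true_cv && true_cv <= s$cv_ci[2]
  })
  expect_gt(mean(cover), 0.8)   # nominal 95%, small-n bootstrap bias allowed
})
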