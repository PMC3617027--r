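p64 <- reduced_params(n_grid = 64)
p128 <- reduced_params(n_grid = 128)

test_that("the activation function is non-negative and monotone", {
  I <- seq(-1, 2, by = 0.01)
  r <- activation(I, p64)
  expect_true(all(r >= 0))
  expect_true(all(diff(r) > 0))
  expect_lt(activation(-5, p64), 1e-6)
  # hand evaluation at one operating point
  x <- p64$a * 0.5 - p64$b
  expect_equal(activation(0.5, p64), x / (1 - exp(-p64$d * x)))
  # analytic derivative matches finite differences
  h <- 1e-6
  expect_equal(timingnet:::activation_deriv(0.42, p64),
               (activation(0.42 + h, p64) - activation(0.42 - h, p64)) /
                 (2 * h), tolerance = 1e-5)
})

test_that("the reduced rhs vanishes at flat fixed points and is
           translation-equivariant", {
  fl <- timingnet:::flat_steady_states(p64)
  expect_gte(length(fl), 1)
  for (s in fl)
    expect_lt(max(abs(reduced_rhs(rep(s, 64), p64))), 1e-10)

  # ring symmetry: rotating the state rotates the derivative
  set.seed(4)
  S <- 0.1 + 0.3 * exp(-((1:64) - 20)^2 / 30) + runif(64, 0, 0.01)
  k <- 17
  rot <- function(v) v[((seq_along(v) - 1 + k) %% length(v)) + 1]
  expect_equal(reduced_rhs(rot(S), p64), rot(reduced_rhs(S, p64)),
               tolerance = 1e-9)
})

test_that("ring convolution equals the brute-force double loop", {
  set.seed(5)
  v <- runif(64)
  brute <- vapply(1:64, function(i)
    sum(p64$kernel[((i - (1:64)) %% 64) + 1] * v), numeric(1))
  expect_equal(timingnet:::ring_convolve(p64, v), brute, tolerance = 1e-12)
})

test_that("analytic Jacobian agrees with central finite differences", {
  set.seed(6)
  S <- 0.15 + 0.2 * exp(-((1:64) - 32)^2 / 40)
  Ja <- reduced_jacobian(S, p64, method = "analytic")
  Jf <- reduced_jacobian(S, p64, method = "fd")
  expect_lt(max(abs(Ja - Jf)), 1e-5)
})

test_that("flat-state eigenvalues match the Fourier-mode formula", {
  p <- p128
  p$rho <- 1.8
  fl <- min(timingnet:::flat_steady_states(p))
  eig <- linearize_and_eigen(rep(fl, 128), p)
  modes <- flat_state_mode_eigenvalues(fl, p, k_max = 6)
  # every mode eigenvalue appears in the full spectrum (twice, +/- k)
  for (lam in modes$eigenvalue)
    expect_lt(min(abs(eig$values - lam)), 1e-8)
  expect_equal(eig$leading_value, max(modes$eigenvalue), tolerance = 1e-8)
})

test_that("the three regimes appear in order along the NMDA strength axis", {
  regimes <- vapply(c(1.0, 1.3, 1.6), function(r) {
    p <- p128; p$rho <- r
    classify_regime(p)$regime
  }, integer(1))
  expect_equal(regimes, c(1L, 2L, 3L))
})

test_that("steady states satisfy their defining equations and labels", {
  p <- p128; p$rho <- 1.6
  cls <- classify_regime(p)
  shapes <- vapply(cls$states, function(s) s$shape, character(1))
  stable <- vapply(cls$states, function(s) s$stable, logical(1))
  for (st in cls$states)
    expect_lt(st$residual, 1e-8)
  flat <- cls$states[[which(shapes == "flat")[1]]]
  bump <- cls$states[[which(shapes == "bump" & stable)[1]]]
  expect_gt(flat$max_eigenvalue, 0)             # unstable in regime 3
  expect_lt(abs(bump$max_eigenvalue), 1e-6)     # translation mode
  # the leading eigenvector of the unstable flat state is a spatial
  # patterning mode (zero-mean, bump-forming), not the uniform mode
  v <- flat$leading_vector
  expect_lt(abs(mean(v)), 0.2 * max(abs(v)))
  expect_gt(stats::sd(v), 0.2 * max(abs(v)))

  # rotating a bump fixed point yields another fixed point
  k <- 31
  Srot <- bump$S[((seq_len(128) - 1 + k) %% 128) + 1]
  expect_lt(max(abs(reduced_rhs(Srot, p))), 1e-8)
})

test_that("eigenvalues are stable under grid refinement", {
  pa <- reduced_params(n_grid = 128); pa$rho <- 1.7
  pb <- reduced_params(n_grid = 256); pb$rho <- 1.7
  la <- min(timingnet:::flat_steady_states(pa))
  lb <- min(timingnet:::flat_steady_states(pb))
  ea <- max(flat_state_mode_eigenvalues(la, pa, 6)$eigenvalue)
  eb <- max(flat_state_mode_eigenvalues(lb, pb, 6)$eigenvalue)
  expect_equal(ea, eb, tolerance = 0.01)
})

test_that("noisy integration leaves an exactly flat unstable state only
           via noise and forms bumps at seed-dependent locations", {
  p <- reduced_params(n_grid = 64); p$rho <- 1.7
  fl <- min(timingnet:::flat_steady_states(p))
  # zero noise from the exact flat state: stays flat
  out0 <- simulate_reduced(p, duration = 300, noise_sd = 0, dt = 0.5,
                           init = rep(fl, 64))
  expect_lt(diff(range(out0$S)), 1e-9)
  expect_true(is.na(out0$crossing_time))

  # small noise: bump emerges; location varies with the seed
  locs <- vapply(1:4, function(s) {
    simulate_reduced(p, duration = 2500, noise_sd = 1e-3, dt = 0.5,
                     seed = s, init = rep(fl, 64))$bump_location
  }, numeric(1))
  expect_gt(length(unique(locs)), 1)
})
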