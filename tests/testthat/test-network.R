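test_that("ring distance is symmetric, wraps, and rejects bad indices", {
  expect_equal(ring_distance(0, 500, 1000), 500)
  expect_equal(ring_distance(10, 990, 1000), 20)
  expect_equal(ring_distance(123, 123, 1000), 0)
  set.seed(1)
  i <- sample(0:999, 50); j <- sample(0:999, 50)
  expect_equal(ring_distance(i, j, 1000), ring_distance(j, i, 1000))
  expect_true(all(ring_distance(i, j, 1000) <= 500))
  expect_error(ring_distance(-1, 0, 10), "indices")
  expect_error(ring_distance(0, 10, 10), "indices")
})

test_that("pyramidal weights follow the Gaussian of ring distance", {
  con <- list(gaussian_amplitude = 1.3, gaussian_width = 60)
  expect_equal(pyramidal_weight(5, 5, con, 1000), 1.3)  # peak at distance 0
  set.seed(2)
  i <- sample(0:999, 30); j <- sample(0:999, 30)
  expect_equal(pyramidal_weight(i, j, con, 1000),
               pyramidal_weight(j, i, con, 1000))
  # at one width from the centre the weight drops by exp(-1/2)
  expect_equal(pyramidal_weight(0, 60, con, 1000) /
                 pyramidal_weight(0, 0, con, 1000),
               exp(-0.5))
  expect_error(pyramidal_weight(0, 1, list(gaussian_amplitude = 1,
                                           gaussian_width = 0), 10),
               "width")
})

test_that("magnesium block is sigmoidal in voltage and off without Mg", {
  expect_equal(mg_block_factor(-20, 0), 1)
  expect_equal(mg_block_factor(55.3, 0), 1)
  expect_gt(mg_block_factor(-50), mg_block_factor(-70))
  v <- seq(-90, 40, by = 1)
  expect_true(all(diff(mg_block_factor(v)) > 0))
  # evaluated from the printed constants at v = 0
  expect_equal(mg_block_factor(0, 1), 1 / (1 + 1 / 3.57))
  expect_error(mg_block_factor(0, -1), "magnesium")
})

test_that("build_network lays out structured and unstructured blocks", {
  cfg <- default_network_config()
  net <- build_network(cfg)
  expect_equal(cfg$populations$pyramidal$n, 1000L)
  expect_equal(cfg$populations$interneuron$n, 250L)
  expect_equal(dim(net$W), c(1000, 1000))
  expect_equal(diag(net$W), rep(cfg$connectivity$gaussian_amplitude, 1000))
  # weight matrix matches the pairwise definition
  idx <- c(0L, 3L, 499L, 998L)
  for (a in idx) for (b in idx)
    expect_equal(net$W[a + 1, b + 1],
                 pyramidal_weight(a, b, cfg$connectivity, 1000L))
  expect_warning(validate_network_config(
    suppressWarnings(scale_network_config(cfg, 250))), "4:1")
})

test_that("rho = 0 removes all NMDA influence from the simulation", {
  net <- tiny_network(40)
  net$config$connectivity$rho <- 0
  # doubling NMDA conductances must not change anything when rho = 0
  net2 <- net
  net2$config$synapses$onto_pyramidal$g_nmda <- 999
  net2$config$synapses$onto_interneuron$g_nmda <- 999
  r1 <- simulate_network(net, 200, seed = 5)
  r2 <- simulate_network(net2, 200, seed = 5)
  expect_equal(r1$time_ms, r2$time_ms)
  expect_equal(r1$neuron_id, r2$neuron_id)
})

test_that("synaptic gating follows the saturating kinetics", {
  # pure decay: one tau elapsed reduces single-exponential gating by ~e^-1
  tr <- timingnet:::cpp_gating_trace(0, 2, 0.0005, 2, 2, 0.5, 0L)
  i_tau <- which.min(abs(tr[, 1] - 2))
  expect_equal(tr[i_tau, 2], exp(-1), tolerance = 2e-3)

  # NMDA trace under one spike matches an independent fine-step integrator
  dt <- 0.01
  tr <- timingnet:::cpp_gating_trace(c(5), 60, dt, 100, 2, 0.5, 1L)
  s <- 0; x <- 0; ref <- numeric(nrow(tr))
  for (k in seq_len(nrow(tr) - 1)) {
    t <- (k - 1) * dt
    s <- s + dt * (-s / 100 + 0.5 * x * (1 - s))
    x <- x * (1 - dt / 2)
    if (abs(t - 5) < dt / 2) x <- x + 1
    ref[k + 1] <- s
  }
  expect_equal(tr[, 2], ref, tolerance = 1e-10)

  # sustained high-rate input saturates NMDA gating below 1
  spikes <- seq(0, 500, by = 2)          # 500 Hz
  tr <- timingnet:::cpp_gating_trace(spikes, 500, 0.02, 100, 2, 0.5, 1L)
  expect_lt(max(tr[, 2]), 1)
  expect_gt(max(tr[, 2]), 0.9)
  expect_true(all(tr[, 2] >= 0))
})

test_that("membrane dynamics match the LIF closed form under injection", {
  net <- silent_network(8)
  pop_e <- net$config$populations$pyramidal
  for (i_inj in c(600, 900)) {
    r <- simulate_network(net, 2000,
                          protocol = list(i_inject_pyramidal = i_inj),
                          seed = 3)
    counts <- tabulate(r$neuron_id[r$neuron_id < 8] + 1, 8)
    rate <- mean(counts) / 2            # spikes / 2 s -> Hz
    expect_equal(rate, lif_rate_hz(i_inj, pop_e), tolerance = 0.02)
  }
  # zero input: relaxation toward the leak reversal, no spikes
  r0 <- simulate_network(net, 500, seed = 3)
  expect_equal(nrow(r0), 0)
})

test_that("refractoriness forbids interspike intervals below tau_ref", {
  net <- silent_network(4)
  r <- simulate_network(net, 1000,
                        protocol = list(i_inject_pyramidal = 2000),
                        seed = 4)
  isis <- unlist(lapply(spike_trains(r, "pyramidal"), diff))
  expect_true(all(isis >= net$config$populations$pyramidal$refractory_period))
})

test_that("noise conductances follow the discrete OU process", {
  # deterministic limit: conductance converges to its mean and stays
  set.seed(1)
  g <- timingnet:::cpp_noise_trace(2000, 0.1, 12.1, 2.728, 0)
  expect_equal(g[1], 12.1)
  expect_equal(unname(g[2001]), 12.1)

  # stationary moments and lag-one autocorrelation of the OU update
  set.seed(42)
  dt <- 0.1; tau <- 2.728; D <- 2 * 3^2 / tau
  g <- timingnet:::cpp_noise_trace(4e5, dt, 12.1, tau, D)
  g <- g[-(1:1000)]                     # discard transient
  expect_equal(sd(g), sqrt(D * tau / 2), tolerance = 0.02)
  expect_equal(mean(g), 12.1, tolerance = 0.01)
  expect_equal(cor(g[-1], g[-length(g)]), exp(-dt / tau), tolerance = 0.005)
})

test_that("simulations are reproducible under a fixed seed", {
  net <- tiny_network(40)
  r1 <- simulate_network(net, 300, seed = 9)
  r2 <- simulate_network(net, 300, seed = 9)
  r3 <- simulate_network(net, 300, seed = 10)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_false(identical(r1$time_ms, r3$time_ms))
})

test_that("raster round-trips losslessly through CSV", {
  net <- tiny_network(40)
  r <- simulate_network(net, 200, seed = 2)
  path <- tempfile(fileext = ".csv")
  write_raster_csv(r, path)
  r2 <- read_raster_csv(path)
  expect_equal(as.data.frame(r), as.data.frame(r2))
  expect_equal(attr(r2, "duration"), attr(r, "duration"))
  expect_equal(attr(r2, "n_pyramidal"), attr(r, "n_pyramidal"))
  unlink(path)
})

test_that("network configuration validates its invariants and round-trips", {
  cfg <- default_network_config()
  bad <- cfg
  bad$populations$pyramidal$reset_potential <- 0   # above threshold
  expect_error(validate_network_config(bad))
  bad2 <- cfg
  bad2$synapses$onto_pyramidal$tau_nmda <- 1       # faster than AMPA
  expect_error(validate_network_config(bad2), "NMDA decay")
  path <- tempfile(fileext = ".json")
  write_network_config(cfg, path)
  cfg2 <- read_network_config(path)
  expect_equal(cfg2$synapses, cfg$synapses)
  expect_equal(cfg2$noise, cfg$noise, tolerance = 1e-12)
  unlink(path)
})

test_that("conductance currents vanish at their reversal potentials", {
  cfg <- default_network_config()
  cfg$connectivity$rho <- 1.7
  VE <- cfg$synapses$excitatory_reversal
  VI <- cfg$synapses$inhibitory_reversal
  # all drives zero, noise off: no current at all
  z <- total_current(-55, cfg)
  expect_equal(z$total, 0)
  # at the excitatory reversal AMPA and NMDA currents vanish
  at_ve <- total_current(VE, cfg, ampa_drive = 3, nmda_drive = 5,
                         gaba_drive = 2, g_e = 10, g_i = 4)
  expect_equal(at_ve$ampa, 0)
  expect_equal(at_ve$nmda, 0)
  expect_gt(at_ve$gaba, 0)              # outward at V > V_I
  # at the inhibitory reversal the GABA current vanishes
  at_vi <- total_current(VI, cfg, ampa_drive = 3, nmda_drive = 5,
                         gaba_drive = 2, g_e = 10, g_i = 4)
  expect_equal(at_vi$gaba, 0)
  expect_lt(at_vi$ampa, 0)              # depolarizing below V_E
  # negative sampled noise conductances are clamped at use
  clamped <- total_current(-55, cfg, g_e = -5, g_i = -2)
  expect_equal(clamped$background, 0)
  # NMDA current scales with rho
  cfg2 <- cfg; cfg2$connectivity$rho <- 3.4
  expect_equal(total_current(-55, cfg2, nmda_drive = 5)$nmda,
               2 * total_current(-55, cfg, nmda_drive = 5)$nmda)
})

test_that("halving the integration step leaves crossing times within
           trial-to-trial variability", {
  net <- small_network(250, dt = 0.1)
  prot <- timing_protocol(rho = 2.0, trial_duration = 1500,
                          bump_halfwidth = 35, n_trials = 6)
  est_at <- function(dt) {
    net$config$integration$dt <- dt
    vapply(1:6, function(k)
      run_interval_trial(net, 2.0, prot, seed = 700 + k)$estimate,
      numeric(1))
  }
  a <- est_at(0.1)
  b <- est_at(0.05)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  expect_gte(length(a), 4)
  expect_gte(length(b), 4)
  # no resolvable discretization shift beyond sampling error
  expect_gt(stats::t.test(a, b)$p.value, 0.01)
})
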