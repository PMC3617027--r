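# Shared fixtures: tiny networks for mechanics tests, a desk-scale network
# for dynamics, all built once per test run.

tiny_network <- function(n = 40, dt = 0.1, ...) {
  cfg <- suppressWarnings(
    scale_network_config(default_network_config(), n, dt = dt))
  suppressWarnings(build_network(cfg))
}

# a network with all synapses and noise silenced: isolated LIF neurons
silent_network <- function(n = 8, dt = 0.02) {
  cfg <- suppressWarnings(
    scale_network_config(default_network_config(), n, dt = dt))
  for (tgt in c("onto_pyramidal", "onto_interneuron"))
    for (g in c("g_ampa", "g_nmda", "g_gaba"))
      cfg$synapses[[tgt]][[g]] <- 0
  for (pop in c("pyramidal", "interneuron")) {
    cfg$noise[[pop]]$mean_exc_conductance <- 0
    cfg$noise[[pop]]$mean_inh_conductance <- 0
    cfg$noise[[pop]]$exc_diffusion <- 0
    cfg$noise[[pop]]$inh_diffusion <- 0
  }
  suppressWarnings(build_network(cfg))
}

# closed-form steady firing rate of a LIF neuron under constant current
lif_rate_hz <- function(i_pa, pop) {
  tau_m <- pop$membrane_capacitance / pop$leak_conductance
  num <- i_pa / pop$leak_conductance + pop$leak_reversal - pop$reset_potential
  den <- i_pa / pop$leak_conductance + pop$leak_reversal - pop$spike_threshold
  if (den <= 0) return(0)
  1000 / (pop$refractory_period + tau_m * log(num / den))
}
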