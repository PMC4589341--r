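# Shared fixtures: canonical parameter sets and a short-transient config for
# unit tests (the full 3000 ms default transient is reserved for the
# acceptance runs, where it matters).

p_chaotic <- function(d = -16) neuron_params(a = 0.2, b = 2, c = -56, d = d,
                                             I = -99)
p_rs <- function() neuron_params(a = 0.02, b = 0.2, c = -65, d = 8, I = 10)

cfg_fast <- function(t_transient = 1000) {
  integrator_config(t_transient = t_transient)
}

# A random state in the neighbourhood the trajectories actually visit
random_state <- function() {
  izh_state(t = runif(1, 0, 100), v = runif(1, -80, 20), u = runif(1, -110, 5))
}
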