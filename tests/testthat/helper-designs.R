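# Shared fixtures: the two worked-example pathway designs.

example_design_m0 <- function() design_pathway(k_syn = 1, Es = 160, m = 0)

example_design_m5 <- function()
  design_pathway(k_syn = 1, Es = 160, m = -5, tau_mem_bar = 500)

# a resting initial state (no randomness), for transient experiments
rest_state <- function(net) {
  spk <- net$neurons$type == "glif"
  list(U = numeric(nrow(net$neurons)),
       theta = ifelse(spk, net$neurons$theta0, 0),
       Gs = numeric(nrow(net$synapses)))
}
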