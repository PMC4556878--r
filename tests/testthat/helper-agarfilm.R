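# Shared fixtures: the reference-preset runs most tests read from.
# Computed once per test session; each takes well under a second.
ref_sim10 <- simulate_biofilm(horizon = 10)
ref_sim30 <- simulate_biofilm(settings = solver_settings(tspan = c(0, 30)))

# Random parameter set within +-50% of the reference preset, with a safe
# initial active fraction (f must leave room for water and inert biomass).
random_params_nearby <- function() {
  base <- unlist(biofilm_params())
  p <- as.list(base * runif(length(base), 0.5, 1.5))
  p$eps_a <- min(p$eps_a, 0.95)
  do.call(biofilm_params, p)
}

safe_init_for <- function(params) {
  biofilm_state(f = min(0.15, 0.75 * (1 - params$eps_a)))
}
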