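# Canonical parameter set shared across tests.
canon <- jr_params()

# Canonical sigmoid value at y = 0, computed from first principles (not via
# the package): 2 e0 / (1 + exp(r v0)) = 5 / (1 + e^3.36).
sigm0 <- 5 / (1 + exp(0.56 * 6))

# Deterministic single-column run at constant input p from a given initial
# state (length-6 vector).
det_run <- function(p_const, init = numeric(6), duration = 40,
                    transient = 10, h = 1e-3) {
  simulate_network(
    net = jr_network(N = 1, K = 0, p_const = p_const),
    ou = ou_config(D = 0, tau = 0.15),
    sim = sim_config(h = h, duration = duration, transient = transient,
                     seed = 1),
    init = jr_state(matrix(init, 6, 1), 0)
  )
}

# Upper-branch equilibrium state (largest y1 - y2) at input p.
upper_equilibrium <- function(p_const, params = canon) {
  eqs <- fixed_points(p_const, params)
  eqs[[length(eqs)]]$state
}
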