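# shared fixtures: parameter sets used across tests

mouse_params <- function(K_sigma = 2, K_tau = 52, mu1 = 0.1, beta2 = 0.2,
                         ...) {
  gr_params(kinetics = kinetic_params(mu1 = mu1, beta2 = beta2),
            gains = gain_params(K_sigma_c = K_sigma, K_sigma_m = K_sigma,
                                K_tau_c = K_tau, K_tau_m = K_tau),
            ...)
}

# cache simulations shared between test blocks within a file
sim_cache <- local({
  store <- new.env(parent = emptyenv())
  function(key, expr) {
    if (is.null(store[[key]])) store[[key]] <- force(expr)
    store[[key]]
  }
})

# independent central finite difference
fd_deriv <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)
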