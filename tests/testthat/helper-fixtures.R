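# Shared fixtures: expensive simulations are computed once per test run.

ow_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(ow_cache[[key]])) ow_cache[[key]] <- force(expr)
  ow_cache[[key]]
}

# the default-configuration simulation (the study condition)
default_sim <- function() memo("default_sim", simulate_wave(sim_params()))

# reduced-scale parameters for fitting tests: same physics, shorter horizon
fit_params <- function(...) {
  sim_params(domain_length = 600, n_grid = 601, t_end = 24,
             x_front0 = 250, save_every = 1, ...)
}

fit_truth <- function() memo("fit_truth", {
  sim <- simulate_wave(fit_params())
  displacement_observables(sim, n_tracers = 1, D = 0)$curves
})

# small parameter set for cheap dynamical tests
small_params <- function(...) {
  sim_params(domain_length = 400, n_grid = 401, t_end = 8,
             x_front0 = 200, save_every = 1, ...)
}

# a synthetic flow-field container for tracer tests (constant-in-time field)
flow_sim <- function(v_of_x, L = 500, n = 501, times = c(0, 50), D = 0) {
  x <- seq(0, L, length.out = n)
  v <- matrix(rep(v_of_x(x), each = length(times)), length(times), n,
              byrow = FALSE)
  structure(list(params = sim_params(D = D), x = x, dx = x[2] - x[1],
                 times = times,
                 v = matrix(v_of_x(x), length(times), n, byrow = TRUE)),
            class = "wave_sim")
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), .Machine$double.eps),
            tol)
}
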