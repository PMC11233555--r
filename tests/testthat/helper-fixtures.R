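# Shared fixtures, generated in code. Sessions are cached per test run so
# several test files can reuse one simulation.

local_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = local_cache)) {
    assign(key, force(expr), envir = local_cache)
  }
  get(key, envir = local_cache)
}

# a small single-context session with one tuned unit (no coupling)
small_session <- function() {
  cached("small_session", {
    cfg <- session_config(n_trials = 60L, seed = 11L)
    beh <- simulate_behavior(cfg)
    pc <- population_config(n_units = 2L, coupling_density = 0,
                            covariates = list(lin_vel = c(0, 200)))
    pop <- sample_ground_truth(pc, seed = 7L)
    counts <- simulate_spikes(pop, beh$covariates, seed = 5L)
    list(cfg = cfg, beh = beh, pop = pop, counts = counts)
  })
}

# a session with strong injected coupling between two of four units
coupled_session <- function() {
  cached("coupled_session", {
    cfg <- session_config(n_trials = 80L, seed = 21L)
    beh <- simulate_behavior(cfg)
    pc <- population_config(n_units = 4L, coupling_density = 0,
                            covariates = list(lin_vel = c(0, 200)),
                            baseline_range = c(8, 15))
    pop <- sample_ground_truth(pc, seed = 9L)
    cp_spec <- basis_spec("coupling", "coupling", domain = c(1, 6))
    beta <- kernel_coefs_test(cp_spec, c(1.2, 0.9, 0.5, 0.25, 0.1, 0.02))
    pop$coupling <- list(list(sender = 1L, receiver = 2L, spec = cp_spec,
                              beta = beta))
    counts <- simulate_spikes(pop, beh$covariates, seed = 13L)
    list(cfg = cfg, beh = beh, pop = pop, counts = counts)
  })
}

# least-squares basis coefficients representing given kernel values
kernel_coefs_test <- function(spec, values) {
  B <- build_basis(spec, seq(spec$domain[1], spec$domain[2]))
  qr.solve(B, values)
}

# independent de Boor recursion for a single B-spline basis function
deboor <- function(knots, i, k, x) {
  if (k == 1) {
    return(as.numeric(knots[i] <= x & x < knots[i + 1]))
  }
  d1 <- knots[i + k - 1] - knots[i]
  d2 <- knots[i + k] - knots[i + 1]
  t1 <- if (d1 > 0) (x - knots[i]) / d1 * deboor(knots, i, k - 1, x) else 0
  t2 <- if (d2 > 0) (knots[i + k] - x) / d2 * deboor(knots, i + 1, k - 1, x) else 0
  t1 + t2
}
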