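# shared fixtures, computed once per test run

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# the reference step study (noiseless + two noise levels), used by the
# acceptance tests and the Kalman recovery checks
step_study_fixture <- function() {
  fixture("step_study", run_step_study(noise_variances = c(0, 1e-8, 1e-6),
                                       seed = 101))
}

# a small sealed two-compartment column (no convection) for conservation
# and steady-state checks
toy_compartments <- function(n_interior = 3) {
  list(
    compartment_spec("lower", height = 1, D = 0.1, u = 0, H = 1,
                     n_interior = n_interior),
    compartment_spec("upper", height = 0.5, D = 0.02, u = 0, H = 2,
                     n_interior = n_interior)
  )
}
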