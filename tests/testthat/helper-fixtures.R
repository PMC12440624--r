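# Shared fixtures, all generated in code.

fix_consts <- function() default_constants()

# Small, fast controls for unit tests (full-size fixtures are exercised once
# in test-flow.R).
fix_controls <- function(seed = 42, cells_n = 3000, particles_n = 20000) {
  generate_control_fixtures(
    control_fixture_spec(cells_n = cells_n, particles_n = particles_n),
    seed = seed)
}

# Degenerate controls: every cell reads `a`, every particle `f`.
fix_controls_const <- function(a = 100, f = 10) {
  control_data(cells = rep(a, 5L), particles = rep(f, 5L))
}

fix_hyper_recovery <- function() hyper_params(2.96e-7, 2.92e-6, 51.2, 53.3)
fix_hyper_intermediate <- function() hyper_params(3.86e-7, 4.57e-7, 10, 2)

fix_times <- function() c(1, 2, 4, 8, 16, 24)

# Numeric integration of the homogeneous depletion ODE (independent oracle
# for the analytic solution).
ode_homogeneous_P <- function(t_h, r, K, consts, rtol = 1e-11) {
  ts <- t_h * 3600
  f <- function(t, y, p) {
    P <- consts$V * (consts$u0 - y)
    list(-(consts$C * consts$S * r / consts$V) * (1 - P / K) * y)
  }
  out <- deSolve::ode(y = consts$u0, times = c(0, ts), func = f, parms = NULL,
                      rtol = rtol, atol = consts$u0 * 1e-12)
  consts$V * (consts$u0 - out[-1, 2])
}

# Hand-built point-mass "abcsmc" object for prediction-method tests.
fix_pointmass_fit <- function(theta = c(3.86e-7, 4.57e-7, 10, 2), n = 25,
                              controls = fix_controls_const(),
                              consts = fix_consts(), times = fix_times(),
                              n_cells = 100) {
  th <- matrix(rep(theta, each = n), n, 4,
               dimnames = list(NULL, c("m_r", "s_r", "m_K", "s_K")))
  structure(list(theta = th, weights = rep(1 / n, n),
                 distances = rep(0, n), threshold_history = c(Inf, 1),
                 target_threshold = 1, acceptance_rates = c(1, 1),
                 n_simulations = n, prior = default_prior(),
                 controls = controls, consts = consts,
                 obs = NULL, obs_times = times, n_cells = n_cells,
                 m_eval = 50, distance = "ad", seed = 1),
            class = "abcsmc")
}
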