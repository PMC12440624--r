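test_that("analytic homogeneous solution matches numeric integration of the depletion ODE", {
  consts <- fix_consts()
  # fixture parameter set
  t <- fix_times()
  a <- homogeneous_solution(t, r = 3.86e-7, K = 10, consts)
  b <- ode_homogeneous_P(t, r = 3.86e-7, K = 10, consts)
  expect_lt(max(abs(a - b) / b), 1e-6)
  # 20 random parameter sets spanning slow/fast rates and small/large K
  set.seed(11)
  for (i in 1:20) {
    r <- 10^runif(1, -8.5, -5.5)
    K <- 10^runif(1, 0.3, 2.5)
    tt <- sort(runif(3, 0.5, 24))
    a <- homogeneous_solution(tt, r, K, consts)
    b <- ode_homogeneous_P(tt, r, K, consts)
    expect_lt(max(abs(a - b) / pmax(b, 1e-12)), 1e-6)
  }
})

test_that("homogeneous solution honours limits, bounds and the supply branch", {
  consts <- fix_consts()
  Vu0 <- consts$V * consts$u0
  expect_equal(homogeneous_solution(0, 1e-6, 10, consts), 0)
  expect_equal(homogeneous_solution(c(1, 10), 0, 10, consts), c(0, 0))
  # long-time limit is K when K < V*u0
  expect_equal(homogeneous_solution(1e6, 1e-6, 10, consts), 10, tolerance = 1e-9)
  # bounded by min(K, V*u0) and monotone nondecreasing
  P <- homogeneous_solution(seq(0, 24, by = 0.5), 5e-6, 800, consts)
  expect_true(all(P <= min(800, Vu0) + 1e-9))
  expect_true(all(diff(P) >= -1e-9))
  # continuity across the K = V*u0 branch switch
  near <- homogeneous_solution(5, 1e-7, Vu0 * (1 + 1e-10), consts)
  at <- homogeneous_solution(5, 1e-7, Vu0, consts)
  off <- homogeneous_solution(5, 1e-7, Vu0 * (1 + 1e-7), consts)
  expect_equal(near, at, tolerance = 1e-8)
  expect_equal(off, at, tolerance = 1e-5)
  # parameter validation
  expect_error(homogeneous_solution(-1, 1e-6, 10, consts), "times")
  expect_error(homogeneous_solution(1, 1e-6, -10, consts), "capacity")
})

test_that("lognormal mean/SD conversion is exact and consistent with draws", {
  # degenerate limit
  p <- lognormal_natural_params(1, 1e-12)
  expect_equal(unname(p), c(0, 0), tolerance = 1e-10)
  # scale equivariance: (c*m, c*s) shifts meanlog by log(c), keeps sdlog
  p1 <- lognormal_natural_params(51.2, 53.3)
  p2 <- lognormal_natural_params(7 * 51.2, 7 * 53.3)
  expect_equal(p2[["meanlog"]] - p1[["meanlog"]], log(7), tolerance = 1e-12)
  expect_equal(p2[["sdlog"]], p1[["sdlog"]], tolerance = 1e-12)
  # Monte Carlo: draws from the converted parameters have the target moments
  set.seed(7)
  x <- rlnorm(1e6, p1[["meanlog"]], p1[["sdlog"]])
  expect_lt(abs(mean(x) - 51.2) / 51.2, 0.01)
  expect_lt(abs(sd(x) - 53.3) / 53.3, 0.02)
  expect_error(lognormal_natural_params(-1, 1), "> 0")
  expect_error(lognormal_natural_params(1, -1), ">= 0")
})

test_that("trait sampling is reproducible, degenerate at s = 0, and lognormal", {
  hy <- fix_hyper_recovery()
  a <- sample_cell_traits(hy, 500, seed = 9)
  b <- sample_cell_traits(hy, 500, seed = 9)
  expect_identical(a, b)
  # CLT bound on the empirical mean of K
  tr <- sample_cell_traits(hy, 20000, seed = 10)
  expect_lt(abs(mean(tr$K) - hy$m_K), 3 * hy$s_K / sqrt(20000))
  # degenerate population
  d <- sample_cell_traits(hyper_params(1e-7, 0, 10, 0), 50, seed = 1)
  expect_true(all(abs(d$r - 1e-7) < 1e-18))
  expect_true(all(abs(d$K - 10) < 1e-9))
  # log-traits are Gaussian with the converted parameters
  big <- sample_cell_traits(hy, 1e5, seed = 12)
  pr <- lognormal_natural_params(hy$m_r, hy$s_r)
  pK <- lognormal_natural_params(hy$m_K, hy$s_K)
  expect_gt(ks.test(log(big$r), "pnorm", pr[1], pr[2])$p.value, 0.01)
  expect_gt(ks.test(log(big$K), "pnorm", pK[1], pK[2])$p.value, 0.01)
})

test_that("media trajectory starts at u0, decreases, and matches the homogeneous limit", {
  consts <- fix_consts()
  hy <- fix_hyper_intermediate()
  med <- media_concentration_approx(24, hy, consts, seed = 3)
  expect_equal(med$ubar[1], consts$u0)
  expect_true(all(diff(med$ubar) <= 1e-9 * consts$u0))
  expect_true(all(med$ubar >= 0 & med$ubar <= consts$u0))
  expect_equal(med$cumint[1], 0)
  expect_true(all(diff(med$cumint) >= 0))
  # depletion is bounded by the capacity distribution (up to sampling noise)
  expect_true(min(med$ubar) >=
                consts$u0 - (hy$m_K + 5 * hy$s_K) / consts$V - 1e-6 * consts$u0)
  # degenerate population: ubar equals the homogeneous u(t) pointwise
  hy0 <- hyper_params(3.86e-7, 0, 10, 0)
  med0 <- media_concentration_approx(24, hy0, consts, m_eval = 3, seed = 4)
  u_exact <- consts$u0 - homogeneous_solution(med0$times_h, 3.86e-7, 10, consts) / consts$V
  expect_equal(med0$ubar, u_exact, tolerance = 1e-10)
})

test_that("approximate heterogeneous solution reduces to the homogeneous model", {
  consts <- fix_consts()
  hy0 <- hyper_params(3.86e-7, 0, 10, 0)
  traits <- sample_cell_traits(hy0, 20, seed = 5)
  media <- media_concentration_approx(24, hy0, consts, m_eval = 3, seed = 6)
  P <- heterogeneous_solution_approx(fix_times(), traits, media, consts)
  hom <- homogeneous_solution(fix_times(), 3.86e-7, 10, consts)
  for (j in 1:20) expect_equal(unname(P[j, ]), hom, tolerance = 1e-6)
})

test_that("per-cell trajectories are positive, capped by K_j and start at zero", {
  consts <- fix_consts()
  hy <- fix_hyper_recovery()
  traits <- sample_cell_traits(hy, 200, seed = 8)
  media <- media_concentration_approx(24, hy, consts, seed = 8)
  P <- heterogeneous_solution_approx(c(0, fix_times()), traits, media, consts)
  expect_true(all(P >= 0))
  expect_equal(unname(P[, 1]), rep(0, 200))
  expect_true(all(P < traits$K))
  expect_true(all(P <= consts$V * consts$u0))
  expect_true(all(diff(t(unclass(P))) >= -1e-12))
  expect_error(heterogeneous_solution_approx(25, traits, media, consts),
               "outside the media trajectory grid")
})

test_that("full coupled model conserves particles and reduces to the homogeneous solution", {
  consts <- fix_consts()
  # identical cells
  traits <- list(r = rep(3.86e-7, 40), K = rep(10, 40))
  full <- heterogeneous_solution_full(fix_times(), traits, consts)
  hom <- homogeneous_solution(fix_times(), 3.86e-7, 10, consts)
  expect_equal(unname(full[1, ]), hom, tolerance = 1e-6)
  # conservation: N V u(t) + sum_j P_j(t) = N V u0
  hy <- fix_hyper_intermediate()
  tr <- sample_cell_traits(hy, 100, seed = 21)
  sol <- heterogeneous_solution_full(fix_times(), tr, consts)
  total <- 100 * consts$V * attr(sol, "u") + colSums(sol)
  expect_equal(total, rep(100 * consts$V * consts$u0, 6), tolerance = 1e-6)
  # faster cells deplete the media faster at every time
  tr2 <- list(r = 2 * tr$r, K = tr$K)
  sol2 <- heterogeneous_solution_full(fix_times(), tr2, consts)
  expect_true(all(attr(sol2, "u") <= attr(sol, "u") + 1e-6 * consts$u0))
})

test_that("approximation error vs the full model vanishes as the particle supply grows", {
  consts0 <- fix_consts()
  hy <- fix_hyper_intermediate()
  tr <- sample_cell_traits(hy, 100, seed = 31)
  err_at_u0 <- function(u0_mult) {
    consts <- experiment_constants(consts0$C, consts0$S, consts0$V,
                                   consts0$u0 * u0_mult)
    full <- heterogeneous_solution_full(24, tr, consts)
    # evaluate the decoupled form with the same traits
    media <- media_concentration_approx(24, hy, consts, m_eval = 100, seed = 32)
    appr <- heterogeneous_solution_approx(24, tr, media, consts)
    max(abs(appr - full) / pmax(full, 1e-9))
  }
  errs <- vapply(c(0.2, 1, 5), err_at_u0, numeric(1))
  expect_true(all(diff(errs) < 0))
})
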