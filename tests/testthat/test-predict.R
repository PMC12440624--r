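test_that("particles-per-cell bands start at zero, are ordered and nondecreasing in the median", {
  fit <- fix_pointmass_fit()
  pb <- predict(fit, "pband", n_draws = 10, n_cells = 100, seed = 23)
  expect_equal(pb[pb$time_h == 0, -1], data.frame(lower95 = 0, lower50 = 0,
               median = 0, upper50 = 0, upper95 = 0), ignore_attr = TRUE)
  expect_true(all(pb$lower95 <= pb$lower50 & pb$lower50 <= pb$median &
                  pb$median <= pb$upper50 & pb$upper50 <= pb$upper95))
  expect_true(all(diff(pb$median) >= -1e-9))
})

test_that("histogram bands conserve counts and collapse for a point-mass posterior", {
  ctrl <- fix_controls_const(a = 100, f = 10)
  fit <- fix_pointmass_fit(controls = ctrl, n_cells = 80, times = c(4, 24))
  obs <- simulate_dataset(c(3.86e-7, 4.57e-7, 10, 2), fix_consts(), c(4, 24),
                          ctrl, n_cells = 80, seed = 24)
  fit$obs <- obs
  fit$obs_times <- obs$times
  hb <- predict(fit, "histograms", bins = 12, n_draws = 8, seed = 25)
  expect_length(hb, 2)
  for (h in hb) {
    # counts conserved: every dataset holds n_cells values, so the observed
    # bars sum exactly and the pointwise median bars sum approximately
    expect_equal(sum(h$observed), 80)
    expect_equal(sum(h$median), 80, tolerance = 0.1)
    expect_true(all(h$lower <= h$median & h$median <= h$upper))
  }
})

test_that("inferred trait distributions integrate to one and collapse for point masses", {
  fit <- fix_pointmass_fit(theta = c(3.86e-7, 4.57e-7, 10, 2))
  bd <- predict(fit, "distribution", trait = "K",
                grid = seq(0.01, 60, length.out = 3000))
  # point-mass posterior: band width is zero
  expect_equal(bd$lower, bd$upper, tolerance = 1e-12)
  # each pdf draw integrates to ~1 on a wide grid
  dx <- diff(bd$grid[1:2])
  expect_equal(sum(bd$median) * dx, 1, tolerance = 0.01)
  # mixed posterior: band has positive width and brackets the median
  fit$theta[1:10, "s_K"] <- 6
  bd2 <- inferred_distribution(fit, "K", grid = seq(0.1, 40, length.out = 200))
  expect_true(all(bd2$lower <= bd2$median + 1e-12 &
                  bd2$median <= bd2$upper + 1e-12))
  expect_gt(max(bd2$upper - bd2$lower), 0)
})

test_that("fraction near capacity is a step at the homogeneous crossing time", {
  consts <- fix_consts()
  r <- 3.86e-7; K <- 10
  traits <- list(r = rep(r, 50), K = rep(K, 50))
  # closed-form crossing time of P(t) = K/2 from the analytic solution
  t_half <- uniroot(function(t) homogeneous_solution(t, r, K, consts) - K / 2,
                    c(1e-3, 24))$root
  media <- media_concentration_approx(24, hyper_params(r, 0, K, 0), consts,
                                      m_eval = 3, seed = 26)
  tt <- c(t_half * 0.9, t_half * 1.1)
  P <- heterogeneous_solution_approx(tt, traits, media, consts)
  fr <- fraction_near_capacity(P, traits, beta = 0.5)
  expect_equal(unname(fr), c(0, 100))
  # t = 0 gives 0% for any beta; monotone in t, antitone in beta
  P0 <- heterogeneous_solution_approx(c(0, 4, 24), traits, media, consts)
  expect_equal(unname(fraction_near_capacity(P0, traits, 0.2)[1]), 0)
  hy <- fix_hyper_intermediate()
  tr2 <- sample_cell_traits(hy, 400, seed = 27)
  P2 <- heterogeneous_solution_approx(c(2, 8, 24), tr2, media_concentration_approx(
    24, hy, consts, seed = 27), consts)
  f_half <- fraction_near_capacity(P2, tr2, 0.5)
  f_90 <- fraction_near_capacity(P2, tr2, 0.9)
  expect_true(all(diff(f_half) >= 0))
  expect_true(all(f_90 <= f_half))
  expect_error(fraction_near_capacity(P2, tr2, 1.5), "beta")
})

test_that("fraction-band prediction collapses for a point-mass posterior with fixed seed", {
  fit <- fix_pointmass_fit()
  fb <- predict(fit, "fraction", beta = 0.5, times = c(0, 8, 24),
                n_draws = 6, n_cells = 150, seed = 28)
  expect_equal(fb$lower[1], 0)
  expect_true(all(fb$lower <= fb$median & fb$median <= fb$upper))
})
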