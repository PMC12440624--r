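test_that("fluorescence generation is exact for degenerate controls", {
  ctrl <- fix_controls_const(a = 100, f = 10)
  # empty particle sum: autofluorescence draw alone
  expect_equal(simulate_fluorescence(0, ctrl, seed = 1), 100)
  # integer load: a + p * f
  expect_equal(simulate_fluorescence(2, ctrl, seed = 1), 120)
  # fractional load: floor draws plus the scaled extra draw
  expect_equal(simulate_fluorescence(1.5, ctrl, seed = 1), 115)
  expect_equal(simulate_fluorescence(c(0, 2, 1.5, 0.25), ctrl, seed = 1),
               c(100, 120, 115, 102.5))
  expect_error(simulate_fluorescence(-0.1, ctrl), ">= 0")
})

test_that("fluorescence draws converge on the median transform as skew vanishes", {
  # tight controls: the stochastic reading concentrates on the median model
  spec <- control_fixture_spec(cells_n = 5000, particles_n = 5000,
                               cells_sdlog = 0.01, particles_sdlog = 0.01)
  ctrl <- generate_control_fixtures(spec, seed = 2)
  p <- 7.3
  reps <- simulate_fluorescence(rep(p, 4000), ctrl, seed = 3)
  expect_equal(median(reps), median_fluorescence(p, ctrl), tolerance = 0.02)
})

test_that("median fluorescence model is deterministic arithmetic on control medians", {
  ctrl <- fix_controls_const(a = 100, f = 10)
  expect_equal(median_fluorescence(0, ctrl), 100)
  expect_equal(median_fluorescence(1, ctrl), 110)
  expect_equal(median_fluorescence(20, ctrl), 300)
})

test_that("control fixtures have the configured sizes and are right-skewed", {
  spec <- control_fixture_spec()
  expect_identical(spec$cells_n, 11605L)
  expect_identical(spec$particles_n, 500000L)
  ctrl <- generate_control_fixtures(control_fixture_spec(cells_n = 20000,
                                                         particles_n = 20000),
                                    seed = 5)
  skew <- function(x) mean((x - mean(x))^3) / sd(x)^3
  expect_gt(skew(ctrl$cells), 0)
  expect_gt(skew(ctrl$particles), 0)
  expect_true(all(ctrl$cells > 0) && all(ctrl$particles > 0))
  # degenerate spec gives constant controls
  cst <- generate_control_fixtures(
    control_fixture_spec(cells_n = 10, particles_n = 10, cells_sdlog = 0,
                         particles_sdlog = 0), seed = 6)
  expect_equal(var(cst$cells), 0)
})

test_that("simulated datasets have full size, no missing values, and are seed-reproducible", {
  ctrl <- fix_controls(cells_n = 1000, particles_n = 5000)
  hy <- fix_hyper_intermediate()
  d1 <- simulate_dataset(hy, fix_consts(), fix_times(), ctrl, n_cells = 300, seed = 7)
  d2 <- simulate_dataset(hy, fix_consts(), fix_times(), ctrl, n_cells = 300, seed = 7)
  expect_identical(d1$samples, d2$samples)
  expect_equal(vapply(d1$samples, length, 1L), rep(300L, 6))
  expect_false(anyNA(unlist(d1$samples)))
})

test_that("dataset simulation with degenerate controls equals the noise-free transform", {
  ctrl <- fix_controls_const(a = 50, f = 4)
  hy <- fix_hyper_intermediate()
  d <- simulate_dataset(hy, fix_consts(), fix_times(), ctrl, n_cells = 200, seed = 8)
  P <- attr(d, "P")
  for (i in seq_along(d$times)) {
    expect_equal(d$samples[[i]], unname(50 + 4 * P[, i]), tolerance = 1e-12)
  }
})

test_that("a vanishing association rate reproduces the cell-only control distribution", {
  ctrl <- fix_controls(cells_n = 4000, particles_n = 10000)
  hy <- hyper_params(1e-15, 1e-16, 10, 2)
  d <- simulate_dataset(hy, fix_consts(), c(8, 24), ctrl, n_cells = 2000, seed = 9)
  # resampling null: AD distance between two resamples of the cell-only control
  set.seed(10)
  null_d <- replicate(200, {
    ad2_stat(sample(ctrl$cells, 2000, replace = TRUE),
             sample(ctrl$cells, 2000, replace = TRUE))
  })
  thr <- quantile(null_d, 0.95)
  for (i in 1:2) {
    expect_lt(ad2_stat(d$samples[[i]], sample(ctrl$cells, 2000, replace = TRUE)),
              thr * 1.5)
  }
})

test_that("per-time keyed seeding makes subsets of the candidate grid reproducible", {
  ctrl <- fix_controls(cells_n = 500, particles_n = 2000)
  hy <- fix_hyper_intermediate()
  cand <- default_candidate_times()
  full <- simulate_dataset(hy, fix_consts(), cand, ctrl, n_cells = 100,
                           seed = 11, t_grid_max = max(cand))
  sub_times <- c(1, 8, 20)
  sub <- simulate_dataset(hy, fix_consts(), sub_times, ctrl, n_cells = 100,
                          seed = 11, t_grid_max = max(cand))
  for (k in seq_along(sub_times)) {
    expect_identical(sub$samples[[k]],
                     full$samples[[match(sub_times[k], full$times)]])
  }
})
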