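test_that("design enumeration is exhaustive, sorted and duplicate-free", {
  d <- enumerate_designs(default_candidate_times(), 6)
  expect_equal(nrow(d), choose(14, 6))
  expect_equal(nrow(enumerate_designs(c(1, 2, 4, 8, 16, 24), 6)), 1)
  expect_true(all(apply(d, 1, function(x) all(diff(x) > 0))))
  expect_equal(anyDuplicated(d), 0)
  expect_error(enumerate_designs(c(1, 2), 6), "exceeds")
  # reference fixture designs
  expect_equal(length(default_candidate_times()), 14)
  expect_true(all(c(1, 2, 4, 8, 16, 24) %in% default_candidate_times()))
})

test_that("scenario hyperparameter draws are positive, seeded and collapse as cv -> 0", {
  spec <- design_scenarios()$low
  expect_equal(spec$hyper_means, c(3.86e-8, 4.57e-8, 10, 2))
  ctrl <- fix_controls(cells_n = 200, particles_n = 500)
  d1 <- sample_scenario_datasets(spec, 3, fix_consts(), ctrl,
                                 candidates = c(2, 24), n_cells = 40, seed = 33)
  d2 <- sample_scenario_datasets(spec, 3, fix_consts(), ctrl,
                                 candidates = c(2, 24), n_cells = 40, seed = 33)
  expect_identical(attr(d1, "thetas"), attr(d2, "thetas"))
  expect_true(all(attr(d1, "thetas") > 0))
  tiny <- scenario_spec("tiny-cv", spec$hyper_means, cv = 1e-9)
  d3 <- sample_scenario_datasets(tiny, 4, fix_consts(), ctrl,
                                 candidates = c(2, 24), n_cells = 20, seed = 34)
  th <- attr(d3, "thetas")
  expect_lt(max(apply(th, 2, sd) / colMeans(th)), 1e-8)
})

test_that("inverse-determinant utility matches hand-computed covariances", {
  # eight points whose empirical covariance is the 4x4 identity
  base <- rbind(diag(4), -diag(4)) * sqrt(7 / 2)
  expect_equal(design_utility(base), 1, tolerance = 1e-12)
  # diagonal covariance (1, 2, 3, 4) has determinant 24
  scaled <- base %*% diag(sqrt(c(1, 2, 3, 4)))
  expect_equal(design_utility(scaled), 1 / 24, tolerance = 1e-12)
  # scaling all thetas by c multiplies the utility by c^-8
  expect_equal(design_utility(3 * base), 3^-8, tolerance = 1e-12)
  # mean over multiple sets; degenerate sets hit the cap
  expect_equal(design_utility(list(base, scaled)), (1 + 1 / 24) / 2,
               tolerance = 1e-12)
  degen <- matrix(1, 10, 4)
  expect_equal(design_utility(degen, cap = 1e6), 1e6)
})

test_that("reference-table rejection uses only the design's time points", {
  ctrl <- fix_controls(cells_n = 200, particles_n = 500)
  prior <- default_prior()
  cand <- c(1, 4, 12, 24)
  tab <- build_reference_table(prior, n_pre = 80, fix_consts(), ctrl,
                               candidates = cand, n_cells = 40, seed = 35)
  expect_equal(nrow(tab$thetas), 80)
  expect_length(tab$datasets, 80)
  obs <- simulate_dataset(fix_hyper_intermediate(), fix_consts(), cand, ctrl,
                          n_cells = 40, seed = 36, t_grid_max = max(cand))
  acc <- abc_rejection_posterior(tab, obs, design = c(1, 12), n_accept = 20)
  # perturbing an excluded time point changes nothing
  obs2 <- obs
  obs2$samples[[which(obs2$times == 24)]] <-
    obs2$samples[[which(obs2$times == 24)]] + 500
  acc2 <- abc_rejection_posterior(tab, obs2, design = c(1, 12), n_accept = 20)
  expect_identical(acc, acc2)
  # n_accept = table size accepts the whole prior sample
  all_acc <- abc_rejection_posterior(tab, obs, design = cand, n_accept = 80)
  expect_equal(sort(all_acc[, 1]), sort(tab$thetas[, 1]))
  expect_error(abc_rejection_posterior(tab, obs, cand, n_accept = 81), "exceeds")
  # memory guard trips with an instructive message
  expect_error(build_reference_table(prior, 1e9, fix_consts(), ctrl,
                                     candidates = cand, n_cells = 1000),
               "reduce n_pre")
})

test_that("rejection ABC concentrates around the generating parameters", {
  ctrl <- fix_controls(cells_n = 400, particles_n = 1500)
  prior <- default_prior()
  cand <- c(1, 2, 4, 8, 16, 24)
  tab <- build_reference_table(prior, n_pre = 2000, fix_consts(), ctrl,
                               candidates = cand, n_cells = 150, seed = 37)
  truth <- c(3.86e-7, 4.57e-7, 10, 2)
  obs <- simulate_dataset(truth, fix_consts(), cand, ctrl, n_cells = 150,
                          seed = 38, t_grid_max = max(cand))
  acc <- abc_rejection_posterior(tab, obs, design = cand, n_accept = 200)
  # accepted-set mean is closer to truth (log-scale Euclidean) than the prior mean
  dist_log <- function(th) sqrt(sum((log(th) - log(truth))^2))
  expect_lt(dist_log(colMeans(acc)), dist_log(colMeans(tab$thetas)))
})

test_that("design ranking normalises the optimum to one and is order-invariant", {
  designs <- enumerate_designs(c(1, 2, 4, 8), 2)
  set.seed(39)
  u <- runif(nrow(designs))
  rk <- rank_designs(designs, u)
  expect_equal(max(rk$normalized_utility), 1)
  expect_equal(rk$rank[which.max(u)], 1)
  expect_equal(sort(rk$rank), seq_len(nrow(designs)))
  # permuting the design order permutes but does not change ranks
  perm <- sample(nrow(designs))
  rk2 <- rank_designs(designs[perm, ], u[perm])
  expect_equal(rk2$rank[order(perm)], rk$rank)
  # ties broken lexicographically
  rk3 <- rank_designs(designs, rep(1, nrow(designs)))
  expect_equal(rk3$rank, seq_len(nrow(designs)))
  # overall optimum: single scenario reduces to that scenario's best design
  ov <- overall_optimal(list(rk))
  expect_equal(ov$design, unname(unlist(rk[rk$rank == 1, 1:2])))
  ov2 <- overall_optimal(list(rk, rk))
  expect_equal(ov2$average_ranks, rk$rank)
})
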