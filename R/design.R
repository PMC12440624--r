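# Bayesian optimal design of measurement time points.
#
# Every design is a set of k (default 6) distinct times from a candidate
# grid. Designs are scored with a pre-simulation strategy: one reference
# table of prior draws, each simulated once over the FULL candidate grid, is
# shared by every design and every scenario dataset; a design's rejection-ABC
# posterior is obtained by summing the per-time-point distances over the
# design's time points only and keeping the n_accept closest prior draws.
# The utility of a design is the mean (over scenario datasets) of the inverse
# determinant of the 4x4 empirical covariance of the accepted
# hyperparameters: it rewards designs whose data make the posterior precise.

#' Default candidate measurement times
#'
#' @return `c(0.5, 1, 2, 4, ..., 24)` hours: half an hour, one hour, then
#'   every two hours to 24 h (14 candidates).
#' @export
default_candidate_times <- function() c(0.5, 1, seq(2, 24, by = 2))

#' Enumerate all measurement-time designs
#'
#' All size-`k` subsets of the candidate grid, in lexicographic order with
#' times sorted within each design. With the default 14 candidates and
#' `k = 6` this yields `choose(14, 6) = 3003` designs.
#'
#' @param candidates numeric vector of candidate times, hours.
#' @param k design size (default 6).
#' @return Numeric matrix with one design per row and `k` columns.
#' @export
enumerate_designs <- function(candidates = default_candidate_times(), k = 6) {
  candidates <- sort(as.numeric(candidates))
  if (anyDuplicated(candidates)) stop_param("candidate times must be distinct")
  if (k > length(candidates)) stop_param("k exceeds the number of candidates")
  t(utils::combn(candidates, k))
}

#' Scenario specification for design evaluation
#'
#' A particle-cell scenario is summarised by the means of the four
#' heterogeneity hyperparameters; scenario datasets are generated at
#' hyperparameters drawn from independent Gaussians truncated to positive
#' values, with SD = `cv * mean`.
#'
#' @param name scenario label.
#' @param hyper_means length-4 vector of positive means for
#'   `(m_r, s_r, m_K, s_K)`.
#' @param cv coefficient of variation (default 0.1).
#' @return list of class `"scenario_spec"`.
#' @export
scenario_spec <- function(name, hyper_means, cv = 0.1) {
  hyper_means <- as.numeric(hyper_means)
  if (length(hyper_means) != 4L || any(hyper_means <= 0)) {
    stop_param("hyper_means must be 4 positive values")
  }
  if (!is.finite(cv) || cv <= 0) stop_param("cv must be > 0")
  structure(list(name = name, hyper_means = hyper_means, cv = cv),
            class = "scenario_spec")
}

#' Reference particle-cell scenarios
#'
#' Three scenarios differing only in the association-rate scale, with the
#' carrying-capacity law fixed at mean 10 and SD 2 particles/cell:
#' low rate (`m_r = 3.86e-8`, `s_r = 4.57e-8` m/s; trajectories stay far from
#' capacity over 24 h), intermediate rate (ten-fold faster; both the rise and
#' the saturation are observed) and high rate (thousand-fold faster;
#' trajectories sit at capacity from the first measurement).
#'
#' @return Named list of three [scenario_spec()] objects
#'   (`low`, `intermediate`, `high`).
#' @export
design_scenarios <- function() {
  list(
    low = scenario_spec("low", c(3.86e-8, 4.57e-8, 10, 2)),
    intermediate = scenario_spec("intermediate", c(3.86e-7, 4.57e-7, 10, 2)),
    high = scenario_spec("high", c(3.86e-5, 4.57e-5, 10, 2))
  )
}

rtrunc_norm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Pre-simulate scenario datasets
#'
#' Draws `j_reps` hyperparameter vectors from the scenario's truncated
#' Gaussians and simulates one synthetic fluorescence dataset per draw over
#' the full candidate grid (so any design can later subset its time points).
#'
#' @param spec a [scenario_spec()].
#' @param j_reps number of datasets (default 20).
#' @param consts [experiment_constants()].
#' @param controls [control_data()].
#' @param candidates candidate time grid, hours.
#' @param n_cells cells per time point.
#' @param seed optional integer seed.
#' @return list of [timecourse()] objects with attribute `thetas`
#'   (`j_reps x 4` matrix of generating hyperparameters).
#' @export
sample_scenario_datasets <- function(spec, j_reps = 20, consts, controls,
                                     candidates = default_candidate_times(),
                                     n_cells = 1000, seed = NULL) {
  with_seed(seed, {
    thetas <- vapply(seq_len(4L), function(j) {
      rtrunc_norm_pos(j_reps, spec$hyper_means[j], spec$cv * spec$hyper_means[j])
    }, numeric(j_reps))
    if (j_reps == 1L) thetas <- matrix(thetas, nrow = 1L)
    colnames(thetas) <- c("m_r", "s_r", "m_K", "s_K")
    out <- lapply(seq_len(j_reps), function(j) {
      simulate_dataset(thetas[j, ], consts, candidates, controls,
                       n_cells = n_cells, t_grid_max = max(candidates))
    })
    attr(out, "thetas") <- thetas
    out
  })
}

#' Build a pre-simulated reference table
#'
#' Draws `n_pre` hyperparameter vectors from the prior and simulates each
#' once over the full candidate grid. The table is shared by all designs and
#' all scenario datasets; designs subset its time points rather than
#' re-simulating.
#'
#' @param prior a [prior_box()].
#' @param n_pre number of prior draws.
#' @param consts [experiment_constants()].
#' @param controls [control_data()].
#' @param candidates candidate time grid, hours.
#' @param n_cells cells per time point.
#' @param seed optional integer seed.
#' @param max_bytes guard on the dataset storage footprint (default 4 GiB);
#'   exceeding it raises an error suggesting smaller `n_pre` or `n_cells`.
#' @return list of class `"reference_table"` with elements `thetas`
#'   (`n_pre x 4`), `datasets` (list of `n_cells x n_times` matrices) and
#'   `candidates`.
#' @export
build_reference_table <- function(prior, n_pre, consts, controls,
                                  candidates = default_candidate_times(),
                                  n_cells = 1000, seed = NULL,
                                  max_bytes = 4 * 1024^3) {
  need <- 8 * as.numeric(n_pre) * n_cells * length(candidates)
  if (need > max_bytes) {
    stop_param(sprintf(
      "reference table would need %.1f GiB; reduce n_pre (%d) or n_cells (%d)",
      need / 1024^3, n_pre, n_cells))
  }
  candidates <- sort(as.numeric(candidates))
  with_seed(seed, {
    thetas <- prior_sample(prior, n_pre)
    datasets <- vector("list", n_pre)
    for (i in seq_len(n_pre)) {
      sim <- simulate_dataset(thetas[i, ], consts, candidates, controls,
                              n_cells = n_cells, t_grid_max = max(candidates))
      datasets[[i]] <- matrix(unlist(sim$samples), nrow = n_cells)
    }
    structure(list(thetas = thetas, datasets = datasets, candidates = candidates),
              class = "reference_table")
  })
}

#' @export
print.reference_table <- function(x, ...) {
  cat(sprintf("Reference table: %d prior draws x %d candidate times x %d cells\n",
              nrow(x$thetas), length(x$candidates), nrow(x$datasets[[1L]])))
  invisible(x)
}

#' Per-time-point distances between a reference table and one dataset
#'
#' The workhorse of the shared-table design search: the two-sample statistic
#' between every reference dataset and the observed dataset, at every
#' candidate time point. Any design's summed distance is then a row sum over
#' the design's columns.
#'
#' @param table a [build_reference_table()] result.
#' @param obs a [timecourse()] observed at all candidate times.
#' @param distance distance name (`"ad"`, `"cvm"`, `"ks"`).
#' @return `n_pre x n_candidates` matrix.
#' @export
reference_distances <- function(table, obs, distance = c("ad", "cvm", "ks")) {
  stat <- distance_fun(match.arg(distance), "stat")
  if (length(obs$times) != length(table$candidates) ||
      any(abs(obs$times - table$candidates) > 1e-9)) {
    stop_param("observed dataset must cover the full candidate grid")
  }
  n_pre <- length(table$datasets)
  D <- matrix(NA_real_, n_pre, length(table$candidates))
  for (ti in seq_along(table$candidates)) {
    o <- obs$samples[[ti]]
    for (i in seq_len(n_pre)) D[i, ti] <- stat(table$datasets[[i]][, ti], o)
  }
  D
}

design_columns <- function(table, design) {
  idx <- match(round(design * 64), round(table$candidates * 64))
  if (anyNA(idx)) stop_param("design contains times outside the candidate grid")
  idx
}

#' Rejection-ABC posterior for one design
#'
#' Sums the per-time-point distances over the design's time points only and
#' accepts the `n_accept` prior draws with the smallest summed distance
#' (equivalent to thresholding at the `n_accept`-th order statistic, which
#' guarantees every design's posterior carries the same number of samples).
#'
#' @param table a [build_reference_table()] result.
#' @param obs a [timecourse()] over the full candidate grid, or a
#'   precomputed [reference_distances()] matrix.
#' @param design numeric vector of design times (subset of the candidates).
#' @param n_accept number of accepted draws (default 200).
#' @param distance distance name.
#' @return `n_accept x 4` matrix of accepted hyperparameters, with attribute
#'   `threshold` (the achieved distance of the last accepted draw).
#' @export
abc_rejection_posterior <- function(table, obs, design, n_accept = 200,
                                    distance = "ad") {
  if (n_accept > nrow(table$thetas)) {
    stop_param("n_accept exceeds the reference table size")
  }
  D <- if (is.matrix(obs)) obs else reference_distances(table, obs, distance)
  cols <- design_columns(table, design)
  d <- rowSums(D[, cols, drop = FALSE])
  o <- order(d)[seq_len(n_accept)]
  structure(table$thetas[o, , drop = FALSE], threshold = d[o[n_accept]])
}

#' Inverse-determinant design utility
#'
#' Mean over accepted-parameter sets of `1 / det(Cov(theta))`: large when the
#' ABC posteriors concentrate, i.e. when the design's measurements pin down
#' the hyperparameters. A degenerate (singular or near-singular) covariance
#' contributes the cap value instead of an infinite utility.
#'
#' @param posteriors list of accepted-theta matrices (one per scenario
#'   dataset), or a single matrix.
#' @param cap ceiling on a single set's contribution (default 1e12).
#' @return Positive scalar.
#' @export
design_utility <- function(posteriors, cap = 1e12) {
  if (is.matrix(posteriors)) posteriors <- list(posteriors)
  contrib <- vapply(posteriors, function(th) {
    dt <- det(stats::cov(th))
    if (!is.finite(dt) || dt <= 1 / cap) cap else 1 / dt
  }, numeric(1))
  mean(contrib)
}

#' Rank designs by utility
#'
#' @param designs design matrix from [enumerate_designs()].
#' @param utilities numeric vector of utilities, one per design row.
#' @return data.frame with the design times (`t1..tk`), `utility`,
#'   `normalized_utility` (utility / max utility, so the per-scenario optimum
#'   scores 1) and `rank` (1 = best; ties broken by lexicographic design
#'   order).
#' @export
rank_designs <- function(designs, utilities) {
  if (nrow(designs) != length(utilities)) {
    stop_param("one utility per design is required")
  }
  o <- do.call(order, c(list(-utilities), lapply(seq_len(ncol(designs)),
                                                 function(j) designs[, j])))
  rk <- integer(length(utilities))
  rk[o] <- seq_along(o)
  out <- as.data.frame(designs)
  names(out) <- paste0("t", seq_len(ncol(designs)))
  out$utility <- utilities
  out$normalized_utility <- utilities / max(utilities)
  out$rank <- rk
  out
}

#' Overall optimal design across scenarios
#'
#' Averages each design's rank across the per-scenario rankings and returns
#' the design minimising the average rank (ties broken lexicographically).
#'
#' @param rankings list of [rank_designs()] data.frames over the same design
#'   set, in the same row order.
#' @return list with `design` (numeric times), `average_rank`, and
#'   `average_ranks` (vector over all designs).
#' @export
overall_optimal <- function(rankings) {
  if (length(rankings) < 1L) stop_param("at least one ranking is required")
  k <- sum(startsWith(names(rankings[[1L]]), "t"))
  avg <- rowMeans(vapply(rankings, function(r) r$rank, numeric(nrow(rankings[[1L]]))))
  dmat <- as.matrix(rankings[[1L]][, seq_len(k)])
  o <- do.call(order, c(list(avg), lapply(seq_len(k), function(j) dmat[, j])))
  best <- o[1L]
  list(design = unname(dmat[best, ]), average_rank = avg[best],
       average_ranks = avg)
}

#' Full design search for one scenario
#'
#' End-to-end: enumerate designs, pre-simulate `j_reps` scenario datasets and
#' an `n_pre`-row reference table over the candidate grid, precompute the
#' per-time-point distance matrices, then score and rank every design.
#'
#' @param spec a [scenario_spec()].
#' @param prior a [prior_box()].
#' @param consts [experiment_constants()].
#' @param controls [control_data()].
#' @param candidates candidate times, hours.
#' @param k design size (default 6).
#' @param n_pre reference-table size (default 2000; increase for production
#'   runs).
#' @param j_reps scenario datasets (default 5; the reference analysis uses 20).
#' @param n_accept accepted draws per posterior (default 200).
#' @param n_cells cells per time point (default 1000).
#' @param distance distance name (default `"ad"`).
#' @param seed optional integer seed.
#' @param verbose print stage progress.
#' @return [rank_designs()] data.frame with attributes `scenario`,
#'   `thetas` (generating hyperparameters of the scenario datasets).
#' @export
design_search <- function(spec, prior = default_prior(), consts = default_constants(),
                          controls, candidates = default_candidate_times(), k = 6,
                          n_pre = 2000, j_reps = 5, n_accept = 200, n_cells = 1000,
                          distance = "ad", seed = NULL, verbose = FALSE) {
  with_seed(seed, {
    designs <- enumerate_designs(candidates, k)
    if (verbose) message(sprintf("scoring %d designs for scenario '%s'",
                                 nrow(designs), spec$name))
    obs_list <- sample_scenario_datasets(spec, j_reps, consts, controls,
                                         candidates, n_cells)
    table <- build_reference_table(prior, n_pre, consts, controls, candidates,
                                   n_cells)
    if (verbose) message("reference table simulated; computing distances")
    Dlist <- lapply(obs_list, function(o) reference_distances(table, o, distance))
    if (verbose) message("distance matrices ready; ranking designs")
    thetas <- table$thetas
    utilities <- vapply(seq_len(nrow(designs)), function(di) {
      cols <- design_columns(table, designs[di, ])
      design_utility(lapply(Dlist, function(D) {
        d <- rowSums(D[, cols, drop = FALSE])
        thetas[order(d)[seq_len(n_accept)], , drop = FALSE]
      }))
    }, numeric(1))
    out <- rank_designs(designs, utilities)
    attr(out, "scenario") <- spec$name
    attr(out, "thetas") <- attr(obs_list, "thetas")
    out
  })
}
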