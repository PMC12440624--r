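# ABC-SMC inference of the heterogeneity hyperparameters.
#
# Standard adaptive sequential scheme: generation 1 is a prior-predictive
# sample (threshold Inf); each later generation resamples ancestors by
# weight, perturbs with a multivariate Gaussian kernel on the LOG scale
# (all four hyperparameters are positive and span orders of magnitude, so a
# natural-scale kernel would waste almost every proposal mid-run) whose
# covariance is twice the weighted empirical covariance of the previous
# generation's log-parameters, rejects proposals outside the prior box
# before simulating, accepts simulations whose distance to the observed time
# course falls below the current threshold, and assigns kernel-corrected
# importance weights (including the log-transform Jacobian). The threshold
# sequence is the median of the previous generation's accepted distances.
# Termination: at an explicit target threshold when one is supplied;
# otherwise at the simulator's noise floor - estimated each generation by
# re-simulating replicate datasets at particles drawn from the current
# posterior and measuring their distances to the observation. Once the
# threshold is at or below that floor, tightening further only fits the
# sampling noise of the particular observed dataset (and biases the
# posterior), so the run stops. An acceptance-rate floor (`min_acceptance`)
# provides a cost backstop.

#' Fit the heterogeneous association model by ABC-SMC
#'
#' Likelihood-free inference of the lognormal heterogeneity hyperparameters
#' `(m_r, s_r, m_K, s_K)` from an observed single-cell fluorescence time
#' course. Candidate hyperparameters are scored by simulating a complete
#' synthetic flow cytometry dataset ([simulate_dataset()]) and measuring its
#' distance to the observations (summed per-time-point two-sample statistic;
#' see [distance_anderson_darling()]).
#'
#' @param obs observed [timecourse()].
#' @param prior a [prior_box()]; defaults to [default_prior()].
#' @param controls [control_data()] used by the fluorescence noise model.
#' @param consts [experiment_constants()].
#' @param distance distance name: `"ad"` (Anderson-Darling, default),
#'   `"cvm"` or `"ks"`.
#' @param n_particles number of SMC particles (posterior sample size).
#' @param n_cells cells simulated per proposal and time point; defaults to
#'   the observed per-time sample size.
#' @param target_threshold terminal ABC threshold; the run stops once a full
#'   generation is accepted at (or below) it. `NULL` (default) runs until the
#'   acceptance-rate floor or the generation cap is hit.
#' @param min_acceptance acceptance-rate floor (default 0.02): when a
#'   generation accepts fewer than this fraction of its simulated proposals
#'   the run stops with that generation as the posterior (cost backstop).
#' @param n_floor_reps replicate simulations per generation used to estimate
#'   the noise floor - the typical distance between the observation and
#'   re-simulations at posterior-supported parameters (default 6). When the
#'   threshold reaches the median replicate distance, the run stops:
#'   tightening below the noise floor fits the observation's sampling noise
#'   and biases the posterior. Set to 0 to disable.
#' @param max_generations upper bound on SMC generations.
#' @param max_attempts_factor per-generation simulation budget, as a multiple
#'   of `n_particles`.
#' @param m_eval media-trajectory Monte Carlo size per simulation.
#' @param seed integer seed governing every stochastic step of the run.
#' @param verbose print per-generation progress.
#' @return An object of class `"abcsmc"`: list with elements `theta`
#'   (`n_particles x 4` matrix), `weights` (normalised), `distances`,
#'   `threshold_history`, `target_threshold`, `n_simulations`,
#'   `acceptance_rates`, plus the inputs needed for posterior prediction
#'   (`prior`, `controls`, `consts`, `obs_times`, `obs`, `n_cells`,
#'   `distance`, `seed`).
#' @seealso [predict.abcsmc()], [hpd_interval()], [summary.abcsmc()]
#' @export
abc_smc <- function(obs, prior = default_prior(), controls,
                    consts = default_constants(),
                    distance = c("ad", "cvm", "ks"),
                    n_particles = 1000, n_cells = NULL,
                    target_threshold = NULL, min_acceptance = 0.02,
                    n_floor_reps = 6, max_generations = 20,
                    max_attempts_factor = 50,
                    m_eval = 100, seed = NULL, verbose = FALSE) {
  distance <- match.arg(distance)
  dfun <- distance_fun(distance)
  if (!inherits(obs, "timecourse")) stop_param("'obs' must be a timecourse")
  if (is.null(n_cells)) n_cells <- max(vapply(obs$samples, length, 1L))
  if (n_particles < 2) stop_param("n_particles must be >= 2")
  times <- obs$times
  np <- as.integer(n_particles)
  # distances are permutation-invariant; sorting the fixed observed samples
  # once lets the compiled statistics skip re-sorting them on every proposal
  obs_sorted <- obs
  obs_sorted$samples <- lapply(obs$samples, sort)

  with_seed(seed, {
    simulate_distance <- function(theta) {
      sim <- simulate_dataset(theta, consts, times, controls,
                              n_cells = n_cells, m_eval = m_eval)
      dfun(sim, obs_sorted)
    }

    # generation 1: prior predictive
    theta <- prior_sample(prior, np)
    d <- apply(theta, 1L, simulate_distance)
    w <- rep.int(1 / np, np)
    n_sims <- np
    target <- target_threshold %||% 0
    thresholds <- Inf
    acc_rates <- 1
    gen <- 1L
    if (verbose) {
      message(sprintf("gen 1: prior predictive, median distance %.4g",
                      stats::median(d)))
    }

    floor_history <- numeric(0)
    while (gen < max_generations && thresholds[gen] > target &&
           acc_rates[gen] >= min_acceptance) {
      eps <- max(target, unname(stats::median(d)))
      if (n_floor_reps > 0 && is.null(target_threshold)) {
        # noise-floor estimate: the smallest mean replicate distance among the
        # current best particles (the attainable expected distance, not the
        # lucky draw that got them accepted)
        best_idx <- order(d)[seq_len(min(3L, np))]
        reps_per <- max(2L, ceiling(n_floor_reps / length(best_idx)))
        floor_means <- vapply(best_idx, function(b) {
          mean(vapply(seq_len(reps_per),
                      function(i) simulate_distance(theta[b, ]), numeric(1)))
        }, numeric(1))
        n_sims <- n_sims + reps_per * length(best_idx)
        floor_est <- min(floor_means)
        floor_history <- c(floor_history, floor_est)
        if (eps <= floor_est) {
          if (verbose) {
            message(sprintf(
              "stopping: next threshold %.4g is at the noise floor (%.4g)",
              eps, floor_est))
          }
          break
        }
      }
      phi <- log(theta)
      sigma <- 2 * stats::cov.wt(phi, wt = w)$cov
      # ridge keeps the kernel proper when a component has degenerated
      diag(sigma) <- diag(sigma) + 1e-10
      R <- chol(sigma)
      new_theta <- matrix(NA_real_, np, 4L, dimnames = list(NULL, rownames(prior)))
      new_d <- numeric(np)
      accepted <- 0L
      attempts <- 0L
      proposals <- 0L
      budget <- max_attempts_factor * np
      while (accepted < np && attempts < budget && proposals < 1000L * np) {
        proposals <- proposals + 1L
        anc <- phi[sample.int(np, 1L, prob = w), ]
        prop <- exp(anc + drop(stats::rnorm(4L) %*% R))
        if (!prior_contains(prior, prop)) next
        attempts <- attempts + 1L
        n_sims <- n_sims + 1L
        di <- simulate_distance(prop)
        if (di <= eps) {
          accepted <- accepted + 1L
          new_theta[accepted, ] <- prop
          new_d[accepted] <- di
        }
      }
      if (accepted < np) {
        warning(sprintf(
          "simulation budget exhausted in generation %d (accepted %d of %d); returning generation %d",
          gen + 1L, accepted, np, gen), call. = FALSE)
        break
      }
      # kernel-corrected importance weights (uniform prior => constant numerator)
      w <- kernel_weights(log(new_theta), phi, w, R)
      theta <- new_theta
      d <- new_d
      gen <- gen + 1L
      thresholds <- c(thresholds, eps)
      acc_rates <- c(acc_rates, accepted / max(attempts, 1L))
      if (verbose) {
        message(sprintf("gen %d: eps %.4g, acceptance %.1f%%, ESS %.0f",
                        gen, eps, 100 * accepted / attempts, 1 / sum(w^2)))
      }
    }
    if (!is.null(target_threshold) && thresholds[gen] > target) {
      warning("stopped before reaching the requested target threshold", call. = FALSE)
    }

    structure(list(theta = theta, weights = w, distances = d,
                   threshold_history = thresholds,
                   target_threshold = target,
                   noise_floor_history = floor_history,
                   acceptance_rates = acc_rates,
                   n_simulations = n_sims,
                   prior = prior, controls = controls, consts = consts,
                   obs = obs, obs_times = times, n_cells = n_cells,
                   m_eval = m_eval, distance = distance, seed = seed),
              class = "abcsmc")
  })
}

# Kernel-corrected importance weights, computed stably in log space. With a
# uniform prior on theta and a Gaussian kernel on phi = log(theta), the
# proposal density of particle i is
#   q(theta_i) = [sum_k w_k N(phi_i; phi_k, Sigma)] * prod_j 1/theta_ij,
# so the (unnormalised) weight is prod_j theta_ij / mixture density; constant
# factors cancel in the final normalisation. R is the Cholesky factor of the
# kernel covariance on the log scale.
kernel_weights <- function(new_phi, old_phi, old_w, R) {
  np <- nrow(new_phi)
  log_dens <- numeric(np)
  # Sigma = R'R with R upper triangular, so Mahalanobis z = diff %*% R^{-1}
  Rinv <- backsolve(R, diag(4L))
  lw <- log(old_w)
  for (i in seq_len(np)) {
    z <- (new_phi[rep.int(i, nrow(old_phi)), , drop = FALSE] - old_phi) %*% Rinv
    q <- lw - 0.5 * rowSums(z^2)
    m <- max(q)
    log_dens[i] <- m + log(sum(exp(q - m)))
  }
  lw_new <- rowSums(new_phi) - log_dens
  w <- exp(lw_new - max(lw_new))
  w / sum(w)
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval containing at least `level` of the (weighted)
#' sample mass: the sample is sorted and every window of cumulative weight
#' >= `level` is scanned for minimal width.
#'
#' @param samples numeric vector (>= 2 values unless all equal).
#' @param weights optional nonnegative weights (default equal).
#' @param level probability mass in (0, 1), default 0.95.
#' @return Object of class `"hpd_interval"`: named numeric
#'   `c(lower, upper, level)`.
#' @export
hpd_interval <- function(samples, weights = NULL, level = 0.95) {
  if (!is.finite(level) || level <= 0 || level >= 1) {
    stop_param("level must lie strictly between 0 and 1")
  }
  n <- length(samples)
  if (n < 1L) stop_param("at least one sample is required")
  if (is.null(weights)) weights <- rep.int(1, n)
  if (length(weights) != n || any(weights < 0)) stop_param("invalid weights")
  o <- order(samples)
  x <- samples[o]
  cw <- c(0, cumsum(weights[o] / sum(weights)))
  best <- c(x[1L], x[n])
  for (i in seq_len(n)) {
    # smallest j with mass(x[i..j]) >= level
    j <- which(cw[-seq_len(i)] - cw[i] >= level - 1e-12)[1L]
    if (is.na(j)) break
    j <- j + i - 1L
    if (x[j] - x[i] < best[2L] - best[1L]) best <- c(x[i], x[j])
  }
  structure(c(lower = best[1L], upper = best[2L], level = level),
            class = "hpd_interval")
}

#' @export
print.hpd_interval <- function(x, ...) {
  cat(sprintf("%.0f%% HPD interval: (%.6g, %.6g)\n",
              100 * x[["level"]], x[["lower"]], x[["upper"]]))
  invisible(x)
}

#' @export
print.abcsmc <- function(x, ...) {
  cat("ABC-SMC fit of the heterogeneous association model\n")
  cat(sprintf("  %d particles, %d generations, %d model simulations\n",
              nrow(x$theta), length(x$threshold_history), x$n_simulations))
  cat(sprintf("  distance: %s; final threshold %.4g (target %.4g)\n",
              x$distance, x$threshold_history[length(x$threshold_history)],
              x$target_threshold))
  cat("  posterior medians:\n")
  print(coef(x))
  invisible(x)
}

#' @export
coef.abcsmc <- function(object, ...) {
  vapply(seq_len(4L), function(j) weighted_median(object$theta[, j], object$weights),
         numeric(1)) |>
    stats::setNames(colnames(object$theta))
}

#' Posterior summary of an ABC-SMC fit
#'
#' @param object an `"abcsmc"` fit.
#' @param level HPD mass (default 0.95).
#' @param ... unused.
#' @return data.frame with the weighted posterior median and HPD bounds per
#'   hyperparameter, plus the HPD width as a fraction of the prior width
#'   (a practical-identifiability diagnostic: values near 1 mean the data do
#'   not constrain the parameter beyond its prior).
#' @export
summary.abcsmc <- function(object, level = 0.95, ...) {
  stats_tab <- t(vapply(seq_len(4L), function(j) {
    h <- hpd_interval(object$theta[, j], object$weights, level)
    med <- weighted_median(object$theta[, j], object$weights)
    c(median = med, h[["lower"]], h[["upper"]])
  }, numeric(3)))
  colnames(stats_tab) <- c("median", "hpd_lower", "hpd_upper")
  prior_width <- object$prior[, 2] - object$prior[, 1]
  out <- data.frame(parameter = colnames(object$theta), stats_tab,
                    hpd_frac_prior = (stats_tab[, 3] - stats_tab[, 2]) / prior_width,
                    row.names = NULL)
  attr(out, "level") <- level
  class(out) <- c("summary.abcsmc", "data.frame")
  out
}

#' @export
print.summary.abcsmc <- function(x, ...) {
  cat(sprintf("Posterior summary (%.0f%% HPD):\n", 100 * attr(x, "level")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Posterior-predictive simulation from an ABC-SMC fit
#'
#' Draws hyperparameters from the weighted posterior and simulates one
#' complete synthetic fluorescence time course per draw.
#'
#' @param object an `"abcsmc"` fit.
#' @param nsim number of datasets (default 1).
#' @param seed optional integer seed.
#' @param times measurement times (default: the fitted times).
#' @param n_cells cells per time point (default: as fitted).
#' @param ... unused.
#' @return A list of [timecourse()] objects of length `nsim`.
#' @export
simulate.abcsmc <- function(object, nsim = 1, seed = NULL, times = object$obs_times,
                            n_cells = object$n_cells, ...) {
  with_seed(seed, {
    idx <- sample.int(nrow(object$theta), nsim, replace = TRUE, prob = object$weights)
    lapply(idx, function(i) {
      simulate_dataset(object$theta[i, ], object$consts, times, object$controls,
                       n_cells = n_cells, m_eval = object$m_eval)
    })
  })
}

#' Plot marginal ABC posteriors
#'
#' Weighted histograms of the four hyperparameter marginals over their prior
#' ranges, with the weighted posterior median marked.
#'
#' @param x an `"abcsmc"` fit.
#' @param breaks histogram breaks per panel.
#' @param ... further arguments passed to [graphics::hist()].
#' @return Invisibly, `x`.
#' @export
plot.abcsmc <- function(x, breaks = 30, ...) {
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  labs <- c(m_r = "m_r [m/s]", s_r = "s_r [m/s]",
            m_K = "m_K [particles/cell]", s_K = "s_K [particles/cell]")
  for (j in seq_len(4L)) {
    nm <- colnames(x$theta)[j]
    h <- graphics::hist(x$theta[, j], breaks = breaks, plot = FALSE)
    wcount <- vapply(seq_len(length(h$breaks) - 1L), function(b) {
      sel <- x$theta[, j] > h$breaks[b] & x$theta[, j] <= h$breaks[b + 1L]
      sum(x$weights[sel])
    }, numeric(1))
    graphics::plot(h$mids, wcount, type = "h", lwd = 3,
                   xlab = labs[[nm]] %||% nm, ylab = "posterior mass",
                   main = nm, ...)
    graphics::abline(v = weighted_median(x$theta[, j], x$weights),
                     col = "red3", lty = 2)
  }
  invisible(x)
}
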