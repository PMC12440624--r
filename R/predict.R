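# Posterior prediction: particles-per-cell bands, fluorescence histogram
# bands, inferred trait distributions and capacity-fraction curves, all by
# propagating weighted posterior draws through the generative model.

posterior_draw_idx <- function(object, n_draws) {
  sample.int(nrow(object$theta), n_draws, replace = TRUE, prob = object$weights)
}

#' Predict from an ABC-SMC fit
#'
#' Dispatches to the posterior-prediction helpers:
#' `type = "pband"` gives [predict_p_band()] (particles-per-cell prediction
#' bands), `"histograms"` gives [posterior_predict_histograms()]
#' (per-bin fluorescence histogram bands), `"distribution"` gives
#' [inferred_distribution()] (pointwise bands of the lognormal trait pdf) and
#' `"fraction"` gives [predict_fraction_band()] (percentage of cells above a
#' capacity fraction `beta`).
#'
#' @param object an `"abcsmc"` fit.
#' @param type one of `"pband"`, `"histograms"`, `"distribution"`,
#'   `"fraction"`.
#' @param ... passed to the corresponding helper.
#' @return See the helpers.
#' @export
predict.abcsmc <- function(object,
                           type = c("pband", "histograms", "distribution", "fraction"),
                           ...) {
  switch(match.arg(type),
         pband = predict_p_band(object, ...),
         histograms = posterior_predict_histograms(object, ...),
         distribution = inferred_distribution(object, ...),
         fraction = predict_fraction_band(object, ...))
}

#' Prediction bands for particles per cell
#'
#' For each posterior draw, samples a synthetic cell population and evaluates
#' its noise-free particle trajectories; cells are pooled across posterior
#' draws and the pooled distribution is summarised per time point by its
#' median, 50% band (quartiles) and 95% band. A time grid starting at 0 is
#' used so bands start at zero.
#'
#' @param object an `"abcsmc"` fit.
#' @param times time grid, hours (default: 25 points from 0 to the last
#'   fitted time).
#' @param n_draws posterior draws (default 100).
#' @param n_cells cells per draw (default 200).
#' @param seed optional integer seed.
#' @return data.frame with columns `time_h`, `lower95`, `lower50`, `median`,
#'   `upper50`, `upper95`.
#' @export
predict_p_band <- function(object, times = NULL, n_draws = 100, n_cells = 200,
                           seed = NULL) {
  if (is.null(times)) times <- seq(0, max(object$obs_times), length.out = 25)
  times <- sort(times)
  pos <- times[times > 0]
  with_seed(seed, {
    idx <- posterior_draw_idx(object, n_draws)
    P_all <- matrix(NA_real_, n_draws * n_cells, length(pos))
    for (k in seq_along(idx)) {
      th <- as_hyper(object$theta[idx[k], ])
      traits <- sample_cell_traits(th, n_cells)
      media <- media_concentration_approx(max(times), th, object$consts,
                                          m_eval = object$m_eval)
      P_all[(k - 1L) * n_cells + seq_len(n_cells), ] <-
        unclass(heterogeneous_solution_approx(pos, traits, media, object$consts))
    }
    q <- apply(P_all, 2L, stats::quantile, probs = c(0.025, 0.25, 0.5, 0.75, 0.975))
    out <- data.frame(time_h = times,
                      lower95 = 0, lower50 = 0, median = 0, upper50 = 0, upper95 = 0)
    out[match(pos, times), -1L] <- t(q)
    out
  })
}

#' Posterior-predictive histogram bands for fluorescence data
#'
#' Per posterior draw, simulates one full synthetic fluorescence dataset and
#' bins it on bins shared with the observed data (pooled observed + simulated
#' range, count scale); reports the 2.5/50/97.5 percentiles of each bar
#' height across draws, together with the observed bar heights.
#'
#' @param object an `"abcsmc"` fit.
#' @param obs observed [timecourse()] (default: the fitted one).
#' @param bins number of histogram bins (default 30).
#' @param n_draws posterior draws (default 50).
#' @param n_cells cells per simulated dataset (default: as fitted).
#' @param seed optional integer seed.
#' @return Named list (one entry per time point) of data.frames with columns
#'   `mid`, `lower`, `median`, `upper`, `observed`.
#' @export
posterior_predict_histograms <- function(object, obs = object$obs, bins = 30,
                                         n_draws = 50, n_cells = object$n_cells,
                                         seed = NULL) {
  if (nrow(object$theta) < 1L) stop_param("empty posterior")
  with_seed(seed, {
    idx <- posterior_draw_idx(object, n_draws)
    sims <- lapply(idx, function(i) {
      simulate_dataset(object$theta[i, ], object$consts, obs$times,
                       object$controls, n_cells = n_cells, m_eval = object$m_eval)
    })
    out <- vector("list", length(obs$times))
    names(out) <- format(obs$times)
    for (ti in seq_along(obs$times)) {
      pooled <- range(c(obs$samples[[ti]],
                        unlist(lapply(sims, function(s) range(s$samples[[ti]])))))
      breaks <- seq(pooled[1], pooled[2], length.out = bins + 1L)
      counts <- vapply(sims, function(s) {
        graphics::hist(s$samples[[ti]], breaks = breaks, plot = FALSE)$counts
      }, numeric(bins))
      q <- apply(counts, 1L, stats::quantile, probs = c(0.025, 0.5, 0.975))
      out[[ti]] <- data.frame(
        mid = (breaks[-1L] + breaks[-(bins + 1L)]) / 2,
        lower = q[1L, ], median = q[2L, ], upper = q[3L, ],
        observed = graphics::hist(obs$samples[[ti]], breaks = breaks,
                                  plot = FALSE)$counts)
    }
    out
  })
}

#' Inferred trait distribution with uncertainty bands
#'
#' The posterior over hyperparameters induces a family of lognormal densities
#' for a per-cell trait (`r` or `K`). For each posterior draw the pdf is
#' evaluated on `grid`; the pointwise weighted median and central band are
#' returned.
#'
#' @param object an `"abcsmc"` fit.
#' @param trait `"r"` or `"K"`.
#' @param grid evaluation grid on the natural scale (default: 200 points
#'   covering the posterior-median distribution's central mass).
#' @param level band mass (default 0.95).
#' @param n_draws posterior draws (default: all particles, weighted).
#' @return data.frame with columns `grid`, `lower`, `median`, `upper`.
#' @export
inferred_distribution <- function(object, trait = c("r", "K"), grid = NULL,
                                  level = 0.95, n_draws = NULL) {
  trait <- match.arg(trait)
  cols <- if (trait == "r") c("m_r", "s_r") else c("m_K", "s_K")
  th <- object$theta[, cols, drop = FALSE]
  w <- object$weights
  if (!is.null(n_draws)) {
    idx <- posterior_draw_idx(object, n_draws)
    th <- th[idx, , drop = FALSE]
    w <- rep.int(1 / n_draws, n_draws)
  }
  if (is.null(grid)) {
    med <- c(weighted_median(th[, 1L], w), weighted_median(th[, 2L], w))
    p <- lognormal_natural_params(med[1L], max(med[2L], med[1L] * 1e-6))
    grid <- seq(stats::qlnorm(1e-4, p[1L], p[2L]),
                stats::qlnorm(0.995, p[1L], p[2L]), length.out = 200L)
  }
  dens <- apply(th, 1L, function(ms) {
    p <- lognormal_natural_params(ms[1L], ms[2L])
    stats::dlnorm(grid, p[1L], p[2L])
  })
  alpha <- (1 - level) / 2
  q <- apply(dens, 1L, function(v) weighted_quantile(v, w, c(alpha, 0.5, 1 - alpha)))
  data.frame(grid = grid, lower = q[1L, ], median = q[2L, ], upper = q[3L, ])
}

#' Posterior band for the fraction of cells near capacity
#'
#' Per posterior draw, simulates a cell population and computes the
#' percentage of cells with `P_j(t) > beta * K_j` ([fraction_near_capacity()]);
#' reports pointwise median and central 95% band across draws.
#'
#' @param object an `"abcsmc"` fit.
#' @param beta capacity fraction in (0, 1), default 0.5.
#' @param times time grid, hours (default as in [predict_p_band()]).
#' @param n_draws posterior draws (default 100).
#' @param n_cells cells per draw (default 200).
#' @param seed optional integer seed.
#' @return data.frame with columns `time_h`, `lower`, `median`, `upper`
#'   (percentages).
#' @export
predict_fraction_band <- function(object, beta = 0.5, times = NULL,
                                  n_draws = 100, n_cells = 200, seed = NULL) {
  if (is.null(times)) times <- seq(0, max(object$obs_times), length.out = 25)
  times <- sort(times)
  pos <- times[times > 0]
  with_seed(seed, {
    idx <- posterior_draw_idx(object, n_draws)
    fr <- matrix(0, length(idx), length(pos))
    for (k in seq_along(idx)) {
      th <- as_hyper(object$theta[idx[k], ])
      traits <- sample_cell_traits(th, n_cells)
      media <- media_concentration_approx(max(times), th, object$consts,
                                          m_eval = object$m_eval)
      P <- heterogeneous_solution_approx(pos, traits, media, object$consts)
      fr[k, ] <- fraction_near_capacity(P, traits, beta)
    }
    q <- apply(fr, 2L, stats::quantile, probs = c(0.025, 0.5, 0.975))
    out <- data.frame(time_h = times, lower = 0, median = 0, upper = 0)
    out[match(pos, times), -1L] <- t(q)
    out
  })
}
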