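# Point-estimate baselines against which the hierarchical ABC approach is
# compared: the median fluorescence transform with least-squares fitting of
# the homogeneous model, and the per-cell fluorescence transform.

#' Median-transform point estimates of particles per cell
#'
#' Classical summary of a fluorescence time course: per time point,
#' `Po(t) = (median(Dexp(t)) - median(Dcells)) / median(Dparticles)`, with
#' `Po(0) = 0` prepended. Reduces thousands of single-cell measurements per
#' time point to one number and discards all heterogeneity.
#'
#' @param exp observed [timecourse()].
#' @param controls [control_data()].
#' @return data.frame of class `"point_obs"` with columns `time_h`, `Po`
#'   (first row is `time_h = 0, Po = 0`).
#' @export
median_transform <- function(exp, controls) {
  med_p <- stats::median(controls$particles)
  if (med_p == 0) stop_param("median particle fluorescence is zero")
  med_c <- stats::median(controls$cells)
  Po <- vapply(exp$samples, function(s) (stats::median(s) - med_c) / med_p,
               numeric(1))
  structure(data.frame(time_h = c(0, exp$times), Po = c(0, unname(Po))),
            class = c("point_obs", "data.frame"))
}

#' Per-cell transform of fluorescence to particle counts
#'
#' Applies the median-control transform to every single-cell measurement:
#' `Po_j(t) = (d_j(t) - median(Dcells)) / median(Dparticles)`. When the
#' signal is close to the autofluorescence background this yields many
#' non-physical negative values; they are never dropped here (discarding them
#' biases downstream estimates upward) and the fraction of negative values
#' per time point is always reported.
#'
#' @param exp observed [timecourse()].
#' @param controls [control_data()].
#' @return list of class `"per_cell_obs"` with elements `times` (hours),
#'   `Po` (list of numeric vectors, one per time point, negatives preserved)
#'   and `frac_negative` (per time point).
#' @export
per_cell_transform <- function(exp, controls) {
  med_p <- stats::median(controls$particles)
  if (med_p == 0) stop_param("median particle fluorescence is zero")
  med_c <- stats::median(controls$cells)
  Po <- lapply(exp$samples, function(s) (s - med_c) / med_p)
  structure(list(times = exp$times, Po = Po,
                 frac_negative = vapply(Po, function(v) mean(v < 0), numeric(1))),
            class = "per_cell_obs")
}

#' @export
print.per_cell_obs <- function(x, ...) {
  cat("Per-cell particle-count estimates\n")
  print(data.frame(time_h = x$times,
                   median_Po = vapply(x$Po, stats::median, numeric(1)),
                   frac_negative = x$frac_negative))
  invisible(x)
}

#' Least-squares fit of the homogeneous model to point estimates
#'
#' Minimises the unweighted sum of squared differences between observed point
#' estimates `Po(t_i)` (including `t = 0`) and the homogeneous analytic
#' solution `P(t_i; r, K)`. The optimisation runs on `(log r, log K)` with
#' bounded quasi-Newton iterations from multiple log-uniform starts spanning
#' the search box, because plausible association rates span several orders of
#' magnitude. No Gaussian error model is attached to the fit: the returned
#' quantity is the point estimate and its achieved SSE only.
#'
#' Note the structural non-identifiability of the product `C * S * r`:
#' rescaling `S` while inversely rescaling `r` leaves the fitted curve
#' unchanged, so `r` is only meaningful relative to the supplied constants.
#'
#' @param obs a `"point_obs"` data.frame from [median_transform()] (or any
#'   data.frame with `time_h` and `Po` columns), >= 3 time points.
#' @param consts [experiment_constants()].
#' @param lower,upper named bounds for `r` (m/s) and `K` (particles/cell).
#' @param n_starts number of multistarts (default 10).
#' @param seed seed for the start draws (default 1, so fits are reproducible
#'   by default).
#' @return Object of class `"assoc_ls"`: list with `r`, `K`, `sse`,
#'   `convergence`, `obs`, `consts`, `starts`.
#' @export
least_squares_fit <- function(obs, consts, lower = c(r = 1e-9, K = 1),
                              upper = c(r = 1e-4, K = 500),
                              n_starts = 10, seed = 1) {
  if (nrow(obs) < 3L) stop_param("at least 3 time points are required")
  t_h <- obs$time_h
  Po <- obs$Po
  sse <- function(lp) {
    sum((Po - homogeneous_solution(t_h, exp(lp[1L]), exp(lp[2L]), consts))^2)
  }
  llo <- log(lower); lup <- log(upper)
  starts <- with_seed(seed, {
    cbind(stats::runif(n_starts, llo[1L], lup[1L]),
          stats::runif(n_starts, llo[2L], lup[2L]))
  })
  best <- NULL
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      stats::optim(starts[i, ], sse, method = "L-BFGS-B",
                   lower = llo, upper = lup,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    stop("least-squares optimisation failed from every start; check the data scale",
         call. = FALSE)
  }
  structure(list(r = exp(best$par[[1L]]), K = exp(best$par[[2L]]),
                 sse = best$value, convergence = best$convergence,
                 obs = obs, consts = consts, starts = starts),
            class = "assoc_ls")
}

#' @export
print.assoc_ls <- function(x, ...) {
  cat("Homogeneous-model least-squares fit\n")
  cat(sprintf("  r = %.4g m/s, K = %.4g particles/cell, SSE = %.4g\n",
              x$r, x$K, x$sse))
  invisible(x)
}

#' @export
coef.assoc_ls <- function(object, ...) c(r = object$r, K = object$K)

#' @export
predict.assoc_ls <- function(object, times = object$obs$time_h, ...) {
  homogeneous_solution(times, object$r, object$K, object$consts)
}

#' @export
fitted.assoc_ls <- function(object, ...) predict(object)

#' @export
residuals.assoc_ls <- function(object, ...) object$obs$Po - fitted(object)
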