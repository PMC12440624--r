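# Domain value objects: experimental constants, heterogeneity hyperparameters,
# prior boxes, and the lognormal mean/SD <-> natural-parameter conversion.

SECONDS_PER_HOUR <- 3600

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(..., call. = FALSE)

# Evaluate `code` under a temporary RNG seed, restoring the caller's stream.
# seed = NULL leaves the current stream untouched (and consumes from it).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_param("'seed' must be a single integer or NULL")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Experimental setup constants
#'
#' Fixed, known quantities of the incubation experiment: the fractional
#' surface coverage of the cell available for association, the cell surface
#' area, the media volume per cell, and the initial particle concentration
#' per cell. Together `V * u0` is the initial number of particles available
#' per cell.
#'
#' @param C fractional surface coverage, dimensionless, in (0, 1].
#' @param S cell surface area in m^2.
#' @param V media volume per cell in m^3.
#' @param u0 initial particle concentration in particles cell^-1 m^-3.
#' @return An object of class `"experiment_constants"` (a named list).
#' @seealso [default_constants()]
#' @export
experiment_constants <- function(C, S, V, u0) {
  vals <- c(C = C, S = S, V = V, u0 = u0)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_param("all experiment constants must be finite and strictly positive")
  }
  if (C > 1) stop_param("fractional surface coverage C must be <= 1")
  structure(list(C = C, S = S, V = V, u0 = u0),
            class = "experiment_constants")
}

#' Default experimental constants
#'
#' A named configuration emulating a typical particle-cell incubation setup
#' (monocyte-like cells of ~6 micron radius incubated with a particle dose of
#' one thousand particles per cell). These are placeholders standing in for a
#' concrete instrument calibration; all operations take the constants as an
#' argument and none hard-codes them.
#'
#' @return An `"experiment_constants"` object with
#'   `C = 0.3`, `S = 4.5e-10` m^2, `V = 1e-10` m^3, `u0 = 1e13`
#'   particles cell^-1 m^-3 (so `V * u0 = 1000` particles per cell).
#' @export
default_constants <- function() {
  experiment_constants(C = 0.3, S = 4.5e-10, V = 1e-10, u0 = 1e13)
}

#' @export
print.experiment_constants <- function(x, ...) {
  cat("Experiment constants:\n")
  cat(sprintf("  C  = %g (fractional surface coverage)\n", x$C))
  cat(sprintf("  S  = %g m^2 (cell surface area)\n", x$S))
  cat(sprintf("  V  = %g m^3 (media volume per cell)\n", x$V))
  cat(sprintf("  u0 = %g particles cell^-1 m^-3 (V*u0 = %g particles/cell)\n",
              x$u0, x$V * x$u0))
  invisible(x)
}

#' Heterogeneity hyperparameters
#'
#' Means and standard deviations of the lognormal distributions describing
#' cell-to-cell variability in the association rate `r` and the carrying
#' capacity `K`. The lognormals are parameterised directly by their mean and
#' SD on the natural scale (see [lognormal_natural_params()]); `r` and `K`
#' are assumed independent across cells.
#'
#' @param m_r mean association rate, m s^-1 (> 0).
#' @param s_r SD of the association rate, m s^-1 (>= 0; 0 gives a degenerate,
#'   homogeneous population and is accepted for limiting checks).
#' @param m_K mean carrying capacity, particles cell^-1 (> 0).
#' @param s_K SD of the carrying capacity, particles cell^-1 (>= 0).
#' @return An object of class `"hyper_params"`.
#' @export
hyper_params <- function(m_r, s_r, m_K, s_K) {
  vals <- c(m_r = m_r, s_r = s_r, m_K = m_K, s_K = s_K)
  if (any(!is.finite(vals))) stop_param("hyperparameters must be finite")
  if (m_r <= 0 || m_K <= 0) stop_param("means m_r and m_K must be > 0")
  if (s_r < 0 || s_K < 0) stop_param("SDs s_r and s_K must be >= 0")
  structure(as.list(vals), class = "hyper_params")
}

#' @export
print.hyper_params <- function(x, ...) {
  cat("Lognormal heterogeneity hyperparameters:\n")
  cat(sprintf("  r: mean %.4g m/s, SD %.4g m/s\n", x$m_r, x$s_r))
  cat(sprintf("  K: mean %.4g particles/cell, SD %.4g particles/cell\n",
              x$m_K, x$s_K))
  invisible(x)
}

as_hyper <- function(theta) {
  if (inherits(theta, "hyper_params")) return(theta)
  theta <- as.numeric(theta)
  if (length(theta) != 4L) stop_param("expected 4 hyperparameters (m_r, s_r, m_K, s_K)")
  hyper_params(theta[1], theta[2], theta[3], theta[4])
}

#' Natural parameters of a lognormal from its mean and SD
#'
#' Converts a (mean, SD) pair on the natural scale into the log-scale
#' location and scale `(meanlog, sdlog)` of the lognormal distribution with
#' that mean and SD:
#' `meanlog = log(m^2 / sqrt(m^2 + s^2))`, `sdlog = sqrt(log(1 + s^2/m^2))`.
#'
#' @param m mean on the natural scale (> 0).
#' @param s standard deviation on the natural scale (>= 0; `s = 0` returns
#'   the degenerate `(log(m), 0)`).
#' @return Named numeric vector `c(meanlog, sdlog)`.
#' @examples
#' p <- lognormal_natural_params(51.2, 53.3)
#' exp(p["meanlog"] + p["sdlog"]^2 / 2)  # recovers the mean 51.2
#' @export
lognormal_natural_params <- function(m, s) {
  if (!is.finite(m) || m <= 0) stop_param("lognormal mean 'm' must be > 0")
  if (!is.finite(s) || s < 0) stop_param("lognormal SD 's' must be >= 0")
  v <- log1p((s / m)^2)
  c(meanlog = log(m) - v / 2, sdlog = sqrt(v))
}

#' Uniform prior box over the heterogeneity hyperparameters
#'
#' Independent uniform priors (on the natural scale) for
#' `(m_r, s_r, m_K, s_K)`.
#'
#' @param m_r,s_r,m_K,s_K length-2 numeric vectors `c(lower, upper)` with
#'   `0 < lower < upper`.
#' @return An object of class `"prior_box"`: a 4 x 2 matrix with rows
#'   `m_r, s_r, m_K, s_K` and columns `lower, upper`.
#' @seealso [default_prior()]
#' @export
prior_box <- function(m_r, s_r, m_K, s_K) {
  b <- rbind(m_r = m_r, s_r = s_r, m_K = m_K, s_K = s_K)
  if (ncol(b) != 2L) stop_param("each prior bound must be c(lower, upper)")
  colnames(b) <- c("lower", "upper")
  if (any(!is.finite(b)) || any(b[, 1] <= 0) || any(b[, 1] >= b[, 2])) {
    stop_param("prior bounds must satisfy 0 < lower < upper")
  }
  structure(b, class = c("prior_box", "matrix"))
}

#' Default hyperparameter prior
#'
#' Wide uniform bounds covering association rates spanning several orders of
#' magnitude (slow surface binders through fast internalisers) and carrying
#' capacities from single particles to several hundred per cell. Every run
#' records the prior actually used; these defaults are a starting point, not
#' a recommendation for any particular particle-cell pair.
#'
#' @return A [prior_box()] with `m_r` in `[1e-9, 1e-4]` m/s, `s_r` in
#'   `[1e-9, 1e-4]` m/s, `m_K` in `[1, 500]` and `s_K` in `[0.1, 500]`
#'   particles/cell.
#' @export
default_prior <- function() {
  prior_box(m_r = c(1e-9, 1e-4), s_r = c(1e-9, 1e-4),
            m_K = c(1, 500), s_K = c(0.1, 500))
}

#' @export
print.prior_box <- function(x, ...) {
  cat("Uniform prior box (natural scale):\n")
  print(unclass(x))
  invisible(x)
}

prior_sample <- function(prior, n = 1L) {
  lo <- prior[, 1]; hi <- prior[, 2]
  m <- matrix(stats::runif(4L * n, rep(lo, each = n), rep(hi, each = n)),
              nrow = n, ncol = 4L)
  colnames(m) <- rownames(prior)
  m
}

prior_contains <- function(prior, theta) {
  all(theta >= prior[, 1] & theta <= prior[, 2])
}

# Weighted quantile of type "inverse CDF on sorted atoms".
weighted_quantile <- function(x, w = NULL, probs = 0.5) {
  if (is.null(w)) w <- rep.int(1, length(x))
  if (length(x) != length(w)) stop_param("x and w must have equal length")
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) x[o][which(cw >= p)[1L]], numeric(1))
}

weighted_median <- function(x, w = NULL) weighted_quantile(x, w, 0.5)
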