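# Mechanistic association models.
#
# Homogeneous population: with fractional coverage C, cell area S, rate r,
# capacity K and media concentration u(t) (per cell), particle depletion obeys
#   du/dt = -(C S r / V) * (1 - P/K) * u,    P(t) = V (u0 - u(t)),
# which has the closed-form solution implemented in homogeneous_solution().
#
# Heterogeneous population: each cell j carries its own (r_j, K_j) drawn from
# independent lognormals. The full model couples N cells to one shared media
# compartment (heterogeneous_solution_full()); the fast approximation
# replaces the shared media concentration with a pre-computed mean trajectory
# ubar(t) and solves each cell independently:
#   P_j(t) = K_j * (1 - exp(-(C S r_j / K_j) * integral_0^t ubar)).
#
# All user-facing times are in hours; conversion to seconds happens here so
# that r [m/s], S [m^2], V [m^3] and u0 [particles cell^-1 m^-3] are
# dimensionally consistent.

#' Analytic solution of the homogeneous association model
#'
#' Number of particles associated per cell at time `t` for a homogeneous
#' population with association rate `r` and carrying capacity `K`, under
#' conservation of particles in a well-mixed media compartment:
#' \deqn{P(t) = V u_0 \left(1 - \frac{V u_0 - K}{V u_0 - K \exp(-r C S (V u_0 - K) t / (K V))}\right)}
#' with the separate branch
#' \deqn{P(t) = \frac{r C S K u_0 t}{K + r C S u_0 t}}
#' when `K` equals the particle supply `V u0` (selected when
#' `|V u0 - K| / (V u0)` falls below `branch_tol` to avoid catastrophic
#' cancellation).
#'
#' @param t time(s) in hours, >= 0; vectorised.
#' @param r association rate in m s^-1, >= 0.
#' @param K carrying capacity in particles cell^-1, > 0.
#' @param consts an [experiment_constants()] object.
#' @param branch_tol relative tolerance on `|V u0 - K| / (V u0)` below which
#'   the `K = V u0` branch is used.
#' @return Numeric vector of particles per cell, bounded by `min(K, V u0)`.
#' @examples
#' homogeneous_solution(c(1, 2, 4, 8, 16, 24), r = 3.86e-7, K = 10,
#'                      consts = default_constants())
#' @export
homogeneous_solution <- function(t, r, K, consts, branch_tol = 1e-9) {
  if (any(!is.finite(t)) || any(t < 0)) stop_param("times must be finite and >= 0")
  if (!is.finite(r) || r < 0) stop_param("association rate r must be >= 0")
  if (!is.finite(K) || K <= 0) stop_param("carrying capacity K must be > 0")
  ts <- t * SECONDS_PER_HOUR
  C <- consts$C; S <- consts$S; V <- consts$V; u0 <- consts$u0
  Vu0 <- V * u0
  if (abs(Vu0 - K) / Vu0 < branch_tol) {
    a <- r * C * S * u0 * ts
    return(K * a / (K + a))
  }
  ex <- exp(-r * C * S * (Vu0 - K) * ts / (K * V))
  P <- Vu0 * (1 - (Vu0 - K) / (Vu0 - K * ex))
  pmin(pmax(P, 0), min(K, Vu0))
}

# Vectorised homogeneous solution: one row per (r_i, K_i) pair, one column
# per time. Used by the media-trajectory estimator where it is evaluated for
# M trait draws on a dense grid.
hom_solution_matrix <- function(t, r, K, consts, branch_tol = 1e-9) {
  ts <- t * SECONDS_PER_HOUR
  C <- consts$C; S <- consts$S; V <- consts$V; u0 <- consts$u0
  Vu0 <- V * u0
  m <- length(r)
  P <- matrix(0, m, length(ts))
  eq <- abs(Vu0 - K) / Vu0 < branch_tol
  if (any(!eq)) {
    rr <- r[!eq]; KK <- K[!eq]
    A <- Vu0 - KK
    E <- exp(outer(-rr * C * S * A / (KK * V), ts))
    Pg <- Vu0 * (1 - A / (Vu0 - KK * E))       # A, KK recycle down columns
    P[!eq, ] <- pmin(pmax(Pg, 0), pmin(KK, Vu0))
  }
  if (any(eq)) {
    a <- outer(r[eq] * C * S * u0, ts)
    P[eq, ] <- K[eq] * a / (K[eq] + a)
  }
  P
}

#' Sample per-cell association traits
#'
#' Draws `n` independent `(r_j, K_j)` pairs from the lognormal heterogeneity
#' model: `r` and `K` lognormal with natural-scale means/SDs given by `hyper`,
#' independent of each other.
#'
#' @param hyper a [hyper_params()] object.
#' @param n number of cells (>= 1).
#' @param seed optional integer seed; the caller's RNG stream is restored
#'   afterwards. `NULL` draws from the current stream.
#' @return An object of class `"cell_traits"`: list with numeric vectors
#'   `r` and `K` of length `n`.
#' @export
sample_cell_traits <- function(hyper, n, seed = NULL) {
  hyper <- as_hyper(hyper)
  if (!is.numeric(n) || n < 1) stop_param("n must be >= 1")
  n <- as.integer(n)
  with_seed(seed, {
    pr <- lognormal_natural_params(hyper$m_r, hyper$s_r)
    pK <- lognormal_natural_params(hyper$m_K, hyper$s_K)
    structure(list(r = stats::rlnorm(n, pr[1], pr[2]),
                   K = stats::rlnorm(n, pK[1], pK[2])),
              class = "cell_traits")
  })
}

#' @export
print.cell_traits <- function(x, ...) {
  cat(sprintf("Cell traits for %d cells\n", length(x$r)))
  cat(sprintf("  r: median %.3g m/s (IQR %.3g-%.3g)\n",
              stats::median(x$r), stats::quantile(x$r, 0.25), stats::quantile(x$r, 0.75)))
  cat(sprintf("  K: median %.3g (IQR %.3g-%.3g) particles/cell\n",
              stats::median(x$K), stats::quantile(x$K, 0.25), stats::quantile(x$K, 0.75)))
  invisible(x)
}

#' Approximate media concentration trajectory
#'
#' Estimates the mean particle concentration remaining in the media,
#' `ubar(t) = u0 - mean_M[P_hom(t; r_i, K_i)] / V`, by averaging `m_eval`
#' evaluations of the homogeneous analytic solution at traits drawn from the
#' heterogeneity model, on a uniform grid of `n_grid` points over
#' `[0, t_max]`. The cumulative integral `int_0^t ubar` (needed by the
#' approximate heterogeneous solution) is accumulated with the trapezoid rule
#' and interpolated linearly at requested times.
#'
#' @param t_max final time of the grid, hours (> 0).
#' @param hyper a [hyper_params()] object.
#' @param consts an [experiment_constants()] object.
#' @param m_eval number of homogeneous evaluations averaged (default 100).
#' @param n_grid grid resolution (default 1001).
#' @param seed optional seed for the trait draws.
#' @return Object of class `"media_trajectory"`: list with `times_h`, `ubar`
#'   (particles cell^-1 m^-3) and `cumint` (particles cell^-1 m^-3 s).
#' @export
media_concentration_approx <- function(t_max, hyper, consts, m_eval = 100,
                                       n_grid = 1001, seed = NULL) {
  hyper <- as_hyper(hyper)
  if (!is.finite(t_max) || t_max <= 0) stop_param("t_max must be > 0")
  if (m_eval < 1) stop_param("m_eval must be >= 1")
  times_h <- seq(0, t_max, length.out = n_grid)
  with_seed(seed, {
    traits <- sample_cell_traits(hyper, m_eval)
    Pbar <- colMeans(hom_solution_matrix(times_h, traits$r, traits$K, consts))
    ubar <- pmax(consts$u0 - Pbar / consts$V, 0)
    dt_s <- diff(times_h) * SECONDS_PER_HOUR
    cumint <- c(0, cumsum(dt_s * (ubar[-n_grid] + ubar[-1]) / 2))
    structure(list(times_h = times_h, ubar = ubar, cumint = cumint),
              class = "media_trajectory")
  })
}

#' @export
print.media_trajectory <- function(x, ...) {
  n <- length(x$times_h)
  cat(sprintf("Media trajectory on [0, %g] h (%d grid points)\n",
              x$times_h[n], n))
  cat(sprintf("  ubar: %.4g -> %.4g particles cell^-1 m^-3\n",
              x$ubar[1], x$ubar[n]))
  invisible(x)
}

media_cumint_at <- function(media, times_h) {
  rng <- range(media$times_h)
  if (any(times_h < rng[1] - 1e-12) || any(times_h > rng[2] + 1e-9)) {
    stop_param("requested time outside the media trajectory grid [",
               rng[1], ", ", rng[2], "] h")
  }
  stats::approx(media$times_h, media$cumint, xout = pmin(times_h, rng[2]),
                rule = 1)$y
}

#' Approximate heterogeneous population solution
#'
#' Per-cell particle counts under the decoupled approximation: each cell
#' follows `P_j(t) = K_j (1 - exp(-(C S r_j / K_j) * int_0^t ubar))`, with the
#' shared media integral taken from a [media_concentration_approx()]
#' trajectory. Cost is linear in `n_cells * length(times)`, which makes it
#' usable inside simulation-based inference.
#'
#' @param times measurement times, hours; must lie within the media grid.
#' @param traits a `"cell_traits"` object.
#' @param media a `"media_trajectory"` object covering `[0, max(times)]`.
#' @param consts an [experiment_constants()] object.
#' @return Matrix of dimension `n_cells x length(times)` (class
#'   `"trajectory_set"`) with attribute `times_h`.
#' @export
heterogeneous_solution_approx <- function(times, traits, media, consts) {
  if (any(times < 0)) stop_param("times must be >= 0")
  I <- media_cumint_at(media, times)                 # [particles/cell/m^3 * s]
  a <- consts$C * consts$S * traits$r / traits$K     # [m^3 s^-1 / particles-per-cell]
  P <- traits$K * (1 - exp(-outer(a, I)))
  structure(P, times_h = times, class = c("trajectory_set", class(P)))
}

#' Full coupled heterogeneous population solution
#'
#' Numerically integrates the `N + 1` dimensional system in which every cell
#' depletes one shared media compartment:
#' \deqn{dP_j/dt = C S r_j (1 - P_j/K_j) u(t), \quad
#'       du/dt = -\frac{C S}{N V} \sum_j r_j (1 - P_j/K_j) u(t)}
#' with `P_j(0) = 0`, `u(0) = u0`. This captures cell-cell competition for
#' particles exactly (total particles `N V u + sum_j P_j` are conserved) and
#' serves as the verification oracle for
#' [heterogeneous_solution_approx()]. Intended for modest `N` (hundreds to a
#' few thousand); it reduces to the homogeneous model when all cells are
#' identical.
#'
#' @param times output times, hours (0 is added internally).
#' @param traits a `"cell_traits"` object (length `N`).
#' @param consts an [experiment_constants()] object.
#' @param rtol,atol solver tolerances passed to [deSolve::ode()].
#' @return A `"trajectory_set"` matrix `N x length(times)` with attributes
#'   `times_h` and `u` (media concentration at the output times).
#' @export
heterogeneous_solution_full <- function(times, traits, consts,
                                        rtol = 1e-8, atol = 1e-8) {
  if (any(times < 0)) stop_param("times must be >= 0")
  n <- length(traits$r)
  C <- consts$C; S <- consts$S; V <- consts$V; u0 <- consts$u0
  r <- traits$r; K <- traits$K
  t_out <- sort(unique(c(0, times))) * SECONDS_PER_HOUR
  deriv <- function(t, y, parms) {
    P <- y[seq_len(n)]
    u <- y[n + 1L]
    g <- r * pmax(1 - P / K, 0)
    dP <- C * S * g * u
    du <- -(C * S / (n * V)) * sum(g) * u
    list(c(dP, du))
  }
  sol <- deSolve::ode(y = c(rep(0, n), u0), times = t_out, func = deriv,
                      parms = NULL, method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0) {
    stop("ODE solver failed for the full heterogeneous model (istate = ",
         attr(sol, "istate")[1L], "); consider loosening tolerances",
         call. = FALSE)
  }
  idx <- match(round(times * SECONDS_PER_HOUR, 9), round(t_out, 9))
  P <- t(sol[idx, 1L + seq_len(n), drop = FALSE])
  dimnames(P) <- NULL
  structure(P, times_h = times, u = sol[idx, n + 2L],
            class = c("trajectory_set", class(P)))
}

#' Fraction of cells near their carrying capacity
#'
#' Percentage of cells whose particle load exceeds `beta` times their own
#' carrying capacity at each measurement time, `100 * #\{j : P_j(t) > beta
#' K_j\} / N`. Useful for dose optimisation: when most cells sit near
#' capacity, increasing the dose mostly wastes particles.
#'
#' @param traj a `"trajectory_set"` matrix (cells x times).
#' @param traits the `"cell_traits"` used to generate `traj`.
#' @param beta capacity fraction in (0, 1), default 0.5.
#' @return Named numeric vector of percentages, one per time point.
#' @export
fraction_near_capacity <- function(traj, traits, beta = 0.5) {
  if (!is.finite(beta) || beta <= 0 || beta >= 1) {
    stop_param("beta must lie strictly between 0 and 1")
  }
  pct <- 100 * colMeans(traj > beta * traits$K)
  names(pct) <- format(attr(traj, "times_h", exact = TRUE))
  pct
}

#' Export a trajectory set as tidy data
#'
#' @param traj a `"trajectory_set"` matrix.
#' @return data.frame with columns `cell_id`, `time_h`, `P`.
#' @export
trajectory_to_df <- function(traj) {
  times <- attr(traj, "times_h", exact = TRUE)
  data.frame(cell_id = rep(seq_len(nrow(traj)), times = ncol(traj)),
             time_h = rep(times, each = nrow(traj)),
             P = as.vector(unclass(traj)))
}

#' Export a media trajectory as tidy data
#'
#' @param media a `"media_trajectory"`.
#' @return data.frame with columns `time_h`, `ubar`, `cumint`.
#' @export
media_to_df <- function(media) {
  data.frame(time_h = media$times_h, ubar = media$ubar, cumint = media$cumint)
}
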