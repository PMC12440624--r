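# Generative flow cytometry model.
#
# A measured single-cell fluorescence value is modelled as one autofluorescence
# draw from the empirical cell-only control plus the summed fluorescence of
# the particles the cell carries, each particle drawn from the empirical
# particle-only control; a non-integer particle count contributes one extra
# draw scaled by the fractional part. All control resampling is uniform with
# replacement and independent across cells, particles and time points.

#' Empirical control data container
#'
#' Holds the cell-only control (autofluorescence of particle-free cells,
#' conceptually the `t = 0` measurement) and the particle-only control
#' (fluorescence of individual particles). Calibrated values may in principle
#' be slightly negative after instrument calibration; readers accept any
#' reals, the bundled generator emits positives.
#'
#' @param cells numeric vector of calibrated cell-only fluorescence values (AU).
#' @param particles numeric vector of calibrated single-particle fluorescence
#'   values (AU).
#' @return An object of class `"control_data"`.
#' @export
control_data <- function(cells, particles) {
  if (length(cells) < 1L || length(particles) < 1L) {
    stop_param("both control samples must be nonempty")
  }
  if (any(!is.finite(cells)) || any(!is.finite(particles))) {
    stop_param("control values must be finite")
  }
  structure(list(cells = as.numeric(cells), particles = as.numeric(particles)),
            class = "control_data")
}

#' @export
print.control_data <- function(x, ...) {
  cat(sprintf("Control data: %d cell-only values (median %.4g AU), %d particle-only values (median %.4g AU)\n",
              length(x$cells), stats::median(x$cells),
              length(x$particles), stats::median(x$particles)))
  invisible(x)
}

#' Specification of synthetic control fixtures
#'
#' Sample sizes and log-scale location/scale parameters used by
#' [generate_control_fixtures()] to emulate calibrated control measurements:
#' right-skewed, strictly positive, with single-particle fluorescence far
#' below the spread of cell autofluorescence so that individual particles
#' cannot be resolved from a single cell measurement.
#'
#' @param cells_n,particles_n sample sizes (defaults follow typical acquired
#'   control sizes: 11605 cell-only and 500000 particle-only events).
#' @param cells_meanlog,cells_sdlog log-scale location and scale of the
#'   cell-only control (defaults: median 200 AU, sdlog 0.7 - a weak,
#'   right-skewed autofluorescence background).
#' @param particles_meanlog,particles_sdlog log-scale location and scale of
#'   the particle-only control (defaults: median 30 AU, sdlog 0.5 - a single
#'   particle is unresolvable against the autofluorescence spread, while tens
#'   of labelled particles dominate the background, as in typical
#'   fluorescently labelled particle assays).
#' @return A list of class `"control_fixture_spec"`.
#' @export
control_fixture_spec <- function(cells_n = 11605, particles_n = 500000,
                                 cells_meanlog = log(200), cells_sdlog = 0.7,
                                 particles_meanlog = log(30), particles_sdlog = 0.5) {
  if (cells_n < 1 || particles_n < 1) stop_param("fixture sizes must be >= 1")
  if (cells_sdlog < 0 || particles_sdlog < 0) stop_param("sdlog values must be >= 0")
  structure(list(cells_n = as.integer(cells_n),
                 particles_n = as.integer(particles_n),
                 cells_meanlog = cells_meanlog, cells_sdlog = cells_sdlog,
                 particles_meanlog = particles_meanlog,
                 particles_sdlog = particles_sdlog),
            class = "control_fixture_spec")
}

#' Generate synthetic control data
#'
#' Draws right-skewed positive control samples (log-scale Gaussian draws)
#' emulating calibrated cell-only and particle-only flow cytometry controls.
#'
#' @param spec a [control_fixture_spec()].
#' @param seed optional integer seed.
#' @return A [control_data()] object.
#' @export
generate_control_fixtures <- function(spec = control_fixture_spec(), seed = NULL) {
  with_seed(seed, {
    control_data(
      cells = stats::rlnorm(spec$cells_n, spec$cells_meanlog, spec$cells_sdlog),
      particles = stats::rlnorm(spec$particles_n, spec$particles_meanlog,
                                spec$particles_sdlog)
    )
  })
}

#' Simulate fluorescence readings for given particle loads
#'
#' For each particle count `p >= 0`, returns one autofluorescence draw from
#' the cell-only control plus the sum of `floor(p)` single-particle draws
#' plus the fractional part of `p` times one further particle draw. All draws
#' are uniform with replacement and independent. Vectorised over `p`; a
#' scalar `p` gives a single reading.
#'
#' @param p numeric vector of particles-per-cell values, all >= 0.
#' @param controls a [control_data()] object.
#' @param seed optional integer seed.
#' @return Numeric vector of simulated fluorescence values (AU), same length
#'   as `p`.
#' @export
simulate_fluorescence <- function(p, controls, seed = NULL) {
  if (any(!is.finite(p)) || any(p < 0)) stop_param("particle loads must be >= 0")
  with_seed(seed, {
    .simulate_fluorescence_cpp(as.numeric(p), controls$cells, controls$particles)
  })
}

#' Noise-free median fluorescence for a particle load
#'
#' Deterministic counterpart of [simulate_fluorescence()] built on control
#' medians: `median(cells) + p * median(particles)`. Cell autofluorescence
#' contributes additively and particle fluorescence multiplicatively in the
#' particle count.
#'
#' @param p particles per cell, >= 0 (vectorised).
#' @param controls a [control_data()] object.
#' @return Numeric vector of fluorescence values (AU).
#' @export
median_fluorescence <- function(p, controls) {
  if (any(!is.finite(p)) || any(p < 0)) stop_param("particle loads must be >= 0")
  stats::median(controls$cells) + p * stats::median(controls$particles)
}

#' Time course dataset container
#'
#' A snapshot time series: each time point holds fluorescence measurements of
#' different cells (no cell is measured twice).
#'
#' @param times numeric vector of distinct positive time labels, hours.
#' @param samples list of numeric vectors, one per time point.
#' @return An object of class `"timecourse"`.
#' @export
timecourse <- function(times, samples) {
  if (length(times) != length(samples)) {
    stop_param("'times' and 'samples' must have equal length")
  }
  if (anyDuplicated(times)) stop_param("time labels must be distinct")
  if (any(times <= 0)) stop_param("time labels must be positive")
  o <- order(times)
  structure(list(times = as.numeric(times[o]), samples = samples[o]),
            class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf("Fluorescence time course: %d time points (h): %s\n",
              length(x$times), paste(format(x$times), collapse = ", ")))
  cat(sprintf("  sample sizes: %s\n",
              paste(vapply(x$samples, length, 1L), collapse = ", ")))
  invisible(x)
}

# Deterministic small-integer sub-seed for per-time-point noise, keyed on the
# time label so that simulating a subset of times under the same master seed
# reproduces the shared time points exactly.
time_subseed <- function(seed, t) {
  (as.integer(seed) %% 1000003L) * 1009L + (as.integer(round(t * 64)) %% 100003L)
}

#' Simulate a complete synthetic flow cytometry time course
#'
#' End-to-end generative pipeline: sample `n_cells` trait pairs from the
#' heterogeneity model, build the approximate media trajectory, evaluate the
#' per-cell particle loads at the requested times, and convert every
#' (cell, time) load to a fluorescence reading by control resampling. Cells
#' keep their trait identity across time points, but autofluorescence and
#' particle draws are fresh at every time point (snapshot data: no cell is
#' measured twice).
#'
#' When `seed` is supplied, noise at each time point uses an independent
#' sub-seed keyed on the time label, so simulating any subset of `times`
#' (with the same `seed`, `n_cells` and `t_grid_max`) reproduces the shared
#' time points exactly. This is what lets the design-search module simulate
#' once over a full candidate grid and subset later.
#'
#' @param hyper a [hyper_params()] object (or 4-vector).
#' @param consts an [experiment_constants()] object.
#' @param times measurement times, hours.
#' @param controls a [control_data()] object.
#' @param n_cells number of cells per time point (default 20000, matching
#'   typical acquisition counts).
#' @param seed optional integer seed.
#' @param t_grid_max final time of the media grid (defaults to `max(times)`;
#'   fix it to the maximum candidate time when subset-consistency across
#'   different `times` vectors is required).
#' @param m_eval media-trajectory Monte Carlo size (default 100).
#' @return A [timecourse()] with attributes `traits` (the generating
#'   `"cell_traits"`) and `P` (the noise-free `"trajectory_set"`).
#' @export
simulate_dataset <- function(hyper, consts, times, controls, n_cells = 20000,
                             seed = NULL, t_grid_max = max(times), m_eval = 100) {
  hyper <- as_hyper(hyper)
  if (length(times) < 1L) stop_param("at least one measurement time is required")
  if (n_cells < 1) stop_param("n_cells must be >= 1")
  times <- sort(as.numeric(times))
  with_seed(seed, {
    traits <- sample_cell_traits(hyper, n_cells)
    media <- media_concentration_approx(t_grid_max, hyper, consts, m_eval = m_eval)
    P <- heterogeneous_solution_approx(times, traits, media, consts)
    samples <- vector("list", length(times))
    for (i in seq_along(times)) {
      sub <- if (is.null(seed)) NULL else time_subseed(seed, times[i])
      samples[[i]] <- simulate_fluorescence(P[, i], controls, seed = sub)
    }
    tc <- timecourse(times, samples)
    attr(tc, "traits") <- traits
    attr(tc, "P") <- P
    tc
  })
}
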