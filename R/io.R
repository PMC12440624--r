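# Plain-text interchange: CSV readers/writers for fluorescence data and run
# artefacts, YAML run configuration and JSON run metadata. CSV (after FCS
# conversion) is the canonical interchange format; values round-trip at full
# double precision.

fmt_full <- function(x) formatC(x, digits = 17, format = "g")

#' Read calibrated fluorescence data from CSV
#'
#' Accepts two layouts: a control file with a single `fluorescence` column
#' (returned as a numeric vector of class `"fluorescence_sample"`), or a long
#' time-course file with `time_h` and `fluorescence` columns (returned as a
#' [timecourse()]).
#'
#' @param path CSV file path.
#' @return `"fluorescence_sample"` numeric vector or [timecourse()].
#' @export
read_fluorescence_csv <- function(path) {
  if (!file.exists(path)) stop_param("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!"fluorescence" %in% names(df)) {
    stop_param("missing required column 'fluorescence' in ", path)
  }
  fl <- suppressWarnings(as.numeric(df$fluorescence))
  if (anyNA(fl)) {
    bad <- which(is.na(fl))[1L]
    stop_param("non-numeric fluorescence value at data line ", bad, " of ", path)
  }
  if ("time_h" %in% names(df)) {
    th <- suppressWarnings(as.numeric(df$time_h))
    if (anyNA(th)) {
      bad <- which(is.na(th))[1L]
      stop_param("non-numeric time_h value at data line ", bad, " of ", path)
    }
    times <- sort(unique(th))
    return(timecourse(times, lapply(times, function(t) fl[th == t])))
  }
  structure(fl, class = "fluorescence_sample")
}

#' Write fluorescence data to CSV
#'
#' `write_control_csv()` writes a single-column `fluorescence` file;
#' `write_timecourse_csv()` writes long format (`time_h`, `fluorescence`).
#' Values are written with 17 significant digits so that a write/read
#' round-trip is bit-stable.
#'
#' @param values numeric vector of fluorescence values.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_control_csv <- function(values, path) {
  utils::write.csv(data.frame(fluorescence = fmt_full(values)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_control_csv
#' @param tc a [timecourse()].
#' @export
write_timecourse_csv <- function(tc, path) {
  df <- data.frame(
    time_h = fmt_full(rep(tc$times, vapply(tc$samples, length, 1L))),
    fluorescence = fmt_full(unlist(tc$samples)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an ABC posterior to CSV
#'
#' One row per particle: the four hyperparameters, the normalised weight and
#' the achieved distance.
#'
#' @param fit an `"abcsmc"` fit.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_posterior_csv <- function(fit, path) {
  df <- as.data.frame(fit$theta)
  df$weight <- fit$weights
  df$distance <- fit$distances
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write run metadata as JSON
#'
#' Records everything needed to reproduce an artefact: the seed, the resolved
#' configuration and (optionally) the threshold history of an SMC run.
#'
#' @param path output file path.
#' @param seed integer seed of the run.
#' @param config named list of resolved configuration values.
#' @param ... further named fields (e.g. `threshold_history`).
#' @return Invisibly, `path`.
#' @export
write_run_metadata <- function(path, seed, config = list(), ...) {
  meta <- c(list(seed = seed, config = config,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 package_version = as.character(utils::packageVersion("hetassoc"))),
            list(...))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML configuration with optional blocks `constants` (C, S, V, u0),
#' `prior` (per-hyperparameter `[lower, upper]`), `abc` (n_particles,
#' target_threshold, max_generations, distance, n_cells), `design`
#' (candidates, k, n_pre, j_reps, cv, n_accept), `fixtures`
#' (control fixture spec fields) and `seed`. Missing blocks fall back to the
#' package defaults.
#'
#' @param path YAML file path (`NULL` returns the defaults).
#' @return list of class `"run_config"` with fully resolved components:
#'   `constants` ([experiment_constants()]), `prior` ([prior_box()]), `abc`,
#'   `design`, `fixtures` ([control_fixture_spec()]), `seed`.
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  cn <- raw$constants %||% list()
  consts <- experiment_constants(
    C = cn$C %||% 0.3, S = cn$S %||% 4.5e-10,
    V = cn$V %||% 1e-10, u0 = cn$u0 %||% 1e13)
  pr <- raw$prior %||% list()
  dp <- default_prior()
  prior <- prior_box(
    m_r = unlist(pr$m_r %||% dp["m_r", ]),
    s_r = unlist(pr$s_r %||% dp["s_r", ]),
    m_K = unlist(pr$m_K %||% dp["m_K", ]),
    s_K = unlist(pr$s_K %||% dp["s_K", ]))
  ab <- raw$abc %||% list()
  abc <- list(n_particles = ab$n_particles %||% 1000,
              n_cells = ab$n_cells,
              target_threshold = ab$target_threshold,
              target_quantile = ab$target_quantile %||% 0.01,
              max_generations = ab$max_generations %||% 20,
              distance = ab$distance %||% "ad")
  dg <- raw$design %||% list()
  design <- list(candidates = unlist(dg$candidates %||% default_candidate_times()),
                 k = dg$k %||% 6, n_pre = dg$n_pre %||% 2000,
                 j_reps = dg$j_reps %||% 5, cv = dg$cv %||% 0.1,
                 n_accept = dg$n_accept %||% 200,
                 n_cells = dg$n_cells %||% 1000)
  fx <- raw$fixtures %||% list()
  fixtures <- control_fixture_spec(
    cells_n = fx$cells_n %||% 11605,
    particles_n = fx$particles_n %||% 500000,
    cells_meanlog = fx$cells_meanlog %||% log(200),
    cells_sdlog = fx$cells_sdlog %||% 0.7,
    particles_meanlog = fx$particles_meanlog %||% log(30),
    particles_sdlog = fx$particles_sdlog %||% 0.5)
  structure(list(constants = consts, prior = prior, abc = abc, design = design,
                 fixtures = fixtures, seed = raw$seed %||% 1L),
            class = "run_config")
}
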