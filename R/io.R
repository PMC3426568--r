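#' Load a run configuration from a YAML file
#'
#' Reads a human-editable YAML description of a full run — network size and
#' model parameters, stimulus, noise, diversity, integration and metric
#' settings — validates every field against the owning type's invariants,
#' and fills defaults for anything omitted. An empty file yields the complete
#' default configuration (N = 20, T_day = 24000 ms, f_w = 2/3).
#'
#' Recognized top-level keys: `network` (`N`, `params`), `stimulus`
#' (`delta_I`, `delta_T`, `period`, `enabled`), `noise` (`D_A`, `D_B`),
#' `diversity` (`site`, `mean`, `width`, `seed`), `integration` (`dt`,
#' `n_periods`, `duration`, `seed`), `metric` (`f_w`, `gap`,
#' `skip_periods`), `output_dir`.
#'
#' @param path Path to a YAML file.
#' @return A list of class `somnox_runconfig` with elements `config` (a
#'   [network_config()]), `integration`, `metric`, and `output_dir`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("network", "stimulus", "noise", "diversity", "integration",
             "metric", "output_dir")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))

  take <- function(block, fields) {
    x <- raw[[block]]
    if (is.null(x)) return(list())
    # YAML 1.1 parses a bare `N:` key as boolean FALSE; map it back
    names(x)[names(x) == "FALSE"] <- "N"
    extra <- setdiff(names(x), fields)
    if (length(extra))
      stop("unknown field(s) in '", block, "': ",
           paste(extra, collapse = ", "))
    x
  }
  net <- take("network", c("N", "params"))
  params <- do.call(model_params, as.list(net$params))
  stim <- do.call(stimulus_spec, take("stimulus",
                                      c("delta_I", "delta_T", "period",
                                        "enabled", "waveform")))
  noise <- do.call(noise_spec, take("noise", c("D_A", "D_B")))
  div <- do.call(diversity_spec, take("diversity",
                                      c("site", "mean", "width", "seed")))
  config <- network_config(N = if (is.null(net$N)) 20 else net$N,
                           params = params, stimulus = stim, noise = noise,
                           diversity = div)
  integ <- utils::modifyList(list(dt = 0.1, n_periods = 10, duration = NULL,
                                  seed = 1L),
                             take("integration",
                                  c("dt", "n_periods", "duration", "seed")))
  metric <- utils::modifyList(list(f_w = 2 / 3, gap = 150, skip_periods = 1),
                              take("metric", c("f_w", "gap", "skip_periods")))
  if (!(metric$f_w > 0 && metric$f_w < 1)) stop("metric f_w must lie in (0, 1)")
  structure(list(config = config, integration = integ, metric = metric,
                 output_dir = raw$output_dir %||% "."),
            class = "somnox_runconfig")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# strip a config down to plain lists for JSON echoing
config_as_list <- function(config) {
  list(N = config$N,
       params = unclass(config$params),
       stimulus = unclass(config$stimulus),
       noise = unclass(config$noise),
       diversity = unclass(config$diversity),
       thresholds_BA = config$thresholds_BA,
       thresholds_AB = config$thresholds_AB)
}

#' Write simulation and metric outputs to a directory
#'
#' Writes `spikes.csv` (`neuron_id`, `t_ms`), `qreport.csv` (one row per
#' retained period: `period`, `W_day_ms`, `W_night_ms`, plus a single-row
#' `qsummary.csv` with `Q`, `f_w`, `T`, `n_periods`), a JSON configuration
#' echo (`config.json`, including the master seed), and a short run log.
#'
#' @param record A `somnox_sim` from [run_simulation()].
#' @param report Optional `somnox_qreport` from [quality_coefficient()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_outputs <- function(record, report = NULL, dir = ".") {
  stopifnot(inherits(record, "somnox_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character()
  f <- file.path(dir, "spikes.csv")
  readr::write_csv(record$spikes, f)
  files <- c(files, f)
  echo <- c(config_as_list(record$config),
            list(dt = record$dt, t0 = record$t0, duration = record$duration,
                 seed = record$seed))
  f <- file.path(dir, "config.json")
  jsonlite::write_json(echo, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, f)
  if (!is.null(report)) {
    stopifnot(inherits(report, "somnox_qreport"))
    f <- file.path(dir, "qreport.csv")
    readr::write_csv(report$periods, f)
    files <- c(files, f)
    f <- file.path(dir, "qsummary.csv")
    readr::write_csv(tibble::tibble(Q = report$Q, f_w = report$f_w,
                                    T = report$T,
                                    n_periods = nrow(report$periods)), f)
    files <- c(files, f)
  }
  f <- file.path(dir, "run.log")
  writeLines(c(sprintf("somnox %s", as.character(utils::packageVersion("somnox"))),
               sprintf("R %s", getRversion()),
               sprintf("seed %d", record$seed),
               sprintf("duration %g ms, dt %g ms", record$duration,
                       record$dt),
               sprintf("spikes %d", nrow(record$spikes))), f)
  files <- c(files, f)
  invisible(files)
}

#' Read a spike table written by [write_outputs()]
#' @param path Path to a `spikes.csv` file.
#' @return A tibble with columns `neuron_id` (character) and `t_ms`.
#' @export
read_spikes <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    neuron_id = readr::col_character(), t_ms = readr::col_double()))
}

#' Export / import a quenched threshold realization
#'
#' Two-column CSV (`neuron_id`, `theta_mV`) so a diversity sweep can be
#' replayed exactly.
#'
#' @param thresholds Numeric vector of thresholds (mV).
#' @param path Output CSV path.
#' @return `write_thresholds`: invisibly, `path`. `read_thresholds`: the
#'   numeric threshold vector, named by neuron id.
#' @export
write_thresholds <- function(thresholds, path) {
  readr::write_csv(tibble::tibble(
    neuron_id = paste0("A", seq_along(thresholds) - 1),
    theta_mV = thresholds), path)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    neuron_id = readr::col_character(), theta_mV = readr::col_double()))
  stats::setNames(df$theta_mV, df$neuron_id)
}

#' Write sweep results
#'
#' Writes `q_curve.csv` (`kind`, `value`, `seed`, `Q`, `periodicity`,
#' `night_wake_ms`) plus a JSON manifest with the reference configuration
#' echo.
#'
#' @param sweep A `somnox_sweep` from [sweep_disorder()].
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_sweep <- function(sweep, dir = ".") {
  stopifnot(inherits(sweep, "somnox_sweep"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f1 <- file.path(dir, "q_curve.csv")
  readr::write_csv(sweep$results, f1)
  f2 <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(kind = sweep$kind,
                            config = config_as_list(sweep$config)),
                       f2, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(f1, f2))
}
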