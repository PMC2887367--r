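log_schema <- c("t", "target_x", "target_y", "hand_x", "hand_y",
                "field_on", "catch", "phase", "lap")

#' Read and write trajectory logs
#'
#' Trajectory logs are plain CSV with one row per 100 Hz sample and columns
#' `t, target_x, target_y, hand_x, hand_y, field_on, catch, phase, lap`
#' (SI units; extra columns such as the target phase angle `alpha` are
#' preserved). Comment lines at the top of the file (`# key: value`) carry
#' the seed and a fingerprint of the generating configuration for
#' provenance. Reading validates the schema, the strict 1/fs time spacing
#' and the monotone lap counter, and fails with the offending column or row.
#'
#' @param path File path.
#' @param fs Expected sampling rate (Hz) used to validate time spacing.
#' @return `read_trajectory_log()` returns a `trajectory_log` tibble;
#'   `write_trajectory_log()` returns `path` invisibly.
#' @export
read_trajectory_log <- function(path, fs = 100) {
  hdr <- character(0)
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line) || !startsWith(line, "#")) break
    hdr <- c(hdr, line)
  }
  close(con); on.exit(NULL)
  log <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  missing <- setdiff(log_schema, names(log))
  if (length(missing))
    abort(paste0("log is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  dtv <- diff(log$t)
  bad <- which(abs(dtv - 1 / fs) > 0.25 / fs)
  if (length(bad))
    abort(sprintf(
      "non-uniform time base: gap of %.4f s between rows %d and %d (expected %.4f s).",
      dtv[bad[1]], bad[1], bad[1] + 1, 1 / fs))
  if (is.unsorted(log$lap))
    abort("lap counter is not non-decreasing.")
  meta <- parse_header(hdr)
  log$lap <- as.integer(log$lap)
  log$field_on <- as.integer(log$field_on)
  log$catch <- as.integer(log$catch)
  class(log) <- c("trajectory_log", class(log))
  attr(log, "seed") <- meta$seed
  attr(log, "fingerprint") <- meta$fingerprint
  log
}

#' @rdname read_trajectory_log
#' @param log A `trajectory_log`.
#' @export
write_trajectory_log <- function(log, path) {
  seed <- attr(log, "seed")
  fp <- attr(log, "fingerprint") %||% config_fingerprint(attr(log, "cfg"),
                                                         attr(log, "params"))
  hdr <- c(sprintf("# seed: %s", seed %||% "NA"),
           sprintf("# fingerprint: %s", fp))
  writeLines(hdr, path)
  cols <- c(log_schema, setdiff(names(log), log_schema))
  readr::write_csv(as_tibble(log)[, cols], path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

parse_header <- function(lines) {
  get <- function(key) {
    hit <- grep(paste0("^#\\s*", key, ":"), lines, value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1]))
  }
  seed <- get("seed")
  list(seed = if (!is.null(seed) && seed != "NA") as.integer(seed),
       fingerprint = get("fingerprint"))
}

config_fingerprint <- function(cfg, params = NULL) {
  if (is.null(cfg)) return("unknown")
  payload <- paste(
    paste(names(unclass(cfg)), unlist(unclass(cfg)), sep = "=",
          collapse = ";"),
    if (!is.null(params))
      paste(names(unclass(params)), unlist(unclass(params)), sep = "=",
            collapse = ";"),
    sep = "|")
  # short stable fingerprint without extra dependencies
  sprintf("%08x", sum(utf8ToInt(payload) * (seq_along(utf8ToInt(payload)) %% 251 + 1)) %% .Machine$integer.max)
}

#' Run the full analysis pipeline
#'
#' Simulates a session (or loads an existing log), computes kinematics and
#' the per-lap indicator table, decomposes the catch trials, fits the
#' per-phase learning curves, and writes `trajectory_log.csv`,
#' `lap_metrics.csv` and a versioned `report.json` to `out_dir`. The report
#' echoes the configuration and seed for provenance and names indicators
#' with the conventional symbols (DUR, NP, delta, delta_l, delta_n, FE, CC,
#' PAC, FMC); lengths are reported in meters in the tables and the report.
#'
#' @param config_path Path to a YAML configuration file ([read_config()]);
#'   `NULL` uses all defaults.
#' @param out_dir Output directory, created if needed; `NULL` writes no
#'   files and only returns the report list.
#' @param log An existing `trajectory_log` to analyse instead of
#'   simulating.
#' @return The report as a list, invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(config_path = NULL, out_dir = NULL, log = NULL) {
  conf <- if (is.null(config_path))
    list(task = task_config(), subject = subject_params(),
         protocol = session_protocol())
  else read_config(config_path)

  if (is.null(log)) {
    log <- simulate_session(conf$protocol, conf$subject, conf$task)
  } else {
    attr(log, "cfg") <- attr(log, "cfg") %||% conf$task
    attr(log, "protocol") <- attr(log, "protocol") %||% conf$protocol
  }
  cfg <- attr(log, "cfg")

  laps <- lap_table(log, cfg)
  phases <- phase_summary(laps)

  trials <- extract_catch_trials(log, cfg = cfg)
  decomp <- if (nrow(trials)) decompose_forces(trials) else NULL
  pac <- if (!is.null(decomp) && sum(decomp$valid) >= 2)
    aggregate_pac(decomp) else NULL

  fits <- lapply(split(laps, phase_group(laps$phase)), function(d) {
    d <- dplyr::filter(d, .data$proper)
    if (nrow(d) < 5) return(NULL)
    fit_learning_curve(d$delta, seq_len(nrow(d)) - 1)
  })
  fits <- fits[!vapply(fits, is.null, TRUE)]

  report <- list(
    schema_version = "1.0",
    seed = attr(log, "seed"),
    fingerprint = config_fingerprint(cfg, attr(log, "params")),
    config = list(task = unclass(cfg),
                  subject = if (!is.null(attr(log, "params")))
                    unclass(attr(log, "params"))),
    phase_summary = phases,
    catch_trials = if (!is.null(decomp)) as_tibble(decomp),
    force_control = pac,
    learning = lapply(fits, function(f)
      list(A0 = f$A0, A1 = f$A1, tau = f$tau, r2 = f$r2,
           n_laps = f$n_laps, converged = f$converged))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trajectory_log(log, file.path(out_dir, "trajectory_log.csv"))
    readr::write_csv(as_tibble(laps), file.path(out_dir, "lap_metrics.csv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", na = "null")
    return(invisible(report))
  }
  report
}

# FA1/FA2 -> FA etc., so learning curves span both sets of a condition
phase_group <- function(phase) sub("[0-9]+$", "", phase)
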