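# File interfaces: waveform CSVs (`time_s,flow_ml_s`), velocity CSVs
# (`time_s,velocity_cm_s`), measurement bundles (JSON + waveform CSVs),
# YAML run configuration, and the end-to-end pipeline driver.

#' Read / write a flow-waveform CSV
#'
#' Two-column numeric CSV with header `time_s,flow_ml_s`; round-trips at full
#' stored precision. Malformed rows are reported with their line numbers.
#'
#' @param path file path.
#' @param site site tag for the waveform.
#' @param T_cycle cycle length (s).
#' @param w a [flow_waveform()] (writer).
#' @return the reader returns a [flow_waveform()]; the writer returns `path`
#'   invisibly.
#' @export
read_waveform_csv <- function(path, site, T_cycle) {
  if (!file.exists(path)) stop_hemofit("no such file: %s", path)
  lines <- readLines(path)
  if (length(lines) < 2) stop_hemofit("empty or header-only waveform file: %s", path)
  if (trimws(lines[1]) != "time_s,flow_ml_s")
    stop_hemofit("bad header '%s'; expected 'time_s,flow_ml_s'", trimws(lines[1]))
  parts <- strsplit(lines[-1], ",", fixed = TRUE)
  bad <- which(vapply(parts, function(p)
    length(p) != 2 || anyNA(suppressWarnings(as.numeric(p))), TRUE))
  if (length(bad))
    stop_hemofit("malformed waveform row(s) at line(s): %s",
                 paste(bad + 1, collapse = ", "))
  m <- do.call(rbind, lapply(parts, as.numeric))
  flow_waveform(site, m[, 1], m[, 2], T_cycle)
}

#' @rdname read_waveform_csv
#' @export
write_waveform_csv <- function(w, path) {
  stopifnot(inherits(w, "flow_waveform"))
  df <- data.frame(time_s = w$time, flow_ml_s = w$flow)
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a measurement bundle
#'
#' One JSON file per occasion holding the scalars, plus one waveform CSV per
#' site (`<stem>_<site>.csv`) and, when present, a velocity CSV
#' (`<stem>_velocity.csv`).
#'
#' @param bundle a [measurement_bundle()].
#' @param stem output path stem (no extension).
#' @param path path to the JSON file (reader).
#' @return the writer returns the JSON path invisibly; the reader a
#'   [measurement_bundle()].
#' @export
write_bundle <- function(bundle, stem) {
  stopifnot(inherits(bundle, "measurement_bundle"))
  sites <- names(bundle$waveforms)
  for (s in sites)
    write_waveform_csv(bundle$waveforms[[s]], paste0(stem, "_", s, ".csv"))
  if (!is.null(bundle$velocity)) {
    df <- data.frame(time_s = bundle$velocity$time,
                     velocity_cm_s = bundle$velocity$velocity)
    utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     paste0(stem, "_velocity.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  meta <- list(subject_id = bundle$subject_id, occasion = bundle$occasion,
               T_cycle = bundle$T_cycle, esv = bundle$esv, eoa = bundle$eoa,
               a_lvot = bundle$a_lvot, sbp = bundle$sbp, dbp = bundle$dbp,
               waveform_files = stats::setNames(
                 as.list(paste0(basename(stem), "_", sites, ".csv")), sites),
               velocity_file = if (is.null(bundle$velocity)) NULL else
                 paste0(basename(stem), "_velocity.csv"))
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paste0(stem, ".json"))
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  dir <- dirname(path)
  waveforms <- lapply(stats::setNames(nm = names(meta$waveform_files)),
    function(s) read_waveform_csv(file.path(dir, meta$waveform_files[[s]]),
                                  s, meta$T_cycle))
  velocity <- NULL
  if (!is.null(meta$velocity_file)) {
    vv <- utils::read.csv(file.path(dir, meta$velocity_file))
    velocity <- velocity_trace(vv$time_s, vv$velocity_cm_s)
  }
  measurement_bundle(meta$subject_id, meta$occasion, meta$T_cycle, meta$esv,
                     meta$eoa, meta$a_lvot, meta$sbp, meta$dbp, waveforms,
                     velocity)
}

.CONFIG_KEYS <- c("out_dir", "seed", "n_subjects", "n_starts", "maxiter",
                  "periodicity_tol", "n_cycles_max", "sensitivity_grid",
                  "comparisons")

#' Read and validate a pipeline run configuration (YAML)
#'
#' Strict schema: unknown keys are rejected, a seed is mandatory (no implicit
#' nondeterminism), everything else has defaults.
#'
#' @param path YAML file, or `NULL` for pure defaults plus `overrides`.
#' @param overrides named list overriding file values.
#' @return a validated `run_config` list.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  unknown <- setdiff(names(cfg), .CONFIG_KEYS)
  if (length(unknown))
    stop_hemofit("unknown config key(s): %s", paste(unknown, collapse = ", "))
  if (is.null(cfg$seed))
    stop_hemofit("config must set an integer 'seed'")
  defaults <- list(out_dir = "results", n_subjects = 10, n_starts = 1,
                   maxiter = 40, periodicity_tol = 1e-3, n_cycles_max = 30,
                   sensitivity_grid = seq(-0.10, 0.10, by = 0.025),
                   comparisons = c("intra", "inter", "sequence"))
  for (nm in names(defaults)) cfg[[nm]] <- cfg[[nm]] %||% defaults[[nm]]
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Run the full personalization-and-repeatability pipeline
#'
#' Cohort generation, per-occasion parameter estimation, one variability
#' report per comparison, and the input sensitivity sweep, with all artifacts
#' written under `config$out_dir` together with a manifest recording the
#' package version, seeds and MD5 hashes of every output file.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return file path of the manifest, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- "cohort"
  res <- tryCatch({
    say("[cohort] generating %d subjects (seed %d)", config$n_subjects,
        config$seed)
    cohort <- build_cohort(config$n_subjects, seed = config$seed)
    for (s in cohort$subjects)
      for (b in s$bundles)
        write_bundle(b, file.path(out, sprintf("%s_%s", b$subject_id,
                                               b$occasion)))
    stage <- "estimation"
    occ <- unique(unlist(.COMPARISONS[config$comparisons]))
    say("[estimation] fitting %d occasions x %d subjects", length(occ),
        config$n_subjects)
    est <- fit_cohort(cohort, occasions = occ, seed = config$seed,
                      n_starts = config$n_starts, maxiter = config$maxiter)
    stage <- "variability"
    for (cmp in config$comparisons) {
      rep <- run_variability_study(cohort, cmp, estimates = est)
      write_report_csv(rep, file.path(out, paste0("variability_", cmp, ".csv")))
    }
    stage <- "sensitivity"
    base <- cohort$subjects[[1]]$truth
    sens <- do.call(rbind, lapply(c("eoa", "a_lvot", "lv_emax"), function(nm)
      sweep_input(base, nm, grid = config$sensitivity_grid)$table))
    utils::write.csv(sens, file.path(out, "sensitivity.csv"),
                     row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (inherits(res, "error")) {
    writeLines(sprintf("FAILED at stage '%s': %s", stage,
                       conditionMessage(res)),
               file.path(out, "FAILED"))
    stop_hemofit("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(res))
  }
  files <- sort(setdiff(list.files(out, full.names = TRUE),
                        file.path(out, "manifest.json")))
  manifest <- list(
    package = "hemofit",
    version = as.character(utils::packageVersion("hemofit")),
    seed = config$seed, n_subjects = config$n_subjects,
    n_starts = config$n_starts,
    hashes = as.list(stats::setNames(unname(tools::md5sum(files)),
                                     basename(files))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("[done] manifest written")
  invisible(file.path(out, "manifest.json"))
}
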