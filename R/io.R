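# condition helpers: validation problems carry class "conch_validation_error"
# so the command-line layer can map them to exit code 2
validation_error <- function(...) {
  stop(structure(class = c("conch_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

normalize_headers <- function(x) {
  x <- tolower(trimws(x))
  gsub("[ .]+", "_", x)
}

check_columns <- function(df, required, file, strict) {
  if (!strict) names(df) <- normalize_headers(names(df))
  missing <- setdiff(required, names(df))
  if (length(missing))
    validation_error("file ", file, ": missing column(s) ",
                     paste(missing, collapse = ", "))
  df
}

check_range <- function(df, col, file, lo = -Inf, hi = Inf,
                        strict_lo = FALSE, allow_na = FALSE) {
  v <- df[[col]]
  if (!is.numeric(v))
    validation_error("file ", file, ", column ", col, ": not numeric")
  bad <- if (strict_lo) v <= lo | v > hi else v < lo | v > hi
  if (allow_na) bad <- bad & !is.na(v) else bad <- bad | is.na(v)
  if (any(bad))
    validation_error("file ", file, ", column ", col, ", row ",
                     which(bad)[1], ": value ", v[which(bad)[1]],
                     " out of range [", lo, ", ", hi, "]")
  invisible(df)
}

obs_columns <- c("source", "density_per_ha", "pct_mating")
results_columns <- c("design_index", "density", "speed", "rest", "tracking",
                     "pd_max", "tau", "barrier", "mean_pct_mating",
                     "ci_lo", "ci_hi", "mean_pct_spawning", "sp_ci_lo",
                     "sp_ci_hi", "replicates")

#' Read an observations table
#'
#' CSV with columns `source`, `density_per_ha`, `pct_mating` and optional
#' `pct_spawning`.  Validation rejects non-positive densities and
#' percentages outside `[0, 100]`, naming the offending row and column.
#' With `strict = FALSE`, header case/spacing variants are normalised to
#' the canonical names; with `strict = TRUE` they are rejected.
#'
#' @param path CSV file path.
#' @param strict Require exact canonical headers.
#' @return Validated data.frame.
#' @export
read_observations <- function(path, strict = TRUE) {
  if (!file.exists(path)) validation_error("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  df <- check_columns(df, obs_columns, path, strict)
  check_range(df, "density_per_ha", path, lo = 0, strict_lo = TRUE)
  check_range(df, "pct_mating", path, lo = 0, hi = 100)
  if ("pct_spawning" %in% names(df))
    check_range(df, "pct_spawning", path, lo = 0, hi = 100,
                allow_na = TRUE)
  df
}

#' Write an observations table
#' @param observations data.frame to write.
#' @param path Output CSV path.
#' @export
write_observations <- function(observations, path) {
  write_table_full_precision(observations, path)
}

#' Read a design-results table
#' @param path CSV file path.
#' @param strict Require exact canonical headers.
#' @return Validated data.frame.
#' @export
read_results <- function(path, strict = TRUE) {
  if (!file.exists(path)) validation_error("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  df <- check_columns(df, results_columns, path, strict)
  check_range(df, "density", path, lo = 0, strict_lo = TRUE)
  check_range(df, "mean_pct_mating", path, lo = 0, hi = 100)
  check_range(df, "mean_pct_spawning", path, lo = 0, hi = 100)
  df
}

#' Write a design-results table
#' @param results data.frame from [run_design()].
#' @param path Output CSV path.
#' @export
write_results <- function(results, path) {
  write_table_full_precision(results, path)
}

#' Write an event ledger
#'
#' One row per event: `replicate`, `day`, `type` (`mating`/`spawn`),
#' `male_id`, `female_id`.
#'
#' @param run A `conch_run` (with events kept).
#' @param path Output CSV path.
#' @param replicate Replicate number recorded in the ledger.
#' @export
write_events <- function(run, path, replicate = 1L) {
  stopifnot(inherits(run, "conch_run"))
  if (is.null(run$events))
    stop("run was executed with keep_events = FALSE")
  ev <- data.frame(replicate = replicate, day = run$events$day,
                   type = "mating", male_id = run$events$male_id,
                   female_id = run$events$female_id)
  if (nrow(run$spawns)) {
    ev <- rbind(ev, data.frame(replicate = replicate, day = run$spawns$day,
                               type = "spawn", male_id = NA_integer_,
                               female_id = run$spawns$female_id))
  }
  write_table_full_precision(ev, path)
}

# CSV writer preserving doubles to full precision (round-trip <= 1e-15
# relative)
write_table_full_precision <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  out <- df
  for (j in which(num)) out[[j]] <- sprintf("%.17g", df[[j]])
  write.csv(out, path, row.names = FALSE, quote = which(!num & vapply(df, is.character, TRUE)))
  invisible(path)
}

#' Read a run configuration (YAML or JSON)
#'
#' The file mirrors [run_config()] fields plus optional factor levels for
#' [build_design_grid()] under a `factors` entry.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return List with `config` (a `conch_config`) and `factors` (list of
#'   level vectors, possibly empty).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) validation_error("file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
  cfg_fields <- intersect(names(raw), c("arena_side", "days", "replicates",
                                        "spawn_delay", "mating_metric",
                                        "base_seed"))
  cfg <- do.call(run_config, raw[cfg_fields])
  factors <- raw$factors
  if (is.null(factors)) factors <- list()
  list(config = cfg, factors = factors)
}

#' Write a run configuration
#' @param config A `conch_config`.
#' @param path Output path (`.yaml`/`.yml` or `.json`).
#' @param factors Optional factor-level list stored alongside.
#' @export
write_run_config <- function(config, path, factors = NULL) {
  x <- unclass(config)
  if (!is.null(factors)) x$factors <- factors
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(x, path)
  else
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(path)
}
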