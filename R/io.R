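# File plumbing: the beat-record CSV dialect, subject sidecars, and the
# trend/event/profile outputs. One documented CSV dialect is used throughout:
# header `t,hr,sbp,dbp,mbp,lvet,pep,z0,dzmax,trc`, one row per beat, empty
# cell = recording gap, UTF-8, decimal point.

BEAT_COLUMNS <- c("t", "hr", "sbp", "dbp", "mbp", "lvet", "pep",
                  "z0", "dzmax", "trc")

#' Read / write beat-record CSV files
#'
#' `read_beats()` reads the package's beat-record dialect (columns
#' `t, hr, sbp, dbp, mbp, lvet, pep, z0, dzmax, trc`, optional derived
#' columns; empty cells are gaps) and validates the basic record invariants
#' (strictly increasing times, positive HR/LVET/Z0, SBP >= DBP where both
#' present). `write_beats()` writes the same dialect, stamping a provenance
#' comment line.
#'
#' @param path CSV file path.
#' @param records Data frame of beat records.
#' @return `read_beats()` returns a data frame; `write_beats()` returns
#'   `path` invisibly.
#' @export
read_beats <- function(path) {
  .check(file.exists(path), paste("input file not found:", path))
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  missing_cols <- setdiff(BEAT_COLUMNS, names(df))
  .check(length(missing_cols) == 0,
         paste("malformed beat CSV, missing column(s):",
               paste(missing_cols, collapse = ", ")))
  for (cn in names(df)) {
    if (!is.numeric(df[[cn]])) {
      suppressWarnings(v <- as.numeric(df[[cn]]))
      bad <- which(!is.na(df[[cn]]) & df[[cn]] != "" & is.na(v))
      .check(length(bad) == 0,
             sprintf("malformed value in column '%s' at data row %d", cn, bad[1]))
      df[[cn]] <- v
    }
  }
  .check(all(diff(df$t) > 0), "beat times must be strictly increasing")
  .check(!.bad(df$hr, function(v) v <= 0), "hr must be positive")
  .check(!.bad(df$lvet, function(v) v <= 0), "lvet must be positive")
  .check(!.bad(df$z0, function(v) v <= 0), "z0 must be positive")
  both <- !is.na(df$sbp) & !is.na(df$dbp)
  .check(all(df$sbp[both] >= df$dbp[both]), "sbp must be >= dbp where both present")
  df
}

provenance_line <- function(config = NULL, seed = NULL) {
  sprintf("# qctrends %s%s%s",
          as.character(packageVersion("qctrends")),
          if (!is.null(seed)) sprintf(" seed=%s", format(seed)) else "",
          if (!is.null(config)) sprintf(" config=%s", config_hash(config)) else "")
}

#' @rdname read_beats
#' @param config,seed Optional provenance information stamped into the header.
#' @export
write_beats <- function(records, path, config = NULL, seed = NULL) {
  .check(is.data.frame(records), "records must be a data frame")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_line(config, seed), con)
  write.csv(records, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a subject sidecar file
#'
#' Subject metadata (weight, height, sex, optional `cvp_assumed` and
#' `vept_correction`) from a YAML or JSON sidecar.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A [qct_subject()].
#' @export
read_subject <- function(path) {
  .check(file.exists(path), paste("subject file not found:", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  # JSON parsers may hand back integers; the subject fields are doubles
  qct_subject(weight = as.numeric(raw$weight), height = as.numeric(raw$height),
              sex = raw$sex,
              cvp = if (is.null(raw$cvp_assumed)) 6
                    else as.numeric(raw$cvp_assumed),
              vept_correction = if (is.null(raw$vept_correction)) 1
                                else as.numeric(raw$vept_correction))
}

#' Write a subject sidecar file
#'
#' @param subject A [qct_subject()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_subject <- function(subject, path) {
  .check(inherits(subject, "qct_subject"), "subject must be a qct_subject")
  yaml::write_yaml(list(weight = subject$weight, height = subject$height,
                        sex = subject$sex, cvp_assumed = subject$cvp,
                        vept_correction = subject$vept_correction), path)
  invisible(path)
}

#' Write a complexity trend as CSV
#'
#' One row per window: `window_index`, `window_end_time`, `C`, `C_min`,
#' `C_critical`, `n_beats_used`, followed by the per-variable profile
#' percentage columns. A provenance comment line (package version, seed,
#' config hash) heads the file.
#'
#' @param fit A `qct_trend` from [qct()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trend_csv <- function(fit, path) {
  .check(inherits(fit, "qct_trend"), "fit must be a qct_trend")
  df <- as.data.frame(fit)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_line(fit$config, fit$seed), con)
  write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Write event annotations as JSON
#'
#' @param events A list of event annotations (each with `kind`, `time`,
#'   `detail`), e.g. from [detect_surge()] / [reference_events()].
#' @param path Output JSON path.
#' @param config,seed Optional provenance information.
#' @return `path`, invisibly.
#' @export
write_events_json <- function(events, path, config = NULL, seed = NULL) {
  events <- events[!vapply(events, is.null, logical(1))]
  payload <- list(
    provenance = list(package = "qctrends",
                      version = as.character(packageVersion("qctrends")),
                      seed = seed,
                      config = if (is.null(config)) NULL else config_hash(config)),
    events = lapply(unname(events), function(e)
      list(kind = e$kind, time = e$time, detail = e$detail)))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}
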