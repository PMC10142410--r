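# Subject-table readers and writers. Canonical dialect: comma-delimited,
# dot-decimal CSV with the schema header
#   subject_id, sbp, dbp, pep_ms, et_ms, sv_ml, edv_ref_ml
# (edv_ref_ml optional). Header matching is case-insensitive; unparseable
# numeric cells are flagged per row, never silently coerced.

SUBJECT_COLUMNS <- c("subject_id", "sbp", "dbp", "pep_ms", "et_ms", "sv_ml",
                     "edv_ref_ml")
REQUIRED_COLUMNS <- SUBJECT_COLUMNS[1:6]

#' Read a subject table from delimited text
#'
#' @param path File path.
#' @param delim Field delimiter: `","` (canonical) or `"\t"`.
#' @param timings_seconds If `TRUE`, `pep_ms` and `et_ms` in the file are in
#'   seconds and are converted to milliseconds on read.
#' @return A data frame of class `subject_table` with the canonical columns;
#'   rows whose numeric cells fail to parse carry `flag = "unparseable"`,
#'   rows with empty required cells carry `flag = "missing data"` (routed to
#'   [apply_exclusions()] downstream). Attribute `provenance` records the
#'   source file and row count.
#' @export
read_subjects <- function(path, delim = ",", timings_seconds = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- tryCatch(
    utils::read.table(path, sep = delim, header = TRUE,
                      colClasses = "character", strip.white = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        stop(sprintf("empty file: %s", path), call. = FALSE)
      }
      stop(e)
    }
  )
  found <- names(raw)
  names(raw) <- tolower(found)
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop(sprintf("schema error: missing column(s) %s; header found: %s",
                 paste(missing_cols, collapse = ", "),
                 paste(found, collapse = ", ")), call. = FALSE)
  }
  if (!"edv_ref_ml" %in% names(raw)) raw$edv_ref_ml <- ""

  numeric_cols <- setdiff(SUBJECT_COLUMNS, "subject_id")
  out <- data.frame(subject_id = raw$subject_id, stringsAsFactors = FALSE)
  flag <- rep("", nrow(raw))
  for (col in numeric_cols) {
    cell <- raw[[col]]
    # Locale-independent dot-decimal parsing.
    val <- suppressWarnings(as.numeric(cell))
    bad <- !is.na(cell) & nzchar(cell) & is.na(val)
    flag[bad] <- "unparseable"
    blank <- is.na(cell) | !nzchar(cell)
    if (col != "edv_ref_ml") flag[blank & flag == ""] <- "missing data"
    out[[col]] <- val
  }
  if (timings_seconds) {
    out$pep_ms <- out$pep_ms * 1000
    out$et_ms <- out$et_ms * 1000
  }
  out$flag <- flag
  attr(out, "provenance") <- list(source = path, rows = nrow(out),
                                  flagged = which(nzchar(flag)))
  class(out) <- c("subject_table", "data.frame")
  out
}

#' Write a subject table as canonical CSV
#'
#' Values are written at 6 significant digits, so a write/read round trip is
#' lossless at that precision.
#'
#' @param subjects A subject table (or compatible data frame).
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_subjects <- function(subjects, path, delim = ",") {
  subjects <- as.data.frame(subjects)
  cols <- intersect(SUBJECT_COLUMNS, names(subjects))
  out <- subjects[cols]
  for (col in setdiff(cols, "subject_id")) {
    out[[col]] <- signif(out[[col]], 6)
  }
  utils::write.table(out, path, sep = delim, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Write a cohort results table
#'
#' @param results A `cohort_results` data frame from [estimate_cohort()].
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, delim = ",") {
  utils::write.table(as.data.frame(results), path, sep = delim,
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
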