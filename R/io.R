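#' Read and write BOLD matrices as tab-delimited text
#'
#' The canonical orientation is rows = regions, columns = volumes; set
#' `transpose = TRUE` for files stored the other way round.
#'
#' @param path File path.
#' @param transpose Transpose after reading.
#' @return Numeric matrix, regions x volumes.
#' @export
read_bold_matrix <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop(sprintf("BOLD file not found: %s", path))
  m <- as.matrix(utils::read.table(path, header = FALSE, sep = "\t"))
  dimnames(m) <- NULL
  if (!is.numeric(m)) stop(sprintf("non-numeric values in %s", path))
  if (!all(is.finite(m))) stop(sprintf("non-finite values in %s", path))
  if (transpose) m <- t(m)
  m
}

#' @rdname read_bold_matrix
#' @param bold Numeric matrix to write.
#' @export
write_bold_matrix <- function(bold, path) {
  utils::write.table(format(bold, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BIDS-style events TSV
#'
#' Expects header columns `onset` and `duration` (seconds); returns an
#' `event_timeline` with `onset`/`offset` columns. Rows are validated
#' (non-negative durations, within the scan when `scan_dur` is given) with
#' the offending line reported.
#'
#' @param path File path.
#' @param scan_dur Optional scan duration for a unit sanity check.
#' @return An `event_timeline`.
#' @export
read_events_tsv <- function(path, scan_dur = NULL) {
  if (!file.exists(path)) stop(sprintf("events file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("onset", "duration") %in% names(df)))
    stop(sprintf("%s must have 'onset' and 'duration' columns", path))
  for (i in seq_len(nrow(df))) {
    if (!is.finite(df$onset[i]) || !is.finite(df$duration[i]) ||
        df$duration[i] < 0 || df$onset[i] < 0)
      stop(sprintf("malformed event at line %d of %s", i + 1L, path))
    if (!is.null(scan_dur) && df$onset[i] + df$duration[i] > scan_dur + 1e-9)
      stop(sprintf("event at line %d of %s extends beyond the scan",
                   i + 1L, path))
  }
  df <- df[order(df$onset), , drop = FALSE]
  tl <- data.frame(onset = df$onset, offset = df$onset + df$duration)
  class(tl) <- c("event_timeline", "data.frame")
  attr(tl, "truncated") <- FALSE
  tl
}

#' @rdname read_events_tsv
#' @param timeline An `event_timeline` to write.
#' @export
write_events_tsv <- function(timeline, path) {
  df <- data.frame(onset = timeline$onset,
                   duration = timeline$offset - timeline$onset)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' Tab-delimited with header `subject_id`, `group`, `bold_path`,
#' `events_path` and optionally `tr`. Relative paths are resolved against the
#' manifest's directory; missing files are an error naming the subject.
#'
#' @param path Manifest path.
#' @param tr Fallback repetition time when the manifest has no `tr` column.
#' @return data.frame with absolute `bold_path`/`events_path`.
#' @export
read_manifest <- function(path, tr = NULL) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path))
  mf <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "bold_path", "events_path")
  if (!all(need %in% names(mf)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (!"tr" %in% names(mf)) {
    if (is.null(tr)) stop("manifest has no 'tr' column and no fallback given")
    mf$tr <- tr
  }
  base <- dirname(normalizePath(path))
  for (col in c("bold_path", "events_path")) {
    rel <- !grepl("^(/|[A-Za-z]:)", mf[[col]])
    mf[[col]][rel] <- file.path(base, mf[[col]][rel])
    for (i in seq_len(nrow(mf))) if (!file.exists(mf[[col]][i]))
      stop(sprintf("file missing for subject %s: %s",
                   mf$subject_id[i], mf[[col]][i]))
  }
  mf
}
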