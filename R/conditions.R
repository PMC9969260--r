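# mark event volumes on the original scan clock: volume t (0-based) covers
# [t*tr, (t+1)*tr); episode boundaries are rounded to the nearest volume index
# (half away from zero) and marked on the half-open range [onset_idx, offset_idx)
episodes_to_volumes <- function(timeline, tr, n_volumes) {
  labels <- integer(n_volumes)
  dropped <- 0L
  merged <- 0L
  scan_dur <- n_volumes * tr
  if (nrow(timeline)) {
    if (any(timeline$onset >= scan_dur | timeline$offset <= 0))
      stop("episode entirely outside the scan")
    for (e in seq_len(nrow(timeline))) {
      a <- round_half_away(timeline$onset[e] / tr)
      b <- round_half_away(timeline$offset[e] / tr)
      a <- max(a, 0); b <- min(b, n_volumes)
      if (b <= a) { dropped <- dropped + 1L; next }
      idx <- (a + 1):b  # 1-based columns for 0-based volumes a..b-1
      if (any(labels[idx] == 1L)) merged <- merged + 1L
      labels[idx] <- 1L
    }
  }
  attr(labels, "n_dropped") <- dropped
  attr(labels, "n_merged") <- merged
  labels
}

#' Convert an event timeline to a per-volume condition array
#'
#' Episode onsets/offsets (seconds) are rounded to the nearest volume index —
#' the rounding rule with the lowest total duration deviation — marked as 1
#' (event) on the original scan clock, then aligned with the trimmed phase
#' series by dropping the first `front_trim` and last `back_trim` volumes.
#' Zero-length episodes after rounding are dropped and counted; overlaps
#' created by rounding are merged and counted.
#'
#' @param timeline An `event_timeline` (columns `onset`, `offset`, seconds).
#' @param tr Repetition time, seconds.
#' @param n_volumes_original Volumes on the original clock (e.g. 800).
#' @param front_trim,back_trim Volumes discarded at the edges (default 10+10).
#' @return A list of class `"condition_array"`: `labels` (1 = event,
#'   0 = rest, per retained volume), `window` (half-open `[start, end)`
#'   0-based over retained volumes, initially the full range),
#'   `shift_applied` (TRs), `tr`, `n_dropped`, `n_merged`.
#' @export
events_to_condition_array <- function(timeline, tr, n_volumes_original,
                                      front_trim = 10L, back_trim = 10L) {
  full <- episodes_to_volumes(timeline, tr, n_volumes_original)
  retained <- trim_edges(as.integer(full), front_trim, back_trim)
  structure(list(labels = as.integer(retained),
                 window = c(0L, length(retained)),
                 shift_applied = 0L, tr = tr,
                 n_dropped = attr(full, "n_dropped"),
                 n_merged = attr(full, "n_merged")),
            class = "condition_array")
}

#' Total duration deviation introduced by nearest-integer rounding
#'
#' Sum over episodes of |rounded duration - original duration| in seconds,
#' a diagnostic for how much the volume grid distorts the reported episode
#' lengths. Bounded by one TR per episode boundary pair.
#'
#' @param timeline An `event_timeline`.
#' @param tr Repetition time, seconds.
#' @return Seconds (non-negative).
#' @export
rounding_deviation <- function(timeline, tr) {
  if (!nrow(timeline)) return(0)
  a <- round_half_away(timeline$onset / tr)
  b <- round_half_away(timeline$offset / tr)
  sum(abs((b - a) * tr - (timeline$offset - timeline$onset)))
}

#' Shift a condition array later in time by whole TRs
#'
#' Accounts for the hemodynamic delay: the BOLD response peaks ~4-6 s after
#' the experience, so event labels are moved `n_tr` volumes later (default 8
#' TRs = 4.8 s at TR 0.6 s). Vacated head volumes become rest; labels pushed
#' past the end are discarded (a warning reports how many non-zero labels
#' were lost).
#'
#' @param arr A `condition_array`.
#' @param n_tr Non-negative shift in TRs; default 8.
#' @return The shifted `condition_array` with `shift_applied` updated.
#' @export
shift_condition_array <- function(arr, n_tr = 8L) {
  stopifnot(inherits(arr, "condition_array"))
  if (n_tr < 0) stop("n_tr must be non-negative")
  n <- length(arr$labels)
  if (n_tr >= n) stop("shift exceeds array length")
  if (n_tr > 0) {
    lost <- sum(arr$labels[(n - n_tr + 1):n])
    if (lost > 0)
      warning(sprintf("%d event volumes shifted past the end were discarded",
                      lost))
    arr$labels <- c(integer(n_tr), arr$labels[1:(n - n_tr)])
  }
  arr$shift_applied <- arr$shift_applied + as.integer(n_tr)
  arr
}

#' Individual analysis window from state and condition changes
#'
#' The first and last state of a scan have no definitive start or end, so the
#' window opens at the earliest volume where either the state label or the
#' condition label changes from its predecessor, and closes at the latest
#' such volume; the window is half-open `[start, end)` in 0-based retained
#' indices. A constant state and condition throughout is an error.
#'
#' @param states Integer state label per retained volume.
#' @param condition A `condition_array` or a plain 0/1 label vector of the
#'   same length.
#' @return Integer vector `c(start, end)`.
#' @export
analysis_window <- function(states, condition) {
  cond <- if (inherits(condition, "condition_array")) condition$labels
          else condition
  stopifnot(length(states) == length(cond))
  chg <- which(diff(states) != 0 | diff(cond) != 0)  # x[i+1] differs from x[i]
  if (!length(chg)) stop("no state or condition change: empty analysis window")
  c(start = as.integer(min(chg)), end = as.integer(max(chg)))
}

#' Mask a state sequence by condition
#'
#' Volumes of the other condition are set to label 0 so that two episodes of
#' the condition of interest separated by the other condition cannot
#' concatenate into one inflated dwell, and so that transitions in and out of
#' "0" expose which states precede or follow a condition change.
#'
#' @param states Integer state labels (1..k) per volume.
#' @param condition A `condition_array` or a 0/1 vector of equal length.
#' @param condition_of_interest 1 (event) or 0 (rest).
#' @param tr Repetition time, seconds (taken from the `condition_array` when
#'   available).
#' @return A list of class `"masked_states"`: `labels` (0..k),
#'   `condition_of_interest`, `tr`.
#' @export
mask_states_by_condition <- function(states, condition, condition_of_interest,
                                     tr = NULL) {
  if (inherits(condition, "condition_array")) {
    if (is.null(tr)) tr <- condition$tr
    condition <- condition$labels
  }
  stopifnot(length(states) == length(condition),
            condition_of_interest %in% c(0L, 1L))
  labels <- as.integer(states)
  labels[condition != condition_of_interest] <- 0L
  structure(list(labels = labels,
                 condition_of_interest = as.integer(condition_of_interest),
                 tr = tr),
            class = "masked_states")
}

# subset a condition array (and a parallel state vector) to a window
apply_window <- function(x, window) {
  idx <- (window[1] + 1):window[2]
  if (inherits(x, "condition_array")) {
    x$labels <- x$labels[idx]
    x$window <- c(0L, length(idx))
    x
  } else x[idx]
}
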