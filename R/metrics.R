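#' State-switching frequency within a condition
#'
#' Number of consecutive-volume pairs with both volumes in the condition of
#' interest and differing state labels, divided by the condition duration in
#' seconds (condition volumes x TR). Transitions straddling a condition
#' boundary count for neither condition.
#'
#' @param states Integer state labels per volume (within the analysis window).
#' @param condition A `condition_array` or 0/1 vector of equal length.
#' @param condition_of_interest 1 (event) or 0 (rest).
#' @param tr Repetition time, seconds.
#' @return Switches per second; `NA` (with attribute `missing = TRUE`) when
#'   the condition has no volumes.
#' @export
switching_frequency <- function(states, condition, condition_of_interest, tr) {
  cond <- if (inherits(condition, "condition_array")) condition$labels
          else condition
  stopifnot(length(states) == length(cond))
  in_cond <- cond == condition_of_interest
  n_cond <- sum(in_cond)
  if (n_cond == 0) return(structure(NA_real_, missing = TRUE))
  n <- length(states)
  both <- in_cond[-n] & in_cond[-1]
  switches <- sum(both & states[-n] != states[-1])
  switches / (n_cond * tr)
}

#' Fractional occupancy of each state within a condition
#'
#' For each state 1..k, the fraction of condition volumes assigned to it;
#' fractions sum to 1 over states.
#'
#' @inheritParams switching_frequency
#' @param k Number of states.
#' @return Numeric vector of length `k`; all `NA` when the condition has no
#'   volumes.
#' @export
occurrence_probability <- function(states, condition, condition_of_interest,
                                   k) {
  cond <- if (inherits(condition, "condition_array")) condition$labels
          else condition
  stopifnot(length(states) == length(cond))
  in_cond <- cond == condition_of_interest
  n_cond <- sum(in_cond)
  if (n_cond == 0) return(structure(rep(NA_real_, k), missing = TRUE))
  tabulate(states[in_cond], nbins = k) / n_cond
}

#' Mean dwell time per state from a masked sequence
#'
#' Mean length of maximal runs of consecutive identical non-zero labels,
#' times TR. Runs are broken by the 0 labels marking the other condition and
#' by the window edges. States never present yield `NA` with the
#' corresponding entry of the `missing` attribute set.
#'
#' @param masked A `masked_states` object (see [mask_states_by_condition()]),
#'   or a plain 0..k label vector (then pass `tr`).
#' @param k Number of states.
#' @param tr Repetition time, seconds.
#' @return Numeric vector of length `k` (seconds).
#' @export
mean_dwell_time <- function(masked, k, tr = NULL) {
  if (inherits(masked, "masked_states")) {
    if (is.null(tr)) tr <- masked$tr
    masked <- masked$labels
  }
  stopifnot(!is.null(tr))
  r <- rle(masked)
  out <- rep(NA_real_, k)
  for (s in seq_len(k)) {
    runs <- r$lengths[r$values == s]
    if (length(runs)) out[s] <- mean(runs) * tr
  }
  attr(out, "missing") <- is.na(out)
  out
}

#' Transition counts and switch probabilities from a masked sequence
#'
#' Every consecutive pair with differing labels — including pairs involving
#' the 0 mask state — counts as one switch (from, to). Rows are normalized
#' over observed outgoing switches; rows with no outgoing switch have `NA`
#' probabilities and are flagged.
#'
#' @inheritParams mean_dwell_time
#' @return A list of class `"transition_counts"`: `counts` and
#'   `probabilities`, both `(k+1) x (k+1)` with dimnames `0..k`, and
#'   `no_outgoing` (logical per from-state).
#' @export
switch_probabilities <- function(masked, k) {
  if (inherits(masked, "masked_states")) masked <- masked$labels
  n <- length(masked)
  counts <- matrix(0L, k + 1, k + 1,
                   dimnames = list(from = 0:k, to = 0:k))
  if (n >= 2) {
    from <- masked[-n]; to <- masked[-1]
    ch <- from != to
    if (any(ch)) {
      tab <- table(factor(from[ch], levels = 0:k),
                   factor(to[ch], levels = 0:k))
      counts <- counts + unclass(tab)
    }
  }
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs == 0, NA, rs)
  structure(list(counts = counts, probabilities = probs,
                 no_outgoing = rs == 0),
            class = "transition_counts")
}

#' All four temporal metrics for one subject and both conditions
#'
#' Applies the analysis window, computes switching frequency and occupancy on
#' condition-restricted volumes, and mean dwell time and switch probabilities
#' on the 0-masked sequences, for condition 1 (event) and 0 (rest).
#'
#' @param states Integer state labels per retained volume.
#' @param condition A `condition_array` aligned with `states`.
#' @param k Number of states.
#' @param tr Repetition time, seconds.
#' @param subject_id,group,shift Identifiers copied into the output rows.
#' @return A long data.frame with columns `subject_id`, `group`, `condition`
#'   ("event"/"rest"), `shift`, `metric`, `state`, `to_state`, `value`,
#'   `missing`.
#' @export
subject_metrics <- function(states, condition, k, tr,
                            subject_id = "sub", group = "g", shift = 0L) {
  win <- analysis_window(states, condition)
  st <- apply_window(states, win)
  ca <- apply_window(condition, win)
  rows <- list()
  add <- function(condition_name, metric, state, to_state, value) {
    rows[[length(rows) + 1]] <<- data.frame(
      subject_id = subject_id, group = group, condition = condition_name,
      shift = shift, metric = metric, state = state, to_state = to_state,
      value = as.numeric(value), missing = is.na(value),
      stringsAsFactors = FALSE)
  }
  for (coi in c(1L, 0L)) {
    cname <- if (coi == 1L) "event" else "rest"
    add(cname, "switch_freq", NA_integer_, NA_integer_,
        switching_frequency(st, ca, coi, tr))
    occ <- occurrence_probability(st, ca, coi, k)
    for (s in seq_len(k)) add(cname, "occupancy", s, NA_integer_, occ[s])
    m <- mask_states_by_condition(st, ca, coi, tr)
    dw <- mean_dwell_time(m, k)
    for (s in seq_len(k)) add(cname, "dwell_time", s, NA_integer_, dw[s])
    tc <- switch_probabilities(m, k)
    for (s in 0:k) for (s2 in 0:k) {
      if (s == s2) next
      add(cname, "switch_prob", s, s2, tc$probabilities[s + 1, s2 + 1])
    }
  }
  do.call(rbind, rows)
}

#' Assemble per-subject metric tables into one long table
#'
#' @param metric_tables List of data.frames from [subject_metrics()].
#' @return One long data.frame; duplicate
#'   (subject, condition, shift, metric, state, to_state) keys are an error.
#' @export
assemble_metrics <- function(metric_tables) {
  out <- do.call(rbind, metric_tables)
  rownames(out) <- NULL
  key <- with(out, paste(subject_id, condition, shift, metric, state,
                         to_state, sep = "|"))
  if (anyDuplicated(key)) stop("duplicate metric keys in assembled table")
  out
}

#' Write / read a metrics table as tab-delimited text
#'
#' Fixed column order, full double precision; write then read round-trips
#' values exactly.
#'
#' @param metrics Long metrics data.frame.
#' @param path File path.
#' @return `read_metrics_table` returns the data.frame.
#' @export
write_metrics_table <- function(metrics, path) {
  cols <- c("subject_id", "group", "condition", "shift", "metric", "state",
            "to_state", "value", "missing")
  m <- metrics[, cols]
  m$value <- sprintf("%.17g", m$value)
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  out$value <- as.numeric(out$value)
  out$missing <- as.logical(out$missing)
  out
}
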