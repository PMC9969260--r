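#' Configuration for a synthetic BOLD cohort
#'
#' Collects every knob of the synthetic-data generator. Defaults emulate the
#' acquisition and event statistics of a hallucination balloon-press resting
#' paradigm: 90 regions, 800 volumes at TR = 0.6 s, two groups of 21
#' subjects, and events covering roughly a quarter to a third of scan time in
#' about 14 episodes of ~9.5 s mean duration. The planted dynamics are a
#' Markov chain over `k_true` phase-locking states, each state a region-wise
#' phase-offset pattern in the 0.04-0.07 Hz carrier.
#'
#' @param n_regions Number of regions (rows of each BOLD matrix).
#' @param n_volumes Number of volumes (columns); must exceed 20.
#' @param tr Repetition time in seconds.
#' @param n_per_group Subjects per group.
#' @param group_labels Character vector of two group labels.
#' @param k_true Number of planted phase-locking states (>= 1).
#' @param carrier_freq Carrier frequency in Hz; keep inside the analysis band.
#' @param noise_sd Standard deviation of additive white Gaussian noise, in
#'   units of the unit-amplitude carrier.
#' @param state_dwell_mean Mean planted state dwell in seconds. A planted
#'   switch is an instantaneous phase jump, which the narrow band-pass smears
#'   over a transition zone of roughly +/- 3 volumes; segments must be long
#'   relative to that zone (and to the band's ~1/bandwidth ring, about 33 s
#'   for 0.04-0.07 Hz) for the planted labels to be recoverable. The default
#'   72 s keeps smeared volumes below ~5 % of each segment.
#' @param event_rate Expected number of event episodes per scan.
#' @param event_dur_mean Mean episode duration in seconds.
#' @param min_gap Minimum gap between consecutive episodes in seconds.
#' @param condition_coupling Multiplicative scaling of the state-transition
#'   probability during events; 1 means no condition effect.
#' @param seed Integer RNG seed.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_regions = 90L, n_volumes = 800L, tr = 0.6,
                          n_per_group = 21L,
                          group_labels = c("nonclinical", "clinical"),
                          k_true = 4L, carrier_freq = 0.055, noise_sd = 0.1,
                          state_dwell_mean = 72, event_rate = 14,
                          event_dur_mean = 9.5, min_gap = 1,
                          condition_coupling = 1, seed = 1L) {
  cfg <- list(n_regions = as.integer(n_regions),
              n_volumes = as.integer(n_volumes), tr = tr,
              n_per_group = as.integer(n_per_group),
              group_labels = as.character(group_labels),
              k_true = as.integer(k_true), carrier_freq = carrier_freq,
              noise_sd = noise_sd, state_dwell_mean = state_dwell_mean,
              event_rate = event_rate, event_dur_mean = event_dur_mean,
              min_gap = min_gap, condition_coupling = condition_coupling,
              seed = as.integer(seed))
  if (cfg$n_volumes <= 20L) stop("n_volumes must exceed 20")
  if (cfg$tr <= 0) stop("tr must be positive")
  if (cfg$k_true < 1L) stop("k_true must be at least 1")
  if (cfg$n_regions < 2L) stop("n_regions must be at least 2")
  if (length(cfg$group_labels) != 2L) stop("exactly two group labels required")
  if (cfg$state_dwell_mean <= 0 || cfg$event_dur_mean <= 0)
    stop("durations must be positive")
  if (cfg$event_rate < 0) stop("event_rate must be non-negative")
  if (cfg$condition_coupling < 0) stop("condition_coupling must be >= 0")
  class(cfg) <- "cohort_config"
  cfg
}

#' Generate an event timeline with exponential on/off durations
#'
#' Alternating exponential off (gap) and on (episode) durations, calibrated so
#' that the expected episode count over the scan is `rate` and the mean
#' episode duration is `dur_mean`. Episodes are sorted, non-overlapping,
#' clipped to `[0, scan_dur]`, and separated by at least `min_gap`.
#'
#' @param rate Expected number of episodes per scan (>= 0).
#' @param dur_mean Mean episode duration, seconds.
#' @param scan_dur Scan duration, seconds.
#' @param min_gap Minimum inter-episode gap, seconds.
#' @param seed Integer seed.
#' @return A data.frame of class `"event_timeline"` with columns `onset` and
#'   `offset` (seconds). Attribute `truncated` is TRUE when the requested
#'   rate could not be fit into the scan.
#' @export
generate_events <- function(rate, dur_mean, scan_dur, min_gap = 0,
                            seed = 1L) {
  if (scan_dur <= 0) stop("scan_dur must be positive")
  if (rate < 0) stop("rate must be non-negative")
  if (rate == 0) return(empty_timeline())
  if (dur_mean <= 0) stop("dur_mean must be positive")

  gap_mean <- scan_dur / rate - dur_mean - min_gap
  truncated <- FALSE
  if (gap_mean <= 0) {
    truncated <- TRUE
    gap_mean <- 0.1 * dur_mean  # densest feasible packing; fewer events result
  }

  set.seed(as.integer(seed))
  onsets <- numeric(0); offsets <- numeric(0)
  t <- stats::rexp(1, 1 / gap_mean)
  while (t < scan_dur) {
    dur <- stats::rexp(1, 1 / dur_mean)
    off <- min(t + dur, scan_dur)
    if (off > t) { onsets <- c(onsets, t); offsets <- c(offsets, off) }
    t <- off + min_gap + stats::rexp(1, 1 / gap_mean)
  }
  tl <- data.frame(onset = onsets, offset = offsets)
  class(tl) <- c("event_timeline", "data.frame")
  attr(tl, "truncated") <- truncated || (nrow(tl) < rate / 2)
  tl
}

empty_timeline <- function() {
  tl <- data.frame(onset = numeric(0), offset = numeric(0))
  class(tl) <- c("event_timeline", "data.frame")
  attr(tl, "truncated") <- FALSE
  tl
}

#' Fraction of scan time covered by events
#'
#' @param timeline An `event_timeline`.
#' @param scan_dur Scan duration in seconds.
#' @return Fraction in `[0, 1]`.
#' @export
event_occupancy <- function(timeline, scan_dur) {
  if (nrow(timeline) == 0) return(0)
  sum(timeline$offset - timeline$onset) / scan_dur
}

# per-state region phase-offset patterns: antiphase blocks of 25-45% of the
# regions, all patterns distinct, minority block so the in-phase majority
# carries the eigenvector sign convention
plant_phase_offsets <- function(k_true, n_regions) {
  pats <- matrix(0, k_true, n_regions)
  keys <- character(0)
  for (s in seq_len(k_true)) {
    repeat {
      m <- max(1L, round(n_regions * stats::runif(1, 0.25, 0.45)))
      idx <- sample.int(n_regions, m)
      key <- paste(sort(idx), collapse = ",")
      if (!key %in% keys) break
    }
    keys <- c(keys, key)
    pats[s, idx] <- pi
  }
  pats
}

# Markov state sequence: geometric dwell with mean state_dwell_mean seconds;
# switch probability multiplied by condition_coupling during event volumes
simulate_state_sequence <- function(n_volumes, tr, k_true, dwell_mean,
                                    event_vol, coupling) {
  p_base <- min(tr / dwell_mean, 0.9)
  states <- integer(n_volumes)
  states[1] <- sample.int(k_true, 1)
  if (k_true == 1L) return(rep(1L, n_volumes))
  for (t in 2:n_volumes) {
    p <- if (event_vol[t]) min(p_base * coupling, 0.95) else p_base
    if (stats::runif(1) < p) {
      others <- setdiff(seq_len(k_true), states[t - 1])
      states[t] <- if (length(others) == 1L) others else sample(others, 1)
    } else states[t] <- states[t - 1]
  }
  states
}

#' Generate a synthetic multi-subject BOLD cohort with planted states
#'
#' Each subject's signal is `cos(2*pi*f*t + phi_s(n)) + N(0, noise_sd)` where
#' `phi_s` is the region-wise phase-offset pattern of the planted state `s`
#' active at volume `t`. The state sequence is a Markov chain whose dwell
#' parameter is `state_dwell_mean`, with transition probability scaled by
#' `condition_coupling` during that subject's events.
#'
#' @param config A [cohort_config()].
#' @return A list of class `"plock_cohort"` with elements `recordings`
#'   (list of `subject_recording`: `subject_id`, `group`, `bold`, `tr`),
#'   `events` (list of `event_timeline`), and `truth` (list with
#'   `states` — per-subject planted label per volume —, `phase_offsets`
#'   (`k_true x n_regions`, radians) and the config).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  scan_dur <- cfg$n_volumes * cfg$tr
  n_sub <- 2L * cfg$n_per_group
  ids <- sprintf("sub-%02d", seq_len(n_sub))
  groups <- rep(cfg$group_labels, each = cfg$n_per_group)

  set.seed(derive_seed(cfg$seed, "phase-offsets"))
  offsets <- plant_phase_offsets(cfg$k_true, cfg$n_regions)

  tt <- (seq_len(cfg$n_volumes) - 1) * cfg$tr
  recordings <- vector("list", n_sub)
  events <- vector("list", n_sub)
  truth_states <- matrix(0L, n_sub, cfg$n_volumes,
                         dimnames = list(ids, NULL))
  for (i in seq_len(n_sub)) {
    tl <- generate_events(cfg$event_rate, cfg$event_dur_mean, scan_dur,
                          cfg$min_gap,
                          seed = derive_seed(cfg$seed, paste0("events/", ids[i])))
    events[[i]] <- tl
    ev_vol <- episodes_to_volumes(tl, cfg$tr, cfg$n_volumes) == 1L

    set.seed(derive_seed(cfg$seed, paste0("signal/", ids[i])))
    st <- simulate_state_sequence(cfg$n_volumes, cfg$tr, cfg$k_true,
                                  cfg$state_dwell_mean, ev_vol,
                                  cfg$condition_coupling)
    truth_states[i, ] <- st
    carrier <- 2 * pi * cfg$carrier_freq * tt
    bold <- matrix(0, cfg$n_regions, cfg$n_volumes)
    for (n in seq_len(cfg$n_regions))
      bold[n, ] <- cos(carrier + offsets[cbind(st, n)])
    if (cfg$noise_sd > 0)
      bold <- bold + matrix(stats::rnorm(length(bold), 0, cfg$noise_sd),
                            nrow(bold))
    recordings[[i]] <- subject_recording(ids[i], groups[i], bold, cfg$tr)
  }
  structure(list(recordings = recordings, events = events,
                 truth = list(states = truth_states, phase_offsets = offsets,
                              config = cfg)),
            class = "plock_cohort")
}

#' Construct a subject recording
#'
#' @param subject_id Character id.
#' @param group Character group label.
#' @param bold Numeric matrix, regions x volumes, finite.
#' @param tr Repetition time, seconds.
#' @return A list of class `"subject_recording"`.
#' @export
subject_recording <- function(subject_id, group, bold, tr) {
  if (!is.matrix(bold) || !all(is.finite(bold)))
    stop("bold must be a finite numeric matrix")
  if (ncol(bold) <= 20L) stop("recording must have more than 20 volumes")
  if (nrow(bold) < 2L) stop("recording must have at least 2 regions")
  stop_if_not_scalar_number(tr, "tr")
  if (tr <= 0) stop("tr must be positive")
  structure(list(subject_id = as.character(subject_id),
                 group = as.character(group), bold = bold, tr = tr),
            class = "subject_recording")
}

#' Planted instantaneous phases for a subject's ground-truth sequence
#'
#' Returns the noise-free phase matrix `theta(n, t) = 2*pi*f*t + phi_s(t)(n)`
#' wrapped to `(-pi, pi]`, i.e. what an ideal phase estimator would recover.
#' Useful for validating the coherence/eigenvector/clustering stages in
#' isolation from filtering and Hilbert estimation.
#'
#' @param truth The `truth` element of a [generate_cohort()] result.
#' @param subject Subject index (row of `truth$states`).
#' @return Matrix of radians, regions x volumes.
#' @export
planted_phases <- function(truth, subject) {
  cfg <- truth$config
  st <- truth$states[subject, ]
  tt <- (seq_along(st) - 1) * cfg$tr
  carrier <- 2 * pi * cfg$carrier_freq * tt
  ph <- matrix(0, cfg$n_regions, length(st))
  for (n in seq_len(cfg$n_regions))
    ph[n, ] <- carrier + truth$phase_offsets[cbind(st, n)]
  wrap_phase(ph)
}

#' Write a cohort to disk as plain-text files
#'
#' One tab-delimited BOLD matrix per subject (rows = regions), one BIDS-style
#' events TSV per subject (`onset`, `duration` in seconds), a manifest TSV
#' (`subject_id`, `group`, `bold_path`, `events_path`, `tr`), and a
#' ground-truth label table (subjects x volumes).
#'
#' @param cohort A `plock_cohort`.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "plock_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(cohort$recordings, function(rec) {
    bp <- file.path(dir, paste0(rec$subject_id, "_bold.tsv"))
    ep <- file.path(dir, paste0(rec$subject_id, "_events.tsv"))
    write_bold_matrix(rec$bold, bp)
    i <- which(vapply(cohort$recordings, function(r) r$subject_id,
                      "") == rec$subject_id)
    write_events_tsv(cohort$events[[i]], ep)
    data.frame(subject_id = rec$subject_id, group = rec$group,
               bold_path = basename(bp), events_path = basename(ep),
               tr = rec$tr)
  })
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$truth$states,
                     file.path(dir, "ground_truth_states.tsv"),
                     sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(mp)
}
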