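#' Zero-phase Butterworth band-pass filter
#'
#' Designs a Butterworth band-pass of the given order and applies it
#' forward-backward ([signal::filtfilt()]) so the output carries no
#' frequency-dependent phase lag — essential here because everything
#' downstream is phase-based. The forward-backward pass doubles the
#' effective magnitude order.
#'
#' @param bold Numeric matrix, regions x volumes; filtered row-wise. A plain
#'   vector is also accepted.
#' @param tr Sampling interval in seconds.
#' @param low,high Band edges in Hz; must satisfy `0 < low < high < 1/(2*tr)`.
#' @param order Butterworth order (per pass); default 5.
#' @return Filtered matrix (or vector) of the same shape.
#' @export
bandpass_filter <- function(bold, tr, low = 0.04, high = 0.07, order = 5L) {
  vec <- is.null(dim(bold))
  x <- if (vec) matrix(bold, nrow = 1) else bold
  if (!all(is.finite(x))) stop("input contains non-finite values")
  stop_if_not_scalar_number(tr, "tr")
  nyq <- 1 / (2 * tr)
  if (!(low > 0 && low < high && high < nyq))
    stop(sprintf("invalid band [%g, %g] Hz for Nyquist %g Hz", low, high, nyq))
  if (order < 1L) stop("order must be >= 1")
  if (ncol(x) < 3 * (2 * order + 1))
    stop("series too short for the filter transient")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  out <- t(apply(x, 1, function(r) filtfilt_reflect(bf, r)))
  if (vec) drop(out) else out
}

# Factor a designed band-pass into second-order sections. The direct
# polynomial recursion of a high-order narrow band is numerically
# ill-conditioned (interior noise ~1e-6); a biquad cascade is accurate to
# near machine precision. Band-pass Butterworth zeros are exactly +/-1 in
# equal number, so each section carries numerator (1, 0, -1); poles come from
# the companion-matrix roots of the denominator and are paired conjugates.
sos_sections <- function(filt) {
  p <- polyroot(rev(filt$a))
  cplx <- p[Im(p) > 1e-9]
  real <- sort(Re(p[abs(Im(p)) <= 1e-9]))
  sections <- list()
  for (pp in cplx)
    sections[[length(sections) + 1]] <- c(1, -2 * Re(pp), Mod(pp)^2)
  while (length(real) >= 2) {
    sections[[length(sections) + 1]] <- c(1, -(real[1] + real[2]),
                                          real[1] * real[2])
    real <- real[-(1:2)]
  }
  if (length(real) == 1)
    sections[[length(sections) + 1]] <- c(1, -real[1], 0)
  list(a = sections, gain = filt$b[1])
}

# one biquad with numerator (1, 0, -1), steady-state initial conditions
biquad_bp <- function(x, a) {
  n <- length(x)
  v <- x - c(x[1], x[1], x[-c(n - 1, n)])        # x[t] - x[t-2]
  y0 <- 0                                         # band-pass DC gain is 0
  as.numeric(stats::filter(v, c(-a[2], -a[3]), method = "recursive",
                           init = c(y0, y0)))
}

sos_cascade <- function(x, sos) {
  for (a in sos$a) x <- biquad_bp(x, a)
  x * sos$gain
}

# forward-backward application over an odd-reflection padded series: the
# filter ring-down (long for a narrow band) decays inside the padding, the
# result is zero-phase and commutes with time reversal up to corner effects
filtfilt_reflect <- function(filt, x, pad_target = 2000L) {
  n <- length(x)
  # iterate the odd reflection until the padding reaches pad_target per side
  # (one reflection is capped at length - 1, short series need several)
  xx <- x
  pad <- 0L
  while (pad < pad_target) {
    m <- length(xx)
    p <- min(m - 1L, pad_target - pad)
    xx <- c(2 * xx[1] - xx[(p + 1):2], xx,
            2 * xx[m] - xx[(m - 1):(m - p)])
    pad <- pad + p
  }
  sos <- sos_sections(filt)
  y <- sos_cascade(xx, sos)
  y <- rev(sos_cascade(rev(y), sos))
  as.numeric(y[(pad + 1):(pad + n)])
}

# wrap radians to (-pi, pi]
wrap_phase <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

# analytic signal of one demeaned series via FFT (positive-frequency doubling)
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) { h[2:(n / 2)] <- 2; h[n / 2 + 1] <- 1
  } else h[2:((n + 1) / 2)] <- 2
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase via the Hilbert transform
#'
#' Each row is demeaned (a DC offset biases the analytic-signal angle) and its
#' analytic signal computed by FFT; the returned phase is the angle of that
#' signal, wrapped to `(-pi, pi]`.
#'
#' @param filtered Numeric matrix, regions x volumes (band-limited input).
#' @return Matrix of radians, same shape.
#' @export
instantaneous_phase <- function(filtered) {
  x <- if (is.null(dim(filtered))) matrix(filtered, nrow = 1) else filtered
  if (!all(is.finite(x))) stop("input contains non-finite values")
  ph <- matrix(0, nrow(x), ncol(x))
  for (n in seq_len(nrow(x))) {
    r <- x[n, ] - mean(x[n, ])
    if (all(r == 0))
      stop(sprintf("region %d is constant: instantaneous phase undefined", n))
    ph[n, ] <- Arg(analytic_signal(r))
  }
  ph <- wrap_phase(ph)
  if (is.null(dim(filtered))) drop(ph) else ph
}

#' Discard edge volumes
#'
#' Drops `front` leading and `back` trailing volumes (columns for a matrix,
#' elements for a vector) to remove Hilbert-transform edge effects. The
#' default 10 + 10 reduces an 800-volume scan to 780 retained timepoints.
#'
#' @param x Matrix (columns = volumes) or vector.
#' @param front,back Counts of volumes to drop.
#' @return Same type as `x` with attribute `retained_index_offset = front`.
#' @export
trim_edges <- function(x, front = 10L, back = 10L) {
  if (front < 0 || back < 0) stop("trim counts must be non-negative")
  nv <- if (is.null(dim(x))) length(x) else ncol(x)
  if (nv <= front + back)
    stop(sprintf("cannot trim %d + %d volumes from %d", front, back, nv))
  keep <- (front + 1):(nv - back)
  out <- if (is.null(dim(x))) x[keep] else x[, keep, drop = FALSE]
  attr(out, "retained_index_offset") <- as.integer(front)
  out
}

#' Band-limited instantaneous phases for one subject
#'
#' Filter (optional), Hilbert phase, then edge trimming — the transform sees
#' the full series so that trimming removes its edge effects.
#'
#' @param recording A `subject_recording`.
#' @param low,high,order Band-pass parameters, see [bandpass_filter()].
#' @param front,back Edge volumes to discard, see [trim_edges()].
#' @param filter If FALSE the band-pass is skipped (for signals already known
#'   to be in-band, e.g. noise-free synthetic carriers).
#' @return A list of class `"phase_series"`: `subject_id`, `phases`
#'   (regions x retained volumes, radians) and `retained_index_offset`.
#' @export
phase_series <- function(recording, low = 0.04, high = 0.07, order = 5L,
                         front = 10L, back = 10L, filter = TRUE) {
  stopifnot(inherits(recording, "subject_recording"))
  x <- recording$bold
  if (filter) x <- bandpass_filter(x, recording$tr, low, high, order)
  ph <- instantaneous_phase(x)
  ph <- trim_edges(ph, front, back)
  structure(list(subject_id = recording$subject_id, phases = ph,
                 retained_index_offset = as.integer(front)),
            class = "phase_series")
}
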