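#' Derive a child RNG seed from a global seed and a stage tag
#'
#' One global seed fans out to per-stage and per-subject seeds so that every
#' stage is independently replayable without seed collisions. The result is
#' always a valid 32-bit integer seed.
#'
#' @param seed Integer global seed.
#' @param tag Character stage tag (e.g. `"events/sub-03"`).
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- 0
  for (u in utf8ToInt(tag)) h <- (h * 131 + u) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 means identical up to label permutation, 0 is chance level.
#'
#' @param a,b Label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 1)
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  expected <- ai * bj / choose(n, 2)
  denom <- (ai + bj) / 2 - expected
  if (denom == 0) return(1)  # both partitions trivial and identical
  (sum_ij - expected) / denom
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}
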