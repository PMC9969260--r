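# Independent oracles: deliberately brute-force / from-definition routes that
# never share code with the implementation they check.

empty_tl <- function() {
  tl <- data.frame(onset = numeric(0), offset = numeric(0))
  class(tl) <- c("event_timeline", "data.frame")
  tl
}

# subset a plain vector to a half-open 0-based window [start, end)
apply_window_vec <- function(x, w) x[(w[1] + 1):w[2]]

# circular difference wrapped to (-pi, pi]
wrapped_diff <- function(a, b) {
  d <- (a - b + pi) %% (2 * pi) - pi
  d[d == -pi] <- pi
  d
}

# leading eigenvector by plain power iteration (sign-agnostic); the
# Gershgorin-bound shift makes the algebraically largest eigenvalue dominant
# without collapsing the convergence-driving gap ratio
power_iteration_oracle <- function(C, iters = 200000, tol = 1e-13) {
  s <- max(rowSums(abs(C)))
  A <- C + diag(nrow(C)) * s
  set.seed(nrow(C))            # fixed start, avoids an orthogonal start
  v <- rnorm(nrow(C))
  v <- v / sqrt(sum(v^2))
  for (i in seq_len(iters)) {
    w <- as.vector(A %*% v)
    lam <- sqrt(sum(w^2))
    w <- w / lam
    if (sqrt(sum((A %*% w - lam * w)^2)) < tol * lam) { v <- w; break }
    v <- w
  }
  v
}

# mean dwell per state by explicit run enumeration
rle_dwell_oracle <- function(labels, k, tr) {
  out <- rep(NA_real_, k)
  for (s in seq_len(k)) {
    runs <- c(); cur <- 0
    for (x in c(labels, -1L)) {       # sentinel flushes the last run
      if (x == s) cur <- cur + 1
      else if (cur > 0) { runs <- c(runs, cur); cur <- 0 }
    }
    if (length(runs)) out[s] <- mean(runs) * tr
  }
  out
}

# transition counts by explicit pair loop
transition_oracle <- function(labels, k) {
  counts <- matrix(0L, k + 1, k + 1)
  for (t in seq_len(length(labels) - 1)) {
    a <- labels[t]; b <- labels[t + 1]
    if (a != b) counts[a + 1, b + 1] <- counts[a + 1, b + 1] + 1L
  }
  counts
}

# switching frequency by explicit pair loop
switchfreq_oracle <- function(states, cond, interest, tr) {
  n_cond <- sum(cond == interest)
  if (n_cond == 0) return(NA_real_)
  sw <- 0L
  for (t in seq_len(length(states) - 1))
    if (cond[t] == interest && cond[t + 1] == interest &&
        states[t] != states[t + 1]) sw <- sw + 1L
  sw / (n_cond * tr)
}

# Dunn index by exhaustive O(N^2) pair scan
dunn_oracle <- function(points, labels) {
  n <- nrow(points)
  inter <- Inf; intra <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dd <- sqrt(sum((points[i, ] - points[j, ])^2))
    if (labels[i] == labels[j]) intra <- max(intra, dd)
    else inter <- min(inter, dd)
  }
  if (intra == 0) Inf else inter / intra
}

# Pearson r from the covariance/variance definition
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# two-sample KS D on the pooled evaluation grid
ks_oracle <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  Fx <- vapply(grid, function(g) mean(x <= g), 0)
  Fy <- vapply(grid, function(g) mean(y <= g), 0)
  max(abs(Fx - Fy))
}

# textbook paired t
paired_t_oracle <- function(x, y) {
  d <- x - y
  mean(d) / (stats::sd(d) / sqrt(length(d)))
}

# small cohort used across tests (scaled-down problem size, fixed seed)
small_cohort <- function(seed = 11, noise_sd = 0.1, k_true = 4L,
                         n_regions = 40L, n_volumes = 400L,
                         n_per_group = 3L, coupling = 1) {
  generate_cohort(cohort_config(
    n_regions = n_regions, n_volumes = n_volumes, n_per_group = n_per_group,
    k_true = k_true, noise_sd = noise_sd, event_rate = 7,
    condition_coupling = coupling, seed = seed))
}

# pooled eigenvectors from planted phases (+ optional phase jitter):
# the planted-partition route that isolates coherence/eigenvector/clustering
# from filtering and Hilbert estimation
planted_pool <- function(cohort, jitter_sd = 0, front = 10L, back = 10L,
                         seed = 99) {
  truth <- cohort$truth
  set.seed(seed)
  sets <- lapply(seq_len(nrow(truth$states)), function(i) {
    ph <- planted_phases(truth, i)
    if (jitter_sd > 0)
      ph <- ph + matrix(stats::rnorm(length(ph), 0, jitter_sd),
                        nrow(ph), ncol(ph))
    eigenvector_series(trim_edges(ph, front, back), paste0("s", i))
  })
  concatenate_eigenvectors(sets)
}

trimmed_truth_labels <- function(cohort, front = 10L, back = 10L) {
  nv <- ncol(cohort$truth$states)
  as.vector(t(cohort$truth$states[, (front + 1):(nv - back)]))
}

# long metrics-style table for a balanced mixed design, optionally with a
# planted group effect (in units of the residual SD)
simulate_anova_table <- function(n_per_group = 5, within_levels = 2,
                                 group_effect_sd = 0, seed = 1) {
  set.seed(seed)
  subj <- sprintf("s%02d", seq_len(2 * n_per_group))
  grp <- rep(c("A", "B"), each = n_per_group)
  d <- expand.grid(subject_id = subj,
                   condition = paste0("c", seq_len(within_levels)),
                   stringsAsFactors = FALSE)
  d$group <- grp[match(d$subject_id, subj)]
  d$value <- stats::rnorm(nrow(d)) +
    ifelse(d$group == "B", group_effect_sd, 0)
  d
}
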