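#' Phase-coherence matrix at one timepoint
#'
#' Entry (n, p) is `cos(theta_n - theta_p)`: 1 for phase-locked regions, 0 for
#' orthogonal phases, -1 for anti-phase. The result is symmetric with unit
#' diagonal, and invariant to adding a global phase constant.
#'
#' @param phases_at_t Numeric vector of radians, one per region.
#' @return Symmetric regions x regions matrix with entries in `[-1, 1]`.
#' @export
phase_coherence <- function(phases_at_t) {
  if (!all(is.finite(phases_at_t))) stop("phases must be finite")
  d <- outer(phases_at_t, phases_at_t, "-")
  C <- cos(d)
  C <- (C + t(C)) / 2
  diag(C) <- 1
  C
}

#' Leading eigenvector of a coherence matrix
#'
#' Unit-norm eigenvector of the largest eigenvalue, sign-normalized so that
#' the strict majority of components are negative; on an exact tie the vector
#' is flipped so its first component is non-positive. A fixed orientation is
#' required for the eigenvectors to be clusterable.
#'
#' @param C Symmetric numeric matrix.
#' @return Unit-norm numeric vector.
#' @export
leading_eigenvector <- function(C) {
  if (!isSymmetric(unname(C), tol = 1e-8)) stop("matrix must be symmetric")
  v <- eigen(C, symmetric = TRUE)$vectors[, 1]
  v <- v / sqrt(sum(v^2))
  npos <- sum(v > 0); nneg <- sum(v < 0)
  if (npos > nneg) v <- -v
  else if (npos == nneg && v[1] > 0) v <- -v
  v
}

#' Leading eigenvectors for all timepoints of a phase series
#'
#' @param phases A `phase_series` or a plain regions x volumes phase matrix.
#' @param subject_id Used when `phases` is a plain matrix.
#' @return A list of class `"eigenvector_set"`: `vectors` (timepoints x
#'   regions), `subject_id`, `timepoint` (1-based retained-volume index).
#' @export
eigenvector_series <- function(phases, subject_id = NULL) {
  if (inherits(phases, "phase_series")) {
    subject_id <- phases$subject_id
    phases <- phases$phases
  }
  nt <- ncol(phases)
  V <- matrix(0, nt, nrow(phases))
  for (t in seq_len(nt))
    V[t, ] <- leading_eigenvector(phase_coherence(phases[, t]))
  structure(list(vectors = V, subject_id = as.character(subject_id),
                 timepoint = seq_len(nt)),
            class = "eigenvector_set")
}

#' Pool eigenvector sets across subjects
#'
#' Stacks per-subject timepoints x regions eigenvector matrices into one
#' pooled matrix (e.g. 42 subjects x 780 timepoints = 32,760 rows for the
#' reference cohort), with a row index preserving provenance.
#'
#' @param sets List of `eigenvector_set` objects sharing a region count.
#' @return List with `vectors` (pooled matrix) and `index` (data.frame
#'   `subject_id`, `timepoint`).
#' @export
concatenate_eigenvectors <- function(sets) {
  stopifnot(length(sets) >= 1)
  p <- ncol(sets[[1]]$vectors)
  for (s in sets) if (ncol(s$vectors) != p)
    stop("eigenvector sets disagree on region count")
  vectors <- do.call(rbind, lapply(sets, function(s) s$vectors))
  index <- do.call(rbind, lapply(sets, function(s)
    data.frame(subject_id = s$subject_id, timepoint = s$timepoint,
               stringsAsFactors = FALSE)))
  list(vectors = vectors, index = index)
}

#' Cluster pooled eigenvectors into phase-locking states
#'
#' k-means (Euclidean, which is monotone in cosine distance on unit-norm
#' vectors) with k-means++-style restarts: the best-inertia solution over
#' `n_restarts` seeded starts is kept.
#'
#' @param pooled Numeric matrix, rows = pooled eigenvectors.
#' @param k Number of states.
#' @param n_restarts Random restarts.
#' @param seed Integer seed; fixed seed gives identical labels on repeat.
#' @return A list of class `"cluster_model"`: `k`, `centroids` (k x regions),
#'   `labels` (state 1..k per row), `inertia`, `dunn` (NA until computed).
#' @export
kmeans_states <- function(pooled, k, n_restarts = 20L, seed = 1L) {
  if (nrow(pooled) < k) stop("fewer rows than clusters requested")
  set.seed(as.integer(seed))
  fit <- NULL
  for (attempt in 1:5) {  # rare empty-cluster failures: retry with new starts
    fit <- tryCatch(
      suppressWarnings(
        stats::kmeans(pooled, centers = k, nstart = n_restarts,
                      iter.max = 200)),
      error = function(e) e)
    if (!inherits(fit, "condition")) break
  }
  if (inherits(fit, "condition"))
    stop("k-means failed after restarts: ", conditionMessage(fit))
  structure(list(k = as.integer(k), centroids = unname(fit$centers),
                 labels = as.integer(fit$cluster),
                 inertia = fit$tot.withinss, dunn = NA_real_),
            class = "cluster_model")
}

#' Dunn cluster-validity index
#'
#' Classic variant: the minimum single-linkage inter-cluster distance divided
#' by the maximum complete-diameter intra-cluster distance (Euclidean).
#' Exact computation is O(N^2); above `subsample` points a seeded uniform
#' subsample is used and recorded in the `subsampled` attribute.
#'
#' @param points Numeric matrix of observations.
#' @param labels Cluster label per row (>= 2 non-empty clusters).
#' @param subsample Optional cap on points used; NULL for exact.
#' @param seed Seed for the subsample draw.
#' @return Numeric scalar; `+Inf` (with attribute `zero_diameter = TRUE`)
#'   when every cluster has zero diameter but clusters are distinct.
#' @export
dunn_index <- function(points, labels, subsample = NULL, seed = 1L) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 1)
  stopifnot(nrow(points) == length(labels))
  if (length(unique(labels)) < 2) stop("at least 2 clusters required")
  used_subsample <- FALSE
  if (!is.null(subsample) && nrow(points) > subsample) {
    set.seed(as.integer(seed))
    keep <- sort(sample.int(nrow(points), subsample))
    points <- points[keep, , drop = FALSE]
    labels <- labels[keep]
    used_subsample <- TRUE
    if (length(unique(labels)) < 2)
      stop("subsample lost all but one cluster; increase 'subsample'")
  }
  D <- as.matrix(stats::dist(points))
  same <- outer(labels, labels, "==")
  ut <- upper.tri(D)
  inter <- min(D[!same])
  intra_vals <- D[same & ut]
  intra <- if (length(intra_vals)) max(intra_vals) else 0
  if (intra == 0) {
    out <- Inf
    attr(out, "zero_diameter") <- TRUE
  } else out <- inter / intra
  attr(out, "subsampled") <- used_subsample
  out
}

#' Select the number of states by the Dunn index
#'
#' Runs [kmeans_states()] for every `k` in `k_range`, scores each partition
#' with [dunn_index()], and returns the model with the maximal index
#' (smallest `k` wins ties — parsimony).
#'
#' @param pooled Pooled eigenvector matrix.
#' @param k_range Candidate cluster counts; default 3..15.
#' @param n_restarts Restarts per k.
#' @param seed Integer seed (a child seed is derived per k).
#' @param dunn_subsample Point cap for the Dunn computation; default 8000.
#' @return List with `best` (the winning `cluster_model`, `dunn` filled in)
#'   and `table` (data.frame `k`, `dunn`, `inertia`).
#' @export
select_optimal_k <- function(pooled, k_range = 3:15, n_restarts = 20L,
                             seed = 1L, dunn_subsample = 8000L) {
  stopifnot(length(k_range) >= 1)
  models <- vector("list", length(k_range))
  dunns <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    m <- kmeans_states(pooled, k_range[i], n_restarts,
                       seed = derive_seed(seed, paste0("kmeans/k=", k_range[i])))
    d <- dunn_index(pooled, m$labels, subsample = dunn_subsample,
                    seed = derive_seed(seed, paste0("dunn/k=", k_range[i])))
    m$dunn <- as.numeric(d)
    models[[i]] <- m
    dunns[i] <- as.numeric(d)
  }
  best <- which(dunns == max(dunns))[1]  # ties: smallest k (k_range sorted by caller)
  list(best = models[[best]],
       table = data.frame(k = as.integer(k_range), dunn = dunns,
                          inertia = vapply(models, `[[`, 0, "inertia")))
}

#' Correlate state centroids with reference network templates
#'
#' Pearson correlation of each centroid with each user-supplied network map,
#' two-sided p from the t distribution with `regions - 2` df, Bonferroni
#' significance over all (state x template) tests.
#'
#' @param centroids k x regions matrix (e.g. `cluster_model$centroids`).
#' @param templates Named list of numeric vectors over regions, or a
#'   data.frame/matrix with one column per template.
#' @param alpha Family-wise alpha before Bonferroni division.
#' @return data.frame with `state`, `template`, `r`, `p`, `significant`,
#'   `degenerate` (TRUE where a zero-variance input made r undefined).
#' @export
template_correlation <- function(centroids, templates, alpha = 0.05) {
  if (is.data.frame(templates) || is.matrix(templates))
    templates <- as.list(as.data.frame(templates))
  p <- ncol(centroids)
  if (p < 3) stop("at least 3 regions required")
  for (nm in names(templates)) if (length(templates[[nm]]) != p)
    stop(sprintf("template '%s' length differs from region count", nm))
  n_tests <- nrow(centroids) * length(templates)
  rows <- list()
  for (s in seq_len(nrow(centroids))) for (nm in names(templates)) {
    x <- centroids[s, ]; y <- templates[[nm]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        state = s, template = nm, r = NA_real_, p = NA_real_,
        significant = FALSE, degenerate = TRUE)
      next
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    rows[[length(rows) + 1]] <- data.frame(
      state = s, template = nm, r = unname(ct$estimate),
      p = ct$p.value, significant = ct$p.value < alpha / n_tests,
      degenerate = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
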