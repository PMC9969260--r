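test_that("phase coherence matches its closed forms and gauge invariance", {
  expect_equal(phase_coherence(c(0.3, 0.3, 0.3)), matrix(1, 3, 3))
  expect_equal(phase_coherence(c(0, pi / 2))[1, 2], 0)
  expect_equal(phase_coherence(c(0, pi))[1, 2], -1)

  set.seed(2)
  th <- runif(10, -pi, pi)
  expect_equal(phase_coherence(th), phase_coherence(th + 1.234),
               tolerance = 1e-12)
  C <- phase_coherence(th)
  expect_true(isSymmetric(C))
  expect_equal(diag(C), rep(1, 10))
  expect_true(all(C >= -1 - 1e-12 & C <= 1 + 1e-12))
})

test_that("leading eigenvector solves the all-ones and block closed forms", {
  C1 <- matrix(1, 3, 3)
  v <- leading_eigenvector(C1)
  expect_equal(v, rep(-1 / sqrt(3), 3), tolerance = 1e-12)
  ev <- eigen(C1, symmetric = TRUE)$values[1]
  expect_equal(ev, 3, tolerance = 1e-12)

  # two perfectly coherent, mutually anti-coherent blocks
  C2 <- rbind(c(1, 1, -1, -1), c(1, 1, -1, -1),
              c(-1, -1, 1, 1), c(-1, -1, 1, 1))
  v2 <- leading_eigenvector(C2)
  expect_equal(abs(v2), rep(0.5, 4), tolerance = 1e-12)
  expect_true(sign(v2[1]) == sign(v2[2]) && sign(v2[3]) == sign(v2[4]) &&
                sign(v2[1]) != sign(v2[3]))
})

test_that("leading eigenvector agrees with power iteration on random input", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    A <- matrix(rnorm(n * n), n)
    C <- (A + t(A)) / 2
    v <- leading_eigenvector(C)
    w <- power_iteration_oracle(C)
    expect_gt(abs(sum(v * w)), 1 - 1e-9)
  }
})

test_that("eigenvector sign convention and equivariance hold", {
  set.seed(3)
  for (i in 1:50) {
    th <- runif(9, -pi, pi)
    v <- leading_eigenvector(phase_coherence(th))
    npos <- sum(v > 0); nneg <- sum(v < 0)
    expect_true(nneg > npos || (nneg == npos && v[1] <= 0))
    expect_equal(sum(v^2), 1, tolerance = 1e-9)
    perm <- sample(9)
    vp <- leading_eigenvector(phase_coherence(th[perm]))
    expect_equal(vp, v[perm], tolerance = 1e-8)
  }
})

test_that("eigenvector pooling preserves counts and provenance", {
  set.seed(5)
  mk <- function(id, nt) {
    ph <- matrix(runif(6 * nt, -pi, pi), 6)
    eigenvector_series(ph, id)
  }
  pooled <- concatenate_eigenvectors(list(mk("a", 5), mk("b", 7)))
  expect_equal(nrow(pooled$vectors), 12)
  expect_equal(pooled$index$subject_id, rep(c("a", "b"), c(5, 7)))
  expect_equal(pooled$index$timepoint, c(1:5, 1:7))

  one <- mk("solo", 4)
  p1 <- concatenate_eigenvectors(list(one))
  expect_equal(p1$vectors, one$vectors)

  bad <- eigenvector_series(matrix(runif(5 * 3, -pi, pi), 5), "c")
  expect_error(concatenate_eigenvectors(list(mk("a", 5), bad)),
               "region count")
})

test_that("k-means recovers a planted partition and is deterministic", {
  coh <- small_cohort(seed = 9, noise_sd = 0, n_regions = 20,
                      n_volumes = 200, n_per_group = 1)
  pool <- planted_pool(coh)
  m <- kmeans_states(pool$vectors, 4, n_restarts = 10, seed = 2)
  truth <- trimmed_truth_labels(coh)
  expect_equal(adjusted_rand_index(m$labels, truth), 1)

  m2 <- kmeans_states(pool$vectors, 4, n_restarts = 10, seed = 2)
  expect_identical(m$labels, m2$labels)

  m1 <- kmeans_states(pool$vectors, 1, seed = 2)
  expect_equal(drop(m1$centroids), colMeans(pool$vectors), tolerance = 1e-12)

  expect_error(kmeans_states(pool$vectors[1:3, ], 5), "fewer rows")
})

test_that("restarting k-means never worsens the best inertia", {
  set.seed(12)
  x <- rbind(matrix(rnorm(60, 0), ncol = 2), matrix(rnorm(60, 3), ncol = 2),
             matrix(rnorm(60, 6), ncol = 2))
  i1 <- kmeans_states(x, 5, n_restarts = 1, seed = 5)$inertia
  i20 <- kmeans_states(x, 5, n_restarts = 20, seed = 5)$inertia
  expect_lte(i20, i1 + 1e-9)
})

test_that("Dunn index matches hand and brute-force oracles", {
  pts <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  lab <- c(1, 1, 2, 2)
  expect_equal(as.numeric(dunn_index(pts, lab)), 10)

  # duplicate points in one cluster, far singleton second cluster
  dup <- rbind(c(1, 1), c(1, 1), c(50, 50))
  d <- dunn_index(dup, c(1, 1, 2))
  expect_true(is.infinite(d))
  expect_true(attr(d, "zero_diameter"))

  expect_error(dunn_index(pts, rep(1, 4)), "2 clusters")

  set.seed(10)
  x <- matrix(rnorm(60 * 3), 60)
  lab <- sample(1:3, 60, replace = TRUE)
  expect_equal(as.numeric(dunn_index(x, lab)), dunn_oracle(x, lab),
               tolerance = 1e-12)
  # scale invariance: numerator and denominator both scale linearly
  expect_equal(as.numeric(dunn_index(x * 7.3, lab)),
               as.numeric(dunn_index(x, lab)), tolerance = 1e-12)
})

test_that("seeded subsampling keeps the Dunn computation reproducible", {
  set.seed(1)
  x <- matrix(rnorm(500 * 2), 500)
  lab <- rep(1:2, each = 250)
  d1 <- dunn_index(x, lab, subsample = 100, seed = 3)
  d2 <- dunn_index(x, lab, subsample = 100, seed = 3)
  expect_identical(as.numeric(d1), as.numeric(d2))
  expect_true(attr(d1, "subsampled"))
})

test_that("Dunn-index model selection recovers the planted state count", {
  coh <- small_cohort(seed = 11)
  pool <- planted_pool(coh, jitter_sd = 0.1, seed = 42)
  sel <- select_optimal_k(pool$vectors, 2:8, n_restarts = 10, seed = 5)
  expect_equal(sel$best$k, 4L)
  expect_equal(nrow(sel$table), 7)
  expect_equal(sel$best$dunn, max(sel$table$dunn))

  single <- select_optimal_k(pool$vectors, 4, n_restarts = 5, seed = 5)
  expect_equal(single$best$k, 4L)
})

test_that("equal Dunn values break ties toward the smaller k", {
  # symmetric 4-point square: k=2 solutions found for both orderings give
  # identical Dunn; the first (smaller k) must win
  pts <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1),
               c(0, 0.5), c(10, 0.5))
  sel <- select_optimal_k(pts, c(2, 2), n_restarts = 5, seed = 1)
  expect_equal(sel$best$k, 2L)
  expect_equal(sel$table$dunn[1], sel$table$dunn[2])
})

test_that("template correlations match the from-definition Pearson oracle", {
  set.seed(6)
  cents <- matrix(rnorm(3 * 20), 3)
  templ <- list(net1 = rnorm(20), net2 = rnorm(20))
  out <- template_correlation(cents, templ, alpha = 0.05)
  expect_equal(nrow(out), 6)
  for (i in seq_len(nrow(out))) {
    r_oracle <- pearson_oracle(cents[out$state[i], ],
                               templ[[out$template[i]]])
    expect_equal(out$r[i], r_oracle, tolerance = 1e-12)
  }

  # centroid proportional to its template
  prop <- template_correlation(matrix(2.5 * templ$net1, 1), templ["net1"])
  expect_equal(prop$r, 1, tolerance = 1e-12)

  # orthogonal zero-mean pair
  x <- c(1, -1, 1, -1); y <- c(1, 1, -1, -1)
  orth <- template_correlation(matrix(x, 1), list(t = y))
  expect_equal(orth$r, 0, tolerance = 1e-12)

  # zero-variance template is flagged, not an error
  dg <- template_correlation(cents, list(flat = rep(1, 20)))
  expect_true(all(dg$degenerate))
})
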