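test_that("observed mixed-design F matches the aov error-strata oracle", {
  # 2 groups x 3 subjects x 2 conditions (fixed fixture)
  subj <- sprintf("s%d", 1:6)
  d <- expand.grid(subject_id = subj, condition = c("event", "rest"),
                   stringsAsFactors = FALSE)
  d$group <- rep(c("A", "B"), each = 3)[match(d$subject_id, subj)]
  d$value <- c(4.1, 5.2, 3.9, 6.0, 6.4, 5.8,
               4.9, 5.8, 4.4, 7.1, 7.9, 6.6)
  res <- perm_rm_anova(d, within = "condition", n_perm = 20, seed = 1)

  da <- transform(d, subject_id = factor(subject_id), group = factor(group),
                  condition = factor(condition))
  a <- summary(stats::aov(value ~ group * condition +
                            Error(subject_id / condition), data = da))
  f_between <- a[["Error: subject_id"]][[1]]["group", "F value"]
  f_within <- a[["Error: subject_id:condition"]][[1]][
    c("condition", "group:condition"), "F value"]
  expect_equal(res$F[res$effect == "group"], f_between, tolerance = 1e-10)
  expect_equal(res$F[res$effect == "condition"], f_within[1],
               tolerance = 1e-10)
  expect_equal(res$F[res$effect == "group:condition"], f_within[2],
               tolerance = 1e-10)
  expect_equal(res$df_num, rep(1, 3))
  expect_equal(res$df_den, rep(4, 3))
})

test_that("two within factors reproduce the full aov decomposition", {
  set.seed(42)
  subj <- sprintf("s%02d", 1:8)
  d <- expand.grid(subject_id = subj, condition = c("event", "rest"),
                   state = paste0("pl", 1:3), stringsAsFactors = FALSE)
  d$group <- rep(c("A", "B"), each = 4)[match(d$subject_id, subj)]
  d$value <- rnorm(nrow(d)) + ifelse(d$condition == "event", 0.5, 0)
  res <- perm_rm_anova(d, within = c("condition", "state"), n_perm = 10,
                       seed = 3)

  da <- as.data.frame(lapply(d[c("subject_id", "group", "condition",
                                 "state")], factor))
  da$value <- d$value
  a <- summary(stats::aov(value ~ group * condition * state +
                            Error(subject_id / (condition * state)),
                          data = da))
  pick <- function(stratum, term)
    a[[stratum]][[1]][term, "F value"]
  expect_equal(res$F[res$effect == "group"],
               pick("Error: subject_id", "group"), tolerance = 1e-10)
  expect_equal(res$F[res$effect == "condition"],
               pick("Error: subject_id:condition", "condition"),
               tolerance = 1e-10)
  expect_equal(res$F[res$effect == "group:condition"],
               pick("Error: subject_id:condition", "group:condition"),
               tolerance = 1e-10)
  expect_equal(res$F[res$effect == "state"],
               pick("Error: subject_id:state", "state"), tolerance = 1e-10)
  expect_equal(res$F[res$effect == "group:state"],
               pick("Error: subject_id:state", "group:state"),
               tolerance = 1e-10)
  expect_equal(res$F[res$effect == "condition:state"],
               pick("Error: subject_id:condition:state", "condition:state"),
               tolerance = 1e-10)
  expect_equal(res$F[res$effect == "group:condition:state"],
               pick("Error: subject_id:condition:state",
                    "group:condition:state"), tolerance = 1e-10)
  expect_equal(res$df_den[res$effect == "state"], 12)
})

test_that("permutation p-values respect the add-one floor and structure", {
  d <- simulate_anova_table(n_per_group = 4, seed = 2)
  res <- perm_rm_anova(d, within = "condition", n_perm = 99, seed = 5)
  expect_true(all(res$p_perm >= 1 / 100))
  expect_true(all(res$p_perm <= 1))
  expect_error(perm_rm_anova(d, within = "condition", n_perm = 0), "n_perm")
})

test_that("incomplete designs and missing values are rejected", {
  d <- simulate_anova_table(n_per_group = 3, seed = 4)
  expect_error(perm_rm_anova(d[-1, ], within = "condition"), "incomplete")
  d2 <- d; d2$value[3] <- NA
  expect_error(perm_rm_anova(d2, within = "condition"), "impute")
  d3 <- d; d3$group <- "A"
  expect_error(perm_rm_anova(d3, within = "condition"), "2 groups")
})

test_that("a strong planted group effect is detected", {
  d <- simulate_anova_table(n_per_group = 5, group_effect_sd = 3, seed = 9)
  res <- perm_rm_anova(d, within = "condition", n_perm = 400, seed = 10)
  expect_lte(res$p_perm[res$effect == "group"], 0.01)
})

test_that("paired permutation t-test matches the closed form and enumeration", {
  x <- c(5.1, 6.3, 4.8, 7.0, 5.9, 6.6)
  y <- c(4.6, 6.1, 5.0, 6.2, 5.1, 6.0)
  d <- data.frame(subject_id = rep(sprintf("s%d", 1:6), 2),
                  cell = rep(c("a", "b"), each = 6),
                  value = c(x, y))
  pairs <- list(list(label = "a-vs-b", a = list(cell = "a"),
                     b = list(cell = "b")))
  out <- pairwise_perm_ttests(d, pairs, paired = TRUE, n_perm = 64, seed = 1)
  expect_equal(out$t, paired_t_oracle(x, y), tolerance = 1e-10)

  # exhaustive enumeration oracle over all 2^6 sign patterns
  dif <- x - y
  tobs <- paired_t_oracle(x, y)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 6)))
  tstar <- apply(signs, 1, function(s) {
    ds <- dif * s
    mean(ds) / (sd(ds) / sqrt(6))
  })
  p_exact <- mean(abs(tstar) >= abs(tobs) - 1e-12)
  expect_equal(out$p_perm, p_exact, tolerance = 1e-12)

  # identical paired samples: t = 0, p = 1
  d0 <- d; d0$value <- rep(x, 2)
  out0 <- pairwise_perm_ttests(d0, pairs, paired = TRUE, n_perm = 50,
                               seed = 2)
  expect_equal(out0$t, 0)
  expect_equal(out0$p_perm, 1)
})

test_that("unpaired permutation t-test permutes group labels", {
  set.seed(12)
  d <- data.frame(subject_id = sprintf("s%d", 1:12),
                  grp = rep(c("A", "B"), each = 6),
                  value = c(rnorm(6), rnorm(6) + 4))
  pairs <- list(list(label = "A-vs-B", a = list(grp = "A"),
                     b = list(grp = "B")))
  out <- pairwise_perm_ttests(d, pairs, paired = FALSE, n_perm = 500,
                              seed = 3)
  tt <- t.test(value ~ grp, data = d, var.equal = TRUE)
  expect_equal(out$t, unname(tt$statistic), tolerance = 1e-10)
  expect_lt(out$p_perm, 0.02)
  expect_true(is.na(out$p_fdr) || out$p_fdr >= out$p_perm)
})

test_that("Benjamini-Hochberg adjustment follows the step-up rule", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(6)
  p <- runif(30)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p - 1e-15))
  expect_true(all(adj <= 1))
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-15))
  # rejections at alpha 0.01 are a subset of rejections at alpha 0.05
  expect_true(all(which(adj <= 0.01) %in% which(adj <= 0.05)))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("2x2 chi-square reproduces the printed demographic statistics", {
  sex <- chi_square_2x2(rbind(c(4, 17), c(7, 14)))
  expect_equal(sex$statistic, 0.49267, tolerance = 5e-6)
  hand <- chi_square_2x2(rbind(c(14, 7), c(13, 8)))
  expect_equal(hand$statistic, 0, tolerance = 1e-12)

  # symmetric rows give 0 with or without correction
  sym <- rbind(c(9, 5), c(9, 5))
  expect_equal(chi_square_2x2(sym, yates = TRUE)$statistic, 0)
  expect_equal(chi_square_2x2(sym, yates = FALSE)$statistic, 0)

  # without Yates: classic sum (O-E)^2/E identity
  tab <- rbind(c(12, 5), c(7, 16))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(chi_square_2x2(tab, yates = FALSE)$statistic,
               sum((tab - E)^2 / E), tolerance = 1e-12)

  expect_error(chi_square_2x2(rbind(c(0, 0), c(3, 4))), "margin")
})

test_that("pooled t from summaries reproduces the printed age comparison", {
  res <- pooled_t_from_summaries(46.524, 11.622, 21, 39.952, 11.320, 21)
  expect_equal(res$t, 1.856, tolerance = 1e-3)
  expect_equal(res$df, 40L)

  eq <- pooled_t_from_summaries(5, 1, 10, 5, 2, 10)
  expect_equal(eq$t, 0)

  # matches a from-raw-data oracle
  set.seed(30)
  x <- rnorm(15, 3, 2); y <- rnorm(12, 2, 2)
  res2 <- pooled_t_from_summaries(mean(x), sd(x), 15, mean(y), sd(y), 12)
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res2$t, unname(tt$statistic), tolerance = 1e-10)

  deg <- pooled_t_from_summaries(5, 0, 5, 5, 0, 5)
  expect_true(deg$undefined)
})

test_that("KS D matches the pooled-grid ECDF oracle", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_two_sample(1:5, 11:15), 1)
  expect_equal(ks_two_sample(c(1, 3), c(2, 4)), 0.5)
  set.seed(40)
  for (i in 1:50) {
    x <- rnorm(sample(5:30, 1)); y <- rnorm(sample(5:30, 1), 0.5)
    expect_equal(ks_two_sample(x, y), ks_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("group mean imputation fills gaps without touching observations", {
  v <- c(10, NA, 20, 5, NA)
  g <- c("A", "A", "A", "B", "B")
  out <- group_mean_impute(v, g)
  expect_equal(out$values, c(10, 15, 20, 5, 5))
  expect_equal(out$imputed, c(2L, 5L))

  clean <- group_mean_impute(c(1, 2), c("A", "B"))
  expect_equal(clean$values, c(1, 2))
  expect_length(clean$imputed, 0)

  expect_error(group_mean_impute(c(1, NA), c("A", "B")), "no observed")
})
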