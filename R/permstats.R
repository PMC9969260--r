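# ---------------------------------------------------------------------------
# Mixed-design (one between-subject factor, m within-subject factors,
# fully crossed and complete) ANOVA by the classical balanced sums-of-squares
# decomposition, plus permutation p-values.
#
# Internal representation: Y is an N_subjects x W matrix (W = product of
# within-factor level counts, columns indexed by the within-cell combination),
# `group` the between label per subject. Every SS is an inclusion-exclusion
# over "T terms" T_F = sum over cells of F of (cell total)^2 / (cell size):
#   SS_E        = sum_{F subset E} (-1)^{|E|-|F|} T_F          (T_empty = G^2/N)
#   SS_S(G)     = T_S - T_B
#   SS_{VxS(G)} = sum_{U subset V} (-1)^{|V|-|U|} (T_{U+S} - T_{U+B})
# with error terms: subjects-within-groups for the between effect, and
# V x subjects-within-groups for any effect whose within part is V.
# ---------------------------------------------------------------------------

# all subsets of an index vector, smallest first (safe for length-1 input,
# unlike combn which reinterprets a scalar)
powerset <- function(v) {
  subs <- list(integer(0))
  for (j in v) subs <- c(subs, lapply(subs, function(u) c(u, j)))
  subs[order(lengths(subs))]
}

# build the design structure once; `data` is long with columns subject,
# group, one column per within factor, and the dv
rm_design <- function(data, dv, between, within, subject) {
  for (col in c(dv, between, within, subject))
    if (!col %in% names(data)) stop(sprintf("column '%s' not found", col))
  if (any(is.na(data[[dv]])))
    stop("missing values in the dependent variable; impute first")
  subj <- factor(data[[subject]])
  wfac <- lapply(within, function(w) factor(data[[w]]))
  names(wfac) <- within
  wlev <- lapply(wfac, levels)
  nlev <- vapply(wlev, length, 0L)
  W <- prod(nlev)
  # column index of each row's within-cell combination
  cell <- rep(1L, nrow(data))
  mult <- 1L
  for (j in seq_along(wfac)) {
    cell <- cell + (as.integer(wfac[[j]]) - 1L) * mult
    mult <- mult * nlev[j]
  }
  subjects <- levels(subj)
  N <- length(subjects)
  Y <- matrix(NA_real_, N, W)
  Y[cbind(as.integer(subj), cell)] <- data[[dv]]
  if (anyNA(Y)) stop("design is incomplete: every subject needs one ",
                     "observation per within-cell")
  if (any(table(subj, cell) != 1))
    stop("duplicate observations in at least one subject x cell")
  gmap <- tapply(as.character(data[[between]]), subj, function(g) g[1])
  group <- factor(unname(gmap[subjects]))
  if (nlevels(group) < 2) stop("at least 2 groups required")
  if (any(table(group) < 2)) stop("fewer than 2 subjects in a group")
  # per within-subset column groupings (cell id within the subset's margins)
  subsets <- unlist(lapply(seq_along(within), function(m)
    utils::combn(seq_along(within), m, simplify = FALSE)), recursive = FALSE)
  wl <- matrix(0L, W, length(within))  # level index of each column per factor
  idx <- 0:(W - 1)
  for (j in seq_along(within)) {
    wl[, j] <- (idx %/% prod(c(1L, nlev)[seq_len(j)])) %% nlev[j] + 1L
  }
  colgroup <- lapply(subsets, function(us) {
    g <- rep(1L, W); mult <- 1L
    for (j in us) { g <- g + (wl[, j] - 1L) * mult; mult <- mult * nlev[j] }
    g
  })
  names(colgroup) <- vapply(subsets, function(us)
    paste(sort(us), collapse = ","), "")
  list(Y = Y, group = group, within = within, nlev = nlev, W = W, N = N,
       subsets = subsets, colgroup = colgroup, wl = wl)
}

# T terms for a given Y and group assignment.
# Returns a closure-free list the F computation indexes into.
rm_tterms <- function(d, Y, group) {
  N <- d$N; W <- d$W
  gsizes <- table(group)
  total <- sum(Y)
  T0 <- total^2 / (N * W)
  TS <- sum(rowSums(Y)^2) / W
  gsum <- rowsum(rowSums(Y), group)
  TB <- sum(gsum^2 / (as.numeric(gsizes[rownames(gsum)]) * W))
  TU <- list(); TUB <- list(); TUS <- list()
  for (nm in names(d$colgroup)) {
    cg <- d$colgroup[[nm]]
    csize <- tabulate(cg)                      # columns per margin cell
    colsums_by <- rowsum(t(Y), cg)             # margin x subjects
    mtot <- rowSums(colsums_by)                # margin totals over all subjects
    TU[[nm]] <- sum(mtot^2 / (csize * N))
    gm <- rowsum(t(colsums_by), group)         # groups x margins
    TUB[[nm]] <- sum(gm^2 / outer(as.numeric(gsizes[rownames(gm)]), csize))
    TUS[[nm]] <- sum(colsums_by^2 / csize)
  }
  list(T0 = T0, TS = TS, TB = TB, TU = TU, TUB = TUB, TUS = TUS)
}

# F statistic for one effect; effect = list(between = TRUE/FALSE,
# within = integer subset of within-factor positions)
rm_effect_F <- function(d, tt, effect) {
  key <- function(us) paste(sort(us), collapse = ",")
  tval <- function(us, with_b) {
    if (!length(us)) { if (with_b) tt$TB else tt$T0 }
    else if (with_b) tt$TUB[[key(us)]] else tt$TU[[key(us)]]
  }
  V <- effect$within
  # numerator SS by inclusion-exclusion over sub-effects
  ss <- 0
  nsub <- length(V)
  subs <- powerset(V)
  for (us in subs) {
    sgn_u <- (-1)^(nsub - length(us))
    if (effect$between) {
      ss <- ss + sgn_u * (tval(us, TRUE) - tval(us, FALSE))
    } else {
      ss <- ss + sgn_u * tval(us, FALSE)
    }
  }
  df_num <- prod(d$nlev[V] - 1)
  if (effect$between) df_num <- df_num * (nlevels(d$group) - 1)
  if (!effect$between && !length(V)) stop("empty effect")
  # error SS
  a <- nlevels(d$group)
  if (!length(V)) {                       # pure between effect
    ss_err <- tt$TS - tt$TB
    df_err <- d$N - a
  } else {
    ss_err <- 0
    for (us in subs[vapply(subs, function(u) all(u %in% V), TRUE)]) {
      sgn_u <- (-1)^(length(V) - length(us))
      tus <- if (length(us)) tt$TUS[[key(us)]] else tt$TS
      tub <- tval(us, TRUE)
      ss_err <- ss_err + sgn_u * (tus - tub)
    }
    df_err <- prod(d$nlev[V] - 1) * (d$N - a)
  }
  F <- (ss / df_num) / (ss_err / df_err)
  list(F = F, df_num = df_num, df_den = df_err, ss = ss, ss_err = ss_err)
}

# balanced effect estimate per (subject x cell) for the Freedman-Lane reduced
# model: grand mean + all fixed effects except `skip`
rm_reduced_fit <- function(d, Y, group, skip) {
  N <- d$N; W <- d$W
  fit <- matrix(mean(Y), N, W)
  eff_names <- function(e) paste(e$between, paste(e$within, collapse = ","))
  for (e in rm_all_effects(d)) {
    if (identical(eff_names(e), eff_names(skip))) next
    fit <- fit + rm_effect_estimate(d, Y, group, e)
  }
  fit
}

# inclusion-exclusion estimate of one fixed effect, broadcast to N x W
rm_effect_estimate <- function(d, Y, group, effect) {
  key <- function(us) paste(sort(us), collapse = ",")
  V <- effect$within
  nsub <- length(V)
  subs <- powerset(V)
  est <- matrix(0, d$N, d$W)
  for (us in subs) {
    sgn_u <- (-1)^(nsub - length(us))
    terms <- list(FALSE)
    if (effect$between) terms <- list(TRUE, FALSE)
    for (wb in terms) {
      sgn <- sgn_u * (if (effect$between && !wb) -1 else 1)
      m <- rm_margin_mean(d, Y, group, us, wb)   # N x W matrix of margin means
      est <- est + sgn * m
    }
  }
  est
}

rm_margin_mean <- function(d, Y, group, us, with_b) {
  if (!length(us)) {
    if (with_b) {
      gm <- rowsum(Y, group) / as.vector(table(group))
      return(matrix(rowMeans(gm)[as.integer(group)], d$N, d$W))
    }
    return(matrix(mean(Y), d$N, d$W))
  }
  cg <- d$colgroup[[paste(sort(us), collapse = ",")]]
  csize <- tabulate(cg)
  if (with_b) {
    sums <- rowsum(t(rowsum(Y, group)), cg)           # margins x groups
    cnt <- outer(csize, as.vector(table(group)))
    means <- sums / cnt                                # margins x groups
    return(t(means[cg, as.integer(group), drop = FALSE]))
  }
  msum <- rowsum(colSums(Y), cg)
  means <- msum / (csize * d$N)
  matrix(rep(means[cg], each = d$N), d$N, d$W)
}

rm_all_effects <- function(d) {
  m <- length(d$within)
  effs <- list()
  wsubs <- c(list(integer(0)), unlist(lapply(seq_len(m), function(j)
    utils::combn(seq_len(m), j, simplify = FALSE)), recursive = FALSE))
  for (b in c(TRUE, FALSE)) for (us in wsubs) {
    if (!b && !length(us)) next
    effs[[length(effs) + 1]] <- list(between = b, within = us)
  }
  effs
}

rm_effect_label <- function(d, between_name, effect) {
  parts <- character(0)
  if (effect$between) parts <- between_name
  parts <- c(parts, d$within[effect$within])
  paste(parts, collapse = ":")
}

#' Permutation repeated-measures ANOVA
#'
#' Classical mixed-design F statistics (one between-subject factor, any
#' number of fully crossed within-subject factors; the between-effect error
#' is subjects-within-groups, within effects and interactions use the
#' effect x subject-within-group mean square), with permutation p-values:
#' between-subject effects permute whole-subject group labels; within-subject
#' main effects permute that factor's levels independently within each
#' subject; interactions use Freedman-Lane residual permutation (residuals of
#' the model without the tested effect, permuted within the appropriate
#' exchangeability blocks). p-values use the add-one estimator
#' `(1 + #(F* >= F_obs)) / (1 + n_perm)`.
#'
#' @param data Long data.frame with one row per observation.
#' @param dv Name of the dependent-variable column.
#' @param between Name of the between-subject factor column (group).
#' @param within Character vector of within-subject factor columns.
#' @param subject Name of the subject-id column.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return data.frame with `effect`, `F`, `df_num`, `df_den`, `p_perm`.
#'   An effect whose numerator and error sums of squares are both exactly
#'   zero (inestimable, e.g. a compositional dependent variable whose cell
#'   means are constrained) is reported with `F = NaN` and `p_perm = NA`.
#' @export
perm_rm_anova <- function(data, dv = "value", between = "group",
                          within = c("condition", "state"),
                          subject = "subject_id", n_perm = 10000L,
                          seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  d <- rm_design(data, dv, between, within, subject)
  tt_obs <- rm_tterms(d, d$Y, d$group)
  effects <- rm_all_effects(d)
  obs <- lapply(effects, function(e) rm_effect_F(d, tt_obs, e))
  set.seed(as.integer(seed))
  p_perm <- numeric(length(effects))
  for (i in seq_along(effects)) {
    e <- effects[[i]]
    Fobs <- obs[[i]]$F
    if (!is.finite(Fobs)) {
      # 0/0: the effect is inestimable (e.g. a compositional dependent
      # variable whose cell means are constrained, as fractional occupancy
      # summed over states); report NA rather than permute nothing
      p_perm[i] <- NA_real_
      next
    }
    cnt <- 0L
    pure_between <- e$between && !length(e$within)
    within_main <- !e$between && length(e$within) == 1L
    if (!pure_between && !within_main) {
      fit <- rm_reduced_fit(d, d$Y, d$group, e)
      res <- d$Y - fit
    }
    for (p in seq_len(n_perm)) {
      if (pure_between) {
        gperm <- d$group[sample.int(d$N)]
        tt <- rm_tterms(d, d$Y, gperm)
        Fp <- rm_effect_F(d, tt, e)$F
      } else if (within_main) {
        Yp <- permute_within_factor(d, d$Y, e$within)
        tt <- rm_tterms(d, Yp, d$group)
        Fp <- rm_effect_F(d, tt, e)$F
      } else if (e$between) {
        # effect involves group: permute whole-subject residual blocks
        Yp <- fit + res[sample.int(d$N), , drop = FALSE]
        tt <- rm_tterms(d, Yp, d$group)
        Fp <- rm_effect_F(d, tt, e)$F
      } else {
        # pure within interaction: permute residual cells within each subject
        rp <- t(apply(res, 1, function(r) r[sample.int(d$W)]))
        Yp <- fit + rp
        tt <- rm_tterms(d, Yp, d$group)
        Fp <- rm_effect_F(d, tt, e)$F
      }
      # a degenerate permuted table (zero error variance) leaves F undefined;
      # counting it as an exceedance keeps the p-value conservative
      if (is.na(Fp) || Fp >= Fobs) cnt <- cnt + 1L
    }
    p_perm[i] <- (1 + cnt) / (1 + n_perm)
  }
  data.frame(
    effect = vapply(effects, function(e) rm_effect_label(d, between, e), ""),
    F = vapply(obs, `[[`, 0, "F"),
    df_num = vapply(obs, `[[`, 0, "df_num"),
    df_den = vapply(obs, `[[`, 0, "df_den"),
    p_perm = p_perm,
    stringsAsFactors = FALSE)
}

# within-main permutation: per subject, relabel factor j's levels by a random
# permutation (moves whole slices, keeping the other within factors aligned)
permute_within_factor <- function(d, Y, j) {
  lv <- d$nlev[j]
  Yp <- Y
  for (i in seq_len(d$N)) {
    pj <- sample.int(lv)
    # column with level l of factor j takes the values of level pj[l]
    newcol <- order_columns_by_level(d, j, pj)
    Yp[i, ] <- Y[i, newcol]
  }
  Yp
}

order_columns_by_level <- function(d, j, pj) {
  wl <- d$wl
  # for destination column c with level l = wl[c, j], source column has level
  # pj[l] in factor j and identical levels elsewhere
  src <- integer(d$W)
  mults <- cumprod(c(1L, d$nlev))[seq_along(d$nlev)]
  for (cc in seq_len(d$W)) {
    levs <- wl[cc, ]
    levs[j] <- pj[levs[j]]
    src[cc] <- 1L + sum((levs - 1L) * mults)
  }
  src
}

#' Post hoc pairwise permutation t-tests with FDR correction
#'
#' Each comparison contrasts two cells of the metrics table. Cells differing
#' only in within-subject factors are compared with a paired t-test whose
#' permutation distribution flips the signs of the within-subject
#' differences; cells differing in group use an unpaired pooled t-test with
#' group-label permutation. p-values use the add-one estimator and are
#' Benjamini-Hochberg adjusted over the emitted family. When all `2^n` sign
#' patterns of a paired comparison fit within `n_perm`, the permutation
#' distribution is enumerated exhaustively and the p-value is exact.
#'
#' @param data Long data.frame (as for [perm_rm_anova()]).
#' @param pairs List of comparisons; each element is a list with `label`,
#'   `a` and `b` — `a`/`b` being named lists of column = value filters
#'   selecting one cell each.
#' @param dv,subject Column names.
#' @param paired Logical per pair, or a single logical; TRUE when the two
#'   cells share subjects.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return data.frame `pair`, `t`, `p_perm`, `p_fdr`, `n`, `excluded`.
#' @export
pairwise_perm_ttests <- function(data, pairs, dv = "value",
                                 subject = "subject_id", paired = TRUE,
                                 n_perm = 10000L, seed = 1L) {
  paired <- rep_len(paired, length(pairs))
  set.seed(as.integer(seed))
  rows <- list()
  pick <- function(filters) {
    keep <- rep(TRUE, nrow(data))
    for (col in names(filters)) keep <- keep & data[[col]] == filters[[col]]
    data[keep, c(subject, dv)]
  }
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    A <- pick(pr$a); B <- pick(pr$b)
    if (paired[i]) {
      m <- merge(A, B, by = subject)
      dif <- m[[paste0(dv, ".x")]] - m[[paste0(dv, ".y")]]
      dif <- dif[!is.na(dif)]
      n <- length(dif)
      if (n < 2) {
        rows[[length(rows) + 1]] <- data.frame(pair = pr$label, t = NA,
          p_perm = NA, n = n, excluded = TRUE)
        next
      }
      tobs <- paired_t_stat(dif)
      if (2^n <= n_perm) {
        # full enumeration of the 2^n sign patterns: exact p, no add-one
        tol <- 1e-12
        cnt <- 0L
        for (code in 0:(2^n - 1)) {
          signs <- 1 - 2 * as.integer(intToBits(code)[1:n])
          if (abs(paired_t_stat(dif * signs)) >= abs(tobs) - tol)
            cnt <- cnt + 1L
        }
        rows[[length(rows) + 1]] <- data.frame(
          pair = pr$label, t = tobs, p_perm = cnt / 2^n, n = n,
          excluded = FALSE)
        next
      }
      cnt <- 0L
      for (p in seq_len(n_perm)) {
        signs <- sample(c(-1, 1), n, replace = TRUE)
        if (abs(paired_t_stat(dif * signs)) >= abs(tobs)) cnt <- cnt + 1L
      }
    } else {
      x <- A[[dv]][!is.na(A[[dv]])]; y <- B[[dv]][!is.na(B[[dv]])]
      n <- length(x) + length(y)
      if (length(x) < 2 || length(y) < 2) {
        rows[[length(rows) + 1]] <- data.frame(pair = pr$label, t = NA,
          p_perm = NA, n = n, excluded = TRUE)
        next
      }
      tobs <- unpaired_t_stat(x, y)
      pooled <- c(x, y); nx <- length(x)
      cnt <- 0L
      for (p in seq_len(n_perm)) {
        idx <- sample.int(n, nx)
        if (abs(unpaired_t_stat(pooled[idx], pooled[-idx])) >= abs(tobs))
          cnt <- cnt + 1L
      }
    }
    rows[[length(rows) + 1]] <- data.frame(
      pair = pr$label, t = tobs, p_perm = (1 + cnt) / (1 + n_perm), n = n,
      excluded = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  ok <- !out$excluded
  if (any(ok)) out$p_fdr[ok] <- bh_fdr(out$p_perm[ok])
  rownames(out) <- NULL
  out[, c("pair", "t", "p_perm", "p_fdr", "n", "excluded")]
}

paired_t_stat <- function(dif) {
  n <- length(dif)
  s <- stats::sd(dif)
  if (s == 0) return(0)
  mean(dif) / (s / sqrt(n))
}

unpaired_t_stat <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 == 0) return(0)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: monotone, capped at 1, original order restored.
#'
#' @param pvals Numeric vector in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Pearson chi-square for a 2x2 table
#'
#' Yates continuity correction is on by default for 2x2 tables.
#'
#' @param counts 2x2 matrix of non-negative counts with positive margins.
#' @param yates Apply the continuity correction.
#' @return List with `statistic` and `df` (= 1).
#' @export
chi_square_2x2 <- function(counts, yates = TRUE) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2, 2)), all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin in contingency table")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = yates))
  list(statistic = unname(ct$statistic), df = 1L)
}

#' Pooled two-sample t statistic from summary statistics
#'
#' Equal-variance two-sample t from group means, SDs and sizes;
#' `df = n1 + n2 - 2`.
#'
#' @param m1,sd1,n1 Mean, SD and size of sample 1.
#' @param m2,sd2,n2 Mean, SD and size of sample 2.
#' @return List with `t`, `df` and `undefined` (TRUE when both SDs are zero
#'   and the means are equal).
#' @export
pooled_t_from_summaries <- function(m1, sd1, n1, m2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (sp2 == 0 && m1 == m2)
    return(list(t = NA_real_, df = n1 + n2 - 2L, undefined = TRUE))
  list(t = (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2)),
       df = as.integer(n1 + n2 - 2), undefined = FALSE)
}

#' Two-sample Kolmogorov-Smirnov D statistic
#'
#' Supremum absolute difference of the two empirical CDFs.
#'
#' @param x,y Non-empty numeric samples.
#' @return The D statistic.
#' @export
ks_two_sample <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  unname(suppressWarnings(stats::ks.test(x, y))$statistic)
}

#' Group-wise mean imputation
#'
#' Missing entries are replaced by the mean of the observed entries of their
#' group; observed values are untouched.
#'
#' @param values Numeric vector with `NA`s.
#' @param groups Group label per value.
#' @return List with `values` (completed) and `imputed` (indices replaced).
#' @export
group_mean_impute <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  miss <- which(is.na(values))
  for (i in miss) {
    obs <- values[groups == groups[i] & !is.na(values)]
    if (!length(obs))
      stop(sprintf("group '%s' has no observed values", groups[i]))
    values[i] <- mean(obs)
  }
  list(values = values, imputed = miss)
}
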