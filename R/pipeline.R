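#' Pipeline run configuration
#'
#' Collects every stage parameter with the defaults of the reference
#' analysis: 0.04-0.07 Hz fifth-order zero-phase band-pass, 10 + 10 edge
#' volumes discarded, K scanned over 3..15 with 20 restarts, 8-TR hemodynamic
#' shift variant, 10,000 permutations.
#'
#' @param manifest Path to a cohort manifest (see [read_manifest()]).
#' @param out_dir Output directory for stage artifacts; NULL for none.
#' @param low,high,order Band-pass parameters.
#' @param front_trim,back_trim Edge volumes discarded.
#' @param k_range Candidate cluster counts (a single value fixes K).
#' @param n_restarts k-means restarts.
#' @param dunn_subsample Point cap for the Dunn index.
#' @param shift_tr Hemodynamic shift variant, in TRs (0 disables).
#' @param n_perm Permutations for the ANOVA.
#' @param alpha Significance level.
#' @param seed Global seed; per-stage child seeds are derived from it.
#' @param tr Fallback TR when the manifest lacks a `tr` column.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(manifest, out_dir = NULL, low = 0.04, high = 0.07,
                       order = 5L, front_trim = 10L, back_trim = 10L,
                       k_range = 3:15, n_restarts = 20L,
                       dunn_subsample = 8000L, shift_tr = 8L,
                       n_perm = 10000L, alpha = 0.05, seed = 1L, tr = NULL) {
  structure(list(manifest = manifest, out_dir = out_dir, low = low,
                 high = high, order = as.integer(order),
                 front_trim = as.integer(front_trim),
                 back_trim = as.integer(back_trim), k_range = k_range,
                 n_restarts = as.integer(n_restarts),
                 dunn_subsample = dunn_subsample,
                 shift_tr = as.integer(shift_tr),
                 n_perm = as.integer(n_perm), alpha = alpha,
                 seed = as.integer(seed), tr = tr),
            class = "run_config")
}

#' Run the full phase-locking analysis
#'
#' Stages: load cohort, band-pass + Hilbert phases + trimming, per-timepoint
#' coherence and leading eigenvectors, pooled k-means with Dunn-index K
#' selection, per-subject condition arrays (unshifted and hemodynamically
#' shifted), analysis windows, the four temporal state metrics, and the
#' permutation repeated-measures ANOVAs per metric. Missing state x condition
#' cells are imputed by the group x condition x state(x to-state) cell mean
#' before the ANOVA, with the imputation count reported.
#'
#' @param config A [run_config()].
#' @return A list of class `"run_report"`: `cluster` (the selected
#'   `cluster_model`), `k_table` (k vs Dunn), `metrics` (long table over both
#'   shift variants), `anova` (named list of effect tables per metric, for
#'   shift 0), `counts` (bookkeeping: subjects, retained volumes, pooled
#'   rows, dropped/merged episodes, imputed cells), `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  mf <- read_manifest(cfg$manifest, tr = cfg$tr)
  n_sub <- nrow(mf)

  sets <- vector("list", n_sub)
  retained <- integer(n_sub)
  recs <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    bold <- read_bold_matrix(mf$bold_path[i])
    rec <- subject_recording(mf$subject_id[i], mf$group[i], bold, mf$tr[i])
    ps <- phase_series(rec, cfg$low, cfg$high, cfg$order,
                       cfg$front_trim, cfg$back_trim)
    sets[[i]] <- eigenvector_series(ps)
    retained[i] <- ncol(ps$phases)
    recs[[i]] <- list(rec = rec, n_volumes = ncol(bold))
  }
  pooled <- concatenate_eigenvectors(sets)

  if (length(cfg$k_range) == 1L) {
    model <- kmeans_states(pooled$vectors, cfg$k_range, cfg$n_restarts,
                           seed = derive_seed(cfg$seed, "kmeans/fixed"))
    model$dunn <- as.numeric(dunn_index(pooled$vectors, model$labels,
                                        subsample = cfg$dunn_subsample,
                                        seed = derive_seed(cfg$seed, "dunn")))
    k_table <- data.frame(k = model$k, dunn = model$dunn,
                          inertia = model$inertia)
  } else {
    sel <- select_optimal_k(pooled$vectors, cfg$k_range, cfg$n_restarts,
                            seed = cfg$seed,
                            dunn_subsample = cfg$dunn_subsample)
    model <- sel$best
    k_table <- sel$table
  }
  k <- model$k

  dropped <- 0L; merged <- 0L
  shifts <- unique(c(0L, cfg$shift_tr))
  tables <- list()
  for (i in seq_len(n_sub)) {
    rec <- recs[[i]]$rec
    tl <- read_events_tsv(mf$events_path[i],
                          scan_dur = recs[[i]]$n_volumes * rec$tr)
    ca0 <- events_to_condition_array(tl, rec$tr, recs[[i]]$n_volumes,
                                     cfg$front_trim, cfg$back_trim)
    dropped <- dropped + ca0$n_dropped; merged <- merged + ca0$n_merged
    st <- model$labels[pooled$index$subject_id == rec$subject_id]
    for (sh in shifts) {
      ca <- if (sh > 0) suppressWarnings(shift_condition_array(ca0, sh))
            else ca0
      tables[[length(tables) + 1]] <-
        subject_metrics(st, ca, k, rec$tr, rec$subject_id, rec$group,
                        shift = sh)
    }
  }
  metrics <- assemble_metrics(tables)

  anova <- list()
  imputed <- 0L
  for (metric in c("switch_freq", "occupancy", "dwell_time")) {
    sub <- metrics[metrics$metric == metric & metrics$shift == 0L, ]
    within <- if (metric == "switch_freq") "condition"
              else c("condition", "state")
    imp <- impute_metric_cells(sub)
    imputed <- imputed + imp$n_imputed
    anova[[metric]] <- perm_rm_anova(
      imp$data, dv = "value", between = "group", within = within,
      subject = "subject_id", n_perm = cfg$n_perm,
      seed = derive_seed(cfg$seed, paste0("anova/", metric)))
  }

  report <- structure(list(
    cluster = model, k_table = k_table, metrics = metrics, anova = anova,
    index = pooled$index,
    counts = list(n_subjects = n_sub, retained_volumes = retained,
                  pooled_rows = nrow(pooled$vectors),
                  dropped_episodes = dropped, merged_episodes = merged,
                  imputed_cells = imputed),
    config = cfg), class = "run_report")

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_metrics_table(metrics, file.path(cfg$out_dir, "metrics.tsv"))
    utils::write.table(k_table, file.path(cfg$out_dir, "k_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(model$centroids,
                       file.path(cfg$out_dir, "centroids.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    for (metric in names(anova))
      utils::write.table(anova[[metric]],
                         file.path(cfg$out_dir,
                                   paste0("anova_", metric, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}

# complete missing (value NA) cells with the group x condition x state
# (x to_state) cell mean of the observed subjects
impute_metric_cells <- function(data) {
  eq <- function(a, b) if (is.na(b)) is.na(a) else !is.na(a) & a == b
  miss <- which(data$missing | is.na(data$value))
  for (i in miss) {
    same <- data$group == data$group[i] &
      data$condition == data$condition[i] &
      eq(data$state, data$state[i]) &
      eq(data$to_state, data$to_state[i]) &
      !is.na(data$value)
    obs <- data$value[same]
    if (!length(obs))
      stop("cannot impute: an entire group x cell is missing")
    data$value[i] <- mean(obs)
    data$missing[i] <- FALSE
  }
  list(data = data, n_imputed = length(miss))
}

#' @export
print.run_report <- function(x, ...) {
  cat("phase-locking analysis run\n")
  cat(sprintf("  subjects: %d, pooled eigenvectors: %d rows\n",
              x$counts$n_subjects, x$counts$pooled_rows))
  cat(sprintf("  selected K = %d (Dunn %.4g)\n", x$cluster$k, x$cluster$dunn))
  cat(sprintf("  episodes dropped by rounding: %d, merged: %d, imputed cells: %d\n",
              x$counts$dropped_episodes, x$counts$merged_episodes,
              x$counts$imputed_cells))
  for (m in names(x$anova)) {
    cat(sprintf("  ANOVA [%s]:\n", m))
    print(x$anova[[m]], row.names = FALSE)
  }
  invisible(x)
}
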