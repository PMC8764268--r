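# Repeated-seed random-forest cross-validation: error-vs-feature-count
# curves with fold-internal feature ranking, one-SD marker selection, the
# union marker set across seeds, and pooled out-of-fold ROC/AUC.

# deterministic sub-seed derivation so every RF fit is reproducible
derive_seed <- function(base, a = 0L, b = 0L) {
  as.integer((as.double(base) * 7919 + a * 104729 + b * 1299709) %% 2147483647) + 1L
}

# stratified fold assignment: per class, shuffle then deal round-robin
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  set.seed(seed)
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Random-forest cross-validation error curves
#'
#' For each seed: stratified k-fold split; within each fold, features are
#' ranked by random-forest importance computed on the training part only
#' (leakage-safe), then the held-out error is evaluated for nested top-m
#' feature subsets with m halving from all features down to 1. Out-of-fold
#' class probabilities at the full feature set are recorded for ROC.
#'
#' @param core a `core_table`, [abundance_table], or samples-x-taxa matrix.
#' @param labels binary class labels, one per sample.
#' @param k_folds folds per seed (default 5).
#' @param seeds integer seeds, one repeat each (default `1:10`).
#' @param n_trees trees per forest.
#' @param importance `"permutation"` (mean decrease in accuracy, default) or
#'   `"impurity"` (mean decrease in Gini).
#' @return object of class `rfcv_result`: list with `subset_sizes`
#'   (decreasing, ending at 1), `error_mean` / `error_sd` (seed x size
#'   matrices, across folds), `ranking_per_seed` (aggregate feature ranking),
#'   `cv_predictions` (sample x seed out-of-fold probability of the second
#'   class level), `labels`, `seeds`, `taxa`.
#' @export
rfcv_curves <- function(core, labels, k_folds = 5L, seeds = 1:10,
                        n_trees = 500L,
                        importance = c("permutation", "impurity")) {
  importance <- match.arg(importance)
  x <- if (inherits(core, "core_table")) sample_matrix(core$abundance)
       else if (inherits(core, "abundance_table")) sample_matrix(core)
       else as.matrix(core)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2) stop("binary class labels required")
  if (k_folds > min(table(labels)))
    stop("k_folds exceeds the smallest class size")
  p <- ncol(x)
  sizes <- p
  while (sizes[length(sizes)] > 1) sizes <- c(sizes, ceiling(sizes[length(sizes)] / 2))
  sizes <- unique(as.integer(sizes))
  imp_type <- if (importance == "permutation") 1L else 2L
  pos_level <- levels(labels)[2]

  err_mean <- matrix(NA_real_, length(seeds), length(sizes),
                     dimnames = list(seeds, sizes))
  err_sd <- err_mean
  preds <- matrix(NA_real_, nrow(x), length(seeds),
                  dimnames = list(rownames(x), seeds))
  ranking <- list()

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  for (si in seq_along(seeds)) {
    seed <- seeds[si]
    folds <- stratified_folds(labels, k_folds, derive_seed(seed))
    fold_err <- matrix(NA_real_, k_folds, length(sizes))
    rank_acc <- matrix(NA_real_, k_folds, p, dimnames = list(NULL, colnames(x)))
    for (f in seq_len(k_folds)) {
      tr <- folds != f
      set.seed(derive_seed(seed, f, 0L))
      fit_full <- randomForest::randomForest(
        x[tr, , drop = FALSE], labels[tr], ntree = n_trees,
        importance = importance == "permutation")
      imp <- randomForest::importance(fit_full, type = imp_type)[, 1]
      ord <- order(-imp, colnames(x))
      rank_acc[f, colnames(x)[ord]] <- seq_len(p)
      for (mi in seq_along(sizes)) {
        m <- sizes[mi]
        feats <- colnames(x)[ord[seq_len(m)]]
        if (m == p) {
          fit <- fit_full
        } else {
          set.seed(derive_seed(seed, f, mi))
          fit <- randomForest::randomForest(
            x[tr, feats, drop = FALSE], labels[tr], ntree = n_trees)
        }
        pred <- stats::predict(fit, x[!tr, feats, drop = FALSE])
        fold_err[f, mi] <- mean(pred != labels[!tr])
        if (m == p) {
          prob <- stats::predict(fit, x[!tr, feats, drop = FALSE],
                                 type = "prob")[, pos_level]
          preds[!tr, si] <- prob
        }
      }
    }
    err_mean[si, ] <- colMeans(fold_err)
    err_sd[si, ] <- apply(fold_err, 2, stats::sd)
    ranking[[as.character(seed)]] <- colMeans(rank_acc)
  }
  structure(list(subset_sizes = sizes, error_mean = err_mean,
                 error_sd = err_sd, ranking_per_seed = ranking,
                 cv_predictions = preds, labels = labels,
                 positive_level = pos_level, seeds = seeds,
                 taxa = colnames(x), k_folds = k_folds, n_trees = n_trees),
            class = "rfcv_result")
}

#' Select marker taxa from RFCV error curves
#'
#' Per seed, the selected feature count m* is the smallest m whose mean CV
#' error is within one standard deviation (taken at the curve's minimum) of
#' the minimum (`rule = "one_sd"`), or the smallest m attaining the minimum
#' (`rule = "min"`). Each seed's marker set is its top-m* taxa by aggregate
#' (mean across folds) importance ranking; the union over seeds is the
#' final marker set.
#'
#' @param result an `rfcv_result`.
#' @param rule `"one_sd"` (default) or `"min"`.
#' @return list with `m_star` (per seed), `selected_per_seed` (list of taxon
#'   sets) and `union_markers`.
#' @export
select_markers <- function(result, rule = c("one_sd", "min")) {
  rule <- match.arg(rule)
  sizes <- result$subset_sizes
  sel <- list()
  m_star <- stats::setNames(integer(length(result$seeds)),
                            as.character(result$seeds))
  for (si in seq_along(result$seeds)) {
    mean_err <- result$error_mean[si, ]
    sd_err <- result$error_sd[si, ]
    i_min <- which(mean_err == min(mean_err))
    # among ties for the minimum, take the smallest subset size
    i_min <- i_min[which.min(sizes[i_min])]
    thr <- if (rule == "one_sd") mean_err[i_min] + sd_err[i_min]
           else mean_err[i_min]
    ok <- which(mean_err <= thr + 1e-12)
    m <- min(sizes[ok])
    m_star[si] <- m
    rk <- result$ranking_per_seed[[as.character(result$seeds[si])]]
    sel[[as.character(result$seeds[si])]] <-
      names(sort(rk))[seq_len(m)]
  }
  list(m_star = m_star, selected_per_seed = sel,
       union_markers = sort(unique(unlist(sel))))
}

#' Pooled cross-validation ROC and AUC
#'
#' Pools the out-of-fold class probabilities (averaged across seeds per
#' sample) and traces the ROC curve over all thresholds; the AUC is the
#' trapezoidal area, identical to the normalized Mann-Whitney U statistic.
#'
#' @param result an `rfcv_result`.
#' @param positive_label class treated as positive (default: the second
#'   factor level, whose probability was recorded).
#' @return list with `roc` (data.frame: threshold, fpr, tpr) and `auc`.
#' @export
cv_roc <- function(result, positive_label = result$positive_level) {
  probs <- rowMeans(result$cv_predictions)
  labels <- result$labels
  if (!positive_label %in% levels(labels)) stop("unknown positive label")
  score <- if (positive_label == result$positive_level) probs else 1 - probs
  pos <- labels == positive_label
  if (all(pos) || !any(pos)) stop("both classes are required for ROC")
  roc_points(score, pos)
}

# ROC step curve + trapezoidal AUC from scores and a positive indicator
roc_points <- function(score, pos) {
  ord <- order(-score)
  score <- score[ord]; pos <- pos[ord]
  n1 <- sum(pos); n0 <- sum(!pos)
  # group tied scores so the curve moves diagonally through ties
  grp <- cumsum(!duplicated(score))
  tp <- tapply(pos, grp, sum); fp <- tapply(!pos, grp, sum)
  tpr <- c(0, cumsum(tp) / n1)
  fpr <- c(0, cumsum(fp) / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(threshold = c(Inf, unique(score)), fpr = fpr, tpr = tpr),
       auc = auc)
}
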