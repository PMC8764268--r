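# Subject regrouping: mixed-type distances, seeded clustering, and the
# cluster-number vote over validity indices.

#' Subject-subject distance over clinical features
#'
#' `euclidean` z-scores each continuous column (so dietary items measured on
#' different scales weigh equally) and requires complete data on the chosen
#' features; `gower` handles mixed continuous/categorical features and
#' missing cells by averaging, over the non-missing features of each pair,
#' the range-scaled absolute difference (continuous) or the 0/1 mismatch
#' indicator (categorical).
#'
#' @param meta clinical data.frame, samples as rows.
#' @param features character vector of column names (default: all columns).
#' @param metric `"euclidean"` or `"gower"`.
#' @return a `stats::dist` object labelled with sample ids.
#' @export
mixed_distance <- function(meta, features = colnames(meta),
                           metric = c("euclidean", "gower")) {
  metric <- match.arg(metric)
  missing_feat <- setdiff(features, colnames(meta))
  if (length(missing_feat) > 0)
    stop("unknown feature(s): ", paste(missing_feat, collapse = ", "))
  sub <- meta[, features, drop = FALSE]
  if (metric == "euclidean") {
    if (!all(vapply(sub, is.numeric, logical(1))))
      stop("euclidean distance requires all-continuous features; use gower")
    if (anyNA(sub))
      stop("euclidean distance requires complete data; drop incomplete ",
           "subjects or use gower")
    z <- scale(as.matrix(sub))
    z[, attr(z, "scaled:scale") == 0] <- 0
    d <- stats::dist(z)
  } else {
    sub[] <- lapply(sub, function(col) if (is.character(col)) factor(col) else col)
    d <- cluster::daisy(sub, metric = "gower", warnBin = FALSE,
                        warnAsym = FALSE, warnConst = FALSE)
    if (anyNA(d)) {
      dm <- as.matrix(d)
      bad <- which(is.na(dm), arr.ind = TRUE)[1, ]
      stop(sprintf("gower distance undefined for subjects '%s' and '%s': no shared non-missing feature",
                   rownames(sub)[bad[1]], rownames(sub)[bad[2]]))
    }
    class(d) <- "dist"
  }
  attr(d, "Labels") <- rownames(sub)
  d
}

# k-means++ seeding: spread the initial centers with probability
# proportional to squared distance from the chosen set
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[idx, ], n, ncol(x), byrow = TRUE))^2)
  while (length(idx) < k) {
    if (sum(d2) == 0) {
      cand <- setdiff(seq_len(n), idx)
      idx <- c(idx, cand[sample.int(length(cand), 1L)])
    } else {
      idx <- c(idx, sample.int(n, 1L, prob = d2))
    }
    dn <- rowSums((x - matrix(x[idx[length(idx)], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, dn)
  }
  x[idx, , drop = FALSE]
}

#' Assign samples to k clusters
#'
#' `kmeans` runs on coordinate data with k-means++ initialization, `n_init`
#' restarts and the best (lowest) total within-cluster sum of squares kept;
#' `pam` and `hierarchical-ward` (Ward.D2 linkage) accept a distance matrix
#' or coordinates. Deterministic given `seed`.
#'
#' @param x numeric matrix (observations x features) or `dist` object.
#' @param k number of clusters, `2 <= k < n`.
#' @param method `"kmeans"`, `"pam"` or `"ward"`.
#' @param seed RNG seed.
#' @param n_init number of k-means restarts.
#' @param max_iter k-means iteration cap.
#' @return integer vector of labels in `1..k`, named by sample id when
#'   available.
#' @export
cluster_assign <- function(x, k, method = c("kmeans", "pam", "ward"),
                           seed = 1L, n_init = 25L, max_iter = 300L) {
  method <- match.arg(method)
  n <- if (inherits(x, "dist")) attr(x, "Size") else nrow(x)
  if (k < 2) stop("k must be at least 2")
  if (k >= n) stop("k must be smaller than the number of observations (", n, ")")
  ids <- if (inherits(x, "dist")) attr(x, "Labels") else rownames(x)
  if (method == "kmeans") {
    if (inherits(x, "dist"))
      stop("kmeans requires coordinate data; use pam or ward on a distance matrix")
    x <- as.matrix(x)
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    best <- NULL
    for (i in seq_len(n_init)) {
      centers <- kmeanspp_centers(x, k)
      fit <- suppressWarnings(stats::kmeans(x, centers = centers,
                                            iter.max = max_iter))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    labels <- best$cluster
  } else {
    d <- if (inherits(x, "dist")) x else stats::dist(as.matrix(x))
    labels <- if (method == "pam") {
      cluster::pam(d, k, diss = TRUE, cluster.only = TRUE)
    } else {
      stats::cutree(stats::hclust(d, method = "ward.D2"), k = k)
    }
  }
  labels <- as.integer(factor(labels))
  names(labels) <- ids
  labels
}

#' Vote for the number of clusters
#'
#' Clusters the (z-scored, complete-case) feature block at every candidate k
#' and lets each validity index nominate its best k: standalone indices by
#' the arg-max/arg-min of their score over `k_range`; `ball_hall` by the
#' largest drop between successive k; `hartigan` by its published rule
#' (smallest k with \eqn{H(k) = (W_k/W_{k+1} - 1)(n-k-1) \le 10});
#' `krzanowski_lai` by the arg-max of
#' \eqn{|DIFF_k|/|DIFF_{k+1}|} with
#' \eqn{DIFF_k = (k-1)^{2/p} W_{k-1} - k^{2/p} W_k}. The winning k is the
#' modal nomination, ties broken toward the smallest k. Indices that cannot
#' be evaluated abstain.
#'
#' @param data numeric matrix or all-continuous data.frame (samples x
#'   features). Rows with missing values are excluded from the vote and
#'   reported.
#' @param k_range candidate cluster numbers, within `[2, n-1]`.
#' @param method clustering method passed to [cluster_assign].
#' @param indices validity indices to poll (default: all twelve).
#' @param seed RNG seed for the clusterings.
#' @param scale z-score columns before clustering (default TRUE).
#' @param n_init k-means restarts.
#' @return object of class `cluster_vote`: list with `k_range`,
#'   `index_names`, `best_k_per_index`, `tally`, `best_k`, `scores` (index x
#'   k matrix), `labels` (per-k assignments on the complete cases),
#'   `dropped` (ids excluded for missingness), `n_used`.
#' @export
vote_best_k <- function(data, k_range = 2:6, method = "kmeans",
                        indices = VALIDITY_INDICES, seed = 1L,
                        scale = TRUE, n_init = 25L) {
  data <- as.data.frame(data)
  if (!all(vapply(data, is.numeric, logical(1))))
    stop("vote_best_k needs continuous features; encode or drop categorical columns")
  complete <- stats::complete.cases(data)
  dropped <- rownames(data)[!complete]
  x <- as.matrix(data[complete, , drop = FALSE])
  n <- nrow(x)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(indices) == 0) stop("at least one validity index is required")
  indices <- match.arg(indices, VALIDITY_INDICES, several.ok = TRUE)
  if (min(k_range) < 2 || max(k_range) > n - 1)
    stop("k_range must lie within [2, n-1]")
  if (scale) {
    x <- base::scale(x)
    x[, attr(x, "scaled:scale") == 0] <- 0
    x <- x[, , drop = FALSE]
  }

  need_seq <- any(indices %in% c("ball_hall", "hartigan", "krzanowski_lai"))
  k_eval <- k_range
  if (need_seq)
    k_eval <- sort(unique(c(k_range, min(k_range) - 1L, max(k_range) + 1L)))
  k_eval <- k_eval[k_eval >= 1 & k_eval <= n - 1]

  labels_by_k <- list()
  W <- stats::setNames(rep(NA_real_, length(k_eval)), k_eval)
  for (k in k_eval) {
    lab <- if (k == 1) rep(1L, n) else cluster_assign(x, k, method, seed = seed,
                                                      n_init = n_init)
    labels_by_k[[as.character(k)]] <- lab
    W[as.character(k)] <- wgss(x, lab)
  }

  standalone <- setdiff(indices, c("hartigan", "krzanowski_lai"))
  scores <- matrix(NA_real_, nrow = length(indices), ncol = length(k_range),
                   dimnames = list(indices, k_range))
  best_per_index <- stats::setNames(rep(NA_integer_, length(indices)), indices)

  for (ind in standalone) {
    dir <- NULL
    for (k in k_range) {
      v <- validity_index(x, labels_by_k[[as.character(k)]], ind)
      scores[ind, as.character(k)] <- v$score
      dir <- v$direction
    }
    s <- scores[ind, ]
    if (ind == "ball_hall") {
      # elbow rule: largest drop of W/k between successive k
      prev <- W[as.character(k_range - 1L)] / pmax(k_range - 1L, 1L)
      drop_k <- prev - s
      if (all(is.na(drop_k))) next
      best_per_index[ind] <- k_range[which.max(drop_k)]
    } else if (!all(is.na(s))) {
      best_per_index[ind] <- if (dir == "max") k_range[which.max(s)]
                             else k_range[which.min(s)]
    }
  }

  if ("hartigan" %in% indices) {
    H <- vapply(k_range, function(k) {
      wk <- W[as.character(k)]; wk1 <- W[as.character(k + 1L)]
      if (is.na(wk) || is.na(wk1) || wk1 == 0) return(NA_real_)
      (wk / wk1 - 1) * (n - k - 1)
    }, numeric(1))
    scores["hartigan", ] <- H
    ok <- which(!is.na(H) & H <= 10)
    if (length(ok) > 0) best_per_index["hartigan"] <- k_range[ok[1]]
  }
  if ("krzanowski_lai" %in% indices) {
    p <- ncol(x)
    DIFF <- function(k) {
      wkm1 <- W[as.character(k - 1L)]; wk <- W[as.character(k)]
      if (is.na(wkm1) || is.na(wk)) return(NA_real_)
      (k - 1)^(2 / p) * wkm1 - k^(2 / p) * wk
    }
    KL <- vapply(k_range, function(k) {
      num <- DIFF(k); den <- DIFF(k + 1L)
      if (is.na(num) || is.na(den) || den == 0) return(NA_real_)
      abs(num) / abs(den)
    }, numeric(1))
    scores["krzanowski_lai", ] <- KL
    if (!all(is.na(KL))) best_per_index["krzanowski_lai"] <- k_range[which.max(KL)]
  }

  votes <- best_per_index[!is.na(best_per_index)]
  if (length(votes) == 0) stop("every validity index abstained; cannot vote")
  tally <- table(factor(votes, levels = k_range))
  winners <- as.integer(names(tally)[tally == max(tally)])
  structure(list(k_range = k_range, index_names = indices,
                 best_k_per_index = best_per_index, tally = tally,
                 best_k = min(winners), scores = scores,
                 labels = labels_by_k[as.character(k_range)],
                 dropped = dropped, n_used = n),
            class = "cluster_vote")
}

#' @export
print.cluster_vote <- function(x, ...) {
  cat(sprintf("cluster vote over k = {%s}: best k = %d\n",
              paste(x$k_range, collapse = ","), x$best_k))
  print(x$tally)
  invisible(x)
}

#' Composite regrouping labels
#'
#' Combines a base clinical status with a cluster assignment into composite
#' labels of the form `status_cluster` (e.g. `Cases_1`), the regrouping used
#' for all downstream per-group analyses.
#'
#' @param base_status character/factor of clinical status labels.
#' @param cluster integer/character cluster labels, same sample order.
#' @return character vector of composite labels.
#' @export
regroup_labels <- function(base_status, cluster) {
  if (length(base_status) != length(cluster))
    stop("status and cluster labels differ in length")
  paste(as.character(base_status), as.character(cluster), sep = "_")
}
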