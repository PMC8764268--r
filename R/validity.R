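# Cluster-validity indices used by the regrouping vote. Each index follows
# its published formula; `direction` says whether larger or smaller is
# better for a fixed k. The elbow-type indices (hartigan, krzanowski-lai)
# need the within-cluster sum of squares at neighboring k and are therefore
# evaluated inside vote_best_k(), not here.

VALIDITY_INDICES <- c("calinski_harabasz", "silhouette", "davies_bouldin",
                      "dunn", "c_index", "mcclain_rao", "point_biserial",
                      "ball_hall", "xie_beni", "ratkowsky_lance",
                      "hartigan", "krzanowski_lai")

# total within-cluster sum of squares around cluster centroids
wgss <- function(x, labels) {
  sum(vapply(split(seq_len(nrow(x)), labels), function(idx) {
    xi <- x[idx, , drop = FALSE]
    sum(sweep(xi, 2, colMeans(xi))^2)
  }, numeric(1)))
}

cluster_centers <- function(x, labels) {
  do.call(rbind, lapply(split(seq_len(nrow(x)), labels), function(idx)
    colMeans(x[idx, , drop = FALSE])))
}

#' Cluster-validity index
#'
#' Scores one clustering of one data set with a named validity index. The
#' returned `direction` states whether the index is maximized or minimized
#' by a good clustering. Indices that are undefined for the given clustering
#' (e.g. distance ratios when every cluster is a singleton) abstain by
#' returning `NA`.
#'
#' @param x numeric matrix (observations x features). Distance-based indices
#'   use the euclidean distances of `x`.
#' @param labels integer cluster labels, at least two non-empty clusters.
#' @param index one of `"calinski_harabasz"`, `"silhouette"`,
#'   `"davies_bouldin"`, `"dunn"`, `"c_index"`, `"mcclain_rao"`,
#'   `"point_biserial"`, `"ball_hall"`, `"xie_beni"`, `"ratkowsky_lance"`.
#'   The sequence indices `"hartigan"` and `"krzanowski_lai"` compare
#'   clusterings at neighboring k and are available through [vote_best_k].
#' @return list with `score` (numeric, `NA` when the index abstains) and
#'   `direction` (`"max"` or `"min"`).
#' @export
validity_index <- function(x, labels, index) {
  index <- match.arg(index, VALIDITY_INDICES)
  x <- as.matrix(x)
  labels <- as.integer(factor(labels))
  if (length(labels) != nrow(x)) stop("one label per observation required")
  k <- length(unique(labels))
  n <- nrow(x)
  if (k < 2) stop("need at least two non-empty clusters")
  if (index %in% c("hartigan", "krzanowski_lai"))
    stop(index, " compares clusterings at neighboring k; use vote_best_k()")

  if (index == "calinski_harabasz") {
    W <- wgss(x, labels)
    Tss <- sum(sweep(x, 2, colMeans(x))^2)
    if (W <= 0) return(list(score = NA_real_, direction = "max"))
    return(list(score = ((Tss - W) / (k - 1)) / (W / (n - k)), direction = "max"))
  }
  if (index == "ball_hall")
    return(list(score = wgss(x, labels) / k, direction = "min"))
  if (index == "xie_beni") {
    cent <- cluster_centers(x, labels)
    within <- sum((x - cent[labels, , drop = FALSE])^2)
    sep <- min(stats::dist(cent)^2)
    if (sep == 0) return(list(score = NA_real_, direction = "min"))
    return(list(score = within / (n * sep), direction = "min"))
  }
  if (index == "ratkowsky_lance") {
    ratios <- vapply(seq_len(ncol(x)), function(j) {
      tj <- sum((x[, j] - mean(x[, j]))^2)
      if (tj == 0) return(NA_real_)
      wj <- sum(vapply(split(x[, j], labels), function(v) sum((v - mean(v))^2),
                       numeric(1)))
      sqrt((tj - wj) / tj)
    }, numeric(1))
    return(list(score = mean(ratios, na.rm = TRUE) / sqrt(k), direction = "max"))
  }
  if (index == "davies_bouldin") {
    cent <- cluster_centers(x, labels)
    S <- vapply(seq_len(k), function(g) {
      idx <- which(labels == g)
      mean(sqrt(rowSums((x[idx, , drop = FALSE] -
                           matrix(cent[g, ], length(idx), ncol(x), byrow = TRUE))^2)))
    }, numeric(1))
    M <- as.matrix(stats::dist(cent))
    r <- vapply(seq_len(k), function(i) {
      others <- setdiff(seq_len(k), i)
      max((S[i] + S[others]) / M[i, others])
    }, numeric(1))
    return(list(score = mean(r), direction = "min"))
  }

  # distance-based indices
  d <- stats::dist(x)
  if (index == "silhouette") {
    sw <- cluster::silhouette(labels, d)
    return(list(score = mean(sw[, "sil_width"]), direction = "max"))
  }
  dm <- as.matrix(d)
  same <- outer(labels, labels, "==")
  ut <- upper.tri(dm)
  dw <- dm[ut & same]
  db <- dm[ut & !same]
  if (index == "dunn") {
    diam <- max(c(0, dw))
    if (diam == 0 || length(db) == 0)
      return(list(score = NA_real_, direction = "max"))
    return(list(score = min(db) / diam, direction = "max"))
  }
  if (index == "c_index") {
    nw <- length(dw)
    if (nw == 0) return(list(score = NA_real_, direction = "min"))
    alldist <- sort(dm[ut])
    smin <- sum(alldist[seq_len(nw)])
    smax <- sum(alldist[seq(length(alldist) - nw + 1, length(alldist))])
    if (smax == smin) return(list(score = NA_real_, direction = "min"))
    return(list(score = (sum(dw) - smin) / (smax - smin), direction = "min"))
  }
  if (index == "mcclain_rao") {
    if (length(dw) == 0 || length(db) == 0 || mean(db) == 0)
      return(list(score = NA_real_, direction = "min"))
    return(list(score = mean(dw) / mean(db), direction = "min"))
  }
  if (index == "point_biserial") {
    dvec <- dm[ut]
    between <- as.numeric(!same[ut])
    if (stats::sd(dvec) == 0 || stats::sd(between) == 0)
      return(list(score = NA_real_, direction = "max"))
    return(list(score = stats::cor(dvec, between), direction = "max"))
  }
  stop("unreachable")
}
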