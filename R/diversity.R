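# Alpha diversity, group comparison, Bray-Curtis beta diversity, PCoA and
# one-factor permutational MANOVA.

ALPHA_INDICES <- c("shannon", "simpson", "invsimpson", "pielou")

#' Per-sample alpha diversity
#'
#' Each sample's composition is renormalized to sum 1 over its non-zero taxa
#' before computing: Shannon \eqn{H = -\sum p \ln p}, Simpson
#' \eqn{1 - \sum p^2}, inverse Simpson \eqn{1/\sum p^2}, and Pielou evenness
#' \eqn{H / \ln S_{obs}} with \eqn{S_{obs}} the number of non-zero taxa
#' (undefined, reported `NA`, when a sample holds a single taxon).
#'
#' @param abundance an [abundance_table] or a samples-x-taxa numeric matrix.
#' @param index one or more of `"shannon"`, `"simpson"`, `"invsimpson"`,
#'   `"pielou"`.
#' @return data.frame, one row per sample, one column per index.
#' @export
alpha_diversity <- function(abundance, index = ALPHA_INDICES) {
  index <- match.arg(index, ALPHA_INDICES, several.ok = TRUE)
  m <- if (inherits(abundance, "abundance_table")) sample_matrix(abundance)
       else as.matrix(abundance)
  if (any(m < 0)) stop("negative abundances")
  tot <- rowSums(m)
  if (any(tot == 0))
    stop("all-zero sample(s): ", paste(rownames(m)[tot == 0], collapse = ", "))
  p <- m / tot
  H <- vegan::diversity(p, index = "shannon")
  s_obs <- rowSums(p > 0)
  out <- data.frame(matrix(nrow = nrow(m), ncol = 0))
  if (!is.null(rownames(m))) rownames(out) <- rownames(m)
  for (ind in index) {
    out[[ind]] <- switch(ind,
      shannon = H,
      simpson = vegan::diversity(p, index = "simpson"),
      invsimpson = vegan::diversity(p, index = "invsimpson"),
      pielou = ifelse(s_obs > 1, H / log(s_obs), NA_real_))
  }
  out
}

#' Rarefied alpha diversity for count data
#'
#' Subsamples each sample without replacement to a common depth `n_draws`
#' times and reports the mean alpha value per index. Only defined for
#' integer counts; relative abundances should go straight to
#' [alpha_diversity].
#'
#' @param counts samples-x-taxa integer matrix.
#' @param depth rarefaction depth, at most the smallest sample depth.
#' @param seed RNG seed; results are deterministic given it.
#' @param n_draws number of subsampling draws.
#' @param index alpha indices to report.
#' @return data.frame of mean rarefied values, one row per sample.
#' @export
rarefy_alpha <- function(counts, depth, seed = 1L, n_draws = 50L,
                         index = ALPHA_INDICES) {
  counts <- as.matrix(counts)
  if (any(counts != round(counts)))
    stop("rarefaction needs integer counts; compute alpha_diversity() ",
         "directly on relative abundances instead")
  if (depth > min(rowSums(counts)))
    stop("depth exceeds the smallest sample depth (", min(rowSums(counts)), ")")
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  acc <- NULL
  for (i in seq_len(n_draws)) {
    sub <- suppressWarnings(vegan::rrarefy(counts, depth))
    a <- as.matrix(alpha_diversity(sub, index = index))
    acc <- if (is.null(acc)) a else acc + a
  }
  as.data.frame(acc / n_draws)
}

#' Compare a per-sample quantity across groups
#'
#' Two groups: two-sample t test (Welch by default, pooled-variance via
#' `pooled`). More than two: one-way ANOVA plus Fisher LSD pairwise p-values
#' from the pooled mean square error (optionally BH-adjusted).
#'
#' @param values numeric vector, one value per sample.
#' @param groups group labels.
#' @param pooled use the pooled-variance t test for two groups.
#' @param adjust `"none"` (Fisher LSD, default) or `"BH"`.
#' @return list with `test` (data.frame: method, statistic, p) and
#'   `pairwise` (data.frame of pairwise comparisons, `NULL` for two groups).
#' @export
compare_groups <- function(values, groups, pooled = FALSE,
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  ok <- !is.na(values)
  values <- values[ok]
  groups <- droplevels(as.factor(groups[ok]))
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least two groups")
  if (any(sizes < 2)) stop("every group needs at least two samples")
  if (nlevels(groups) == 2) {
    if (stats::var(values) == 0) {
      test <- data.frame(method = "t", statistic = 0, p = 1)
      return(list(test = test, pairwise = NULL))
    }
    tt <- stats::t.test(values ~ groups, var.equal = pooled)
    return(list(test = data.frame(method = if (pooled) "t" else "welch t",
                                  statistic = unname(tt$statistic),
                                  p = tt$p.value),
                pairwise = NULL))
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  mse <- tab["Residuals", "Mean Sq"]
  dfe <- tab["Residuals", "Df"]
  means <- tapply(values, groups, mean)
  lev <- levels(groups)
  pw <- do.call(rbind, lapply(utils::combn(lev, 2, simplify = FALSE), function(pr) {
    diff <- means[pr[1]] - means[pr[2]]
    se <- sqrt(mse * (1 / sizes[pr[1]] + 1 / sizes[pr[2]]))
    tstat <- if (se == 0) 0 else diff / se
    data.frame(group1 = pr[1], group2 = pr[2], diff = unname(diff),
               t = unname(tstat),
               p = if (se == 0) 1 else unname(2 * stats::pt(-abs(tstat), dfe)),
               stringsAsFactors = FALSE)
  }))
  if (adjust == "BH") pw$p_adj <- stats::p.adjust(pw$p, "BH")
  rownames(pw) <- NULL
  list(test = data.frame(method = "anova",
                         statistic = tab[["F value"]][1],
                         p = tab[["Pr(>F)"]][1]),
       pairwise = pw)
}

#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{d(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}. A pair of
#' all-zero samples has no shared mass; its dissimilarity is reported as 0
#' with a warning.
#'
#' @param abundance an [abundance_table] or samples-x-taxa matrix.
#' @return a `stats::dist` object.
#' @export
bray_curtis <- function(abundance) {
  m <- if (inherits(abundance, "abundance_table")) sample_matrix(abundance)
       else as.matrix(abundance)
  if (any(m < 0)) stop("negative abundances")
  d <- vegan::vegdist(m, method = "bray")
  if (anyNA(d)) {
    warning("all-zero sample pair(s); their Bray-Curtis distance is set to 0")
    d[is.na(d)] <- 0
  }
  d
}

#' Principal coordinates analysis
#'
#' Gower double-centering of \eqn{-D^2/2} followed by a symmetric
#' eigendecomposition; coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues. Negative eigenvalues are reported
#' but never used for axes; the proportion explained is taken over the
#' positive eigenvalues.
#'
#' @param dist a `stats::dist` object (n >= 3).
#' @param n_axes number of axes to return (truncated with a warning when it
#'   exceeds the number of positive eigenvalues).
#' @return object of class `pcoa_result`: list with `coordinates`
#'   (samples x axes), `eigenvalues` (all, decreasing), and
#'   `proportion_explained` per returned axis.
#' @export
pcoa <- function(dist, n_axes = 2) {
  n <- attr(dist, "Size")
  if (is.null(n) || n < 3) stop("PCoA needs at least 3 samples")
  D2 <- as.matrix(dist)^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D2 %*% J
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  pos <- which(eig$values > 1e-10 * max(abs(eig$values)))
  if (n_axes > length(pos)) {
    warning("only ", length(pos), " positive eigenvalue(s); truncating axes")
    n_axes <- length(pos)
  }
  take <- pos[seq_len(n_axes)]
  coords <- eig$vectors[, take, drop = FALSE] %*%
    diag(sqrt(eig$values[take]), nrow = n_axes)
  rownames(coords) <- attr(dist, "Labels")
  colnames(coords) <- paste0("PCo", seq_len(n_axes))
  structure(list(coordinates = coords,
                 eigenvalues = eig$values,
                 proportion_explained =
                   eig$values[take] / sum(eig$values[pos])),
            class = "pcoa_result")
}

#' One-factor permutational MANOVA
#'
#' Pseudo-F on a distance matrix:
#' \eqn{SS_{tot} = \frac{1}{N}\sum_{i<j} d_{ij}^2},
#' \eqn{SS_{within} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2},
#' \eqn{F = \frac{(SS_{tot}-SS_{within})/(a-1)}{SS_{within}/(N-a)}},
#' \eqn{R^2 = 1 - SS_{within}/SS_{tot}}. The p-value permutes group labels
#' with the `(1 + \#\{F_{perm} \ge F_{obs}\})/(1 + n_{perm})` convention.
#' When the design is small enough that the number of distinct label
#' arrangements does not exceed `n_perm`, all arrangements are enumerated
#' instead and the p-value is exact
#' (\eqn{\#\{F \ge F_{obs}\} / \#arrangements}, the observed arrangement
#' counted once).
#'
#' @param dist a `stats::dist` object.
#' @param groups group label per sample (>= 2 levels).
#' @param n_perm number of label permutations.
#' @param seed RNG seed for the permutations (unused when enumerating).
#' @return object of class `permanova_result`: list with `F`, `R2`, `p`,
#'   `n_perm`, `seed`, `df`, `exact`.
#' @export
permanova <- function(dist, groups, n_perm = 999, seed = 1L) {
  groups <- droplevels(as.factor(groups))
  n <- attr(dist, "Size")
  if (length(groups) != n) stop("one group label per sample required")
  a <- nlevels(groups)
  if (a < 2) stop("all samples are in one group")
  d2 <- as.matrix(dist)^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  f_stat <- function(g) {
    ss_within <- sum(vapply(levels(g), function(lev) {
      idx <- which(g == lev)
      sum(d2[idx, idx][upper.tri(d2[idx, idx, drop = FALSE])]) / length(idx)
    }, numeric(1)))
    ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
  }
  F_obs <- f_stat(groups)
  sizes <- as.integer(table(groups))
  n_arrange <- exp(lfactorial(n) - sum(lfactorial(sizes)))
  if (n_arrange <= n_perm + 1) {
    # complete enumeration of the distinct label arrangements: exact p
    arrangements <- enumerate_assignments(sizes)
    F_all <- apply(arrangements, 1, function(idx)
      f_stat(factor(levels(groups)[idx], levels = levels(groups))))
    p <- mean(F_all >= F_obs - 1e-12)
    exact <- TRUE
  } else {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    F_perm <- vapply(seq_len(n_perm), function(i) f_stat(sample(groups)),
                     numeric(1))
    p <- (1 + sum(F_perm >= F_obs - 1e-12)) / (1 + n_perm)
    exact <- FALSE
  }
  sw <- sum(vapply(levels(groups), function(lev) {
    idx <- which(groups == lev)
    sum(d2[idx, idx][upper.tri(d2[idx, idx, drop = FALSE])]) / length(idx)
  }, numeric(1)))
  structure(list(F = F_obs,
                 R2 = 1 - sw / ss_total,
                 p = p,
                 n_perm = n_perm, seed = seed,
                 df = c(between = a - 1, within = n - a),
                 exact = exact),
            class = "permanova_result")
}

# all distinct assignments of group sizes to positions, one row per
# arrangement, entries are group-level indices
enumerate_assignments <- function(sizes) {
  n <- sum(sizes)
  fill <- function(free, sizes_left, level, template) {
    if (length(sizes_left) == 0) return(matrix(template, nrow = 1))
    combs <- utils::combn(free, sizes_left[1], simplify = FALSE)
    do.call(rbind, lapply(combs, function(sel) {
      tmpl <- template
      tmpl[sel] <- level
      fill(setdiff(free, sel), sizes_left[-1], level + 1L, tmpl)
    }))
  }
  fill(seq_len(n), sizes, 1L, integer(n))
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: F = %.4g (df %d, %d), R2 = %.4g, p = %.4g (%d permutations)\n",
              x$F, x$df["between"], x$df["within"], x$R2, x$p, x$n_perm))
  invisible(x)
}
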