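# Independent brute-force oracles for the validity indices: naive loops over
# points and pairs, written directly from each index's defining sums.

oracle_wgss <- function(x, lab) {
  s <- 0
  for (g in unique(lab)) {
    xi <- x[lab == g, , drop = FALSE]
    cen <- colMeans(xi)
    for (i in seq_len(nrow(xi))) s <- s + sum((xi[i, ] - cen)^2)
  }
  s
}

oracle_ch <- function(x, lab) {
  n <- nrow(x); k <- length(unique(lab))
  W <- oracle_wgss(x, lab)
  Tot <- oracle_wgss(x, rep(1, n))
  ((Tot - W) / (k - 1)) / (W / (n - k))
}

oracle_silhouette <- function(x, lab) {
  dm <- as.matrix(dist(x))
  s <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    own <- which(lab == lab[i] & seq_along(lab) != i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(dm[i, own])
    b <- min(vapply(setdiff(unique(lab), lab[i]), function(g)
      mean(dm[i, lab == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

oracle_db <- function(x, lab) {
  ks <- sort(unique(lab))
  cen <- t(vapply(ks, function(g) colMeans(x[lab == g, , drop = FALSE]),
                  numeric(ncol(x))))
  S <- vapply(seq_along(ks), function(gi) {
    xi <- x[lab == ks[gi], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xi, 2, cen[gi, ])^2)))
  }, numeric(1))
  mean(vapply(seq_along(ks), function(i)
    max(vapply(setdiff(seq_along(ks), i), function(j)
      (S[i] + S[j]) / sqrt(sum((cen[i, ] - cen[j, ])^2)), numeric(1))),
    numeric(1)))
}

oracle_dunn <- function(x, lab) {
  dm <- as.matrix(dist(x))
  inter <- Inf; diam <- 0
  for (i in seq_len(nrow(x))) for (j in seq_len(nrow(x))) {
    if (i == j) next
    if (lab[i] == lab[j]) diam <- max(diam, dm[i, j])
    else inter <- min(inter, dm[i, j])
  }
  inter / diam
}

oracle_cindex <- function(x, lab) {
  dm <- as.matrix(dist(x))
  dw <- c(); dall <- c()
  for (i in seq_len(nrow(x) - 1)) for (j in (i + 1):nrow(x)) {
    dall <- c(dall, dm[i, j])
    if (lab[i] == lab[j]) dw <- c(dw, dm[i, j])
  }
  nw <- length(dw)
  srt <- sort(dall)
  (sum(dw) - sum(srt[1:nw])) / (sum(rev(srt)[1:nw]) - sum(srt[1:nw]))
}

oracle_mcclain <- function(x, lab) {
  dm <- as.matrix(dist(x))
  dw <- c(); db <- c()
  for (i in seq_len(nrow(x) - 1)) for (j in (i + 1):nrow(x)) {
    if (lab[i] == lab[j]) dw <- c(dw, dm[i, j]) else db <- c(db, dm[i, j])
  }
  mean(dw) / mean(db)
}

oracle_pb <- function(x, lab) {
  dm <- as.matrix(dist(x))
  dvec <- c(); ind <- c()
  for (i in seq_len(nrow(x) - 1)) for (j in (i + 1):nrow(x)) {
    dvec <- c(dvec, dm[i, j]); ind <- c(ind, as.numeric(lab[i] != lab[j]))
  }
  cor(dvec, ind)
}

oracle_xb <- function(x, lab) {
  ks <- sort(unique(lab))
  cen <- t(vapply(ks, function(g) colMeans(x[lab == g, , drop = FALSE]),
                  numeric(ncol(x))))
  within <- sum(vapply(seq_len(nrow(x)), function(i)
    sum((x[i, ] - cen[match(lab[i], ks), ])^2), numeric(1)))
  sep <- Inf
  for (i in seq_along(ks)[-length(ks)]) for (j in (i + 1):length(ks))
    sep <- min(sep, sum((cen[i, ] - cen[j, ])^2))
  within / (nrow(x) * sep)
}

oracle_rl <- function(x, lab) {
  k <- length(unique(lab))
  ratios <- vapply(seq_len(ncol(x)), function(j) {
    tj <- sum((x[, j] - mean(x[, j]))^2)
    wj <- sum(vapply(unique(lab), function(g) {
      v <- x[lab == g, j]; sum((v - mean(v))^2)
    }, numeric(1)))
    sqrt((tj - wj) / tj)
  }, numeric(1))
  mean(ratios) / sqrt(k)
}

test_that("mixed_distance satisfies the defining formulas", {
  meta <- data.frame(x = c(1, 1, 4), y = c(2, 2, 8),
                     row.names = paste0("S", 1:3))
  d <- mixed_distance(meta, metric = "euclidean")
  # identical rows at distance 0
  expect_equal(as.matrix(d)["S1", "S2"], 0)
  # hand-computed z-scored euclidean oracle
  z <- scale(as.matrix(meta))
  expect_equal(as.matrix(d)["S1", "S3"],
               sqrt(sum((z[1, ] - z[3, ])^2)), tolerance = 1e-12)

  # gower: maximal dissimilarity when every feature is maximally apart
  mix <- data.frame(x = c(0, 10), cat = factor(c("A", "B")),
                    row.names = c("a", "b"))
  dg <- mixed_distance(mix, metric = "gower")
  expect_equal(as.numeric(dg), 1)

  # gower stays within [0, 1] with missing values handled pairwise
  set.seed(7)
  big <- data.frame(a = rnorm(20), b = rnorm(20),
                    c = factor(sample(letters[1:3], 20, TRUE)))
  big$a[c(3, 8)] <- NA
  dg2 <- mixed_distance(big, metric = "gower")
  expect_true(all(dg2 >= 0 & dg2 <= 1))

  expect_error(mixed_distance(mix, metric = "euclidean"), "all-continuous")
})

test_that("euclidean distance is permutation-invariant in features", {
  set.seed(8)
  meta <- data.frame(a = rnorm(10), b = rnorm(10), c = rnorm(10))
  d1 <- mixed_distance(meta, metric = "euclidean")
  d2 <- mixed_distance(meta[, c("c", "a", "b")], metric = "euclidean")
  expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 1e-12)
})

test_that("cluster_assign recovers well-separated structure", {
  blobs <- make_blobs(20, 2, sep = 100, seed = 11)
  lab <- cluster_assign(blobs$x, 2, "kmeans", seed = 3)
  expect_equal(length(unique(lab)), 2L)
  # perfect split up to label permutation
  expect_equal(max(table(lab, blobs$labels)), 10)

  # 12-point planted 3-blob set: exact recovery for all methods
  b3 <- make_blobs(12, 3, sep = 50, seed = 12)
  for (m in c("kmeans", "pam", "ward")) {
    input <- if (m == "kmeans") b3$x else dist(b3$x)
    l3 <- cluster_assign(input, 3, m, seed = 5)
    tab <- table(l3, b3$labels)
    expect_equal(sum(apply(tab, 1, max)), 12)  # adjusted Rand = 1
  }

  expect_error(cluster_assign(b3$x, 12, "kmeans"), "smaller")
})

test_that("more k-means restarts never worsen the kept solution", {
  set.seed(9)
  x <- matrix(rnorm(60 * 4), 60, 4)
  l1 <- cluster_assign(x, 4, "kmeans", seed = 2, n_init = 1)
  l25 <- cluster_assign(x, 4, "kmeans", seed = 2, n_init = 25)
  expect_lte(clinmicro:::wgss(x, l25), clinmicro:::wgss(x, l1) + 1e-9)
})

test_that("validity indices match independent brute-force oracles", {
  oracles <- list(calinski_harabasz = oracle_ch, silhouette = oracle_silhouette,
                  davies_bouldin = oracle_db, dunn = oracle_dunn,
                  c_index = oracle_cindex, mcclain_rao = oracle_mcclain,
                  point_biserial = oracle_pb, xie_beni = oracle_xb,
                  ratkowsky_lance = oracle_rl,
                  ball_hall = function(x, lab)
                    oracle_wgss(x, lab) / length(unique(lab)))
  for (seed in 1:3) {
    set.seed(seed)
    n <- sample(8:12, 1)
    x <- matrix(rnorm(n * 2), n, 2)
    lab <- sample(rep(1:3, length.out = n))
    for (ind in names(oracles)) {
      got <- validity_index(x, lab, ind)$score
      expect_equal(got, oracles[[ind]](x, lab), tolerance = 1e-9,
                   label = sprintf("%s (seed %d)", ind, seed))
    }
  }
})

test_that("hand-worked Calinski-Harabasz on a 6-point 2-cluster set", {
  x <- cbind(c(0, 0, 1, 10, 10, 11), c(0, 1, 0, 10, 11, 10))
  lab <- rep(1:2, each = 3)
  # direct arithmetic: W = sum of squared deviations around (1/3, 1/3)
  # within each cluster = 4/3 per cluster per axis pattern
  W <- oracle_wgss(x, lab)
  Tot <- sum(sweep(x, 2, colMeans(x))^2)
  expected <- ((Tot - W) / 1) / (W / 4)
  expect_equal(validity_index(x, lab, "calinski_harabasz")$score, expected,
               tolerance = 1e-12)
})

test_that("silhouette approaches 1 for increasingly separated equal blobs", {
  prev <- -Inf
  for (sep in c(5, 50, 500)) {
    b <- make_blobs(12, 2, sep = sep, seed = 4)
    s <- validity_index(b$x, b$labels, "silhouette")$score
    expect_gt(s, prev)
    prev <- s
  }
  expect_gt(prev, 0.99)
})

test_that("davies-bouldin and silhouette rank the planted k best over 2..6", {
  b <- make_blobs(30, 3, sep = 30, seed = 21)
  scores <- sapply(2:6, function(k) {
    lab <- cluster_assign(b$x, k, "kmeans", seed = 2)
    c(sil = validity_index(b$x, lab, "silhouette")$score,
      db = validity_index(b$x, lab, "davies_bouldin")$score)
  })
  expect_equal((2:6)[which.max(scores["sil", ])], 3)
  expect_equal((2:6)[which.min(scores["db", ])], 3)
})

test_that("sequence indices are routed through vote_best_k", {
  b <- make_blobs(12, 2, sep = 20, seed = 1)
  expect_error(validity_index(b$x, b$labels, "hartigan"), "vote_best_k")
  expect_error(validity_index(b$x, b$labels, "krzanowski_lai"), "vote_best_k")
})

test_that("vote_best_k recovers a planted 3-blob structure", {
  b <- make_blobs(60, 3, p = 4, sep = 8, seed = 31)
  vote <- vote_best_k(b$x, k_range = 2:6, seed = 17)
  expect_equal(vote$best_k, 3)
  expect_gte(vote$tally[["3"]] / sum(vote$tally), 2 / 3)
})

test_that("vote_best_k handles degenerate ranges and missing rows", {
  b <- make_blobs(20, 2, sep = 10, seed = 6)
  single <- vote_best_k(b$x, k_range = 2, seed = 1)
  expect_equal(single$best_k, 2)

  df <- as.data.frame(b$x)
  df[3, 1] <- NA
  v <- vote_best_k(df, k_range = 2:3, seed = 1)
  expect_equal(v$dropped, "P3")
  expect_equal(v$n_used, 19)
})

test_that("regroup_labels builds composite status-cluster labels", {
  status <- c("Control", "Control", "Cases", "Cases")
  clus <- c(1, 2, 1, 2)
  expect_equal(regroup_labels(status, clus),
               c("Control_1", "Control_2", "Cases_1", "Cases_2"))
  # single cluster degenerates to status_1
  expect_equal(unique(regroup_labels(rep("A", 3), rep(1, 3))), "A_1")
  # hand-assigned toy oracle
  expect_equal(regroup_labels(c("x", "y"), c(2, 3)), c("x_2", "y_3"))
  expect_error(regroup_labels(c("a", "b"), 1:3), "length")
})
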