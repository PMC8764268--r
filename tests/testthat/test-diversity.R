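# high-precision direct evaluation of the alpha formulas, independent of the
# package implementation
oracle_alpha <- function(p) {
  p <- p[p > 0] / sum(p[p > 0])
  H <- -sum(p * log(p))
  c(shannon = H, simpson = 1 - sum(p^2), invsimpson = 1 / sum(p^2),
    pielou = if (length(p) > 1) H / log(length(p)) else NA_real_)
}

test_that("alpha indices match closed forms and the formula oracle", {
  uniform <- matrix(rep(0.25, 4), nrow = 1, dimnames = list("u", NULL))
  a <- alpha_diversity(uniform)
  expect_equal(a$shannon, log(4), tolerance = 1e-12)
  expect_equal(a$simpson, 0.75, tolerance = 1e-12)
  expect_equal(a$invsimpson, 4, tolerance = 1e-12)
  expect_equal(a$pielou, 1, tolerance = 1e-12)

  single <- matrix(c(1, 0, 0), nrow = 1, dimnames = list("s", NULL))
  s <- alpha_diversity(single)
  expect_equal(s$shannon, 0)
  expect_equal(s$simpson, 0)
  expect_equal(s$invsimpson, 1)
  expect_true(is.na(s$pielou))

  set.seed(13)
  comp <- matrix(rexp(10), nrow = 1)
  comp <- comp / sum(comp)
  got <- alpha_diversity(comp)
  exp_vals <- oracle_alpha(comp[1, ])
  for (ind in names(exp_vals))
    expect_equal(got[[ind]], unname(exp_vals[ind]), tolerance = 1e-12)

  zero <- matrix(c(0.5, 0.5, 0, 0), nrow = 2, byrow = TRUE,
                 dimnames = list(c("ok", "empty"), NULL))
  expect_error(alpha_diversity(zero), "empty")
})

test_that("alpha indices respect their analytic bounds and taxa permutation", {
  set.seed(14)
  m <- matrix(rexp(8 * 20), nrow = 8)
  m <- m / rowSums(m)
  a <- alpha_diversity(m)
  s_obs <- rowSums(m > 0)
  expect_true(all(a$shannon <= log(s_obs) + 1e-12))
  expect_true(all(a$invsimpson >= 1 & a$invsimpson <= s_obs + 1e-12))
  perm <- alpha_diversity(m[, sample(ncol(m))])
  expect_equal(a, perm, tolerance = 1e-12)
})

test_that("rarefaction converges to the plain value at full depth", {
  set.seed(15)
  counts <- matrix(rpois(3 * 12, 40), nrow = 3,
                   dimnames = list(c("a", "b", "c"), NULL))
  full <- rarefy_alpha(counts, depth = min(rowSums(counts)), n_draws = 3)
  direct <- alpha_diversity(counts)
  # the shallowest sample is subsampled at its own full depth: identical
  shallowest <- which.min(rowSums(counts))
  expect_equal(full$shannon[shallowest], direct$shannon[shallowest],
               tolerance = 1e-12)

  one <- rarefy_alpha(counts, depth = 1, n_draws = 5)
  expect_equal(one$shannon, rep(0, 3))

  expect_error(rarefy_alpha(counts / 2, depth = 1), "integer")
  expect_error(rarefy_alpha(counts, depth = 1e6), "depth exceeds")
})

test_that("rarefied diversity is reproducible and depth-consistent", {
  set.seed(16)
  base <- rmultinom(1, 500, prob = rexp(12))[, 1]
  counts <- rbind(deep = base * 4L, shallow = base)
  r1 <- rarefy_alpha(counts, depth = 400, seed = 9, n_draws = 200)
  r2 <- rarefy_alpha(counts, depth = 400, seed = 9, n_draws = 200)
  expect_identical(r1, r2)
  # same composition at different depth: rarefied Shannon nearly equal
  expect_lt(abs(r1$shannon[1] - r1$shannon[2]), 0.05)
})

test_that("compare_groups reproduces hand-computed ANOVA and LSD", {
  # textbook 3-group instance
  v <- c(4, 5, 6, 7, 8, 9, 10, 11, 12)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- compare_groups(v, g)
  # formula oracle: F from explicit sums of squares
  gm <- mean(v)
  ssb <- sum(3 * (tapply(v, g, mean) - gm)^2)
  ssw <- sum((v - rep(tapply(v, g, mean), each = 3))^2)
  F_hand <- (ssb / 2) / (ssw / 6)
  expect_equal(res$test$statistic, F_hand, tolerance = 1e-12)
  # LSD pairwise p from pooled MSE
  mse <- ssw / 6
  t_ab <- (mean(v[1:3]) - mean(v[4:6])) / sqrt(mse * (2 / 3))
  expect_equal(res$pairwise$p[res$pairwise$group1 == "a" &
                              res$pairwise$group2 == "b"],
               2 * pt(-abs(t_ab), 6), tolerance = 1e-12)

  same <- compare_groups(rep(c(1, 2), 4), rep(c("x", "y"), each = 4))
  expect_equal(same$test$p, 1)
  expect_equal(same$test$statistic, 0)

  expect_error(compare_groups(1:3, c("a", "a", "b")), "at least two samples")
})

test_that("bray_curtis matches hand arithmetic and its bounds", {
  m <- rbind(x = c(0.2, 0.8), y = c(0.5, 0.5))
  expect_equal(as.numeric(bray_curtis(m)), 0.3, tolerance = 1e-12)

  ident <- rbind(a = c(0.3, 0.7), b = c(0.3, 0.7))
  expect_equal(as.numeric(bray_curtis(ident)), 0)

  disjoint <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(as.numeric(bray_curtis(disjoint)), 1)

  set.seed(17)
  m2 <- matrix(rexp(6 * 10), nrow = 6)
  d <- as.matrix(bray_curtis(m2 / rowSums(m2)))
  expect_true(all(d >= 0 & d <= 1 + 1e-12))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
})

test_that("PCoA embeds Euclidean configurations exactly", {
  # 4 points on a line: axis 1 recovers the line
  line <- matrix(c(0, 1, 3, 6), ncol = 1)
  ord <- pcoa(dist(line), n_axes = 1)
  expect_equal(as.matrix(dist(ord$coordinates[, 1])), as.matrix(dist(line)),
               tolerance = 1e-9, ignore_attr = TRUE)

  # random 5-point configuration: full reconstruction
  set.seed(18)
  x <- matrix(rnorm(5 * 3), 5, 3)
  d <- dist(x)
  ord2 <- pcoa(d, n_axes = 4)
  expect_equal(as.matrix(dist(ord2$coordinates)), as.matrix(d),
               tolerance = 1e-9, ignore_attr = TRUE)

  # spectral identity: eigenvalue sum equals the centered-matrix trace
  D2 <- as.matrix(d)^2
  J <- diag(5) - matrix(1 / 5, 5, 5)
  B <- -0.5 * J %*% D2 %*% J
  expect_equal(sum(ord2$eigenvalues), sum(diag(B)), tolerance = 1e-9)

  # explained proportions are non-increasing
  expect_true(all(diff(ord2$proportion_explained) <= 1e-12))
  expect_warning(pcoa(d, n_axes = 5), "truncating")
})

test_that("permanova matches an independent loop-based computation", {
  set.seed(19)
  x <- matrix(rnorm(10 * 3), 10, 3)
  d <- dist(x)
  g <- rep(c("A", "B"), each = 5)
  res <- permanova(d, g, n_perm = 99, seed = 1)
  # naive double loops over pairs
  dm <- as.matrix(d)
  sst <- 0
  for (i in 1:9) for (j in (i + 1):10) sst <- sst + dm[i, j]^2
  sst <- sst / 10
  ssw <- 0
  for (lev in c("A", "B")) {
    idx <- which(g == lev)
    for (i in idx) for (j in idx) if (i < j) ssw <- ssw + dm[i, j]^2 / 5
  }
  expect_equal(res$R2, 1 - ssw / sst, tolerance = 1e-10)
  expect_equal(res$F, ((sst - ssw) / 1) / (ssw / 8), tolerance = 1e-10)

  # invariance to group-name relabeling
  relabeled <- permanova(d, ifelse(g == "A", "zzz", "aaa"), n_perm = 99, seed = 1)
  expect_equal(relabeled$F, res$F)

  expect_error(permanova(d, rep("A", 10)), "one group")
})

test_that("permanova agrees with vegan::adonis2 on F and R2", {
  set.seed(20)
  m <- matrix(rexp(12 * 8), 12, 8)
  m <- m / rowSums(m)
  d <- bray_curtis(m)
  g <- rep(c("A", "B", "C"), each = 4)
  ours <- permanova(d, g, n_perm = 199, seed = 2)
  ref <- vegan::adonis2(d ~ g, permutations = 199)
  expect_equal(ours$F, ref$F[1], tolerance = 1e-10)
  expect_equal(ours$R2, ref$R2[1], tolerance = 1e-10)
})

test_that("strongly displaced groups reach the smallest attainable p", {
  set.seed(21)
  x <- rbind(matrix(rnorm(24, 0, 0.1), 8), matrix(rnorm(24, 50, 0.1), 8))
  d <- dist(x)
  g <- rep(c("lo", "hi"), each = 8)
  res <- permanova(d, g, n_perm = 999, seed = 3)
  expect_false(res$exact)
  expect_equal(res$p, 1 / 1000)
})
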