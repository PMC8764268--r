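# brute-force graph oracles on an adjacency matrix
oracle_graph_stats <- function(adj) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  triangles <- sum(diag(adj %*% adj %*% adj)) / 6
  triples <- sum(deg * (deg - 1) / 2)
  c(transitivity = if (triples == 0) NA_real_ else 3 * triangles / triples,
    centralization_degree = sum(max(deg) - deg) / ((n - 1) * (n - 2)),
    graph_density = sum(adj) / (n * (n - 1)))
}

net_from_adj <- function(adj) {
  n <- nrow(adj)
  rownames(adj) <- colnames(adj) <- paste0("t", seq_len(n))
  r <- adj * 0.9
  p <- ifelse(adj == 1, 0.001, 0.9)
  diag(p) <- 0; diag(r) <- 1
  build_network(r, p, keep_isolated = TRUE)
}

test_that("spearman correlations follow rank invariance", {
  m <- rbind(a = c(1, 4, 9, 16, 25, 36),
             b = c(1, 2, 3, 4, 5, 6),       # monotone in a, nonlinear
             c = c(6, 5, 4, 3, 2, 1))
  sp <- spearman_matrix(m)
  expect_equal(unname(diag(sp$r)), rep(1, 3))
  expect_equal(unname(sp$r["a", "b"]), 1)
  expect_equal(unname(sp$r["a", "c"]), -1)
  expect_equal(unname(sp$p["a", "b"]), 0)

  flat <- rbind(m, d = rep(0.5, 6))
  sp2 <- spearman_matrix(flat)
  expect_equal(sp2$zero_variance, "d")
  expect_true(is.na(sp2$r["d", "a"]))

  expect_error(spearman_matrix(m[, 1:3]), "at least 4 samples")
})

test_that("t-approximation p-values agree with cor.test", {
  set.seed(23)
  m <- matrix(rnorm(4 * 8), nrow = 4, dimnames = list(paste0("t", 1:4), NULL))
  sp <- spearman_matrix(m)
  for (i in 1:3) for (j in (i + 1):4) {
    ref <- suppressWarnings(cor.test(m[i, ], m[j, ], method = "spearman"))
    expect_equal(unname(sp$r[i, j]), unname(ref$estimate), tolerance = 1e-12)
  }
})

test_that("exact permutation p matches an independent enumeration at n = 5", {
  set.seed(24)
  m <- matrix(rnorm(3 * 5), nrow = 3, dimnames = list(paste0("t", 1:3), NULL))
  sp <- spearman_matrix(m, exact = TRUE)
  # independent oracle: enumerate orderings via recursion on index vectors
  perms <- expand.grid(rep(list(1:5), 5))
  perms <- as.matrix(perms[apply(perms, 1, function(r) length(unique(r)) == 5), ])
  expect_equal(nrow(perms), 120L)
  for (i in 1:2) for (j in (i + 1):3) {
    ri <- rank(m[i, ]); rj <- rank(m[j, ])
    obs <- cor(ri, rj)
    rhos <- apply(perms, 1, function(pm) cor(ri, rj[pm]))
    expect_equal(unname(sp$p[i, j]), mean(abs(rhos) >= abs(obs) - 1e-12),
                 tolerance = 1e-12)
  }
  expect_error(spearman_matrix(matrix(rnorm(20), 2, 10), exact = TRUE),
               "n <= 9")
})

test_that("build_network applies the |r|/p thresholds exactly", {
  taxa <- paste0("t", 1:4)
  r <- matrix(0.1, 4, 4, dimnames = list(taxa, taxa)); diag(r) <- 1
  p <- matrix(0.5, 4, 4, dimnames = list(taxa, taxa)); diag(p) <- 0
  r["t1", "t2"] <- r["t2", "t1"] <- 0.8;  p["t1", "t2"] <- p["t2", "t1"] <- 0.001
  r["t1", "t3"] <- r["t3", "t1"] <- -0.5; p["t1", "t3"] <- p["t3", "t1"] <- 0.01
  r["t2", "t3"] <- r["t3", "t2"] <- 0.9;  p["t2", "t3"] <- p["t3", "t2"] <- 0.2  # p too big
  r["t3", "t4"] <- r["t4", "t3"] <- 0.2;  p["t3", "t4"] <- p["t4", "t3"] <- 0.001 # r too small

  net <- build_network(r, p, r_thresh = 0.3, p_thresh = 0.05)
  expect_equal(nrow(net$edges), 2L)
  keys <- apply(net$edges[, 1:2], 1, paste, collapse = "|")
  expect_setequal(keys, c("t1|t2", "t1|t3"))
  expect_setequal(net$edges$sign, c("positive", "negative"))
  # isolated t4 dropped by default, kept on request
  expect_setequal(net$vertices, c("t1", "t2", "t3"))
  iso <- build_network(r, p, r_thresh = 0.3, p_thresh = 0.05,
                       keep_isolated = TRUE)
  expect_setequal(iso$vertices, taxa)

  # empty network when nothing clears the threshold
  empty <- suppressWarnings(build_network(r, p, r_thresh = 0.95, p_thresh = 0.05))
  expect_equal(nrow(empty$edges), 0L)

  # permissive thresholds with keep_isolated give the complete defined graph
  complete <- build_network(r, p, r_thresh = 0, p_thresh = 1.1,
                            keep_isolated = TRUE)
  expect_equal(nrow(complete$edges), choose(4, 2))
})

test_that("edges are invariant to taxon reordering and threshold monotone", {
  set.seed(25)
  m <- matrix(rexp(8 * 12), nrow = 8, dimnames = list(paste0("t", 1:8), NULL))
  sp <- spearman_matrix(m)
  base <- build_network(sp$r, sp$p, 0.3, 0.05)
  perm <- sample(8)
  sp2 <- spearman_matrix(m[perm, ])
  net2 <- build_network(sp2$r, sp2$p, 0.3, 0.05)
  key <- function(net) sort(apply(net$edges[, 1:2], 1,
                                  function(e) paste(sort(e), collapse = "|")))
  expect_equal(key(net2), key(base))

  tighter_r <- suppressWarnings(build_network(sp$r, sp$p, 0.5, 0.05))
  tighter_p <- suppressWarnings(build_network(sp$r, sp$p, 0.3, 0.01))
  expect_true(all(key(tighter_r) %in% key(base)))
  expect_true(all(key(tighter_p) %in% key(base)))
})

test_that("graph statistics match closed forms for K3 and the 3-star", {
  k3 <- matrix(1, 3, 3) - diag(3)
  s3 <- net_from_adj(k3)
  expect_equal(unname(s3$stats), c(1, 0, 1))

  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  st <- net_from_adj(star)
  expect_equal(unname(st$stats), c(0, 1, 0.5))
})

test_that("graph statistics agree with adjacency-matrix enumeration", {
  set.seed(26)
  for (rep in 1:5) {
    n <- 10
    adj <- matrix(0, n, n)
    adj[upper.tri(adj)] <- rbinom(choose(n, 2), 1, 0.3)
    adj <- adj + t(adj)
    if (sum(adj) == 0) next
    net <- net_from_adj(adj)
    expect_equal(unname(net$stats), unname(oracle_graph_stats(adj)),
                 tolerance = 1e-12)
  }
})

test_that("tiny networks report undefined statistics with a warning", {
  taxa <- c("a", "b")
  r <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(taxa, taxa))
  p <- matrix(c(0, 0.001, 0.001, 0), 2, dimnames = list(taxa, taxa))
  expect_warning(net <- build_network(r, p), "fewer than 3")
  expect_true(is.na(net$stats["transitivity"]))
})

test_that("compare_networks performs exact set algebra", {
  adj <- matrix(0, 4, 4)
  adj[1, 2] <- adj[2, 1] <- adj[2, 3] <- adj[3, 2] <- adj[3, 4] <- adj[4, 3] <- 1
  a <- net_from_adj(adj)
  identical_cmp <- compare_networks(list(x = a, y = a))
  expect_equal(length(identical_cmp$unique_vertices_a[[1]]), 0L)
  expect_equal(length(identical_cmp$unique_edges_a[[1]]), 0L)
  expect_equal(identical_cmp$shared_edges, 3L)

  adj2 <- adj
  adj2[1, 2] <- adj2[2, 1] <- 0
  adj2[1, 4] <- adj2[4, 1] <- 1
  b <- net_from_adj(adj2)
  cmp <- compare_networks(list(a = a, b = b))
  expect_equal(cmp$unique_edges_a[[1]], "t1|t2")
  expect_equal(cmp$unique_edges_b[[1]], "t1|t4")
})
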