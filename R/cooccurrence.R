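# Per-group Spearman co-occurrence networks: correlation/p matrices,
# thresholded graph construction, graph statistics, cross-group comparison.

#' Spearman correlation and p-value matrices over taxa
#'
#' Ranks (average ranks for ties) are correlated with Pearson's formula.
#' Two-sided p-values come from the t approximation
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on n-2 degrees of freedom; an exact
#' permutation p over all n! orderings is available for small n. Taxa with
#' zero variance across the samples get undefined correlations (NA) and are
#' flagged.
#'
#' @param x a `core_table`, [abundance_table], or taxa-x-samples matrix
#'   (already restricted to one group's samples).
#' @param exact compute exact permutation p-values (only allowed for
#'   n <= 9 samples).
#' @return list with `r`, `p` (taxa x taxa matrices), `n` (samples used) and
#'   `zero_variance` (taxon ids).
#' @export
spearman_matrix <- function(x, exact = FALSE) {
  if (inherits(x, "core_table")) x <- x$abundance
  m <- if (inherits(x, "abundance_table")) x$values else as.matrix(x)
  n <- ncol(m)
  if (n < 4) stop("need at least 4 samples for co-occurrence correlations")
  zero_var <- rownames(m)[apply(m, 1, stats::var) == 0]
  r <- suppressWarnings(stats::cor(t(m), method = "spearman"))
  diag(r) <- 1
  if (exact) {
    if (n > 9) stop("exact permutation p-values are limited to n <= 9 samples")
    p <- exact_spearman_p(m, r)
  } else {
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p[abs(r) >= 1 - 1e-12] <- 0
  }
  diag(p) <- 0
  p[is.na(r)] <- NA
  list(r = r, p = p, n = n, zero_variance = zero_var)
}

# exhaustive two-sided permutation p: P(|rho_perm| >= |rho_obs|) over all
# orderings of one variable
exact_spearman_p <- function(m, r) {
  n <- ncol(m)
  perms <- all_permutations(n)
  p <- matrix(NA_real_, nrow(m), nrow(m), dimnames = dimnames(r))
  for (i in seq_len(nrow(m))) {
    ri <- rank(m[i, ])
    for (j in seq_len(nrow(m))) {
      if (is.na(r[i, j])) next
      rj <- rank(m[j, ])
      rhos <- apply(perms, 1, function(pm) stats::cor(ri, rj[pm]))
      p[i, j] <- mean(abs(rhos) >= abs(r[i, j]) - 1e-12)
    }
  }
  p
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(pos) {
    cbind(pos, ifelse(sub >= pos, sub + 1L, sub), deparse.level = 0)
  }))
}

#' Build a co-occurrence network from correlation matrices
#'
#' Keeps the edges with `|r| > r_thresh` and `p < p_thresh` (undirected,
#' each pair stored once, no self-loops). By default the vertex set is the
#' taxa incident to at least one edge; `keep_isolated = TRUE` keeps every
#' taxon as a vertex.
#'
#' @param r,p symmetric taxa-x-taxa matrices from [spearman_matrix].
#' @param r_thresh absolute-correlation threshold (strict).
#' @param p_thresh p-value threshold (strict).
#' @param keep_isolated keep edge-less taxa as vertices.
#' @return object of class `cooc_network`: list with `vertices`, `edges`
#'   (data.frame: taxon_i, taxon_j, r, p, sign), `graph` (igraph object) and
#'   `stats` (see [graph_stats]).
#' @export
build_network <- function(r, p, r_thresh = 0.3, p_thresh = 0.05,
                          keep_isolated = FALSE) {
  if (!isTRUE(all.equal(dim(r), dim(p))) ||
      !identical(rownames(r), rownames(p)))
    stop("r and p matrices must share dimensions and taxa")
  taxa <- rownames(r)
  keep <- upper.tri(r) & !is.na(r) & !is.na(p) &
    abs(r) > r_thresh & p < p_thresh
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(taxon_i = taxa[idx[, 1]], taxon_j = taxa[idx[, 2]],
                      r = r[keep], p = p[keep],
                      sign = ifelse(r[keep] >= 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  vertices <- if (keep_isolated) taxa
              else sort(unique(c(edges$taxon_i, edges$taxon_j)))
  g <- igraph::graph_from_data_frame(edges[, c("taxon_i", "taxon_j")],
                                     directed = FALSE,
                                     vertices = data.frame(name = vertices))
  net <- structure(list(vertices = vertices, edges = edges, graph = g,
                        thresholds = c(r = r_thresh, p = p_thresh),
                        keep_isolated = keep_isolated, stats = NULL),
                   class = "cooc_network")
  net$stats <- graph_stats(net)
  net
}

#' @export
print.cooc_network <- function(x, ...) {
  cat(sprintf("cooc_network: %d vertices, %d edges (|r| > %g, p < %g)\n",
              length(x$vertices), nrow(x$edges),
              x$thresholds["r"], x$thresholds["p"]))
  invisible(x)
}

#' Global statistics of a co-occurrence network
#'
#' Transitivity (global clustering coefficient,
#' \eqn{3 \times \#triangles / \#connected\ triples}), degree
#' centralization (\eqn{\sum_i (d_{max} - d_i) / ((n-1)(n-2))}; 1 for a
#' star, 0 for a regular graph) and graph density
#' (\eqn{2E / (n(n-1))}), all on the network's vertex set as built. With
#' fewer than 3 vertices the statistics are undefined and returned as `NA`
#' with a warning.
#'
#' @param net a `cooc_network`.
#' @return named numeric vector `transitivity`, `centralization_degree`,
#'   `graph_density`.
#' @export
graph_stats <- function(net) {
  stopifnot(inherits(net, "cooc_network"))
  g <- net$graph
  n <- igraph::vcount(g)
  if (n < 3) {
    warning("graph statistics are undefined for fewer than 3 vertices")
    return(c(transitivity = NA_real_, centralization_degree = NA_real_,
             graph_density = if (n >= 2) igraph::edge_density(g) else NA_real_))
  }
  tr <- igraph::transitivity(g, type = "global")
  if (is.nan(tr)) tr <- NA_real_
  c(transitivity = tr,
    centralization_degree = igraph::centr_degree(g, mode = "all",
                                                 loops = FALSE)$centralization,
    graph_density = igraph::edge_density(g))
}

# canonical undirected edge key, order-free
edge_keys <- function(net) {
  if (nrow(net$edges) == 0) return(character(0))
  apply(net$edges[, c("taxon_i", "taxon_j")], 1,
        function(e) paste(sort(e), collapse = "|"))
}

#' Compare co-occurrence networks across groups
#'
#' Pairwise set algebra on vertex ids and canonical (sorted) edge keys.
#'
#' @param nets named list of `cooc_network` objects (>= 2).
#' @return data.frame with one row per ordered network pair: shared/unique
#'   vertex and edge counts and the unique element lists.
#' @export
compare_networks <- function(nets) {
  if (length(nets) < 2) stop("need at least two networks")
  if (is.null(names(nets)) || any(!nzchar(names(nets))))
    stop("networks must be named")
  prs <- utils::combn(names(nets), 2, simplify = FALSE)
  out <- lapply(prs, function(pr) {
    a <- nets[[pr[1]]]; b <- nets[[pr[2]]]
    ea <- edge_keys(a); eb <- edge_keys(b)
    data.frame(network_a = pr[1], network_b = pr[2],
               shared_vertices = length(intersect(a$vertices, b$vertices)),
               unique_vertices_a = I(list(setdiff(a$vertices, b$vertices))),
               unique_vertices_b = I(list(setdiff(b$vertices, a$vertices))),
               shared_edges = length(intersect(ea, eb)),
               unique_edges_a = I(list(setdiff(ea, eb))),
               unique_edges_b = I(list(setdiff(eb, ea))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
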