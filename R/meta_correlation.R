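# Taxa-by-clinical-feature correlation matrices (pearson / spearman /
# kendall tau-b), pairwise-complete, with BH adjustment across the matrix,
# plus heatmap-style and long-form exports.

#' Correlate core taxa with continuous clinical features
#'
#' Every (taxon, feature) cell is computed on its pairwise-complete
#' observations. Kendall is the tie-corrected tau-b. P-values use the t
#' approximation for pearson/spearman and the normal approximation
#' \eqn{z = 3\tau\sqrt{n(n-1)} / \sqrt{2(2n+5)}} for kendall; BH q-values
#' are adjusted across the whole matrix per method. Cells with fewer than
#' `min_n` complete pairs, or a constant column, are undefined (NA) and
#' flagged.
#'
#' @param core a `core_table`, [abundance_table], or samples-x-taxa matrix.
#' @param meta clinical data.frame (samples as rows, aligned to the same
#'   samples); only its numeric columns are used.
#' @param method `"pearson"`, `"spearman"` or `"kendall"`.
#' @param min_n minimum pairwise-complete observations per cell (default 4).
#' @return object of class `correlation_result`: list with matrices `r`,
#'   `p`, `q`, `n` (taxa x features), `method` and `flagged` (data.frame of
#'   undefined cells).
#' @export
correlate_meta <- function(core, meta, method = c("pearson", "spearman", "kendall"),
                           min_n = 4L) {
  method <- match.arg(method)
  x <- if (inherits(core, "core_table")) sample_matrix(core$abundance)
       else if (inherits(core, "abundance_table")) sample_matrix(core)
       else as.matrix(core)
  num_cols <- vapply(meta, is.numeric, logical(1))
  y <- as.matrix(meta[, num_cols, drop = FALSE])
  if (ncol(y) == 0) stop("no continuous clinical features to correlate")
  if (nrow(y) != nrow(x)) stop("core table and clinical table sample counts differ")
  taxa <- colnames(x); feats <- colnames(y)
  r <- p <- nmat <- matrix(NA_real_, length(taxa), length(feats),
                           dimnames = list(taxa, feats))
  for (i in seq_along(taxa)) {
    for (j in seq_along(feats)) {
      ok <- !is.na(x[, i]) & !is.na(y[, j])
      n <- sum(ok)
      nmat[i, j] <- n
      if (n < min_n) next
      xi <- x[ok, i]; yj <- y[ok, j]
      if (stats::sd(xi) == 0 || stats::sd(yj) == 0) next
      rv <- stats::cor(xi, yj, method = method)
      r[i, j] <- rv
      p[i, j] <- cor_pvalue(rv, n, method)
    }
  }
  q <- matrix(stats::p.adjust(p, method = "BH"), nrow = nrow(p),
              dimnames = dimnames(p))
  flagged <- which(is.na(r), arr.ind = TRUE)
  flagged <- data.frame(taxon = taxa[flagged[, 1]], feature = feats[flagged[, 2]],
                        n = nmat[is.na(r)], stringsAsFactors = FALSE)
  structure(list(r = r, p = p, q = q, n = nmat, method = method,
                 flagged = flagged),
            class = "correlation_result")
}

cor_pvalue <- function(r, n, method) {
  if (method %in% c("pearson", "spearman")) {
    if (abs(r) >= 1 - 1e-12) return(0)
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  } else {
    z <- 3 * r * sqrt(n * (n - 1)) / sqrt(2 * (2 * n + 5))
    2 * stats::pnorm(-abs(z))
  }
}

#' Export a correlation heat table
#'
#' Writes the correlation matrix as TSV together with a parallel mark matrix
#' distinguishing raw significance (`*` for p < 0.05) from
#' multiplicity-adjusted significance (`#` for q < 0.05), and optionally an
#' SVG heatmap.
#'
#' @param result a `correlation_result`.
#' @param path output TSV path (the mark matrix goes to `<path>.marks.tsv`).
#' @param svg optional SVG figure path.
#' @return `path`, invisibly.
#' @export
export_heat <- function(result, path, svg = NULL) {
  stopifnot(inherits(result, "correlation_result"))
  marks <- matrix("", nrow(result$r), ncol(result$r),
                  dimnames = dimnames(result$r))
  marks[!is.na(result$p) & result$p < 0.05] <- "*"
  marks[!is.na(result$q) & result$q < 0.05] <- "#"
  write_tsv_matrix(result$r, path, id_col = "taxon")
  write_tsv_matrix(marks, paste0(path, ".marks.tsv"), id_col = "taxon")
  if (!is.null(svg)) {
    grDevices::svg(svg, width = 7, height = 7)
    on.exit(grDevices::dev.off())
    rr <- result$r
    rr[is.na(rr)] <- 0
    stats::heatmap(rr, scale = "none", col = grDevices::hcl.colors(64, "Blue-Red"),
                   margins = c(8, 8))
  }
  invisible(path)
}

#' Long-form pairwise correlation detail
#'
#' One row per (taxon, feature) pair with r, p, q and the number of
#' pairwise-complete observations; restricted to `pairs` when given.
#'
#' @param result a `correlation_result`.
#' @param pairs optional 2-column data.frame/matrix of (taxon, feature)
#'   pairs; an unknown pair is an error.
#' @return data.frame with columns `taxon`, `feature`, `r`, `p`, `q`, `n`.
#' @export
export_detail <- function(result, pairs = NULL) {
  stopifnot(inherits(result, "correlation_result"))
  all_pairs <- expand.grid(taxon = rownames(result$r),
                           feature = colnames(result$r),
                           stringsAsFactors = FALSE)
  if (!is.null(pairs)) {
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    colnames(pairs)[1:2] <- c("taxon", "feature")
    bad <- !(pairs$taxon %in% rownames(result$r)) |
      !(pairs$feature %in% colnames(result$r))
    if (any(bad))
      stop("unknown pair(s): ",
           paste(pairs$taxon[bad], pairs$feature[bad], sep = "/", collapse = ", "))
    all_pairs <- pairs[, c("taxon", "feature")]
  }
  idx <- cbind(match(all_pairs$taxon, rownames(result$r)),
               match(all_pairs$feature, colnames(result$r)))
  data.frame(all_pairs,
             r = result$r[idx], p = result$p[idx], q = result$q[idx],
             n = result$n[idx], stringsAsFactors = FALSE)
}

# shared TSV writer: id column + matrix, '.' decimals, tab delimiter
write_tsv_matrix <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
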