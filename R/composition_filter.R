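# Core-taxon filtering by abundance/prevalence thresholds and top-N
# composition summaries.

#' Per-taxon per-group abundance and prevalence
#'
#' For every taxon and group: the mean relative abundance over all of the
#' group's samples (zeros included) and the prevalence, i.e. the fraction of
#' the group's samples where the taxon is non-zero.
#'
#' @param abundance an [abundance_table].
#' @param groups group label per sample (same order as the table's samples).
#' @return list with matrices `mean_abundance` and `prevalence`
#'   (taxa x groups) and `group_sizes`.
#' @export
taxon_stats <- function(abundance, groups) {
  stopifnot(inherits(abundance, "abundance_table"))
  groups <- as.factor(groups)
  if (length(groups) != ncol(abundance$values))
    stop("one group label per sample required")
  if (any(table(groups) == 0)) stop("empty group level present")
  glev <- levels(droplevels(groups))
  vals <- abundance$values
  mean_ab <- sapply(glev, function(g) rowMeans(vals[, groups == g, drop = FALSE]))
  prev <- sapply(glev, function(g) rowMeans(vals[, groups == g, drop = FALSE] > 0))
  mean_ab <- matrix(mean_ab, nrow = nrow(vals),
                    dimnames = list(rownames(vals), glev))
  prev <- matrix(prev, nrow = nrow(vals),
                 dimnames = list(rownames(vals), glev))
  list(mean_abundance = mean_ab, prevalence = prev,
       group_sizes = table(droplevels(groups)))
}

#' Filter core taxa by abundance and prevalence thresholds
#'
#' A taxon qualifies in a group when its group-mean relative abundance is at
#' least `min_abund` AND its prevalence in that group is at least `min_prev`.
#' With `mode = "any"` (default) a taxon is retained when it qualifies in at
#' least one group; with `mode = "all"` it must qualify in every group. The
#' defaults (0.001, 0.7) implement the common 1-per-mille abundance /
#' 70 percent prevalence decontamination rule.
#'
#' @param abundance an [abundance_table].
#' @param groups group label per sample. A single level treats the whole
#'   cohort as one group.
#' @param min_abund minimum group-mean relative abundance, in `[0, 1]`.
#' @param min_prev minimum prevalence, in `[0, 1]`.
#' @param mode `"any"` or `"all"`.
#' @return object of class `core_table`: list with `abundance` (the filtered
#'   [abundance_table]), `retained_ids`, `stats` (the [taxon_stats] result),
#'   `excluded` (data.frame of dropped taxa with reasons), `thresholds`,
#'   `mode`.
#' @export
filter_core <- function(abundance, groups, min_abund = 0.001, min_prev = 0.7,
                        mode = c("any", "all")) {
  mode <- match.arg(mode)
  if (min_abund < 0 || min_abund > 1 || min_prev < 0 || min_prev > 1)
    stop("thresholds must lie in [0, 1]")
  st <- taxon_stats(abundance, groups)
  qualifies <- st$mean_abundance >= min_abund & st$prevalence >= min_prev
  keep <- if (mode == "any") rowSums(qualifies) > 0 else rowSums(!qualifies) == 0
  if (!any(keep))
    stop("no taxa survive the thresholds (", min_abund, ", ", min_prev, ")")
  excluded <- data.frame(
    taxon = rownames(st$mean_abundance)[!keep],
    max_group_mean = apply(st$mean_abundance[!keep, , drop = FALSE], 1, max),
    max_group_prevalence = apply(st$prevalence[!keep, , drop = FALSE], 1, max),
    stringsAsFactors = FALSE)
  excluded$reason <- ifelse(
    excluded$max_group_mean < min_abund & excluded$max_group_prevalence < min_prev,
    "abundance+prevalence",
    ifelse(excluded$max_group_mean < min_abund, "abundance", "prevalence"))
  rownames(excluded) <- NULL
  ab2 <- abundance
  ab2$values <- abundance$values[keep, , drop = FALSE]
  ab2$lineages <- abundance$lineages[keep]
  ab2$taxa_ids <- abundance$taxa_ids[keep]
  structure(list(abundance = ab2, retained_ids = abundance$taxa_ids[keep],
                 stats = st, excluded = excluded,
                 thresholds = c(min_abund = min_abund, min_prev = min_prev),
                 mode = mode),
            class = "core_table")
}

#' @export
print.core_table <- function(x, ...) {
  cat(sprintf("core_table: %d of %d taxa retained (min_abund=%g, min_prev=%g, mode=%s)\n",
              length(x$retained_ids),
              length(x$retained_ids) + nrow(x$excluded),
              x$thresholds["min_abund"], x$thresholds["min_prev"], x$mode))
  invisible(x)
}

#' Top-N composition table
#'
#' Ranks taxa by overall mean relative abundance (ties broken
#' lexicographically by taxon id), keeps the top `top_n` and pools the rest
#' into an `Others` row, conserving each sample's original column total.
#'
#' @param abundance an [abundance_table].
#' @param groups optional group labels; when given, per-group mean
#'   compositions are returned as well.
#' @param top_n number of named taxa to keep.
#' @return list with `per_sample` ((top_n + 1) x samples matrix including the
#'   `Others` row), `per_group` (same by group mean, or `NULL`) and
#'   `top_taxa`.
#' @export
structure_table <- function(abundance, groups = NULL, top_n = 10) {
  stopifnot(inherits(abundance, "abundance_table"))
  if (top_n < 1) stop("top_n must be at least 1")
  vals <- abundance$values
  top_n <- min(top_n, nrow(vals))
  overall <- rowMeans(vals)
  ord <- order(-overall, rownames(vals))
  top_ids <- rownames(vals)[ord[seq_len(top_n)]]
  rest <- setdiff(rownames(vals), top_ids)
  others <- if (length(rest) > 0) colSums(vals[rest, , drop = FALSE])
            else stats::setNames(rep(0, ncol(vals)), colnames(vals))
  per_sample <- rbind(vals[top_ids, , drop = FALSE], Others = others)
  per_group <- NULL
  if (!is.null(groups)) {
    groups <- droplevels(as.factor(groups))
    per_group <- sapply(levels(groups), function(g)
      rowMeans(per_sample[, groups == g, drop = FALSE]))
    per_group <- matrix(per_group, nrow = nrow(per_sample),
                        dimnames = list(rownames(per_sample), levels(groups)))
  }
  list(per_sample = per_sample, per_group = per_group, top_taxa = top_ids)
}
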