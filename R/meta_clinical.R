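# Clinical meta-data handling. A clinical table is a plain data.frame with
# sample ids as row names; column class carries the feature type (numeric =
# continuous, factor/character = categorical). Missing values are NA.

#' Read a clinical meta-data table
#'
#' Tab-separated, first column sample identifiers. Columns that parse fully
#' as numbers become continuous features; everything else is categorical.
#' Empty cells and the literal strings `NA`/`na` become missing.
#'
#' @param path path to the TSV file.
#' @return data.frame with sample ids as row names.
#' @export
read_clinical <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE,
                           na.strings = c("", "NA", "na"))
  colnames(raw) <- sub("^#", "", colnames(raw))
  ids <- trimws(as.character(raw[[1]]))
  if (anyDuplicated(ids)) stop("duplicated sample ids in clinical table")
  out <- raw[, -1, drop = FALSE]
  rownames(out) <- ids
  out
}

#' Summarize missing values in clinical meta-data
#'
#' @param meta clinical data.frame (samples as rows).
#' @return list with `per_feature` (named missing counts), `pattern`
#'   (logical sample-by-feature missingness matrix, row order as `meta`) and
#'   `complete_cases` (number of rows with no missing value).
#' @export
missing_summary <- function(meta) {
  pattern <- is.na(as.matrix(meta))
  list(per_feature = colSums(pattern),
       pattern = pattern,
       complete_cases = sum(rowSums(pattern) == 0))
}

#' Bivariate ("three-line") clinical summary table
#'
#' One row per continuous feature (mean +/- sd per group, one-way ANOVA p;
#' Welch two-sample t when there are exactly two groups) and one block per
#' categorical feature (count and percent per level per group, chi-square p,
#' replaced by Fisher's exact test when any expected cell is below 5).
#' Missing values are dropped pairwise per feature. A continuous feature with
#' zero variance in every group is flagged and reported with p = 1.
#'
#' @param meta clinical data.frame, samples as rows.
#' @param group character/factor vector of group labels, one per row of
#'   `meta`.
#' @param pooled_t use the classic pooled-variance t test instead of Welch
#'   for two-group continuous comparisons.
#' @return data.frame with columns `feature`, `level`, one summary column per
#'   group, `test`, `statistic`, `p`, `flag`.
#' @export
describe_by_group <- function(meta, group, pooled_t = FALSE) {
  group <- as.factor(group)
  if (length(group) != nrow(meta)) stop("one group label per sample required")
  if (nlevels(droplevels(group)) < 2) stop("need at least two groups")
  group <- droplevels(group)
  rows <- list()
  for (feat in colnames(meta)) {
    x <- meta[[feat]]
    if (is.numeric(x)) {
      ok <- !is.na(x)
      cells <- vapply(levels(group), function(g) {
        xi <- x[ok & group == g]
        sprintf("%.3g ± %.3g", mean(xi), stats::sd(xi))
      }, character(1))
      vars <- tapply(x[ok], group[ok], stats::var)
      if (all(is.na(vars) | vars == 0)) {
        rows[[length(rows) + 1L]] <- c(feature = feat, level = "", cells,
                                       test = "anova", statistic = "0",
                                       p = "1", flag = "degenerate variance")
        next
      }
      if (nlevels(group) == 2) {
        tt <- stats::t.test(x[ok] ~ group[ok], var.equal = pooled_t)
        rows[[length(rows) + 1L]] <- c(feature = feat, level = "", cells,
                                       test = if (pooled_t) "t" else "welch t",
                                       statistic = format(unname(tt$statistic), digits = 15),
                                       p = format(tt$p.value, digits = 15), flag = "")
      } else {
        fit <- stats::aov(x[ok] ~ group[ok])
        tab <- summary(fit)[[1]]
        rows[[length(rows) + 1L]] <- c(feature = feat, level = "", cells,
                                       test = "anova",
                                       statistic = format(tab[["F value"]][1], digits = 15),
                                       p = format(tab[["Pr(>F)"]][1], digits = 15), flag = "")
      }
    } else {
      xf <- factor(x)
      ok <- !is.na(xf)
      tab <- table(xf[ok], group[ok])
      exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      use_fisher <- any(exp_counts < 5)
      p <- if (use_fisher) {
        stats::fisher.test(tab)$p.value
      } else {
        suppressWarnings(stats::chisq.test(tab)$p.value)
      }
      stat <- if (use_fisher) NA_real_
              else unname(suppressWarnings(stats::chisq.test(tab)$statistic))
      for (lev in rownames(tab)) {
        cells <- vapply(levels(group), function(g) {
          n <- tab[lev, g]
          sprintf("%d (%.1f%%)", n, 100 * n / max(1, sum(tab[, g])))
        }, character(1))
        first <- lev == rownames(tab)[1]
        rows[[length(rows) + 1L]] <- c(
          feature = feat, level = lev, cells,
          test = if (first) (if (use_fisher) "fisher" else "chisq") else "",
          statistic = if (first && !use_fisher) format(stat, digits = 15) else "",
          p = if (first) format(p, digits = 15) else "", flag = "")
      }
    }
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Exclude subjects by categorical criteria
#'
#' A subject is removed when it matches at least one `feature == value`
#' predicate. A missing value in a criterion feature counts as non-matching
#' (the subject is retained) and is reported.
#'
#' @param meta clinical data.frame, samples as rows.
#' @param criteria named list, `feature = value` (value may be a vector of
#'   matching levels).
#' @return list with `retained` (sample ids), `excluded` (sample ids) and
#'   `na_retained` (ids retained despite a missing criterion cell).
#' @export
exclude_subjects <- function(meta, criteria = list()) {
  ids <- rownames(meta)
  if (length(criteria) == 0)
    return(list(retained = ids, excluded = character(0),
                na_retained = character(0)))
  unknown <- setdiff(names(criteria), colnames(meta))
  if (length(unknown) > 0)
    stop("unknown feature(s) in exclusion criteria: ",
         paste(unknown, collapse = ", "))
  hit <- rep(FALSE, nrow(meta))
  saw_na <- rep(FALSE, nrow(meta))
  for (feat in names(criteria)) {
    x <- meta[[feat]]
    saw_na <- saw_na | is.na(x)
    hit <- hit | (!is.na(x) & as.character(x) %in% as.character(criteria[[feat]]))
  }
  list(retained = ids[!hit], excluded = ids[hit],
       na_retained = ids[!hit & saw_na])
}
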