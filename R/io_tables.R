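RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")
RANK_PREFIXES <- c(kingdom = "k__", phylum = "p__", class = "c__", order = "o__",
                   family = "f__", genus = "g__", species = "s__")

#' Construct an abundance table
#'
#' The canonical container for taxon relative abundances: a taxa-by-samples
#' numeric matrix together with the taxonomic rank of the rows and the
#' rank-prefixed lineage string of each taxon (greengenes/QIIME style,
#' `k__...;p__...;...`). Values are dimensionless fractions; each sample
#' column sums to at most 1 (plus floating-point slack).
#'
#' @param values numeric matrix, taxa as rows, samples as columns. Row names
#'   are taxon identifiers, column names sample identifiers.
#' @param lineages character vector of lineage strings, one per row of
#'   `values`. Defaults to the row names.
#' @param rank taxonomic rank of the rows, one of `"phylum"` ... `"species"`.
#'   Auto-detected from the lineages when `NULL`.
#' @return An object of class `abundance_table` with fields `values`,
#'   `lineages`, `rank`, `taxa_ids`, `sample_ids`.
#' @export
abundance_table <- function(values, lineages = rownames(values), rank = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("abundance table is empty")
  if (anyNA(values))
    stop("abundance table contains missing cells; refusing to impute zeros")
  if (any(values < 0))
    stop("abundance table contains negative values")
  if (is.null(rownames(values))) {
    if (is.null(lineages)) stop("taxon identifiers are required")
    rownames(values) <- taxon_labels(lineages)
  }
  if (is.null(colnames(values))) stop("sample identifiers are required")
  if (anyDuplicated(rownames(values)))
    stop("duplicate taxon identifiers")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers")
  if (is.null(lineages)) lineages <- rownames(values)
  lineages <- as.character(lineages)
  if (length(lineages) != nrow(values))
    stop("one lineage string per taxon is required")
  csums <- colSums(values)
  if (any(csums > 1 + 1e-6)) {
    # percent-scale exports (columns summing near 100) are rescaled, anything
    # else is a hard error
    if (all(csums <= 100 + 1e-4) && stats::median(csums) > 50) {
      warning("columns sum near 100; rescaling percent abundances to fractions")
      values <- values / 100
    } else {
      stop("per-sample abundances sum to more than 1 and do not look like percentages")
    }
  }
  if (is.null(rank)) rank <- detect_rank(lineages)
  rank <- match.arg(rank, RANKS)
  structure(
    list(values = values, lineages = lineages, rank = rank,
         taxa_ids = rownames(values), sample_ids = colnames(values)),
    class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d taxa (%s level) x %d samples\n",
              nrow(x$values), x$rank, ncol(x$values)))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Samples-as-rows view of an abundance table
#'
#' Taxa-as-rows is canonical on disk; most statistical routines want the
#' transposed orientation.
#'
#' @param x an `abundance_table`.
#' @return numeric matrix, samples x taxa.
#' @export
sample_matrix <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  t(x$values)
}

# deepest populated greengenes prefix across all lineages; mixed depths are
# rejected rather than guessed at
detect_rank <- function(lineages) {
  depth_one <- function(lin) {
    fields <- trimws(strsplit(lin, ";", fixed = TRUE)[[1]])
    deepest <- 0L
    for (i in seq_along(RANK_PREFIXES)) {
      hit <- grepl(paste0("^", RANK_PREFIXES[i]), fields)
      if (any(hit) && any(nchar(sub(paste0("^", RANK_PREFIXES[i]), "", fields[hit])) > 0))
        deepest <- i
    }
    deepest
  }
  depths <- vapply(lineages, depth_one, integer(1), USE.NAMES = FALSE)
  if (all(depths == 0L)) {
    # no greengenes prefixes at all: plain taxon names, treat as species level
    return("species")
  }
  populated <- depths[depths > 0L]
  if (length(unique(populated)) > 1L)
    stop("lineages are annotated at mixed depths (",
         paste(RANKS[sort(unique(populated))], collapse = ", "),
         "); split the file by rank before reading")
  RANKS[populated[1]]
}

# short display label: last populated rank field of the lineage
taxon_labels <- function(lineages) {
  lab <- vapply(lineages, function(lin) {
    fields <- trimws(strsplit(lin, ";", fixed = TRUE)[[1]])
    fields <- fields[nchar(gsub("^[kpcofgs]__", "", fields)) > 0]
    if (length(fields) == 0) return(lin)
    fields[length(fields)]
  }, character(1), USE.NAMES = FALSE)
  make.unique(lab)
}

#' Read a taxon relative-abundance table
#'
#' Reads the tab-separated QIIME `summarize_taxa`-style dialect: first column
#' holds the rank-prefixed lineage, remaining columns one sample each. Rows
#' with byte-identical lineages are merged by summation. The taxonomic rank is
#' auto-detected from the deepest populated lineage prefix unless `rank_hint`
#' is given. Tables whose columns sum near 100 are rescaled to fractions with
#' a warning.
#'
#' @param path path to a TSV file.
#' @param rank_hint optional rank, one of `"phylum"` ... `"species"`;
#'   overrides auto-detection.
#' @return An [abundance_table].
#' @export
read_abundance <- function(path, rank_hint = NULL) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L) stop("empty abundance table: ", path)
  lineages <- trimws(raw[[1]])
  samples <- trimws(colnames(raw)[-1])
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals) & nzchar(vals), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric abundance cell at row '%s', sample '%s'",
                 lineages[bad[1, 1]], samples[bad[1, 2]]))
  if (anyNA(num))
    stop("missing abundance cells found; refusing to impute zeros")
  if (any(num < 0)) {
    idx <- which(num < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at row '%s', sample '%s'",
                 lineages[idx[1]], samples[idx[2]]))
  }
  # merge duplicate lineages by summation
  if (anyDuplicated(lineages)) {
    num <- rowsum(num, group = lineages, reorder = FALSE)
    lineages <- rownames(num)
  }
  dimnames(num) <- list(taxon_labels(lineages), samples)
  abundance_table(num, lineages = lineages, rank = rank_hint)
}

#' Write an abundance table
#'
#' Emits the same TSV dialect [read_abundance] consumes (lineage first column,
#' tab delimiter, '.' decimal separator), so that a read/write round trip
#' preserves values to full double precision and lineage strings byte-exactly.
#'
#' @param x an [abundance_table].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(x, path) {
  stopifnot(inherits(x, "abundance_table"))
  df <- data.frame(Taxon = x$lineages, x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a QIIME-dialect mapping file
#'
#' Tab-separated with a header; the QIIME convention of starting the header
#' with `#SampleID` is accepted (the leading `#` is stripped from all header
#' names). Sample identifiers are whitespace-trimmed and matched
#' case-sensitively everywhere in the package.
#'
#' @param path path to the mapping TSV.
#' @param group_col name of the column holding the group label
#'   (default `"Group"`).
#' @return A `data.frame` with columns `sample_id`, `group`, plus any extra
#'   mapping columns, of class `mapping_table`.
#' @export
read_mapping <- function(path, group_col = "Group") {
  raw <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  colnames(raw) <- sub("^#", "", colnames(raw))
  mapping_table(raw, group_col = group_col)
}

#' Construct a mapping table from a data frame
#'
#' @param df data.frame whose first column (or `SampleID` column) holds sample
#'   identifiers.
#' @param group_col name of the group column.
#' @return A `mapping_table` data.frame with `sample_id` and `group` first.
#' @export
mapping_table <- function(df, group_col = "Group") {
  id_col <- if ("SampleID" %in% colnames(df)) "SampleID" else colnames(df)[1]
  if (!group_col %in% colnames(df))
    stop("group column '", group_col, "' not found; available columns: ",
         paste(setdiff(colnames(df), id_col), collapse = ", "))
  ids <- trimws(as.character(df[[id_col]]))
  if (anyDuplicated(ids))
    stop("duplicated sample id(s) in mapping: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  grp <- as.character(df[[group_col]])
  if (any(is.na(grp) | !nzchar(grp)))
    stop("every sample needs a non-empty group label")
  out <- data.frame(sample_id = ids, group = grp,
                    df[, setdiff(colnames(df), c(id_col, group_col)), drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- out$sample_id
  class(out) <- c("mapping_table", "data.frame")
  out
}

#' Align an abundance table to a mapping file
#'
#' Restricts both tables to their shared samples and orders the abundance
#' columns by the mapping order, so that sub-group or regrouped analyses only
#' ever require editing the mapping file. Samples present on one side only are
#' dropped (never an error) and reported through the returned log.
#'
#' @param abundance an [abundance_table].
#' @param mapping a `mapping_table`.
#' @return A list with elements `abundance`, `mapping` (both restricted to the
#'   shared samples, identically ordered) and `log` (character vectors
#'   `dropped_from_abundance`, `dropped_from_mapping`).
#' @export
align_tables <- function(abundance, mapping) {
  stopifnot(inherits(abundance, "abundance_table"))
  ab_ids <- trimws(abundance$sample_ids)
  map_ids <- mapping$sample_id
  shared <- map_ids[map_ids %in% ab_ids]
  if (length(shared) == 0)
    stop(sprintf("no shared samples between abundance (%d ids) and mapping (%d ids)",
                 length(ab_ids), length(map_ids)))
  vals <- abundance$values
  colnames(vals) <- ab_ids
  ab2 <- abundance
  ab2$values <- vals[, shared, drop = FALSE]
  ab2$sample_ids <- shared
  map2 <- mapping[match(shared, map_ids), , drop = FALSE]
  list(abundance = ab2, mapping = map2,
       log = list(dropped_from_abundance = setdiff(ab_ids, shared),
                  dropped_from_mapping = setdiff(map_ids, shared)))
}
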