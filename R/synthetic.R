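# Synthetic clinical-microbiome datasets with planted structure: a
# compositional abundance table with group-dependent differential taxa, a
# binary clinical status, a dietary block with planted cluster structure
# and missing cells, and planted taxon-feature associations. The truth
# record makes every planted element machine-readable for
# parameter-recovery tests.

#' Specify a synthetic dataset
#'
#' Samples are drawn per status group; taxon intensities are log-normal
#' (taxon base log-mean ~ N(0, `base_sd`), per-sample log noise sd
#' `noise_sd`), with `effect_size` added to the log-intensity of each
#' planted differential taxon in the second status group, then exponentiated
#' and closed to sum 1 (relative abundances, matching QIIME
#' `summarize_taxa` output). The dietary block draws `diet_features`
#' continuous features from `diet_clusters` Gaussian clusters whose centers
#' sit `separation` noise-sd apart per feature; a `missing_rate` fraction of
#' dietary cells is masked. Planted taxon-feature associations share a
#' latent standard-normal driver added (scaled by `assoc_strength`) to both
#' sides.
#'
#' @param n_per_group named integer vector of samples per status group
#'   (default `c(Control = 30, Cases = 30)`).
#' @param n_taxa number of taxa.
#' @param planted_taxa integer indices of differential taxa (default none).
#' @param effect_size log-fold effect added in the second group.
#' @param base_sd sd of taxon base log-means.
#' @param noise_sd per-sample log-intensity noise sd.
#' @param diet_features number of dietary columns.
#' @param diet_clusters planted number of dietary clusters.
#' @param separation cluster-center spacing in noise-sd units (default 8).
#' @param missing_rate fraction of dietary cells masked missing.
#' @param assoc_pairs optional 2-column matrix/data.frame of (taxon index,
#'   dietary feature index) planted associations.
#' @param assoc_strength latent-driver loading for planted associations.
#' @param depth optional sequencing depth; when given, integer multinomial
#'   counts are generated alongside the relative abundances.
#' @param seed RNG seed; the spec plus seed fully determines the dataset.
#' @return a `sim_spec` list.
#' @export
sim_spec <- function(n_per_group = c(Control = 30, Cases = 30),
                     n_taxa = 20, planted_taxa = integer(0),
                     effect_size = 2, base_sd = 1.2, noise_sd = 1,
                     diet_features = 6, diet_clusters = 2, separation = 8,
                     missing_rate = 0.05, assoc_pairs = NULL,
                     assoc_strength = 1, depth = NULL, seed = 1L) {
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group))))
    stop("n_per_group must be a named vector of status groups")
  if (length(planted_taxa) > 0 &&
      (min(planted_taxa) < 1 || max(planted_taxa) > n_taxa))
    stop("planted taxon index outside 1..n_taxa")
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must be in [0,1]")
  if (!is.null(assoc_pairs)) {
    assoc_pairs <- as.matrix(assoc_pairs)
    if (max(assoc_pairs[, 1]) > n_taxa || max(assoc_pairs[, 2]) > diet_features)
      stop("association pair index out of range")
  }
  structure(list(n_per_group = n_per_group, n_taxa = n_taxa,
                 planted_taxa = as.integer(planted_taxa),
                 effect_size = effect_size, base_sd = base_sd,
                 noise_sd = noise_sd, diet_features = diet_features,
                 diet_clusters = diet_clusters, separation = separation,
                 missing_rate = missing_rate, assoc_pairs = assoc_pairs,
                 assoc_strength = assoc_strength, depth = depth,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Generate a synthetic dataset
#'
#' @param spec a [sim_spec].
#' @return list with `abundance` (an [abundance_table]), `mapping` (a
#'   `mapping_table` whose `group` is the status), `meta` (clinical
#'   data.frame: `status`, `age`, `sex`, dietary columns with planted
#'   missingness), `counts` (integer matrix or `NULL`) and `truth` (planted
#'   taxa, cluster assignment, associations, seed).
#' @export
gen_dataset <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  n <- sum(spec$n_per_group)
  status <- rep(names(spec$n_per_group), spec$n_per_group)
  ids <- sprintf("S%03d", seq_len(n))
  second <- names(spec$n_per_group)[min(2, length(spec$n_per_group))]

  # latent driver for planted taxon-feature associations
  z <- stats::rnorm(n)

  # log-normal intensities, closed to relative abundances
  mu <- stats::rnorm(spec$n_taxa, 0, spec$base_sd)
  logint <- matrix(stats::rnorm(spec$n_taxa * n, 0, spec$noise_sd),
                   nrow = spec$n_taxa) + mu
  if (length(spec$planted_taxa) > 0)
    logint[spec$planted_taxa, status == second] <-
      logint[spec$planted_taxa, status == second] + spec$effect_size
  if (!is.null(spec$assoc_pairs))
    for (k in seq_len(nrow(spec$assoc_pairs)))
      logint[spec$assoc_pairs[k, 1], ] <-
        logint[spec$assoc_pairs[k, 1], ] + spec$assoc_strength * z
  intens <- exp(logint)
  vals <- sweep(intens, 2, colSums(intens), "/")
  lineages <- sprintf(
    "k__Bacteria;p__P%02d;c__C;o__O;f__F;g__G%02d;s__Taxon_%03d",
    (seq_len(spec$n_taxa) - 1) %% 6 + 1, seq_len(spec$n_taxa),
    seq_len(spec$n_taxa))
  dimnames(vals) <- list(sprintf("s__Taxon_%03d", seq_len(spec$n_taxa)), ids)
  abundance <- abundance_table(vals, lineages = lineages)

  counts <- NULL
  if (!is.null(spec$depth)) {
    counts <- apply(vals, 2, function(pcol) stats::rmultinom(1, spec$depth, pcol))
    dimnames(counts) <- dimnames(vals)
  }

  # dietary block: balanced cluster assignment, centers `separation` sd apart
  clus <- rep_len(seq_len(spec$diet_clusters), n)[sample.int(n)]
  diet <- matrix(stats::rnorm(n * spec$diet_features), nrow = n)
  diet <- diet + (clus - 1) * spec$separation
  colnames(diet) <- sprintf("diet_%02d", seq_len(spec$diet_features))
  if (!is.null(spec$assoc_pairs))
    for (k in seq_len(nrow(spec$assoc_pairs)))
      diet[, spec$assoc_pairs[k, 2]] <-
        diet[, spec$assoc_pairs[k, 2]] + spec$assoc_strength * z
  if (spec$missing_rate > 0) {
    mask <- matrix(stats::runif(length(diet)) < spec$missing_rate,
                   nrow = nrow(diet))
    diet[mask] <- NA
  }

  meta <- data.frame(status = status,
                     age = round(stats::rnorm(n, 50, 10), 1),
                     sex = sample(c("F", "M"), n, replace = TRUE),
                     diet, row.names = ids, stringsAsFactors = FALSE)
  mapping <- mapping_table(data.frame(SampleID = ids, Group = status,
                                      stringsAsFactors = FALSE))
  truth <- list(planted_taxa = rownames(vals)[spec$planted_taxa],
                effect_size = spec$effect_size,
                affected_group = second,
                diet_clusters = spec$diet_clusters,
                cluster_assignment = stats::setNames(clus, ids),
                assoc_pairs = if (is.null(spec$assoc_pairs)) NULL else
                  data.frame(taxon = rownames(vals)[spec$assoc_pairs[, 1]],
                             feature = colnames(diet)[spec$assoc_pairs[, 2]],
                             stringsAsFactors = FALSE),
                seed = spec$seed)
  list(abundance = abundance, mapping = mapping, meta = meta,
       counts = counts, truth = truth)
}

#' Write a synthetic dataset to disk
#'
#' Emits the exact dialects the readers consume: abundance TSV (lineage
#' first column), QIIME-style mapping TSV (`#SampleID` header), clinical
#' TSV, and a `truth.json` ground-truth record.
#'
#' @param dat a [gen_dataset] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_abundance(dat$abundance, file.path(dir, "abundance.tsv"))
  map <- dat$mapping
  colnames(map)[1:2] <- c("#SampleID", "Group")
  utils::write.table(map, file.path(dir, "mapping.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- data.frame(SampleID = rownames(dat$meta), dat$meta,
                     check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(meta, file.path(dir, "meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- dat$truth
  truth$cluster_assignment <- as.list(truth$cluster_assignment)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
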