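# Shared fixture builders; all data is generated in code at test time.

# abundance table from a plain matrix, generating species-level lineages
make_abundance <- function(values, samples = NULL, taxa = NULL) {
  if (is.null(samples)) samples <- sprintf("S%d", seq_len(ncol(values)))
  if (is.null(taxa))
    taxa <- if (!is.null(rownames(values))) rownames(values)
            else sprintf("t%d", seq_len(nrow(values)))
  lineages <- sprintf("k__Bacteria;p__P;c__C;o__O;f__F;g__G;s__%s", taxa)
  dimnames(values) <- list(sprintf("s__%s", taxa), samples)
  abundance_table(values, lineages = lineages)
}

# random compositional matrix (taxa x samples), strictly positive
random_composition <- function(n_taxa, n_samples, seed = 1) {
  set.seed(seed)
  m <- matrix(rexp(n_taxa * n_samples), n_taxa, n_samples)
  sweep(m, 2, colSums(m), "/")
}

write_tsv_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# planted Gaussian blobs: n points, k clusters, centers `sep` apart per dim
make_blobs <- function(n, k, p = 2, sep = 8, seed = 1) {
  set.seed(seed)
  lab <- rep_len(seq_len(k), n)
  x <- matrix(rnorm(n * p), n, p) + (lab - 1) * sep
  rownames(x) <- sprintf("P%d", seq_len(n))
  list(x = x, labels = lab)
}
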