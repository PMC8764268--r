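# One-step orchestration: align -> (exclude/regroup) -> filter -> structure
# -> alpha -> beta -> network -> rfcv -> correlation, with plain-file
# outputs and a JSON manifest echoing every parameter used. Re-runs skip
# stages whose configuration hash is unchanged and whose outputs exist.

#' Default pipeline configuration
#'
#' All stage parameters with their defaults: core filter 0.001 minimum
#' group-mean relative abundance and 0.7 minimum prevalence; network
#' thresholds |r| > 0.3, p < 0.05; RFCV with 5 folds and 10 seeds;
#' PERMANOVA with 999 permutations. `overrides` is a nested list merged
#' over the defaults. Per-stage seeds are derived deterministically from
#' the single global `seed` and recorded in the manifest.
#'
#' @param overrides nested list of settings to override.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(overrides = list()) {
  defaults <- list(
    seed = 1L,
    exclude = list(criteria = list()),
    regroup = list(enabled = FALSE, features = NULL, metric = "euclidean",
                   method = "kmeans", k_range = 2:6,
                   indices = VALIDITY_INDICES, status_col = "status"),
    filter = list(min_abund = 0.001, min_prev = 0.7, mode = "any"),
    structure = list(top_n = 10L),
    alpha = list(indices = ALPHA_INDICES),
    beta = list(n_perm = 999L, n_axes = 2L),
    network = list(r_thresh = 0.3, p_thresh = 0.05, keep_isolated = FALSE),
    rfcv = list(k_folds = 5L, n_seeds = 10L, n_trees = 500L,
                rule = "one_sd", importance = "permutation",
                status_col = "status"),
    cor = list(method = "spearman", min_n = 4L))
  merge_config <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_config(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  structure(merge_config(defaults, overrides), class = "pipeline_config")
}

config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, force = TRUE, digits = NA), tf)
  substr(unname(tools::md5sum(tf)), 1, 12)
}

#' Run the full downstream workflow
#'
#' Executes every stage in dependency order on aligned inputs and writes
#' plain-text tables plus `manifest.json` (package version, full parameter
#' echo, per-stage status, derived seeds, output checksums) into `outdir`.
#' A stage failure halts its dependents but preserves completed outputs;
#' the manifest marks the failed stage. Re-running against the same
#' `outdir` skips stages whose config hash is unchanged and whose outputs
#' still exist.
#'
#' @param abundance an [abundance_table] or path to an abundance TSV.
#' @param mapping a `mapping_table` or path to a mapping TSV. Its `group`
#'   column defines the comparison groups (composite labels when regrouping
#'   is enabled upstream).
#' @param meta optional clinical data.frame or TSV path (needed for the
#'   exclude, regroup and correlation stages).
#' @param outdir output directory.
#' @param config a [pipeline_config].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(abundance, mapping, meta = NULL, outdir,
                         config = pipeline_config()) {
  if (is.character(abundance)) abundance <- read_abundance(abundance)
  if (is.character(mapping)) mapping <- read_mapping(mapping)
  if (is.character(meta)) meta <- read_clinical(meta)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  prev <- NULL
  manifest_path <- file.path(outdir, "manifest.json")
  if (file.exists(manifest_path))
    prev <- tryCatch(jsonlite::read_json(manifest_path), error = function(e) NULL)

  stage_seed <- function(i) derive_seed(config$seed, i)
  manifest <- list(package = "clinmicro",
                   version = as.character(utils::packageVersion("clinmicro")),
                   config = config,
                   seeds = list(global = config$seed),
                   stages = list())
  state <- new.env(parent = emptyenv())
  state$failed <- character(0)

  # stages that only build in-memory state for their dependents are cheap and
  # always re-run; expensive leaf stages are skipped when their config hash
  # and outputs are unchanged
  run_stage <- function(name, deps, cfg, outputs, fun, cacheable = FALSE) {
    if (any(deps %in% state$failed)) {
      manifest$stages[[name]] <<- list(status = "skipped",
                                       reason = "dependency failed")
      state$failed <- c(state$failed, name)
      return(invisible(NULL))
    }
    h <- config_hash(list(cfg = cfg, seed = config$seed))
    paths <- file.path(outdir, outputs)
    cached <- cacheable && !is.null(prev) &&
      identical(prev$stages[[name]]$hash, as.character(h)) &&
      isTRUE(prev$stages[[name]]$status %in% c("complete", "cached")) &&
      all(file.exists(paths))
    if (cached) {
      manifest$stages[[name]] <<- list(status = "cached", hash = h,
                                       outputs = as.list(outputs))
      return(invisible(NULL))
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed", hash = h,
                                       error = conditionMessage(res))
      state$failed <- c(state$failed, name)
    } else {
      sums <- tools::md5sum(paths[file.exists(paths)])
      manifest$stages[[name]] <<- list(status = "complete", hash = h,
                                       outputs = as.list(outputs),
                                       checksums = as.list(unname(sums)))
    }
    invisible(NULL)
  }

  # --- align ---
  aligned <- NULL
  run_stage("align", character(0), list(), "align_log.json", function() {
    aligned <<- align_tables(abundance, mapping)
    jsonlite::write_json(aligned$log, file.path(outdir, "align_log.json"),
                         auto_unbox = FALSE)
  })

  # --- exclude ---
  run_stage("exclude", "align", config$exclude, "exclusion.json", function() {
    crit <- config$exclude$criteria
    if (length(crit) > 0 && !is.null(meta)) {
      keep <- exclude_subjects(meta[aligned$mapping$sample_id, , drop = FALSE],
                               crit)
      m2 <- aligned$mapping[aligned$mapping$sample_id %in% keep$retained, ,
                            drop = FALSE]
      aligned <<- align_tables(aligned$abundance, m2)
      jsonlite::write_json(keep[c("excluded", "na_retained")],
                           file.path(outdir, "exclusion.json"))
    } else {
      jsonlite::write_json(list(excluded = character(0)),
                           file.path(outdir, "exclusion.json"))
    }
  })

  # --- regroup ---
  groups <- NULL
  run_stage("regroup", "exclude", config$regroup,
            c("regrouped_mapping.tsv", "vote_tally.tsv"), function() {
    if (isTRUE(config$regroup$enabled) && !is.null(meta)) {
      rg <- config$regroup
      m <- meta[aligned$mapping$sample_id, , drop = FALSE]
      feats <- rg$features
      if (is.null(feats))
        feats <- setdiff(colnames(m)[vapply(m, is.numeric, logical(1))],
                         rg$status_col)
      block <- m[, feats, drop = FALSE]
      vote <- vote_best_k(block, k_range = rg$k_range, method = rg$method,
                          indices = rg$indices, seed = stage_seed(3L))
      lab <- vote$labels[[as.character(vote$best_k)]]
      used <- names(lab)
      status <- m[used, rg$status_col]
      comp <- regroup_labels(status, lab)
      m2 <- aligned$mapping[aligned$mapping$sample_id %in% used, , drop = FALSE]
      m2$group <- comp[match(m2$sample_id, used)]
      aligned <<- align_tables(aligned$abundance, m2)
      utils::write.table(
        data.frame(k = names(vote$tally), votes = as.integer(vote$tally)),
        file.path(outdir, "vote_tally.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    } else {
      utils::write.table(data.frame(k = integer(0), votes = integer(0)),
                         file.path(outdir, "vote_tally.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    groups <<- aligned$mapping$group
    map_out <- aligned$mapping
    colnames(map_out)[1:2] <- c("#SampleID", "Group")
    utils::write.table(map_out, file.path(outdir, "regrouped_mapping.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  # --- filter ---
  core <- NULL
  run_stage("filter", "regroup", config$filter,
            c("core_table.tsv", "exclusion_report.tsv"), function() {
    core <<- filter_core(aligned$abundance, groups,
                         min_abund = config$filter$min_abund,
                         min_prev = config$filter$min_prev,
                         mode = config$filter$mode)
    write_abundance(core$abundance, file.path(outdir, "core_table.tsv"))
    utils::write.table(core$excluded, file.path(outdir, "exclusion_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  upstream <- list(exclude = config$exclude, regroup = config$regroup,
                   filter = config$filter)

  # --- structure ---
  run_stage("structure", "filter", c(list(structure = config$structure), upstream),
            "structure.tsv", cacheable = TRUE, function() {
    st <- structure_table(core$abundance, groups, top_n = config$structure$top_n)
    write_tsv_matrix(st$per_sample, file.path(outdir, "structure.tsv"),
                     id_col = "taxon")
  })

  # --- alpha ---
  run_stage("alpha", "filter", c(list(alpha = config$alpha), upstream),
            c("alpha.tsv", "alpha_tests.tsv"), cacheable = TRUE, function() {
    a <- alpha_diversity(core$abundance, index = config$alpha$indices)
    utils::write.table(data.frame(sample_id = rownames(a), a),
                       file.path(outdir, "alpha.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tests <- do.call(rbind, lapply(colnames(a), function(ind) {
      ct <- compare_groups(a[[ind]], groups)
      data.frame(index = ind, ct$test)
    }))
    utils::write.table(tests, file.path(outdir, "alpha_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  # --- beta ---
  run_stage("beta", "filter", c(list(beta = config$beta), upstream),
            c("distance.tsv", "pcoa.tsv", "permanova.tsv"), cacheable = TRUE,
            function() {
    d <- bray_curtis(core$abundance)
    write_tsv_matrix(as.matrix(d), file.path(outdir, "distance.tsv"),
                     id_col = "sample_id")
    ord <- pcoa(d, n_axes = config$beta$n_axes)
    utils::write.table(
      data.frame(sample_id = rownames(ord$coordinates), ord$coordinates),
      file.path(outdir, "pcoa.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    pm <- permanova(d, groups, n_perm = config$beta$n_perm,
                    seed = stage_seed(6L))
    utils::write.table(
      data.frame(F = pm$F, R2 = pm$R2, p = pm$p, n_perm = pm$n_perm),
      file.path(outdir, "permanova.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  })

  # --- network ---
  run_stage("network", "filter", c(list(network = config$network), upstream),
            c("edges.tsv", "network_stats.tsv"), cacheable = TRUE, function() {
    glev <- unique(groups)
    edges <- list(); stats_rows <- list()
    for (g in glev) {
      sub <- core$abundance$values[, groups == g, drop = FALSE]
      sp <- spearman_matrix(sub)
      net <- build_network(sp$r, sp$p,
                           r_thresh = config$network$r_thresh,
                           p_thresh = config$network$p_thresh,
                           keep_isolated = config$network$keep_isolated)
      if (nrow(net$edges) > 0)
        edges[[g]] <- data.frame(group = g, net$edges)
      stats_rows[[g]] <- data.frame(group = g, t(net$stats))
    }
    edges_df <- if (length(edges) > 0) do.call(rbind, edges)
                else data.frame(group = character(0), taxon_i = character(0),
                                taxon_j = character(0), r = numeric(0),
                                p = numeric(0), sign = character(0))
    utils::write.table(edges_df, file.path(outdir, "edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(do.call(rbind, stats_rows),
                       file.path(outdir, "network_stats.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })

  # --- rfcv ---
  run_stage("rfcv", "filter", c(list(rfcv = config$rfcv), upstream),
            c("rfcv_curves.tsv", "markers.tsv", "roc.tsv", "rfcv_summary.json"),
            cacheable = TRUE, function() {
    status <- if (!is.null(meta) &&
                  config$rfcv$status_col %in% colnames(meta)) {
      meta[aligned$mapping$sample_id, config$rfcv$status_col]
    } else groups
    seeds <- derive_seed(stage_seed(8L), seq_len(config$rfcv$n_seeds))
    res <- rfcv_curves(core, status, k_folds = config$rfcv$k_folds,
                       seeds = seeds, n_trees = config$rfcv$n_trees,
                       importance = config$rfcv$importance)
    curves <- expand.grid(seed = res$seeds, m = res$subset_sizes)
    curves$mean_error <- as.vector(res$error_mean)
    curves$sd_error <- as.vector(res$error_sd)
    utils::write.table(curves, file.path(outdir, "rfcv_curves.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sel <- select_markers(res, rule = config$rfcv$rule)
    utils::write.table(data.frame(taxon = sel$union_markers),
                       file.path(outdir, "markers.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    roc <- cv_roc(res)
    utils::write.table(roc$roc, file.path(outdir, "roc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(auc = roc$auc, n_markers = length(sel$union_markers),
           m_star = as.list(sel$m_star)),
      file.path(outdir, "rfcv_summary.json"), auto_unbox = TRUE, digits = NA)
  })

  # --- correlation ---
  run_stage("cor", "filter", c(list(cor = config$cor), upstream),
            c("correlation.tsv", "correlation_detail.tsv"), cacheable = TRUE,
            function() {
    if (is.null(meta)) stop("correlation stage needs clinical meta-data")
    m <- meta[aligned$mapping$sample_id, , drop = FALSE]
    cr <- correlate_meta(core, m, method = config$cor$method,
                         min_n = config$cor$min_n)
    export_heat(cr, file.path(outdir, "correlation.tsv"))
    utils::write.table(export_detail(cr),
                       file.path(outdir, "correlation_detail.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  manifest$seeds$stages <- list(regroup = stage_seed(3L), beta = stage_seed(6L),
                                rfcv = stage_seed(8L))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE, null = "null")
  invisible(manifest)
}
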