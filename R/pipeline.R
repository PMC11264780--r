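# End-to-end orchestration: harmonize -> per-stratum diversity -> assembly
# null models -> core taxa -> correlations/regressions -> Mantel tests,
# with every parameter and seed recorded in a run manifest.

#' Pipeline run configuration
#'
#' @param counts,tree,metadata,taxonomy input file paths (`taxonomy`
#'   optional, `NULL` to skip rank-level analyses).
#' @param out_dir output directory.
#' @param group_cols stratification columns (default niche, health).
#' @param null_config a [null_model_config()].
#' @param thresholds a [classification_thresholds()].
#' @param ens_mode ENS mode for alpha diversity.
#' @param rarefaction_depth depth for repeated rarefaction; `NULL` uses the
#'   minimum sample total per stratum; `NA` disables rarefaction.
#' @param n_rarefactions rarefaction draws (default 100).
#' @param n_permutations permutations for PERMANOVA/dispersion/Mantel.
#' @param seed master seed; every stochastic stage derives from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(counts, tree, metadata, taxonomy = NULL,
                       out_dir = "ecoassembly_out",
                       group_cols = c("niche", "health"),
                       null_config = null_model_config(),
                       thresholds = classification_thresholds(),
                       ens_mode = "inverse_simpson",
                       rarefaction_depth = NULL, n_rarefactions = 100,
                       n_permutations = 999, seed = 1) {
  for (p in c(counts, tree, metadata, taxonomy))
    if (!file.exists(p)) ea_stop("input path does not exist: ", p,
                                 class = "ecoassembly_config_error")
  structure(list(counts = counts, tree = tree, metadata = metadata,
                 taxonomy = taxonomy, out_dir = out_dir,
                 group_cols = group_cols, null_config = null_config,
                 thresholds = thresholds, ens_mode = ens_mode,
                 rarefaction_depth = rarefaction_depth,
                 n_rarefactions = n_rarefactions,
                 n_permutations = n_permutations, seed = as.integer(seed)),
            class = "run_config")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Reads and harmonizes the inputs, then per stratum (niche x health):
#' per-sample ENS (with repeated rarefaction unless disabled), Bray-Curtis
#' and weighted UniFrac distances, PCoA, PERMANOVA and dispersion tests of
#' health within each niche, betaNTI/RC-bray assembly classification with
#' per-group process fractions, core taxa per niche with healthy/unhealthy
#' Venn partitions, phylum-chemistry Spearman correlations, ENS-chemistry
#' regressions, and Mantel tests of community distance against geographic
#' and chemistry distances. All tables are written as TSV under
#' `config$out_dir` together with a JSON manifest holding every parameter,
#' seed and assumption flag; strata with fewer than 2 samples are skipped
#' with a logged reason.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with all result tables and the manifest.
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      ea_stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(config$out_dir, "run.log")
  logf <- function(...) cat(paste0(..., "\n"), file = log_file, append = TRUE)
  cat("", file = log_file)

  inputs <- stage("read", {
    list(table = read_count_table(config$counts),
         tree = read_tree(config$tree),
         meta = read_metadata(config$metadata),
         taxonomy = if (!is.null(config$taxonomy))
           read_taxonomy(config$taxonomy) else NULL)
  })
  h <- stage("harmonize", withCallingHandlers(
    harmonize(inputs$table, inputs$tree, inputs$meta),
    message = function(m) { logf(conditionMessage(m)); invokeRestart("muffleMessage") }))
  table <- h$table; tree <- h$tree; meta <- h$meta
  grp <- interaction(meta[config$group_cols], drop = TRUE, sep = ":")
  logf("harmonized: ", nrow(table), " taxa x ", ncol(table), " samples, ",
       nlevels(grp), " strata")

  # --- alpha diversity -------------------------------------------------
  diversity <- stage("diversity", {
    pieces <- lapply(levels(grp), function(g) {
      sel <- grp == g
      tab_g <- table[, sel, drop = FALSE]
      depth <- config$rarefaction_depth
      if (is.null(depth)) depth <- min(colSums(tab_g))
      if (is.na(depth)) depth <- NULL
      out <- suppressMessages(alpha_diversity(
        tab_g, mode = config$ens_mode, depth = depth,
        n_draws = config$n_rarefactions, seed = config$seed))
      out$group <- g
      out
    })
    do.call(rbind, pieces)
  })

  # --- beta diversity per niche: health contrast -----------------------
  beta_tests <- stage("beta_diversity", {
    rows <- list()
    for (nh in unique(meta$niche)) {
      sel <- meta$niche == nh
      if (sum(sel) < 4 || length(unique(meta$health[sel])) < 2) {
        logf("beta_diversity: skipping niche ", nh, " (too few samples/groups)")
        next
      }
      tab_n <- table[, sel, drop = FALSE]
      tab_n <- tab_n[rowSums(tab_n) > 0, , drop = FALSE]
      duf <- weighted_unifrac_matrix(tab_n, tree, normalized = TRUE)
      ord <- pcoa(duf, k = 2)
      pmv <- permanova(duf, meta$health[sel], config$n_permutations,
                       seed = config$seed)
      dsp <- dispersion_test(duf, meta$health[sel], config$n_permutations,
                             seed = config$seed)
      rows[[nh]] <- data.frame(
        niche = nh, axis1_explained = ord$explained[1],
        axis2_explained = ord$explained[2],
        permanova_F = pmv$statistic, permanova_p = pmv$p_value,
        betadisper_F = dsp$statistic, betadisper_p = dsp$p_value,
        n_permutations = config$n_permutations, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })

  # --- assembly null models -------------------------------------------
  keep_strata <- names(which(table(grp) >= 2))
  assembly <- stage("assembly", withCallingHandlers(
    assembly_analysis(table[, grp %in% keep_strata, drop = FALSE],
                      tree, meta[grp %in% keep_strata, , drop = FALSE],
                      group_cols = config$group_cols,
                      config = config$null_config,
                      thresholds = config$thresholds),
    message = function(m) { logf(conditionMessage(m)); invokeRestart("muffleMessage") }))

  # --- core taxa per niche, healthy vs unhealthy -----------------------
  core <- stage("core_taxa", {
    rows <- list()
    for (nh in unique(meta$niche)) {
      ids_h <- meta$sample_id[meta$niche == nh & meta$health == "healthy"]
      ids_u <- meta$sample_id[meta$niche == nh & meta$health == "unhealthy"]
      if (!length(ids_h) || !length(ids_u)) next
      ch <- core_taxa(table, ids_h); cu <- core_taxa(table, ids_u)
      vp <- venn_partition(ch$core, cu$core)
      rows[[nh]] <- data.frame(
        niche = nh, n_core_healthy = length(ch$core),
        n_core_unhealthy = length(cu$core),
        n_only_healthy = length(vp$only_a),
        n_only_unhealthy = length(vp$only_b),
        n_shared = length(vp$shared), stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })

  # --- associations ----------------------------------------------------
  correlations <- regressions <- NULL
  if (!is.null(inputs$taxonomy)) {
    correlations <- stage("spearman_chemistry", {
      phylum <- aggregate_to_rank(table, inputs$taxonomy, "phylum")
      spearman_chemistry(to_relative(phylum), meta,
                         group_cols = config$group_cols)
    })
  }
  regressions <- stage("ens_regression",
    ens_chemistry_regression(diversity, meta, group_cols = config$group_cols,
                             on_constant = "flag"))

  mantel_results <- stage("mantel", {
    rows <- list()
    for (nh in unique(meta$niche)) for (hl in unique(meta$health)) {
      sel <- meta$niche == nh & meta$health == hl
      if (sum(sel) < 4) {
        logf("mantel: skipping ", nh, ":", hl, " (n < 4)")
        next
      }
      tab_g <- table[, sel, drop = FALSE]
      tab_g <- tab_g[rowSums(tab_g) > 0, , drop = FALSE]
      dbc <- bray_curtis_matrix(to_relative(tab_g))
      meta_g <- meta[sel, , drop = FALSE]
      dgeo <- geographic_distance_matrix(meta_g, level = "sample")
      for (target in c("geographic", "chemistry")) {
        d2 <- if (target == "geographic") dgeo else
          tryCatch(chemistry_distance_matrix(meta_g, level = "sample"),
                   error = function(e) NULL)
        if (is.null(d2)) next
        mt <- tryCatch(
          mantel_test(dbc, d2, n_permutations = config$n_permutations,
                      seed = config$seed),
          error = function(e) { logf("mantel ", nh, ":", hl, " vs ", target,
                                     ": ", conditionMessage(e)); NULL })
        if (is.null(mt)) next
        rows[[paste(nh, hl, target)]] <- data.frame(
          niche = nh, health = hl, target = target,
          statistic = mt$statistic, p = mt$p_value,
          n_permutations = mt$n_permutations, method = mt$method,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("ecoassembly")),
    seed = config$seed, group_cols = config$group_cols,
    null_model = unclass(config$null_config),
    thresholds = unclass(config$thresholds),
    ens_mode = config$ens_mode,
    rarefaction = list(depth = config$rarefaction_depth,
                       n_draws = config$n_rarefactions),
    n_permutations = config$n_permutations,
    inputs = list(counts = config$counts, tree = config$tree,
                  metadata = config$metadata, taxonomy = config$taxonomy),
    assumptions = c(
      "betaMNTD abundance-weighted; null shuffles tips within each stratum pool",
      "RC-bray: occupancy-weighted richness draw, abundance-weighted fill, min 1 read per drawn taxon",
      "boundary ties classified toward the non-drift category",
      "Mantel: Pearson, one-sided greater"))

  results <- list(diversity = diversity, beta_tests = beta_tests,
                  assembly_pairs = assembly$pairs,
                  assembly_fractions = assembly$fractions,
                  core_taxa = core, correlations = correlations,
                  regressions = regressions, mantel = mantel_results,
                  manifest = manifest)

  write_tsv(diversity, file.path(config$out_dir, "alpha_diversity.tsv"))
  if (!is.null(beta_tests))
    write_tsv(beta_tests, file.path(config$out_dir, "beta_diversity.tsv"))
  write_tsv(assembly$pairs, file.path(config$out_dir, "assembly_pairs.tsv"))
  write_tsv(assembly$fractions,
            file.path(config$out_dir, "assembly_fractions.tsv"))
  if (!is.null(core)) write_tsv(core, file.path(config$out_dir, "core_taxa.tsv"))
  if (!is.null(correlations))
    write_tsv(correlations, file.path(config$out_dir, "correlations.tsv"))
  if (!is.null(regressions))
    write_tsv(regressions, file.path(config$out_dir, "regressions.tsv"))
  if (!is.null(mantel_results))
    write_tsv(mantel_results, file.path(config$out_dir, "mantel.tsv"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(results)
}
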