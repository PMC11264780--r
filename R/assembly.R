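# Null-model quantification of community assembly: betaMNTD/betaNTI with
# phylogeny-shuffling nulls, the abundance-based Raup-Crick metric on
# Bray-Curtis (RC-bray), and the five-way process classification.

process_levels <- c("heterogeneous_selection", "homogeneous_selection",
                    "dispersal_limitation_drift", "homogenizing_dispersal",
                    "drift")

#' Null-model configuration
#'
#' @param n_reps number of null replicates (>= 99; default 999).
#' @param seed RNG seed.
#' @param abundance_weighted weight betaMNTD by relative abundances
#'   (default `TRUE`).
#' @param pool_scope `"group"` (nulls drawn within each niche x health
#'   stratum, the reporting unit of the per-group process fractions) or
#'   `"all_samples"` (one pool across the whole table).
#' @return list of class `null_model_config`.
#' @export
null_model_config <- function(n_reps = 999, seed = 1, abundance_weighted = TRUE,
                              pool_scope = c("group", "all_samples")) {
  if (n_reps < 99) ea_stop("n_reps must be >= 99")
  structure(list(n_reps = as.integer(n_reps), seed = as.integer(seed),
                 abundance_weighted = isTRUE(abundance_weighted),
                 pool_scope = match.arg(pool_scope)),
            class = "null_model_config")
}

#' Classification thresholds for assembly processes
#'
#' @param bnti_threshold |betaNTI| at and beyond which turnover is called
#'   selection (default 2).
#' @param rc_threshold |RC-bray| at and beyond which, given |betaNTI| below
#'   its threshold, turnover is called dispersal (default 0.95).
#' @return list of class `classification_thresholds`.
#' @export
classification_thresholds <- function(bnti_threshold = 2, rc_threshold = 0.95) {
  if (bnti_threshold <= 0 || rc_threshold <= 0)
    ea_stop("thresholds must be positive")
  structure(list(bnti_threshold = bnti_threshold, rc_threshold = rc_threshold),
            class = "classification_thresholds")
}

# Shared prep: drop zero-total taxa, prune tree, return relab + patristic D.
prep_bmntd_inputs <- function(table, tree) {
  missing_taxa <- setdiff(rownames(table), tree$tip.label)
  if (length(missing_taxa))
    ea_stop("taxa absent from tree: ", paste(missing_taxa, collapse = ", "),
            class = "ecoassembly_mismatch_error")
  tab <- table[rowSums(table) > 0, , drop = FALSE]
  if (any(colSums(tab) == 0)) ea_stop("empty sample in betaMNTD input")
  tr <- if (length(setdiff(tree$tip.label, rownames(tab))))
    ape::keep.tip(tree, rownames(tab)) else tree
  D <- patristic_distances(tr)[rownames(tab), rownames(tab), drop = FALSE]
  list(relab = to_relative(tab), D = D)
}

#' Beta mean nearest taxon distance of one sample pair
#'
#' Mean patristic distance from each taxon present in one community to its
#' phylogenetically closest taxon in the other, averaged over both
#' directions. Weighted form weights each taxon by its relative abundance
#' within its sample; unweighted form weights uniformly. Shared taxa
#' contribute distance 0.
#'
#' @param x,y named abundance vectors (counts or proportions; names are
#'   tree leaves).
#' @param tree rooted `phylo` tree with branch lengths.
#' @param abundance_weighted logical.
#' @return non-negative scalar.
#' @export
beta_mntd <- function(x, y, tree, abundance_weighted = TRUE) {
  taxa <- union(names(x)[x > 0], names(y)[y > 0])
  if (!length(names(x)) || !length(names(y)) || !sum(x > 0) || !sum(y > 0))
    ea_stop("beta_mntd: empty sample")
  tab <- matrix(0, length(taxa), 2, dimnames = list(taxa, c("x", "y")))
  tab[names(x)[x > 0], "x"] <- x[x > 0]
  tab[names(y)[y > 0], "y"] <- y[y > 0]
  inp <- prep_bmntd_inputs(tab, tree)
  eng <- bmntd_engine_cpp(inp$relab, inp$D, abundance_weighted,
                          matrix(integer(0), 0, nrow(inp$relab)))
  as.numeric(eng$obs)
}

#' Observed betaMNTD matrix over all sample pairs
#'
#' @param table count (or relative-abundance) matrix, taxa rows.
#' @inheritParams beta_mntd
#' @return symmetric matrix of betaMNTD values over samples.
#' @export
bmntd_matrix <- function(table, tree, abundance_weighted = TRUE) {
  inp <- prep_bmntd_inputs(table, tree)
  eng <- bmntd_engine_cpp(inp$relab, inp$D, abundance_weighted,
                          matrix(integer(0), 0, nrow(inp$relab)))
  n <- ncol(table)
  m <- matrix(0, n, n, dimnames = list(colnames(table), colnames(table)))
  m[lower.tri(m)] <- NA  # filled by symmetry below
  q <- 1
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    m[a, b] <- m[b, a] <- eng$obs[q]
    q <- q + 1
  }
  m
}

# Unordered pair index data.frame for n samples (column order of the engine).
pair_index <- function(ids) {
  n <- length(ids)
  a <- rep(seq_len(n - 1), times = (n - 1):1)
  b <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  data.frame(sample_i = ids[a], sample_j = ids[b], stringsAsFactors = FALSE)
}

#' betaNTI for all sample pairs
#'
#' For each pair, the observed betaMNTD is standardized against a null
#' distribution obtained by shuffling taxon identities uniformly at random
#' across the tips of the pooled (pruned) tree and recomputing betaMNTD,
#' `n_reps` times: betaNTI = (obs - null mean) / null sd. One tip shuffle
#' is drawn per replicate and applied to every pair. Pairs whose null sd is
#' zero get `NA` betaNTI and are excluded from classification.
#'
#' @param table count matrix (taxa rows) for one sample pool.
#' @param tree rooted `phylo` tree containing all table taxa as leaves.
#' @param config a [null_model_config()].
#' @return data.frame with one row per unordered pair: `sample_i`,
#'   `sample_j`, `bmntd_obs`, `null_mean`, `null_sd`, `bnti`.
#' @export
bnti_matrix <- function(table, tree, config = null_model_config()) {
  if (ncol(table) < 2) ea_stop("need at least 2 samples")
  inp <- prep_bmntd_inputs(table, tree)
  S <- nrow(inp$relab)
  perms <- with_seed(config$seed,
                     t(vapply(seq_len(config$n_reps),
                              function(i) sample.int(S), integer(S))))
  eng <- bmntd_engine_cpp(inp$relab, inp$D, config$abundance_weighted, perms)
  out <- pair_index(colnames(table))
  out$bmntd_obs <- as.numeric(eng$obs)
  out$null_mean <- colMeans(eng$nulls)
  out$null_sd <- apply(eng$nulls, 2, sd)
  out$bnti <- ifelse(out$null_sd > 0,
                     (out$bmntd_obs - out$null_mean) / out$null_sd, NA_real_)
  n_undef <- sum(is.na(out$bnti))
  if (n_undef) message("bnti_matrix: ", n_undef,
                       " pair(s) with zero null sd flagged undefined")
  out
}

# One null community over the full taxon pool (R reference implementation
# of the compiled engine's per-sample draw; used by tests as an
# independent oracle for the null's marginal behaviour).
rc_null_sample <- function(S_x, N_x, occupancy, pool_rel) {
  drawn <- order(rexp(length(occupancy)) / occupancy)[seq_len(S_x)]
  counts <- rep(1L, S_x)
  extra <- N_x - S_x
  if (extra > 0) {
    p <- pool_rel[drawn]
    if (sum(p) <= 0) p <- rep(1, S_x)
    counts <- counts + as.integer(rmultinom(1, extra, p))
  }
  list(idx = drawn, counts = counts)
}

#' Raup-Crick metric on Bray-Curtis for all sample pairs
#'
#' For each replicate a null version of every sample is assembled from the
#' pool defined by the input table: the sample's observed richness is drawn
#' without replacement with probability proportional to taxon occupancy
#' (fraction of pool samples occupied), and its observed read total is
#' distributed over the drawn taxa by multinomial sampling proportional to
#' pool-wide relative abundances, with at least one read per drawn taxon.
#' RC = 2 ((#\{null BC < observed\} + 0.5 #\{null BC = observed\}) /
#' n_reps) - 1, in \[-1, 1\].
#'
#' @inheritParams bnti_matrix
#' @return data.frame with one row per unordered pair: `sample_i`,
#'   `sample_j`, `bc_obs`, `rc_bray`.
#' @export
rc_bray_matrix <- function(table, config = null_model_config()) {
  if (ncol(table) < 2) ea_stop("need at least 2 samples")
  tab <- table[rowSums(table) > 0, , drop = FALSE]
  if (nrow(tab) < 2) ea_stop("pool must contain at least 2 taxa")
  n <- ncol(tab)
  S_taxa <- nrow(tab)
  occupancy <- rowMeans(tab > 0)
  pool_rel <- rowSums(tab) / sum(tab)
  S_x <- colSums(tab > 0)
  N_x <- colSums(tab)
  if (any(S_x > S_taxa)) ea_stop("sample richness exceeds pool taxon count")
  obs <- vegan::vegdist(t(tab), method = "bray")
  counts <- with_seed(config$seed,
    rc_null_counts_cpp(as.integer(S_x), as.integer(N_x), occupancy,
                       pool_rel, as.numeric(obs), config$n_reps))
  out <- pair_index(colnames(tab))
  out$bc_obs <- as.numeric(obs)
  out$rc_bray <- 2 * ((counts[, 1] + 0.5 * counts[, 2]) / config$n_reps) - 1
  out
}

#' Classify pairwise turnover into assembly processes
#'
#' Mapping (with thresholds t_b = 2, t_r = 0.95 by default):
#' betaNTI >= t_b -> heterogeneous selection; betaNTI <= -t_b ->
#' homogeneous selection; otherwise RC >= t_r -> dispersal limitation with
#' drift; RC <= -t_r -> homogenizing dispersal; else drift. Boundary values
#' resolve toward the non-drift category.
#'
#' @param bnti,rc numeric vectors (finite), recycled to common length.
#' @param thresholds a [classification_thresholds()].
#' @return character vector of process labels.
#' @export
classify_process <- function(bnti, rc, thresholds = classification_thresholds()) {
  if (any(!is.finite(bnti)) || any(!is.finite(rc)))
    ea_stop("classify_process: non-finite input")
  tb <- thresholds$bnti_threshold; tr <- thresholds$rc_threshold
  out <- ifelse(bnti >= tb, "heterogeneous_selection",
         ifelse(bnti <= -tb, "homogeneous_selection",
         ifelse(rc >= tr, "dispersal_limitation_drift",
         ifelse(rc <= -tr, "homogenizing_dispersal", "drift"))))
  out
}

#' Per-group fractions of assembly processes
#'
#' @param results data.frame with a `process` column (`NA` for pairs whose
#'   betaNTI was undefined) and the grouping column named by `group_col`
#'   (default `"group"`); within-group pairs only.
#' @param group_col name of the grouping column.
#' @return data.frame: one row per group x process with columns `group`,
#'   `process`, `fraction`, `n_pairs`; fractions sum to 1 within group.
#' @export
process_fractions <- function(results, group_col = "group") {
  if (!group_col %in% names(results))
    ea_stop("missing grouping column: ", group_col)
  groups <- unique(results[[group_col]])
  rows <- lapply(groups, function(g) {
    sub <- results[results[[group_col]] == g, , drop = FALSE]
    cls <- sub$process[!is.na(sub$process)]
    if (!length(cls)) ea_stop("group with zero classified pairs: ", g)
    counts <- table(factor(cls, levels = process_levels))
    data.frame(group = g, process = process_levels,
               fraction = as.numeric(counts) / length(cls),
               n_pairs = length(cls), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full assembly analysis per stratum
#'
#' Runs [bnti_matrix()] and [rc_bray_matrix()] within each stratum defined
#' by `group_cols` (default niche x health, the study's reporting unit),
#' classifies every within-stratum pair, and tabulates per-stratum process
#' fractions. With `pool_scope = "all_samples"` the null models use the
#' whole table as the pool, and only within-stratum pairs are classified.
#'
#' @param table harmonized count matrix.
#' @param tree harmonized `phylo` tree.
#' @param meta harmonized metadata (one row per table column).
#' @param group_cols metadata columns defining strata.
#' @param config a [null_model_config()].
#' @param thresholds a [classification_thresholds()].
#' @return list with `pairs` (per-pair statistics, process label, group)
#'   and `fractions` (per-group process fractions).
#' @export
assembly_analysis <- function(table, tree, meta,
                              group_cols = c("niche", "health"),
                              config = null_model_config(),
                              thresholds = classification_thresholds()) {
  stopifnot(identical(colnames(table), meta$sample_id))
  grp <- interaction(meta[group_cols], drop = TRUE, sep = ":")
  run_pool <- function(tab_g, seed_offset) {
    cfg <- config
    cfg$seed <- (config$seed + seed_offset) %% .Machine$integer.max
    bn <- bnti_matrix(tab_g, tree, cfg)
    rc <- rc_bray_matrix(tab_g, cfg)
    merge(bn, rc, by = c("sample_i", "sample_j"), sort = FALSE)
  }
  if (config$pool_scope == "all_samples") {
    res <- run_pool(table, 0L)
    gmap <- setNames(as.character(grp), meta$sample_id)
    res$group <- ifelse(gmap[res$sample_i] == gmap[res$sample_j],
                        gmap[res$sample_i], NA_character_)
    res <- res[!is.na(res$group), , drop = FALSE]
  } else {
    pieces <- lapply(seq_along(levels(grp)), function(k) {
      g <- levels(grp)[k]
      sel <- which(grp == g)
      if (length(sel) < 2) {
        message("assembly_analysis: skipping stratum ", g, " (< 2 samples)")
        return(NULL)
      }
      tab_g <- table[, sel, drop = FALSE]
      tab_g <- tab_g[rowSums(tab_g) > 0, , drop = FALSE]
      out <- run_pool(tab_g, k)
      out$group <- g
      out
    })
    res <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  }
  ok <- is.finite(res$bnti) & is.finite(res$rc_bray)
  res$process <- NA_character_
  res$process[ok] <- classify_process(res$bnti[ok], res$rc_bray[ok], thresholds)
  list(pairs = res, fractions = process_fractions(res))
}
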