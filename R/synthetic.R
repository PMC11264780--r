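# Synthetic study generator: Yule tree, Brownian traits, communities
# assembled under known regimes (selection / dispersal limitation / drift),
# and farm-level metadata with coordinates and soil chemistry. Gives every
# pipeline stage a fully seeded input with ground-truth process labels.

#' Simulate a Yule (pure-birth) phylogeny
#'
#' Exponential waiting times between speciations, rescaled to unit
#' root-to-tip depth (ultrametric). Leaves are labelled `T0001`, `T0002`, ...
#'
#' @param n_taxa number of leaves (>= 2).
#' @param seed RNG seed.
#' @return `phylo` tree.
#' @export
simulate_tree <- function(n_taxa, seed = 1) {
  if (n_taxa < 2) ea_stop("n_taxa must be >= 2")
  tree <- with_seed(seed, ape::rphylo(n_taxa, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("T%04d", seq_len(n_taxa))
  tree
}

#' Simulate Brownian traits on a tree
#'
#' Root value 0; along each branch the trait changes by
#' Normal(0, sigma^2 x branch length). Provides the phylogenetic signal
#' that makes betaNTI informative about selection.
#'
#' @param tree `phylo` tree.
#' @param sigma Brownian rate (trait sd per unit branch length), > 0.
#' @param seed RNG seed.
#' @return named numeric vector of tip trait values.
#' @export
simulate_traits <- function(tree, sigma = 1, seed = 1) {
  if (sigma <= 0) ea_stop("sigma must be > 0")
  with_seed(seed, ape::rTraitCont(tree, model = "BM", sigma = sigma,
                                  root.value = 0))
}

#' Draw a farm-local taxon pool
#'
#' Subsamples a uniform fraction `m` of the metacommunity's taxa to act as
#' the farm's dispersal-limited species pool (shared by all of the farm's
#' samples). The draw is uniform over taxa, so two farms' pools overlap by
#' an expected fraction `m` of each other and differ even in their abundant
#' members — the signature dispersal limitation leaves in composition.
#'
#' @param pool_rel metacommunity relative abundances (named).
#' @param m fraction of taxa retained, in (0, 1].
#' @param seed RNG seed.
#' @return integer indices of the retained taxa.
#' @export
draw_local_pool <- function(pool_rel, m, seed = 1) {
  stopifnot(m > 0, m <= 1)
  size <- max(2L, round(m * length(pool_rel)))
  with_seed(seed, sample.int(length(pool_rel), size))
}

#' Self-consistent neutral-assembly statistics
#'
#' The neutral ("drift") regime assembles each sample by random placement:
#' draw the sample's richness, place that many taxa with probability
#' proportional to an occupancy vector `q`, then distribute the remaining
#' reads multinomially with probability proportional to a fill vector,
#' one read per placed taxon guaranteed. For the regime to represent pure
#' drift, `q` and the fill must be a fixed point of the recipe: the
#' statistics measured on assembled communities must equal the statistics
#' used to assemble them. This function finds that fixed point by
#' iterating "assemble a calibration cohort, re-measure occupancy and mean
#' abundance" a few times, starting from the binomial expectation
#' `q = 1 - (1 - p)^depth`.
#'
#' @param pool_rel metacommunity relative abundances.
#' @param depth reads per calibration sample.
#' @param n_iter fixed-point iterations (default 4).
#' @param n_cal calibration samples per iteration (default 60).
#' @param seed RNG seed.
#' @return list with `q` (occupancy) and `fill` (abundance weights).
#' @export
neutral_placement_stats <- function(pool_rel, depth, n_iter = 4, n_cal = 60,
                                    seed = 1) {
  n <- length(pool_rel)
  q <- 1 - (1 - pool_rel / sum(pool_rel))^depth
  fill <- pool_rel / sum(pool_rel)
  with_seed(seed, for (it in seq_len(n_iter)) {
    cal <- vapply(seq_len(n_cal), function(j)
      place_neutral_sample(depth, q, fill), integer(n))
    q <- pmax(rowMeans(cal > 0), 1e-6)
    fill <- rowSums(cal) / sum(cal)
  })
  list(q = q, fill = fill)
}

# One random-placement draw: richness ~ Binomial around the expected
# occupancy total, identities weighted by q, abundances by fill (min 1).
place_neutral_sample <- function(depth, q, fill) {
  n <- length(q)
  S <- max(1L, min(n, depth, rbinom(1, n, sum(q) / n)))
  idx <- order(rexp(n) / q)[seq_len(S)]  # weighted draw via exponential keys
  x <- integer(n)
  x[idx] <- 1L
  if (depth > S) {
    fw <- fill[idx]
    if (sum(fw) <= 0) fw <- rep(1, S)
    x[idx] <- x[idx] + as.integer(rmultinom(1, depth - S, fw))
  }
  x
}

#' Assemble one community under a known regime
#'
#' Sampling weights over the metacommunity pool:
#' selection — `pool_i * exp(-(trait_i - env)^2 / (2 sigma_sel^2))`
#' (Gaussian environmental filtering toward the trait optimum `env`);
#' drift — the pool itself (neutral); dispersal_limitation — neutral
#' within the farm-local pool given by `local_pool`. `depth` reads are
#' drawn multinomially from the weights.
#'
#' Selection regimes multiply Gaussian environmental filtering into the
#' pool weights together with a per-sample competitive-lottery term
#' `exp(Normal(0, lottery_sd^2))`, so samples under the same filter share
#' the suitable clade but differ in which of its members dominate. The
#' drift regime is self-consistent random placement (see
#' [neutral_placement_stats()]): identities as well as abundances turn
#' over stochastically between samples, as they do under genuine
#' ecological drift. Dispersal limitation confines a neutral multinomial
#' draw to the farm's local pool.
#'
#' @param regime `"selection"`, `"drift"` or `"dispersal_limitation"`.
#' @param env environmental optimum, trait units (selection only).
#' @param pool_rel metacommunity relative abundances (named by taxon).
#' @param traits named trait vector (selection only).
#' @param depth total reads to draw (>= 1).
#' @param selection_strength sigma_sel, trait units (selection only).
#' @param lottery_sd sd of the per-sample log-normal lottery term
#'   (selection only; 0 disables).
#' @param local_pool indices from [draw_local_pool()]
#'   (dispersal_limitation only).
#' @param placement_stats output of [neutral_placement_stats()] (drift
#'   only; computed on the fly if missing).
#' @param seed RNG seed.
#' @return named integer count vector over all pool taxa, summing to
#'   `depth`.
#' @export
assemble_community <- function(regime, env = 0, pool_rel, traits = NULL,
                               depth = 5000, selection_strength = 1,
                               lottery_sd = 1, local_pool = NULL,
                               placement_stats = NULL, seed = 1) {
  stopifnot(depth >= 1)
  if (regime == "drift") {
    if (is.null(placement_stats))
      placement_stats <- neutral_placement_stats(pool_rel, depth, seed = seed)
    counts <- with_seed(seed, place_neutral_sample(
      depth, placement_stats$q, placement_stats$fill))
    names(counts) <- names(pool_rel)
    return(counts)
  }
  w <- switch(regime,
    selection = {
      stopifnot(!is.null(traits), selection_strength > 0)
      base <- pool_rel * exp(-(traits - env)^2 / (2 * selection_strength^2))
      if (lottery_sd > 0)
        base <- base * exp(with_seed(seed + 1L,
          rnorm(length(base), 0, lottery_sd)))
      base
    },
    dispersal_limitation = {
      if (is.null(local_pool)) ea_stop("dispersal_limitation needs local_pool")
      w0 <- numeric(length(pool_rel))
      w0[local_pool] <- pool_rel[local_pool]
      w0
    },
    ea_stop("unknown regime: ", regime))
  if (sum(w) <= 0) ea_stop("empty effective pool")
  counts <- with_seed(seed, as.integer(rmultinom(1, depth, w)))
  names(counts) <- names(pool_rel)
  counts
}

#' Synthetic study scenario
#'
#' Defaults emulate the design of a 13-farm organic strawberry survey in
#' south-east Poland: four niches (bulk soil, rhizosphere soil, root,
#' shoot), farms split healthy/unhealthy (7/6), farm coordinates jittered
#' within half a degree of 50N 23E, soil chemistry tied to the latent
#' environmental axis, and sequencing depths around 5000 reads.
#'
#' The metacommunity is much richer than any one sample (default 1000 taxa
#' against a few hundred reads' worth of realized richness), mirroring
#' amplicon surveys where tens of thousands of ASVs stand behind each
#' sample. Selection optima sit symmetrically in the two tails of the
#' trait distribution (healthy at `-env_health_shift/2`, unhealthy at
#' `+env_health_shift/2`, in units of the realized trait sd), so each
#' health status filters a deep clade and the statuses diverge.
#'
#' @param n_taxa metacommunity richness (default 1000).
#' @param n_farms number of farms (default 13).
#' @param niches niches to simulate (default all four).
#' @param samples_per_group samples per niche x health group (default 20).
#' @param regime `"selection"`, `"drift"`, `"dispersal_limitation"`, or
#'   `"mixed"` (healthy groups under selection, unhealthy under drift); or
#'   a named vector `niche:health -> regime`.
#' @param trait_sigma Brownian rate for traits (default 1).
#' @param selection_strength sigma_sel in trait units; `NULL` (default)
#'   means 0.2 x the realized trait sd (strong filtering).
#' @param lottery_sd per-sample lottery sd for selection regimes
#'   (default 1).
#' @param m dispersal-limitation local-pool fraction (default 0.2).
#' @param depth_mean mean sequencing depth (default 5000, lognormal
#'   variation).
#' @param env_health_shift separation of the two health-status optima in
#'   trait-sd units (default 3).
#' @param seed RNG seed.
#' @return list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_taxa = 1000, n_farms = 13,
                               niches = niche_levels, samples_per_group = 20,
                               regime = "mixed", trait_sigma = 1,
                               selection_strength = NULL, lottery_sd = 1,
                               m = 0.2, depth_mean = 5000,
                               env_health_shift = 3, seed = 1) {
  stopifnot(n_taxa >= 2, n_farms >= 1, samples_per_group >= 1,
            m > 0, m <= 1, depth_mean >= 1)
  structure(list(n_taxa = n_taxa, n_farms = n_farms, niches = niches,
                 samples_per_group = samples_per_group, regime = regime,
                 trait_sigma = trait_sigma,
                 selection_strength = selection_strength,
                 lottery_sd = lottery_sd, m = m,
                 depth_mean = depth_mean, env_health_shift = env_health_shift,
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

# Phylum labels from the tree's deep structure: average-linkage clusters of
# patristic distance, so related taxa share a phylum.
synthetic_taxonomy <- function(tree, n_phyla = 8) {
  d <- patristic_distances(tree)
  k <- min(n_phyla, nrow(d))
  cl <- stats::cutree(stats::hclust(stats::as.dist(d), method = "average"), k = k)
  setNames(lapply(cl, function(g)
    c("Bacteria", sprintf("Phylum_%02d", g))), names(cl))
}

#' Generate a complete synthetic study
#'
#' Tree, traits, farm environments and chemistry, and communities for every
#' niche x health group under the scenario's regime, with ground truth.
#'
#' @param scenario a [synthetic_scenario()].
#' @return list with `table` (counts), `tree`, `meta`, `taxonomy`, and
#'   `truth` (regime per group, traits, farm environments, local pools).
#' @export
generate_dataset <- function(scenario) {
  sc <- scenario
  tree <- simulate_tree(sc$n_taxa, sc$seed)
  traits <- simulate_traits(tree, sc$trait_sigma, sc$seed + 1L)
  sel_sigma <- if (is.null(sc$selection_strength))
    0.2 * sd(traits) else sc$selection_strength
  taxonomy <- synthetic_taxonomy(tree)

  farms <- sprintf("F%02d", seq_len(sc$n_farms))
  farm_health <- ifelse(seq_len(sc$n_farms) %% 2 == 1, "healthy", "unhealthy")
  groups <- expand.grid(niche = sc$niches, health = health_levels,
                        stringsAsFactors = FALSE)
  group_name <- function(niche, health) paste(niche, health, sep = ":")
  regimes <- setNames(rep(NA_character_, nrow(groups)),
                      group_name(groups$niche, groups$health))
  for (i in seq_len(nrow(groups))) {
    g <- names(regimes)[i]
    regimes[i] <- if (length(sc$regime) > 1 || !is.null(names(sc$regime))) {
      if (!g %in% names(sc$regime)) ea_stop("no regime for group ", g)
      sc$regime[[g]]
    } else if (sc$regime == "mixed") {
      if (groups$health[i] == "healthy") "selection" else "drift"
    } else sc$regime
  }

  with_seed(sc$seed + 2L, {
    pool_rel <- rlnorm(sc$n_taxa, 0, 1)
    pool_rel <- setNames(pool_rel / sum(pool_rel), tree$tip.label)
    lat <- 50 + runif(sc$n_farms, -0.5, 0.5)
    lon <- 23 + runif(sc$n_farms, -0.5, 0.5)
    # env is the group-level trait optimum: shared by every farm of a
    # health status, placed in opposite tails of the trait distribution so
    # each status filters a deep clade and the statuses diverge.
    half <- sc$env_health_shift / 2 * sd(traits)
    env_farm <- ifelse(farm_health == "healthy", -half, half)
    chem <- data.frame(
      farm_id = farms,
      pH = 6.5 + 0.4 * env_farm + rnorm(sc$n_farms, 0, 0.3),
      P2O5 = exp(rnorm(sc$n_farms, log(15), 0.3)),
      Mg = 8 + 1.5 * env_farm + rnorm(sc$n_farms, 0, 0.3),
      K2O = exp(rnorm(sc$n_farms, log(20), 0.3)),
      organic_carbon = exp(rnorm(sc$n_farms, log(1.8), 0.25)),
      stringsAsFactors = FALSE)
    local_pools <- lapply(seq_len(sc$n_farms), function(f)
      draw_local_pool(pool_rel, sc$m, sample.int(2^30, 1)))
    names(local_pools) <- farms
    placement <- if (any(regimes == "drift"))
      neutral_placement_stats(pool_rel, sc$depth_mean,
                              seed = sample.int(2^30, 1)) else NULL

    meta_rows <- list(); count_cols <- list()
    sid <- 0L
    for (i in seq_len(nrow(groups))) {
      nh <- groups$niche[i]; hl <- groups$health[i]
      g <- group_name(nh, hl)
      farm_idx <- which(farm_health == hl)
      if (!length(farm_idx)) next
      farm_seq <- rep(farm_idx, length.out = sc$samples_per_group)
      for (f in farm_seq) {
        sid <- sid + 1L
        sample_id <- sprintf("S%03d", sid)
        depth <- max(100L, as.integer(round(rlnorm(1, log(sc$depth_mean) -
                                                      0.3^2 / 2, 0.3))))
        counts <- assemble_community(
          regime = regimes[g], env = env_farm[f], pool_rel = pool_rel,
          traits = traits, depth = depth, selection_strength = sel_sigma,
          lottery_sd = sc$lottery_sd, local_pool = local_pools[[f]],
          placement_stats = placement, seed = sample.int(2^30, 1))
        count_cols[[sample_id]] <- counts
        meta_rows[[sample_id]] <- data.frame(
          sample_id = sample_id, farm_id = farms[f], niche = nh, health = hl,
          latitude = lat[f], longitude = lon[f],
          pH = chem$pH[f], P2O5 = chem$P2O5[f], Mg = chem$Mg[f],
          K2O = chem$K2O[f], organic_carbon = chem$organic_carbon[f],
          stringsAsFactors = FALSE)
      }
    }
    table <- do.call(cbind, count_cols)
    storage.mode(table) <- "integer"
    rownames(table) <- tree$tip.label
    meta <- do.call(rbind, meta_rows)
    rownames(meta) <- NULL
    validate_count_table(table)
    validate_metadata(meta)
    list(table = table, tree = tree, meta = meta, taxonomy = taxonomy,
         truth = list(regimes = regimes, traits = traits,
                      env_farm = setNames(env_farm, farms),
                      selection_strength = sel_sigma,
                      pool_rel = pool_rel, local_pools = local_pools))
  })
}

#' Write a generated dataset to plain-text files
#'
#' Counts TSV (QIIME2 flat dialect), newick tree, metadata TSV, taxonomy
#' TSV, and a ground-truth JSON.
#'
#' @param dataset output of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             tree = file.path(dir, "tree.nwk"),
             meta = file.path(dir, "metadata.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             truth = file.path(dir, "truth.json"))
  write_count_table(dataset$table, paths["counts"])
  ape::write.tree(dataset$tree, paths["tree"])
  write_metadata(dataset$meta, paths["meta"])
  tax_df <- data.frame(taxon_id = names(dataset$taxonomy),
                       lineage = vapply(dataset$taxonomy, paste,
                                        "", collapse = ";"),
                       stringsAsFactors = FALSE)
  write.table(tax_df, paths["taxonomy"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(regimes = as.list(dataset$truth$regimes),
                            selection_strength = dataset$truth$selection_strength,
                            env_farm = as.list(dataset$truth$env_farm)),
                       paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
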