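# Alpha diversity (effective number of species / Hill numbers) with
# repeated rarefaction, community distance matrices (Bray-Curtis, weighted
# UniFrac), PCoA, and the permutation tests used on them.

#' Convert counts to relative abundances
#'
#' Each sample (column) is divided by its total. All-zero columns are left
#' at zero and recorded in the `"zero_samples"` attribute.
#'
#' @param table count matrix (taxa rows) or any non-negative matrix.
#' @return matrix of proportions with the same dimnames.
#' @export
to_relative <- function(table) {
  totals <- colSums(table)
  zero <- totals == 0
  totals[zero] <- 1
  rel <- sweep(table, 2, totals, "/")
  attr(rel, "zero_samples") <- colnames(table)[zero]
  rel
}

#' Repeated rarefaction
#'
#' Subsamples every retained sample to exactly `depth` reads without
#' replacement, `n_draws` independent times. Samples whose total is below
#' `depth` are dropped and reported in the `"dropped_samples"` attribute.
#'
#' @param table count matrix (taxa rows).
#' @param depth target reads per sample.
#' @param n_draws number of independent rarefaction draws.
#' @param seed RNG seed; identical seed gives identical draws.
#' @return list of `n_draws` rarefied count matrices.
#' @export
rarefy <- function(table, depth, n_draws = 100, seed = 1) {
  stopifnot(depth >= 1, n_draws >= 1)
  totals <- colSums(table)
  keep <- totals >= depth
  if (!any(keep))
    ea_stop("rarefaction depth ", depth, " exceeds every sample total")
  dropped <- colnames(table)[!keep]
  if (length(dropped))
    message("rarefy: dropping ", length(dropped),
            " sample(s) below depth ", depth)
  tab <- table[, keep, drop = FALSE]
  draws <- with_seed(seed, lapply(seq_len(n_draws), function(i) {
    r <- withCallingHandlers(
      t(vegan::rrarefy(t(tab), depth)),
      # rrarefy's advisory about count granularity; depth contract is ours
      warning = function(w) if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning"))
    storage.mode(r) <- "integer"
    r
  }))
  attr(draws, "dropped_samples") <- dropped
  attr(draws, "depth") <- depth
  draws
}

#' Effective number of species of one sample
#'
#' Hill-number style diversity from a vector of proportions. Modes:
#' `inverse_simpson` (Hill order 2, the default), `exp_shannon` (Hill order
#' 1), and `exp_simpson_literal` = exp(1 - sum p^2), the exponential applied
#' directly to the Gini-Simpson index. The literal mode is bounded above by
#' e and cannot reach the species count for uniform communities; it is kept
#' only for comparability and flagged by its name.
#'
#' @param proportions numeric vector summing to 1 (non-negative).
#' @param mode one of `"inverse_simpson"`, `"exp_shannon"`,
#'   `"exp_simpson_literal"`.
#' @return positive scalar.
#' @export
ens <- function(proportions,
                mode = c("inverse_simpson", "exp_shannon", "exp_simpson_literal")) {
  mode <- match.arg(mode)
  p <- proportions[proportions > 0]
  if (!length(p)) ea_stop("ens: all-zero abundance vector")
  if (abs(sum(proportions) - 1) > 1e-6)
    ea_stop("ens: proportions do not sum to 1")
  switch(mode,
    inverse_simpson = 1 / sum(p^2),
    exp_shannon = exp(-sum(p * log(p))),
    exp_simpson_literal = exp(1 - sum(p^2)))
}

#' Per-sample ENS with optional repeated rarefaction
#'
#' With `depth = NULL` the ENS is computed on the raw relative abundances.
#' With a depth, ENS is computed on each of `n_draws` rarefaction draws and
#' averaged per sample; samples below the depth are dropped.
#'
#' @inheritParams rarefy
#' @inheritParams ens
#' @return data.frame with columns `sample_id`, `ens`, `mode`,
#'   `rarefaction_depth`, `n_rarefactions`.
#' @export
alpha_diversity <- function(table, mode = "inverse_simpson",
                            depth = NULL, n_draws = 100, seed = 1) {
  if (is.null(depth)) {
    rel <- to_relative(table)
    vals <- apply(rel, 2, ens, mode = mode)
    out <- data.frame(sample_id = colnames(table), ens = as.numeric(vals),
                      mode = mode, rarefaction_depth = NA_integer_,
                      n_rarefactions = 0L, stringsAsFactors = FALSE)
  } else {
    draws <- rarefy(table, depth, n_draws, seed)
    per_draw <- vapply(draws, function(d) apply(to_relative(d), 2, ens, mode = mode),
                       numeric(ncol(draws[[1]])))
    per_draw <- matrix(per_draw, ncol = length(draws))
    out <- data.frame(sample_id = colnames(draws[[1]]),
                      ens = rowMeans(per_draw), mode = mode,
                      rarefaction_depth = as.integer(depth),
                      n_rarefactions = as.integer(n_draws),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i), computed over samples
#' (columns). Works on counts or relative abundances.
#'
#' @param table taxa x samples matrix with at least two samples.
#' @return symmetric distance matrix over samples.
#' @export
bray_curtis_matrix <- function(table) {
  if (ncol(table) < 2) ea_stop("need at least 2 samples")
  zero <- colnames(table)[colSums(table) == 0]
  if (length(zero) >= 2)
    ea_stop("Bray-Curtis undefined for all-zero sample pair: ",
            zero[1], ", ", zero[2])
  d <- vegan::vegdist(t(table), method = "bray")
  validate_distance_matrix(dist_to_matrix(d))
  dist_to_matrix(d)
}

#' Weighted UniFrac distance matrix
#'
#' Raw form: sum over branches of branch length times the absolute
#' difference in the proportion of each sample's reads descending from the
#' branch. Normalized form divides by the abundance-weighted total branch
#' length, giving values in \[0, 1\].
#'
#' @param table count matrix (taxa rows); every taxon must be a tree leaf.
#' @param tree rooted `phylo` tree with branch lengths.
#' @param normalized divide by the weighted tree depth (default `FALSE`).
#' @return symmetric distance matrix over samples.
#' @export
weighted_unifrac_matrix <- function(table, tree, normalized = FALSE) {
  missing_taxa <- setdiff(rownames(table), tree$tip.label)
  if (length(missing_taxa))
    ea_stop("taxa absent from tree: ", paste(missing_taxa, collapse = ", "),
            class = "ecoassembly_mismatch_error")
  tr <- ape::keep.tip(tree, rownames(table))
  rel <- to_relative(table)[tr$tip.label, , drop = FALSE]
  n_tip <- length(tr$tip.label)
  n_samp <- ncol(rel)
  # proportion of each sample's reads descending from every node, by
  # postorder accumulation over the edge matrix
  nodep <- matrix(0, n_tip + tr$Nnode, n_samp)
  nodep[seq_len(n_tip), ] <- rel
  edges <- ape::reorder.phylo(tr, "postorder")$edge
  lens <- ape::reorder.phylo(tr, "postorder")$edge.length
  for (e in seq_len(nrow(edges)))
    nodep[edges[e, 1], ] <- nodep[edges[e, 1], ] + nodep[edges[e, 2], ]
  branchp <- nodep[edges[, 2], , drop = FALSE]
  m <- matrix(0, n_samp, n_samp,
              dimnames = list(colnames(rel), colnames(rel)))
  for (a in seq_len(n_samp - 1)) {
    for (b in (a + 1):n_samp) {
      num <- sum(lens * abs(branchp[, a] - branchp[, b]))
      if (normalized) {
        den <- sum(lens * (branchp[, a] + branchp[, b]))
        num <- if (den > 0) num / den else 0
      }
      m[a, b] <- m[b, a] <- num
    }
  }
  validate_distance_matrix(m)
  m
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a distance matrix via eigendecomposition of
#' the double-centred Gram matrix. Negative eigenvalues are reported and
#' excluded from the explained-variance denominator.
#'
#' @param d validated distance matrix.
#' @param k number of axes to retain (clipped to n - 1 with a warning).
#' @return list with `coordinates` (samples x axes), `explained`
#'   (proportion of positive-eigenvalue variance per retained axis),
#'   `eigenvalues`, `n_negative_eigenvalues`, and `degenerate` (all
#'   eigenvalues ~ 0).
#' @export
pcoa <- function(d, k = 2) {
  validate_distance_matrix(d)
  n <- nrow(d)
  if (k > n - 1) {
    ea_warn("k clipped from ", k, " to ", n - 1)
    k <- n - 1
  }
  fit <- suppressWarnings(cmdscale(as_dist_obj(d), k = k, eig = TRUE))
  eig <- fit$eig
  pos <- sum(eig[eig > 1e-12])
  degenerate <- pos <= 1e-12
  coords <- fit$points
  if (degenerate) {
    coords <- matrix(0, n, k, dimnames = list(rownames(d), NULL))
    explained <- rep(NA_real_, k)
  } else {
    if (ncol(coords) < k) {  # cmdscale drops axes with non-positive eigenvalues
      pad <- matrix(0, n, k - ncol(coords))
      coords <- cbind(coords, pad)
    }
    explained <- pmax(eig[seq_len(k)], 0) / pos
  }
  colnames(coords) <- paste0("PCo", seq_len(k))
  list(coordinates = coords, explained = explained, eigenvalues = eig,
       n_negative_eigenvalues = sum(eig < -1e-12), degenerate = degenerate)
}

# Seeded permutation matrix (rows = permutations of 1..n).
perm_matrix <- function(n, n_permutations, seed) {
  with_seed(seed, t(vapply(seq_len(n_permutations),
                           function(i) sample.int(n), integer(n))))
}

#' PERMANOVA on a distance matrix
#'
#' Single-factor permutational MANOVA: pseudo-F from among/within sums of
#' squared distances, with p = (1 + #\{permuted F >= observed\}) /
#' (1 + n_permutations) under free permutation of sample labels.
#'
#' @param d validated distance matrix.
#' @param labels group label per sample (same order as `d` ids).
#' @param n_permutations number of label permutations (>= 99).
#' @param seed RNG seed for the permutation stream.
#' @param permutations optional explicit permutation matrix (one
#'   permutation of `1:n` per row, e.g. a complete enumeration); overrides
#'   `n_permutations`/`seed`.
#' @return list with `statistic` (pseudo-F), `p_value`, `n_permutations`,
#'   `method`.
#' @export
permanova <- function(d, labels, n_permutations = 999, seed = 1,
                      permutations = NULL) {
  validate_distance_matrix(d)
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) ea_stop("permanova needs >= 2 groups")
  if (is.null(permutations)) stopifnot(n_permutations >= 99)
  stopifnot(length(labels) == nrow(d))
  perms <- if (is.null(permutations))
    perm_matrix(nrow(d), n_permutations, seed) else permutations
  n_permutations <- nrow(perms)
  fit <- vegan::adonis2(as_dist_obj(d) ~ g,
                        data = data.frame(g = labels), permutations = perms)
  list(statistic = fit$F[1], p_value = fit$`Pr(>F)`[1],
       n_permutations = n_permutations, method = "permanova")
}

#' Homogeneity of multivariate dispersions
#'
#' Distance of each sample to its group centroid in PCoA space, tested with
#' an ANOVA F statistic whose null distribution comes from permuting the
#' group labels.
#'
#' @inheritParams permanova
#' @return list with `statistic` (F), `p_value`, `n_permutations`, `method`.
#' @export
dispersion_test <- function(d, labels, n_permutations = 999, seed = 1) {
  validate_distance_matrix(d)
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) ea_stop("dispersion test needs >= 2 groups")
  stopifnot(n_permutations >= 99, length(labels) == nrow(d))
  bd <- vegan::betadisper(as_dist_obj(d), labels)
  perms <- perm_matrix(nrow(d), n_permutations, seed)
  pt <- vegan::permutest(bd, permutations = perms)
  list(statistic = pt$tab$F[1], p_value = pt$tab$`Pr(>F)`[1],
       n_permutations = n_permutations, method = "betadisper")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration for combined n <= 20 (without ties); tie-corrected
#' normal approximation otherwise.
#'
#' @param x,y numeric vectors, each non-empty.
#' @return list with `statistic` (W), `p_value`, `n_permutations` (`NA`),
#'   `method`.
#' @export
rank_sum_test <- function(x, y) {
  if (!length(x) || !length(y)) ea_stop("rank_sum_test: empty group")
  exact <- (length(x) + length(y)) <= 20
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n_permutations = NA_integer_, method = "rank_sum")
}
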