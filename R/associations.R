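# Core-taxon detection, rank aggregation, phylum-chemistry correlations,
# alpha-diversity regressions, and Mantel tests against geographic and
# soil-chemistry distances.

taxonomy_ranks <- c("domain", "phylum", "class", "order", "family",
                    "genus", "species")

#' Core taxa of a sample group
#'
#' A taxon is core when it occurs (count > 0) in at least
#' `prevalence_min` of the group's samples AND its relative abundance
#' meets `abundance_min`. Both comparisons use `>=` so boundary cases
#' (exactly 95% prevalence, exactly 0.1% abundance) qualify. Relative
#' abundances are per sample over the full table. `abundance_scope`
#' decides whether the abundance filter applies to the mean across the
#' group's samples (default) or must hold in every sample where the taxon
#' occurs.
#'
#' @param table count matrix (taxa rows), full community.
#' @param group_samples character vector of sample ids defining the group.
#' @param prevalence_min minimum occupancy fraction (default 0.95).
#' @param abundance_min minimum relative abundance (default 0.001).
#' @param abundance_scope `"mean"` or `"per_sample"`.
#' @return list with `core` (taxon ids), `prevalence_min`, `abundance_min`,
#'   `abundance_scope`, `n_samples`.
#' @export
core_taxa <- function(table, group_samples, prevalence_min = 0.95,
                      abundance_min = 0.001,
                      abundance_scope = c("mean", "per_sample")) {
  abundance_scope <- match.arg(abundance_scope)
  if (!length(group_samples)) ea_stop("core_taxa: empty sample subset")
  missing_s <- setdiff(group_samples, colnames(table))
  if (length(missing_s))
    ea_stop("samples not in table: ", paste(missing_s, collapse = ", "))
  counts <- table[, group_samples, drop = FALSE]
  rel <- to_relative(table)[, group_samples, drop = FALSE]
  prevalence <- rowMeans(counts > 0)
  ab_ok <- if (abundance_scope == "mean") {
    rowMeans(rel) >= abundance_min
  } else {
    apply(rel, 1, function(r) all(r[r > 0] >= abundance_min)) & prevalence > 0
  }
  core <- rownames(table)[prevalence >= prevalence_min & ab_ok]
  list(core = core, prevalence_min = prevalence_min,
       abundance_min = abundance_min, abundance_scope = abundance_scope,
       n_samples = length(group_samples))
}

#' Partition two core-taxon sets into a Venn layout
#'
#' @param core_a,core_b character vectors of taxon ids.
#' @return list with `only_a`, `only_b`, `shared`.
#' @export
venn_partition <- function(core_a, core_b) {
  list(only_a = setdiff(core_a, core_b),
       only_b = setdiff(core_b, core_a),
       shared = intersect(core_a, core_b))
}

#' Aggregate a count table to a taxonomic rank
#'
#' Counts are summed within each value of the requested rank; taxa with no
#' lineage, or a lineage shorter than the rank, go into an `"Unclassified"`
#' row. Column totals are conserved exactly.
#'
#' @param table count matrix (taxa rows).
#' @param taxonomy named list of rank vectors (see [read_taxonomy()]).
#' @param rank one of domain, phylum, class, order, family, genus, species.
#' @return aggregated count matrix (rank values as rows).
#' @export
aggregate_to_rank <- function(table, taxonomy, rank = "phylum") {
  ri <- match(rank, taxonomy_ranks)
  if (is.na(ri)) ea_stop("unknown rank: ", rank)
  labels <- vapply(rownames(table), function(id) {
    lin <- taxonomy[[id]]
    if (is.null(lin) || length(lin) < ri || lin[ri] == "unclassified")
      "Unclassified" else lin[ri]
  }, "")
  out <- rowsum(table, group = labels)
  storage.mode(out) <- storage.mode(table)
  out
}

#' Spearman correlations of phylum abundances with soil chemistry
#'
#' Within each stratum (default niche x health), correlates each taxon row
#' of `rel` (typically phylum-level relative abundances) with each
#' chemistry variable across samples, using midrank-tie Spearman rho and a
#' two-sided p. p-values are Benjamini-Hochberg adjusted within each
#' stratum across all phylum x chemistry tests. Pairs with missing
#' chemistry are dropped pairwise; tests with fewer than `min_n` complete
#' pairs, or a constant vector, yield `NA` and are flagged.
#'
#' @param rel relative-abundance matrix (rows = phyla, columns = samples).
#' @param meta metadata with sample_id, grouping columns and chemistry.
#' @param group_cols metadata columns defining strata.
#' @param variables chemistry variables to test.
#' @param min_n minimum complete pairs per test (default 4).
#' @return data.frame: `group`, `phylum`, `variable`, `rho`, `p`,
#'   `p_adjusted`, `n`, `flag`.
#' @export
spearman_chemistry <- function(rel, meta, group_cols = c("niche", "health"),
                               variables = chemistry_vars, min_n = 4) {
  stopifnot(all(colnames(rel) %in% meta$sample_id))
  meta <- meta[match(colnames(rel), meta$sample_id), , drop = FALSE]
  grp <- interaction(meta[group_cols], drop = TRUE, sep = ":")
  rows <- list()
  for (g in levels(grp)) {
    sel <- grp == g
    for (ph in rownames(rel)) {
      for (v in variables) {
        x <- as.numeric(rel[ph, sel]); y <- meta[[v]][sel]
        ok <- !is.na(x) & !is.na(y)
        n <- sum(ok)
        if (n < min_n || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
          rows[[length(rows) + 1L]] <- data.frame(
            group = g, phylum = ph, variable = v, rho = NA_real_,
            p = NA_real_, n = n, flag = if (n < min_n) "too_few" else "constant",
            stringsAsFactors = FALSE)
        } else {
          ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman",
                                          exact = FALSE))
          rows[[length(rows) + 1L]] <- data.frame(
            group = g, phylum = ph, variable = v,
            rho = unname(ct$estimate), p = ct$p.value, n = n, flag = "",
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- NA_real_
  for (g in unique(out$group)) {
    sel <- out$group == g & !is.na(out$p)
    out$p_adjusted[sel] <- p.adjust(out$p[sel], method = "BH")
  }
  out[, c("group", "phylum", "variable", "rho", "p", "p_adjusted", "n", "flag")]
}

#' Regress alpha diversity on soil chemistry
#'
#' Ordinary least squares of per-sample ENS on one chemistry variable at a
#' time, within each stratum. Missing chemistry is dropped pairwise; a fit
#' with zero predictor variance is an error, and strata with fewer than
#' `min_n` complete pairs yield a flagged `NA` row.
#'
#' @param diversity data.frame from [alpha_diversity()] (`sample_id`, `ens`).
#' @param meta metadata with sample_id, grouping columns and chemistry.
#' @param group_cols metadata columns defining strata.
#' @param variables chemistry variables to regress on.
#' @param min_n minimum complete pairs (default 4).
#' @param on_constant `"error"` (default) to fail on a zero-variance
#'   predictor, or `"flag"` to emit an `NA` row (used by the pipeline,
#'   where single-farm strata legitimately have constant chemistry).
#' @return data.frame: `group`, `variable`, `slope`, `intercept`,
#'   `adjusted_r2`, `p`, `n`, `flag`.
#' @export
ens_chemistry_regression <- function(diversity, meta,
                                     group_cols = c("niche", "health"),
                                     variables = chemistry_vars, min_n = 4,
                                     on_constant = c("error", "flag")) {
  on_constant <- match.arg(on_constant)
  meta <- meta[match(diversity$sample_id, meta$sample_id), , drop = FALSE]
  grp <- interaction(meta[group_cols], drop = TRUE, sep = ":")
  rows <- list()
  for (g in levels(grp)) {
    sel <- grp == g
    for (v in variables) {
      y <- diversity$ens[sel]; x <- meta[[v]][sel]
      ok <- !is.na(x) & !is.na(y)
      n <- sum(ok)
      if (n < min_n) {
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, variable = v, slope = NA_real_, intercept = NA_real_,
          adjusted_r2 = NA_real_, p = NA_real_, n = n, flag = "too_few",
          stringsAsFactors = FALSE)
        next
      }
      if (var(x[ok]) == 0) {
        if (on_constant == "error")
          ea_stop("zero predictor variance: ", v, " in ", g)
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, variable = v, slope = NA_real_, intercept = NA_real_,
          adjusted_r2 = NA_real_, p = NA_real_, n = n, flag = "constant",
          stringsAsFactors = FALSE)
        next
      }
      fit <- lm(y[ok] ~ x[ok])
      sm <- summary(fit)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, variable = v, slope = unname(coef(fit)[2]),
        intercept = unname(coef(fit)[1]),
        adjusted_r2 = sm$adj.r.squared,
        p = sm$coefficients[2, 4], n = n, flag = "",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Great-circle distance matrix from coordinates
#'
#' Haversine distance with Earth radius 6371.0 km, in km. At farm level,
#' one unit per farm; at sample level, farm distances are expanded to
#' sample pairs by farm membership (within-farm distance 0).
#'
#' @param meta metadata with `farm_id`, `latitude`, `longitude`
#'   (and `sample_id` for sample level).
#' @param level `"farm"` or `"sample"`.
#' @return symmetric distance matrix in km.
#' @export
geographic_distance_matrix <- function(meta, level = c("farm", "sample")) {
  level <- match.arg(level)
  farms <- unique(meta$farm_id)
  coords <- t(vapply(farms, function(f) {
    sub <- meta[meta$farm_id == f, , drop = FALSE]
    c(lon = sub$longitude[1], lat = sub$latitude[1])
  }, c(lon = 0, lat = 0)))
  if (anyNA(coords)) {
    bad <- farms[apply(is.na(coords), 1, any)]
    ea_stop("missing coordinates for: ", paste(bad, collapse = ", "))
  }
  dm <- geosphere::distm(coords, fun = function(a, b)
    geosphere::distHaversine(a, b, r = 6371000)) / 1000
  dimnames(dm) <- list(farms, farms)
  if (level == "sample") {
    fm <- meta$farm_id
    dm <- dm[fm, fm, drop = FALSE]
    dimnames(dm) <- list(meta$sample_id, meta$sample_id)
  }
  validate_distance_matrix(dm, tol = 1e-6)
  dm
}

#' Euclidean distance matrix on soil chemistry
#'
#' Distances between farms on the listed chemistry variables, after
#' per-variable z-scoring (mean 0, sd 1 across farms) unless
#' `standardize = FALSE`. Farm values are means over the farm's samples.
#'
#' @param meta metadata with `farm_id` (and `sample_id` for sample level)
#'   plus the chemistry columns.
#' @param variables chemistry variables to include.
#' @param standardize z-score each variable first (default `TRUE`).
#' @param level `"farm"` or `"sample"` (expanded by farm membership).
#' @return symmetric distance matrix.
#' @export
chemistry_distance_matrix <- function(meta, variables = chemistry_vars,
                                      standardize = TRUE,
                                      level = c("farm", "sample")) {
  level <- match.arg(level)
  missing_v <- setdiff(variables, names(meta))
  if (length(missing_v))
    ea_stop("missing chemistry column(s): ", paste(missing_v, collapse = ", "))
  farms <- unique(meta$farm_id)
  if (length(farms) < 2) ea_stop("need at least 2 units")
  vals <- do.call(rbind, lapply(farms, function(f)
    colMeans(meta[meta$farm_id == f, variables, drop = FALSE], na.rm = TRUE)))
  if (anyNA(vals) || any(!is.finite(vals))) {
    bad <- farms[apply(!is.finite(vals), 1, any)]
    ea_stop("missing chemistry for: ", paste(bad, collapse = ", "))
  }
  if (standardize) {
    sds <- apply(vals, 2, sd)
    if (any(sds == 0))
      ea_stop("zero-variance chemistry variable: ",
              paste(variables[sds == 0], collapse = ", "))
    vals <- scale(vals)
  }
  dm <- as.matrix(stats::dist(vals))
  dimnames(dm) <- list(farms, farms)
  if (level == "sample") {
    fm <- meta$farm_id
    dm <- dm[fm, fm, drop = FALSE]
    dimnames(dm) <- list(meta$sample_id, meta$sample_id)
  }
  validate_distance_matrix(dm, tol = 1e-6)
  dm
}

#' Mantel test between two distance matrices
#'
#' Correlation of the upper-triangle entries, with a one-sided (greater)
#' permutation p-value from simultaneous row/column permutations of the
#' second matrix: p = (1 + #\{permuted r >= observed\}) /
#' (1 + n_permutations).
#'
#' @param d1,d2 validated distance matrices over the same ids in the same
#'   order.
#' @param method `"pearson"` (default, the distance-decay convention) or
#'   `"spearman"`.
#' @param n_permutations number of permutations (default 999).
#' @param seed RNG seed.
#' @return list with `statistic`, `p_value`, `n_permutations`, `method`.
#' @export
mantel_test <- function(d1, d2, method = c("pearson", "spearman"),
                        n_permutations = 999, seed = 1) {
  method <- match.arg(method)
  validate_distance_matrix(d1, tol = 1e-6)
  validate_distance_matrix(d2, tol = 1e-6)
  if (!identical(rownames(d1), rownames(d2)))
    ea_stop("id mismatch between distance matrices",
            class = "ecoassembly_mismatch_error")
  if (nrow(d1) < 4) ea_stop("mantel test needs n >= 4")
  ut1 <- d1[upper.tri(d1)]; ut2 <- d2[upper.tri(d2)]
  if (sd(ut1) == 0 || sd(ut2) == 0)
    ea_stop("constant distance matrix: Mantel statistic undefined")
  fit <- with_seed(seed, withCallingHandlers(
    vegan::mantel(as_dist_obj(d1), as_dist_obj(d2), method = method,
                  permutations = n_permutations),
    # small n: vegan enumerates all permutations, which makes the test
    # exact; the advisory is not actionable here
    warning = function(w)
      if (grepl("minperm|entire set|complete enumeration", conditionMessage(w)))
        invokeRestart("muffleWarning"),
    message = function(m)
      if (grepl("minperm|entire set|complete enumeration", conditionMessage(m)))
        invokeRestart("muffleMessage")))
  list(statistic = unname(fit$statistic), p_value = fit$signif,
       n_permutations = n_permutations, method = method)
}
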