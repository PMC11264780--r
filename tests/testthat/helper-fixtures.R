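# Fixture builders shared across the suite. Everything is generated in
# code; no data files.

# Small count matrix with named taxa/samples.
tiny_table <- function(values, taxa = NULL, samples = NULL) {
  m <- as.matrix(values)
  storage.mode(m) <- "integer"
  rownames(m) <- taxa %||% paste0("t", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("S", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random count table drawn from a lognormal pool (neutral sampling).
random_table <- function(n_taxa, n_samples, depth, seed) {
  withr::with_seed(seed, {
    pool <- rlnorm(n_taxa)
    pool <- pool / sum(pool)
    tab <- vapply(seq_len(n_samples),
                  function(j) as.integer(rmultinom(1, depth, pool)),
                  integer(n_taxa))
    tiny_table(tab)
  })
}

# Metadata frame covering the required columns for n samples over farms.
tiny_metadata <- function(sample_ids, farm_ids = NULL,
                          niche = "bulk_soil", health = "healthy",
                          lat = NULL, lon = NULL) {
  n <- length(sample_ids)
  farm_ids <- farm_ids %||% paste0("F", seq_len(n))
  data.frame(sample_id = sample_ids, farm_id = farm_ids,
             niche = rep_len(niche, n), health = rep_len(health, n),
             latitude = lat %||% (50 + seq_len(n) / 10),
             longitude = lon %||% (23 + seq_len(n) / 10),
             pH = 6 + seq_len(n) / 10, P2O5 = 10 + seq_len(n),
             Mg = 5 + seq_len(n), K2O = 15 + seq_len(n),
             organic_carbon = 1 + seq_len(n) / 10,
             stringsAsFactors = FALSE)
}

# All permutations of 1..n (for exhaustive enumeration oracles; n <= 7).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1))
  }))
}

# Independent brute-force betaMNTD: plain double loop over taxa, no
# sharing with the package's engine.
oracle_bmntd <- function(x, y, D, weighted) {
  ix <- which(x > 0); iy <- which(y > 0)
  fx <- unname(x[ix] / sum(x[ix])); fy <- unname(y[iy] / sum(y[iy]))
  if (!weighted) { fx <- rep(1 / length(ix), length(ix))
                   fy <- rep(1 / length(iy), length(iy)) }
  sx <- 0
  for (k in seq_along(ix)) sx <- sx + fx[k] * min(D[ix[k], iy])
  sy <- 0
  for (k in seq_along(iy)) sy <- sy + fy[k] * min(D[iy[k], ix])
  0.5 * (sx + sy)
}

# Brute-force single-factor PERMANOVA pseudo-F from a distance matrix.
oracle_pseudo_f <- function(d, labels) {
  n <- nrow(d)
  k <- length(unique(labels))
  ss_total <- sum(d[upper.tri(d)]^2) / n
  ss_within <- sum(vapply(unique(labels), function(g) {
    idx <- which(labels == g)
    dg <- d[idx, idx, drop = FALSE]
    sum(dg[upper.tri(dg)]^2) / length(idx)
  }, 0))
  ((ss_total - ss_within) / (k - 1)) / (ss_within / (n - k))
}
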