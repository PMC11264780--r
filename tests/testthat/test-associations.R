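# Core taxa, rank aggregation, correlations, regressions, Mantel tests.

test_that("core taxa obey the joint prevalence/abundance rule with >= boundaries", {
  # 20 samples; taxon "edge" present in exactly 19 (95%) at 0.1% mean
  n <- 20
  tab <- matrix(0L, 3, n, dimnames = list(c("common", "edge", "rare"),
                                          paste0("S", 1:n)))
  tab["common", ] <- 989L
  tab["edge", 1:19] <- 1L
  tab["common", 20] <- 990L          # keep totals at 990 everywhere
  tab["rare", ] <- 1L                # 100% prevalence, 0.1% abundance
  # totals: 990+1(rare)+edge -> adjust common so each column sums to 1000
  tab["common", ] <- 1000L - tab["edge", ] - tab["rare", ]
  res <- core_taxa(tab, colnames(tab))
  expect_true("common" %in% res$core)
  # edge: prevalence 19/20 = 0.95, mean abundance 19/20 * 1/1000 -> below
  # 0.1%; raise its counts so the mean is exactly 0.1%
  tab2 <- tab
  tab2["edge", 1:19] <- 0L
  tab2["edge", 1:19] <- 1L
  tab2["edge", 1] <- 2L              # mean = 20/20000 = 0.1% exactly
  tab2["common", ] <- 1000L - tab2["edge", ] - tab2["rare", ]
  res2 <- core_taxa(tab2, colnames(tab2))
  expect_true("edge" %in% res2$core)
  expect_true("rare" %in% res2$core) # 100% prevalence at exactly 0.1%

  # abundance filter alone excludes a ubiquitous but scarce taxon
  tab3 <- tab2
  tab3["rare", ] <- 0L
  tab3["rare", seq(1, n, 2)] <- 1L   # 50% prevalence
  tab3["common", ] <- 1000L - tab3["edge", ] - tab3["rare", ]
  expect_false("rare" %in% core_taxa(tab3, colnames(tab3))$core)
  expect_error(core_taxa(tab, character(0)), "empty")
})

test_that("core taxa are monotone in both thresholds", {
  tab <- random_table(30, 12, 500, seed = 17)
  base <- core_taxa(tab, colnames(tab), 0.5, 0.0005)$core
  for (pm in c(0.6, 0.8, 1)) {
    expect_true(all(core_taxa(tab, colnames(tab), pm, 0.0005)$core %in% base))
  }
  for (am in c(0.001, 0.01)) {
    expect_true(all(core_taxa(tab, colnames(tab), 0.5, am)$core %in% base))
  }
})

test_that("venn partition splits core sets correctly", {
  v <- venn_partition(c("x", "y", "z"), c("y", "z", "w"))
  expect_equal(v$only_a, "x")
  expect_equal(v$only_b, "w")
  expect_setequal(v$shared, c("y", "z"))
  v2 <- venn_partition(c("a", "b"), c("a", "b"))
  expect_equal(length(v2$only_a), 0)
  expect_equal(length(unlist(venn_partition(c("a"), c("b"))["shared"])), 0)
})

test_that("rank aggregation conserves column totals and buckets unknowns", {
  tab <- tiny_table(rbind(c(3L, 1L), c(4L, 2L), c(5L, 9L)))
  tax <- list(t1 = c("Bacteria", "Proteobacteria"),
              t2 = c("Bacteria", "Proteobacteria"),
              t3 = c("Bacteria"))
  agg <- aggregate_to_rank(tab, tax, "phylum")
  expect_equal(colSums(agg), colSums(tab))
  expect_equal(unname(agg["Proteobacteria", ]), c(7, 3))
  expect_equal(unname(agg["Unclassified", ]), c(5, 9))
  expect_error(aggregate_to_rank(tab, tax, "cohort"), "unknown rank")
})

test_that("Spearman correlations match a rank-based oracle and BH is monotone", {
  x <- c(1, 2, 3, 4, 5); y <- c(5, 6, 7, 8, 7)
  rel <- matrix(x / sum(x), 1, 5,
                dimnames = list("PhylumA", paste0("S", 1:5)))
  # build metadata whose pH column is y
  meta <- tiny_metadata(paste0("S", 1:5), farm_ids = paste0("F", 1:5))
  meta$pH <- y
  out <- spearman_chemistry(rel, meta, group_cols = "niche",
                            variables = "pH")
  expect_equal(out$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_equal(out$n, 5)

  # perfectly monotone pair
  meta$pH <- c(2, 4, 8, 16, 32)
  expect_equal(spearman_chemistry(rel, meta, group_cols = "niche",
                                  variables = "pH")$rho, 1)

  # BH adjustment is monotone in raw p within the family
  rel2 <- random_table(6, 10, 400, seed = 23)
  rel2 <- to_relative(rel2)
  rownames(rel2) <- paste0("Ph", 1:6)
  meta2 <- tiny_metadata(colnames(rel2), farm_ids = paste0("F", 1:10))
  withr::with_seed(4, for (v in c("pH", "P2O5", "Mg", "K2O", "organic_carbon"))
    meta2[[v]] <- rnorm(10))
  out2 <- spearman_chemistry(rel2, meta2, group_cols = "niche")
  ok <- !is.na(out2$p)
  o <- order(out2$p[ok])
  expect_true(all(diff(out2$p_adjusted[ok][o]) >= -1e-12))
  expect_true(all(out2$p_adjusted[ok] >= out2$p[ok] - 1e-12))
})

test_that("ENS-chemistry regression matches lm and flags degenerate inputs", {
  div <- data.frame(sample_id = paste0("S", 1:8),
                    ens = c(2, 4, 6, 8, 10, 12, 14, 16))
  meta <- tiny_metadata(paste0("S", 1:8), farm_ids = paste0("F", 1:8))
  meta$pH <- 1:8                      # exact linear relation
  out <- suppressWarnings(  # exact fit: lm flags the perfect residuals
    ens_chemistry_regression(div, meta, group_cols = "niche",
                             variables = "pH"))
  expect_equal(out$adjusted_r2, 1, tolerance = 1e-9)
  expect_equal(out$slope, 2, tolerance = 1e-9)
  expect_lt(out$p, 1e-10)

  # duplicating every row keeps the slope and shrinks the p-value
  div2 <- rbind(div, transform(div, sample_id = paste0(sample_id, "b")))
  meta2 <- rbind(meta, transform(meta, sample_id = paste0(sample_id, "b")))
  meta2$pH <- rep(1:8, 2)
  withr::with_seed(2, {
    div$ens <- div$ens + rnorm(8)
    div2$ens <- c(div$ens, div$ens)
  })
  fit1 <- ens_chemistry_regression(div, meta, group_cols = "niche",
                                   variables = "pH")
  fit2 <- ens_chemistry_regression(div2, meta2, group_cols = "niche",
                                   variables = "pH")
  expect_equal(fit1$slope, fit2$slope, tolerance = 1e-9)
  expect_lt(fit2$p, fit1$p)

  meta$pH <- rep(3, 8)
  expect_error(ens_chemistry_regression(div, meta, group_cols = "niche",
                                        variables = "pH"), "variance")
  flagged <- ens_chemistry_regression(div, meta, group_cols = "niche",
                                      variables = "pH", on_constant = "flag")
  expect_equal(flagged$flag, "constant")
  expect_true(is.na(flagged$slope))
})

test_that("geographic distances use the haversine on a 6371 km sphere", {
  meta <- tiny_metadata(c("S1", "S2"), farm_ids = c("F1", "F2"),
                        lat = c(50, 51), lon = c(23, 23))
  d <- geographic_distance_matrix(meta, level = "farm")
  expect_equal(d["F1", "F2"], 111.19, tolerance = 0.01)
  meta2 <- tiny_metadata(c("S1", "S2"), farm_ids = c("F1", "F1"),
                         lat = c(50, 50), lon = c(23, 23))
  expect_equal(max(geographic_distance_matrix(meta2, level = "sample")), 0)
  # metric properties on random coordinates
  meta3 <- tiny_metadata(paste0("S", 1:6), farm_ids = paste0("F", 1:6))
  d3 <- geographic_distance_matrix(meta3, level = "farm")
  validate_distance_matrix(d3, tol = 1e-6)
  meta3$latitude[2] <- NA
  expect_error(geographic_distance_matrix(meta3), "F2")
})

test_that("chemistry distances z-score variables and catch degenerate input", {
  meta <- tiny_metadata(c("S1", "S2"), farm_ids = c("F1", "F2"))
  meta$pH <- c(1, 3)
  d <- chemistry_distance_matrix(meta, variables = "pH", standardize = FALSE)
  expect_equal(d["F1", "F2"], 2)
  dz <- chemistry_distance_matrix(meta, variables = "pH")
  expect_equal(dz["F1", "F2"], sqrt(2), tolerance = 1e-9)  # z-scores +-1/sqrt(2)

  meta$pH <- c(2, 2)
  expect_error(chemistry_distance_matrix(meta, variables = "pH"), "pH")
})

test_that("Mantel statistic hits 1 on identical or rank-equivalent matrices", {
  set.seed(3)
  coords <- matrix(rnorm(12), 6, 2)
  d1 <- as.matrix(dist(coords))
  dimnames(d1) <- list(paste0("S", 1:6), paste0("S", 1:6))
  res <- mantel_test(d1, d1, n_permutations = 99, seed = 1)
  expect_equal(res$statistic, 1, tolerance = 1e-9)
  d2 <- d1^3  # strictly increasing transform
  expect_equal(mantel_test(d1, d2, method = "spearman",
                           n_permutations = 99, seed = 1)$statistic, 1,
               tolerance = 1e-9)
  # invariant to joint reordering of ids
  ord <- c(4, 2, 6, 1, 3, 5)
  res2 <- mantel_test(d1[ord, ord], d2[ord, ord], method = "spearman",
                      n_permutations = 99, seed = 1)
  expect_equal(res2$statistic, 1, tolerance = 1e-9)
  expect_gte(res$p_value, 1 / 100)

  dz <- matrix(1, 6, 6) - diag(6)
  dimnames(dz) <- dimnames(d1)
  expect_error(mantel_test(d1, dz, n_permutations = 99, seed = 1), "constant")
  d3 <- d1[c(2, 1, 3, 4, 5, 6), c(2, 1, 3, 4, 5, 6)]
  expect_error(mantel_test(d1, d3, n_permutations = 99, seed = 1),
               class = "ecoassembly_mismatch_error")
})
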