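# Alpha diversity, distances, ordination and permutation tests.

test_that("to_relative normalizes columns and flags all-zero samples", {
  tab <- tiny_table(cbind(c(6L, 2L, 0L), c(0L, 0L, 0L)))
  rel <- to_relative(tab)
  expect_equal(unname(rel[, 1]), c(0.75, 0.25, 0))
  expect_equal(unname(rel[, 2]), c(0, 0, 0))
  expect_equal(attr(rel, "zero_samples"), "S2")
})

test_that("ens matches closed forms and Hill-number properties", {
  expect_equal(ens(rep(0.25, 4), "inverse_simpson"), 4)
  expect_equal(ens(rep(0.25, 4), "exp_shannon"), 4)
  expect_equal(ens(c(0.5, 0.5), "exp_simpson_literal"), exp(0.5))
  expect_equal(ens(1, "inverse_simpson"), 1)
  expect_equal(ens(1, "exp_shannon"), 1)
  # permutation invariance and uniform maximum at S
  p <- c(0.5, 0.3, 0.2)
  for (mode in c("inverse_simpson", "exp_shannon")) {
    expect_equal(ens(p, mode), ens(rev(p), mode))
    expect_lt(ens(p, mode), 3)
    expect_gte(ens(p, mode), 1)
  }
  expect_error(ens(c(0, 0)), "all-zero")
  expect_error(ens(c(0.2, 0.2)), "sum")
})

test_that("rarefaction preserves depth, drops shallow samples, is seeded", {
  tab <- tiny_table(cbind(c(4L, 0L), c(30L, 20L), c(1L, 0L)))
  draws <- suppressMessages(rarefy(tab, depth = 2, n_draws = 20, seed = 7))
  expect_equal(attr(draws, "dropped_samples"), "S3")
  for (d in draws) {
    expect_equal(unname(colSums(d)), c(2, 2))
    expect_equal(unname(d[, "S1"]), c(2, 0))  # only possible subsample
  }
  again <- suppressMessages(rarefy(tab, depth = 2, n_draws = 20, seed = 7))
  expect_identical(draws[], again[])
  # depth equal to a sample total leaves it unchanged
  d3 <- rarefy(tab[, 2, drop = FALSE], depth = 50, n_draws = 3, seed = 1)
  expect_equal(unname(d3[[2]][, 1]), c(30, 20))
  expect_error(rarefy(tab, depth = 100, n_draws = 2, seed = 1), "depth")
})

test_that("alpha_diversity averages ENS over rarefaction draws", {
  tab <- random_table(40, 5, 800, seed = 3)
  out <- alpha_diversity(tab, depth = 500, n_draws = 10, seed = 2)
  expect_equal(out$sample_id, colnames(tab))
  expect_true(all(out$ens >= 1))
  expect_equal(out$n_rarefactions[1], 10L)
  out2 <- alpha_diversity(tab, depth = 500, n_draws = 10, seed = 2)
  expect_identical(out, out2)
})

test_that("Bray-Curtis matches hand values and the equal-total identity", {
  tab <- tiny_table(cbind(c(6L, 2L, 0L), c(2L, 2L, 4L)))
  d <- bray_curtis_matrix(tab)
  expect_equal(d["S1", "S2"], 0.5)
  expect_equal(bray_curtis_matrix(tiny_table(cbind(c(10L, 0L), c(0L, 10L))))[1, 2], 1)
  expect_equal(bray_curtis_matrix(tiny_table(cbind(c(3L, 1L), c(3L, 1L))))[1, 2], 0)
  # counts vs relative abundances agree when totals are equal
  tab2 <- random_table(30, 4, 1000, seed = 5)
  expect_equal(bray_curtis_matrix(tab2), bray_curtis_matrix(to_relative(tab2)))
  zz <- tiny_table(cbind(c(0L, 0L), c(0L, 0L), c(1L, 1L)))
  expect_error(bray_curtis_matrix(zz), "S1")
})

test_that("weighted UniFrac reproduces the two-leaf case and the star-tree identity", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  tab <- tiny_table(cbind(c(10L, 0L), c(0L, 10L)), taxa = c("A", "B"))
  expect_equal(weighted_unifrac_matrix(tab, tr)["S1", "S2"], 2)
  expect_equal(weighted_unifrac_matrix(tab, tr, normalized = TRUE)["S1", "S2"], 1)
  expect_equal(weighted_unifrac_matrix(cbind(tab, S3 = tab[, 1]), tr)["S1", "S3"], 0)

  # star tree with unit branches: raw WUF equals the L1 distance between
  # relative-abundance vectors (each tip's branch contributes |pA - pB|)
  ntax <- 8
  star <- ape::read.tree(text = paste0(
    "(", paste0("t", 1:ntax, ":1", collapse = ","), ");"))
  tab2 <- random_table(ntax, 4, 200, seed = 11)
  rel <- to_relative(tab2)
  wuf <- weighted_unifrac_matrix(tab2, star)
  for (a in 1:3) for (b in (a + 1):4)
    expect_equal(wuf[a, b], sum(abs(rel[, a] - rel[, b])), tolerance = 1e-9)

  expect_error(weighted_unifrac_matrix(tiny_table(cbind(c(1L), c(2L)),
                                                  taxa = "Z"), tr),
               class = "ecoassembly_mismatch_error")

  # normalized form is bounded by 1
  tr3 <- simulate_tree(12, seed = 4)
  tab3 <- random_table(12, 5, 100, seed = 4)
  rownames(tab3) <- tr3$tip.label
  wn <- weighted_unifrac_matrix(tab3, tr3, normalized = TRUE)
  expect_true(all(wn >= 0 & wn <= 1 + 1e-12))
})

test_that("weighted UniFrac agrees with phyloseq on random trees", {
  skip_if_not_installed("phyloseq")
  tr <- simulate_tree(20, seed = 6)
  tab <- random_table(20, 6, 300, seed = 6)
  rownames(tab) <- tr$tip.label
  ps <- phyloseq::phyloseq(phyloseq::otu_table(tab, taxa_are_rows = TRUE),
                           phyloseq::phy_tree(tr))
  for (norm in c(FALSE, TRUE)) {
    ours <- weighted_unifrac_matrix(tab, tr, normalized = norm)
    ref <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE,
                                       normalized = norm))
    expect_equal(ours[colnames(tab), colnames(tab)],
                 ref[colnames(tab), colnames(tab)], tolerance = 1e-9)
  }
})

test_that("PCoA recovers simple geometries and reports explained variance", {
  # three equidistant points: two axes, 50/50 explained
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(paste0("S", 1:3), paste0("S", 1:3))
  ord <- pcoa(d3, k = 2)
  expect_equal(ord$explained, c(0.5, 0.5), tolerance = 1e-9)

  # collinear points: first axis explains everything
  x <- c(0, 1, 3, 7)
  dl <- as.matrix(dist(x))
  dimnames(dl) <- list(paste0("S", 1:4), paste0("S", 1:4))
  ordl <- pcoa(dl, k = 2)
  expect_equal(ordl$explained[1], 1, tolerance = 1e-9)
  # coordinates reproduce the line's distances
  expect_equal(as.matrix(dist(ordl$coordinates[, 1])),
               unname(dl), ignore_attr = TRUE, tolerance = 1e-9)

  dz <- matrix(0, 3, 3, dimnames = dimnames(d3))
  ordz <- pcoa(dz, k = 2)
  expect_true(ordz$degenerate)
  expect_warning(pcoa(d3, k = 5), "clipped")
})

test_that("permanova p-value matches exhaustive brute-force enumeration at n = 6", {
  set.seed(42)
  coords <- matrix(rnorm(12), 6, 2)
  d <- as.matrix(dist(coords))
  dimnames(d) <- list(paste0("S", 1:6), paste0("S", 1:6))
  labels <- rep(c("a", "b"), each = 3)
  perms <- all_perms(6)
  res <- permanova(d, labels, permutations = perms)
  # independent oracle: enumerate all label orderings directly
  f_obs <- oracle_pseudo_f(d, labels)
  f_all <- apply(perms, 1, function(p) oracle_pseudo_f(d, labels[p]))
  p_oracle <- (sum(f_all >= f_obs - 1e-12) + 1) / (nrow(perms) + 1)
  expect_equal(res$statistic, f_obs, tolerance = 1e-9)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
})

test_that("permanova on duplicated identical groups is exchangeable (p = 1)", {
  coords <- matrix(rnorm(10), 5, 2)
  d <- as.matrix(dist(rbind(coords, coords)))
  ids <- paste0("S", 1:10)
  dimnames(d) <- list(ids, ids)
  res <- permanova(d, rep(c("a", "b"), each = 5), n_permutations = 99, seed = 3)
  expect_equal(res$p_value, 1)
  expect_error(permanova(d, rep("a", 10)), "2 groups")
})

test_that("dispersion test flags scale differences and is null-calibrated on identical groups", {
  set.seed(8)
  big <- matrix(rnorm(80, sd = 5), 40, 2)
  small <- matrix(rnorm(80, sd = 1), 40, 2)
  d <- as.matrix(dist(rbind(big, small)))
  ids <- paste0("S", 1:80)
  dimnames(d) <- list(ids, ids)
  res <- dispersion_test(d, rep(c("wide", "narrow"), each = 40),
                         n_permutations = 999, seed = 5)
  expect_lt(res$p_value, 0.01)
  # identical groups: every permutation ties or beats the observed F
  coords <- matrix(rnorm(10), 5, 2)
  d2 <- as.matrix(dist(rbind(coords, coords)))
  dimnames(d2) <- list(paste0("S", 1:10), paste0("S", 1:10))
  res2 <- dispersion_test(d2, rep(c("a", "b"), each = 5),
                          n_permutations = 99, seed = 2)
  expect_equal(res2$p_value, 1)
})

test_that("rank-sum test uses exact enumeration for small samples", {
  res <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 0.1)  # 2/20 arrangements as extreme
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  set.seed(1)
  res2 <- rank_sum_test(rnorm(50), rnorm(50) + 2)
  expect_lt(res2$p_value, 1e-6)
  expect_error(rank_sum_test(numeric(0), 1), "empty")
})
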