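# Differential expression: filtering rules, TMM against a brute-force oracle
# and edgeR, conditional-likelihood dispersion recovery, and the exact test
# against enumeration.

test_that("low-count filter drops all-zero and single-sample genes and keeps
          a hand-enumerated set", {
  m <- rbind(
    g1 = c(0, 0, 0, 0),        # all zero -> removed
    g2 = c(500, 0, 600, 0),    # 1 sample per group -> removed at min 2
    g3 = c(500, 600, 0, 0),    # 2 samples in group A -> kept
    g4 = c(2, 1, 2, 1),        # cpm >= 1 everywhere (small libs) -> kept
    g5 = c(0, 0, 700, 800))    # 2 samples in group B -> kept
  counts <- counts_tbl(m)
  groups <- groups_tbl(sprintf("s%02d", 1:4), c("a", "a", "b", "b"))
  kept <- filter_low_counts(counts, groups)$gene_id
  expect_identical(kept, c("g3", "g4", "g5"))
  expect_warning(
    filter_low_counts(counts_tbl(rbind(g1 = c(1, 0, 0, 1))), groups),
    "every gene")
})

test_that("TMM factors are 1 for identical and depth-scaled columns and match
          an independent brute-force oracle", {
  m <- matrix(rpois(200, 50), ncol = 4)
  same <- counts_tbl(cbind(m[, 1], m[, 1], m[, 1]))
  expect_equal(tmm_factors(same)$norm_factor, rep(1, 3))

  two <- counts_tbl(cbind(a = m[, 1] + 1, b = 2 * (m[, 1] + 1)))
  expect_equal(tmm_factors(two)$norm_factor, rep(1, 2), tolerance = 1e-12)

  # brute-force oracle: sort-based double trim and explicit weighted mean
  set.seed(42)
  mm <- matrix(rnbinom(40, mu = 80, size = 5) + 1, ncol = 2)
  counts <- counts_tbl(mm)
  got <- tmm_factors(counts, ref_sample = "s02")$norm_factor[1]
  n1 <- sum(mm[, 1]); n2 <- sum(mm[, 2])
  M <- log2((mm[, 1] / n1) / (mm[, 2] / n2))
  A <- 0.5 * log2((mm[, 1] / n1) * (mm[, 2] / n2))
  w <- (n1 - mm[, 1]) / (n1 * mm[, 1]) + (n2 - mm[, 2]) / (n2 * mm[, 2])
  n <- length(M)
  keepM <- order(M)[(floor(0.3 * n) + 1):(n - floor(0.3 * n))]
  keepA <- order(A)[(floor(0.05 * n) + 1):(n - floor(0.05 * n))]
  keep <- intersect(keepM, keepA)
  f_raw <- 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  f_expected <- f_raw / exp(mean(log(c(f_raw, 1))))
  expect_equal(got, f_expected, tolerance = 1e-10)

  zero <- counts_tbl(cbind(a = c(1, 2), b = c(0, 0)))
  expect_error(tmm_factors(zero), "all-zero")
})

test_that("TMM factors agree with edgeR::calcNormFactors on simulated data", {
  skip_if_not_installed("edgeR")
  sim <- simulate_bulk_counts(n_genes = 500, n_samples_per_group = 4,
                              n_de_genes = 50, seed = 31)
  m <- as.matrix(sim$counts[-1])
  rownames(m) <- sim$counts$gene_id
  ours <- tmm_factors(sim$counts)$norm_factor
  theirs <- edgeR::calcNormFactors(m, method = "TMM")
  # same recipe up to reference choice and edgeR's q2q pseudo handling
  expect_equal(ours, unname(theirs), tolerance = 0.02)
})

test_that("dispersion estimation recovers the truth and shrinks to common", {
  pois <- simulate_bulk_counts(n_genes = 2000, n_samples_per_group = 5,
                               n_de_genes = 0, dispersion = 0, seed = 41)
  f <- tmm_factors(pois$counts)
  d0 <- estimate_dispersion(pois$counts, pois$groups, f)
  expect_lte(d0$common, 0.01)

  nb <- simulate_bulk_counts(n_genes = 2000, n_samples_per_group = 5,
                             n_de_genes = 0, dispersion = 0.2, seed = 42)
  f <- tmm_factors(nb$counts)
  d <- estimate_dispersion(nb$counts, nb$groups, f)
  expect_gt(d$common, 0.15)
  expect_lt(d$common, 0.25)

  # infinite prior pins every tagwise value to the common one
  dinf <- estimate_dispersion(nb$counts[1:100, ], nb$groups, f,
                              prior_df = 1e6)
  expect_lt(max(abs(dinf$tagwise$dispersion - dinf$common)), 1e-3)

  one <- counts_tbl(matrix(c(5, 9), ncol = 2))
  expect_error(
    estimate_dispersion(one, groups_tbl(c("s01", "s02"), c("a", "b")),
                        tmm_factors(one)),
    "undefined")
})

test_that("common dispersion is close to edgeR's qCML estimate", {
  skip_if_not_installed("edgeR")
  sim <- simulate_bulk_counts(n_genes = 1000, n_samples_per_group = 5,
                              n_de_genes = 0, dispersion = 0.15, seed = 43)
  m <- as.matrix(sim$counts[-1])
  rownames(m) <- sim$counts$gene_id
  dge <- edgeR::DGEList(m, group = sim$groups$group)
  dge <- edgeR::calcNormFactors(dge)
  dge <- edgeR::estimateCommonDisp(dge)
  f <- tmm_factors(sim$counts)
  d <- estimate_dispersion(sim$counts, sim$groups, f)
  # q2q pseudo-counts (edgeR) vs common-library rescaling (here): close but
  # not identical, so compare loosely
  expect_equal(d$common, dge$common.dispersion, tolerance = 0.2)
})

test_that("exact test matches binomial enumeration and handles degenerate
          splits", {
  # equal split with equal group sizes is the most probable outcome -> p = 1
  expect_equal(nocimap:::exact_nb_pvalue(5, 5, 3, 3, 0.1), 1)
  expect_equal(nocimap:::exact_nb_pvalue(0, 0, 3, 3, 0.1), 1)

  # phi = 0, total 10, equal sizes: brute-force binomial double tail
  for (za in 0:10) {
    w <- dbinom(0:10, 10, 0.5)
    expected <- sum(w[w <= w[za + 1] + 1e-12])
    expect_equal(nocimap:::exact_nb_pvalue(za, 10 - za, 4, 4, 0),
                 expected, tolerance = 1e-10)
  }

  # NB case against direct negative-hypergeometric enumeration
  phi <- 0.3; na <- 3; nb <- 5; z <- 40
  ra <- na / phi; rb <- nb / phi
  w <- exp(lgamma(0:z + ra) - lgamma(0:z + 1) - lgamma(ra) +
             lgamma(z - 0:z + rb) - lgamma(z - 0:z + 1) - lgamma(rb))
  w <- w / sum(w)
  for (za in c(0, 7, 15, 40)) {
    expected <- sum(w[w <= w[za + 1] * (1 + 1e-10)])
    expect_equal(nocimap:::exact_nb_pvalue(za, z - za, na, nb, phi),
                 expected, tolerance = 1e-10)
  }
})

test_that("BH adjustment properties and group-swap antisymmetry hold", {
  sim <- simulate_bulk_counts(n_genes = 300, n_samples_per_group = 4,
                              n_de_genes = 30, seed = 51)
  f <- tmm_factors(sim$counts)
  d <- estimate_dispersion(sim$counts, sim$groups, f)
  ab <- nb_exact_test(sim$counts, sim$groups, f, d, "case", "control")
  ba <- nb_exact_test(sim$counts, sim$groups, f, d, "control", "case")

  expect_true(all(ab$fdr >= ab$p_value - 1e-12))
  ord <- order(ab$p_value)
  expect_true(all(diff(ab$fdr[ord]) >= -1e-12))
  # swapping groups negates fold changes, p identical
  expect_equal(ab$log2_fc, -ba$log2_fc, tolerance = 1e-10)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
})

test_that("doubling one sample's depth leaves p-values invariant at a fixed
          common library scale", {
  sim <- simulate_bulk_counts(n_genes = 200, n_samples_per_group = 4,
                              n_de_genes = 20, seed = 52)
  counts2 <- sim$counts
  counts2[["case_01"]] <- counts2[["case_01"]] * 2L

  run <- function(counts) {
    f <- tmm_factors(counts)
    d <- estimate_dispersion(counts, sim$groups, f, common_lib_size = 1e6)
    nb_exact_test(counts, sim$groups, f, d, "case", "control",
                  common_lib_size = 1e6)
  }
  # TMM's inverse-variance weights depend on library size, so a pure depth
  # change perturbs the factor (and hence rounded pseudo-counts) slightly;
  # p-values must stay materially unchanged rather than bit-identical
  expect_lt(max(abs(run(sim$counts)$p_value - run(counts2)$p_value)), 0.01)
})

test_that("planted DE is recovered with high sensitivity at FDR 0.05", {
  sim <- simulate_bulk_counts(n_genes = 1000, n_samples_per_group = 8,
                              n_de_genes = 100, dispersion = 0.2,
                              min_abs_lfc = 1, seed = 53)
  de <- run_de(sim$counts, sim$groups, "case", "control")
  j <- dplyr::inner_join(de, sim$truth, by = "gene_id")
  called <- j$fdr <= 0.05
  sens <- sum(called & j$is_de) / sum(j$is_de)
  fdp <- sum(called & !j$is_de) / max(1, sum(called))
  expect_gte(sens, 0.8)
  expect_lte(fdp, 0.10)
})
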