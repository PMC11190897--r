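# Generators: seed determinism, planted-parameter recovery, basic invariants.

test_that("bulk count generator is deterministic and respects its contract", {
  a <- simulate_bulk_counts(n_genes = 100, n_samples_per_group = 4,
                            n_de_genes = 10, seed = 11)
  b <- simulate_bulk_counts(n_genes = 100, n_samples_per_group = 4,
                            n_de_genes = 10, seed = 11)
  expect_identical(a, b)
  m <- as.matrix(a$counts[-1])
  expect_true(all(m >= 0))
  expect_true(all(m == round(m)))
  expect_equal(sum(a$truth$is_de), 10)
  expect_true(all(abs(a$truth$log2_fc[a$truth$is_de]) >= 0.5))
  expect_error(simulate_bulk_counts(n_genes = 0), "positive")
  expect_error(simulate_bulk_counts(n_genes = 5, n_de_genes = 6), "exceed")
})

test_that("dispersion 0 gives Poisson-like counts and phi = 0.2 is recoverable
          by a moment estimator", {
  # Poisson limit: pooled variance/mean ratio near 1
  pois <- simulate_bulk_counts(n_genes = 1000, n_samples_per_group = 10,
                               n_de_genes = 0, dispersion = 0,
                               library_size_range = c(1e6, 1e6), seed = 21)
  m <- as.matrix(pois$counts[-1])
  ratio <- mean(apply(m, 1, var) / rowMeans(m))
  expect_lt(abs(ratio - 1), 0.1)

  # moment recovery of phi: var = mu + phi mu^2, pooled across 2000 genes
  nb <- simulate_bulk_counts(n_genes = 2000, n_samples_per_group = 10,
                             n_de_genes = 0, dispersion = 0.2,
                             library_size_range = c(1e6, 1e6), seed = 22)
  m <- as.matrix(nb$counts[-1])
  mu <- rowMeans(m)
  v <- apply(m, 1, var)
  phi_hat <- sum(v - mu) / sum(mu^2)
  expect_gt(phi_hat, 0.15)
  expect_lt(phi_hat, 0.25)
})

test_that("neuron expression generator plants coverage and joint coexpression", {
  spec <- tibble::tibble(gene = "Agtr1a", positive_rate = 1.0)
  sim <- simulate_neuron_expression(50, c(all = 1), spec, seed = 1)
  cov <- receptor_coverage(sim$tpm, "Agtr1a")
  expect_equal(cov$n_positive, 50)

  # planted conditional coexpression recovered within the binomial 95% CI
  spec2 <- tibble::tibble(
    gene = c("Agtr1a", "Scn10a"),
    positive_rate = c(0.65, 0.8),
    condition_on = c(NA, "Agtr1a"),
    rate_when_negative = c(NA, 0.1))
  sim2 <- simulate_neuron_expression(300, c(all = 1), spec2, seed = 2)
  fr <- coexpress_fraction(sim2$tpm, "Agtr1a", "Scn10a")
  ci_half <- 1.96 * sqrt(0.8 * 0.2 / fr$n_base)
  expect_lt(abs(fr$fraction - 0.8), ci_half)

  expect_identical(sim2, simulate_neuron_expression(300, c(all = 1), spec2,
                                                    seed = 2))
  expect_error(simulate_neuron_expression(10, c(all = 0.7), spec, seed = 1),
               "sum to 1")
})

test_that("trace generator plants responders, dead cells and truth alignment", {
  sim <- simulate_trace_set(n_rois = 60, noise_sd = 0, dead_fraction = 0.1,
                            seed = 5)
  expect_identical(sim, simulate_trace_set(n_rois = 60, noise_sd = 0,
                                           dead_fraction = 0.1, seed = 5))
  expect_setequal(unique(sim$traces$roi_id), sim$truth$roi_id)
  # dead ROIs fail the KCl QC, live ones pass (noiseless)
  qc <- qc_traces(sim$traces, sim$windows, background = sim$background_f)
  j <- dplyr::inner_join(qc, sim$truth, by = "roi_id")
  expect_true(all(j$qc_included[!j$dead]))
  expect_true(all(!j$qc_included[j$dead]))
  expect_error(
    simulate_trace_set(n_rois = 3, duration_s = 100,
                       kcl_window = c(90, 120), seed = 1),
    "within the record")
})

test_that("recording generator produces valid spike trains and flags weak units", {
  sim <- suppressWarnings(
    simulate_recording(duration_s = 20,
                       units = tibble::tibble(amplitude_uv = c(150, 25),
                                              baseline_rate_hz = c(2, 1)),
                       noise_uv = 15, seed = 7))
  expect_true(all(diff(sim$truth$time_s[sim$truth$unit == 1]) > 0))
  # 25 uV sits below the 2x noise RMS detectability bound, 150 uV above it
  expect_setequal(unique(sim$truth$detectable[sim$truth$unit == 1]), TRUE)
  expect_setequal(unique(sim$truth$detectable[sim$truth$unit == 2]), FALSE)
  expect_warning(
    simulate_recording(duration_s = 5,
                       units = tibble::tibble(amplitude_uv = 20,
                                              baseline_rate_hz = 1),
                       noise_uv = 15, seed = 1),
    "twice the noise")
  expect_error(simulate_recording(fs_hz = 5000), "10 kHz")
})

test_that("micrograph generator plants exact object counts and packs or fails", {
  sim <- simulate_micrograph(n_green = 10, n_blue_only = 40, seed = 9)
  expect_equal(sim$truth$neuron_fraction[1], 0.20)
  expect_equal(sum(sim$truth$type == "neuron"), 10)
  expect_equal(nrow(sim$truth), 50)
  expect_true(all(sim$green %in% 0:255) && all(sim$blue %in% 0:255))
  zero <- simulate_micrograph(n_green = 0, n_blue_only = 5,
                              image_shape = c(128, 128), seed = 2)
  expect_equal(zero$truth$neuron_fraction[1], 0)
  expect_error(simulate_micrograph(n_green = 500, n_blue_only = 500,
                                   image_shape = c(64, 64), seed = 1),
               "infeasible")
})
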