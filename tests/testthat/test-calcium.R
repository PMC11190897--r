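# Ca2+ trace pipeline: normalization arithmetic, QC rules, responder
# classification, cosensitivity partition and reporter overlap.

windows_tbl <- function(drug = c(60, 90), kcl = c(240, 270)) {
  tibble::tibble(label = c("drug", "KCl"),
                 start_s = c(drug[1], kcl[1]),
                 end_s = c(drug[2], kcl[2]))
}

# deterministic single-ROI trace: flat baseline 100, drug bump, KCl to 150
flat_trace <- function(drug_amp = 0, n = 825, frame_rate = 2.5) {
  t <- seq(0, by = 1 / frame_rate, length.out = n)
  f <- rep(100, n)
  f[t >= 60 & t < 75] <- 100 + drug_amp
  f[t >= 240 & t < 255] <- 150
  trace_tbl(f, frame_rate)
}

test_that("normalization maps baseline to 0 and the KCl maximum to 1", {
  tr <- flat_trace(drug_amp = 25)
  norm <- normalize_traces(tr, windows_tbl())
  base <- norm$f_norm[norm$time_s >= 50 & norm$time_s < 60]
  expect_equal(mean(base), 0, tolerance = 1e-12)
  expect_equal(max(norm$f_norm), 1, tolerance = 1e-12)
  # planted drug amplitude is half the KCl amplitude -> peak 0.5
  peak <- max(norm$f_norm[norm$time_s >= 60 & norm$time_s <= 90])
  expect_equal(peak, 0.5, tolerance = 1e-12)
})

test_that("normalization is idempotent and scale invariant", {
  tr <- flat_trace(drug_amp = 20)
  norm <- normalize_traces(tr, windows_tbl())
  # renormalizing a trace whose baseline is 0 and KCl max 1 changes nothing
  renorm <- normalize_traces(
    dplyr::rename(norm, f = "f_norm"), windows_tbl())
  expect_equal(renorm$f_norm, norm$f_norm, tolerance = 1e-12)

  # multiplying trace and background by k > 0 leaves the output unchanged
  k <- 3.7
  scaled <- dplyr::mutate(flat_trace(drug_amp = 20), f = f * k)
  norm_scaled <- normalize_traces(scaled, windows_tbl(), background = 0)
  expect_equal(norm_scaled$f_norm, norm$f_norm, tolerance = 1e-12)

  with_bg <- dplyr::mutate(flat_trace(drug_amp = 20), f = (f + 10) * k)
  norm_bg <- normalize_traces(with_bg, windows_tbl(), background = 10 * k)
  expect_equal(norm_bg$f_norm, norm$f_norm, tolerance = 1e-12)
})

test_that("QC excludes weak KCl responses (boundary below 5%), drifting and
          nonpositive baselines", {
  t <- seq(0, by = 0.4, length.out = 825)
  mk <- function(f, roi) trace_tbl(f, roi = roi)
  f_ok <- rep(100, 825); f_ok[t >= 240 & t < 255] <- 150
  f_4pct <- rep(100, 825); f_4pct[t >= 240 & t < 255] <- 104
  f_drift <- 100 + 0.8 * (t - 60); f_drift[t >= 240 & t < 255] <- 160
  traces <- dplyr::bind_rows(mk(f_ok, "ok"), mk(f_4pct, "weak"),
                             mk(f_drift, "drift"))
  qc <- qc_traces(traces, windows_tbl())
  expect_true(qc$qc_included[qc$roi_id == "ok"])
  expect_false(qc$qc_included[qc$roi_id == "weak"])
  expect_match(qc$qc_reasons[qc$roi_id == "weak"], "KCl")
  expect_false(qc$qc_included[qc$roi_id == "drift"])
  expect_match(qc$qc_reasons[qc$roi_id == "drift"], "unstable baseline")

  f_neg <- rep(-5, 825)
  qc_neg <- qc_traces(mk(f_neg, "neg"), windows_tbl())
  expect_match(qc_neg$qc_reasons, "nonpositive")
})

test_that("a 5% KCl rise is excluded and a 50% rise included (strict >)", {
  t <- seq(0, by = 0.4, length.out = 825)
  f5 <- rep(100, 825); f5[t >= 240 & t < 255] <- 105
  f50 <- rep(100, 825); f50[t >= 240 & t < 255] <- 150
  traces <- dplyr::bind_rows(trace_tbl(f5, roi = "five"),
                             trace_tbl(f50, roi = "fifty"))
  qc <- qc_traces(traces, windows_tbl())
  expect_false(qc$qc_included[qc$roi_id == "five"])   # exactly 5%: excluded
  expect_true(qc$qc_included[qc$roi_id == "fifty"])
})

test_that("classification uses a strict 0.1 threshold and recovers noiseless
          truth exactly", {
  # peak exactly 0.1 -> not responsive; 0.15 -> responsive
  tr1 <- flat_trace(drug_amp = 5)    # 5/50 = 0.1 exactly
  tr2 <- dplyr::mutate(flat_trace(drug_amp = 7.5),
                       roi_id = "roi2")  # 0.15
  calls <- classify_responses(dplyr::bind_rows(tr1, tr2), windows_tbl())
  expect_false(calls$responsive[calls$roi_id == "roi1"])
  expect_equal(calls$peak[calls$roi_id == "roi1"], 0.1, tolerance = 1e-12)
  expect_true(calls$responsive[calls$roi_id == "roi2"])

  sim <- simulate_trace_set(n_rois = 80, noise_sd = 0, responder_fraction = 0.4,
                            amplitude_mean = 0.5, seed = 12)
  calls <- classify_responses(sim$traces, sim$windows,
                              background = sim$background_f)
  j <- dplyr::inner_join(calls, sim$truth, by = "roi_id")
  expect_true(all(j$responsive == j$responder))

  expect_error(
    classify_responses(tr1, windows_tbl(drug = c(400, 430)), drug = "drug"),
    "outside")
})

test_that("planted responder fraction 0.4 is recovered within the binomial CI
          at n = 500 with noise", {
  sim <- simulate_trace_set(n_rois = 500, noise_sd = 0.02,
                            responder_fraction = 0.4, seed = 31)
  calls <- classify_responses(sim$traces, sim$windows,
                              background = sim$background_f)
  frac <- response_summary(calls)$fraction
  expect_lt(abs(frac - 0.4), 1.96 * sqrt(0.4 * 0.6 / nrow(calls)))
})

test_that("cosensitivity counts partition the universe and recover planted
          conditional structure", {
  sim <- simulate_trace_set(
    n_rois = 300, noise_sd = 0.01, responder_fraction = 0.5, seed = 41,
    duration_s = 430, kcl_window = c(340, 370),
    drug_b = list(label = "capsaicin", window = c(200, 230),
                  p_given_responder = 0.8, p_given_nonresponder = 0.2))
  calls_a <- classify_responses(sim$traces, sim$windows, drug = "drug",
                                background = sim$background_f)
  calls_b <- classify_responses(sim$traces, sim$windows, drug = "capsaicin",
                                background = sim$background_f)
  cs <- cosensitivity_table(calls_a, calls_b)
  expect_equal(sum(cs$counts$n), nrow(calls_a))
  p_ba <- cs$conditional$fraction[cs$conditional$direction == "b_given_a"]
  n_a <- sum(calls_a$responsive)
  expect_lt(abs(p_ba - 0.8), 1.96 * sqrt(0.8 * 0.2 / n_a))

  # degenerate structures
  all_both <- dplyr::mutate(calls_a, responsive = TRUE)
  cs2 <- cosensitivity_table(all_both, all_both)
  expect_equal(cs2$conditional$fraction, c(1, 1))
  expect_error(cosensitivity_table(calls_a, calls_b[-1, ]), "different ROI")
})

test_that("reporter overlap reports responder and overall fractions with soma
          summaries", {
  sim <- simulate_trace_set(n_rois = 400, noise_sd = 0.01,
                            responder_fraction = 0.5,
                            reporter_rate_responder = 0.85,
                            reporter_rate_nonresponder = 0.75, seed = 51)
  calls <- classify_responses(sim$traces, sim$windows,
                              background = sim$background_f)
  ov <- reporter_overlap(calls, sim$rois)
  n_resp <- ov$responder_reporter$n
  expect_lt(abs(ov$responder_reporter$fraction - 0.85),
            1.96 * sqrt(0.85 * 0.15 / n_resp))
  # responders are small-bodied by construction
  soma <- ov$soma_by_class
  expect_lt(soma$mean_um2[soma$responsive], soma$mean_um2[!soma$responsive])

  none <- dplyr::mutate(calls, responsive = FALSE)
  expect_error(reporter_overlap(none, sim$rois), "no responders")
})
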