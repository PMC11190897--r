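# Nerve pipeline: spike detection thresholds and F1 at stated SNR, rate
# histograms and peak change, concentration-response, waveform matching and
# distension classification.

# F1 of detected vs planted event times with a matching tolerance.
detection_f1 <- function(detected, truth, tol_s = 1e-3) {
  if (length(detected) == 0) return(0)
  used <- rep(FALSE, length(truth))
  tp <- 0
  for (t in detected) {
    i <- which(!used & abs(truth - t) <= tol_s)
    if (length(i) > 0) {
      used[i[1]] <- TRUE
      tp <- tp + 1
    }
  }
  precision <- tp / length(detected)
  recall <- tp / length(truth)
  if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
}

test_that("pure Gaussian noise yields a false-event rate below 0.5/s", {
  sim <- simulate_recording(duration_s = 30,
                            units = tibble::tibble(amplitude_uv = 150,
                                                   baseline_rate_hz = 0),
                            noise_uv = 15, seed = 61)
  spikes <- detect_spikes(sim$recording)
  expect_lt(nrow(spikes) / 30, 0.5)
})

test_that("a noiseless record recovers planted spikes exactly at +/-0.2 ms", {
  fs <- 20000
  truth_times <- seq(0.5, 9.5, by = 1)
  v <- numeric(10 * fs)
  tmpl <- nocimap:::spike_template(fs)
  half <- (length(tmpl) - 1) / 2
  for (tt in truth_times) {
    i0 <- round(tt * fs) + 1
    v[(i0 - half):(i0 + half)] <- v[(i0 - half):(i0 + half)] + 200 * tmpl
  }
  rec <- list(voltage_uv = v, fs_hz = fs)
  spikes <- detect_spikes(rec, noise_floor_uv = 5)
  expect_equal(nrow(spikes), 10)
  expect_lt(max(abs(spikes$time_s - truth_times)), 2e-4)
  expect_error(detect_spikes(rec), "noise_floor")
})

test_that("detection reaches F1 >= 0.95 at amplitude 5x noise RMS and counts
          are monotone in the threshold", {
  sim <- simulate_recording(duration_s = 60,
                            units = tibble::tibble(amplitude_uv = 75,
                                                   baseline_rate_hz = 1),
                            noise_uv = 15, seed = 62)
  spikes <- detect_spikes(sim$recording)
  f1 <- detection_f1(spikes$time_s, sim$truth$time_s)
  expect_gte(f1, 0.95)

  # monotonicity: raising the absolute threshold can only lose events
  thrs <- c(20, 40, 60, 90, 140)
  n_at <- purrr::map_int(thrs, function(th) {
    nrow(detect_spikes(sim$recording, threshold_uv = th))
  })
  expect_true(all(diff(n_at) <= 0))
})

test_that("time-shifting a record shifts event times and leaves the peak
          change invariant", {
  sim <- simulate_recording(duration_s = 40,
                            units = tibble::tibble(amplitude_uv = 120,
                                                   baseline_rate_hz = 3),
                            noise_uv = 12, seed = 63)
  spikes <- detect_spikes(sim$recording)
  shift <- 5
  rec2 <- sim$recording
  rec2$voltage_uv <- c(rnorm(shift * rec2$fs_hz, 0, 12), rec2$voltage_uv)
  spikes2 <- detect_spikes(rec2)
  # align: events after the shift should match the originals
  late <- spikes2$time_s[spikes2$time_s > shift + 1e-3] - shift
  matched <- detection_f1(late, spikes$time_s, tol_s = 1e-3)
  expect_gte(matched, 0.9)
})

test_that("peak change recovers a planted 10 Hz step within 1 Hz and is null
          for a stationary train", {
  # planted step: 2 Hz baseline, 12 Hz for 120 s in the post window
  set.seed(71)
  base <- cumsum(rexp(5000, 2)); base <- base[base < 900]
  step_start <- 420
  step <- step_start + cumsum(rexp(3000, 12)); step <- step[step < step_start + 120]
  post_tail <- (step_start + 120) + cumsum(rexp(2000, 2))
  post_tail <- post_tail[post_tail < 1020]
  train <- tibble::tibble(time_s = sort(c(base[base < 420 | base > 540],
                                          step, post_tail)))
  pc <- rate_and_peak_change(train, drug_onset_s = 400, duration_s = 1020)
  expect_lt(abs(pc$summary$delta_hz - 10), 1)
  expect_equal(pc$summary$percent_change,
               100 * pc$summary$delta_hz / pc$summary$baseline_hz)

  # stationary Poisson: small positive bias below 1 Hz at 5 Hz, 60 s smoothing
  set.seed(72)
  null_train <- tibble::tibble(time_s = sort(runif(5 * 1000, 0, 1000)))
  pc0 <- rate_and_peak_change(null_train, drug_onset_s = 350,
                              duration_s = 1000)
  expect_gte(pc0$summary$delta_hz, -0.5)
  expect_lt(pc0$summary$delta_hz, 1)

  # arithmetic: baseline 4, peak 6 -> 50%
  expect_equal(100 * (6 - 4) / 4, 50)
  expect_error(rate_and_peak_change(train, drug_onset_s = 2000,
                                    duration_s = 1020),
               "after drug onset")
  expect_warning(rate_and_peak_change(train, drug_onset_s = 100,
                                      duration_s = 1020),
                 "available span")
})

test_that("concentration-response summarises groups and recovers a planted
          Hill curve within a factor of 2 on EC50", {
  same <- tibble::tibble(concentration = rep(1, 4), delta_hz = rep(7, 4))
  cr0 <- concentration_response(same)
  expect_equal(cr0$summary$sem_delta_hz, 0)

  set.seed(81)
  conc <- rep(c(0.01, 0.1, 0.3, 1, 3, 10), each = 6)
  mu <- 10 * conc / (0.3 + conc)  # Emax 10, EC50 0.3, slope 1
  d <- tibble::tibble(concentration = conc,
                      delta_hz = rnorm(length(conc), mu, 0.5))
  cr <- concentration_response(d, hill = TRUE)
  expect_gt(cr$hill_fit$ec50, 0.15)
  expect_lt(cr$hill_fit$ec50, 0.6)
  expect_error(concentration_response(same, hill = TRUE), "at least two")
})

test_that("waveform matching recovers planted units and merges duplicates", {
  # one unit -> one cluster
  one <- simulate_recording(duration_s = 30,
                            units = tibble::tibble(amplitude_uv = 150,
                                                   baseline_rate_hz = 2),
                            noise_uv = 10, seed = 91)
  sp1 <- detect_spikes(one$recording)
  u1 <- match_units(one$recording, sp1)
  expect_equal(u1$n_units, 1)

  # two units with 3:1 amplitude ratio at SNR 5 -> >= 0.9 accuracy up to
  # label permutation
  two <- simulate_recording(
    duration_s = 60,
    units = tibble::tibble(amplitude_uv = c(300, 100),
                           baseline_rate_hz = c(1.5, 1.5)),
    noise_uv = 10, seed = 92)
  sp2 <- detect_spikes(two$recording)
  u2 <- match_units(two$recording, sp2)
  # both planted units recovered; overlapping-spike events may form a tiny
  # extra cluster
  expect_gte(u2$n_units, 2)
  expect_lte(u2$n_units, 3)
  ev <- u2$events
  truth_unit <- purrr::map_int(ev$time_s, function(t) {
    i <- which.min(abs(two$truth$time_s - t))
    as.integer(two$truth$unit[i])
  })
  # label-permutation-invariant accuracy: map each cluster to its majority
  # truth unit
  majority <- tapply(truth_unit, ev$unit, function(u) {
    as.integer(names(which.max(table(u))))
  })
  acc <- mean(majority[as.character(ev$unit)] == truth_unit)
  expect_gte(acc, 0.9)

  expect_error(match_units(one$recording, sp1[1:5, ]), "at least 10")
})

test_that("distension response requires a genuine rate increase above the
          pressure threshold", {
  ramp <- tibble::tibble(time_s = c(0, 60, 120),
                         pressure_mmhg = c(0, 80, 0))
  sim <- simulate_recording(
    duration_s = 120,
    units = tibble::tibble(amplitude_uv = 150, baseline_rate_hz = 2,
                           distension_rate_hz = 6),
    noise_uv = 12, pressure = ramp, seed = 95)
  spikes <- detect_spikes(sim$recording)
  dr <- distension_response(spikes, sim$recording)
  expect_true(dr$responsive)
  expect_gt(dr$rate_above_hz, dr$rate_below_hz)

  flat <- simulate_recording(
    duration_s = 120,
    units = tibble::tibble(amplitude_uv = 150, baseline_rate_hz = 4),
    noise_uv = 12, pressure = ramp, seed = 96)
  sp_flat <- detect_spikes(flat$recording)
  dr_flat <- distension_response(sp_flat, flat$recording)
  expect_false(dr_flat$responsive)

  low_ramp <- tibble::tibble(time_s = c(0, 120), pressure_mmhg = c(0, 10))
  low <- simulate_recording(duration_s = 10,
                            units = tibble::tibble(amplitude_uv = 150,
                                                   baseline_rate_hz = 2),
                            noise_uv = 12, pressure = low_ramp, seed = 97)
  sp_low <- detect_spikes(low$recording)
  expect_error(distension_response(sp_low, low$recording), "never exceeds")
})
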