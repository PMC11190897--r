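# Extracellular afferent recording pipeline: threshold spike detection against
# background noise, firing-rate histograms with baseline/peak-change
# quantification, concentration-response summaries, waveform matching into
# single units and distension-response classification.
#
# A recording is a list with elements `voltage_uv` (numeric vector), `fs_hz`,
# optionally `pressure_mmhg` (same clock) and `drug_window` (start/end, s) —
# the shape produced by simulate_recording().

check_recording <- function(rec) {
  stopifnot(is.list(rec), is.numeric(rec$voltage_uv), rec$fs_hz > 0)
  invisible(rec)
}

# Gaussian smoothing kernel on the sample clock (area 1); sd in ms.
gauss_kernel <- function(fs_hz, sd_ms) {
  sd_n <- sd_ms / 1000 * fs_hz
  half <- max(1L, ceiling(4 * sd_n))
  k <- exp(-((-half):half)^2 / (2 * sd_n^2))
  k / sum(k)
}

convolve_same <- function(x, k) {
  half <- (length(k) - 1) / 2
  y <- stats::filter(c(rep(x[1], half), x, rep(x[length(x)], half)), k,
                     sides = 2)
  as.numeric(y)[(half + 1):(half + length(x))]
}

#' Detect field potentials by thresholding against background noise
#'
#' The voltage trace is first smoothed with a Gaussian kernel matched to the
#' width of a spike lobe (matched-filter smoothing, default sd 0.15 ms), then
#' background noise is estimated robustly on the smoothed trace as
#' `1.4826 * MAD`. Events are groups of samples whose absolute smoothed
#' voltage exceeds the threshold `threshold_factor x (noise_pp_factor x
#' robust RMS)` — i.e. twice a peak-to-peak noise estimate by default —
#' separated by at least the dead time; each event is stamped at its absolute
#' peak.
#'
#' @param rec Recording list (see [simulate_recording()]).
#' @param noise_window Optional `c(start_s, end_s)` span used for the noise
#'   estimate (default: the whole record; the median-based estimate is robust
#'   to spikes).
#' @param threshold_factor Multiple of the noise estimate (default 2, the
#'   "twice background noise" rule).
#' @param noise_pp_factor Peak-to-peak proxy: the noise estimate is this
#'   multiple of the robust RMS of the smoothed trace (default 4).
#' @param smooth_sd_ms Gaussian smoothing sd in ms (default 0.15; 0 disables
#'   smoothing).
#' @param dead_time_ms Minimum separation between events (default 2 ms).
#' @param threshold_uv Absolute threshold override in uV (skips the noise
#'   estimate).
#' @param noise_floor_uv Floor for the noise estimate; required to be set if
#'   the estimated noise is zero (noiseless synthetic records).
#' @return A tibble of class `noci_spikes` with columns `time_s`,
#'   `amplitude_uv` (smoothed absolute peak), and attributes `threshold_uv`,
#'   `noise_uv`, `fs_hz`.
#' @examples
#' sim <- simulate_recording(duration_s = 10, seed = 3)
#' spikes <- detect_spikes(sim$recording)
#' @export
detect_spikes <- function(rec, noise_window = NULL, threshold_factor = 2,
                          noise_pp_factor = 4, smooth_sd_ms = 0.15,
                          dead_time_ms = 2, threshold_uv = NULL,
                          noise_floor_uv = NULL) {
  check_recording(rec)
  v <- rec$voltage_uv
  fs <- rec$fs_hz
  s <- if (smooth_sd_ms > 0) convolve_same(v, gauss_kernel(fs, smooth_sd_ms)) else v

  nw <- if (is.null(noise_window)) s else {
    s[seq(max(1, round(noise_window[1] * fs) + 1),
          min(length(s), round(noise_window[2] * fs)))]
  }
  noise_rms <- mad(nw)  # 1.4826 * median absolute deviation
  if (noise_rms == 0) {
    if (is.null(noise_floor_uv)) {
      abort("noise estimate is zero; set noise_floor_uv or threshold_uv")
    }
    noise_rms <- noise_floor_uv
  }
  thr <- threshold_uv %||% (threshold_factor * noise_pp_factor * noise_rms)

  above <- which(abs(s) > thr)
  if (length(above) == 0) {
    out <- tibble(time_s = numeric(), amplitude_uv = numeric())
  } else {
    dead_n <- max(1L, round(dead_time_ms / 1000 * fs))
    grp_start <- c(TRUE, diff(above) > dead_n)
    grp_id <- cumsum(grp_start)
    peaks <- map_int(split(above, grp_id), function(idx) {
      idx[which.max(abs(s[idx]))]
    })
    out <- tibble(time_s = (unname(peaks) - 1) / fs,
                  amplitude_uv = abs(s[unname(peaks)]))
  }
  structure(out, threshold_uv = thr, noise_uv = noise_rms, fs_hz = fs,
            duration_s = length(v) / fs,
            class = c("noci_spikes", class(out)))
}

#' Firing-rate histogram and peak change after drug application
#'
#' Bins spike counts (default 1 s bins), smooths the rate with a centred
#' moving average (default 60 s), and quantifies the drug effect as
#' `peak - baseline` where baseline is the mean smoothed rate over the
#' `baseline_s` seconds (default 300) before drug onset and peak the maximal
#' smoothed rate within `post_s` seconds (default 600) after onset.
#'
#' @param spikes A `noci_spikes` tibble, or any tibble with a `time_s` column
#'   (planted ground-truth trains work directly).
#' @param drug_onset_s Drug application onset (s).
#' @param duration_s Record length; taken from the spike-train attribute when
#'   present.
#' @param bin_s Histogram bin width (default 1 s).
#' @param smooth_s Moving-average span for the smoothed rate (default 60 s).
#' @param baseline_s Baseline span before onset (default 300 s; a shorter
#'   available span is used with a warning).
#' @param post_s Peak search span after onset (default 600 s).
#' @return A list of class `noci_peak_change` with `rates` (tibble `time_s`,
#'   `rate_hz`, `rate_smooth_hz`) and `summary` (one-row tibble
#'   `baseline_hz`, `peak_hz`, `delta_hz`, `percent_change`).
#' @export
rate_and_peak_change <- function(spikes, drug_onset_s, duration_s = NULL,
                                 bin_s = 1, smooth_s = 60,
                                 baseline_s = 300, post_s = 600) {
  duration_s <- duration_s %||% attr(spikes, "duration_s") %||%
    (max(spikes$time_s) + bin_s)
  if (drug_onset_s >= duration_s) abort("no bins after drug onset")
  if (drug_onset_s < baseline_s) {
    warn(sprintf("only %.0f s of pre-drug record; using available span",
                 drug_onset_s))
    baseline_s <- drug_onset_s
  }
  breaks <- seq(0, ceiling(duration_s / bin_s) * bin_s, by = bin_s)
  counts <- graphics::hist(spikes$time_s, breaks = breaks, plot = FALSE)$counts
  rate <- counts / bin_s
  w <- max(1L, round(smooth_s / bin_s))
  if (w %% 2 == 0) w <- w + 1L
  smooth <- convolve_same(rate, rep(1 / w, w))
  mid <- head(breaks, -1) + bin_s / 2

  base_idx <- mid >= drug_onset_s - baseline_s & mid < drug_onset_s
  post_idx <- mid >= drug_onset_s & mid <= drug_onset_s + post_s
  baseline <- mean(smooth[base_idx])
  peak <- max(smooth[post_idx])
  delta <- peak - baseline
  structure(list(
    rates = tibble(time_s = mid, rate_hz = rate, rate_smooth_hz = smooth),
    summary = tibble(baseline_hz = baseline, peak_hz = peak, delta_hz = delta,
                     percent_change = 100 * delta / baseline)),
    class = "noci_peak_change")
}

#' @export
print.noci_peak_change <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Peak change: baseline %.2f Hz, peak %.2f Hz, delta %.2f Hz (%.0f%%)\n",
    s$baseline_hz, s$peak_hz, s$delta_hz, s$percent_change))
  invisible(x)
}

#' Concentration-response summary of peak firing changes
#'
#' Per-concentration n, mean and SEM of the peak change, with an optional
#' three-parameter Hill fit (Emax, EC50, slope) through the means.
#'
#' @param peaks Tibble with columns `concentration` and `delta_hz` (one row
#'   per recording).
#' @param hill Fit a Hill curve (default FALSE; requires >= 2 distinct
#'   concentrations).
#' @return A list of class `noci_conc_response` with `summary` (tibble
#'   `concentration`, `n`, `mean_delta_hz`, `sem_delta_hz`) and, when
#'   requested, `hill_fit` (list `emax`, `ec50`, `slope`).
#' @export
concentration_response <- function(peaks, hill = FALSE) {
  stopifnot(all(c("concentration", "delta_hz") %in% names(peaks)))
  peaks <- peaks[is.finite(peaks$delta_hz), ]
  if (nrow(peaks) == 0) abort("no peak-change values supplied")
  summary <- peaks %>%
    group_by(concentration = .data$concentration) %>%
    summarise(n = n(),
              mean_delta_hz = mean(.data$delta_hz),
              sem_delta_hz = if (n() > 1) sd(.data$delta_hz) / sqrt(n()) else 0,
              .groups = "drop") %>%
    arrange(.data$concentration)

  fit <- NULL
  if (hill) {
    if (nrow(summary) < 2) {
      abort("Hill fit requires at least two concentrations")
    }
    d <- peaks
    start <- list(emax = max(summary$mean_delta_hz),
                  lec50 = log(stats::median(summary$concentration)),
                  slope = 1)
    m <- tryCatch(
      nls(delta_hz ~ emax * (concentration^slope) /
            (exp(lec50)^slope + concentration^slope),
          data = d, start = start,
          control = stats::nls.control(warnOnly = TRUE)),
      error = function(e) NULL)
    if (!is.null(m)) {
      cf <- coef(m)
      fit <- list(emax = unname(cf["emax"]), ec50 = exp(unname(cf["lec50"])),
                  slope = unname(cf["slope"]))
    } else {
      warn("Hill fit did not converge; returning summary only")
    }
  }
  structure(list(summary = summary, hill_fit = fit),
            class = "noci_conc_response")
}

# Extract peak-aligned snippets around event times; rows = events. Events are
# re-aligned to the local absolute peak of the raw signal (within +/-0.5 ms)
# and then to sub-sample precision by parabolic interpolation of the peak, so
# that sampling-phase jitter does not split units.
extract_snippets <- function(rec, spikes, snippet_ms) {
  v <- rec$voltage_uv
  half <- round(snippet_ms / 2 / 1000 * rec$fs_hz)
  w_align <- round(0.5 / 1000 * rec$fs_hz)
  idx0 <- purrr::map_int(round(spikes$time_s * rec$fs_hz) + 1, function(i) {
    lo <- max(1, i - w_align); hi <- min(length(v), i + w_align)
    as.integer(lo + which.max(abs(v[lo:hi])) - 1L)
  })
  keep <- idx0 - half - 1 >= 1 & idx0 + half + 1 <= length(v)
  if (!all(keep)) {
    spikes <- spikes[keep, ]
    idx0 <- idx0[keep]
  }
  if (length(idx0) == 0) abort("no events with a full snippet span")
  snips <- t(vapply(idx0, function(i) {
    # parabolic sub-sample peak offset in (-0.5, 0.5]
    s <- sign(v[i])
    y <- s * v[(i - 1):(i + 1)]
    denom <- y[1] - 2 * y[2] + y[3]
    delta <- if (abs(denom) > 1e-12) 0.5 * (y[1] - y[3]) / denom else 0
    delta <- max(-0.5, min(0.5, delta))
    # resample the snippet on the shifted grid (linear interpolation)
    pos <- i + delta + (-half):half
    lo <- floor(pos)
    frac <- pos - lo
    v[lo] * (1 - frac) + v[lo + 1] * frac
  }, numeric(2 * half + 1)))
  list(snippets = snips, spikes = spikes)
}

#' Match detected events into single units by waveform clustering
#'
#' Extracts peak-aligned snippets (default 3 ms) around each detected event
#' and clusters them by average-linkage agglomeration on Euclidean distance.
#' Starting from a fine partition, clusters are merged while the smallest
#' inter-template distance is below `merge_threshold` times the pooled
#' within-cluster RMS distance, so duplicated waveforms collapse into one
#' unit.
#'
#' @param rec Recording list.
#' @param spikes A `noci_spikes` tibble from [detect_spikes()] (>= 10 events).
#' @param snippet_ms Snippet span (default 3 ms).
#' @param merge_threshold Merge criterion multiplier (default 1.5).
#' @param max_units Upper bound on the initial fine partition (default 8).
#' @return A list of class `noci_units`: `events` (tibble `time_s`,
#'   `amplitude_uv`, `unit`), `templates` (tibble `unit`, `sample`, `mean_uv`)
#'   and `n_units`.
#' @export
match_units <- function(rec, spikes, snippet_ms = 3, merge_threshold = 1.5,
                        max_units = 8) {
  check_recording(rec)
  if (nrow(spikes) < 10) abort("need at least 10 events for unit matching")
  ex <- extract_snippets(rec, spikes, snippet_ms)
  snips <- ex$snippets
  hc <- stats::hclust(stats::dist(snips), method = "average")
  labels <- stats::cutree(hc, k = min(max_units, nrow(snips)))

  templates <- function(lab) {
    t(vapply(sort(unique(lab)), function(u) {
      colMeans(snips[lab == u, , drop = FALSE])
    }, numeric(ncol(snips))))
  }
  within_rms <- function(lab, tmpl) {
    d2 <- map_dbl(seq_len(nrow(snips)), function(i) {
      u <- match(lab[i], sort(unique(lab)))
      sum((snips[i, ] - tmpl[u, ])^2)
    })
    sqrt(mean(d2))
  }

  repeat {
    us <- sort(unique(labels))
    if (length(us) == 1) break
    tmpl <- templates(labels)
    dmat <- as.matrix(stats::dist(tmpl))
    diag(dmat) <- Inf
    wrms <- within_rms(labels, tmpl)
    mn <- min(dmat)
    if (wrms == 0 && mn == 0) {
      # identical duplicated templates with no scatter: merge them
    } else if (mn >= merge_threshold * max(wrms, 1e-12)) break
    pair <- which(dmat == mn, arr.ind = TRUE)[1, ]
    labels[labels == us[pair[2]]] <- us[pair[1]]
  }
  labels <- as.integer(factor(labels))
  tmpl <- templates(labels)
  tmpl_tbl <- purrr::map(sort(unique(labels)), function(u) {
    tibble(unit = u, sample = seq_len(ncol(snips)), mean_uv = tmpl[u, ])
  }) %>% list_rbind()
  structure(list(events = bind_cols(ex$spikes, tibble(unit = labels)),
                 templates = tmpl_tbl,
                 n_units = length(unique(labels))),
            class = "noci_units")
}

#' @export
print.noci_units <- function(x, ...) {
  cat("Waveform matching:", nrow(x$events), "events in", x$n_units, "unit(s)\n")
  print(dplyr::count(x$events, .data$unit))
  invisible(x)
}

#' Classify a unit as distension-responsive
#'
#' Compares firing during supra-threshold luminal pressure (default
#' > 20 mm Hg) against sub-threshold firing: responsive when the
#' supra-threshold mean rate exceeds the sub-threshold mean rate by more than
#' `k_sd` (default 2) times the SD of 1-s binned sub-threshold rates.
#'
#' @param spikes Spike-time tibble for one unit (`time_s`).
#' @param rec Recording list with a `pressure_mmhg` channel.
#' @param pressure_threshold_mmhg Distension criterion (default 20 mm Hg).
#' @param k_sd Required excess in sub-threshold-rate SDs (default 2).
#' @param bin_s Bin width for the rate SD estimate (default 1 s).
#' @return One-row tibble: `responsive`, `rate_above_hz`, `rate_below_hz`,
#'   `sd_below_hz`.
#' @export
distension_response <- function(spikes, rec, pressure_threshold_mmhg = 20,
                                k_sd = 2, bin_s = 1) {
  check_recording(rec)
  if (is.null(rec$pressure_mmhg)) abort("recording has no pressure channel")
  p <- rec$pressure_mmhg
  fs <- rec$fs_hz
  above <- p > pressure_threshold_mmhg
  if (!any(above)) abort("pressure never exceeds the threshold")
  t_above <- sum(above) / fs
  t_below <- sum(!above) / fs
  idx <- pmin(length(p), pmax(1, round(spikes$time_s * fs) + 1))
  n_above <- sum(above[idx])
  n_below <- length(idx) - n_above

  # SD of sub-threshold rates from 1-s bins fully below threshold
  n_bins <- floor(length(p) / (bin_s * fs))
  bin_of <- rep(seq_len(n_bins), each = bin_s * fs)[seq_along(p)]
  below_bins <- which(tapply(above, bin_of, any) == FALSE)
  rate_bins <- tabulate(bin_of[idx], nbins = n_bins) / bin_s
  sd_below <- if (length(below_bins) > 1) sd(rate_bins[below_bins]) else 0

  rate_above <- n_above / t_above
  rate_below <- n_below / t_below
  tibble(responsive = rate_above - rate_below > k_sd * sd_below,
         rate_above_hz = rate_above,
         rate_below_hz = rate_below,
         sd_below_hz = sd_below)
}
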