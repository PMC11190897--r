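# Ca2+ imaging trace pipeline: background subtraction, F/F_pos normalization
# against the KCl positive control, viability QC, responder classification,
# cosensitivity tables and reporter-overlap summaries. Traces travel as a long
# tibble (roi_id, time_s, f); windows as a tibble (label, start_s, end_s) in
# which the KCl positive-control window is labelled "KCl".

check_windows <- function(windows, traces) {
  stopifnot(all(c("label", "start_s", "end_s") %in% names(windows)))
  t_max <- max(traces$time_s)
  if (any(windows$start_s < 0 | windows$end_s > t_max + 1e-9)) {
    abort("window outside the recorded trace")
  }
  if (!"KCl" %in% windows$label) abort("a window labelled 'KCl' is required")
  invisible(windows)
}

window_of <- function(windows, label) {
  w <- windows[windows$label == label, ]
  if (nrow(w) != 1) abort(paste("expected exactly one window labelled", label))
  c(w$start_s, w$end_s)
}

# Per-ROI normalization quantities for one drug window: baseline mean F0 over
# the `baseline_s` seconds before drug onset, KCl-window maximum.
roi_norm_stats <- function(traces, drug_onset_s, kcl_window, background,
                           baseline_s = 10) {
  traces %>%
    group_by(.data$roi_id) %>%
    summarise(
      f0 = mean(.data$f[.data$time_s >= drug_onset_s - baseline_s &
                          .data$time_s < drug_onset_s] - background),
      kcl_max = max(.data$f[.data$time_s >= kcl_window[1] &
                              .data$time_s <= kcl_window[2]] - background),
      baseline_sd = sd(.data$f[.data$time_s >= drug_onset_s - baseline_s &
                                 .data$time_s < drug_onset_s]),
      baseline_slope = {
        tt <- .data$time_s[.data$time_s >= drug_onset_s - baseline_s &
                             .data$time_s < drug_onset_s]
        ff <- .data$f[.data$time_s >= drug_onset_s - baseline_s &
                        .data$time_s < drug_onset_s]
        if (length(tt) >= 2 && var(tt) > 0) cov(tt, ff) / var(tt) else 0
      },
      .groups = "drop")
}

#' Normalize fluorescence traces to baseline and KCl maximum (F/F_pos)
#'
#' After subtracting background, each ROI's trace is rescaled so that the mean
#' over the 10 s (configurable) before drug onset maps to 0 and the maximal
#' fluorescence during KCl application maps to 1:
#' `out = (F - background - F0) / (F_KClmax - F0)`.
#' ROIs whose KCl maximum does not exceed their baseline cannot be normalized
#' and are dropped with a message (they fail viability QC anyway).
#'
#' @param traces Long tibble `roi_id`, `time_s`, `f`.
#' @param windows Window tibble (`label`, `start_s`, `end_s`) including a
#'   `"KCl"` row.
#' @param drug Label of the drug window whose onset anchors the baseline
#'   (default `"drug"`).
#' @param background Background fluorescence: a scalar, or a tibble
#'   `roi_id`, `background` for per-ROI values.
#' @param baseline_s Baseline span before drug onset (default 10 s).
#' @return Long tibble `roi_id`, `time_s`, `f_norm` for normalizable ROIs.
#' @export
normalize_traces <- function(traces, windows, drug = "drug", background = 0,
                             baseline_s = 10) {
  check_windows(windows, traces)
  kcl <- window_of(windows, "KCl")
  onset <- window_of(windows, drug)[1]
  traces <- apply_background(traces, background)
  stats <- roi_norm_stats(traces, onset, kcl, 0, baseline_s)
  bad <- stats$roi_id[stats$kcl_max <= stats$f0]
  if (length(bad) > 0) {
    inform(paste0(length(bad), " ROI(s) dropped: KCl maximum not above baseline"))
  }
  traces %>%
    inner_join(stats[!stats$roi_id %in% bad, c("roi_id", "f0", "kcl_max")],
               by = "roi_id") %>%
    mutate(f_norm = (.data$f - .data$f0) / (.data$kcl_max - .data$f0)) %>%
    select("roi_id", "time_s", "f_norm")
}

# Subtract scalar or per-ROI background, returning traces with adjusted f.
apply_background <- function(traces, background) {
  if (is.data.frame(background)) {
    traces %>% left_join(background, by = "roi_id") %>%
      mutate(f = .data$f - .data$background) %>% select(-"background")
  } else {
    mutate(traces, f = .data$f - background)
  }
}

#' Viability QC of fluorescence traces
#'
#' An ROI is included when (1) its KCl response rises more than
#' `kcl_min_rise` (default 5%) above baseline, relative to baseline
#' fluorescence, and (2) its baseline is stable: absolute linear drift over
#' the baseline window no more than `drift_tol` of F0 and baseline
#' coefficient of variation no more than `cv_tol`. Failure reasons are
#' reported per ROI.
#'
#' @inheritParams normalize_traces
#' @param kcl_min_rise Minimum fractional KCl rise over baseline, strict
#'   (default 0.05).
#' @param drift_tol Maximum |baseline slope| x window / F0 (default 0.05).
#' @param cv_tol Maximum baseline SD / F0 (default 0.10).
#' @return Tibble `roi_id`, `f0`, `kcl_max`, `kcl_rise`, `qc_included`,
#'   `qc_reasons` (character, `""` when included).
#' @export
qc_traces <- function(traces, windows, drug = "drug", background = 0,
                      baseline_s = 10, kcl_min_rise = 0.05,
                      drift_tol = 0.05, cv_tol = 0.10) {
  check_windows(windows, traces)
  kcl <- window_of(windows, "KCl")
  onset <- window_of(windows, drug)[1]
  traces <- apply_background(traces, background)
  stats <- roi_norm_stats(traces, onset, kcl, 0, baseline_s)

  stats %>%
    mutate(
      kcl_rise = (.data$kcl_max - .data$f0) / .data$f0,
      reasons = pmap(list(.data$f0, .data$kcl_max, .data$kcl_rise,
                          .data$baseline_slope, .data$baseline_sd),
                     function(f0, kcl_max, rise, slope, bsd) {
                       r <- character()
                       if (f0 <= 0) r <- c(r, "nonpositive baseline")
                       else {
                         if (!rise > kcl_min_rise) r <- c(r, "insufficient KCl response")
                         if (abs(slope) * baseline_s / f0 > drift_tol) {
                           r <- c(r, "unstable baseline")
                         }
                         if (bsd / f0 > cv_tol) r <- c(r, "noisy baseline")
                       }
                       r
                     }),
      qc_included = lengths(.data$reasons) == 0,
      qc_reasons = map_chr(.data$reasons, paste, collapse = "; ")) %>%
    select("roi_id", "f0", "kcl_max", "kcl_rise", "qc_included", "qc_reasons")
}

#' Classify drug responses of QC-included ROIs
#'
#' Normalizes each trace for the given drug window and calls an ROI responsive
#' when its normalized fluorescence strictly exceeds `threshold`
#' (default 0.1 F/F_pos) anywhere within `response_window_s` seconds of drug
#' onset. Only QC-included ROIs receive calls.
#'
#' @inheritParams qc_traces
#' @param threshold Responder criterion on the F/F_pos scale (strict `>`,
#'   default 0.1).
#' @param response_window_s Search window after drug onset (default 90 s,
#'   clipped to the record).
#' @param qc Optional precomputed output of [qc_traces()]; computed with
#'   default settings when omitted.
#' @return Tibble of class `noci_calls`: `roi_id`, `drug`, `peak`
#'   (max normalized amplitude in the window), `responsive`, `qc_included`.
#' @examples
#' sim <- simulate_trace_set(n_rois = 20, noise_sd = 0, seed = 2)
#' calls <- classify_responses(sim$traces, sim$windows,
#'                             background = sim$background_f)
#' @export
classify_responses <- function(traces, windows, drug = "drug", background = 0,
                               baseline_s = 10, threshold = 0.1,
                               response_window_s = 90, qc = NULL) {
  check_windows(windows, traces)
  onset <- window_of(windows, drug)[1]
  if (onset + 1e-9 > max(traces$time_s)) abort("response window outside record")
  if (is.null(qc)) {
    qc <- qc_traces(traces, windows, drug, background, baseline_s)
  }
  norm <- normalize_traces(traces, windows, drug, background, baseline_s)
  t_end <- min(onset + response_window_s, max(traces$time_s))

  peaks <- norm %>%
    filter(.data$time_s >= onset, .data$time_s <= t_end) %>%
    group_by(.data$roi_id) %>%
    summarise(peak = max(.data$f_norm), .groups = "drop")

  out <- qc %>%
    filter(.data$qc_included) %>%
    left_join(peaks, by = "roi_id") %>%
    mutate(drug = drug,
           responsive = .data$peak > threshold) %>%
    select("roi_id", "drug", "peak", "responsive", "qc_included")
  class(out) <- c("noci_calls", class(out))
  out
}

#' Cosensitivity between two drugs
#'
#' Partitions the common QC-included ROI universe of two call tables into
#' both / A-only / B-only / neither and reports the conditional response
#' fractions P(B | A) and P(A | B).
#'
#' @param calls_a,calls_b `noci_calls` tibbles for the two drugs over the same
#'   ROI universe.
#' @return A list of class `noci_cosensitivity` with `counts` (tibble
#'   `class`, `n`, `fraction`) and `conditional` (tibble `direction`,
#'   `fraction`).
#' @export
cosensitivity_table <- function(calls_a, calls_b) {
  if (!setequal(calls_a$roi_id, calls_b$roi_id)) {
    abort("the two call tables cover different ROI sets")
  }
  j <- inner_join(select(calls_a, "roi_id", a = "responsive"),
                  select(calls_b, "roi_id", b = "responsive"),
                  by = "roi_id")
  n <- nrow(j)
  counts <- tibble(
    class = c("both", "a_only", "b_only", "neither"),
    n = c(sum(j$a & j$b), sum(j$a & !j$b), sum(!j$a & j$b), sum(!j$a & !j$b)))
  counts$fraction <- counts$n / n
  conditional <- tibble(
    direction = c("b_given_a", "a_given_b"),
    fraction = c(if (sum(j$a) > 0) sum(j$a & j$b) / sum(j$a) else NA_real_,
                 if (sum(j$b) > 0) sum(j$a & j$b) / sum(j$b) else NA_real_))
  structure(list(counts = counts, conditional = conditional, n = n),
            class = "noci_cosensitivity")
}

#' @export
print.noci_cosensitivity <- function(x, ...) {
  cat("Cosensitivity over", x$n, "QC-included ROIs\n")
  print(x$counts)
  print(x$conditional)
  invisible(x)
}

#' Reporter overlap of drug responders and soma-area summaries
#'
#' Reports the fraction of drug responders that carry a genetic reporter
#' (e.g. tdTomato driven in Na_V_1.8-positive neurons), the overall reporter
#' fraction across all QC-included ROIs, and per-class soma-area
#' mean +/- SEM with histogram counts.
#'
#' @param calls A `noci_calls` tibble.
#' @param rois Tibble `roi_id`, `soma_area_um2`, `reporter` (logical).
#' @param bin_um2 Soma-area histogram bin width (default 100 um^2).
#' @return A list of class `noci_reporter_overlap`: `responder_reporter`
#'   (k, n, fraction, pct), `overall_reporter`, `soma_by_class` (tibble with
#'   mean, SEM, n per responsive class) and `soma_histogram`.
#' @export
reporter_overlap <- function(calls, rois, bin_um2 = 100) {
  if (!all(calls$roi_id %in% rois$roi_id)) {
    abort("reporter/soma annotations missing for some ROIs")
  }
  j <- inner_join(calls, rois, by = "roi_id")
  if (any(is.na(j$reporter))) abort("reporter flags missing for some ROIs")
  n_resp <- sum(j$responsive)
  if (n_resp == 0) abort("no responders: reporter overlap undefined")

  responder_reporter <- count_proportion(sum(j$responsive & j$reporter), n_resp)
  overall_reporter <- count_proportion(sum(j$reporter), nrow(j))
  soma_by_class <- j %>%
    group_by(responsive = .data$responsive) %>%
    summarise(n = n(),
              mean_um2 = mean(.data$soma_area_um2),
              sem_um2 = sd(.data$soma_area_um2) / sqrt(n()),
              .groups = "drop")
  breaks <- seq(0, max(j$soma_area_um2) + bin_um2, by = bin_um2)
  soma_histogram <- j %>%
    mutate(bin = cut(.data$soma_area_um2, breaks, right = FALSE)) %>%
    group_by(responsive = .data$responsive, bin = .data$bin) %>%
    summarise(n = n(), .groups = "drop")

  structure(list(responder_reporter = responder_reporter,
                 overall_reporter = overall_reporter,
                 soma_by_class = soma_by_class,
                 soma_histogram = soma_histogram),
            class = "noci_reporter_overlap")
}

#' @export
print.noci_reporter_overlap <- function(x, ...) {
  cat(sprintf("Reporter+ among responders: %d/%d (%.1f%%)\n",
              x$responder_reporter$k, x$responder_reporter$n,
              x$responder_reporter$pct))
  cat(sprintf("Reporter+ overall:          %d/%d (%.1f%%)\n",
              x$overall_reporter$k, x$overall_reporter$n,
              x$overall_reporter$pct))
  print(x$soma_by_class)
  invisible(x)
}

#' Summarise responder calls
#'
#' @param calls A `noci_calls` tibble.
#' @return One-row tibble: `drug`, `n_included`, `n_responsive`, `fraction`,
#'   `pct`.
#' @export
response_summary <- function(calls) {
  tibble(drug = calls$drug[1],
         n_included = nrow(calls),
         n_responsive = sum(calls$responsive),
         fraction = sum(calls$responsive) / nrow(calls),
         pct = 100 * sum(calls$responsive) / nrow(calls))
}
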