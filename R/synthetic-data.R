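# Synthetic-data generators. Each generator returns its data together with the
# ground truth used to plant it, so every downstream stage can be exercised
# against known answers without any external download.

#' Simulate a bulk RNA-seq count matrix with planted differential expression
#'
#' Draws per-gene baseline means from a log-normal distribution, plants a
#' chosen number of differentially expressed genes with log2 fold changes
#' sampled from a zero-centred normal truncated away from zero, and generates
#' negative-binomial counts with per-sample library-depth scaling. With
#' `dispersion = 0` counts are Poisson.
#'
#' The planted effect is split symmetrically between the two groups (half the
#' log fold change up in the case group, half down in the control group) so the
#' overall expression level of DE genes stays comparable to the background.
#'
#' @param n_genes Number of genes.
#' @param n_samples_per_group Samples per group (length 1, recycled, or length 2).
#' @param n_de_genes Number of genes carrying a planted fold change; must not
#'   exceed `n_genes`.
#' @param baseline_mean_log_mu,baseline_sd_log_mu Mean and SD of the natural-log
#'   baseline expression means.
#' @param dispersion Negative-binomial dispersion phi (variance
#'   `mu + phi * mu^2`); `0` gives Poisson counts.
#' @param fold_change_log_sd SD (log2 scale) of planted fold changes.
#' @param min_abs_lfc Planted |log2 fold change| is resampled until it exceeds
#'   this floor, so "true DE" is well defined (default 0.5).
#' @param library_size_range Range of expected library depth factors; each
#'   sample's depth multiplier is uniform on this range divided by its mean.
#' @param group_names Length-2 character vector; first entry is the case group.
#' @param seed Integer seed; identical arguments give bit-identical output.
#' @return A list with `counts` (wide tibble: `gene_id` plus one column per
#'   sample), `groups` (tibble `sample_id`, `group`) and `truth` (tibble
#'   `gene_id`, `is_de`, `log2_fc` on the case-over-control scale).
#' @examples
#' sim <- simulate_bulk_counts(n_genes = 50, n_samples_per_group = 3,
#'                             n_de_genes = 5, seed = 1)
#' head(sim$counts)
#' @export
simulate_bulk_counts <- function(n_genes = 2000,
                                 n_samples_per_group = 8,
                                 n_de_genes = 200,
                                 baseline_mean_log_mu = log(100),
                                 baseline_sd_log_mu = 1,
                                 dispersion = 0.2,
                                 fold_change_log_sd = 2,
                                 min_abs_lfc = 0.5,
                                 library_size_range = c(8e5, 1.2e6),
                                 group_names = c("case", "control"),
                                 seed = 1) {
  if (n_genes < 1 || any(n_samples_per_group < 1)) {
    abort("n_genes and n_samples_per_group must be positive")
  }
  if (n_de_genes > n_genes) abort("n_de_genes must not exceed n_genes")
  if (dispersion < 0) abort("dispersion must be >= 0")
  if (length(n_samples_per_group) == 1) {
    n_samples_per_group <- rep(n_samples_per_group, 2)
  }
  stopifnot(length(group_names) == 2, length(library_size_range) == 2)

  with_seed(seed, {
    gene_ids <- sprintf("gene%05d", seq_len(n_genes))
    mu0 <- exp(rnorm(n_genes, baseline_mean_log_mu, baseline_sd_log_mu))

    lfc <- numeric(n_genes)
    if (n_de_genes > 0) {
      de_idx <- seq_len(n_de_genes)  # gene order is random in mu0 already
      draw <- rnorm(n_de_genes, 0, fold_change_log_sd)
      while (any(small <- abs(draw) < min_abs_lfc)) {
        draw[small] <- rnorm(sum(small), 0, fold_change_log_sd)
      }
      lfc[de_idx] <- draw
    }

    n_a <- n_samples_per_group[1]
    n_b <- n_samples_per_group[2]
    sample_ids <- c(sprintf("%s_%02d", group_names[1], seq_len(n_a)),
                    sprintf("%s_%02d", group_names[2], seq_len(n_b)))
    group <- rep(group_names, c(n_a, n_b))

    lib <- runif(n_a + n_b, library_size_range[1], library_size_range[2])
    depth <- lib / mean(lib)

    # per-gene mean per sample: baseline x half-effect x depth
    eff <- outer(lfc / 2, ifelse(group == group_names[1], 1, -1))
    mu <- sweep(2^eff, 1, mu0, `*`)
    mu <- sweep(mu, 2, depth, `*`)

    counts <- if (dispersion == 0) {
      matrix(rpois(length(mu), mu), nrow = n_genes)
    } else {
      matrix(rnbinom(length(mu), size = 1 / dispersion, mu = mu),
             nrow = n_genes)
    }
    dimnames(counts) <- list(gene_ids, sample_ids)

    list(
      counts = matrix_to_wide(counts),
      groups = tibble(sample_id = sample_ids, group = group),
      truth = tibble(gene_id = gene_ids,
                     is_de = lfc != 0,
                     log2_fc = lfc)
    )
  })
}

#' Simulate a single-neuron expression matrix with planted receptor/marker
#' coexpression
#'
#' Emulates a gene-by-cell TPM matrix of sensory neurons split into labelled
#' populations. Each row of `gene_spec` plants one gene in one population (or
#' in all populations with `population = NA`): cells are positive with the
#' stated rate and positive cells get log-normal TPM values. A row may instead
#' condition on another planted gene (`condition_on`), in which case the
#' positive rate applies among cells positive for that gene and
#' `rate_when_negative` among the rest, which gives direct control over the
#' joint coexpression rate seen downstream.
#'
#' @param n_cells Number of cells.
#' @param populations Tibble with columns `population` and `fraction`
#'   (fractions must sum to 1), or a named numeric vector of fractions.
#' @param gene_spec Tibble with columns `gene`, `positive_rate` and optionally
#'   `population`, `mean_log_tpm`, `sd_log_tpm`, `condition_on`,
#'   `rate_when_negative`.
#' @param dropout_tpm TPM value given to negative cells (default 0).
#' @param seed Integer seed.
#' @return A list with `tpm` (wide tibble `gene_id` x cells), `cells`
#'   (tibble `cell_id`, `population`) and `truth` (long tibble of planted
#'   positivity flags: `gene`, `cell_id`, `positive`).
#' @examples
#' spec <- tibble::tibble(gene = "Agtr1a", positive_rate = 0.65)
#' sim <- simulate_neuron_expression(50, c(all = 1), spec, seed = 1)
#' @export
simulate_neuron_expression <- function(n_cells,
                                       populations,
                                       gene_spec,
                                       dropout_tpm = 0,
                                       seed = 1) {
  if (is.numeric(populations)) {
    populations <- tibble(population = names(populations),
                          fraction = unname(populations))
  }
  if (abs(sum(populations$fraction) - 1) > 1e-8) {
    abort("population fractions must sum to 1")
  }
  stopifnot(all(c("gene", "positive_rate") %in% names(gene_spec)))

  with_seed(seed, {
    n_per <- diff(round(cumsum(c(0, populations$fraction)) * n_cells))
    pop <- rep(populations$population, n_per)
    cell_ids <- sprintf("cell%04d", seq_len(n_cells))
    genes <- unique(gene_spec$gene)
    tpm <- matrix(dropout_tpm, nrow = length(genes), ncol = n_cells,
                  dimnames = list(genes, cell_ids))
    positive <- matrix(FALSE, nrow = length(genes), ncol = n_cells,
                       dimnames = list(genes, cell_ids))

    for (i in seq_len(nrow(gene_spec))) {
      row <- gene_spec[i, ]
      in_pop <- if (!"population" %in% names(row) || is.na(row$population)) {
        rep(TRUE, n_cells)
      } else {
        pop == row$population
      }
      pos <- rep(FALSE, n_cells)
      cond <- if ("condition_on" %in% names(row)) row$condition_on else NA
      if (!is.na(cond)) {
        base_pos <- positive[cond, ] & in_pop
        base_neg <- !positive[cond, ] & in_pop
        rate_neg <- row$rate_when_negative %||% 0
        pos[base_pos] <- runif(sum(base_pos)) < row$positive_rate
        pos[base_neg] <- runif(sum(base_neg)) < rate_neg
      } else {
        pos[in_pop] <- runif(sum(in_pop)) < row$positive_rate
      }
      mlt <- if ("mean_log_tpm" %in% names(row) && !is.na(row$mean_log_tpm)) {
        row$mean_log_tpm
      } else log(50)
      slt <- if ("sd_log_tpm" %in% names(row) && !is.na(row$sd_log_tpm)) {
        row$sd_log_tpm
      } else 1
      tpm[row$gene, pos] <- rlnorm(sum(pos), mlt, slt)
      positive[row$gene, ] <- positive[row$gene, ] | pos
    }

    list(
      tpm = matrix_to_wide(tpm),
      cells = tibble(cell_id = cell_ids, population = pop),
      truth = as_tibble(as.table(positive), .name_repair = "minimal") %>%
        setNames(c("gene", "cell_id", "positive"))
    )
  })
}

# Difference-of-exponentials transient, normalised to unit peak.
ca_kernel <- function(t, rise_s = 1, decay_s = 8) {
  k <- ifelse(t < 0, 0, exp(-t / decay_s) - exp(-t / rise_s))
  tpk <- log(decay_s / rise_s) / (1 / rise_s - 1 / decay_s)
  k / (exp(-tpk / decay_s) - exp(-tpk / rise_s))
}

#' Simulate a set of Ca2+ imaging fluorescence traces
#'
#' Generates per-ROI fluorescence time series at a fixed frame rate: a constant
#' background plus per-ROI baseline, difference-of-exponential transients
#' (rise 1 s, decay 8 s) for the drug response of planted responders and for
#' the KCl positive control of all viable ROIs, and additive Gaussian noise.
#' A planted "dead" fraction of ROIs receives a sub-criterion KCl response so
#' that the downstream viability QC has true failures to find. Soma areas and
#' genetic-reporter flags are planted per ROI, with nociceptor-like defaults
#' (responders small-bodied and mostly reporter-positive).
#'
#' @param n_rois Number of ROIs.
#' @param frame_rate_hz Acquisition rate (default 2.5 Hz).
#' @param duration_s Record length in seconds.
#' @param drug_window,kcl_window Numeric `c(start_s, end_s)` application
#'   windows; must lie within the record and not overlap.
#' @param responder_fraction Fraction of viable ROIs that respond to the drug.
#' @param amplitude_mean,amplitude_sd Normalised drug transient amplitude
#'   (units of the KCl response) drawn per responder; clipped at 0.05.
#' @param kcl_amplitude_f Raw fluorescence amplitude of the KCl transient.
#' @param noise_sd Gaussian noise SD on the normalised (F/F_pos) scale.
#' @param dead_fraction Fraction of ROIs given a sub-5% KCl rise.
#' @param background_f Constant background fluorescence added to every frame.
#' @param baseline_f Mean per-ROI baseline fluorescence.
#' @param soma_area_responder,soma_area_nonresponder Mean soma areas (um^2).
#' @param reporter_rate_responder,reporter_rate_nonresponder Probability that a
#'   responder / non-responder carries the reporter.
#' @param drug_b Optional second-drug specification for cosensitivity studies:
#'   a list with elements `label`, `window` (start/end), `p_given_responder`,
#'   `p_given_nonresponder`, and optionally `amplitude_mean`.
#' @param seed Integer seed.
#' @return A list with `traces` (long tibble `roi_id`, `time_s`, `f`), `rois`
#'   (tibble `roi_id`, `soma_area_um2`, `reporter`), `windows` (tibble `label`,
#'   `start_s`, `end_s`, KCl labelled `"KCl"`), `frame_rate_hz`, `background_f`
#'   and `truth` (per-ROI responder flags, planted amplitudes, dead flags).
#' @export
simulate_trace_set <- function(n_rois = 100,
                               frame_rate_hz = 2.5,
                               duration_s = 330,
                               drug_window = c(60, 90),
                               kcl_window = c(240, 270),
                               responder_fraction = 0.4,
                               amplitude_mean = 0.5,
                               amplitude_sd = 0.15,
                               kcl_amplitude_f = 50,
                               noise_sd = 0.02,
                               dead_fraction = 0,
                               background_f = 10,
                               baseline_f = 100,
                               soma_area_responder = 437,
                               soma_area_nonresponder = 821,
                               reporter_rate_responder = 0.87,
                               reporter_rate_nonresponder = 0.77,
                               drug_b = NULL,
                               seed = 1) {
  windows <- tibble(label = c("drug", "KCl"),
                    start_s = c(drug_window[1], kcl_window[1]),
                    end_s = c(drug_window[2], kcl_window[2]))
  if (!is.null(drug_b)) {
    windows <- bind_rows(windows,
                         tibble(label = drug_b$label,
                                start_s = drug_b$window[1],
                                end_s = drug_b$window[2]))
  }
  if (any(windows$start_s < 0 | windows$end_s > duration_s)) {
    abort("application windows must lie within the record")
  }
  ord <- order(windows$start_s)
  if (any(windows$start_s[ord][-1] < windows$end_s[ord][-nrow(windows)])) {
    abort("application windows must not overlap")
  }

  with_seed(seed, {
    t <- seq(0, duration_s - 1 / frame_rate_hz, by = 1 / frame_rate_hz)
    roi_ids <- sprintf("roi%04d", seq_len(n_rois))
    dead <- runif(n_rois) < dead_fraction
    responder <- !dead & runif(n_rois) < responder_fraction
    amp <- ifelse(responder,
                  pmax(0.05, rnorm(n_rois, amplitude_mean, amplitude_sd)), 0)
    soma <- pmax(80, rnorm(n_rois,
                           ifelse(responder, soma_area_responder,
                                  soma_area_nonresponder),
                           ifelse(responder, 120, 220)))
    reporter <- runif(n_rois) < ifelse(responder, reporter_rate_responder,
                                       reporter_rate_nonresponder)
    kcl_amp <- ifelse(dead, 0.02 * baseline_f,
                      kcl_amplitude_f * runif(n_rois, 0.8, 1.2))

    resp_b <- rep(FALSE, n_rois)
    amp_b <- rep(0, n_rois)
    if (!is.null(drug_b)) {
      p_b <- ifelse(responder, drug_b$p_given_responder,
                    drug_b$p_given_nonresponder)
      resp_b <- !dead & runif(n_rois) < p_b
      amp_b <- ifelse(resp_b,
                      pmax(0.05, rnorm(n_rois,
                                       drug_b$amplitude_mean %||% amplitude_mean,
                                       amplitude_sd)), 0)
    }

    traces <- map(seq_len(n_rois), function(i) {
      f <- background_f + baseline_f +
        amp[i] * kcl_amp[i] * ca_kernel(t - drug_window[1]) +
        kcl_amp[i] * ca_kernel(t - kcl_window[1]) +
        rnorm(length(t), 0, noise_sd * max(kcl_amp[i], 1e-12))
      if (!is.null(drug_b)) {
        f <- f + amp_b[i] * kcl_amp[i] * ca_kernel(t - drug_b$window[1])
      }
      tibble(roi_id = roi_ids[i], time_s = t, f = f)
    }) %>% list_rbind()

    truth <- tibble(roi_id = roi_ids, dead = dead, responder = responder,
                    amplitude = amp, soma_area_um2 = soma, reporter = reporter)
    if (!is.null(drug_b)) {
      truth[[paste0("responder_", drug_b$label)]] <- resp_b
      truth[[paste0("amplitude_", drug_b$label)]] <- amp_b
    }

    list(traces = traces,
         rois = tibble(roi_id = roi_ids, soma_area_um2 = soma,
                       reporter = reporter),
         windows = windows,
         frame_rate_hz = frame_rate_hz,
         background_f = background_f,
         truth = truth)
  })
}

# Biphasic difference-of-Gaussians spike template, scaled to unit positive
# peak; total duration about 2 ms.
spike_template <- function(fs_hz, width_ms = 2, lobe_sd_ms = 0.15,
                           lobe_sep_ms = 0.3) {
  half <- round(width_ms / 2 * fs_hz / 1000)
  t_ms <- (seq(-half, half)) * 1000 / fs_hz
  # dominant positive phase followed by a smaller repolarising phase, as in
  # extracellular field potentials; the asymmetry keeps peak alignment stable
  w <- exp(-(t_ms + lobe_sep_ms / 2)^2 / (2 * lobe_sd_ms^2)) -
    0.6 * exp(-(t_ms - lobe_sep_ms / 2)^2 / (2 * lobe_sd_ms^2))
  # roll so the positive peak sits at the centre sample: the planted event
  # time then coincides with the detected absolute peak
  shift <- (half + 1) - which.max(w)
  w <- c(rep(0, max(0, shift)), w, rep(0, max(0, -shift)))
  w <- w[seq_len(2 * half + 1) + max(0, -shift)]
  w / max(w)
}

#' Simulate an extracellular afferent nerve recording
#'
#' Builds a single-channel voltage record as a sum of biphasic
#' difference-of-Gaussians spike templates (about 2 ms long, dominant positive
#' phase) placed at Poisson event times, plus white Gaussian noise of stated
#' RMS. Each unit fires at its
#' baseline rate outside the drug window and at its drug rate inside it, and
#' may carry an extra distension-evoked rate applied whenever the optional
#' luminal pressure channel exceeds a threshold.
#'
#' @param duration_s Record length (s).
#' @param fs_hz Sampling rate (default 20 kHz; must be >= 10 kHz).
#' @param units Tibble with one row per unit: `amplitude_uv` (positive peak of
#'   the template), `baseline_rate_hz`, and optionally `drug_rate_hz`
#'   (defaults to baseline) and `distension_rate_hz` (extra rate above the
#'   pressure threshold, default 0).
#' @param noise_uv RMS of the additive Gaussian noise (uV).
#' @param drug_window Numeric `c(start_s, end_s)` or NULL.
#' @param pressure Optional tibble `time_s`, `pressure_mmhg` sampled at any
#'   rate; linearly interpolated onto the voltage clock.
#' @param pressure_threshold_mmhg Pressure above which `distension_rate_hz`
#'   applies (default 20 mm Hg).
#' @param seed Integer seed.
#' @return A list with `recording` (list: `voltage_uv`, `fs_hz`,
#'   `pressure_mmhg` or NULL, `drug_window`) and `truth` (tibble `unit`,
#'   `time_s` of every planted event, plus a `detectable` flag per unit marking
#'   amplitudes at or below twice the noise RMS).
#' @export
simulate_recording <- function(duration_s = 120,
                               fs_hz = 20000,
                               units = tibble(amplitude_uv = 150,
                                              baseline_rate_hz = 1),
                               noise_uv = 15,
                               drug_window = NULL,
                               pressure = NULL,
                               pressure_threshold_mmhg = 20,
                               seed = 1) {
  if (fs_hz < 10000) abort("fs_hz must be at least 10 kHz")
  stopifnot(nrow(units) >= 1)
  if (!"drug_rate_hz" %in% names(units)) {
    units$drug_rate_hz <- units$baseline_rate_hz
  }
  if (!"distension_rate_hz" %in% names(units)) units$distension_rate_hz <- 0

  with_seed(seed, {
    n <- round(duration_s * fs_hz)
    v <- rnorm(n, 0, noise_uv)
    tmpl <- spike_template(fs_hz)
    half <- (length(tmpl) - 1) / 2

    p_on_clock <- NULL
    if (!is.null(pressure)) {
      p_on_clock <- approxfun(pressure$time_s, pressure$pressure_mmhg,
                              rule = 2)((seq_len(n) - 1) / fs_hz)
    }

    events <- map(seq_len(nrow(units)), function(u) {
      spec <- units[u, ]
      # thinning: simulate at the max instantaneous rate, keep by local rate
      rmax <- max(spec$baseline_rate_hz, spec$drug_rate_hz) +
        max(spec$distension_rate_hz, 0)
      if (rmax <= 0) return(tibble(unit = integer(), time_s = numeric()))
      n_ev <- rpois(1, rmax * duration_s)
      tt <- sort(runif(n_ev, 0, duration_s))
      rate <- rep(spec$baseline_rate_hz, length(tt))
      if (!is.null(drug_window)) {
        in_drug <- tt >= drug_window[1] & tt <= drug_window[2]
        rate[in_drug] <- spec$drug_rate_hz
      }
      if (!is.null(p_on_clock) && spec$distension_rate_hz > 0) {
        idx <- pmin(n, pmax(1, round(tt * fs_hz) + 1))
        rate <- rate + spec$distension_rate_hz *
          (p_on_clock[idx] > pressure_threshold_mmhg)
      }
      keep <- runif(length(tt)) < rate / rmax
      tibble(unit = u, time_s = tt[keep])
    }) %>% list_rbind()

    # enforce a refractory gap within each unit so planted trains are valid
    events <- events %>% group_by(.data$unit) %>%
      filter(c(TRUE, diff(.data$time_s) > 0.002)) %>% ungroup()

    for (i in seq_len(nrow(events))) {
      c0 <- round(events$time_s[i] * fs_hz) + 1
      idx <- (c0 - half):(c0 + half)
      ok <- idx >= 1 & idx <= n
      amp <- units$amplitude_uv[events$unit[i]]
      v[idx[ok]] <- v[idx[ok]] + amp * tmpl[ok]
    }

    truth <- events %>% arrange(.data$unit, .data$time_s) %>%
      left_join(tibble(unit = seq_len(nrow(units)),
                       detectable = units$amplitude_uv > 2 * noise_uv),
                by = "unit")
    if (any(!truth$detectable) || any(units$amplitude_uv <= 2 * noise_uv)) {
      warn("some units have amplitude at or below twice the noise RMS")
    }

    list(recording = list(voltage_uv = v, fs_hz = fs_hz,
                          pressure_mmhg = p_on_clock,
                          drug_window = drug_window),
         truth = truth)
  })
}

#' Simulate a two-channel immunocytochemistry micrograph
#'
#' Places disk-shaped cells in a frame: `n_green` neurons visible in both the
#' neuronal-marker (green) channel and, through a smaller nucleus, the nuclear
#' (blue) channel; `n_blue_only` non-neuronal cells visible only in blue.
#' Intensities are well separated from background and quantised to 8 bits.
#'
#' @param n_green Number of marker-positive (neuronal) cells.
#' @param n_blue_only Number of nuclear-only (non-neuronal) cells.
#' @param image_shape `c(rows, cols)` of the 8-bit frame.
#' @param radius_range Range of cell radii in pixels.
#' @param min_gap_px Minimum gap between object borders; negative values allow
#'   controlled overlap (touching pairs) to exercise watershed splitting.
#' @param fg_mean,bg_mean Foreground / background mean intensities (8-bit).
#' @param noise_sd Gaussian intensity noise SD before quantisation.
#' @param seed Integer seed.
#' @return A list with `green` and `blue` (integer matrices in 0..255) and
#'   `truth` (tibble `x`, `y`, `radius_px`, `type` in `"neuron"`/`"other"`,
#'   plus the planted `neuron_fraction`).
#' @export
simulate_micrograph <- function(n_green = 10,
                                n_blue_only = 40,
                                image_shape = c(512, 512),
                                radius_range = c(8, 14),
                                min_gap_px = 2,
                                fg_mean = 180,
                                bg_mean = 20,
                                noise_sd = 6,
                                seed = 1) {
  n_total <- n_green + n_blue_only
  with_seed(seed, {
    centres <- matrix(numeric(0), ncol = 3)
    attempts <- 0
    while (nrow(centres) < n_total) {
      attempts <- attempts + 1
      if (attempts > 20000) abort("could not place all objects: packing infeasible")
      r <- runif(1, radius_range[1], radius_range[2])
      x <- runif(1, r + 1, image_shape[1] - r - 1)
      y <- runif(1, r + 1, image_shape[2] - r - 1)
      if (nrow(centres) > 0) {
        d <- sqrt((centres[, 1] - x)^2 + (centres[, 2] - y)^2)
        if (any(d < centres[, 3] + r + min_gap_px)) next
      }
      centres <- rbind(centres, c(x, y, r))
    }
    type <- rep(c("neuron", "other"), c(n_green, n_blue_only))

    xg <- matrix(rep(seq_len(image_shape[1]), image_shape[2]),
                 nrow = image_shape[1])
    yg <- matrix(rep(seq_len(image_shape[2]), each = image_shape[1]),
                 nrow = image_shape[1])
    paint <- function(idx, shrink = 1) {
      img <- matrix(0, image_shape[1], image_shape[2])
      for (i in idx) {
        mask <- (xg - centres[i, 1])^2 + (yg - centres[i, 2])^2 <=
          (centres[i, 3] * shrink)^2
        img[mask] <- 1
      }
      img
    }
    quantise <- function(mask) {
      raw <- bg_mean + (fg_mean - bg_mean) * mask +
        rnorm(length(mask), 0, noise_sd)
      m <- matrix(pmin(255, pmax(0, round(raw))), nrow = nrow(mask))
      storage.mode(m) <- "integer"
      m
    }
    green <- quantise(paint(which(type == "neuron")))
    # every neuron has a nucleus (smaller disk); non-neuronal cells blue only
    blue <- quantise(pmax(paint(which(type == "neuron"), shrink = 0.6),
                          paint(which(type == "other"))))

    list(green = green, blue = blue,
         truth = tibble(x = centres[, 1], y = centres[, 2],
                        radius_px = centres[, 3], type = type,
                        neuron_fraction = n_green / n_total))
  })
}
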