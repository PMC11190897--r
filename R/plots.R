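# ggplot2 figure helpers for each result type.

#' Volcano plot of a differential-expression table
#'
#' @param de A `noci_de` tibble.
#' @param alpha FDR cutoff used to colour genes (default 1e-4).
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, alpha = 1e-4) {
  de <- mutate(de, status = dplyr::case_when(
    .data$fdr <= alpha & .data$log2_fc > 0 ~ "up",
    .data$fdr <= alpha & .data$log2_fc < 0 ~ "down",
    TRUE ~ "ns"))
  ggplot2::ggplot(de, ggplot2::aes(.data$log2_fc, -log10(.data$p_value),
                                   colour = .data$status)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(up = "#2166ac", down = "#ef8a62",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bubble plot of enrichment results
#'
#' Terms against odds ratio, sized by overlap and coloured by combined score,
#' mirroring the usual enrichment bubble-plot layout.
#'
#' @param enr A `noci_enrichment` tibble (with `combined_score`).
#' @param top Number of top terms to show (default 20).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enr, top = 20) {
  d <- head(arrange(enr, desc(.data$combined_score)), top)
  d$term <- factor(d$term, levels = rev(d$term))
  ggplot2::ggplot(d, ggplot2::aes(.data$odds_ratio, .data$term,
                                  size = .data$k,
                                  colour = .data$combined_score)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = "odds ratio", y = NULL, size = "overlap",
                  colour = "combined\nscore") +
    ggplot2::theme_minimal()
}

#' Mediator prioritization scatter
#'
#' Fold change against receptor coverage for each candidate mediator, the
#' screen's headline figure: strong candidates sit top-right (high fold
#' change, receptors on a large fraction of afferents).
#'
#' @param pri A `noci_prioritization` tibble.
#' @param min_coverage Coverage cutoff drawn as a dashed rule (default 0.10).
#' @return A ggplot object.
#' @export
plot_prioritization <- function(pri, min_coverage = 0.10) {
  ggplot2::ggplot(pri, ggplot2::aes(.data$coverage, .data$fold_change,
                                    colour = .data$selected)) +
    ggplot2::geom_vline(xintercept = min_coverage, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$mediator),
                       vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "receptor coverage (fraction of neurons)",
                  y = "fold change (case / control)", colour = "selected") +
    ggplot2::theme_minimal()
}

#' Plot normalized fluorescence traces
#'
#' @param norm Output of [normalize_traces()].
#' @param rois Optional ROI ids to display (default: first 10).
#' @param threshold Responder criterion drawn as a dashed rule (default 0.1).
#' @return A ggplot object.
#' @export
plot_traces <- function(norm, rois = NULL, threshold = 0.1) {
  rois <- rois %||% head(unique(norm$roi_id), 10)
  d <- filter(norm, .data$roi_id %in% rois)
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$f_norm,
                                  group = .data$roi_id)) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "time (s)", y = "F/F_pos") +
    ggplot2::theme_minimal()
}

#' Plot a firing-rate histogram with its smoothed trace
#'
#' @param pc A `noci_peak_change` object.
#' @param drug_onset_s Optional drug onset drawn as a vertical rule.
#' @return A ggplot object.
#' @export
plot_rate_histogram <- function(pc, drug_onset_s = NULL) {
  p <- ggplot2::ggplot(pc$rates, ggplot2::aes(.data$time_s, .data$rate_hz)) +
    ggplot2::geom_col(width = 1, fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$rate_smooth_hz),
                       colour = "#2166ac") +
    ggplot2::labs(x = "time (s)", y = "firing rate (spikes/s)") +
    ggplot2::theme_minimal()
  if (!is.null(drug_onset_s)) {
    p <- p + ggplot2::geom_vline(xintercept = drug_onset_s,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.noci_de <- function(object, ...) plot_volcano(object, ...)

#' @exportS3Method ggplot2::autoplot
autoplot.noci_prioritization <- function(object, ...) {
  plot_prioritization(object, ...)
}

#' @exportS3Method ggplot2::autoplot
autoplot.noci_peak_change <- function(object, ...) {
  plot_rate_histogram(object, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
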