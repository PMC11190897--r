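# broom-style tidiers for the package's fitted/estimated objects.

#' Tidy a dispersion estimate
#'
#' @param x A `noci_dispersion` object.
#' @param ... Unused.
#' @return Tibble `gene_id`, `dispersion`.
#' @exportS3Method generics::tidy
tidy.noci_dispersion <- function(x, ...) x$tagwise

#' One-row summary of a dispersion estimate
#'
#' @param x A `noci_dispersion` object.
#' @param ... Unused.
#' @return Tibble `common_dispersion`, `prior_df`, `n_genes`,
#'   `median_tagwise`.
#' @exportS3Method generics::glance
glance.noci_dispersion <- function(x, ...) {
  tibble(common_dispersion = x$common, prior_df = x$prior_df,
         n_genes = nrow(x$tagwise),
         median_tagwise = median(x$tagwise$dispersion))
}

#' Tidy a peak-change result
#'
#' @param x A `noci_peak_change` object.
#' @param ... Unused.
#' @return The binned/smoothed rate tibble.
#' @exportS3Method generics::tidy
tidy.noci_peak_change <- function(x, ...) x$rates

#' One-row summary of a peak-change result
#'
#' @param x A `noci_peak_change` object.
#' @param ... Unused.
#' @return Tibble `baseline_hz`, `peak_hz`, `delta_hz`, `percent_change`.
#' @exportS3Method generics::glance
glance.noci_peak_change <- function(x, ...) x$summary

#' Tidy a concentration-response summary
#'
#' @param x A `noci_conc_response` object.
#' @param ... Unused.
#' @return Per-concentration summary tibble.
#' @exportS3Method generics::tidy
tidy.noci_conc_response <- function(x, ...) x$summary

#' One-row summary of a concentration-response fit
#'
#' @param x A `noci_conc_response` object.
#' @param ... Unused.
#' @return Tibble with `n_concentrations` and, when a Hill fit is present,
#'   `emax`, `ec50`, `slope`.
#' @exportS3Method generics::glance
glance.noci_conc_response <- function(x, ...) {
  out <- tibble(n_concentrations = nrow(x$summary))
  if (!is.null(x$hill_fit)) {
    out$emax <- x$hill_fit$emax
    out$ec50 <- x$hill_fit$ec50
    out$slope <- x$hill_fit$slope
  }
  out
}

#' Tidy a unit assignment
#'
#' @param x A `noci_units` object.
#' @param ... Unused.
#' @return Event tibble with unit labels.
#' @exportS3Method generics::tidy
tidy.noci_units <- function(x, ...) x$events

#' One-row summary of a unit assignment
#'
#' @param x A `noci_units` object.
#' @param ... Unused.
#' @return Tibble `n_events`, `n_units`.
#' @exportS3Method generics::glance
glance.noci_units <- function(x, ...) {
  tibble(n_events = nrow(x$events), n_units = x$n_units)
}

#' Tidy a segmentation result
#'
#' @param x A `noci_segmentation` object.
#' @param ... Unused.
#' @return Per-object area tibble.
#' @exportS3Method generics::tidy
tidy.noci_segmentation <- function(x, ...) x$areas

#' One-row summary of a segmentation result
#'
#' @param x A `noci_segmentation` object.
#' @param ... Unused.
#' @return Tibble `count`, `median_area_px`.
#' @exportS3Method generics::glance
glance.noci_segmentation <- function(x, ...) {
  tibble(count = x$count,
         median_area_px = if (x$count > 0) median(x$areas$area_px) else NA_real_)
}

#' Tidy a cosensitivity table
#'
#' @param x A `noci_cosensitivity` object.
#' @param ... Unused.
#' @return The population-count tibble.
#' @exportS3Method generics::tidy
tidy.noci_cosensitivity <- function(x, ...) x$counts

#' One-row summary of a cosensitivity table
#'
#' @param x A `noci_cosensitivity` object.
#' @param ... Unused.
#' @return Tibble `n`, `b_given_a`, `a_given_b`.
#' @exportS3Method generics::glance
glance.noci_cosensitivity <- function(x, ...) {
  tibble(n = x$n,
         b_given_a = x$conditional$fraction[1],
         a_given_b = x$conditional$fraction[2])
}

#' Tidy a group comparison
#'
#' @param x A `noci_comparison` object.
#' @param ... Unused.
#' @return The post-hoc pairwise table when present, otherwise the one-row
#'   test summary.
#' @exportS3Method generics::tidy
tidy.noci_comparison <- function(x, ...) {
  if (!is.null(x$posthoc[[1]])) x$posthoc[[1]]
  else select(as_tibble(x), "design", "test_used", "statistic", "p_value")
}

#' One-row summary of a group comparison
#'
#' @param x A `noci_comparison` object.
#' @param ... Unused.
#' @return Tibble `design`, `test_used`, `statistic`, `p_value`,
#'   `variance_p`.
#' @exportS3Method generics::glance
glance.noci_comparison <- function(x, ...) {
  select(as_tibble(x), "design", "test_used", "statistic", "p_value",
         "variance_p")
}
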