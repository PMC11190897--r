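# Immunocytochemistry cell counting: minimum-error (Kittler-Illingworth)
# thresholding of 8-bit channel images, watershed separation of touching
# objects, object counting and the neuron / (neuron + non-neuron) ratio.
# Images are plain numeric matrices with values in 0..255.

check_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img)) abort("image must be a numeric matrix")
  if (any(img < 0 | img > 255)) abort("image values must lie in 0..255")
  invisible(img)
}

#' Minimum-error (Kittler-Illingworth) threshold of an 8-bit image
#'
#' Models the intensity histogram as a mixture of two Gaussians split at a
#' candidate threshold t and minimizes the classification-error criterion
#' `J(t) = 1 + 2 [P1 ln s1 + P2 ln s2] - 2 [P1 ln P1 + P2 ln P2]`,
#' where P, s are the weight and standard deviation of each side. The search
#' is exhaustive over t in 0..254 (a pixel is foreground when its value is
#' strictly greater than t); candidates leaving either side empty are skipped
#' and ties break toward the lower threshold.
#'
#' @param img Numeric matrix with values in 0..255.
#' @return Integer threshold level.
#' @examples
#' img <- matrix(c(rep(20, 50), rep(200, 50)), 10, 10)
#' min_error_threshold(img)
#' @export
min_error_threshold <- function(img) {
  check_image(img)
  h <- tabulate(as.integer(round(img)) + 1L, nbins = 256)
  if (sum(h > 0) < 2) abort("image has fewer than two distinct intensity levels")
  lev <- 0:255
  n <- sum(h)
  csum <- cumsum(h)
  cmean <- cumsum(h * lev)
  csq <- cumsum(h * lev^2)

  best_t <- NA_integer_
  best_j <- Inf
  for (t in 0:254) {
    n1 <- csum[t + 1]; n2 <- n - n1
    if (n1 == 0 || n2 == 0) next
    p1 <- n1 / n; p2 <- n2 / n
    m1 <- cmean[t + 1] / n1
    m2 <- (cmean[256] - cmean[t + 1]) / n2
    v1 <- csq[t + 1] / n1 - m1^2
    v2 <- (csq[256] - csq[t + 1]) / n2 - m2^2
    # variance floor keeps degenerate single-level classes finite
    v1 <- max(v1, 1e-2); v2 <- max(v2, 1e-2)
    j <- 1 + 2 * (p1 * log(sqrt(v1)) + p2 * log(sqrt(v2))) -
      2 * (p1 * log(p1) + p2 * log(p2))
    if (j < best_j - 1e-12) {
      best_j <- j
      best_t <- t
    }
  }
  if (is.na(best_t)) abort("no admissible threshold found")
  as.integer(best_t)
}

#' Segment a binary image into objects with watershed splitting
#'
#' Labels connected foreground components, separates touching objects with a
#' distance-transform watershed, and discards components smaller than
#' `min_area_px`.
#'
#' @param binary Logical or 0/1 numeric matrix (foreground TRUE/1).
#' @param min_area_px Minimum object area in pixels (default 30).
#' @param watershed_tolerance Minimum depth between catchment basins before
#'   they are split (passed to the watershed; default 1).
#' @return A list of class `noci_segmentation`: `labels` (integer matrix with
#'   objects numbered 1..count), `count`, `areas` (tibble `object`,
#'   `area_px`).
#' @export
segment_objects <- function(binary, min_area_px = 30,
                            watershed_tolerance = 1) {
  if (is.logical(binary)) binary <- binary * 1
  if (!all(binary %in% c(0, 1))) abort("expected a binary image")
  if (sum(binary) == 0) {
    return(structure(list(labels = matrix(0L, nrow(binary), ncol(binary)),
                          count = 0L,
                          areas = tibble(object = integer(),
                                         area_px = integer())),
                     class = "noci_segmentation"))
  }
  dm <- EBImage::distmap(binary)
  ws <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1)
  lab <- EBImage::imageData(ws)
  sizes <- table(lab[lab > 0])
  keep <- as.integer(names(sizes)[sizes >= min_area_px])
  lab[!(lab %in% keep)] <- 0L
  relabel <- match(lab, c(0L, sort(keep))) - 1L
  lab <- matrix(as.integer(relabel), nrow(binary), ncol(binary))
  areas <- tibble(object = sort(unique(lab[lab > 0])))
  areas$area_px <- as.integer(table(lab[lab > 0]))
  structure(list(labels = lab, count = length(keep), areas = areas),
            class = "noci_segmentation")
}

#' @export
print.noci_segmentation <- function(x, ...) {
  cat("Segmentation:", x$count, "object(s)")
  if (x$count > 0) cat(", median area", median(x$areas$area_px), "px")
  cat("\n")
  invisible(x)
}

#' Neuron fraction from marker and nuclear segmentations
#'
#' Ratio of neuronal-marker-positive objects to nuclear-stain-positive objects
#' (neurons plus non-neuronal cells). A ratio above 1 (marker count exceeding
#' the nuclear count, e.g. through segmentation error) is reported with a
#' `clipped` flag.
#'
#' @param marker_seg,nuclear_seg `noci_segmentation` objects for the
#'   neuronal-marker and nuclear channels.
#' @return One-row tibble: `n_neurons`, `n_nuclei`, `ratio`, `clipped`.
#' @export
neuron_fraction <- function(marker_seg, nuclear_seg) {
  if (nuclear_seg$count == 0) abort("no nuclear objects: ratio undefined")
  r <- marker_seg$count / nuclear_seg$count
  tibble(n_neurons = marker_seg$count, n_nuclei = nuclear_seg$count,
         ratio = r, clipped = r > 1)
}

#' Count cells in a two-channel micrograph
#'
#' Full per-image pipeline: minimum-error threshold of each channel, watershed
#' segmentation, object counting and the neuron/(neuron + non-neuron) ratio.
#'
#' @param green,blue 8-bit matrices for the neuronal-marker and nuclear
#'   channels.
#' @param min_area_px Minimum object area (default 30 px).
#' @param threshold_green,threshold_blue Optional manual threshold overrides.
#' @return One-row tibble: `threshold_green`, `threshold_blue`, `n_neurons`,
#'   `n_nuclei`, `ratio`, `clipped`.
#' @examples
#' sim <- simulate_micrograph(n_green = 4, n_blue_only = 8,
#'                            image_shape = c(128, 128), seed = 1)
#' count_cells(sim$green, sim$blue)
#' @export
count_cells <- function(green, blue, min_area_px = 30,
                        threshold_green = NULL, threshold_blue = NULL) {
  tg <- threshold_green %||% min_error_threshold(green)
  tb <- threshold_blue %||% min_error_threshold(blue)
  seg_g <- segment_objects(green > tg, min_area_px)
  seg_b <- segment_objects(blue > tb, min_area_px)
  bind_cols(tibble(threshold_green = tg, threshold_blue = tb),
            neuron_fraction(seg_g, seg_b))
}
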