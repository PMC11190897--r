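# Plain-text I/O for every data kind the pipeline consumes or emits. Counts
# and expression matrices travel as TSV (genes in rows, samples/cells in
# columns, first column gene_id); traces and recordings as long CSV; images
# as PNG (via the png package) or plain TSV of integer intensities.

#' Read a counts or expression matrix from TSV
#'
#' @param path TSV with a `gene_id` first column and one column per sample.
#' @return A wide tibble.
#' @export
read_counts_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write a counts or expression matrix to TSV
#'
#' @param counts Wide tibble (`gene_id` + samples).
#' @param path Output path.
#' @export
write_counts_tsv <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Read sample group labels from TSV
#'
#' @param path TSV with columns `sample_id`, `group`.
#' @return A tibble.
#' @export
read_groups_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' Read a trace set from CSV
#'
#' @param traces_path Long CSV `roi_id`, `time_s`, `f`.
#' @param windows_path CSV `label`, `start_s`, `end_s`.
#' @param rois_path Optional CSV `roi_id`, `soma_area_um2`, `reporter`.
#' @return A list with `traces`, `windows` and optionally `rois`.
#' @export
read_trace_set_csv <- function(traces_path, windows_path, rois_path = NULL) {
  out <- list(traces = readr::read_csv(traces_path, show_col_types = FALSE),
              windows = readr::read_csv(windows_path, show_col_types = FALSE))
  if (!is.null(rois_path)) {
    out$rois <- readr::read_csv(rois_path, show_col_types = FALSE)
  }
  out
}

#' Write a trace set to CSV
#'
#' @param trace_set A list as produced by [simulate_trace_set()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_trace_set_csv <- function(trace_set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(trace_set$traces, file.path(dir, "traces.csv"))
  readr::write_csv(trace_set$windows, file.path(dir, "windows.csv"))
  if (!is.null(trace_set$rois)) {
    readr::write_csv(trace_set$rois, file.path(dir, "rois.csv"))
  }
  invisible(dir)
}

#' Read a recording from CSV
#'
#' @param path CSV with columns `voltage_uv` and optionally `pressure_mmhg`.
#' @param fs_hz Sampling rate.
#' @param drug_window Optional `c(start_s, end_s)`.
#' @return A recording list.
#' @export
read_recording_csv <- function(path, fs_hz, drug_window = NULL) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  list(voltage_uv = d$voltage_uv, fs_hz = fs_hz,
       pressure_mmhg = if ("pressure_mmhg" %in% names(d)) d$pressure_mmhg,
       drug_window = drug_window)
}

#' Write a recording to CSV
#'
#' @param rec A recording list.
#' @param path Output path.
#' @export
write_recording_csv <- function(rec, path) {
  d <- tibble(voltage_uv = rec$voltage_uv)
  if (!is.null(rec$pressure_mmhg)) d$pressure_mmhg <- rec$pressure_mmhg
  readr::write_csv(d, path)
  invisible(path)
}

#' Read an 8-bit channel image
#'
#' PNG files are read through the png package (grayscale or first channel);
#' TSV files are read as integer matrices.
#'
#' @param path Image path (`.png` or `.tsv`).
#' @return Numeric matrix in 0..255.
#' @export
read_channel_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      abort("reading PNG requires the png package")
    }
    a <- png::readPNG(path)
    if (length(dim(a)) == 3) a <- a[, , 1]
    round(a * 255)
  } else {
    as.matrix(utils::read.table(path, sep = "\t"))
  }
}

#' Write an 8-bit channel image
#'
#' @param img Numeric matrix in 0..255.
#' @param path Output path (`.png` or `.tsv`).
#' @export
write_channel_image <- function(img, path) {
  check_image(img)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      abort("writing PNG requires the png package")
    }
    png::writePNG(img / 255, path)
  } else {
    utils::write.table(img, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Read a mediator-receptor map from TSV
#'
#' @param path TSV with columns `mediator`, `receptor` (one row per pair).
#' @return A tibble.
#' @export
read_mediator_map <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
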