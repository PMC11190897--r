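# Shared fixtures built in code.

# Tiny wide counts tibble from a plain matrix.
counts_tbl <- function(m, genes = NULL, samples = NULL) {
  genes <- genes %||% rownames(m) %||% sprintf("g%02d", seq_len(nrow(m)))
  samples <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(gene_id = genes), out)
}

groups_tbl <- function(samples, groups) {
  tibble::tibble(sample_id = samples, group = groups)
}

`%||%` <- rlang::`%||%`

# A deterministic three-term gene-set library over a small universe.
toy_library <- function() {
  tibble::tibble(
    term = c("setA", "setB", "setC"),
    description = "",
    genes = list(sprintf("g%03d", 1:10),
                 sprintf("g%03d", 8:25),
                 sprintf("g%03d", 30:45)))
}

toy_universe <- function() sprintf("g%03d", 1:60)

# Single-ROI trace tibble from a numeric vector at a given frame rate.
trace_tbl <- function(f, frame_rate = 2.5, roi = "roi1") {
  tibble::tibble(roi_id = roi,
                 time_s = seq(0, by = 1 / frame_rate,
                              length.out = length(f)),
                 f = f)
}
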