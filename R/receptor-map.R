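# Mediator -> receptor prioritization: fold changes of secreted mediators in
# the bulk groups, receptor coverage and nociceptor-marker coexpression in a
# single-neuron expression matrix, and the combined screen that selects
# mediators whose receptors reach enough of the afferent population.

#' Fold change of one gene between two sample groups
#'
#' Ratio of group mean expression (RPKM or CPM scale), case over control.
#' A zero control mean yields `Inf` with an `infinite` flag rather than an
#' error.
#'
#' @param expr Wide expression tibble (`gene_id` plus one column per sample);
#'   any normalized scale (RPKM/CPM) is acceptable.
#' @param groups Tibble `sample_id`, `group`.
#' @param gene Gene identifier to summarise.
#' @param group_a,group_b Case and control group labels.
#' @return One-row tibble: `gene`, `mean_a`, `mean_b`, `fold_change`,
#'   `infinite`.
#' @examples
#' expr <- tibble::tibble(gene_id = "Agt",
#'                        uc1 = 10.83, uc2 = 10.83, ctrl1 = 1.42, ctrl2 = 1.42)
#' groups <- tibble::tibble(sample_id = c("uc1", "uc2", "ctrl1", "ctrl2"),
#'                          group = c("UC", "UC", "control", "control"))
#' group_fold_change(expr, groups, "Agt", "UC", "control")
#' @export
group_fold_change <- function(expr, groups, gene, group_a, group_b) {
  m <- wide_to_matrix(expr)
  if (!gene %in% rownames(m)) abort(paste("gene not found:", gene))
  grp <- check_groups(groups, colnames(m))
  mean_a <- mean(m[gene, grp == group_a])
  mean_b <- mean(m[gene, grp == group_b])
  if (!is.finite(mean_a) || !is.finite(mean_b)) abort("undefined group mean")
  fc <- if (mean_b > 0) mean_a / mean_b else Inf
  tibble(gene = gene, mean_a = mean_a, mean_b = mean_b,
         fold_change = fc, infinite = !is.finite(fc))
}

# Logical matrix of cells positive for ANY of `genes` above the TPM threshold.
any_positive <- function(m, genes, tpm_threshold) {
  missing <- setdiff(genes, rownames(m))
  if (length(missing) > 0) {
    abort(paste("receptor gene(s) absent from the matrix:",
                paste(missing, collapse = ", ")))
  }
  sub <- m[genes, , drop = FALSE]
  colSums(sub > tpm_threshold) > 0
}

#' Fraction of cells expressing any of a list of receptors
#'
#' A cell counts as covered if ANY listed receptor exceeds the TPM threshold,
#' matching the "expresses Agtr1a and/or Agtr1b" convention.
#'
#' @param cells Wide TPM tibble (`gene_id` plus one column per cell).
#' @param receptors Character vector of receptor genes (all must be present).
#' @param tpm_threshold Expression threshold; a cell is positive when
#'   TPM is strictly greater than this value (default 0).
#' @return One-row tibble: `n_positive`, `n_total`, `fraction`.
#' @export
receptor_coverage <- function(cells, receptors, tpm_threshold = 0) {
  m <- wide_to_matrix(cells)
  if (ncol(m) == 0) abort("empty expression matrix")
  pos <- any_positive(m, receptors, tpm_threshold)
  tibble(n_positive = sum(pos), n_total = ncol(m),
         fraction = sum(pos) / ncol(m))
}

#' Marker coexpression among receptor-positive cells
#'
#' Among cells positive for ANY of the base genes, the fraction also positive
#' for the marker gene (e.g. Scn10a or Trpv1 coexpression among
#' Agtr1a/Agtr1b-expressing neurons).
#'
#' @inheritParams receptor_coverage
#' @param base_genes Receptor gene list defining the base population
#'   (ANY semantics).
#' @param marker_gene Single marker gene.
#' @return One-row tibble: `n_base`, `n_coexpressing`, `fraction`.
#' @export
coexpress_fraction <- function(cells, base_genes, marker_gene,
                               tpm_threshold = 0) {
  m <- wide_to_matrix(cells)
  base <- any_positive(m, base_genes, tpm_threshold)
  if (sum(base) == 0) abort("no cells positive for the base genes")
  marker <- any_positive(m, marker_gene, tpm_threshold)
  tibble(n_base = sum(base), n_coexpressing = sum(base & marker),
         fraction = sum(base & marker) / sum(base))
}

#' Prioritize secreted mediators by receptor coverage of sensory neurons
#'
#' For each mediator in the map, reports its differential-expression evidence
#' (log2 fold change, FDR), the fraction of profiled neurons expressing any of
#' its receptors, and marker coexpression among receptor-positive cells. A
#' mediator is `selected` when it is significantly upregulated and its
#' receptor coverage is at least `min_coverage` (default 0.10; candidates whose
#' receptors reach fewer than 10% of afferents are screened out). The table is
#' sorted by coverage, then fold change, both descending.
#'
#' @param de A `noci_de` tibble from [nb_exact_test()] or [run_de()].
#' @param map Tibble `mediator`, `receptor`, one row per pair (a mediator's
#'   receptors are combined with ANY semantics). Mediators missing from the DE
#'   table are skipped with a message.
#' @inheritParams receptor_coverage
#' @param markers Marker genes for coexpression columns (default Scn10a,
#'   Trpv1); markers absent from the matrix are skipped.
#' @param alpha Significance cutoff on the DE evidence (default 1e-4).
#' @param use_fdr Apply `alpha` to the BH-adjusted p (default TRUE); set to
#'   FALSE to gate on the raw p-value instead.
#' @param min_coverage Minimum receptor coverage to keep a mediator
#'   (default 0.10, kept when coverage >= this value).
#' @return A tibble of class `noci_prioritization`: `mediator`, `receptors`,
#'   `log2_fc`, `fold_change`, `fdr`, `coverage`, one `coexpr_<marker>`
#'   column per marker, `significant`, `selected`.
#' @export
prioritize_mediators <- function(de, map, cells, tpm_threshold = 0,
                                 markers = c("Scn10a", "Trpv1"),
                                 alpha = 1e-4, use_fdr = TRUE,
                                 min_coverage = 0.10) {
  if (nrow(map) == 0) abort("empty mediator-receptor map")
  stopifnot(all(c("mediator", "receptor") %in% names(map)))
  m <- wide_to_matrix(cells)
  markers <- intersect(markers, rownames(m))

  res <- purrr::map(unique(map$mediator), function(med) {
    if (!med %in% de$gene_id) {
      inform(paste("mediator not in DE table, skipped:", med))
      return(NULL)
    }
    receptors <- map$receptor[map$mediator == med]
    cov <- receptor_coverage(cells, receptors, tpm_threshold)
    row <- de[de$gene_id == med, ]
    out <- tibble(mediator = med,
                  receptors = paste(receptors, collapse = ";"),
                  log2_fc = row$log2_fc,
                  fold_change = 2^row$log2_fc,
                  p_value = row$p_value,
                  fdr = row$fdr,
                  coverage = cov$fraction)
    for (mk in markers) {
      frac <- if (cov$n_positive > 0) {
        coexpress_fraction(cells, receptors, mk, tpm_threshold)$fraction
      } else NA_real_
      out[[paste0("coexpr_", mk)]] <- frac
    }
    out
  }) %>% list_rbind()

  gate_p <- if (use_fdr) res$fdr else res$p_value
  res$significant <- gate_p <= alpha & res$log2_fc > 0
  res$selected <- res$significant & res$coverage >= min_coverage
  res <- arrange(res, desc(.data$coverage), desc(.data$fold_change))
  class(res) <- c("noci_prioritization", class(res))
  res
}

#' Receptor coverage at several TPM thresholds
#'
#' Sensitivity report for the "expressing" threshold, which published
#' single-neuron studies leave implicit: coverage of a receptor list at each
#' threshold in `thresholds`.
#'
#' @inheritParams receptor_coverage
#' @param thresholds Numeric vector of TPM thresholds (default 0, 1, 5).
#' @return Tibble `tpm_threshold`, `n_positive`, `n_total`, `fraction`.
#' @export
coverage_sensitivity <- function(cells, receptors, thresholds = c(0, 1, 5)) {
  map(thresholds, function(th) {
    bind_cols(tibble(tpm_threshold = th),
              receptor_coverage(cells, receptors, th))
  }) %>% list_rbind()
}
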