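# Gene-set enrichment of an upregulated gene list: one-sided Fisher exact
# tests over a gene-set library, BH adjustment, a Monte-Carlo z-score for the
# deviation of each term's rank from its permutation expectation, and the
# combined score -ln(p_adj) * z used to stratify enriched terms.

#' Read a gene-set library from a GMT file
#'
#' Standard GMT format: one term per line, tab-separated as
#' `term<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `term`, `description` and a list-column
#'   `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble(term = map_chr(parts, 1),
         description = map_chr(parts, function(p) if (length(p) > 1) p[2] else ""),
         genes = map(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])])))
}

#' Write a gene-set library to a GMT file
#'
#' @param library A tibble as returned by [read_gmt()].
#' @param path Output path.
#' @export
write_gmt <- function(library, path) {
  lines <- pmap(library[c("term", "description", "genes")],
                function(term, description, genes) {
                  paste(c(term, description, genes), collapse = "\t")
                })
  writeLines(unlist(lines), path)
  invisible(path)
}

# Resolve the background universe: all genes in the library plus any
# explicitly supplied background (e.g. every DE-tested gene).
resolve_universe <- function(library, universe) {
  u <- unique(c(unlist(library$genes), universe))
  if (length(u) == 0) abort("empty universe")
  u
}

#' Fisher-exact term enrichment of a query gene set
#'
#' For each term, builds the 2x2 contingency of query membership against term
#' membership over the universe and computes the one-sided (enrichment)
#' Fisher exact p-value, i.e. the upper hypergeometric tail of the overlap.
#' Odds ratios use the Haldane correction (+0.5 on every cell) whenever a
#' denominator cell is zero, so complete overlaps stay finite while zero
#' overlaps report a zero odds ratio. BH adjustment is applied across the terms of the library. Query
#' genes outside the universe are dropped with a message.
#'
#' @param query Character vector of gene symbols (e.g. upregulated genes).
#' @param library Gene-set tibble from [read_gmt()] (columns `term`, `genes`).
#' @param universe Optional extra background genes beyond the union of term
#'   genes (typically all genes tested for differential expression).
#' @return A tibble of class `noci_enrichment` with columns `term`, `k`
#'   (overlap), `K` (term size), `n` (query size), `N` (universe size),
#'   `odds_ratio`, `p_value`, `p_adj`, `overlap_genes` (list-column).
#' @examples
#' lib <- tibble::tibble(term = c("a", "b"), description = "",
#'                       genes = list(c("g1", "g2", "g3"), c("g4", "g5")))
#' term_enrichment(c("g1", "g2"), lib, universe = paste0("g", 1:20))
#' @export
term_enrichment <- function(query, library, universe = NULL) {
  if (length(query) == 0) abort("empty query")
  u <- resolve_universe(library, universe)
  outside <- setdiff(query, u)
  if (length(outside) > 0) {
    inform(paste0("dropping ", length(outside),
                  " query gene(s) outside the universe"))
  }
  q <- intersect(unique(query), u)
  if (length(q) == 0) abort("no query genes inside the universe")
  n <- length(q); N <- length(u)

  res <- map(seq_len(nrow(library)), function(i) {
    genes <- intersect(library$genes[[i]], u)
    K <- length(genes)
    if (K == 0) return(NULL)
    ov <- intersect(q, genes)
    k <- length(ov)
    # one-sided enrichment p: upper tail of the hypergeometric at k
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    cells <- c(k, K - k, n - k, N - K - n + k)
    # Haldane correction only when a denominator cell vanishes, so k = 0
    # still reports a depleted (zero) odds ratio rather than an inflated one
    if (cells[2] == 0 || cells[3] == 0) cells <- cells + 0.5
    or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    tibble(term = library$term[i], k = k, K = K, n = n, N = N,
           odds_ratio = or, p_value = p, overlap_genes = list(ov))
  }) %>% list_rbind()
  res$p_adj <- p.adjust(res$p_value, method = "BH")
  res <- res %>% select("term", "k", "K", "n", "N", "odds_ratio",
                        "p_value", "p_adj", "overlap_genes")
  class(res) <- c("noci_enrichment", class(res))
  res
}

#' Monte-Carlo z-score for the rank deviation of each enriched term
#'
#' Draws `n_permutations` random query sets of the observed size uniformly
#' from the universe, ranks the library's terms by their Fisher p-value in
#' each draw, and standardises the observed rank of each term against its
#' permutation distribution: `z = (mean_perm_rank - observed_rank) / sd`, so
#' a term ranked earlier (better) than expected scores positive.
#'
#' @param observed A `noci_enrichment` tibble from [term_enrichment()].
#' @param library,universe As in [term_enrichment()].
#' @param n_permutations Number of random query draws (>= 100, default 1000).
#' @param seed Integer seed for the permutation draws.
#' @return `observed` with a `z` column appended.
#' @export
rank_zscore <- function(observed, library, universe = NULL,
                        n_permutations = 1000, seed = 1) {
  if (n_permutations < 100) abort("n_permutations must be at least 100")
  u <- resolve_universe(library, universe)
  terms <- observed$term
  if (length(terms) < 2) {
    warn("library has fewer than two terms; z undefined, returning 0")
    observed$z <- 0
    return(observed)
  }
  lib_genes <- map(library$genes[match(terms, library$term)],
                   function(g) intersect(g, u))
  K <- lengths(lib_genes)
  n <- observed$n[1]; N <- length(u)
  obs_rank <- rank(observed$p_value, ties.method = "average")

  rank_sum <- numeric(length(terms))
  rank_sq <- numeric(length(terms))
  # index-based membership for fast overlap counting
  idx <- map(lib_genes, function(g) match(g, u))
  with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      draw <- sample.int(N, n)
      in_draw <- logical(N)
      in_draw[draw] <- TRUE
      k <- map_int(idx, function(i) sum(in_draw[i]))
      p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      r <- rank(p, ties.method = "average")
      rank_sum <- rank_sum + r
      rank_sq <- rank_sq + r^2
    }
  })
  mean_r <- rank_sum / n_permutations
  sd_r <- sqrt(pmax(0, rank_sq / n_permutations - mean_r^2) *
                 n_permutations / (n_permutations - 1))
  observed$z <- (mean_r - obs_rank) / pmax(sd_r, 1e-6)
  observed
}

#' Combined enrichment score
#'
#' The product of the natural logarithm of the BH-adjusted p-value and the
#' rank z-score, signed so that enriched (earlier-than-expected, small-p)
#' terms score positive: `c = -ln(p_adj) * z`. Adjusted p-values are floored
#' at 1e-300.
#'
#' @param p_adj BH-adjusted p-values in (0, 1].
#' @param z Rank z-scores (finite).
#' @return Numeric vector of combined scores.
#' @examples
#' combined_score(0.01, 3)  # ~13.8
#' @export
combined_score <- function(p_adj, z) {
  stopifnot(all(p_adj > 0 | p_adj == 0), all(is.finite(z)))
  -log(pmax(p_adj, 1e-300)) * z
}

#' Full enrichment analysis of a query gene set
#'
#' Chains [term_enrichment()], [rank_zscore()] and [combined_score()] and
#' sorts terms by combined score.
#'
#' @inheritParams rank_zscore
#' @param query Character vector of gene symbols.
#' @return A `noci_enrichment` tibble with `z` and `combined_score` columns.
#' @export
enrich <- function(query, library, universe = NULL, n_permutations = 1000,
                   seed = 1) {
  res <- term_enrichment(query, library, universe)
  res <- rank_zscore(res, library, universe, n_permutations, seed)
  res$combined_score <- combined_score(res$p_adj, res$z)
  arrange(res, desc(.data$combined_score))
}
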