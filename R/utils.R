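# Internal helpers shared across modules.

# Set the RNG state for a generator call without leaking into the caller's
# session. `seed` must stay below 2^31 - 1 (R integers are 32-bit).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive a per-stage seed from a global seed by stable hashing of the stage
# name (polynomial rolling hash, kept below 2^31).
derive_seed <- function(seed, stage) {
  h <- 0
  for (cp in utf8ToInt(stage)) h <- (h * 131 + cp) %% 2147480009
  as.integer((as.numeric(seed) * 7919 + h) %% 2147480009)
}

geometric_mean <- function(x) exp(mean(log(x)))

# Extract the numeric sample matrix from a wide counts/expression tibble whose
# first column holds feature identifiers.
wide_to_matrix <- function(df, id_col = "gene_id") {
  if (!id_col %in% names(df)) {
    abort(paste0("expected an identifier column named '", id_col, "'"))
  }
  ids <- as.character(df[[id_col]])
  if (anyDuplicated(ids)) abort("duplicate feature identifiers")
  m <- as.matrix(df[setdiff(names(df), id_col)])
  if (anyDuplicated(colnames(m))) abort("duplicate sample identifiers")
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

matrix_to_wide <- function(m, id_col = "gene_id") {
  out <- as_tibble(m, .name_repair = "minimal")
  bind_cols(tibble(!!id_col := rownames(m)), out)
}

check_groups <- function(groups, sample_ids) {
  if (!all(c("sample_id", "group") %in% names(groups))) {
    abort("`groups` must have columns sample_id and group")
  }
  missing <- setdiff(sample_ids, groups$sample_id)
  if (length(missing) > 0) {
    abort(paste("samples without group labels:", paste(missing, collapse = ", ")))
  }
  setNames(as.character(groups$group), groups$sample_id)[sample_ids]
}

#' Express a count out of a total as a fraction and percentage
#'
#' Small reporting helper used when summarising classifier output and published
#' cell tallies (e.g. 203 receptor-positive cells of 314 profiled).
#'
#' @param k Number of positives.
#' @param n Total count; must be positive and at least `k`.
#' @return A one-row tibble with columns `k`, `n`, `fraction`, `pct`.
#' @examples
#' count_proportion(203, 314)
#' @export
count_proportion <- function(k, n) {
  stopifnot(n > 0, k >= 0, k <= n)
  tibble(k = k, n = n, fraction = k / n, pct = 100 * k / n)
}
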