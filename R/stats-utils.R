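# Assumption-gated group comparison shared by all stages: Shapiro-Wilk
# normality per group, F-test (or Bartlett for k groups) homogeneity of
# variances, then the appropriate parametric, Welch-corrected or rank-based
# test, with post-hoc tests for k-group designs.

# Dunn's rank-based post-hoc z tests after a Kruskal-Wallis comparison,
# with tie correction and Bonferroni adjustment.
dunn_test <- function(values, groups) {
  n <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  lev <- unique(groups)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  purrr::map(pairs, function(p) {
    i <- groups == p[1]; j <- groups == p[2]
    z <- (mean(r[i]) - mean(r[j])) /
      sqrt((n * (n + 1) / 12 - tie_corr) * (1 / sum(i) + 1 / sum(j)))
    tibble(group_1 = p[1], group_2 = p[2], z = z,
           p_value = 2 * pnorm(-abs(z)))
  }) %>% list_rbind() %>%
    mutate(p_adj = pmin(1, .data$p_value * length(pairs)))
}

#' Compare groups with assumption-gated test selection
#'
#' Checks Shapiro-Wilk normality within each group and homogeneity of
#' variances (F-test for two groups, Bartlett for more) at `alpha_gate`, then
#' selects the test: for two groups a Student t test (both gates pass),
#' Welch t test (normal but heteroscedastic) or Mann-Whitney U test; for k
#' groups one-way ANOVA with Bonferroni-adjusted pairwise t post-tests, or
#' Kruskal-Wallis with Dunn post-tests. Groups with fewer than three
#' observations cannot be gated and trigger the nonparametric fallback with a
#' warning. The gate diagnostics are always reported.
#'
#' @param data A data frame.
#' @param value,group Column names (strings or bare names) of the measurement
#'   and the group label.
#' @param alpha_gate Significance level for the assumption gates
#'   (default 0.05).
#' @param alternative Alternative hypothesis for two-group tests
#'   (default "two.sided"; one-tailed alternatives are accepted for the
#'   t/Welch/Mann-Whitney branch).
#' @return A one-row tibble of class `noci_comparison`: `design`, `test_used`,
#'   `statistic`, `p_value`, plus list-columns `normality` (per-group
#'   Shapiro-Wilk p), `variance_p` and `posthoc` (pairwise table or NULL).
#' @examples
#' d <- data.frame(y = c(rnorm(10), rnorm(10, 1)),
#'                 g = rep(c("a", "b"), each = 10))
#' compare_groups(d, y, g)
#' @export
compare_groups <- function(data, value, group, alpha_gate = 0.05,
                           alternative = "two.sided") {
  value <- rlang::as_name(rlang::ensym(value))
  group <- rlang::as_name(rlang::ensym(group))
  v <- data[[value]]
  g <- as.character(data[[group]])
  ok <- stats::complete.cases(v, g)
  v <- v[ok]; g <- g[ok]
  lev <- unique(g)
  if (length(lev) < 2) abort("need at least two groups")
  design <- if (length(lev) == 2) "two-group" else "k-group"

  sizes <- table(g)
  gate_possible <- all(sizes >= 3)
  normality <- purrr::map(lev, function(l) {
    x <- v[g == l]
    p <- if (length(x) >= 3 && length(unique(x)) > 1) shapiro.test(x)$p.value
    else NA_real_
    tibble(group = l, n = length(x), shapiro_p = p)
  }) %>% list_rbind()

  if (!gate_possible) {
    warn("a group has fewer than 3 observations; using nonparametric test")
    normal <- FALSE
    var_p <- NA_real_
  } else {
    normal <- all(normality$shapiro_p > alpha_gate, na.rm = FALSE) &&
      !anyNA(normality$shapiro_p)
    var_p <- if (design == "two-group") {
      var.test(v[g == lev[1]], v[g == lev[2]])$p.value
    } else {
      bartlett.test(v, factor(g))$p.value
    }
  }
  homo <- gate_possible && !is.na(var_p) && var_p > alpha_gate

  posthoc <- NULL
  if (design == "two-group") {
    if (normal && homo) {
      ht <- t.test(v[g == lev[1]], v[g == lev[2]], var.equal = TRUE,
                   alternative = alternative)
      test_used <- "t test"
    } else if (normal) {
      ht <- t.test(v[g == lev[1]], v[g == lev[2]], var.equal = FALSE,
                   alternative = alternative)
      test_used <- "Welch t test"
    } else {
      ht <- suppressWarnings(
        wilcox.test(v[g == lev[1]], v[g == lev[2]],
                    alternative = alternative))
      test_used <- "Mann-Whitney U test"
    }
    statistic <- unname(ht$statistic)
    p <- ht$p.value
  } else {
    if (normal && homo) {
      fit <- aov(v ~ factor(g))
      s <- summary(fit)[[1]]
      statistic <- s$`F value`[1]
      p <- s$`Pr(>F)`[1]
      test_used <- "one-way ANOVA"
      pw <- pairwise.t.test(v, g, p.adjust.method = "bonferroni")$p.value
      posthoc <- as_tibble(as.table(pw), .name_repair = "minimal") %>%
        setNames(c("group_1", "group_2", "p_adj")) %>%
        filter(!is.na(.data$p_adj))
    } else {
      ht <- kruskal.test(v, factor(g))
      statistic <- unname(ht$statistic)
      p <- ht$p.value
      test_used <- "Kruskal-Wallis"
      posthoc <- dunn_test(v, g)
    }
  }

  out <- tibble(design = design, test_used = test_used,
                statistic = statistic, p_value = p,
                normality = list(normality), variance_p = var_p,
                posthoc = list(posthoc))
  class(out) <- c("noci_comparison", class(out))
  out
}
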