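#' Multi-group comparisons of per-axon metrics
#'
#' Runs the comparison battery used for morphometric group contrasts:
#' one-way ANOVA with Tukey's honest significant differences (plus a
#' Shapiro-Wilk normality gate on residuals and a Brown-Forsythe
#' homoscedasticity gate), Kruskal-Wallis with Bonferroni-corrected
#' pairwise Wilcoxon tests, or a chi-squared test on contacting versus
#' non-contacting counts with Bonferroni-corrected pairwise 2x2 tests.
#'
#' @param values numeric per-axon metric (for `anova_tukey` /
#'   `kruskal_bonferroni`), or for `chi2_bonferroni` a two-column matrix of
#'   per-group counts (`contacting`, `non_contacting`) with group rownames.
#' @param groups factor or character of group labels (ignored for
#'   `chi2_bonferroni`).
#' @param test one of `"anova_tukey"`, `"kruskal_bonferroni"`,
#'   `"chi2_bonferroni"`.
#' @return list of class `group_comparison` with `test`, `statistic`,
#'   `p_value`, `pairwise` (data.frame of corrected pairwise p-values) and,
#'   for ANOVA, `normality_p` (Shapiro-Wilk on residuals) and
#'   `variance_p` (Brown-Forsythe).
#' @export
compare_groups <- function(values, groups = NULL,
                           test = c("anova_tukey", "kruskal_bonferroni",
                                    "chi2_bonferroni")) {
  test <- match.arg(test)
  if (test == "chi2_bonferroni") {
    counts <- as.matrix(values)
    if (ncol(counts) != 2L || nrow(counts) < 2L)
      stop("chi2_bonferroni needs a groups x 2 count matrix")
    overall <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    gs <- rownames(counts)
    if (is.null(gs)) gs <- paste0("g", seq_len(nrow(counts)))
    pairs <- utils::combn(seq_len(nrow(counts)), 2L)
    pw <- apply(pairs, 2L, function(ij) {
      suppressWarnings(
        stats::chisq.test(counts[ij, , drop = FALSE], correct = FALSE))$p.value
    })
    pw_adj <- pmin(pw * ncol(pairs), 1)
    pairwise <- data.frame(group1 = gs[pairs[1, ]], group2 = gs[pairs[2, ]],
                           p_raw = pw, p_adj = pw_adj,
                           stringsAsFactors = FALSE)
    return(structure(list(test = test,
                          statistic = unname(overall$statistic),
                          p_value = overall$p.value,
                          pairwise = pairwise),
                     class = "group_comparison"))
  }
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (test == "anova_tukey") {
    n_per <- table(groups)
    if (any(n_per < 2L))
      stop("group(s) with n < 2 for ANOVA: ",
           paste(names(n_per)[n_per < 2L], collapse = ", "))
    fit <- stats::aov(values ~ groups)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$groups
    cmp <- strsplit(rownames(tk), "-", fixed = TRUE)
    pairwise <- data.frame(group1 = vapply(cmp, `[`, "", 1L),
                           group2 = vapply(cmp, `[`, "", 2L),
                           diff = tk[, "diff"], p_adj = tk[, "p adj"],
                           stringsAsFactors = FALSE)
    rownames(pairwise) <- NULL
    sw <- tryCatch(stats::shapiro.test(stats::residuals(fit))$p.value,
                   error = function(e) NA_real_)
    bf <- tryCatch(car::leveneTest(values ~ groups,
                                   center = stats::median)[1, "Pr(>F)"],
                   error = function(e) NA_real_)
    structure(list(test = test,
                   statistic = an[1, "F value"],
                   p_value = an[1, "Pr(>F)"],
                   pairwise = pairwise,
                   normality_p = sw,
                   variance_p = bf),
              class = "group_comparison")
  } else {
    kw <- stats::kruskal.test(values, groups)
    pw <- stats::pairwise.wilcox.test(values, groups,
                                      p.adjust.method = "bonferroni",
                                      exact = FALSE)
    m <- pw$p.value
    idx <- which(!is.na(m), arr.ind = TRUE)
    pairwise <- data.frame(group1 = rownames(m)[idx[, 1]],
                           group2 = colnames(m)[idx[, 2]],
                           p_adj = m[idx], stringsAsFactors = FALSE)
    structure(list(test = test,
                   statistic = unname(kw$statistic),
                   p_value = kw$p.value,
                   pairwise = pairwise),
              class = "group_comparison")
  }
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison (%s): statistic %.4g, p = %.4g\n",
              x$test, x$statistic, x$p_value))
  if (!is.null(x$normality_p))
    cat(sprintf("  Shapiro-Wilk p = %.3g; Brown-Forsythe p = %.3g\n",
                x$normality_p, x$variance_p))
  if (nrow(x$pairwise)) {
    cat("  pairwise (corrected):\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}
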