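# Cohort demographic comparisons: Pearson chi-square for categorical
# variables, Kruskal-Wallis across groups, Dunn's post-hoc pairwise z-tests.

group_comparison <- function(variable, test, statistic, df = NA_real_,
                             p_value, pairwise = NULL) {
  assert_that(is.na(p_value) || (p_value >= 0 && p_value <= 1),
              "p_value must lie in [0, 1]")
  out <- list(variable = variable, test = test,
              statistic = statistic, df = df, p_value = p_value)
  if (!is.null(pairwise)) out$pairwise <- pairwise
  structure(out, class = "group_comparison")
}

#' Pearson chi-square test on a group-by-category count table
#'
#' No continuity correction is applied (the convention of common biostatistics
#' software for tables larger than 2x2, and the one that reproduces reported
#' cohort p-values in this field).
#'
#' @param counts A matrix or table of counts, groups in rows, categories in
#'   columns.
#' @param variable Optional variable name carried into the result.
#' @return A `group_comparison` with the X-squared statistic, degrees of
#'   freedom `(r-1)(c-1)` and the chi-square p-value.
#' @export
chi_square_counts <- function(counts, variable = NULL) {
  counts <- as.matrix(counts)
  assert_that(all(dim(counts) >= 2), "need at least a 2x2 table")
  assert_that(all(rowSums(counts) > 0) && all(colSums(counts) > 0),
              "chi-square is undefined with a zero marginal")
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  group_comparison(variable %||% "counts", "chi_square",
                   statistic = unname(res$statistic),
                   df = unname(res$parameter),
                   p_value = min(1, max(0, unname(res$p.value))))
}

#' Kruskal-Wallis rank test across groups
#'
#' Ties are handled by midranks with the standard tie correction. The
#' degenerate case where every observation is equal is reported as H = 0,
#' p = 1 (the tie-corrected statistic is otherwise 0/0).
#'
#' @param values A named list of numeric vectors, one per group; each group
#'   must be non-empty after removing missing values.
#' @param variable Optional variable name carried into the result.
#' @return A `group_comparison` with the tie-corrected H statistic,
#'   `df = groups - 1` and the chi-square approximation p-value.
#' @export
kruskal_wallis <- function(values, variable = NULL) {
  values <- lapply(values, function(v) v[!is.na(v)])
  assert_that(length(values) >= 2, "need at least two groups")
  empty <- names(values)[lengths(values) == 0] %||%
    which(lengths(values) == 0)
  assert_that(all(lengths(values) > 0),
              paste0("empty group(s): ", paste(empty, collapse = ", ")))
  x <- unlist(values, use.names = FALSE)
  g <- factor(rep(seq_along(values), lengths(values)))
  if (length(unique(x)) == 1) {
    return(group_comparison(variable %||% "values", "kruskal_wallis",
                            statistic = 0, df = length(values) - 1,
                            p_value = 1))
  }
  res <- stats::kruskal.test(x, g)
  group_comparison(variable %||% "values", "kruskal_wallis",
                   statistic = unname(res$statistic),
                   df = unname(res$parameter),
                   p_value = min(1, max(0, unname(res$p.value))))
}

#' Dunn's post-hoc pairwise comparisons
#'
#' After a Kruskal-Wallis test, compares every pair of groups with Dunn's
#' z-statistic on mean-rank differences, using pooled midranks and the tie
#' correction
#' `sigma2 = N(N+1)/12 - sum(t^3 - t) / (12 (N - 1))`.
#' Two-sided p-values may optionally be adjusted for the number of pairs.
#'
#' @inheritParams kruskal_wallis
#' @param adjust Multiplicity adjustment over the `k(k-1)/2` pairs:
#'   `"none"` (default), `"bonferroni"` or `"sidak"`. Adjusted p-values are
#'   capped at 1.
#' @return A `group_comparison` with `pairwise`, a named list (one entry per
#'   `"A vs B"` pair) of lists holding `z` and `p_value`.
#' @export
dunn_pairwise <- function(values, adjust = c("none", "bonferroni", "sidak"),
                          variable = NULL) {
  adjust <- match.arg(adjust)
  values <- lapply(values, function(v) v[!is.na(v)])
  assert_that(length(values) >= 2, "need at least two groups")
  assert_that(all(lengths(values) > 0), "every group must be non-empty")
  labels <- names(values) %||% as.character(seq_along(values))
  x <- unlist(values, use.names = FALSE)
  g <- rep(seq_along(values), lengths(values))
  r <- rank(x)
  n <- lengths(values)
  big_n <- length(x)
  mean_ranks <- tapply(r, g, mean)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- big_n * (big_n + 1) / 12 -
    (if (big_n > 1) tie_term / (12 * (big_n - 1)) else 0)
  pairs <- utils::combn(seq_along(values), 2, simplify = FALSE)
  m <- length(pairs)
  pairwise <- list()
  for (pr in pairs) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt(sigma2 * (1 / n[i] + 1 / n[j]))
    z <- if (se > 0) (mean_ranks[[i]] - mean_ranks[[j]]) / se else 0
    p <- 2 * pnorm(-abs(z))
    p_adj <- switch(adjust,
                    none = p,
                    bonferroni = min(1, p * m),
                    sidak = 1 - (1 - p)^m)
    pairwise[[paste(labels[i], "vs", labels[j])]] <-
      list(z = unname(z), p_value = min(1, max(0, p_adj)))
  }
  group_comparison(variable %||% "values", "dunn_pairwise",
                   statistic = NA_real_, df = NA_real_,
                   p_value = NA_real_, pairwise = pairwise)
}

#' Cohort demographic statistics for a study design
#'
#' Mirrors the usual patient-characteristics table of a three-group screen:
#' sex is compared with a Pearson chi-square on the group-by-sex counts;
#' age, MMSE, H-Y and FRSSD scores with Kruskal-Wallis plus Dunn's pairwise
#' comparisons. Missing demographics are excluded pairwise, and a variable
#' observed in fewer than two groups is skipped (e.g. an ordinal staging
#' score recorded for a single disease group).
#'
#' @param design A [study_design()] whose manifest carries demographics.
#' @param adjust Dunn adjustment, see [dunn_pairwise()].
#' @return A named list, one entry per comparable variable, each holding the
#'   test name, statistic, p-value, the groups used and, for continuous
#'   variables, the pairwise Dunn results. Returns an empty list with a
#'   warning when no variable is comparable.
#' @export
cohort_statistics <- function(design, adjust = "none") {
  s <- design$samples
  out <- list()
  sex_ok <- !is.na(s$sex)
  if (any(sex_ok)) {
    tab <- table(factor(s$group[sex_ok], levels = design$group_labels),
                 s$sex[sex_ok])
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (all(dim(tab) >= 2)) {
      cmp <- chi_square_counts(unclass(tab), variable = "sex")
      out$sex <- list(test = cmp$test, statistic = cmp$statistic,
                      df = cmp$df, p_value = cmp$p_value,
                      groups_used = rownames(tab))
    }
  }
  for (var in c("age", "mmse", "hy", "frssd")) {
    vals <- split(s[[var]], factor(s$group, levels = design$group_labels))
    vals <- lapply(vals, function(v) v[!is.na(v)])
    vals <- vals[lengths(vals) > 0]
    if (length(vals) < 2) next
    kw <- kruskal_wallis(vals, variable = var)
    entry <- list(test = kw$test, statistic = kw$statistic, df = kw$df,
                  p_value = kw$p_value, groups_used = names(vals))
    if (length(vals) >= 2) {
      dn <- dunn_pairwise(vals, adjust = adjust, variable = var)
      entry$pairwise <- lapply(dn$pairwise, function(p)
        list(z = p$z, p_value = p$p_value))
    }
    out[[var]] <- entry
  }
  if (length(out) == 0) {
    warning("no demographic variable is comparable across groups", call. = FALSE)
  }
  out
}
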