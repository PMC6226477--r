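# Landscape statistics: ES/dES regressions against sequence features,
# top-vs-bottom ranked comparisons, and target-list overlap.

#' Simple linear regression of a per-gene statistic on a feature
#'
#' Ordinary least squares of `values` on `feature` with the Pearson
#' correlation, R squared (equal to r^2 for simple regression), and the
#' two-sided t-test p-value for a non-zero slope.
#'
#' @param values Per-gene statistic (e.g. ES or dES), numeric.
#' @param feature Per-gene covariate (e.g. G/C fraction, gene length, mean
#'   read count, pG4 density), numeric, same length.
#' @param label Optional analysis label carried into the result.
#' @return A one-row data.frame of class `g4rp_regression`: `label`, `n`,
#'   `r`, `r_squared`, `slope`, `intercept`, `p_value`.
#' @examples
#' feature_regression(2 * (1:10) + 1, 1:10)
#' @export
feature_regression <- function(values, feature, label = NA_character_) {
  if (length(values) != length(feature))
    stop("values and feature must have equal length")
  ok <- is.finite(values) & is.finite(feature)
  values <- values[ok]; feature <- feature[ok]
  n <- length(values)
  if (n < 3L) stop("need at least 3 finite pairs")
  if (stats::sd(feature) == 0 || stats::sd(values) == 0)
    stop("correlation undefined: constant feature or values")
  fit <- stats::lm(values ~ feature)
  ct <- stats::cor.test(feature, values, method = "pearson")
  r <- unname(ct$estimate)
  # for simple OLS the slope t-test equals the correlation t-test
  p <- ct$p.value
  out <- data.frame(label = label, n = n, r = r, r_squared = r^2,
                    slope = unname(stats::coef(fit)[2L]),
                    intercept = unname(stats::coef(fit)[1L]),
                    p_value = p, stringsAsFactors = FALSE)
  class(out) <- c("g4rp_regression", "data.frame")
  out
}

#' Compare a metric between top- and bottom-ranked genes
#'
#' Means of `metric` over the top `k` and bottom `k` genes of a ranking,
#' the top/bottom fold difference, and a two-tailed Student's t-test
#' (equal-variance by default; `welch = TRUE` for Welch's variant).
#'
#' @param ranked_genes Character vector of gene ids in rank order (best
#'   first).
#' @param metric Named numeric vector of per-gene values (e.g. pG4 density
#'   or absolute pG4 count); names must cover `ranked_genes`.
#' @param k Group size (default 100); the ranked list must contain at
#'   least `2 * k` genes.
#' @param welch Use Welch's unequal-variance t-test.
#' @return A one-row data.frame of class `g4rp_group_comparison`:
#'   `k`, `mean_top`, `mean_bottom`, `fold_difference`, `t_statistic`,
#'   `p_value`, `welch`.
#' @export
top_bottom_comparison <- function(ranked_genes, metric, k = 100,
                                  welch = FALSE) {
  k <- as.integer(k)
  if (length(ranked_genes) < 2L * k)
    stop("ranked list has ", length(ranked_genes),
         " genes; need at least 2k = ", 2L * k)
  miss <- setdiff(ranked_genes, names(metric))
  if (length(miss))
    stop("metric missing for ", length(miss), " ranked genes")
  top <- metric[utils::head(ranked_genes, k)]
  bottom <- metric[utils::tail(ranked_genes, k)]
  if (stats::sd(top) == 0 && stats::sd(bottom) == 0) {
    tt <- list(statistic = if (mean(top) == mean(bottom)) 0 else Inf,
               p.value = if (mean(top) == mean(bottom)) 1 else 0)
  } else {
    ht <- stats::t.test(top, bottom, var.equal = !welch,
                        alternative = "two.sided")
    tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
  }
  out <- data.frame(k = k, mean_top = mean(top),
                    mean_bottom = mean(bottom),
                    fold_difference = mean(top) / mean(bottom),
                    t_statistic = tt$statistic, p_value = tt$p.value,
                    welch = welch, stringsAsFactors = FALSE)
  class(out) <- c("g4rp_group_comparison", "data.frame")
  out
}

#' Overlap between two gene lists
#'
#' Exact set partition of two (deduplicated) target lists, as drawn in a
#' two-set Venn diagram.
#'
#' @param a,b Character vectors of gene ids.
#' @return List with `a_only`, `b_only`, `both` (member vectors) and
#'   `n_a_only`, `n_b_only`, `n_both`.
#' @examples
#' list_overlap(c("a", "b", "c"), c("b", "c", "d"))
#' @export
list_overlap <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  both <- intersect(a, b)
  res <- list(a_only = setdiff(a, b), b_only = setdiff(b, a), both = both)
  res$n_a_only <- length(res$a_only)
  res$n_b_only <- length(res$b_only)
  res$n_both <- length(both)
  res
}

#' One- or two-way ANOVA summary table
#'
#' Thin wrapper around [stats::aov()] returning a tidy data.frame, with
#' optional Bonferroni adjustment of the factor p-values (the correction
#' applied to multiple comparisons in plate-assay analyses).
#'
#' @param formula Model formula, e.g. `value ~ treatment` or
#'   `value ~ treatment * target`.
#' @param data data.frame containing the variables.
#' @param bonferroni Multiply term p-values by the number of tested terms
#'   (capped at 1).
#' @return data.frame with `term`, `df`, `sum_sq`, `mean_sq`, `statistic`,
#'   `p_value`.
#' @export
anova_table <- function(formula, data, bonferroni = FALSE) {
  fit <- stats::aov(formula, data = data)
  sm <- summary(fit)[[1L]]
  out <- data.frame(term = trimws(rownames(sm)), df = sm[["Df"]],
                    sum_sq = sm[["Sum Sq"]], mean_sq = sm[["Mean Sq"]],
                    statistic = sm[["F value"]],
                    p_value = sm[["Pr(>F)"]], stringsAsFactors = FALSE)
  if (bonferroni) {
    m <- sum(!is.na(out$p_value))
    out$p_value <- pmin(1, out$p_value * m)
  }
  rownames(out) <- NULL
  out
}
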