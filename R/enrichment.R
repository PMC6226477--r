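# Enrichment Scores (pulldown/input) and ligand-induced Enrichment Score
# Changes, with the abundance and fold-change filters and rankings used to
# define the G4-RNA landscape.

.norm_means <- function(x, size_factors = NULL, pool_inputs = FALSE) {
  stopifnot(inherits(x, "g4rp_counts"))
  if (is.null(size_factors)) size_factors <- compute_size_factors(x)
  norm <- normalize_counts(x, size_factors)
  sm <- x$samples
  conds <- unique(sm$condition)
  input_mean <- pull_mean <- matrix(NA_real_, nrow(norm), length(conds),
                                    dimnames = list(rownames(norm), conds))
  for (cond in conds) {
    icol <- sm$sample_id[sm$condition == cond & sm$assay == "input"]
    pcol <- sm$sample_id[sm$condition == cond & sm$assay == "G4RP"]
    if (pool_inputs) icol <- sm$sample_id[sm$assay == "input"]
    if (length(icol))
      input_mean[, cond] <- rowMeans(norm[, icol, drop = FALSE])
    if (length(pcol))
      pull_mean[, cond] <- rowMeans(norm[, pcol, drop = FALSE])
  }
  list(norm = norm, input_mean = input_mean, pull_mean = pull_mean,
       size_factors = size_factors)
}

#' Per-gene Enrichment Score for one condition
#'
#' The Enrichment Score (ES) is the gene-specific ratio of the pulldown
#' (G4RP) signal to the matched input signal, computed on normalized mean
#' counts with a symmetric pseudocount:
#' `ES = (mean pulldown + eps) / (mean input + eps)`. ES ranks transcripts
#' by their relative propensity to be captured in a G4-folded state; it is
#' not an absolute readout of G4 formation.
#'
#' @param x A [g4rp_counts()] object.
#' @param condition Condition whose pulldown/input pair to use.
#' @param pseudocount Pseudocount `eps` added to both means (default 0.5),
#'   keeping ES finite and positive at zero input.
#' @param size_factors Optional precomputed [compute_size_factors()].
#' @param pool_inputs Use all input samples (any condition) as the
#'   denominator instead of the condition's own input.
#' @return Named numeric vector of ES values (one per gene).
#' @export
enrichment_score <- function(x, condition, pseudocount = 0.5,
                             size_factors = NULL, pool_inputs = FALSE) {
  nm <- .norm_means(x, size_factors, pool_inputs)
  if (!condition %in% colnames(nm$input_mean) ||
      all(is.na(nm$input_mean[, condition])))
    stop("no input sample for condition '", condition, "'")
  if (all(is.na(nm$pull_mean[, condition])))
    stop("no pulldown (G4RP) sample for condition '", condition, "'")
  (nm$pull_mean[, condition] + pseudocount) /
    (nm$input_mean[, condition] + pseudocount)
}

#' Enrichment Score Change between treated and untreated
#'
#' `dES = ES_treated / ES_untreated`: the per-gene fold change in
#' enrichment induced by ligand treatment. Genes with an undefined ES in
#' either condition get `NA` and are excluded from induced lists.
#'
#' @param es_treated,es_untreated Per-gene ES vectors.
#' @return Per-gene ratio vector.
#' @export
enrichment_score_change <- function(es_treated, es_untreated) {
  out <- es_treated / es_untreated
  out[!is.finite(out)] <- NA_real_
  out
}

#' Full enrichment table for a G4RP experiment
#'
#' Normalizes the count matrix (median of ratios), computes per-condition
#' input/pulldown means and ES, the per-ligand Enrichment Score Change
#' relative to the untreated baseline, and applies [filter_and_rank()].
#'
#' @inheritParams enrichment_score
#' @param untreated Label of the baseline condition (default
#'   `"untreated"`; falls back to the first condition present).
#' @param des_mode `"es_ratio"` (default): dES is the ratio of the two
#'   conditions' ES values, so treatment-induced expression changes are
#'   divided out through each condition's own input. `"pulldown_ratio"`:
#'   dES is the ratio of pulldown means only (input-unadjusted).
#' @param min_mean,abundant_mean,des_threshold,strict_abundance Passed to
#'   [filter_and_rank()].
#' @return A data.frame of class `g4rp_enrichment`, one row per gene:
#'   `gene_id`, `mean_read_count`, per condition `input_mean.<c>`,
#'   `pulldown_mean.<c>`, `es.<c>`, `rank_es.<c>`, per ligand `des.<l>`,
#'   `induced.<l>`, `rank_des.<l>`, and logical `expressed`/`abundant`
#'   flags. Parameters are stored in `attr(, "params")`.
#' @export
enrichment_table <- function(x, pseudocount = 0.5, untreated = "untreated",
                             min_mean = 50, abundant_mean = 500,
                             des_threshold = 1.75,
                             strict_abundance = FALSE,
                             pool_inputs = FALSE,
                             des_mode = c("es_ratio", "pulldown_ratio"),
                             size_factors = NULL) {
  des_mode <- match.arg(des_mode)
  stopifnot(inherits(x, "g4rp_counts"))
  conds <- unique(x$samples$condition)
  if (!untreated %in% conds) untreated <- conds[1]
  nm <- .norm_means(x, size_factors, pool_inputs)
  tab <- data.frame(gene_id = rownames(x$counts),
                    mean_read_count = mean_read_count(nm$norm),
                    stringsAsFactors = FALSE)
  es <- list()
  for (cond in conds) {
    if (all(is.na(nm$input_mean[, cond])))
      stop("no input sample for condition '", cond, "'")
    es[[cond]] <- (nm$pull_mean[, cond] + pseudocount) /
      (nm$input_mean[, cond] + pseudocount)
    tab[[paste0("input_mean.", cond)]] <- nm$input_mean[, cond]
    tab[[paste0("pulldown_mean.", cond)]] <- nm$pull_mean[, cond]
    tab[[paste0("es.", cond)]] <- es[[cond]]
  }
  for (lig in setdiff(conds, untreated)) {
    tab[[paste0("des.", lig)]] <- switch(des_mode,
      es_ratio = enrichment_score_change(es[[lig]], es[[untreated]]),
      pulldown_ratio = (nm$pull_mean[, lig] + pseudocount) /
        (nm$pull_mean[, untreated] + pseudocount))
  }
  tab <- filter_and_rank(tab, min_mean = min_mean,
                         abundant_mean = abundant_mean,
                         des_threshold = des_threshold,
                         strict_abundance = strict_abundance)
  attr(tab, "params") <- list(
    pseudocount = pseudocount, untreated = untreated, min_mean = min_mean,
    abundant_mean = abundant_mean, des_threshold = des_threshold,
    strict_abundance = strict_abundance, pool_inputs = pool_inputs,
    des_mode = des_mode, size_factors = nm$size_factors)
  class(tab) <- c("g4rp_enrichment", "data.frame")
  rownames(tab) <- NULL
  tab
}

#' Apply the landscape filters and rankings
#'
#' Flags and ranks an enrichment table:
#' \itemize{
#'   \item `expressed`: mean normalized read count strictly greater than
#'     `min_mean` (default 50), defining the initial gene list;
#'   \item `abundant`: mean read count at least `abundant_mean` (default
#'     500, roughly the top of the expression distribution), the
#'     high-confidence subset used for landscape analyses; set
#'     `strict_abundance = TRUE` for a strict `>` comparison;
#'   \item `induced.<ligand>`: expressed and `dES` strictly greater than
#'     `des_threshold` (default 1.75, i.e. 0.8 on the log2 scale);
#'   \item `rank_es.<condition>` / `rank_des.<ligand>`: descending dense
#'     ranks among expressed genes (1 = highest), ties broken by gene id;
#'     non-expressed genes get `NA` and never enter top/bottom lists.
#' }
#'
#' @param tab data.frame with `gene_id`, `mean_read_count`, `es.<cond>`
#'   and optionally `des.<ligand>` columns.
#' @param min_mean,abundant_mean,des_threshold Filter thresholds.
#' @param strict_abundance Use `>` instead of `>=` for the abundance
#'   filter.
#' @return The table with flag and rank columns added/replaced.
#' @export
filter_and_rank <- function(tab, min_mean = 50, abundant_mean = 500,
                            des_threshold = 1.75,
                            strict_abundance = FALSE) {
  stopifnot(all(c("gene_id", "mean_read_count") %in% names(tab)))
  tab$expressed <- tab$mean_read_count > min_mean
  tab$abundant <- if (strict_abundance) tab$mean_read_count > abundant_mean
                  else tab$mean_read_count >= abundant_mean
  rank_desc <- function(v, keep) {
    r <- rep(NA_integer_, length(v))
    idx <- which(keep & !is.na(v))
    if (length(idx)) {
      o <- idx[order(-v[idx], tab$gene_id[idx])]
      r[o] <- seq_along(o)
    }
    r
  }
  for (col in grep("^es\\.", names(tab), value = TRUE)) {
    cond <- sub("^es\\.", "", col)
    tab[[paste0("rank_es.", cond)]] <- rank_desc(tab[[col]], tab$expressed)
  }
  for (col in grep("^des\\.", names(tab), value = TRUE)) {
    lig <- sub("^des\\.", "", col)
    des <- tab[[col]]
    tab[[paste0("induced.", lig)]] <- tab$expressed & !is.na(des) &
      des > des_threshold
    tab[[paste0("rank_des.", lig)]] <- rank_desc(des, tab$expressed)
  }
  tab
}

#' Top-ranked gene ids from an enrichment table
#'
#' @param tab Enrichment table.
#' @param by Rank column, e.g. `"rank_es.untreated"` or
#'   `"rank_des.BRACO-19"`.
#' @param k Number of genes.
#' @param abundant_only Restrict to the abundant subset before taking the
#'   top `k` (re-ranking within the subset).
#' @return Character vector of up to `k` gene ids in rank order.
#' @export
top_genes <- function(tab, by, k = 100, abundant_only = TRUE) {
  if (!by %in% names(tab)) stop("no column '", by, "' in table")
  keep <- !is.na(tab[[by]])
  if (abundant_only) keep <- keep & tab$abundant
  sub <- tab[keep, , drop = FALSE]
  sub <- sub[order(sub[[by]]), , drop = FALSE]
  utils::head(sub$gene_id, k)
}
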