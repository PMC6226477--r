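#' Median-of-ratios size factors
#'
#' For each sample `j`, the size factor is the median over genes of
#' `counts[i, j] / geomean_i`, where `geomean_i` is the gene's geometric
#' mean across samples; genes containing any zero (undefined log geometric
#' mean) are excluded from the median. Factors are then rescaled to have
#' geometric mean 1, so normalized counts stay on the raw-count scale.
#'
#' @param counts Integer matrix (genes x samples) or a [g4rp_counts()]
#'   object.
#' @param pseudo_reference If no gene is positive in all samples the
#'   standard estimator is undefined; with `pseudo_reference = TRUE` the
#'   per-gene geometric mean is taken over positive entries only (and genes
#'   positive in at least two samples are used), a fallback for very sparse
#'   matrices.
#' @return Named numeric vector of positive per-sample size factors with
#'   geometric mean 1.
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2,
#'             dimnames = list(paste0("g", 1:3), c("a", "b")))
#' compute_size_factors(m)  # c(1/sqrt(2), sqrt(2))
#' @export
compute_size_factors <- function(counts, pseudo_reference = FALSE) {
  if (inherits(counts, "g4rp_counts")) counts <- counts$counts
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  logc <- log(counts)
  if (pseudo_reference) {
    logc[!is.finite(logc)] <- NA
    loggeo <- rowMeans(logc, na.rm = TRUE)
    use <- rowSums(!is.na(logc)) >= 1L & is.finite(loggeo)
  } else {
    loggeo <- rowMeans(logc)
    use <- is.finite(loggeo)
  }
  if (!any(use))
    stop("no gene has positive counts in every sample; rerun with ",
         "pseudo_reference = TRUE to use a positive-entry pseudo-reference")
  sf <- apply(counts[use, , drop = FALSE], 2L, function(cj) {
    lr <- log(cj)
    lr[cj == 0] <- NA  # zero counts never enter the median of ratios
    exp(stats::median(lr - loggeo[use], na.rm = TRUE))
  })
  if (any(!is.finite(sf) | sf <= 0))
    stop("degenerate size factor; check for samples that share no ",
         "expressed genes with the reference")
  sf / exp(mean(log(sf)))
}

#' Normalize a count matrix by size factors
#'
#' Divides each sample column by its size factor:
#' `normalized[i, j] = counts[i, j] / s_j`.
#'
#' @inheritParams compute_size_factors
#' @param size_factors Per-sample factors from [compute_size_factors()];
#'   computed if omitted.
#' @return Numeric matrix of normalized counts.
#' @export
normalize_counts <- function(counts, size_factors = NULL) {
  if (inherits(counts, "g4rp_counts")) counts <- counts$counts
  counts <- as.matrix(counts)
  if (is.null(size_factors)) size_factors <- compute_size_factors(counts)
  if (length(size_factors) != ncol(counts))
    stop("one size factor per sample required")
  if (any(size_factors <= 0)) stop("size factors must be positive")
  sweep(counts, 2L, size_factors, "/")
}

#' Per-gene mean normalized read count
#'
#' Mean of the normalized counts over all samples, the abundance estimate
#' used by the expression (`> 50`) and abundance (`>= 500`) filters.
#'
#' @param normalized Normalized matrix from [normalize_counts()].
#' @return Named numeric vector (one value per gene).
#' @export
mean_read_count <- function(normalized) {
  rowMeans(normalized)
}
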