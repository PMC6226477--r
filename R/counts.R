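#' Construct a G4RP counts object
#'
#' Bundles a nonnegative integer gene-by-sample count matrix with its
#' sample sheet. Each G4RP (pulldown) sample's condition must also have at
#' least one matching input sample, since every Enrichment Score is a
#' pulldown/input ratio within a condition.
#'
#' @param counts Integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param samples data.frame with columns `sample_id`, `condition`,
#'   `assay` (`"input"` or `"G4RP"`) and `replicate`; one row per counts
#'   column.
#' @return An object of class `g4rp_counts`: list with elements `counts`
#'   and `samples`.
#' @export
g4rp_counts <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids in counts")
  if (any(counts < 0)) stop("counts must be nonnegative")
  need <- c("sample_id", "condition", "assay", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  absent <- setdiff(colnames(counts), samples$sample_id)
  if (length(absent))
    stop("samples missing from sample sheet: ",
         paste(absent, collapse = ", "))
  samples <- samples[match(colnames(counts), samples$sample_id), ,
                     drop = FALSE]
  rownames(samples) <- NULL
  bad <- setdiff(unique(samples$assay), c("input", "G4RP"))
  if (length(bad))
    stop("assay must be 'input' or 'G4RP'; found: ",
         paste(bad, collapse = ", "))
  pull_cond <- unique(samples$condition[samples$assay == "G4RP"])
  in_cond <- unique(samples$condition[samples$assay == "input"])
  orphan <- setdiff(pull_cond, in_cond)
  if (length(orphan))
    stop("no input sample for condition(s): ",
         paste(orphan, collapse = ", "))
  structure(list(counts = counts, samples = samples),
            class = "g4rp_counts")
}

#' @export
print.g4rp_counts <- function(x, ...) {
  cat(sprintf("g4rp_counts: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(x$samples$condition, x$samples$assay)
  print(tab)
  invisible(x)
}

#' @export
dim.g4rp_counts <- function(x) dim(x$counts)
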