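# Readers and writers: FASTA for sequences, TSV for matrices and tables,
# CSV for sample sheets and plate-assay tables. Identifiers round-trip
# verbatim; floating point is written with 6 significant digits.

#' Read transcript sequences from FASTA
#'
#' Accepts wrapped or unwrapped FASTA; line-wrapped records are joined.
#' Duplicate identifiers are an error.
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA (wrapped at 60 columns)
#'
#' @param sequences Named character vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a counts matrix and sample sheet
#'
#' The counts TSV has gene ids in the first column and one column per
#' sample; the sample sheet CSV has columns
#' `sample_id,condition,assay,replicate` and must cover every counts
#' column.
#'
#' @param counts_path Counts TSV.
#' @param samples_path Sample sheet CSV.
#' @return A [g4rp_counts()] object.
#' @export
read_counts <- function(counts_path, samples_path) {
  df <- utils::read.delim(counts_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("counts file needs a gene column plus samples")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate gene id(s) in ", counts_path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  samples <- utils::read.csv(samples_path, stringsAsFactors = FALSE)
  g4rp_counts(m, samples)
}

#' Write a counts object to TSV + CSV
#'
#' @param x A [g4rp_counts()] object.
#' @param counts_path,samples_path Output paths.
#' @return `counts_path`, invisibly.
#' @export
write_counts <- function(x, counts_path, samples_path) {
  stopifnot(inherits(x, "g4rp_counts"))
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(x$samples, samples_path, row.names = FALSE,
                   quote = FALSE)
  invisible(counts_path)
}

# Generic numeric-table TSV writer (6 significant digits for doubles).
.write_table <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- .fmt_num(out[[j]])
    if (is.list(out[[j]]))
      out[[j]] <- vapply(out[[j]], paste, "", collapse = ",")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an enrichment table to TSV
#'
#' @param tab [enrichment_table()] result.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(tab, path) .write_table(tab, path)

#' Read an enrichment table written by [write_enrichment()]
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_enrichment <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a transcript feature table to TSV
#'
#' @param features [transcript_features()] result.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) .write_table(features, path)

#' Read long-format melt curves from CSV
#'
#' Expected columns: `temperature`, `emission`, `well`, `label`. One
#' [melt_curve()] is built per well.
#'
#' @param path CSV file.
#' @return Named list of [melt_curve()] objects (names = well ids).
#' @export
read_melt_curves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("temperature", "emission", "well", "label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("melt-curve file missing columns: ", paste(miss, collapse = ", "))
  out <- lapply(split(df, df$well), function(d) {
    d <- d[order(d$temperature), ]
    melt_curve(d$temperature, d$emission, label = d$label[1L])
  })
  out
}

#' Read a qPCR Ct table from CSV
#'
#' Expected columns: `target`, `condition`, `assay`
#' (`pulldown`/`input`), `ct`. Technical replicates are rows. One
#' [qpcr_measurement()] is built per target x condition.
#'
#' @param path CSV file.
#' @return List of [qpcr_measurement()] objects named `target.condition`.
#' @export
read_qpcr_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("target", "condition", "assay", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("qPCR file missing columns: ", paste(miss, collapse = ", "))
  key <- interaction(df$target, df$condition, drop = TRUE)
  lapply(split(df, key), function(d)
    qpcr_measurement(d$target[1L], d$condition[1L],
                     ct_pulldown = d$ct[d$assay == "pulldown"],
                     ct_input = d$ct[d$assay == "input"]))
}

#' Read a dose-response table from CSV
#'
#' Expected columns: `dose`, `confluency` and optionally `replicate`;
#' replicates are averaged per dose before normalization.
#'
#' @param path CSV file.
#' @return A [dose_response_curve()].
#' @export
read_dose_response <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dose", "confluency")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("dose-response file missing columns: ",
         paste(miss, collapse = ", "))
  agg <- stats::aggregate(confluency ~ dose, data = df, FUN = mean)
  agg <- agg[order(agg$dose), ]
  dose_response_curve(agg$dose, agg$confluency)
}

#' Read/write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @return For `read_pipeline_config`, the configuration list; for
#'   `write_pipeline_config`, `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' @rdname read_pipeline_config
#' @param config A [pipeline_config()] list.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
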