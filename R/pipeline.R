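# End-to-end driver: scan -> score -> landscape stats, with a JSON run
# manifest recording version, seed, thresholds and input checksums.

#' Pipeline configuration
#'
#' Paths, thresholds and flags for [run_pipeline()]. Thresholds default to
#' the landscape conventions: expression filter mean > 50, abundance
#' filter mean >= 500, induction filter dES > 1.75, pseudocount 0.5.
#'
#' @param fasta,counts,samples Input paths (FASTA, counts TSV, sample
#'   sheet CSV).
#' @param out_dir Output directory (created if missing).
#' @param presets Character vector of preset names understood by
#'   [g4_preset()].
#' @param untreated Baseline condition label.
#' @param min_mean,abundant_mean,des_threshold,pseudocount Scoring
#'   thresholds.
#' @param strict_abundance,welch,pool_inputs Flags (see
#'   [enrichment_table()] and [top_bottom_comparison()]).
#' @param des_mode dES definition (see [enrichment_table()]).
#' @param top_k Group size for top/bottom comparisons.
#' @param seed Seed recorded in the manifest (the scoring pipeline itself
#'   is deterministic).
#' @return List of class `g4rp_pipeline_config`.
#' @export
pipeline_config <- function(fasta, counts, samples, out_dir = ".",
                            presets = c("G3L1-7", "G3L1-5", "G2L1-10"),
                            untreated = "untreated",
                            min_mean = 50, abundant_mean = 500,
                            des_threshold = 1.75, pseudocount = 0.5,
                            strict_abundance = FALSE, welch = FALSE,
                            pool_inputs = FALSE,
                            des_mode = "es_ratio",
                            top_k = 100, seed = 1L) {
  stopifnot(min_mean > 0, abundant_mean > 0, des_threshold > 0,
            pseudocount > 0, top_k >= 1)
  structure(list(
    fasta = fasta, counts = counts, samples = samples, out_dir = out_dir,
    presets = presets, untreated = untreated, min_mean = min_mean,
    abundant_mean = abundant_mean, des_threshold = des_threshold,
    pseudocount = pseudocount, strict_abundance = strict_abundance,
    welch = welch, pool_inputs = pool_inputs, des_mode = des_mode,
    top_k = as.integer(top_k), seed = as.integer(seed)),
    class = "g4rp_pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

.log_stage <- function(name, msg) {
  message(sprintf("[%s] %s", name, msg))
}

#' Run the full G4RP-seq analysis pipeline
#'
#' Stages: read inputs; scan transcript sequences at every configured
#' stringency; normalize and score the count matrix (ES, dES, filters,
#' ranks); compute landscape statistics (ES and dES regressions on G/C
#' content, gene length and pG4 density over the abundant subset;
#' top-vs-bottom pG4 comparisons; induced-list overlap between ligands);
#' write all tables plus a JSON manifest.
#'
#' Output files in `out_dir`: `features.tsv`, `motifs.bed` (mid-stringency
#' hits), `enrichment.tsv`, `stats_regressions.tsv`,
#' `stats_comparisons.tsv`, `overlap_<A>_vs_<B>.txt`, `manifest.json`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `features`, `enrichment`, `stats`,
#'   `overlap`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "g4rp_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  presets <- lapply(config$presets, g4_preset)

  .log_stage("read", paste("loading", config$fasta))
  seqs <- .stage("read", read_fasta(config$fasta))
  x <- .stage("read", read_counts(config$counts, config$samples))

  .log_stage("scan", sprintf("%d transcripts x %d presets", length(seqs),
                             length(presets)))
  feats <- .stage("scan", transcript_features(seqs, presets))
  hits <- .stage("scan", {
    hl <- lapply(names(seqs), function(id)
      scan_pg4(seqs[[id]], presets[[1L]], id = id))
    do.call(rbind, hl)
  })

  .log_stage("score", "normalizing and computing ES/dES")
  tab <- .stage("score", enrichment_table(
    x, pseudocount = config$pseudocount, untreated = config$untreated,
    min_mean = config$min_mean, abundant_mean = config$abundant_mean,
    des_threshold = config$des_threshold,
    strict_abundance = config$strict_abundance,
    pool_inputs = config$pool_inputs, des_mode = config$des_mode))

  .log_stage("stats", "landscape statistics")
  stats_out <- .stage("stats",
    .landscape_report(tab, feats, seqs, config))
  overlap <- .stage("stats", .ligand_overlap(tab, config))

  .log_stage("write", paste("writing to", config$out_dir))
  p <- function(f) file.path(config$out_dir, f)
  write_features(feats, p("features.tsv"))
  write_bed(hits, p("motifs.bed"))
  write_enrichment(tab, p("enrichment.tsv"))
  .write_table(stats_out$regressions, p("stats_regressions.tsv"))
  if (!is.null(stats_out$comparisons))
    .write_table(stats_out$comparisons, p("stats_comparisons.tsv"))
  for (nm in names(overlap)) {
    ov <- overlap[[nm]]
    writeLines(c(paste0("# both (", ov$n_both, ")"), ov$both,
                 paste0("# a_only (", ov$n_a_only, ")"), ov$a_only,
                 paste0("# b_only (", ov$n_b_only, ")"), ov$b_only),
               p(paste0("overlap_", nm, ".txt")))
  }
  manifest <- list(
    package = "g4rpseq",
    version = as.character(utils::packageVersion("g4rpseq")),
    seed = config$seed,
    thresholds = list(min_mean = config$min_mean,
                      abundant_mean = config$abundant_mean,
                      des_threshold = config$des_threshold,
                      pseudocount = config$pseudocount),
    flags = list(strict_abundance = config$strict_abundance,
                 welch = config$welch, pool_inputs = config$pool_inputs,
                 des_mode = config$des_mode),
    presets = config$presets,
    inputs = as.list(tools::md5sum(c(fasta = config$fasta,
                                     counts = config$counts,
                                     samples = config$samples)))
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(features = feats, enrichment = tab, stats = stats_out,
                 overlap = overlap, manifest = manifest))
}

# Regressions of ES/dES on sequence features over the abundant subset,
# plus top-vs-bottom pG4 comparisons per ranking.
.landscape_report <- function(tab, feats, seqs, config) {
  mid <- paste0("pg4_density.", config$presets[1L])
  midc <- paste0("pg4_count.", config$presets[1L])
  f <- feats[match(tab$gene_id, feats$transcript_id), ]
  keep <- tab$abundant
  rows <- list()
  add_reg <- function(label, values, feature) {
    res <- try(feature_regression(values[keep], feature[keep],
                                  label = label), silent = TRUE)
    if (!inherits(res, "try-error")) rows[[length(rows) + 1L]] <<- res
  }
  es_cols <- grep("^es\\.", names(tab), value = TRUE)
  for (col in es_cols) {
    cond <- sub("^es\\.", "", col)
    add_reg(paste0("ES_", cond, "_vs_gc"), tab[[col]], f$gc_fraction)
    add_reg(paste0("ES_", cond, "_vs_length"), tab[[col]], f$length)
    add_reg(paste0("ES_", cond, "_vs_pg4_density"), tab[[col]], f[[mid]])
  }
  for (col in grep("^des\\.", names(tab), value = TRUE)) {
    lig <- sub("^des\\.", "", col)
    add_reg(paste0("dES_", lig, "_vs_gc"), tab[[col]], f$gc_fraction)
    add_reg(paste0("dES_", lig, "_vs_mean_count"), tab[[col]],
            tab$mean_read_count)
    add_reg(paste0("dES_", lig, "_vs_pg4_density"), tab[[col]], f[[mid]])
  }
  reg <- do.call(rbind, rows)
  # top/bottom comparisons on every ranking with enough genes
  cmp <- list()
  met_d <- stats::setNames(f[[mid]], f$transcript_id)
  met_c <- stats::setNames(f[[midc]], f$transcript_id)
  for (col in grep("^rank_(es|des)\\.", names(tab), value = TRUE)) {
    ranked <- top_genes(tab, col, k = nrow(tab), abundant_only = TRUE)
    if (length(ranked) >= 2L * config$top_k) {
      for (metric in c("pg4_density", "pg4_count")) {
        m <- if (metric == "pg4_density") met_d else met_c
        tb <- top_bottom_comparison(ranked, m, k = config$top_k,
                                    welch = config$welch)
        tb$label <- paste0(sub("^rank_", "", col), "_top_bottom_",
                           metric)
        cmp[[length(cmp) + 1L]] <- tb
      }
    }
  }
  list(regressions = reg,
       comparisons = if (length(cmp)) do.call(rbind, cmp))
}

.ligand_overlap <- function(tab, config) {
  ligs <- sub("^induced\\.", "",
              grep("^induced\\.", names(tab), value = TRUE))
  out <- list()
  if (length(ligs) >= 2L) {
    prs <- utils::combn(ligs, 2L, simplify = FALSE)
    for (pr in prs) {
      la <- tab$gene_id[tab[[paste0("induced.", pr[1])]] & tab$abundant]
      lb <- tab$gene_id[tab[[paste0("induced.", pr[2])]] & tab$abundant]
      out[[paste0(pr[1], "_vs_", pr[2])]] <- list_overlap(la, lb)
    }
  }
  out
}
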