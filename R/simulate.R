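#' Configuration for the synthetic G4RP-seq generator
#'
#' Defines the study design emulated by the generator: a set of transcripts
#' with controllable length, G/C content and planted pG4 motif counts; a
#' latent G4-folding propensity coupled to pG4 density through a logistic
#' link; a pulldown capture rate `r = b + c * f`; and a count design of one
#' input library plus two pulldown replicates per condition (untreated and
#' two G4-stabilizing ligands), with negative-binomial read counts.
#'
#' @param n_transcripts Number of transcripts.
#' @param length_range Transcript length bounds in nt (sampled uniformly).
#' @param gc_target_range Per-transcript target G/C fraction bounds
#'   (sampled uniformly).
#' @param pg4_lambda Poisson mean of the per-transcript planted `G3L1-7`
#'   motif count.
#' @param pg4_max Upper cap on planted motif counts.
#' @param pg4_counts Optional explicit integer vector of planted counts
#'   (length `n_transcripts`); overrides the Poisson draw.
#' @param gc_pg4_correlation Gaussian-copula correlation in `[0, 1)`
#'   coupling the per-transcript G/C target to pG4 density (default 0.5):
#'   pG4-dense transcripts are GC-rich, as in real transcriptomes where
#'   G-tract density and overall G/C content rise together. Set 0 for
#'   independent G/C targets.
#' @param expression_log_mean,expression_log_sd Log-scale mean/sd of the
#'   lognormal relative expression (input abundance) distribution.
#' @param dispersion Negative-binomial dispersion `alpha` (variance
#'   `mu + alpha * mu^2`); 0 gives Poisson counts.
#' @param background_capture Background pulldown rate `b` in (0,1): the
#'   capture rate of a transcript that never folds.
#' @param capture_gain Gain `c > 0` mapping folding propensity to capture:
#'   `r = b + c * f`.
#' @param folding_slope,folding_intercept Logistic-link coefficients mapping
#'   pG4 density (motifs per kb) to baseline folding propensity
#'   `f = plogis(intercept + slope * density_kb)`.
#' @param responder_fraction Fraction of transcripts whose folding
#'   propensity is multiplied under each ligand.
#' @param responder_effect Multiplier (> 1) applied to responders' folding
#'   propensity under ligand (clamped so `f <= 1`).
#' @param responder_bias `"low_pg4"` draws responders preferentially from
#'   low-pG4-density transcripts (the regime in which ligand-induced
#'   stabilization has headroom); `"uniform"` draws them uniformly.
#' @param conditions Condition labels; the first is the untreated baseline.
#' @param n_input_reps,n_pulldown_reps Input and pulldown replicates per
#'   condition.
#' @param library_size Expected total read count per library (scalar, or a
#'   vector named by sample id).
#' @param rrna_spike If `TRUE`, re-labels the 3 most abundant transcripts
#'   as residual rRNA: very high expression with capture rate below
#'   background (such transcripts appear strongly depleted in pulldown).
#' @param seed Integer seed; fully determines the generator output.
#' @param alphabet `"RNA"` (A,C,G,U) or `"DNA"` (A,C,G,T) output alphabet.
#' @return An object of class `g4rp_sim_config` (a validated list).
#' @export
simulation_config <- function(n_transcripts = 2000L,
                              length_range = c(500L, 4000L),
                              gc_target_range = c(0.35, 0.65),
                              pg4_lambda = 2,
                              pg4_max = 10L,
                              pg4_counts = NULL,
                              gc_pg4_correlation = 0.5,
                              expression_log_mean = 5,
                              expression_log_sd = 1.2,
                              dispersion = 0.05,
                              background_capture = 0.01,
                              capture_gain = 0.6,
                              folding_slope = 1.0,
                              folding_intercept = -2.0,
                              responder_fraction = 0.1,
                              responder_effect = 3,
                              responder_bias = c("low_pg4", "uniform"),
                              conditions = c("untreated", "BRACO-19",
                                             "RHPS4"),
                              n_input_reps = 1L,
                              n_pulldown_reps = 2L,
                              library_size = 3e6,
                              rrna_spike = FALSE,
                              seed = 1L,
                              alphabet = c("RNA", "DNA")) {
  responder_bias <- match.arg(responder_bias)
  alphabet <- match.arg(alphabet)
  cfg <- list(
    n_transcripts = as.integer(n_transcripts),
    length_range = as.integer(length_range),
    gc_target_range = as.numeric(gc_target_range),
    pg4_lambda = pg4_lambda, pg4_max = as.integer(pg4_max),
    pg4_counts = if (!is.null(pg4_counts)) as.integer(pg4_counts),
    gc_pg4_correlation = gc_pg4_correlation,
    expression_log_mean = expression_log_mean,
    expression_log_sd = expression_log_sd,
    dispersion = dispersion,
    background_capture = background_capture,
    capture_gain = capture_gain,
    folding_slope = folding_slope,
    folding_intercept = folding_intercept,
    responder_fraction = responder_fraction,
    responder_effect = responder_effect,
    responder_bias = responder_bias,
    conditions = conditions,
    n_input_reps = as.integer(n_input_reps),
    n_pulldown_reps = as.integer(n_pulldown_reps),
    library_size = library_size,
    rrna_spike = isTRUE(rrna_spike),
    seed = as.integer(seed),
    alphabet = alphabet
  )
  stopifnot(
    cfg$n_transcripts >= 1L,
    length(cfg$length_range) == 2L,
    cfg$length_range[1] >= 50L,
    cfg$length_range[1] <= cfg$length_range[2],
    length(cfg$gc_target_range) == 2L,
    cfg$gc_target_range[1] > 0, cfg$gc_target_range[2] < 1,
    cfg$gc_target_range[1] <= cfg$gc_target_range[2],
    cfg$pg4_lambda >= 0, cfg$pg4_max >= 0L,
    cfg$gc_pg4_correlation >= 0, cfg$gc_pg4_correlation < 1,
    cfg$expression_log_sd >= 0,
    cfg$dispersion >= 0,
    cfg$background_capture >= 0, cfg$background_capture < 1,
    cfg$capture_gain >= 0,
    cfg$responder_fraction >= 0, cfg$responder_fraction <= 1,
    cfg$responder_effect >= 1,
    length(cfg$conditions) >= 1L,
    cfg$n_input_reps >= 1L, cfg$n_pulldown_reps >= 1L,
    all(cfg$library_size > 0)
  )
  if (!is.null(cfg$pg4_counts) &&
      length(cfg$pg4_counts) != cfg$n_transcripts)
    stop("pg4_counts must have length n_transcripts")
  class(cfg) <- "g4rp_sim_config"
  cfg
}

#' @export
print.g4rp_sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("g4rp_sim_config: %d transcripts, %d conditions ",
           "(%d input + %d pulldown reps), seed %d\n"),
    x$n_transcripts, length(x$conditions), x$n_input_reps,
    x$n_pulldown_reps, x$seed))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Sequence construction.
#
# Background is drawn from a G-depleted base distribution and any residual
# G run of length >= 3 is broken by replacing its third and later guanines
# with C (G/C content preserved exactly). Exact "GGG loop GGG loop GGG loop
# GGG" cassettes (loops 1-7 nt, G-free) are then spliced between background
# segments of at least 8 nt, so no loop of <= 7 nt can bridge two cassettes
# and the background contributes no G3 tract: the G3L1-7 scan recovers
# exactly the planted count.

.break_g_runs <- function(chars) {
  isg <- chars == "G"
  n <- length(chars)
  if (n >= 3L) {
    third <- isg & c(FALSE, isg[-n])[seq_len(n)] &
      c(FALSE, FALSE, isg[seq_len(n - 2L)])
    chars[third] <- "C"
  }
  chars
}

.random_background <- function(len, gc) {
  if (len == 0L) return(character(0))
  pg <- min(0.06, gc / 2)
  pc <- gc - pg
  pat <- (1 - gc) / 2
  chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                  prob = c(pat, pc, pg, pat))
  .break_g_runs(chars)
}

.make_cassette <- function(preset_g = 3L, n_tracts = 4L, loop_max = 7L) {
  loops <- sample.int(loop_max, n_tracts - 1L, replace = TRUE)
  tract <- strrep("G", preset_g)
  loop_seqs <- vapply(loops, function(l)
    paste(sample(c("A", "C", "T"), l, replace = TRUE,
                 prob = c(0.3, 0.4, 0.3)), collapse = ""), "")
  paste0(tract, paste0(loop_seqs, tract, collapse = ""))
}

# Flip non-cassette positions to meet the target G+C count exactly
# (A/T -> C raises GC, C -> A lowers it; G positions are never touched so
# planted motifs and run structure survive).
.repair_gc <- function(chars, editable, target_gc_count) {
  cur <- sum(chars %in% c("G", "C"))
  delta <- target_gc_count - cur
  if (delta > 0) {
    cand <- which(editable & chars %in% c("A", "T"))
    if (length(cand) >= delta)
      chars[sample(cand, delta)] <- "C"
  } else if (delta < 0) {
    cand <- which(editable & chars == "C")
    if (length(cand) >= -delta)
      chars[sample(cand, -delta)] <- "A"
  }
  chars
}

.simulate_one_sequence <- function(len, gc_target, k, idx) {
  gap <- 8L  # min background segment; > loop_max so cassettes cannot link
  cassettes <- if (k > 0L) vapply(seq_len(k), function(i) .make_cassette(),
                                  "") else character(0)
  cas_len <- sum(nchar(cassettes))
  bg_len <- len - cas_len
  if (bg_len < gap * (k + 1L))
    stop(sprintf(
      "transcript %d: cannot fit %d pG4 motifs in length %d nt", idx, k,
      len))
  # split background into k+1 segments of >= gap nt
  extra <- bg_len - gap * (k + 1L)
  seg <- rep(gap, k + 1L)
  if (extra > 0L && k > 0L) {
    add <- tabulate(sample.int(k + 1L, extra, replace = TRUE), k + 1L)
    seg <- seg + add
  } else if (k == 0L) {
    seg <- bg_len
  }
  # background GC chosen so the assembled sequence lands near target;
  # exact repair below removes residual sampling error
  cas_gc <- sum(strsplit(paste(cassettes, collapse = ""), "")[[1]] %in%
                  c("G", "C"))
  bg_gc <- if (bg_len > 0) (gc_target * len - cas_gc) / bg_len else 0
  bg_gc <- min(max(bg_gc, 0.02), 0.95)
  pieces <- character(2L * k + 1L)
  editable <- vector("list", 2L * k + 1L)
  for (i in seq_len(k + 1L)) {
    bg <- .random_background(seg[i], bg_gc)
    pieces[2L * i - 1L] <- paste(bg, collapse = "")
    editable[[2L * i - 1L]] <- rep(TRUE, seg[i])
    if (i <= k) {
      pieces[2L * i] <- cassettes[i]
      editable[[2L * i]] <- rep(FALSE, nchar(cassettes[i]))
    }
  }
  chars <- strsplit(paste(pieces, collapse = ""), "")[[1]]
  edit <- unlist(editable, use.names = FALSE)
  # never edit a position adjacent to a cassette guanine into G (we only
  # flip to A or C, so run structure is safe)
  chars <- .repair_gc(chars, edit, round(gc_target * len))
  paste(chars, collapse = "")
}

#' Simulate a transcriptome with planted pG4 motifs
#'
#' Generates `n_transcripts` sequences whose `G3L1-7` scan count equals the
#' planted motif count exactly, with per-transcript G/C content within
#' rounding of its sampled target. Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return An object of class `g4rp_transcriptome`: list with `sequences`
#'   (named character vector, in the configured alphabet), `features` (the
#'   [transcript_features()] table plus `gc_target` and `planted_pg4`), and
#'   `config`.
#' @export
simulate_transcriptome <- function(config = simulation_config()) {
  stopifnot(inherits(config, "g4rp_sim_config"))
  n <- config$n_transcripts
  .with_seed(config$seed, {
    len_pool <- seq(config$length_range[1], config$length_range[2])
    lens <- if (length(len_pool) == 1L) rep(len_pool, n)
            else sample(len_pool, n, replace = TRUE)
    ks <- if (!is.null(config$pg4_counts)) config$pg4_counts
          else pmin(stats::rpois(n, config$pg4_lambda), config$pg4_max)
    # G/C target coupled to pG4 density (motifs per nt) via a Gaussian
    # copula: pG4-dense transcripts tend to be GC-rich
    rho <- config$gc_pg4_correlation
    z_dens <- stats::qnorm((rank(ks / lens, ties.method = "random") - 0.5)
                           / n)
    u <- stats::pnorm(rho * z_dens + sqrt(1 - rho^2) * stats::rnorm(n))
    gcs <- config$gc_target_range[1] +
      u * diff(config$gc_target_range)
    seqs <- vapply(seq_len(n), function(i)
      .simulate_one_sequence(lens[i], gcs[i], ks[i], i), "")
  })
  names(seqs) <- sprintf("tx%04d", seq_len(n))
  feats <- transcript_features(seqs)
  feats$gc_target <- gcs
  feats$planted_pg4 <- as.integer(ks)
  mismatch <- which(feats[["pg4_count.G3L1-7"]] != feats$planted_pg4)
  if (length(mismatch))
    stop("internal error: planted/scanned motif count mismatch at ",
         "transcript ", mismatch[1])
  if (config$alphabet == "RNA") seqs <- chartr("T", "U", seqs)
  structure(list(sequences = seqs, features = feats, config = config),
            class = "g4rp_transcriptome")
}

#' @export
print.g4rp_transcriptome <- function(x, ...) {
  cat(sprintf(
    "g4rp_transcriptome: %d transcripts (%d-%d nt), %d planted pG4 motifs\n",
    length(x$sequences), min(x$features$length), max(x$features$length),
    sum(x$features$planted_pg4)))
  invisible(x)
}
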