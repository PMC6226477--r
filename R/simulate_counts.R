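# Count model: input counts ~ NB(mean = s_j * lambda_i, dispersion alpha),
# pulldown counts ~ NB(mean = s_j * lambda_i * r_i(condition), dispersion
# alpha), where r_i = b + c * f_i(condition) is the latent capture rate and
# s_j scales each library to its expected total size.

.nb_draw <- function(mu, alpha) {
  if (alpha <= 0) return(as.integer(stats::rpois(length(mu), mu)))
  out <- integer(length(mu))
  pos <- mu > 0
  out[pos] <- as.integer(stats::rnbinom(sum(pos), mu = mu[pos],
                                        size = 1 / alpha))
  out
}

#' Simulate G4RP-seq read counts with ground truth
#'
#' Applies the latent folding/capture model to a simulated transcriptome
#' and draws negative-binomial counts for the full design: for each
#' condition, `n_input_reps` input libraries and `n_pulldown_reps` pulldown
#' (G4RP) libraries. The first configured condition is the untreated
#' baseline; under every other condition ("ligand"), a fraction of
#' transcripts (responders) has its folding propensity multiplied by
#' `responder_effect` (clamped at 1).
#'
#' @param transcriptome A [simulate_transcriptome()] result.
#' @param config A [simulation_config()]; defaults to the one stored in
#'   `transcriptome`. Counts are drawn from seed `config$seed + 1` so the
#'   sequence and count stages have distinct but linked streams.
#' @return A list of class `g4rp_simulation` with elements
#'   \describe{
#'     \item{counts}{a [g4rp_counts()] object (genes x samples),}
#'     \item{truth}{per-transcript data.frame: `lambda`, pG4 density per
#'       kb, baseline folding propensity `f_base`, and per condition the
#'       responder flag, effect multiplier and realized capture rate
#'       `r.<condition>`,}
#'     \item{size_factors_true}{the per-sample scale factors used,}
#'     \item{config}{the configuration (seed included).}
#'   }
#' @export
simulate_g4rp_counts <- function(transcriptome, config = NULL) {
  stopifnot(inherits(transcriptome, "g4rp_transcriptome"))
  if (is.null(config)) config <- transcriptome$config
  stopifnot(inherits(config, "g4rp_sim_config"))
  feats <- transcriptome$features
  n <- nrow(feats)
  ids <- feats$transcript_id
  dens_kb <- feats[["pg4_density.G3L1-7"]] * 1000
  b <- config$background_capture
  cg <- config$capture_gain
  untreated <- config$conditions[1]
  ligands <- config$conditions[-1]

  .with_seed(config$seed + 1L, {
    lambda <- stats::rlnorm(n, config$expression_log_mean,
                            config$expression_log_sd)
    f_base <- stats::plogis(config$folding_intercept +
                              config$folding_slope * dens_kb)
    is_rrna <- rep(FALSE, n)
    if (config$rrna_spike && n >= 10L) {
      is_rrna[order(lambda, decreasing = TRUE)[1:3]] <- TRUE
      lambda[is_rrna] <- lambda[is_rrna] * 50
    }
    n_resp <- round(config$responder_fraction * n)
    truth <- data.frame(transcript_id = ids, lambda = lambda,
                        pg4_density_kb = dens_kb, f_base = f_base,
                        is_rrna = is_rrna, stringsAsFactors = FALSE)
    f_cond <- list()
    f_cond[[untreated]] <- f_base
    truth[[paste0("responder.", untreated)]] <- FALSE
    truth[[paste0("effect.", untreated)]] <- 1
    for (lig in ligands) {
      w <- switch(config$responder_bias,
        low_pg4 = {
          rk <- rank(dens_kb, ties.method = "random")
          ((n - rk + 1) / n)^4
        },
        uniform = rep(1, n))
      resp <- rep(FALSE, n)
      if (n_resp > 0L)
        resp[sample.int(n, n_resp, prob = w)] <- TRUE
      eff <- ifelse(resp, config$responder_effect, 1)
      f_cond[[lig]] <- pmin(1, f_base * eff)
      truth[[paste0("responder.", lig)]] <- resp
      truth[[paste0("effect.", lig)]] <- eff
    }
    for (cond in config$conditions) {
      r <- b + cg * f_cond[[cond]]
      if (config$rrna_spike) r[is_rrna] <- b / 2
      truth[[paste0("r.", cond)]] <- r
    }

    # sample sheet
    rows <- list()
    for (cond in config$conditions) {
      for (j in seq_len(config$n_input_reps))
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_input_%d", cond, j), condition = cond,
          assay = "input", replicate = j, stringsAsFactors = FALSE)
      for (j in seq_len(config$n_pulldown_reps))
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_G4RP_%d", cond, j), condition = cond,
          assay = "G4RP", replicate = j, stringsAsFactors = FALSE)
    }
    samples <- do.call(rbind, rows)
    lib <- config$library_size
    if (is.null(names(lib))) {
      if (length(lib) == 1L) lib <- rep(lib, nrow(samples))
      else if (length(lib) != nrow(samples))
        stop("library_size must be scalar or one value per sample")
      names(lib) <- samples$sample_id
    } else {
      miss <- setdiff(samples$sample_id, names(lib))
      if (length(miss))
        stop("library_size missing for: ", paste(miss, collapse = ", "))
      lib <- lib[samples$sample_id]
    }
    if (any(lib <= 0)) stop("library sizes must be positive")

    counts <- matrix(0L, nrow = n, ncol = nrow(samples),
                     dimnames = list(ids, samples$sample_id))
    sf_true <- numeric(nrow(samples))
    names(sf_true) <- samples$sample_id
    for (j in seq_len(nrow(samples))) {
      rate <- if (samples$assay[j] == "input") lambda
              else lambda * truth[[paste0("r.", samples$condition[j])]]
      tot <- sum(rate)
      s_j <- if (tot > 0) lib[j] / tot else 0
      sf_true[j] <- s_j
      counts[, j] <- .nb_draw(s_j * rate, config$dispersion)
    }
  })
  structure(list(counts = g4rp_counts(counts, samples), truth = truth,
                 size_factors_true = sf_true, config = config),
            class = "g4rp_simulation")
}

#' @export
print.g4rp_simulation <- function(x, ...) {
  cat("g4rp_simulation (seed ", x$config$seed, ")\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Simulate a full G4RP-seq dataset in one call
#'
#' Convenience wrapper running [simulate_transcriptome()] and
#' [simulate_g4rp_counts()] under one configuration.
#'
#' @param config A [simulation_config()].
#' @return List with `transcriptome` and the `g4rp_simulation` fields
#'   (`counts`, `truth`, `size_factors_true`, `config`).
#' @export
simulate_g4rp_dataset <- function(config = simulation_config()) {
  txome <- simulate_transcriptome(config)
  sim <- simulate_g4rp_counts(txome, config)
  list(transcriptome = txome, counts = sim$counts, truth = sim$truth,
       size_factors_true = sim$size_factors_true, config = config)
}
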