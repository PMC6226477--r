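# Independent oracles, kept deliberately separate from the package's code
# paths.

# PCRE-based pG4 scan: the same lazy (leftmost, shortest) semantics
# expressed as a regex, iterated with resumption after each match end.
# Returns a data.frame of 0-based half-open intervals.
oracle_scan <- function(sequence, preset) {
  s <- chartr("u", "T", toupper(sequence))
  s <- chartr("U", "T", s)
  pat <- sprintf("G{%d,}?(?:[ACGTN]{%d,%d}?G{%d,}?){%d}",
                 preset$g, preset$loop_min, preset$loop_max, preset$g,
                 preset$n_tracts - 1L)
  starts <- integer(0); ends <- integer(0)
  off <- 1L
  repeat {
    sub <- substring(s, off)
    m <- regexpr(pat, sub, perl = TRUE)
    if (m == -1L) break
    st <- off + as.integer(m) - 1L          # 1-based start in s
    en <- st + attr(m, "match.length") - 1L # 1-based inclusive end
    starts <- c(starts, st - 1L)
    ends <- c(ends, en)
    off <- en + 1L
  }
  data.frame(start = starts, end = ends)
}

oracle_count <- function(sequence, preset) nrow(oracle_scan(sequence, preset))

# Exhaustive interval oracle for small sequences: counts non-overlapping
# hits by taking, repeatedly, the leftmost start and the shortest interval
# at that start for which some decomposition fully matches the pattern
# (checked by an anchored regex on every candidate substring).
oracle_scan_enumerative <- function(sequence, preset) {
  s <- chartr("u", "T", toupper(sequence))
  s <- chartr("U", "T", s)
  L <- nchar(s)
  pat <- sprintf("^G{%d,}(?:[ACGTN]{%d,%d}G{%d,}){%d}$",
                 preset$g, preset$loop_min, preset$loop_max, preset$g,
                 preset$n_tracts - 1L)
  minw <- preset$n_tracts * preset$g +
    (preset$n_tracts - 1L) * preset$loop_min
  hits <- data.frame(start = integer(0), end = integer(0))
  pos <- 1L
  while (pos + minw - 1L <= L) {
    found <- FALSE
    for (st in pos:(L - minw + 1L)) {
      for (en in (st + minw - 1L):L) {
        if (grepl(pat, substr(s, st, en), perl = TRUE)) {
          hits <- rbind(hits, data.frame(start = st - 1L, end = en))
          pos <- en + 1L
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    if (!found) break
  }
  hits
}

# Random test sequence with a given G probability.
random_seq <- function(len, g_prob = 0.3, seed = NULL) {
  rest <- (1 - g_prob) / 3
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c(rest, rest, g_prob, rest)), collapse = "")
}

# Closed-form OLS/Pearson oracle (textbook sums formulae).
oracle_ols <- function(y, x) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); syy <- sum(y^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  r <- (n * sxy - sx * sy) /
    sqrt((n * sxx - sx^2) * (n * syy - sy^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(slope = slope, intercept = intercept, r = r, p = p)
}

# Two-sample equal-variance t-test oracle.
oracle_t2 <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * stats::pt(-abs(tstat), df = na + nb - 2)
  list(t = tstat, p = p)
}

# Small deterministic counts fixture: 3 conditions x (1 input + 2
# pulldown), with known structure.
make_toy_counts <- function(n_genes = 8L) {
  conds <- c("untreated", "BRACO-19", "RHPS4")
  rows <- list()
  for (cond in conds) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = paste0(cond, "_input_1"), condition = cond,
      assay = "input", replicate = 1L)
    for (j in 1:2)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("%s_G4RP_%d", cond, j), condition = cond,
        assay = "G4RP", replicate = j)
  }
  samples <- do.call(rbind, rows)
  m <- matrix(100L, nrow = n_genes, ncol = nrow(samples),
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              samples$sample_id))
  g4rp_counts(m, samples)
}
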