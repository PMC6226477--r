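# Quadparser-style pG4 scanner.
#
# Matching policy: leftmost start, then lazy (shortest-first) expansion of
# every tract and loop, i.e. exactly the match a PCRE lazy pattern
# G{g,}?(?:N{lmin,lmax}?G{g,}?){k-1} would return; the scan resumes after
# each hit's end, so reported hits never overlap.

# Uppercase, U->T, and validate the alphabet; returns a character vector of
# single bases. Errors name the first illegal position (1-based).
.normalize_sequence <- function(sequence) {
  if (length(sequence) != 1L || !is.character(sequence))
    stop("sequence must be a single character string")
  s <- chartr("u", "T", toupper(sequence))
  s <- chartr("U", "T", s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop(sprintf("illegal character '%s' at position %d", chars[bad[1]],
                 bad[1]))
  chars
}

# Remaining G-run length at each position: grun[i] = number of consecutive
# G starting at i (0 if chars[i] != G).
.g_runs <- function(chars) {
  isg <- chars == "G"
  if (!length(isg)) return(integer(0))
  rl <- rle(isg)
  unlist(lapply(seq_along(rl$lengths), function(i) {
    if (rl$values[i]) rev(seq_len(rl$lengths[i])) else rep(0L, rl$lengths[i])
  }), use.names = FALSE)
}

# Backtracking matcher at a fixed start. Tries tract lengths then loop
# lengths in ascending order (lazy/PCRE order); memoises failing
# (tract index, position) states. Returns NULL or a list with 1-based
# tract_starts, tract_lens, loop_lens and inclusive end.
.match_pg4_at <- function(start, grun, L, preset) {
  g <- preset$g; lmin <- preset$loop_min; lmax <- preset$loop_max
  k <- preset$n_tracts
  fail <- matrix(FALSE, nrow = k, ncol = L)
  # min width still needed when about to match tract j: tracts j..k plus
  # loops j..k-1
  tail_need <- (k - seq_len(k) + 1L) * g + (k - seq_len(k)) * lmin

  rec <- function(j, pos) {
    if (pos > L || fail[j, pos]) return(NULL)
    avail <- grun[pos]
    if (avail < g || pos + tail_need[j] - 1L > L) {
      fail[j, pos] <<- TRUE
      return(NULL)
    }
    if (j == k) {
      # last tract: lazy => exactly g guanines
      return(list(starts = pos, lens = g, loops = integer(0),
                  end = pos + g - 1L))
    }
    for (t in g:avail) {
      after <- pos + t
      for (l in lmin:lmax) {
        nxt <- after + l
        res <- rec(j + 1L, nxt)
        if (!is.null(res)) {
          return(list(starts = c(pos, res$starts),
                      lens = c(t, res$lens),
                      loops = c(l, res$loops),
                      end = res$end))
        }
      }
    }
    fail[j, pos] <<- TRUE
    NULL
  }
  rec(1L, start)
}

#' Scan a sequence for pG4 motifs
#'
#' Finds non-overlapping predicted G-quadruplex motifs (four or more G
#' tracts separated by short loops) using leftmost, shortest (lazy)
#' matching: the scan proceeds left to right, each match is the shortest
#' one available at the leftmost possible start, and scanning resumes
#' immediately after the match end. `T` and `U` are equivalent and matching
#' is case-insensitive; `N` never counts as G but is allowed in loops.
#'
#' @param sequence A single DNA/RNA string over `A,C,G,T,U,N`
#'   (case-insensitive).
#' @param preset A [g4_preset()]; default the mid-stringency `G3L1-7`.
#' @param id Transcript identifier recorded with each hit.
#' @return A data.frame with one row per hit: `transcript_id`, `start`,
#'   `end` (0-based half-open), `width`, `matched_sequence`, and list
#'   columns `tract_starts` (0-based starts of the G tracts) and
#'   `loop_lengths`.
#' @examples
#' scan_pg4("GGGAGGGTGGGCGGG")            # one canonical hit
#' scan_pg4("AUAUGGGAGGGAGGGAGGGAU")      # RNA input
#' @export
scan_pg4 <- function(sequence, preset = g4_preset("G3L1-7"), id = "seq") {
  stopifnot(inherits(preset, "g4_preset"))
  if (nchar(sequence) == 0L) return(.empty_hits())
  chars <- .normalize_sequence(sequence)
  L <- length(chars)
  grun <- .g_runs(chars)
  minw <- .preset_min_width(preset)
  g <- preset$g

  # candidate starts: run starts with enough G (a failed run start implies
  # failure anywhere inside the same run, since shrinking tract 1 only
  # removes options)
  hits <- list()
  pos <- 1L
  while (pos <= L - minw + 1L) {
    if (grun[pos] < g) {
      # jump to next run of >= g guanines
      nxt <- pos + 1L
      while (nxt <= L - minw + 1L && grun[nxt] < g) nxt <- nxt + 1L
      pos <- nxt
      if (pos > L - minw + 1L) break
    }
    m <- .match_pg4_at(pos, grun, L, preset)
    if (is.null(m)) {
      pos <- pos + grun[pos]  # skip the rest of this G run
    } else {
      hits[[length(hits) + 1L]] <- list(
        start = pos - 1L, end = m$end,
        tract_starts = m$starts - 1L, loop_lengths = m$loops,
        seq = paste(chars[pos:m$end], collapse = "")
      )
      pos <- m$end + 1L
    }
  }
  if (!length(hits)) return(.empty_hits())
  data.frame(
    transcript_id = id,
    start = vapply(hits, `[[`, 0L, "start"),
    end = vapply(hits, `[[`, 0L, "end"),
    width = vapply(hits, function(h) h$end - h$start, 0L),
    matched_sequence = vapply(hits, `[[`, "", "seq"),
    tract_starts = I(lapply(hits, `[[`, "tract_starts")),
    loop_lengths = I(lapply(hits, `[[`, "loop_lengths")),
    stringsAsFactors = FALSE
  )
}

.empty_hits <- function() {
  data.frame(
    transcript_id = character(0), start = integer(0), end = integer(0),
    width = integer(0), matched_sequence = character(0),
    tract_starts = I(list()), loop_lengths = I(list()),
    stringsAsFactors = FALSE
  )
}

#' Count pG4 motifs in a sequence
#'
#' Number of non-overlapping pG4 hits under [scan_pg4()]'s matching policy.
#'
#' @inheritParams scan_pg4
#' @return Integer count.
#' @export
count_pg4 <- function(sequence, preset = g4_preset("G3L1-7")) {
  nrow(scan_pg4(sequence, preset))
}

#' pG4 density (motifs per nucleotide)
#'
#' The per-transcript ratio of motif count to transcript length, the
#' quantity compared between top- and bottom-ranked transcripts in
#' landscape analyses.
#'
#' @param count Motif count(s).
#' @param length Transcript length(s) in nt; must be > 0.
#' @return `count / length`.
#' @export
pg4_density <- function(count, length) {
  if (any(length <= 0)) stop("length must be > 0")
  count / length
}

#' G/C content of a sequence
#'
#' Fraction of G and C bases (case-insensitive; `U` treated as `T`). `N`
#' counts toward the denominator only.
#'
#' @inheritParams scan_pg4
#' @return Fraction in `[0, 1]`.
#' @examples
#' gc_content("GATCN")  # 0.4
#' @export
gc_content <- function(sequence) {
  chars <- .normalize_sequence(sequence)
  if (!length(chars)) stop("empty sequence")
  sum(chars %in% c("G", "C")) / length(chars)
}

#' Per-transcript sequence features
#'
#' Computes length, G/C content and pG4 count/density for each sequence at
#' one or more stringency presets.
#'
#' @param sequences Named character vector of sequences (names are
#'   transcript ids).
#' @param presets List of [g4_preset()] objects; default the three standard
#'   stringencies.
#' @return A data.frame with columns `transcript_id`, `length`,
#'   `gc_fraction`, and for each preset `P` the columns `pg4_count.P` and
#'   `pg4_density.P`.
#' @export
transcript_features <- function(sequences, presets = standard_presets()) {
  if (is.null(names(sequences)) || anyNA(names(sequences)) ||
      any(names(sequences) == ""))
    stop("sequences must be a named character vector")
  if (anyDuplicated(names(sequences)))
    stop("duplicate transcript ids: ",
         paste(unique(names(sequences)[duplicated(names(sequences))]),
               collapse = ", "))
  if (inherits(presets, "g4_preset")) presets <- list(presets)
  pn <- vapply(presets, `[[`, "", "name")
  len <- nchar(sequences)
  out <- data.frame(
    transcript_id = names(sequences),
    length = as.integer(len),
    gc_fraction = vapply(sequences, gc_content, 0, USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(presets)) {
    cnt <- vapply(sequences, count_pg4, 0L, preset = presets[[i]],
                  USE.NAMES = FALSE)
    out[[paste0("pg4_count.", pn[i])]] <- cnt
    out[[paste0("pg4_density.", pn[i])]] <- pg4_density(cnt, len)
  }
  rownames(out) <- NULL
  out
}
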