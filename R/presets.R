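#' Stringency presets for pG4 motif scanning
#'
#' A predicted G-quadruplex (pG4) motif is four runs ("tracts") of at least
#' `g` consecutive guanines separated by three loops of `loop_min` to
#' `loop_max` nucleotides. The named presets correspond to the stringencies
#' commonly used for transcriptome scans: `"G3L1-7"` (mid stringency,
#' tracts of >= 3 G, loops 1-7 nt), `"G3L1-5"` (high stringency) and
#' `"G2L1-10"` (low stringency, 2-G tracts, loops up to 10 nt).
#'
#' @param name One of `"G3L1-7"`, `"G3L1-5"`, `"G2L1-10"`, or any label when
#'   the remaining arguments are supplied explicitly.
#' @param g Minimum G-run (tract) length; >= 2.
#' @param loop_min,loop_max Loop length bounds in nucleotides;
#'   `1 <= loop_min <= loop_max`.
#' @param n_tracts Number of G tracts; >= 4 (4 = intramolecular G4).
#' @return An object of class `g4_preset`: a list with fields `name`, `g`,
#'   `loop_min`, `loop_max`, `n_tracts`.
#' @examples
#' g4_preset("G3L1-7")
#' g4_preset("custom", g = 3, loop_min = 1, loop_max = 12)
#' @export
g4_preset <- function(name = "G3L1-7", g = NULL, loop_min = NULL,
                      loop_max = NULL, n_tracts = 4L) {
  known <- list(
    "G3L1-7"  = list(g = 3L, loop_min = 1L, loop_max = 7L),
    "G3L1-5"  = list(g = 3L, loop_min = 1L, loop_max = 5L),
    "G2L1-10" = list(g = 2L, loop_min = 1L, loop_max = 10L)
  )
  if (is.null(g)) {
    if (!name %in% names(known))
      stop("unknown preset '", name, "'; supply g/loop_min/loop_max for a ",
           "custom preset or use one of: ",
           paste(names(known), collapse = ", "))
    k <- known[[name]]
    g <- k$g; loop_min <- k$loop_min; loop_max <- k$loop_max
  }
  g <- as.integer(g)
  loop_min <- as.integer(loop_min)
  loop_max <- as.integer(loop_max)
  n_tracts <- as.integer(n_tracts)
  if (is.na(g) || g < 2L) stop("g must be an integer >= 2")
  if (is.na(loop_min) || is.na(loop_max) || loop_min < 1L ||
      loop_min > loop_max)
    stop("loop bounds must satisfy 1 <= loop_min <= loop_max")
  if (is.na(n_tracts) || n_tracts < 4L) stop("n_tracts must be >= 4")
  structure(
    list(name = name, g = g, loop_min = loop_min, loop_max = loop_max,
         n_tracts = n_tracts),
    class = "g4_preset"
  )
}

#' @export
print.g4_preset <- function(x, ...) {
  cat(sprintf("pG4 stringency preset '%s': %d tracts of >=%d G, loops %d-%d nt\n",
              x$name, x$n_tracts, x$g, x$loop_min, x$loop_max))
  invisible(x)
}

# Minimal possible motif width for a preset.
.preset_min_width <- function(preset) {
  preset$n_tracts * preset$g + (preset$n_tracts - 1L) * preset$loop_min
}

#' The three standard scan stringencies
#'
#' Convenience list of the `G3L1-7`, `G3L1-5` and `G2L1-10` presets, in that
#' order, named by preset label.
#'
#' @return Named list of [g4_preset()] objects.
#' @export
standard_presets <- function() {
  ps <- lapply(c("G3L1-7", "G3L1-5", "G2L1-10"), g4_preset)
  names(ps) <- vapply(ps, `[[`, "", "name")
  ps
}
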