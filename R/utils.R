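# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Format numerics with 6 significant digits for table output.
.fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(signif(x, 6), format = "g", digits = 6))
}

#' Temperatures of a stepwise melt ramp
#'
#' The melt protocol equilibrates at a start temperature and then steps up
#' by a fixed increment once per cycle, reading fluorescence after each
#' cycle. The default arguments reproduce the standard FRET-melting ramp:
#' 25 degrees C start, 65 cycles of +1 degree C, ending at 90 degrees C.
#'
#' @param start Start (equilibration) temperature, degrees C.
#' @param step Increment per cycle, degrees C.
#' @param cycles Number of cycles.
#' @return Numeric vector of length `cycles + 1`: the start temperature
#'   followed by the temperature after each cycle.
#' @examples
#' max(melt_ramp())  # 90
#' @export
melt_ramp <- function(start = 25, step = 1, cycles = 65) {
  if (cycles < 1) stop("cycles must be >= 1")
  start + step * (0:cycles)
}
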