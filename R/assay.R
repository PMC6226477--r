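# Quantitative wet-lab readouts: FRET melt curves (T1/2), bead capture
# efficiency, G4RP-qPCR fold changes and dose-response LDx interpolation.

#' Construct a melt curve
#'
#' @param temperature Strictly increasing temperatures (degrees C).
#' @param emission Fluorescence emission, same length (arbitrary units).
#' @param label Optional label (sequence, ligand, concentration).
#' @return data.frame of class `melt_curve` with columns `temperature`,
#'   `emission` and attribute `label`.
#' @export
melt_curve <- function(temperature, emission, label = NULL) {
  if (length(temperature) != length(emission))
    stop("temperature and emission must have equal length")
  if (length(temperature) < 2L) stop("need at least 2 points")
  if (any(diff(temperature) <= 0))
    stop("temperatures must be strictly increasing")
  out <- data.frame(temperature = as.numeric(temperature),
                    emission = as.numeric(emission))
  attr(out, "label") <- label
  class(out) <- c("melt_curve", "data.frame")
  out
}

#' Min-max normalize a melt curve to [0, 1]
#'
#' Maps emission affinely so the curve's own minimum is 0 and maximum 1,
#' the convention under which T1/2 is read at 0.5.
#'
#' @param curve A [melt_curve()].
#' @return The curve with a `normalized` column added.
#' @export
normalize_melt <- function(curve) {
  stopifnot(inherits(curve, "melt_curve"))
  rng <- range(curve$emission)
  if (diff(rng) == 0) stop("flat emission: cannot normalize")
  curve$normalized <- (curve$emission - rng[1]) / diff(rng)
  curve
}

#' Half-melting temperature T1/2
#'
#' The temperature at which the normalized emission first crosses 0.5 going
#' upward, linearly interpolated between the bracketing readings. An exact
#' sampled 0.5 is returned as-is; multiple upward crossings trigger a
#' warning and the first is used.
#'
#' @param curve A [melt_curve()] (normalized on the fly if needed).
#' @return T1/2 in degrees C.
#' @export
t_half <- function(curve) {
  stopifnot(inherits(curve, "melt_curve"))
  if (is.null(curve$normalized)) curve <- normalize_melt(curve)
  y <- curve$normalized
  tp <- curve$temperature
  exact <- which(y == 0.5)
  up <- which(y[-length(y)] < 0.5 & y[-1L] > 0.5)
  cand <- sort(c(exact, up + 0.5))  # order events along the curve
  if (!length(cand)) stop("normalized emission never crosses 0.5")
  if (length(cand) > 1L)
    warning("multiple 0.5 crossings; using the first")
  first <- cand[1L]
  if (first == floor(first)) return(tp[first])
  i <- floor(first)
  tp[i] + (0.5 - y[i]) / (y[i + 1L] - y[i]) * (tp[i + 1L] - tp[i])
}

#' Ligand-induced melting temperature shift
#'
#' `dT1/2 = T1/2(with ligand) - T1/2(without ligand)`. Given replicate
#' triplets (lists of curves), the shift is computed per paired replicate
#' and then averaged.
#'
#' @param with_ligand,without_ligand A [melt_curve()] each, or lists of
#'   paired replicate curves of equal length.
#' @return Mean dT1/2 in degrees C.
#' @export
delta_t_half <- function(with_ligand, without_ligand) {
  aslist <- function(x) if (inherits(x, "melt_curve")) list(x) else x
  wl <- aslist(with_ligand); wo <- aslist(without_ligand)
  if (length(wl) != length(wo))
    stop("replicate lists must have equal length")
  mean(vapply(seq_along(wl), function(i)
    t_half(wl[[i]]) - t_half(wo[[i]]), 0))
}

#' Bead capture efficiency
#'
#' Fold enrichment of captured signal over the no-probe control wells:
#' control wells are normalized to 1, so the result is
#' `mean(sample) / mean(control)`.
#'
#' @param sample_signals Emission of sample wells (probe + beads).
#' @param control_signals Emission of control wells (no probe).
#' @return Fold enrichment (controls map to 1).
#' @export
capture_efficiency <- function(sample_signals, control_signals) {
  if (!length(sample_signals) || !length(control_signals))
    stop("need at least one sample and one control well")
  ctrl <- mean(control_signals)
  if (ctrl <= 0) stop("control mean must be positive")
  mean(sample_signals) / ctrl
}

#' A G4RP-qPCR measurement
#'
#' @param target Target transcript name.
#' @param condition Treatment condition.
#' @param ct_pulldown,ct_input Ct values (technical triplicates) for the
#'   pulldown sample and its input control.
#' @return List of class `qpcr_measurement`.
#' @export
qpcr_measurement <- function(target, condition, ct_pulldown, ct_input) {
  if (!length(ct_pulldown) || !length(ct_input))
    stop("pulldown and input Ct values are both required")
  if (any(c(ct_pulldown, ct_input) <= 0)) stop("Ct values must be > 0")
  structure(list(target = target, condition = condition,
                 ct_pulldown = as.numeric(ct_pulldown),
                 ct_input = as.numeric(ct_input)),
            class = "qpcr_measurement")
}

#' qPCR fold change of pulldown enrichment, treated vs untreated
#'
#' Technical triplicates are averaged on the Ct scale; each condition's
#' pulldown Ct is normalized to its input control
#' (`dCt = Ct_pulldown - Ct_input`), and the fold change is
#' `efficiency ^ (dCt_untreated - dCt_treated)` (the delta-delta-Ct
#' method; efficiency 2 assumes perfect doubling per cycle).
#'
#' @param treated,untreated [qpcr_measurement()] objects.
#' @param efficiency Amplification efficiency per cycle (default 2).
#' @return Fold change (1 = no ligand-induced change).
#' @export
qpcr_fold_change <- function(treated, untreated, efficiency = 2) {
  stopifnot(inherits(treated, "qpcr_measurement"),
            inherits(untreated, "qpcr_measurement"))
  if (efficiency <= 1) stop("efficiency must be > 1")
  dct <- function(m) mean(m$ct_pulldown) - mean(m$ct_input)
  efficiency^(dct(untreated) - dct(treated))
}

#' Construct a dose-response curve
#'
#' Confluency (growth) versus ligand dose, min-max normalized with the
#' maximum and minimum achievable confluency so the response lies in
#' [0, 1] (1 = untreated growth, 0 = full inhibition).
#'
#' @param dose Nonnegative doses, strictly increasing.
#' @param response Confluency values, same length.
#' @param normalize Apply min-max normalization (default); set `FALSE` if
#'   `response` is already normalized.
#' @return data.frame of class `dose_response_curve` with columns `dose`,
#'   `response`, `normalized`.
#' @export
dose_response_curve <- function(dose, response, normalize = TRUE) {
  if (length(dose) != length(response))
    stop("dose and response must have equal length")
  if (length(dose) < 2L) stop("need at least 2 doses")
  if (any(dose < 0)) stop("doses must be nonnegative")
  if (any(diff(dose) <= 0)) stop("doses must be strictly increasing")
  norm <- if (normalize) {
    rng <- range(response)
    if (diff(rng) == 0) stop("flat response: cannot normalize")
    (response - rng[1]) / diff(rng)
  } else {
    if (any(response < 0 | response > 1))
      stop("response not in [0, 1]; use normalize = TRUE")
    response
  }
  out <- data.frame(dose = as.numeric(dose),
                    response = as.numeric(response), normalized = norm)
  class(out) <- c("dose_response_curve", "data.frame")
  out
}

#' Interpolate an LDx dose from a dose-response curve
#'
#' The dose at which the normalized response equals `1 - x/100` (x percent
#' growth inhibition), linearly interpolated on log10(dose) between the
#' bracketing measured doses -- the natural scale for serial dilutions.
#' Extrapolation beyond the measured response range is refused.
#'
#' @param curve A [dose_response_curve()].
#' @param x Percent inhibition in (0, 100), e.g. 15 for LD15.
#' @return Interpolated dose (same units as `curve$dose`).
#' @export
ld_dose <- function(curve, x) {
  stopifnot(inherits(curve, "dose_response_curve"))
  if (x <= 0 || x >= 100) stop("x must be in (0, 100)")
  target <- 1 - x / 100
  y <- curve$normalized
  d <- curve$dose
  exact <- which(y == target)
  if (length(exact)) return(d[exact[1L]])
  br <- which((y[-length(y)] - target) * (y[-1L] - target) < 0)
  if (!length(br))
    stop(sprintf(
      "target response %.3f outside the observed range [%.3f, %.3f]; %s",
      target, min(y), max(y), "refusing to extrapolate"))
  i <- br[1L]
  if (d[i] <= 0)
    stop("cannot log-interpolate across dose 0")
  ld <- log10(d[i]) + (target - y[i]) / (y[i + 1L] - y[i]) *
    (log10(d[i + 1L]) - log10(d[i]))
  10^ld
}
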