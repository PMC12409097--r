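#' Sample metadata
#'
#' Per-injection metadata needed to normalize aspartate quantities:
#' culture density (OD750), sampled volume, time after the 13CO2 pulse,
#' injected amount, GC split ratio and the 13C6-sorbitol internal-standard
#' abundance.
#'
#' @param sample_id identifier.
#' @param od750 optical density at 750 nm (> 0).
#' @param volume_ml sampled culture volume (mL, > 0).
#' @param time_min minutes after the label pulse.
#' @param injection_ng injected aspartate amount (ng), if known.
#' @param split_ratio GC split ratio (>= 1; 1 = splitless).
#' @param is_abundance internal-standard summed abundance (counts).
#' @return object of class `sample_meta`.
#' @export
sample_meta <- function(sample_id, od750, volume_ml, time_min = NA_real_,
                        injection_ng = NA_real_, split_ratio = 1,
                        is_abundance = NA_real_) {
  stopifnot(od750 > 0, volume_ml > 0, split_ratio >= 1)
  structure(list(sample_id = as.character(sample_id), od750 = od750,
                 volume_ml = volume_ml, time_min = time_min,
                 injection_ng = injection_ng, split_ratio = split_ratio,
                 is_abundance = is_abundance),
            class = "sample_meta")
}

#' Fit a quantification calibration line
#'
#' Ordinary least squares of internal-standard-normalized response
#' (summed MID abundance / IS abundance) against injected amount (ng),
#' from a dilution series of the non-labeled reference compound.
#'
#' @param levels data.frame with columns `ng` and `response`, at least 3
#'   distinct amounts.
#' @return object of class `calibration_model`: `slope`, `intercept`,
#'   `r_squared`, `range_ng`, `range_response`.
#' @export
fit_calibration <- function(levels) {
  stopifnot(is.data.frame(levels), all(c("ng", "response") %in% names(levels)))
  if (length(unique(levels$ng)) < 3L) {
    stop("calibration needs at least 3 distinct amount levels")
  }
  fit <- stats::lm(response ~ ng, data = levels)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration slope must be positive; got ", signif(slope, 3))
  }
  tss <- sum((levels$response - mean(levels$response))^2)
  structure(list(
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    r_squared = 1 - sum(stats::residuals(fit)^2) / tss,
    range_ng = range(levels$ng),
    range_response = range(levels$response)
  ), class = "calibration_model")
}

#' Molecular weight of aspartic acid (g/mol), monoisotopic-free average
#' used for ng-to-pmol conversion.
#' @export
ASPARTATE_MW <- 133.10

#' Quantify aspartate from summed isotopologue abundance
#'
#' The quantifier is the sum over ALL isotopologue abundances so that the
#' labeling state does not bias the concentration. The IS-normalized
#' response is inverted through the calibration line, corrected for split
#' ratio and extraction aliquot, converted ng -> pmol, and normalized to
#' OD750 x volume.
#'
#' @param sum_mid summed isotopologue abundance (counts).
#' @param meta a [sample_meta()] with positive `is_abundance`.
#' @param cal a [calibration_model()][fit_calibration].
#' @param mw molecular weight (g/mol), default [ASPARTATE_MW].
#' @param aliquot_factor fraction of the extract that reached the
#'   injection (default 1; exposed because extraction aliquot volumes are
#'   workflow-specific).
#' @return list with `conc` (pmol / OD750 / mL), `amount_ng`, `flags`
#'   (`extrapolated` when the response is outside the calibrated range).
#' @export
quantify_aspartate <- function(sum_mid, meta, cal, mw = ASPARTATE_MW,
                               aliquot_factor = 1) {
  stopifnot(inherits(meta, "sample_meta"), inherits(cal, "calibration_model"))
  if (!is.finite(meta$is_abundance) || meta$is_abundance <= 0) {
    stop("internal-standard abundance must be positive")
  }
  flags <- character(0)
  response <- sum_mid / meta$is_abundance
  if (response < cal$range_response[1] || response > cal$range_response[2]) {
    flags <- "extrapolated"
  }
  amount_ng <- (response - cal$intercept) / cal$slope *
    meta$split_ratio / aliquot_factor
  amount_ng <- max(amount_ng, 0)
  pmol <- amount_ng / mw * 1000          # ng / (g/mol) * 1000 = pmol
  list(conc = pmol / (meta$od750 * meta$volume_ml),
       amount_ng = amount_ng, flags = flags)
}

#' Molar 13C per carbon position
#'
#' Multiplies positional enrichments by the aspartate pool to give molar
#' 13C concentration at each backbone position.
#'
#' @param pos a [positional_e13c()] result or bare e1..e4 vector.
#' @param conc aspartate concentration (pmol / OD750 / mL, >= 0).
#' @return numeric vector m1..m4 (pmol 13C / OD750 / mL).
#' @export
positional_molar <- function(pos, conc) {
  stopifnot(conc >= 0)
  e <- if (inherits(pos, "positional_enrichment")) pos$e else as.numeric(pos)
  stopifnot(length(e) == 4)
  e * conc
}
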