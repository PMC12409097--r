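#' Standard mixture design
#'
#' A gravimetric mixture of certified aspartic acid standards.
#'
#' @param components list of `list(cert = standard_certificate,
#'   fraction = mole fraction)`; fractions must sum to 1.
#' @param total_ng_injected total aspartic acid per injection (ng).
#' @param id optional identifier.
#' @return object of class `mixture_design`.
#' @export
mixture_design <- function(components, total_ng_injected = 25, id = NULL) {
  fr <- vapply(components, function(c) c$fraction, numeric(1))
  if (abs(sum(fr) - 1) > 1e-9) stop("mole fractions must sum to 1")
  lapply(components, function(c) {
    stopifnot(inherits(c$cert, "standard_certificate"))
  })
  structure(list(components = components,
                 total_ng_injected = total_ng_injected, id = id),
            class = "mixture_design")
}

#' Expected positional enrichment of a mixture
#'
#' `e_i = sum_c fraction_c * purity_c * [i in label_positions_c]`:
#' linear in mole fractions and invariant to component order.
#'
#' @param design a [mixture_design()].
#' @return numeric e1..e4 (fractions).
#' @export
expected_positional <- function(design) {
  stopifnot(inherits(design, "mixture_design"))
  e <- numeric(4)
  for (comp in design$components) {
    for (p in comp$cert$label_positions) {
      e[p] <- e[p] + comp$fraction * comp$cert$purity
    }
  }
  e
}

#' The 36 validation mixture designs
#'
#' Reconstruction of the standards panel from its stated design rules:
#' each of the five labeled standards (\[U-13C\], \[1-13C\] ... \[4-13C\])
#' mixed with natural aspartic acid at labeled fractions 100, 95, 90, 50,
#' 10 and 5 % (30 designs), the equal 1:1:1:1 mix of the four positional
#' standards isotope-diluted to 100, 50, 20, 10 and 4 % of total (5), and
#' pure natural aspartic acid (1). The exact composition table of the
#' original panel is not redistributed with this package; this
#' reconstruction follows the stated ratio and dilution series.
#'
#' @param total_ng_injected ng per injection (default 25).
#' @return list of 36 [mixture_design()] objects.
#' @export
standard_mixture_designs <- function(total_ng_injected = 25) {
  certs <- aspartate_certificates()
  natural <- certs$natural
  designs <- list()
  labeled <- certs[c("U13C", "C1", "C2", "C3", "C4")]
  for (nm in names(labeled)) {
    for (fr in c(1, 0.95, 0.90, 0.50, 0.10, 0.05)) {
      comps <- list(list(cert = labeled[[nm]], fraction = fr))
      if (fr < 1) {
        comps <- c(comps, list(list(cert = natural, fraction = 1 - fr)))
      }
      designs[[length(designs) + 1L]] <- mixture_design(
        comps, total_ng_injected,
        id = sprintf("%s_%02d", nm, round(100 * fr)))
    }
  }
  for (dil in c(1, 0.5, 0.2, 0.1, 0.04)) {
    comps <- lapply(certs[c("C1", "C2", "C3", "C4")], function(cert) {
      list(cert = cert, fraction = dil / 4)
    })
    names(comps) <- NULL
    if (dil < 1) {
      comps <- c(comps, list(list(cert = natural, fraction = 1 - dil)))
    }
    designs[[length(designs) + 1L]] <- mixture_design(
      comps, total_ng_injected, id = sprintf("mix1111_%03d", round(100 * dil)))
  }
  designs[[length(designs) + 1L]] <- mixture_design(
    list(list(cert = natural, fraction = 1)), total_ng_injected,
    id = "natural")
  designs
}

#' Accuracy and precision of enrichment deviations
#'
#' Deviations are `measured - expected` in percentage points; the mean
#' deviation is the accuracy measure and its SD the precision measure.
#'
#' @param measured numeric vector (or matrix, rows = measurements) of
#'   enrichment fractions.
#' @param expected matching expected fractions (scalar/vector recycled
#'   over rows).
#' @param group grouping label carried through to the output.
#' @return object of class `deviation_stats`: `mean_dev`, `sd_dev`
#'   (percentage points), `n`, `group`.
#' @export
deviation_stats <- function(measured, expected, group = NA_character_) {
  measured <- as.numeric(measured)
  expected <- as.numeric(expected)
  if (length(expected) == 1L) expected <- rep(expected, length(measured))
  if (length(measured) != length(expected)) {
    stop("measured and expected lengths differ")
  }
  dev <- 100 * (measured - expected)
  n <- sum(!is.na(dev))
  structure(list(
    mean_dev = mean(dev, na.rm = TRUE),
    sd_dev = if (n >= 2) stats::sd(dev, na.rm = TRUE) else NA_real_,
    n = n, group = group
  ), class = "deviation_stats")
}

#' Minimal acceptable injection amount per fragment
#'
#' Scans deviation results over an injection dilution series and reports,
#' per fragment, the smallest amount from which the mean absolute
#' deviation stays within `threshold` (default 1 percentage point, the
#' headline accuracy bound) at that and every larger amount.
#'
#' @param results data.frame with columns `fragment`, `injection_ng`,
#'   `dev` (percentage points; one row per measurement).
#' @param threshold percentage points (default 1).
#' @return data.frame with columns `fragment`, `min_ng` (`NA` when no
#'   level passes, reported as "not reached").
#' @export
detection_scan <- function(results, threshold = 1) {
  stopifnot(all(c("fragment", "injection_ng", "dev") %in% names(results)))
  if (length(unique(results$injection_ng)) < 3L) {
    stop("need at least 3 injection levels")
  }
  frs <- unique(results$fragment)
  out <- lapply(frs, function(fr) {
    sub <- results[results$fragment == fr, ]
    levels <- sort(unique(sub$injection_ng))
    ok <- vapply(levels, function(ng) {
      mean(abs(sub$dev[sub$injection_ng == ng]), na.rm = TRUE) <= threshold
    }, logical(1))
    # smallest level such that it and all higher levels pass
    min_ng <- NA_real_
    for (i in rev(seq_along(levels))) {
      if (!ok[i]) break
      min_ng <- levels[i]
    }
    data.frame(fragment = fr, min_ng = min_ng)
  })
  do.call(rbind, out)
}

#' Detector saturation flag
#'
#' Fragment abundances above the saturation threshold (default 1e7
#' arbitrary counts) carry distorted MIDs and are excluded from positional
#' calculations unless re-acquired at an adjusted split ratio.
#'
#' @param abundance summed fragment abundance (counts, >= 0).
#' @param threshold saturation threshold (default 1e7).
#' @return logical.
#' @export
flag_saturation <- function(abundance, threshold = 1e7) {
  stopifnot(all(abundance >= 0))
  abundance > threshold
}
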