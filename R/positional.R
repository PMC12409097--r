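#' Fragment-level enrichment observation
#'
#' One fragment's corrected E13C together with its coverage set and
#' (optionally) a replicate standard deviation, the inputs to the
#' positional algebra.
#'
#' @param coverage integer subset of 1:4 covered by the fragment.
#' @param e13c enrichment fraction. Values slightly outside \[0, 1\]
#'   (within a 0.02 noise tolerance) are kept and flagged, not altered, so
#'   downstream accuracy statistics remain unbiased; values beyond the
#'   tolerance are clipped to the tolerance bound and flagged `clipped`.
#' @param sd replicate standard deviation (fraction), optional.
#' @param fragment optional [fragment_spec()] provenance.
#' @return object of class `fragment_enrichment`.
#' @export
fragment_enrichment <- function(coverage, e13c, sd = NA_real_,
                                fragment = NULL) {
  coverage <- sort(unique(as.integer(coverage)))
  stopifnot(all(coverage %in% 1:4), length(coverage) >= 1)
  flags <- character(0)
  if (e13c < -0.02 || e13c > 1.02) {
    e13c <- min(max(e13c, -0.02), 1.02)
    flags <- c(flags, "clipped")
  }
  if (e13c < 0 || e13c > 1) flags <- c(flags, "out_of_range")
  if (!is.na(sd) && sd < 0) stop("sd must be non-negative")
  structure(list(coverage = coverage, e13c = e13c, sd = sd,
                 fragment = fragment, flags = flags),
            class = "fragment_enrichment")
}

.coverage_key <- function(x) paste(x, collapse = ",")

#' Positional E13C from four fragment coverages
#'
#' Combines whole-backbone and partial fragments into per-carbon
#' enrichments by carbon-number-weighted differences:
#' \deqn{e_1 = 4 E_{1234} - 3 E_{234}}
#' \deqn{e_2 = 3 E_{234} - 2 E_{34}}
#' \deqn{e_3 = 2 E_{23} + 2 E_{34} - 3 E_{234}}
#' \deqn{e_4 = 3 E_{234} - 2 E_{23}}
#' The weights are the fragment carbon numbers because a fragment's E13C
#' is the mean enrichment over its covered positions. Standard deviations
#' are propagated under an independence assumption (see Details).
#'
#' Negative or >1 positional values arising from measurement noise are
#' reported as-is with an `out_of_range` flag, never clipped.
#'
#' @details The four fragments share one ion source, so their errors may
#' be correlated; the independence assumption makes the propagated SDs an
#' approximation (documented limitation). Weights: sd(e1) =
#' sqrt(16 sd(E1234)^2 + 9 sd(E234)^2); sd(e2) = sqrt(9 sd(E234)^2 +
#' 4 sd(E34)^2); sd(e3) = sqrt(4 sd(E23)^2 + 4 sd(E34)^2 + 9 sd(E234)^2);
#' sd(e4) = sqrt(9 sd(E234)^2 + 4 sd(E23)^2).
#'
#' @param E1234 [fragment_enrichment()] with coverage \{1,2,3,4\}.
#' @param E234 coverage \{2,3,4\}.
#' @param E23 coverage \{2,3\}, or `NULL` (then e3 and e4 are `NA`,
#'   reported as undetermined rather than imputed).
#' @param E34 coverage \{3,4\}, or `NULL` (then e2 and e3 are `NA`).
#' @return object of class `positional_enrichment`: list with `e`
#'   (fractions e1..e4), `sd`, `provenance`, `flags`.
#' @export
positional_e13c <- function(E1234, E234, E23 = NULL, E34 = NULL) {
  .check_cov <- function(x, want, name) {
    if (is.null(x)) return(invisible(NULL))
    stopifnot(inherits(x, "fragment_enrichment"))
    if (!identical(x$coverage, as.integer(want))) {
      stop(sprintf("%s must cover {%s}, got {%s}", name,
                   .coverage_key(want), .coverage_key(x$coverage)))
    }
  }
  .check_cov(E1234, 1:4, "E1234")
  .check_cov(E234, 2:4, "E234")
  .check_cov(E23, 2:3, "E23")
  .check_cov(E34, 3:4, "E34")
  if (is.null(E1234) || is.null(E234)) {
    stop("coverages {1,2,3,4} and {2,3,4} are required")
  }
  v <- function(x) if (is.null(x)) NA_real_ else x$e13c
  s <- function(x) if (is.null(x) || is.na(x$sd)) NA_real_ else x$sd
  e <- c(
    4 * v(E1234) - 3 * v(E234),
    3 * v(E234) - 2 * v(E34),
    2 * v(E23) + 2 * v(E34) - 3 * v(E234),
    3 * v(E234) - 2 * v(E23)
  )
  sdv <- c(
    sqrt(16 * s(E1234)^2 + 9 * s(E234)^2),
    sqrt(9 * s(E234)^2 + 4 * s(E34)^2),
    sqrt(4 * s(E23)^2 + 4 * s(E34)^2 + 9 * s(E234)^2),
    sqrt(9 * s(E234)^2 + 4 * s(E23)^2)
  )
  flags <- character(0)
  if (any(!is.na(e) & (e < -0.05 | e > 1.05))) flags <- "out_of_range"
  if (any(is.na(e))) flags <- c(flags, "undetermined_positions")
  prov <- list(E1234 = E1234, E234 = E234, E23 = E23, E34 = E34)
  structure(list(e = e, sd = sdv, provenance = prov, flags = flags),
            class = "positional_enrichment")
}

#' @export
print.positional_enrichment <- function(x, ...) {
  cat("<positional_enrichment> (%):\n")
  for (i in 1:4) {
    cat(sprintf("  %d-C  %7.3f %s\n", i,
                100 * x$e[i],
                if (is.na(x$sd[i])) "" else sprintf("+/- %.3f", 100 * x$sd[i])))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Cross-check alternative positional calculations
#'
#' Alternative fragment combinations (different analytes, derivatives or
#' instruments) should agree; this compares positional enrichments
#' pairwise and flags positions whose maximal absolute difference exceeds
#' `tol`. Intended as an internal sanity check against fragment-specific
#' interferences.
#'
#' @param alternatives list of at least two `positional_enrichment`s.
#' @param tol tolerance on the enrichment fraction (default 0.02).
#' @return list with `max_abs_diff` (per position), `flagged_positions`,
#'   and `pairwise` (data.frame of all pairwise per-position differences).
#' @export
cross_check <- function(alternatives, tol = 0.02) {
  stopifnot(length(alternatives) >= 2)
  lapply(alternatives, function(a) stopifnot(inherits(a, "positional_enrichment")))
  pairs <- utils::combn(length(alternatives), 2)
  rows <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    data.frame(alt_a = i, alt_b = j, position = 1:4,
               diff = alternatives[[i]]$e - alternatives[[j]]$e)
  }))
  max_abs <- vapply(1:4, function(p) {
    d <- abs(rows$diff[rows$position == p])
    if (all(is.na(d))) NA_real_ else max(d, na.rm = TRUE)
  }, numeric(1))
  list(
    max_abs_diff = max_abs,
    flagged_positions = which(!is.na(max_abs) & max_abs > tol),
    pairwise = rows
  )
}
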