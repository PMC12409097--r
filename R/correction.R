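#' Build a natural-isotope-abundance correction matrix
#'
#' Column `j` (tracer count `j = 0..n`, `n` = number of covered backbone
#' carbons) is the expected measured MID of a fragment carrying exactly `j`
#' tracer 13C atoms: the natural pattern of the formula minus the `n`
#' backbone carbons, convolved with a `j`-offset shift and with the binomial
#' natural 13C pattern of the remaining `n - j` backbone carbons. Solving
#' the linear system against a measured MID removes all natural-isotope
#' contributions (13C, 2H, 15N, 17/18O, 29/30Si) so that the solution
#' reflects tracer labeling only.
#'
#' @param frag a [fragment_spec()].
#' @param n_measured number of measured mass offsets (rows); must be at
#'   least `n_tracer + 1`. Default `n_tracer + 4` captures the Si envelope.
#' @param prune pattern prune threshold, see [natural_pattern()].
#' @return matrix (`n_measured` x `n_tracer + 1`) of class
#'   `correction_matrix` with the fragment attached as attribute `fragment`.
#' @export
build_correction_matrix <- function(frag, n_measured = frag$n_tracer + 4L,
                                    prune = 1e-9) {
  stopifnot(inherits(frag, "fragment_spec"))
  n <- frag$n_tracer
  if (n_measured < n + 1L) stop("n_measured must be at least n_tracer + 1")
  f <- frag$ion_formula
  if (is.null(f[["C"]]) || f[["C"]] < n) stop("fragment formula missing carbons")
  rest <- unclass(f)
  rest[["C"]] <- rest[["C"]] - n
  rest <- rest[rest > 0]
  rest_pat <- if (length(rest)) natural_pattern(validate_formula(rest), prune) else 1
  a13 <- ISOTOPES$C$abundance[2]
  M <- matrix(0, nrow = n_measured, ncol = n + 1L)
  for (j in 0:n) {
    resid <- stats::dbinom(0:(n - j), n - j, a13)
    col <- convolve_patterns(rest_pat, resid, normalize = FALSE)
    col <- c(rep(0, j), col)          # shift by j tracer masses
    len <- min(length(col), n_measured)
    M[seq_len(len), j + 1L] <- col[seq_len(len)]
  }
  structure(M, class = c("correction_matrix", "matrix", "array"),
            fragment = frag)
}

#' Forward-model a measured MID from tracer-isotopologue fractions
#'
#' The noise-free expected measured MID for tracer fractions `x`
#' (`length(x) = n_tracer + 1`): the matrix-vector product `M x`. Inverse
#' of [correct_mid()]; used as round-trip oracle and by the simulator.
#'
#' @param M a `correction_matrix`.
#' @param x tracer-isotopologue fractions (non-negative, sum 1).
#' @return numeric measured-MID vector (rows of `M`).
#' @export
forward_mid <- function(M, x) {
  stopifnot(inherits(M, "correction_matrix"), length(x) == ncol(M),
            all(x >= 0))
  as.numeric(M %*% (x / sum(x)))
}

#' Correct a raw MID for natural isotope abundance
#'
#' Solves the non-negative least squares problem
#' `min || M x - m ||` with `m` the raw abundances normalized to sum 1,
#' yielding tracer-isotopologue fractions `x0..xn` and the fractional 13C
#' enrichment E13C. NNLS (Lawson-Hanson, via `pracma::lsqnonneg`) is used
#' rather than plain inversion because inversion produces negative
#' fractions at low abundance; the inversion route is retained in the test
#' suite as an independent cross-check.
#'
#' @param raw a [mid_measurement()] or bare numeric abundance vector.
#' @param M a `correction_matrix` for the same fragment; built on demand
#'   when `NULL`.
#' @param poor_fit_tol relative residual above which the `poor_fit` flag is
#'   set (default 0.05).
#' @return object of class `corrected_mid`: list with `fractions`
#'   (x0..xn, sum 1), `e13c` (fraction in \[0,1\]), `residual_norm`
#'   (relative), `flags` (character subset of `saturated`,
#'   `negative_clipped`, `poor_fit`) and `fragment`.
#' @export
correct_mid <- function(raw, M = NULL, poor_fit_tol = 0.05) {
  flags <- character(0)
  frag <- NULL
  if (inherits(raw, "mid_measurement")) {
    frag <- raw$fragment
    if (isTRUE(raw$saturated)) flags <- c(flags, "saturated")
    raw <- raw$abundances
  }
  raw <- as.numeric(raw)
  if (all(raw == 0)) stop("all-zero abundance vector cannot be corrected")
  if (any(raw < 0)) stop("negative abundances")
  if (is.null(M)) {
    if (is.null(frag)) stop("need a correction matrix or a mid_measurement")
    M <- build_correction_matrix(frag, n_measured = length(raw))
  }
  frag <- attr(M, "fragment")
  n_rows <- nrow(M)
  if (length(raw) > n_rows) {
    raw <- raw[seq_len(n_rows)]
  } else if (length(raw) < n_rows) {
    # documented truncation: drop trailing matrix rows, renormalize columns
    warning("measured vector shorter than correction matrix; truncating matrix")
    M2 <- M[seq_along(raw), , drop = FALSE]
    M2 <- sweep(M2, 2, colSums(M2), "/")
    M <- structure(M2, class = class(M), fragment = frag)
    n_rows <- nrow(M)
  }
  m <- raw / sum(raw)
  sol <- pracma::lsqnonneg(unclass(M), m)
  x <- sol$x
  if (sum(x) <= 0) stop("degenerate correction: NNLS solution is zero")
  resid <- sqrt(sum((unclass(M) %*% x - m)^2)) / sqrt(sum(m^2))
  if (resid > poor_fit_tol) flags <- c(flags, "poor_fit")
  fractions <- x / sum(x)
  n <- ncol(M) - 1L
  structure(list(
    fractions = fractions,
    e13c = e13c_of(fractions, n),
    residual_norm = resid,
    flags = flags,
    fragment = frag
  ), class = "corrected_mid")
}

#' @export
print.corrected_mid <- function(x, ...) {
  cat(sprintf("<corrected_mid> E13C = %.3f %%  residual = %.2e%s\n",
              100 * x$e13c, x$residual_norm,
              if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ","), "]")
              else ""))
  cat("  fractions:", paste(sprintf("%.4f", x$fractions), collapse = " "), "\n")
  invisible(x)
}

#' Fractional 13C enrichment of a tracer-isotopologue distribution
#'
#' `E13C = sum(j * x_j) / n`: the average fraction of tracer-labeled
#' carbons over the `n` covered positions.
#'
#' @param x tracer-isotopologue fractions `x0..xn`.
#' @param n number of tracer carbon positions (> 0).
#' @return fraction in \[0, 1\].
#' @export
e13c_of <- function(x, n) {
  if (n <= 0) stop("n must be positive")
  stopifnot(length(x) >= 1)
  sum((seq_along(x) - 1L) * x) / (sum(x) * n)
}

#' Certificate of a labeled aspartic acid standard
#'
#' @param label_positions integer subset of 1:4 that the standard labels
#'   (integer(0) for natural aspartic acid).
#' @param purity certificate 13C atom fraction at the labeled positions
#'   (0 < purity <= 1).
#' @param name optional display name.
#' @return object of class `standard_certificate`.
#' @export
standard_certificate <- function(label_positions, purity, name = NULL) {
  label_positions <- sort(unique(as.integer(label_positions)))
  stopifnot(all(label_positions %in% 1:4),
            is.numeric(purity), purity > 0, purity <= 1)
  structure(list(label_positions = label_positions, purity = purity,
                 name = name), class = "standard_certificate")
}

#' Certified aspartic acid standards
#'
#' The manufacturer certificates of the six standards used for validation:
#' natural aspartic acid plus \[U-13C\] (99.0 %) and the four positional
#' \[1-13C\] (99.6 %), \[2-13C\] (99.7 %), \[3-13C\] (99.6 %) and
#' \[4-13C\] (99.3 %) standards.
#'
#' @return named list of [standard_certificate()] objects.
#' @export
aspartate_certificates <- function() {
  list(
    natural = standard_certificate(integer(0), purity = 1, name = "natural"),
    U13C = standard_certificate(1:4, 0.990, name = "[U-13C]"),
    C1 = standard_certificate(1L, 0.996, name = "[1-13C]"),
    C2 = standard_certificate(2L, 0.997, name = "[2-13C]"),
    C3 = standard_certificate(3L, 0.996, name = "[3-13C]"),
    C4 = standard_certificate(4L, 0.993, name = "[4-13C]")
  )
}

#' Expected post-correction enrichment of a standard in a mixture
#'
#' Expected E13C after natural-abundance correction for a certified
#' standard present at `fraction_in_mixture`: `fraction * purity` at a
#' labeled position, 0 elsewhere; the whole-molecule value is the mean over
#' the four positions. Measurements themselves are not purity-corrected;
#' the certificate purity instead enters the expectation, the conservative
#' reading of manual tracer-impurity adjustment.
#'
#' @param cert a [standard_certificate()].
#' @param position 1..4, or `"whole"` for the whole-molecule mean.
#' @param fraction_in_mixture mole fraction of the standard (default 1).
#' @return expected enrichment fraction.
#' @export
expected_e13c <- function(cert, position = "whole", fraction_in_mixture = 1) {
  stopifnot(inherits(cert, "standard_certificate"),
            fraction_in_mixture >= 0, fraction_in_mixture <= 1)
  per_pos <- function(p) {
    if (p %in% cert$label_positions) fraction_in_mixture * cert$purity else 0
  }
  if (identical(position, "whole")) {
    mean(vapply(1:4, per_pos, numeric(1)))
  } else {
    stopifnot(position %in% 1:4)
    per_pos(as.integer(position))
  }
}
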