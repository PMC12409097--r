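#' Isotope abundance and mass table
#'
#' Pinned IUPAC/CIAAW representative isotopic compositions and relative atomic
#' masses for the elements that occur in silylated amino acid derivatives
#' (C, H, N, O, Si, S, P). Values are pinned to one published table rather
#' than tracking "latest" so that corrected enrichments are reproducible
#' across package versions.
#'
#' @format A list keyed by element symbol. Each entry is a list with
#'   `mass` (Da, by increasing nominal mass) and `abundance` (fractions
#'   summing to 1). Index 1 is the lightest isotope; successive entries are
#'   +1 nominal mass apart.
#' @references Meija et al. (2016) Isotopic compositions of the elements
#'   2013 (IUPAC Technical Report). Pure Appl. Chem. 88, 293-306.
#' @export
ISOTOPES <- list(
  C  = list(mass = c(12.0, 13.00335484), abundance = c(0.9893, 0.0107)),
  H  = list(mass = c(1.00782503, 2.01410178), abundance = c(0.999885, 0.000115)),
  N  = list(mass = c(14.00307401, 15.00010890), abundance = c(0.99636, 0.00364)),
  O  = list(mass = c(15.99491462, 16.99913176, 17.99915961),
            abundance = c(0.99757, 0.00038, 0.00205)),
  Si = list(mass = c(27.97692653, 28.97649466, 29.97377014),
            abundance = c(0.92223, 0.04685, 0.03092)),
  S  = list(mass = c(31.97207100, 32.97145876, 33.96786690, NA, 35.96708076),
            abundance = c(0.9499, 0.0075, 0.0425, 0, 0.0001)),
  P  = list(mass = c(30.97376163), abundance = c(1))
)

#' Mass difference between 13C and 12C
#'
#' Spacing (Da) between successive 13C isotopologues; used to place
#' high-resolution extraction windows.
#' @export
MASS_SHIFT_13C <- 13.00335484 - 12.0

.supported_elements <- function() names(ISOTOPES)

#' Parse a molecular formula
#'
#' Parses a Hill-notation formula string ("C9H22NO2Si2") into a named
#' integer vector of element counts. Only elements present in [ISOTOPES]
#' are allowed.
#'
#' @param text formula string.
#' @return Named integer vector of class `element_formula`.
#' @examples
#' parse_formula("C4H7NO4")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty formula string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    stop("malformed formula string: ", text)
  }
  counts <- integer(0)
  for (tok in tokens) {
    el <- sub("^([A-Z][a-z]?).*$", "\\1", tok)
    nm <- sub("^[A-Z][a-z]?", "", tok)
    n <- if (nzchar(nm)) as.integer(nm) else 1L
    if (!el %in% .supported_elements()) {
      stop("unsupported element '", el, "' in formula ", text)
    }
    counts[el] <- (if (el %in% names(counts)) counts[el] else 0L) + n
  }
  validate_formula(counts)
}

validate_formula <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L || sum(counts) < 1L) stop("formula has no atoms")
  if (any(counts < 0)) stop("negative element count")
  bad <- setdiff(names(counts), .supported_elements())
  if (length(bad)) stop("unsupported element(s): ", paste(bad, collapse = ", "))
  storage.mode(counts) <- "integer"
  structure(counts, class = "element_formula")
}

#' Canonical Hill-notation string for a formula
#' @param f an `element_formula` (or named count vector).
#' @return character scalar.
#' @export
format_formula <- function(f) {
  f <- f[f > 0]
  els <- names(f)
  # Hill order: C first, H second, rest alphabetical
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(ord, function(el) {
    if (f[[el]] == 1L) el else paste0(el, f[[el]])
  }, character(1)), collapse = "")
}

#' @export
print.element_formula <- function(x, ...) {
  cat("<element_formula>", format_formula(x), "\n")
  invisible(x)
}

#' Monoisotopic mass of a formula
#'
#' Sum of lightest-isotope masses. Electron mass is neglected, which is
#' below the 0.01 Da registry validation tolerance for singly charged ions.
#'
#' @param f `element_formula` or formula string.
#' @return mass in Da.
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  sum(vapply(names(f), function(el) ISOTOPES[[el]]$mass[1] * f[[el]], numeric(1)))
}

#' Natural isotope pattern of a formula
#'
#' Isotopologue probabilities by nominal mass offset (0, +1, +2, ...),
#' computed by convolving per-element multinomial expansions of the pinned
#' isotope abundances. Patterns are binned at nominal (integer) mass
#' offsets; mass defects are only relevant for extraction windows, not for
#' abundance correction.
#'
#' @param f `element_formula` or formula string.
#' @param prune drop trailing probabilities below this threshold (default
#'   1e-9), then renormalize.
#' @return numeric vector of probabilities, index 1 = offset 0; sums to 1.
#' @examples
#' natural_pattern("C1")     # c(0.9893, 0.0107)
#' natural_pattern("C9H22NO2Si2")
#' @export
natural_pattern <- function(f, prune = 1e-9) {
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(prune >= 0, prune <= 1e-6)
  f <- f[f > 0]
  if (length(f) == 0L) stop("empty formula")
  pat <- 1
  for (el in names(f)) {
    ab <- ISOTOPES[[el]]$abundance
    single <- ab / sum(ab)
    pat <- convolve_patterns(pat, .pattern_power(single, f[[el]]), normalize = FALSE)
  }
  .prune_pattern(pat, prune)
}

# pattern^n by binary exponentiation (each convolution is cheap anyway)
.pattern_power <- function(p, n) {
  out <- 1
  base <- p
  while (n > 0) {
    if (n %% 2 == 1) out <- convolve_patterns(out, base, normalize = FALSE)
    base <- convolve_patterns(base, base, normalize = FALSE)
    n <- n %/% 2
  }
  out
}

.prune_pattern <- function(p, prune = 1e-9) {
  keep <- max(c(1L, which(p > prune)))
  p <- p[seq_len(keep)]
  p / sum(p)
}

#' Convolve two isotope patterns
#'
#' Discrete convolution of two nominal-mass-offset probability vectors:
#' the pattern of the union of two independent atom sets.
#'
#' @param a,b numeric probability vectors (index 1 = offset 0).
#' @param normalize renormalize the result to sum 1 (default TRUE).
#' @return numeric vector of length `length(a) + length(b) - 1`.
#' @export
convolve_patterns <- function(a, b, normalize = TRUE) {
  stopifnot(all(a >= 0), all(b >= 0))
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1L
    out[idx] <- out[idx] + a[i] * b
  }
  if (normalize) out / sum(out) else out
}
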