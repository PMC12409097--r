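# Independent oracles and shared fixtures for the test suite.

# strip class and attached fragment from a correction matrix
bare <- function(M) matrix(as.numeric(M), nrow(M))

test_registry <- function() default_registry()
test_frag_set <- function() positional_fragment_set(default_registry())

# Labeled-carbon count distribution by explicit subset enumeration
# (independent of the package's convolution-based generator).
brute_label_distribution <- function(e) {
  n <- length(e)
  out <- numeric(n + 1)
  for (mask in 0:(2^n - 1)) {
    labeled <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    p <- prod(ifelse(labeled, e, 1 - e))
    out[sum(labeled) + 1] <- out[sum(labeled) + 1] + p
  }
  out
}

# Classical carbon-only binomial correction matrix (closed form).
binomial_matrix <- function(n, p13 = 0.0107) {
  M <- matrix(0, n + 1, n + 1)
  for (j in 0:n) {
    M[(j:n) + 1, j + 1] <- stats::dbinom(0:(n - j), n - j, p13)
  }
  M
}

# Monte Carlo natural isotope pattern: sample an isotope for every atom
# and histogram the total nominal mass offset.
mc_natural_pattern <- function(formula_string, n_draws = 2e5) {
  f <- parse_formula(formula_string)
  offsets <- integer(n_draws)
  for (el in names(f)) {
    ab <- ISOTOPES[[el]]$abundance
    ab <- ab / sum(ab)
    for (i in seq_len(f[[el]])) {
      offsets <- offsets + sample(seq_along(ab) - 1L, n_draws,
                                  replace = TRUE, prob = ab)
    }
  }
  tabulate(offsets + 1L, nbins = max(offsets) + 1L) / n_draws
}

# A carbon-only fragment (EI tag skips the exact-mass invariant, which
# only binds APCI entries).
carbon_only_fragment <- function(n = 3L) {
  fragment_spec("synthetic carbon chain", ion_label = 12 * n,
                exact_mz = 12 * n, ion_formula = paste0("C", n),
                backbone_positions = seq(2, 1 + n), ionization = "EI")
}

# Minimal iso_traces object for apex-integration tests.
make_traces <- function(rt, intensity, frag = test_frag_set()$E234) {
  structure(list(rt = rt, intensity = intensity, fragment = frag),
            class = "iso_traces")
}

# Minimal scan_series (centroid spectra) without touching disk.
make_scan_series <- function(rt, peaks) {
  structure(list(rt = rt, peaks = peaks), class = "scan_series")
}
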