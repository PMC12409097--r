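test_that("formula parsing handles Hill notation, composition arithmetic and errors", {
  f <- parse_formula("C4H7NO4")
  expect_equal(unclass(f)[c("C", "H", "N", "O")], c(C = 4L, H = 7L, N = 1L, O = 4L))
  # aspartic acid + 3 TMS groups (TMS = SiC3H9 replacing one H each)
  f3 <- parse_formula("C13H31NO4Si3")
  expect_equal(f3[["C"]], 4L + 3L * 3L)
  expect_equal(f3[["H"]], 7L + 3L * 8L)
  expect_equal(f3[["Si"]], 3L)
  expect_equal(format_formula(f3), "C13H31NO4Si3")
  expect_equal(format_formula(parse_formula(format_formula(f))), "C4H7NO4")
  expect_error(parse_formula("C4Xx2"), "unsupported element")
  expect_error(parse_formula(""), "empty")
})

test_that("natural patterns match the pinned isotope table and binomial closed form", {
  expect_equal(natural_pattern("C1"), c(0.9893, 0.0107), tolerance = 1e-12)
  expect_equal(natural_pattern("Si1"), c(0.92223, 0.04685, 0.03092),
               tolerance = 1e-9)
  for (n in c(1, 4, 9, 13, 20)) {
    p <- natural_pattern(parse_formula(paste0("C", n)), prune = 0)
    expect_equal(p[seq_len(n + 1)], dbinom(0:n, n, 0.0107), tolerance = 1e-10)
  }
  w <- natural_pattern("H2O1")
  expect_gt(w[1], 0.99)         # M0-dominated
  expect_equal(sum(w), 1, tolerance = 1e-9)
})

test_that("composite natural pattern agrees with a Monte Carlo atom-sampling oracle", {
  set.seed(42)
  mc <- mc_natural_pattern("C9H22NO2Si2", n_draws = 2e5)
  p <- natural_pattern("C9H22NO2Si2")
  k <- min(length(mc), length(p), 4)
  expect_equal(p[1:k], mc[1:k], tolerance = 5e-3)
})

test_that("pattern convolution is an identity with delta, binomial on halves, commutative and associative", {
  a <- natural_pattern("C5H10O2")
  expect_equal(convolve_patterns(a, 1), a)
  expect_equal(convolve_patterns(c(0.5, 0.5), c(0.5, 0.5)),
               c(0.25, 0.5, 0.25))
  set.seed(1)
  for (i in 1:20) {
    x <- runif(sample(2:6, 1)); x <- x / sum(x)
    y <- runif(sample(2:6, 1)); y <- y / sum(y)
    z <- runif(sample(2:6, 1)); z <- z / sum(z)
    expect_equal(convolve_patterns(x, y), convolve_patterns(y, x),
                 tolerance = 1e-12)
    expect_equal(convolve_patterns(convolve_patterns(x, y), z),
                 convolve_patterns(x, convolve_patterns(y, z)),
                 tolerance = 1e-12)
    expect_equal(sum(convolve_patterns(x, y)), 1, tolerance = 1e-9)
  }
})

test_that("monoisotopic masses reproduce reference values", {
  expect_equal(monoisotopic_mass("C1"), 12.0)
  expect_equal(monoisotopic_mass("H2O1"), 18.0106, tolerance = 1e-4)
  expect_equal(monoisotopic_mass("C9H22NO2Si2"), 232.12, tolerance = 0.01)
})

test_that("the shipped registry validates, covers the positional sets and supports lookup", {
  reg <- test_registry()
  expect_gte(length(reg), 6)
  for (f in reg) {
    expect_s3_class(f, "fragment_spec")
    if (f$ionization %in% c("APCI", "both")) {
      expect_lt(abs(f$exact_mz - monoisotopic_mass(f$ion_formula)), 0.01)
    }
    expect_lte(f$n_tracer, f$ion_formula[["C"]])
  }
  expect_equal(lookup_fragment(reg, "aspartic acid 3TMS", 232)$backbone_positions,
               2:4)
  f350 <- lookup_fragment(reg, "aspartic acid 3TMS", 350)
  expect_equal(f350$backbone_positions, 1:4)
  expect_match(f350$notes, "overlapped", ignore.case = TRUE)
  expect_s3_class(lookup_fragment(reg, "aspartic acid 2TMS", 262),
                  "fragment_spec")
  expect_error(lookup_fragment(reg, "aspartic acid 3TMS", 999), "no registry")
  covs <- vapply(positional_fragment_set(reg),
                 function(f) paste(f$backbone_positions, collapse = ","),
                 character(1))
  expect_equal(unname(covs), c("1,2,3,4", "2,3,4", "2,3", "3,4"))
})

test_that("fragment_spec rejects inconsistent entries", {
  expect_error(fragment_spec("x", 100, 100.0, "C2H4O1", backbone_positions = 1:3),
               "more backbone carbons")
  expect_error(fragment_spec("x", 100, 101.5, "C2H4O1",
                             backbone_positions = 1:2, ionization = "APCI"),
               "deviates")
})
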