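test_that("simulated mzML round-trips through extraction within 0.1% on MID fractions", {
  frag <- test_frag_set()$E234
  m <- simulate_mid(frag, c(0.2, 0.5, 0.8), scale = 1e6)
  path <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(m, path)
  s <- load_mzml(path)
  expect_s3_class(s, "scan_series")
  expect_true(all(diff(s$rt) > 0))
  rec <- mid_apci(extract_traces(s, frag, rt_window = c(280, 320)), "s1")
  expect_equal(rec$abundances / sum(rec$abundances),
               m$abundances / sum(m$abundances), tolerance = 1e-3)
  expect_equal(rec$quant_mode, "apex_area")
  # RT filter semantics
  s2 <- load_mzml(path, rt_range = c(295, 305))
  expect_true(all(s2$rt >= 295 & s2$rt <= 305))
  expect_lt(length(s2$rt), length(s$rt))
  expect_error(load_mzml(tempfile(fileext = ".mzML")), "not found")
})

test_that("a peak displaced by 0.02 Da falls outside the +/-0.005 Da window", {
  frag <- test_frag_set()$E234
  shifted <- fragment_spec(frag$analyte, frag$ion_label,
                           frag$exact_mz, frag$ion_formula,
                           frag$backbone_positions, ionization = "EI")
  shifted$exact_mz <- frag$exact_mz + 0.02
  m <- simulate_mid(frag, c(0, 0, 0), scale = 1e5)
  path <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(m, path)
  tr <- extract_traces(load_mzml(path), shifted, rt_window = c(280, 320))
  expect_true(all(tr$intensity == 0))
  expect_null(mid_apci(tr))            # missing-measurement signal
})

test_that("two isotopologues with 2:1 areas keep their ratio; tolerance widening is monotone", {
  frag <- test_frag_set()$E1234
  rt <- seq(0, 20, by = 0.5)
  # centroid mass split +/-0.003 Da around each window center emulates
  # residual mass spread inside the window
  mk_peak <- function(center, area, t) {
    h <- area * dnorm(t, 10, 1.5)
    cbind(mz = c(center - 0.003, center + 0.003),
          intensity = c(0.5 * h, 0.5 * h))
  }
  peaks <- lapply(rt, function(t) {
    rbind(mk_peak(frag$exact_mz, 2e5, t),
          mk_peak(frag$exact_mz + MASS_SHIFT_13C, 1e5, t))
  })
  s <- make_scan_series(rt, peaks)
  tr <- extract_traces(s, frag, rt_window = c(0, 20))
  m <- mid_apci(tr)
  expect_equal(m$abundances[1] / m$abundances[2], 2, tolerance = 1e-6)
  area_at <- function(tol) {
    sum(mid_apci(extract_traces(s, frag, rt_window = c(0, 20),
                                tol = tol))$abundances)
  }
  expect_lt(area_at(0.002), area_at(0.005))   # shrinking below the mass spread loses signal
  expect_equal(area_at(0.008), area_at(0.005), tolerance = 1e-9)
  expect_gte(area_at(0.02), area_at(0.005))   # widening never decreases
})

test_that("apex integration uses apex +/- 10 scans and closed-form areas", {
  frag <- test_frag_set()$E234
  rt <- as.numeric(0:299)
  tri <- rep(0, 300)
  tri[99:103] <- c(0, 50, 100, 50, 0)   # triangle spanning 5 scans
  intensity <- cbind(tri, 0, 0, 0, 0, 0, 0)
  m <- mid_apci(make_traces(rt, intensity, frag))
  expect_equal(m$abundances[1], 200)    # trapezoid = triangle area 0.5*4*100
  expect_equal(m$apex_rt, rt[101])
  # integration bounds apex +/- 10: mass outside scans 91..111 is ignored
  intensity2 <- intensity
  intensity2[130, 1] <- 90              # sub-apex signal outside the bounds
  m2 <- mid_apci(make_traces(rt, intensity2, frag))
  expect_equal(m2$abundances[1], 200)
  expect_null(mid_apci(make_traces(rt, matrix(0, 300, 7), frag)))
})

test_that("EI peak tables build MIDs and reject duplicate or incomplete rows", {
  frag <- test_frag_set()$E234
  tab <- data.frame(sample_id = "s1", analyte = frag$analyte,
                    ion_label = 232L, isotopologue = 0:3,
                    abundance = c(100, 40, 15, 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  rows <- read_peak_table(path)
  m <- mid_ei(rows, frag)
  expect_length(m$abundances, 4)
  expect_equal(m$quant_mode, "apex_height")
  expect_error(mid_ei(rbind(rows, rows[1, ]), frag), "duplicate")
  expect_error(mid_ei(rows[1:3, ], frag), "misses isotopologues")
  # natural-like input is accepted; correction handles it downstream
  tab$abundance <- c(100, 1, 0, 0)
  m2 <- mid_ei(tab, frag)
  expect_lt(correct_mid(m2)$e13c, 0.05)
})
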