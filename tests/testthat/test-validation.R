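test_that("mixture expectations follow composition arithmetic", {
  certs <- aspartate_certificates()
  nat <- mixture_design(list(list(cert = certs$natural, fraction = 1)))
  expect_equal(expected_positional(nat), rep(0, 4))
  # equal 1:1:1:1 positional mix diluted to 20% of total
  comps <- lapply(certs[c("C1", "C2", "C3", "C4")],
                  function(cr) list(cert = cr, fraction = 0.05))
  names(comps) <- NULL
  d <- mixture_design(c(comps, list(list(cert = certs$natural, fraction = 0.8))))
  pur <- c(0.996, 0.997, 0.996, 0.993)
  expect_equal(expected_positional(d), 0.05 * pur, tolerance = 1e-12)
  # 95:5 [4-13C]:natural
  d95 <- mixture_design(list(list(cert = certs$C4, fraction = 0.95),
                             list(cert = certs$natural, fraction = 0.05)))
  expect_equal(expected_positional(d95), c(0, 0, 0, 0.95 * 0.993))
  # component order is irrelevant; fractions must sum to 1
  d95b <- mixture_design(rev(d95$components))
  expect_equal(expected_positional(d95b), expected_positional(d95))
  expect_error(mixture_design(list(list(cert = certs$C4, fraction = 0.5))),
               "sum to 1")
})

test_that("the reconstructed standards panel has 36 designs with valid compositions", {
  designs <- standard_mixture_designs()
  expect_length(designs, 36)
  ids <- vapply(designs, function(d) d$id, character(1))
  expect_false(anyDuplicated(ids) > 0)
  for (d in designs) {
    fr <- vapply(d$components, function(cc) cc$fraction, numeric(1))
    expect_equal(sum(fr), 1, tolerance = 1e-9)
    expect_true(all(expected_positional(d) >= 0 & expected_positional(d) <= 1))
  }
})

test_that("deviation statistics implement mean (accuracy) and SD (precision) in points", {
  st <- deviation_stats(c(0.5, 0.5), 0.5)
  expect_equal(st$mean_dev, 0)
  expect_equal(st$sd_dev, 0)
  st <- deviation_stats(c(0.51, 0.49), 0.5)   # deviations +1, -1 points
  expect_equal(st$mean_dev, 0, tolerance = 1e-9)
  expect_equal(st$sd_dev, sqrt(2), tolerance = 1e-9)
  expect_error(deviation_stats(c(0.1, 0.2), c(0.1, 0.2, 0.3)), "differ")
})

test_that("bias-free deviations converge to zero mean at large replication", {
  set.seed(31)
  n <- 1000
  sd_sim <- 0.005
  meas <- 0.5 + rnorm(n, 0, sd_sim)
  st <- deviation_stats(meas, 0.5)
  expect_lt(abs(st$mean_dev), 3 * 100 * sd_sim / sqrt(n))
})

test_that("the detection scan finds the lowest reliably accurate injection amount", {
  mk <- function(devs_by_level) {
    do.call(rbind, lapply(seq_along(devs_by_level), function(i) {
      data.frame(fragment = "f", injection_ng = c(1.25, 2.5, 12.5, 25, 125, 250)[i],
                 dev = devs_by_level[[i]])
    }))
  }
  all_good <- mk(rep(list(c(0.1, -0.1)), 6))
  expect_equal(detection_scan(all_good)$min_ng, 1.25)
  from_3 <- mk(list(c(5, 6), c(2, 3), c(0.3, 0.2), c(0.1, 0), c(0.1, 0), c(0, 0)))
  expect_equal(detection_scan(from_3)$min_ng, 12.5)
  none <- mk(rep(list(c(8, 9)), 6))
  expect_true(is.na(detection_scan(none)$min_ng))
  expect_error(detection_scan(all_good[all_good$injection_ng < 3, ]),
               "3 injection levels")
  # abundance-dependent noise: a noisier detector pushes the limit upward
  scan_for <- function(noise, seed) {
    set.seed(seed)
    frag <- test_frag_set()$E234
    rows <- do.call(rbind, lapply(c(1.25, 2.5, 12.5, 25, 125, 250), function(ng) {
      devs <- vapply(1:4, function(r) {
        m <- simulate_mid(frag, c(0.05, 0.05, 0.05), scale = 2e6 * ng / 25 / 5,
                          noise = noise)
        100 * (correct_mid(m)$e13c - 0.05)
      }, numeric(1))
      data.frame(fragment = "232", injection_ng = ng, dev = devs)
    }))
    detection_scan(rows)$min_ng
  }
  clean <- scan_for(noiseless(), 41)
  noisy <- scan_for(noise_model(cv_multiplicative = 0.01, baseline_sd = 3000), 41)
  expect_equal(clean, 1.25)
  expect_gte(noisy, clean)
})

test_that("saturation flagging applies the configurable 1e7 threshold", {
  expect_false(flag_saturation(9.9e6))
  expect_true(flag_saturation(1.1e7))
  expect_true(flag_saturation(6e6, threshold = 5e6))
  expect_error(flag_saturation(-1))
})
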