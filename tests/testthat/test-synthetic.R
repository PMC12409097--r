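test_that("noise-free simulated MIDs match the forward model and shift fully when saturated with label", {
  frag <- test_frag_set()$E234
  # natural (all-zero enrichment): MID = natural pattern x scale
  m <- simulate_mid(frag, c(0, 0, 0), scale = 1e6)
  pat <- natural_pattern("C9H22NO2Si2")
  k <- min(length(pat), length(m$abundances))
  expect_equal(m$abundances[1:k] / 1e6, pat[1:k], tolerance = 1e-6)
  # fully labeled: envelope shifted +3, residual pattern from non-tracer atoms
  m3 <- simulate_mid(frag, c(1, 1, 1), scale = 1e6)
  expect_equal(m3$abundances[1:3], rep(0, 3))
  rest <- natural_pattern("C6H22NO2Si2")   # formula minus 3 backbone carbons
  expect_equal(m3$abundances[4:k] / 1e6, rest[1:(k - 3)], tolerance = 1e-6)
})

test_that("the simulated tracer distribution equals the subset-enumeration oracle", {
  set.seed(13)
  for (frag in test_frag_set()) {
    for (i in 1:10) {
      e <- runif(frag$n_tracer)
      cm <- correct_mid(simulate_mid(frag, e))
      oracle <- brute_label_distribution(e)
      expect_equal(cm$fractions, oracle, tolerance = 1e-6)
      expect_equal(cm$e13c, mean(e), tolerance = 1e-6)
    }
  }
})

test_that("a full positional vector is subset to the fragment coverage", {
  frag <- test_frag_set()$E34            # covers positions 3,4
  e <- c(0.9, 0.8, 0.1, 0.4)
  cm <- correct_mid(simulate_mid(frag, e))
  expect_equal(cm$e13c, mean(e[3:4]), tolerance = 1e-6)
})

test_that("simulation is deterministic under a fixed seed", {
  frag <- test_frag_set()$E1234
  nm <- noise_model(cv_multiplicative = 0.05, baseline_sd = 200, seed = 99)
  a <- simulate_mid(frag, c(0.2, 0.2, 0.2, 0.2), noise = nm)
  b <- simulate_mid(frag, c(0.2, 0.2, 0.2, 0.2), noise = nm)
  expect_identical(a$abundances, b$abundances)
})

test_that("soft saturation compresses abundances only near the threshold and sets the flag", {
  frag <- test_frag_set()$E234
  nm <- noise_model(cv_multiplicative = 0, baseline_sd = 0,
                    saturation_threshold = 1e7)
  low <- simulate_mid(frag, c(0, 0, 0), scale = 1e5, noise = nm)
  expect_equal(sum(low$abundances), 1e5, tolerance = 1e-3)
  expect_false(low$saturated)
  high <- simulate_mid(frag, c(0, 0, 0), scale = 4e7, noise = nm)
  expect_lt(sum(high$abundances), 4e7)
  expect_true(high$saturated)
  # saturation distorts the MID, not only its scale
  fr_low <- low$abundances / sum(low$abundances)
  fr_high <- high$abundances / sum(high$abundances)
  expect_gt(max(abs(fr_low - fr_high)), 0.005)
})

test_that("the mixture panel has the validated layout and scales with injection", {
  designs <- standard_mixture_designs()[1:3]
  panel <- simulate_mixture_panel(designs, injections = 25, replicates = 4,
                                  noise = noiseless())
  expect_length(panel$records, 12)
  expect_length(simulate_mixture_panel(designs, replicates = 0)$records, 0)
  p1 <- simulate_mixture_panel(designs[1], injections = c(25, 50),
                               noise = noiseless(), replicates = 1)
  tot <- vapply(p1$records, function(r) sum(r$mids$E1234$abundances), numeric(1))
  expect_equal(tot[2] / tot[1], 2, tolerance = 1e-9)
  # full default panel: 36 designs x 4 replicates
  expect_length(simulate_mixture_panel(noise = noiseless())$records, 144)
})

test_that("labeling scenarios enforce the day/night structure", {
  dark <- labeling_scenario("dark")
  expect_equal(dark$y_max[1:3], rep(0, 3))
  expect_equal(scenario_trajectory(dark, 1), rep(0, 7))
  expect_gt(scenario_trajectory(dark, 4, 90), 0.9 * dark$y_max[4])
  # dark onset: signal at 10 min below 5% of plateau, rising after 15 min
  expect_lt(scenario_trajectory(dark, 4, 10), 0.05 * dark$y_max[4])
  light <- labeling_scenario("light")
  expect_true(all(vapply(1:4, function(p) {
    scenario_trajectory(light, p, 90) > 0.5 * light$y_max[p]
  }, logical(1))))
  expect_error(labeling_scenario("dark", y_max = c(10, 0, 0, 50)),
               "positions 1-3")
  expect_error(labeling_scenario("light", y_max = c(1000, 0, 0, 0), pool = 300),
               "exceeds")
})

test_that("a noise-free time course round-trips through the full pipeline", {
  ds <- simulate_timecourse(labeling_scenario("light", pool_cv = 0),
                            noise = noiseless(), replicates = 1)
  rep <- run_labeling_analysis(ds)
  sc <- labeling_scenario("light")
  for (p in c(1, 4)) {
    sub <- rep$rate_summary[rep$rate_summary$position == p, ]
    truth_slope <- sc$k[p] * sc$y_max[p] / 4
    expect_equal(sub$max_slope, truth_slope, tolerance = 0.02)
    expect_equal(sub$half_max_time, sc$t_mid[p], tolerance = 0.05)
  }
  # recovered molar trajectories match the generator within numerical error
  tc <- rep$timecourse
  for (p in 1:4) {
    got <- tc[[paste0("m", p)]]
    want <- scenario_trajectory(sc, p, tc$time_min)
    expect_equal(got, want, tolerance = 0.01)
  }
})
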