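#' Detector noise model
#'
#' Emulates the abundance dependence of enrichment deviations: relative
#' (multiplicative) noise per isotopologue, an additive baseline noise
#' floor, and smooth detector saturation. Saturation uses the rational
#' soft clip `y / (1 + (y/T)^s)^(1/s)`, which is linear far below the
#' threshold `T` and approaches `T` asymptotically; `s` controls how hard
#' the clip is.
#'
#' @param cv_multiplicative relative SD per isotopologue abundance
#'   (default 0.01, the calibration at which the simulated standards panel
#'   reproduces the validated accuracy/precision envelope).
#' @param baseline_sd additive noise floor SD (counts; default 100,
#'   about 1e-5 of the saturation full scale).
#' @param saturation_threshold counts (default 1e7).
#' @param saturation_softness shape exponent `s` (default 4).
#' @param seed optional integer; when set, [simulate_mid()] seeds the RNG
#'   with it (panel- and time-course-level generators manage seeding
#'   themselves).
#' @return object of class `noise_model`.
#' @export
noise_model <- function(cv_multiplicative = 0.01, baseline_sd = 100,
                        saturation_threshold = 1e7,
                        saturation_softness = 4, seed = NULL) {
  stopifnot(cv_multiplicative >= 0, baseline_sd >= 0,
            saturation_threshold > 0, saturation_softness > 0)
  structure(list(cv_multiplicative = cv_multiplicative,
                 baseline_sd = baseline_sd,
                 saturation_threshold = saturation_threshold,
                 saturation_softness = saturation_softness,
                 seed = seed), class = "noise_model")
}

#' Noise-free noise model
#' @return a [noise_model()] with zero noise and saturation disabled.
#' @export
noiseless <- function() {
  noise_model(cv_multiplicative = 0, baseline_sd = 0,
              saturation_threshold = Inf)
}

.soft_clip <- function(y, threshold, s) {
  if (!is.finite(threshold)) return(y)
  y / (1 + (y / threshold)^s)^(1 / s)
}

# distribution of the number of labeled positions under independent
# per-position Bernoulli enrichment
.poisson_binomial <- function(e) {
  out <- 1
  for (p in e) out <- convolve_patterns(out, c(1 - p, p), normalize = FALSE)
  out
}

#' Simulate a raw fragment MID
#'
#' Forward model of the measurement: each covered backbone position is
#' tracer-labeled independently with its positional enrichment
#' probability, the resulting tracer-isotopologue distribution is
#' convolved with the natural isotope pattern of the remaining atoms
#' (including natural 13C of unlabeled backbone carbons), scaled to the
#' requested abundance, soft-clipped at the detector saturation threshold
#' and noised.
#'
#' @param frag a [fragment_spec()].
#' @param e positional tracer enrichments: either a full e1..e4 vector
#'   (subset to the fragment's coverage) or one value per covered
#'   position.
#' @param scale total fragment abundance (counts) before saturation.
#' @param noise a [noise_model()] (default [noiseless()]).
#' @param sample_id sample identifier.
#' @param n_measured measured vector length (default `n_tracer + 4`, which
#'   captures the Si isotope envelope).
#' @return a [mid_measurement()]; its `saturated` flag is set from the
#'   noise model's threshold via [flag_saturation()].
#' @export
simulate_mid <- function(frag, e, scale = 1e6, noise = noiseless(),
                         sample_id = "sim", n_measured = frag$n_tracer + 4L) {
  stopifnot(inherits(frag, "fragment_spec"), inherits(noise, "noise_model"))
  if (length(e) == 4L && frag$n_tracer != 4L) e <- e[frag$backbone_positions]
  if (length(e) != frag$n_tracer) {
    stop("e must have one entry per covered position (or length 4)")
  }
  stopifnot(all(e >= 0), all(e <= 1))
  if (!is.null(noise$seed)) set.seed(noise$seed)
  x <- .poisson_binomial(e)
  M <- build_correction_matrix(frag, n_measured = n_measured)
  mid <- forward_mid(M, x) * scale
  mid <- .soft_clip(mid, noise$saturation_threshold, noise$saturation_softness)
  if (noise$cv_multiplicative > 0) {
    cv <- noise$cv_multiplicative
    mid <- mid * exp(stats::rnorm(length(mid), -cv^2 / 2, cv))
  }
  if (noise$baseline_sd > 0) {
    mid <- mid + stats::rnorm(length(mid), 0, noise$baseline_sd)
  }
  mid <- pmax(mid, 0)
  mid_measurement(frag, sample_id, mid, quant_mode = "apex_area",
                  saturated = flag_saturation(sum(mid),
                                              noise$saturation_threshold))
}

#' Default fragment abundances at 25 ng injected (splitless)
#'
#' Relative detector responses (summed fragment abundance, counts) for a
#' splitless 25 ng aspartic acid injection, chosen so that m/z 232 sits
#' near base-peak abundance and crosses the 1e7 saturation threshold above
#' 125 ng unless acquired in split mode.
#'
#' @return named numeric vector keyed `"analyte/ion_label"`.
#' @export
default_fragment_response <- function() {
  c("aspartic acid 3TMS/349" = 5e5,
    "aspartic acid 3TMS/350" = 1.5e6,
    "aspartic acid 3TMS/232" = 2e6,
    "aspartic acid 3TMS/218" = 3e5,
    "aspartic acid 3TMS/188" = 2e5,
    "aspartic acid 3TMS/190" = 2.5e5,
    "aspartic acid 2TMS/262" = 1e5,
    "aspartic acid 2TMS/245" = 8e4,
    "aspartic acid 2TMS/160" = 1.2e5)
}

.frag_key <- function(frag) paste0(frag$analyte, "/", frag$ion_label)

#' Simulate a standards mixture panel
#'
#' Generates raw MIDs for every fragment x design x injection amount x
#' replicate, with abundance proportional to injected amount over split
#' ratio. Defaults reproduce the validation layout: 36 designs, 4
#' technical replicates, 25 ng, saturation-prone fragments (m/z 232 and
#' 350) acquired at split ratio 5.
#'
#' @param designs list of [mixture_design()] (default
#'   [standard_mixture_designs()]).
#' @param injections ng amounts (default 25).
#' @param replicates technical replicates per design and amount.
#' @param noise a [noise_model()].
#' @param fragments named list of [fragment_spec()] (default
#'   [positional_fragment_set()]).
#' @param response named abundance-at-25-ng vector, see
#'   [default_fragment_response()].
#' @param split_ratios named split-ratio overrides keyed by nominal m/z
#'   (default 5 for 232 and 350), 1 otherwise.
#' @param seed optional RNG seed for the whole panel.
#' @return object of class `mixture_panel`: list with `records` (one per
#'   design x injection x replicate: `design_id`, `expected_e`,
#'   `injection_ng`, `replicate`, `mids` named by fragment role) and
#'   `fragments`.
#' @export
simulate_mixture_panel <- function(designs = standard_mixture_designs(),
                                   injections = 25, replicates = 4,
                                   noise = noise_model(),
                                   fragments = positional_fragment_set(),
                                   response = default_fragment_response(),
                                   split_ratios = c("232" = 5, "350" = 5),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  records <- list()
  if (replicates < 1) {
    return(structure(list(records = list(), fragments = fragments),
                     class = "mixture_panel"))
  }
  for (d in designs) {
    e_true <- expected_positional(d)
    for (ng in injections) {
      for (rep_i in seq_len(replicates)) {
        mids <- lapply(fragments, function(frag) {
          key <- .frag_key(frag)
          resp25 <- if (key %in% names(response)) response[[key]] else 2e5
          split <- 1
          lbl <- as.character(frag$ion_label)
          if (lbl %in% names(split_ratios)) split <- split_ratios[[lbl]]
          simulate_mid(frag, e_true, scale = resp25 * (ng / 25) / split,
                       noise = noise,
                       sample_id = sprintf("%s_%gng_r%d", d$id, ng, rep_i))
        })
        records[[length(records) + 1L]] <- list(
          design_id = d$id, expected_e = e_true, injection_ng = ng,
          replicate = rep_i, mids = mids)
      }
    }
  }
  structure(list(records = records, fragments = fragments),
            class = "mixture_panel")
}

#' Labeling scenario for dynamic 13CO2 pulse experiments
#'
#' Defines per-position logistic trajectories of molar positional 13C
#' (pmol / OD750 / mL) and the aspartate pool over the sampling grid.
#' The defaults emulate the day/night contrast: in the light all four
#' positions label (RUBISCO into 1-C, CBB into 2-C/3-C, PEPC into 4-C)
#' with similar 1-C and 4-C rates; in the dark positions 1-3 stay at zero
#' and 4-C labels at a lower rate with a later half-max, with first
#' detectable signal not before 15 min.
#'
#' @param condition `"light"` or `"dark"`.
#' @param timepoints sampling times (min), default the 0/5/10/15/30/60/90
#'   grid.
#' @param y_max,k,t_mid per-position logistic parameters (length 4):
#'   plateau (pmol / OD750 / mL), rate (1/min), midpoint (min).
#' @param pool aspartate pool (pmol / OD750 / mL), recycled over
#'   timepoints.
#' @param pool_cv between-replicate CV of the pool (default 0.05;
#'   replicate variability in the molar time courses is dominated by the
#'   concentration measurement, not by E13C).
#' @return object of class `labeling_scenario`.
#' @export
labeling_scenario <- function(condition = c("light", "dark"),
                              timepoints = c(0, 5, 10, 15, 30, 60, 90),
                              y_max = NULL, k = NULL, t_mid = NULL,
                              pool = 300, pool_cv = 0.05) {
  condition <- match.arg(condition)
  if (is.null(y_max)) {
    y_max <- if (condition == "light") c(100, 70, 70, 95) else c(0, 0, 0, 60)
  }
  if (is.null(k)) {
    k <- if (condition == "light") c(0.2, 0.15, 0.15, 0.2) else c(0, 0, 0, 0.1)
  }
  if (is.null(t_mid)) {
    t_mid <- if (condition == "light") c(22, 28, 28, 22) else c(NA, NA, NA, 45)
  }
  stopifnot(length(y_max) == 4, length(k) == 4, length(t_mid) == 4,
            all(y_max >= 0))
  pool <- rep_len(pool, length(timepoints))
  if (any(y_max > min(pool))) {
    stop("positional plateau exceeds the aspartate pool")
  }
  if (condition == "dark" && any(y_max[1:3] > 0)) {
    stop("dark scenario must have zero trajectories at positions 1-3")
  }
  structure(list(condition = condition, timepoints = timepoints,
                 y_max = y_max, k = k, t_mid = t_mid, pool = pool,
                 pool_cv = pool_cv), class = "labeling_scenario")
}

#' True molar positional trajectory of a scenario
#' @param scenario a [labeling_scenario()].
#' @param position 1..4.
#' @param times minutes (default the scenario grid).
#' @return pmol / OD750 / mL at each time.
#' @export
scenario_trajectory <- function(scenario, position, times = scenario$timepoints) {
  p <- as.integer(position)
  if (scenario$y_max[p] == 0) return(rep(0, length(times)))
  .logistic(times, scenario$y_max[p], scenario$k[p], scenario$t_mid[p])
}

#' Simulate a dynamic labeling time course
#'
#' Generates, per replicate and timepoint, the full set of inputs the
#' analysis pipeline consumes: fragment MIDs of the positional fragment
#' set at the sample's true enrichments, the internal-standard abundance,
#' and sample metadata. Also returns a matching non-labeled calibration
#' series for [fit_calibration()].
#'
#' @param scenario a [labeling_scenario()].
#' @param noise a [noise_model()].
#' @param replicates biological replicates (default 4).
#' @param fragments named fragment set (default [positional_fragment_set()]).
#' @param response per-fragment abundance at 25 ng, see
#'   [default_fragment_response()].
#' @param is_response internal-standard abundance per injection (counts at
#'   the constant 25 ng spike).
#' @param cal_levels calibration amounts (ng).
#' @param seed optional RNG seed.
#' @return object of class `labeling_dataset`: list with `samples` (each:
#'   `time_min`, `replicate_id`, `meta`, `mids`, `truth`), `calibration`
#'   (data.frame ng/response), `scenario`, `fragments`.
#' @export
simulate_timecourse <- function(scenario, noise = noise_model(),
                                replicates = 4,
                                fragments = positional_fragment_set(),
                                response = default_fragment_response(),
                                is_response = 2e5,
                                cal_levels = c(5, 10, 25, 50, 100),
                                seed = NULL) {
  stopifnot(inherits(scenario, "labeling_scenario"))
  if (!is.null(seed)) set.seed(seed)
  quant_key <- "aspartic acid 3TMS/232"
  quant_resp_per_ng <- response[[quant_key]] / 25
  samples <- list()
  for (rep_i in seq_len(replicates)) {
    pool_factor <- if (scenario$pool_cv > 0) {
      exp(stats::rnorm(1, -scenario$pool_cv^2 / 2, scenario$pool_cv))
    } else 1
    for (ti in seq_along(scenario$timepoints)) {
      t_min <- scenario$timepoints[ti]
      pool <- scenario$pool[ti] * pool_factor
      e_true <- vapply(1:4, function(p) {
        scenario_trajectory(scenario, p, t_min) * pool_factor / pool
      }, numeric(1))
      amount_ng <- pool * ASPARTATE_MW / 1000   # od750 = 1, volume = 1 mL
      is_ab <- is_response
      if (noise$cv_multiplicative > 0) {
        is_ab <- is_ab * exp(stats::rnorm(1, -noise$cv_multiplicative^2 / 2,
                                          noise$cv_multiplicative))
      }
      mids <- lapply(fragments, function(frag) {
        key <- .frag_key(frag)
        resp25 <- if (key %in% names(response)) response[[key]] else 2e5
        simulate_mid(frag, e_true, scale = resp25 * (amount_ng / 25),
                     noise = noise,
                     sample_id = sprintf("%s_t%g_r%d", scenario$condition,
                                         t_min, rep_i))
      })
      samples[[length(samples) + 1L]] <- list(
        time_min = t_min,
        replicate_id = sprintf("r%d", rep_i),
        meta = sample_meta(
          sample_id = sprintf("%s_t%g_r%d", scenario$condition, t_min, rep_i),
          od750 = 1, volume_ml = 1, time_min = t_min,
          injection_ng = amount_ng, split_ratio = 1, is_abundance = is_ab),
        mids = mids,
        truth = list(e = e_true, pool = pool))
    }
  }
  cal <- data.frame(
    ng = cal_levels,
    response = vapply(cal_levels, function(ng) {
      ab <- ng * quant_resp_per_ng
      if (noise$cv_multiplicative > 0) {
        ab <- ab * exp(stats::rnorm(1, -noise$cv_multiplicative^2 / 2,
                                    noise$cv_multiplicative))
      }
      ab / is_response
    }, numeric(1)))
  structure(list(samples = samples, calibration = cal, scenario = scenario,
                 fragments = fragments, is_response = is_response),
            class = "labeling_dataset")
}

#' Write simulated measurements to a centroided mzML file
#'
#' Renders each measurement as Gaussian chromatographic peaks: one
#' extracted-ion peak per isotopologue at `exact_mz + i * 1.00336` Da,
#' with peak area proportional to the isotopologue abundance. All
#' measurements share a retention-time axis; co-eluting fragments are
#' separated by their m/z windows.
#'
#' @param mids list of [mid_measurement()] (or a single one).
#' @param path output mzML path.
#' @param apex_rt apex retention time (s).
#' @param peak_sigma Gaussian peak SD (s).
#' @param scan_interval time between scans (s).
#' @param rt_range retention-time span of the file (s).
#' @return `path`, invisibly.
#' @export
write_mzml <- function(mids, path, apex_rt = 300, peak_sigma = 1.5,
                       scan_interval = 0.5, rt_range = c(270, 330)) {
  if (inherits(mids, "mid_measurement")) mids <- list(mids)
  rt <- seq(rt_range[1], rt_range[2], by = scan_interval)
  n_scan <- length(rt)
  peaks <- vector("list", n_scan)
  for (si in seq_len(n_scan)) {
    mz <- numeric(0)
    int <- numeric(0)
    for (m in mids) {
      frag <- m$fragment
      dens <- stats::dnorm(rt[si], apex_rt, peak_sigma)
      for (i in seq_along(m$abundances)) {
        h <- m$abundances[i] * dens
        if (h <= 0) next
        mz <- c(mz, frag$exact_mz + (i - 1L) * MASS_SHIFT_13C)
        int <- c(int, h)
      }
    }
    ord <- order(mz)
    peaks[[si]] <- cbind(mz = mz[ord], intensity = int[ord])
  }
  hdr <- data.frame(
    seqNum = seq_len(n_scan), acquisitionNum = seq_len(n_scan),
    msLevel = 1L, polarity = 1L,
    peaksCount = vapply(peaks, nrow, integer(1)),
    totIonCurrent = vapply(peaks, function(p) sum(p[, 2]), numeric(1)),
    retentionTime = rt,
    basePeakMZ = vapply(peaks, function(p) {
      if (nrow(p)) p[which.max(p[, 2]), 1] else 0
    }, numeric(1)),
    basePeakIntensity = vapply(peaks, function(p) {
      if (nrow(p)) max(p[, 2]) else 0
    }, numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(peaks, function(p) if (nrow(p)) min(p[, 1]) else 0,
                   numeric(1)),
    highMZ = vapply(peaks, function(p) if (nrow(p)) max(p[, 1]) else 0,
                    numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n_scan)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
    scanWindowUpperLimit = NA_real_)
  mzR::writeMSData(peaks, path, header = hdr, outformat = "mzml")
  invisible(path)
}
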