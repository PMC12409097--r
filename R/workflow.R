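#' Fragment-role expected enrichment
#'
#' A fragment's expected E13C is the mean positional enrichment over its
#' covered positions (a fragment's enrichment is the average over its
#' carbons).
#' @param frag a [fragment_spec()].
#' @param e_true positional enrichment vector e1..e4.
#' @return expected fraction.
#' @keywords internal
expected_fragment_e13c <- function(frag, e_true) {
  mean(e_true[frag$backbone_positions])
}

#' Run the standards validation workflow
#'
#' Corrects every panel measurement for natural isotope abundance,
#' computes fragment-level and positional enrichments, and summarizes
#' accuracy (mean deviation) and precision (SD of deviation) per fragment
#' and per carbon position against the configured bounds. Saturated
#' measurements are excluded from positional calculation and logged.
#'
#' @param panel a `mixture_panel` from [simulate_mixture_panel()], or
#'   `NULL` to simulate the default 36-design x 4-replicate panel at 25 ng.
#' @param noise noise model used when `panel` is `NULL`.
#' @param seed RNG seed used when `panel` is `NULL`.
#' @param accuracy_bound positional mean-deviation bound (percentage
#'   points, default 1).
#' @param precision_bound positional SD bound (default 2.5).
#' @param fragment_bound per-fragment bound on both statistics
#'   (default 1.1).
#' @param exclude_saturated drop saturated measurements (default TRUE).
#' @return object of class `standards_report`: `fragment_stats`,
#'   `position_stats`, `fragment_devs`, `position_devs`, `exclusions`,
#'   `bounds`, `pass`.
#' @export
run_standards_validation <- function(panel = NULL, noise = noise_model(),
                                     seed = NULL, accuracy_bound = 1,
                                     precision_bound = 2.5,
                                     fragment_bound = 1.1,
                                     exclude_saturated = TRUE) {
  if (is.null(panel)) {
    panel <- simulate_mixture_panel(noise = noise, seed = seed)
  }
  roles <- names(panel$fragments)
  frag_rows <- list()
  pos_rows <- list()
  exclusions <- list()
  for (rec in panel$records) {
    enr <- list()
    for (role in roles) {
      m <- rec$mids[[role]]
      if (exclude_saturated && isTRUE(m$saturated)) {
        exclusions[[length(exclusions) + 1L]] <- data.frame(
          sample_id = m$sample_id, fragment = .frag_key(m$fragment),
          reason = "saturated")
        next
      }
      cm <- correct_mid(m)
      exp_e <- expected_fragment_e13c(m$fragment, rec$expected_e)
      frag_rows[[length(frag_rows) + 1L]] <- data.frame(
        design_id = rec$design_id, injection_ng = rec$injection_ng,
        replicate = rec$replicate, role = role,
        fragment = .frag_key(m$fragment),
        e13c = cm$e13c, expected = exp_e,
        dev = 100 * (cm$e13c - exp_e),
        residual = cm$residual_norm)
      enr[[role]] <- fragment_enrichment(m$fragment$backbone_positions,
                                         cm$e13c, fragment = m$fragment)
    }
    if (all(c("E1234", "E234", "E23", "E34") %in% names(enr))) {
      pos <- positional_e13c(enr$E1234, enr$E234, enr$E23, enr$E34)
      pos_rows[[length(pos_rows) + 1L]] <- data.frame(
        design_id = rec$design_id, injection_ng = rec$injection_ng,
        replicate = rec$replicate, position = 1:4,
        e13c = pos$e, expected = rec$expected_e,
        dev = 100 * (pos$e - rec$expected_e))
    } else {
      exclusions[[length(exclusions) + 1L]] <- data.frame(
        sample_id = sprintf("%s_r%d", rec$design_id, rec$replicate),
        fragment = "(positional)", reason = "missing fragment coverage")
    }
  }
  fragment_devs <- do.call(rbind, frag_rows)
  position_devs <- do.call(rbind, pos_rows)
  fragment_stats <- do.call(rbind, lapply(split(
    fragment_devs, fragment_devs$fragment), function(sub) {
      st <- deviation_stats(sub$e13c, sub$expected, group = sub$fragment[1])
      data.frame(fragment = sub$fragment[1], mean_dev = st$mean_dev,
                 sd_dev = st$sd_dev, n = st$n,
                 pass = abs(st$mean_dev) < fragment_bound &
                   st$sd_dev < fragment_bound)
    }))
  position_stats <- if (is.null(position_devs)) NULL else {
    do.call(rbind, lapply(split(position_devs, position_devs$position),
                          function(sub) {
      st <- deviation_stats(sub$e13c, sub$expected,
                            group = paste0(sub$position[1], "-C"))
      data.frame(position = sub$position[1], mean_dev = st$mean_dev,
                 sd_dev = st$sd_dev, n = st$n,
                 pass_accuracy = abs(st$mean_dev) < accuracy_bound,
                 pass_precision = st$sd_dev < precision_bound)
    }))
  }
  exclusions <- if (length(exclusions)) do.call(rbind, exclusions) else
    data.frame(sample_id = character(0), fragment = character(0),
               reason = character(0))
  pass <- !is.null(position_stats) &&
    all(position_stats$pass_accuracy) && all(position_stats$pass_precision)
  structure(list(
    fragment_stats = fragment_stats, position_stats = position_stats,
    fragment_devs = fragment_devs, position_devs = position_devs,
    exclusions = exclusions,
    bounds = c(accuracy = accuracy_bound, precision = precision_bound,
               fragment = fragment_bound),
    pass = pass
  ), class = "standards_report")
}

#' @export
print.standards_report <- function(x, ...) {
  cat("Standards validation report\n")
  cat("Positional accuracy/precision (percentage points):\n")
  if (!is.null(x$position_stats)) print(x$position_stats, row.names = FALSE)
  cat("Fragment-level statistics:\n")
  print(x$fragment_stats, row.names = FALSE)
  if (nrow(x$exclusions)) {
    cat(nrow(x$exclusions), "measurement(s) excluded (see $exclusions)\n")
  }
  cat(if (x$pass) "PASS" else "FAIL",
      sprintf("(bounds: accuracy < %g, precision < %g, fragment < %g)\n",
              x$bounds["accuracy"], x$bounds["precision"],
              x$bounds["fragment"]))
  invisible(x)
}

#' Run the dynamic labeling analysis workflow
#'
#' Full chain from raw fragment MIDs to assimilation rates: NIA
#' correction, positional enrichment (Eqns of the positional module),
#' internal-standard calibrated aspartate quantification, molar
#' positional 13C per timepoint, and per-replicate sigmoidal fits of the
#' 1-C and 4-C time courses (plus 2-C/3-C when requested).
#'
#' @param dataset a `labeling_dataset` from [simulate_timecourse()], or a
#'   named list of them (one per condition); `NULL` simulates the default
#'   light and dark scenarios.
#' @param noise,replicates,seed forwarded to [simulate_timecourse()] when
#'   `dataset` is `NULL`.
#' @param positions carbon positions to fit (default `c(1, 4)`, the
#'   RUBISCO and PEPC proxies).
#' @param threshold_ratio,threshold_aic sigmoid acceptance settings, see
#'   [fit_sigmoid()].
#' @return object of class `labeling_report`: `timecourse` (per sample:
#'   pool and molar positional 13C), `rates` (per replicate x position),
#'   `rate_summary` (median over replicates; `ND` rows where no replicate
#'   fit is sigmoidal).
#' @export
run_labeling_analysis <- function(dataset = NULL, noise = noise_model(),
                                  replicates = 4, seed = NULL,
                                  positions = c(1, 4),
                                  threshold_ratio = 0.75,
                                  threshold_aic = -10) {
  if (is.null(dataset)) {
    if (!is.null(seed)) set.seed(seed)
    dataset <- list(
      light = simulate_timecourse(labeling_scenario("light"), noise = noise,
                                  replicates = replicates),
      dark = simulate_timecourse(labeling_scenario("dark"), noise = noise,
                                 replicates = replicates))
  }
  if (inherits(dataset, "labeling_dataset")) {
    dataset <- stats::setNames(list(dataset), dataset$scenario$condition)
  }
  tc_rows <- list()
  fit_entries <- list()
  for (cond in names(dataset)) {
    ds <- dataset[[cond]]
    if (length(ds$samples) == 0L) stop("empty sample set for ", cond)
    if (!any(vapply(ds$samples, function(s) s$time_min == 0, logical(1)))) {
      stop("labeling analysis requires a t = 0 sample (sigmoid baseline)")
    }
    cal <- fit_calibration(ds$calibration)
    for (s in ds$samples) {
      enr <- lapply(ds$fragments, function(frag) NULL)
      for (role in names(ds$fragments)) {
        cm <- correct_mid(s$mids[[role]])
        enr[[role]] <- fragment_enrichment(
          s$mids[[role]]$fragment$backbone_positions,
          cm$e13c, fragment = s$mids[[role]]$fragment)
      }
      pos <- positional_e13c(enr$E1234, enr$E234, enr$E23, enr$E34)
      sum_mid <- sum(s$mids$E234$abundances)   # m/z 232, the quantifier
      q <- quantify_aspartate(sum_mid, s$meta, cal)
      molar <- positional_molar(pos, q$conc)
      tc_rows[[length(tc_rows) + 1L]] <- data.frame(
        condition = cond, replicate_id = s$replicate_id,
        time_min = s$time_min, pool = q$conc,
        m1 = molar[1], m2 = molar[2], m3 = molar[3], m4 = molar[4],
        e1 = pos$e[1], e2 = pos$e[2], e3 = pos$e[3], e4 = pos$e[4])
    }
  }
  timecourse <- do.call(rbind, tc_rows)
  timecourse <- timecourse[order(timecourse$condition,
                                 timecourse$replicate_id,
                                 timecourse$time_min), ]
  for (cond in unique(timecourse$condition)) {
    for (rep_id in unique(timecourse$replicate_id[
      timecourse$condition == cond])) {
      sub <- timecourse[timecourse$condition == cond &
                          timecourse$replicate_id == rep_id, ]
      for (p in positions) {
        tc <- time_course(sub$time_min, sub[[paste0("m", p)]],
                          replicate_id = rep_id)
        fit <- fit_sigmoid(tc, threshold_ratio = threshold_ratio,
                           threshold_aic = threshold_aic)
        fit_entries[[length(fit_entries) + 1L]] <- list(
          position = p, condition = cond, replicate_id = rep_id, fit = fit)
      }
    }
  }
  rates <- rate_table(fit_entries)
  rate_summary <- do.call(rbind, lapply(
    split(rates, list(rates$position, rates$condition), drop = TRUE),
    function(sub) {
      det <- sub[sub$determined, ]
      data.frame(
        position = sub$position[1], condition = sub$condition[1],
        n_determined = nrow(det), n_replicates = nrow(sub),
        max_slope = if (nrow(det)) stats::median(det$max_slope) else NA_real_,
        half_max_time = if (nrow(det)) stats::median(det$half_max_time)
                        else NA_real_,
        status = if (nrow(det)) "determined" else "ND")
    }))
  rownames(rate_summary) <- NULL
  structure(list(timecourse = timecourse, rates = rates,
                 rate_summary = rate_summary, fits = fit_entries),
            class = "labeling_report")
}

#' @export
print.labeling_report <- function(x, ...) {
  cat("Dynamic labeling analysis\n")
  cat("Assimilation-rate summary (pmol / OD750 / mL / min):\n")
  print(x$rate_summary, row.names = FALSE)
  invisible(x)
}

#' Read a run configuration file
#'
#' YAML configuration consumed by the command-line interface. Top-level
#' keys: `mode` ("standards" or "labeling"), `seed`, `out_dir`, `noise`
#' (`cv`, `baseline_sd`, `saturation_threshold`, `saturation_softness`),
#' plus mode-specific blocks `standards` (`injections`, `replicates`,
#' `accuracy_bound`, `precision_bound`, `fragment_bound`) and `labeling`
#' (`replicates`, `positions`, `threshold_ratio`, `threshold_aic`).
#' An optional `registry` path overrides the shipped fragment registry.
#'
#' @param path YAML file.
#' @return config list with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$mode) || !cfg$mode %in% c("standards", "labeling")) {
    stop("config needs mode: standards or labeling")
  }
  if (!is.null(cfg$registry) && !file.exists(cfg$registry)) {
    stop("registry file not found: ", cfg$registry)
  }
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  nz <- cfg$noise
  cfg$noise_model <- noise_model(
    cv_multiplicative = if (is.null(nz$cv)) 0.01 else nz$cv,
    baseline_sd = if (is.null(nz$baseline_sd)) 100 else nz$baseline_sd,
    saturation_threshold = if (is.null(nz$saturation_threshold)) 1e7
                           else nz$saturation_threshold,
    saturation_softness = if (is.null(nz$saturation_softness)) 4
                          else nz$saturation_softness)
  cfg
}
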