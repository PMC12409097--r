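#' Raw MID measurement
#'
#' Raw isotopologue abundance vector for one fragment in one injection,
#' before natural-isotope-abundance correction.
#'
#' @param fragment a [fragment_spec()].
#' @param sample_id sample identifier.
#' @param abundances numeric vector of isotopologue abundances M0, M+1, ...
#'   (counts); length at least `n_tracer + 1`.
#' @param apex_rt apex retention time (s), `NA` for peak-table input.
#' @param quant_mode `"apex_area"` (APCI trace integration) or
#'   `"apex_height"` (EI peak table).
#' @param saturated logical saturation flag (see [flag_saturation()]).
#' @return object of class `mid_measurement`.
#' @export
mid_measurement <- function(fragment, sample_id, abundances,
                            apex_rt = NA_real_,
                            quant_mode = c("apex_area", "apex_height"),
                            saturated = FALSE) {
  stopifnot(inherits(fragment, "fragment_spec"))
  abundances <- as.numeric(abundances)
  if (any(abundances < 0)) stop("negative isotopologue abundances")
  if (length(abundances) < fragment$n_tracer + 1L) {
    stop("abundance vector shorter than n_tracer + 1")
  }
  structure(list(
    fragment = fragment,
    sample_id = as.character(sample_id),
    abundances = abundances,
    n_tracer = fragment$n_tracer,
    apex_rt = apex_rt,
    quant_mode = match.arg(quant_mode),
    saturated = isTRUE(saturated)
  ), class = "mid_measurement")
}

#' @export
print.mid_measurement <- function(x, ...) {
  cat(sprintf("<mid_measurement> %s m/z %d sample %s (%s%s)\n",
              x$fragment$analyte, x$fragment$ion_label, x$sample_id,
              x$quant_mode, if (x$saturated) ", saturated" else ""))
  cat("  abundances:", paste(signif(x$abundances, 5), collapse = " "), "\n")
  invisible(x)
}

#' Load a centroided mzML chromatogram
#'
#' Reads all MS1 scans of a centroided mzML file into an in-memory scan
#' series. Profile-mode data are rejected: the extraction rules assume
#' centroided peaks.
#'
#' @param path mzML file path.
#' @param rt_range optional `c(min, max)` retention-time filter (s).
#' @return object of class `scan_series`: list with `rt` (s, increasing)
#'   and `peaks` (list of two-column mz/intensity matrices).
#' @export
load_mzml <- function(path, rt_range = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hd <- mzR::header(handle)
  if (nrow(hd) == 0L) stop("no spectra in file: ", path)
  if (any(!is.na(hd$centroided) & !hd$centroided)) {
    stop("profile-mode spectra detected; centroid the data first")
  }
  pk <- mzR::peaks(handle)
  if (is.matrix(pk)) pk <- list(pk)
  rt <- hd$retentionTime
  ord <- order(rt)
  rt <- rt[ord]
  pk <- pk[ord]
  if (!is.null(rt_range)) {
    keep <- rt >= rt_range[1] & rt <= rt_range[2]
    rt <- rt[keep]
    pk <- pk[keep]
    if (length(rt) == 0L) stop("no scans inside the requested RT range")
  }
  structure(list(rt = rt, peaks = pk), class = "scan_series")
}

#' Extract per-isotopologue intensity traces
#'
#' For each isotopologue `i = 0..n_iso-1`, sums all centroid intensities
#' within `tol` (default +/-0.005 Da) of `exact_mz + i * spacing` in each
#' scan inside the retention-time window. Window centers follow the 13C
#' isotopologue spacing (1.00336 Da); 29Si species fall 3.8 mDa low and are
#' still collected by the +/-5 mDa window, consistent with correcting Si
#' contributions through the formula-based NIA correction rather than
#' resolving them.
#'
#' @param s a `scan_series` from [load_mzml()].
#' @param frag a [fragment_spec()].
#' @param rt_window `c(min, max)` retention-time window (s).
#' @param n_iso number of isotopologue traces (default `n_tracer + 4`).
#' @param tol m/z half-window (Da).
#' @param spacing isotopologue spacing (Da), default [MASS_SHIFT_13C].
#' @return object of class `iso_traces`: list with `rt` and `intensity`
#'   (matrix scans x isotopologues), fragment attached.
#' @export
extract_traces <- function(s, frag, rt_window,
                           n_iso = frag$n_tracer + 4L,
                           tol = 0.005, spacing = MASS_SHIFT_13C) {
  stopifnot(inherits(s, "scan_series"), inherits(frag, "fragment_spec"))
  if (rt_window[1] > max(s$rt) || rt_window[2] < min(s$rt)) {
    stop("rt_window outside the scan range")
  }
  keep <- s$rt >= rt_window[1] & s$rt <= rt_window[2]
  rt <- s$rt[keep]
  pk <- s$peaks[keep]
  centers <- frag$exact_mz + (seq_len(n_iso) - 1L) * spacing
  intensity <- matrix(0, nrow = length(rt), ncol = n_iso)
  for (si in seq_along(pk)) {
    p <- pk[[si]]
    if (is.null(p) || nrow(p) == 0L) next
    for (ii in seq_len(n_iso)) {
      sel <- abs(p[, 1] - centers[ii]) <= tol
      if (any(sel)) intensity[si, ii] <- sum(p[sel, 2])
    }
  }
  structure(list(rt = rt, intensity = intensity, fragment = frag),
            class = "iso_traces")
}

#' MID from APCI traces by apex +/- 10 scan integration
#'
#' Locates the apex as the scan maximizing the summed isotopologue trace
#' (robust when M0 vanishes at high enrichment), then integrates each
#' isotopologue trace by the trapezoidal rule over apex +/- `half_width`
#' scans (default 10).
#'
#' @param traces an `iso_traces` object.
#' @param sample_id sample identifier.
#' @param half_width scans on each side of the apex (default 10).
#' @param noise_floor minimum summed apex intensity; below it the
#'   measurement is treated as missing and `NULL` is returned.
#' @return a [mid_measurement()] with `quant_mode = "apex_area"`, or
#'   `NULL` when no apex rises above the noise floor.
#' @export
mid_apci <- function(traces, sample_id = "sample", half_width = 10L,
                     noise_floor = 0) {
  stopifnot(inherits(traces, "iso_traces"))
  total <- rowSums(traces$intensity)
  if (!any(total > noise_floor)) return(NULL)
  apex <- which.max(total)
  lo <- max(1L, apex - half_width)
  hi <- min(length(traces$rt), apex + half_width)
  idx <- lo:hi
  areas <- apply(traces$intensity[idx, , drop = FALSE], 2, function(y) {
    pracma::trapz(traces$rt[idx], y)
  })
  mid_measurement(traces$fragment, sample_id, areas,
                  apex_rt = traces$rt[apex], quant_mode = "apex_area")
}

#' Read an EI peak-table CSV
#'
#' Dialect: header row `sample_id, analyte, ion_label, isotopologue,
#' abundance` with `isotopologue` the mass offset (0 = M0) and `abundance`
#' the apex height. The EI workflow consumes pre-integrated peak tables
#' from vendor deconvolution software; raw nominal-mass extraction is out
#' of scope.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_peak_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "analyte", "ion_label", "isotopologue", "abundance")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("peak table is missing column(s): ", paste(missing, collapse = ", "))
  }
  tab
}

#' MID from EI peak-table rows
#'
#' Builds one measurement from the apex-height rows of a single
#' (sample, fragment) pair.
#'
#' @param rows data.frame in the [read_peak_table()] dialect, all rows for
#'   one sample and one fragment.
#' @param frag the matching [fragment_spec()].
#' @return a [mid_measurement()] with `quant_mode = "apex_height"`.
#' @export
mid_ei <- function(rows, frag) {
  stopifnot(inherits(frag, "fragment_spec"))
  if (nrow(rows) == 0L) stop("no peak-table rows supplied")
  if (length(unique(rows$sample_id)) != 1L ||
      length(unique(rows$ion_label)) != 1L) {
    stop("rows must belong to a single sample and fragment")
  }
  if (anyDuplicated(rows$isotopologue)) {
    stop("duplicate isotopologue rows for ", rows$sample_id[1],
         " m/z ", rows$ion_label[1])
  }
  iso <- as.integer(rows$isotopologue)
  needed <- 0:frag$n_tracer
  if (!all(needed %in% iso)) {
    stop("peak table misses isotopologues M0..M", frag$n_tracer)
  }
  ab <- numeric(max(iso) + 1L)
  ab[iso + 1L] <- rows$abundance
  mid_measurement(frag, rows$sample_id[1], ab, quant_mode = "apex_height")
}
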