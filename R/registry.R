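#' Fragment specification
#'
#' Describes one registered aspartic acid fragment ion: the analyte it
#' derives from, its nominal m/z tag, exact m/z, elemental formula of the
#' charged species as detected, and which backbone carbon positions of
#' aspartate (1-4) it retains through in-source fragmentation.
#'
#' @param analyte analyte name, e.g. "aspartic acid 3TMS".
#' @param ion_label nominal m/z tag (integer-like).
#' @param exact_mz exact m/z of the monoisotopic ion (Da).
#' @param ion_formula `element_formula` or formula string of the detected ion.
#' @param backbone_positions integer subset of 1:4, the aspartate backbone
#'   carbons covered by the fragment.
#' @param ionization `"APCI"`, `"EI"` or `"both"`.
#' @param notes free text.
#' @return object of class `fragment_spec`.
#' @export
fragment_spec <- function(analyte, ion_label, exact_mz, ion_formula,
                          backbone_positions, ionization = "APCI",
                          notes = "") {
  if (is.character(ion_formula)) ion_formula <- parse_formula(ion_formula)
  backbone_positions <- sort(unique(as.integer(backbone_positions)))
  stopifnot(length(backbone_positions) >= 1,
            all(backbone_positions %in% 1:4))
  ionization <- match.arg(ionization, c("APCI", "EI", "both"))
  n_tracer <- length(backbone_positions)
  n_c <- if ("C" %in% names(ion_formula)) ion_formula[["C"]] else 0L
  if (n_tracer > n_c) {
    stop("fragment covers more backbone carbons than the formula contains")
  }
  if (ionization %in% c("APCI", "both")) {
    dm <- abs(exact_mz - monoisotopic_mass(ion_formula))
    if (dm > 0.01) {
      stop(sprintf(
        "exact_mz %.4f deviates %.4f Da from monoisotopic mass of %s",
        exact_mz, dm, format_formula(ion_formula)))
    }
  }
  structure(list(
    analyte = analyte,
    ion_label = as.integer(ion_label),
    exact_mz = exact_mz,
    ion_formula = ion_formula,
    backbone_positions = backbone_positions,
    n_tracer = n_tracer,
    ionization = ionization,
    notes = notes
  ), class = "fragment_spec")
}

#' @export
print.fragment_spec <- function(x, ...) {
  cat(sprintf("<fragment_spec> %s m/z %d (%s, %.4f Da) positions {%s} [%s]\n",
              x$analyte, x$ion_label, format_formula(x$ion_formula),
              x$exact_mz, paste(x$backbone_positions, collapse = ","),
              x$ionization))
  invisible(x)
}

#' Read a fragment registry file
#'
#' The registry is columnar text (CSV) with header columns `analyte`,
#' `ion_label`, `exact_mz`, `ion_formula`, `backbone_positions`
#' (semicolon-separated), `ionization` and optional `notes`, so that new
#' fragment assignments can be dropped in without a code change.
#'
#' @param path path to a registry CSV.
#' @return list of [fragment_spec()] objects, class `fragment_registry`.
#' @export
read_registry <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("analyte", "ion_label", "exact_mz", "ion_formula",
            "backbone_positions", "ionization")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("registry is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!"notes" %in% names(tab)) tab$notes <- ""
  specs <- lapply(seq_len(nrow(tab)), function(i) {
    fragment_spec(
      analyte = tab$analyte[i],
      ion_label = tab$ion_label[i],
      exact_mz = tab$exact_mz[i],
      ion_formula = tab$ion_formula[i],
      backbone_positions = as.integer(strsplit(tab$backbone_positions[i], ";")[[1]]),
      ionization = tab$ionization[i],
      notes = tab$notes[i]
    )
  })
  structure(specs, class = "fragment_registry")
}

#' Default aspartic acid fragment registry
#'
#' Ships the validated aspartic acid 3TMS and 2TMS fragments: m/z 350
#' \[M+H\]+ and m/z 349 \[M\]+ covering 1,2,3,4-C, m/z 232 covering 2,3,4-C,
#' and 2TMS alternatives m/z 262/245/160. Entries for the 2,3-C, 3,4-C and
#' 1,2-C fragments ship as synthetic placeholders with plausible silyl
#' fragment formulas (marked `synthetic-placeholder` in `notes`): they make
#' the full positional pipeline runnable on simulated data but must be
#' replaced with certified assignments before use on real chromatograms.
#' Override any entry via [read_registry()].
#'
#' @return `fragment_registry` (list of [fragment_spec()]).
#' @export
default_registry <- function() {
  read_registry(system.file("extdata", "fragment_registry.csv",
                            package = "posE13C", mustWork = TRUE))
}

#' Look up a fragment in a registry
#'
#' @param registry a `fragment_registry`.
#' @param analyte analyte name.
#' @param ion_label nominal m/z tag.
#' @return the matching [fragment_spec()]; error if absent or ambiguous.
#' @export
lookup_fragment <- function(registry, analyte, ion_label) {
  hit <- Filter(function(f) f$analyte == analyte &&
                  f$ion_label == as.integer(ion_label), registry)
  if (length(hit) == 0L) {
    stop("no registry entry for ", analyte, " m/z ", ion_label)
  }
  if (length(hit) > 1L) {
    stop("ambiguous registry entry for ", analyte, " m/z ", ion_label)
  }
  hit[[1]]
}

#' Fragments covering the canonical positional coverage sets
#'
#' Returns the default fragment set used for Eqns 1-4 positional algebra:
#' coverages \{1,2,3,4\}, \{2,3,4\}, \{2,3\} and \{3,4\} of aspartic acid
#' 3TMS. The \[M+H\]+ m/z 350 adduct is skipped in favor of m/z 349 because
#' its MID is overlapped by the molecular ion.
#'
#' @param registry a `fragment_registry` (default [default_registry()]).
#' @return named list with elements `E1234`, `E234`, `E23`, `E34`.
#' @export
positional_fragment_set <- function(registry = default_registry()) {
  list(
    E1234 = lookup_fragment(registry, "aspartic acid 3TMS", 349),
    E234  = lookup_fragment(registry, "aspartic acid 3TMS", 232),
    E23   = lookup_fragment(registry, "aspartic acid 3TMS", 218),
    E34   = lookup_fragment(registry, "aspartic acid 3TMS", 188)
  )
}
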