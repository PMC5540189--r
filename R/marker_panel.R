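#' Marker panel: compartment and direction of each marker
#'
#' A marker panel declares, for each immunofluorescence marker, which cellular
#' compartment its mean intensity is read from (nuclear or cytoplasm) and in
#' which tail of the intensity distribution a QCC lies (`"low"` or `"high"`).
#' The default is the three-marker quiescence panel: pan-AKT (cytoplasm, low),
#' H3K9me2 (nuclear, low), HES1 (cytoplasm, high).
#'
#' @param markers character vector of marker names.
#' @param compartment named character vector mapping each marker to
#'   `"nuclear"` or `"cytoplasm"`.
#' @param direction named character vector mapping each marker to `"low"` or
#'   `"high"` (the tail a QCC occupies).
#' @return an object of class `marker_panel`.
#' @export
#' @examples
#' marker_panel()
marker_panel <- function(markers = c("AKT", "H3K9me2", "HES1"),
                         compartment = c(AKT = "cytoplasm",
                                         H3K9me2 = "nuclear",
                                         HES1 = "cytoplasm"),
                         direction = c(AKT = "low",
                                       H3K9me2 = "low",
                                       HES1 = "high")) {
  stopifnot(length(markers) >= 1, !anyDuplicated(markers))
  if (!all(markers %in% names(compartment)))
    stop("every marker needs a compartment", call. = FALSE)
  if (!all(markers %in% names(direction)))
    stop("every marker needs a direction", call. = FALSE)
  compartment <- compartment[markers]
  direction <- direction[markers]
  if (!all(compartment %in% c("nuclear", "cytoplasm")))
    stop("compartment must be 'nuclear' or 'cytoplasm'", call. = FALSE)
  if (!all(direction %in% c("low", "high")))
    stop("direction must be 'low' or 'high'", call. = FALSE)
  structure(list(markers = markers, compartment = compartment,
                 direction = direction),
            class = "marker_panel")
}

#' Name of the intensity column holding a marker's measured compartment
#'
#' @param panel a [marker_panel()].
#' @param marker marker name.
#' @return column name, e.g. `"AKT_cytoplasm_mean"`.
#' @export
intensity_column <- function(panel, marker) {
  stopifnot(inherits(panel, "marker_panel"), marker %in% panel$markers)
  paste0(marker, "_", panel$compartment[[marker]], "_mean")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("<marker_panel>", length(x$markers), "markers\n")
  for (m in x$markers)
    cat(sprintf("  %-8s %-9s %s\n", m, x$compartment[[m]], x$direction[[m]]))
  invisible(x)
}

#' Threshold configuration for QCC calling
#'
#' In `relative` mode a cell qualifies on a marker if it lies within the top
#' (direction `"high"`) or bottom (direction `"low"`) fraction `t` of that
#' marker's intensities among the reference population of the same section;
#' the default `t = 0.25` is the working definition of a QCC.  In `absolute`
#' mode fixed intensity cutoffs are applied instead (provided mainly to
#' demonstrate why absolute thresholds are not reproducible across sections).
#'
#' @param mode `"relative"` or `"absolute"`.
#' @param t fraction in \[0, 1\] used in relative mode (default 0.25).
#' @param absolute_cutoffs named numeric vector, one intensity cutoff per
#'   marker; required in absolute mode.
#' @param panel a [marker_panel()].
#' @return object of class `threshold_config`.
#' @export
threshold_config <- function(mode = c("relative", "absolute"), t = 0.25,
                             absolute_cutoffs = NULL,
                             panel = marker_panel()) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "marker_panel"))
  if (mode == "relative") {
    if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0 || t > 1)
      stop("relative mode requires a single t in [0, 1]", call. = FALSE)
  } else {
    if (is.null(absolute_cutoffs) ||
        !all(panel$markers %in% names(absolute_cutoffs)))
      stop("absolute mode requires a cutoff for every marker", call. = FALSE)
    absolute_cutoffs <- absolute_cutoffs[panel$markers]
  }
  structure(list(mode = mode, t = t, absolute_cutoffs = absolute_cutoffs,
                 panel = panel),
            class = "threshold_config")
}
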