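#' Flag cells in one tail of a marker's intensity distribution
#'
#' Rank-based qualification: cells are sorted ascending by intensity with ties
#' broken by `ids` for determinism; `direction = "low"` flags the first
#' `ceiling(t * N)` ranks, `direction = "high"` the last `ceiling(t * N)`.
#' Exactly `ceiling(t * N)` cells are flagged, which makes the rule invariant
#' under any strictly increasing transform of the intensities (per-section
#' batch scaling in particular) and nested across increasing `t`.
#'
#' @param values numeric intensity vector (length >= 1).
#' @param t fraction in \[0, 1\].
#' @param direction `"low"` or `"high"`.
#' @param ids tie-break keys, unique per cell (default positional).
#' @return logical vector of flags, one per cell.
#' @export
#' @examples
#' qualify_marker(c(1, 2, 3, 4), 0.25, "low")   # flags only the value 1
qualify_marker <- function(values, t, direction = c("low", "high"),
                           ids = seq_along(values)) {
  direction <- match.arg(direction)
  n <- length(values)
  if (n < 1L) stop("empty intensity vector", call. = FALSE)
  stopifnot(is.numeric(t), length(t) == 1L, t >= 0, t <= 1,
            length(ids) == n)
  m <- as.integer(ceiling(t * n))
  flags <- logical(n)
  if (m == 0L) return(flags)
  ord <- order(values, ids)
  sel <- if (direction == "low") ord[seq_len(m)] else ord[seq.int(n - m + 1L, n)]
  flags[sel] <- TRUE
  flags
}

# realized intensity cutoff at the rank boundary (value of the last cell in)
realized_threshold <- function(values, t, direction, ids) {
  n <- length(values)
  m <- as.integer(ceiling(t * n))
  if (m == 0L) return(NA_real_)
  ord <- order(values, ids)
  if (direction == "low") values[ord[m]] else values[ord[n - m + 1L]]
}

#' Call QCCs on a section
#'
#' A cell is a QCC iff it qualifies on all three markers simultaneously:
#' pan-AKT low, H3K9me2 low (nuclear compartment), HES1 high.  In relative
#' mode each marker's flags come from [qualify_marker()] with the reference
#' population being the tumor cells of this same section (each section is its
#' own reference); in absolute mode fixed cutoffs are compared directly
#' (`<=` for low, `>=` for high).
#'
#' @param section a [section_table()] containing at least one tumor cell.
#' @param config a [threshold_config()].
#' @param tumor_only if `TRUE` (default) percentiles are computed over tumor
#'   cells only and stroma cells are never called QCC (their per-marker flags
#'   are `NA`).
#' @return object of class `qcc_labels`: a data.frame with `cell_id`,
#'   `fov_id`, `tissue_class`, one flag column per marker (e.g. `akt_low`,
#'   `h3k9me2_low`, `hes1_high`) and `qcc_label`; attributes `thresholds`
#'   (realized per-marker cutoffs), `mode` and `t`.
#' @export
call_qcc <- function(section, config = threshold_config(),
                     tumor_only = TRUE) {
  stopifnot(inherits(section, "section_table"),
            inherits(config, "threshold_config"))
  cells <- section$cells
  panel <- config$panel
  pop <- if (tumor_only) cells$tissue_class == "tumor" else
    rep(TRUE, nrow(cells))
  if (!any(pop))
    stop("no cells in the thresholding population (zero tumor cells?)",
         call. = FALSE)
  ids <- cells$cell_id[pop]
  out <- data.frame(cell_id = cells$cell_id, fov_id = cells$fov_id,
                    tissue_class = cells$tissue_class,
                    stringsAsFactors = FALSE)
  thresholds <- numeric(0)
  qcc <- rep(TRUE, sum(pop))
  for (mk in panel$markers) {
    col <- intensity_column(panel, mk)
    if (!col %in% names(cells))
      stop("missing intensity column '", col, "' for marker ", mk,
           call. = FALSE)
    v <- cells[[col]][pop]
    dir <- panel$direction[[mk]]
    if (config$mode == "relative") {
      fl <- qualify_marker(v, config$t, dir, ids = ids)
      thr <- realized_threshold(v, config$t, dir, ids)
    } else {
      thr <- config$absolute_cutoffs[[mk]]
      fl <- if (dir == "low") v <= thr else v >= thr
    }
    thresholds[mk] <- thr
    flag_col <- paste0(tolower(mk), "_", dir)
    full <- rep(NA, nrow(cells))
    full[pop] <- fl
    out[[flag_col]] <- full
    qcc <- qcc & fl
  }
  out$qcc_label <- FALSE
  out$qcc_label[pop] <- qcc
  structure(out, thresholds = thresholds, mode = config$mode,
            t = if (config$mode == "relative") config$t else NA_real_,
            class = c("qcc_labels", "data.frame"))
}

#' Sweep the relative threshold and tabulate QCC-P / QCC-D
#'
#' Applies [call_qcc()] at each fraction and reports the section-level QCC
#' percentage and the per-FOV densities.  Because rank sets are nested in
#' `t`, QCC-P is non-decreasing along the sweep.
#'
#' @param section a [section_table()].
#' @param fractions ascending fractions (default `c(0.25, 0.33, 0.50)`, the
#'   candidate thresholds evaluated on the control tumors).
#' @param panel a [marker_panel()].
#' @param tumor_only passed to [call_qcc()].
#' @return data.frame with columns `t`, `qcc_p` and a list-column `qcc_d` of
#'   per-FOV fractions (defined FOVs only).
#' @export
threshold_sweep <- function(section, fractions = c(0.25, 0.33, 0.50),
                            panel = marker_panel(), tumor_only = TRUE) {
  stopifnot(!is.unsorted(fractions))
  rows <- lapply(fractions, function(tt) {
    labels <- call_qcc(section, threshold_config(t = tt, panel = panel),
                       tumor_only = tumor_only)
    dens <- qcc_density(labels, section)
    list(t = tt, qcc_p = qcc_percentage(labels),
         qcc_d = dens$qcc_d[!is.na(dens$qcc_d)])
  })
  data.frame(t = vapply(rows, `[[`, 0, "t"),
             qcc_p = vapply(rows, `[[`, 0, "qcc_p"),
             qcc_d = I(lapply(rows, `[[`, "qcc_d")))
}
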