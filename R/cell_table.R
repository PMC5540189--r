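#' Assemble a validated per-section cell table
#'
#' A section table bundles everything measured on one 4-micron tissue section:
#' one row per segmented cell (tile, local pixel coordinates, tumor/stroma
#' class, per-compartment marker mean intensities) plus per-FOV metadata used
#' for quality filtering and tile stitching.  It is the unit on which
#' thresholds are computed and spatial statistics are run.
#'
#' @param cells data.frame with columns `cell_id`, `fov_id`, `x_local`,
#'   `y_local`, `tissue_class` (`"tumor"`/`"stroma"`) and one intensity column
#'   per (marker, compartment) pair, e.g. `AKT_cytoplasm_mean`.
#' @param fovs data.frame with columns `fov_id`, `grid_row`, `grid_col`,
#'   `tile_width`, `tile_height`, `tumor_fraction`, `artifact_fraction`.
#' @param section_id,patient_id,batch_id identifiers.
#' @param sample_type one of `"control"`, `"biopsy"`, `"mastectomy"`,
#'   `"metastasis"`.
#' @param panel a [marker_panel()]; its intensity columns must be present.
#' @param excluded_fovs FOV metadata rows already excluded by QC (kept so maps
#'   can gray out their footprints); usually filled by [filter_fovs()].
#' @return object of class `section_table` (a list with elements `section_id`,
#'   `patient_id`, `sample_type`, `batch_id`, `cells`, `fovs`,
#'   `excluded_fovs`, `panel`).
#' @export
section_table <- function(cells, fovs, section_id,
                          patient_id = NA_character_,
                          sample_type = c("control", "biopsy", "mastectomy",
                                          "metastasis"),
                          batch_id = NA_character_,
                          panel = marker_panel(),
                          excluded_fovs = NULL) {
  sample_type <- match.arg(sample_type)
  stopifnot(is.data.frame(cells), is.data.frame(fovs))
  req_cells <- c("cell_id", "fov_id", "x_local", "y_local", "tissue_class")
  req_fovs <- c("fov_id", "grid_row", "grid_col", "tile_width", "tile_height",
                "tumor_fraction", "artifact_fraction")
  icols <- vapply(panel$markers, function(m) intensity_column(panel, m), "")
  for (cl in c(req_cells, icols))
    if (!cl %in% names(cells))
      stop("cell table is missing column '", cl, "'", call. = FALSE)
  for (cl in req_fovs)
    if (!cl %in% names(fovs))
      stop("FOV table is missing column '", cl, "'", call. = FALSE)
  if (anyDuplicated(cells$cell_id))
    stop("cell_id values must be unique within a section", call. = FALSE)
  if (nrow(cells) && !all(cells$fov_id %in% fovs$fov_id))
    stop("cells reference fov_ids absent from the FOV table", call. = FALSE)
  if (nrow(cells) && !all(cells$tissue_class %in% c("tumor", "stroma")))
    stop("tissue_class must be 'tumor' or 'stroma'", call. = FALSE)
  for (cl in icols) {
    v <- cells[[cl]]
    bad <- !is.finite(v) | v < 0
    if (any(bad))
      stop("non-finite or negative intensity in '", cl, "' for cell_id ",
           cells$cell_id[which(bad)[1L]], call. = FALSE)
  }
  frac_ok <- function(v) all(is.finite(v) & v >= 0 & v <= 1)
  if (!frac_ok(fovs$tumor_fraction) || !frac_ok(fovs$artifact_fraction))
    stop("FOV tumor/artifact fractions must lie in [0, 1]", call. = FALSE)
  if (anyDuplicated(fovs[, c("grid_row", "grid_col")]))
    stop("duplicate (grid_row, grid_col) tile positions", call. = FALSE)
  structure(list(section_id = section_id, patient_id = patient_id,
                 sample_type = sample_type, batch_id = batch_id,
                 cells = cells, fovs = fovs,
                 excluded_fovs = excluded_fovs, panel = panel),
            class = "section_table")
}

#' @export
print.section_table <- function(x, ...) {
  cat(sprintf("<section_table> %s (%s): %d cells (%d tumor) in %d FOVs",
              x$section_id, x$sample_type, nrow(x$cells),
              sum(x$cells$tissue_class == "tumor"), nrow(x$fovs)))
  if (!is.null(x$excluded_fovs) && nrow(x$excluded_fovs))
    cat(sprintf(" (+%d FOVs excluded by QC)", nrow(x$excluded_fovs)))
  cat("\n")
  invisible(x)
}

#' Read a per-cell table and its FOV metadata sidecar
#'
#' Ingests inForm-style per-cell CSV exports.  Column names in the files may
#' differ from the canonical schema; pass `schema` to map them (names are
#' canonical, values are the file's headers).  Coordinates are 0-based pixels
#' with y increasing downward.
#'
#' @param cells_path path to the per-cell CSV.
#' @param fovs_path path to the per-FOV metadata CSV.
#' @param panel a [marker_panel()].
#' @param schema optional named character vector mapping canonical column
#'   names to the file's column names.
#' @param patient_id,sample_type,batch_id section-level metadata (not stored
#'   in the CSVs).
#' @return a validated [section_table()].
#' @export
read_cell_table <- function(cells_path, fovs_path, panel = marker_panel(),
                            schema = NULL,
                            patient_id = NA_character_,
                            sample_type = "control",
                            batch_id = NA_character_) {
  stopifnot(file.exists(cells_path), file.exists(fovs_path))
  cells <- read.csv(cells_path, stringsAsFactors = FALSE, comment.char = "#")
  fovs <- read.csv(fovs_path, stringsAsFactors = FALSE, comment.char = "#")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      have <- schema[[canon]]
      if (!have %in% names(cells) && !have %in% names(fovs))
        stop("schema column '", have, "' (for '", canon,
             "') not found in either file", call. = FALSE)
      names(cells)[names(cells) == have] <- canon
      names(fovs)[names(fovs) == have] <- canon
    }
  }
  icols <- vapply(panel$markers, function(m) intensity_column(panel, m), "")
  for (cl in c("section_id", "cell_id", "fov_id", "x_local", "y_local",
               "tissue_class", icols))
    if (!cl %in% names(cells))
      stop("cell table is missing column '", cl, "'", call. = FALSE)
  sid <- unique(cells$section_id)
  if (length(sid) > 1L)
    stop("cell table mixes multiple section_ids: ",
         paste(sid, collapse = ", "), call. = FALSE)
  if (length(sid) == 0L) sid <- NA_character_
  cells$section_id <- NULL
  section_table(cells, fovs, section_id = sid, patient_id = patient_id,
                sample_type = sample_type, batch_id = batch_id, panel = panel)
}

#' Write a section table to the canonical CSV pair
#'
#' @param section a [section_table()].
#' @param cells_path,fovs_path output paths.
#' @return `section`, invisibly.
#' @export
write_cell_table <- function(section, cells_path, fovs_path) {
  stopifnot(inherits(section, "section_table"))
  hdr <- "# coordinates: 0-based pixels, y increases downward"
  cells <- cbind(section_id = section$section_id, section$cells)
  writeLines(hdr, cells_path)
  suppressWarnings(write.table(cells, cells_path, sep = ",", row.names = FALSE,
                               col.names = TRUE, append = TRUE, qmethod = "double"))
  write.csv(section$fovs, fovs_path, row.names = FALSE)
  invisible(section)
}

#' Exclude low-quality fields of view
#'
#' Drops FOVs with less than `min_tumor` tumor component or more than
#' `max_artifact` technical artifacts (tissue folding, air bubbles, tissue
#' loss), together with all their cells.  Boundary values are kept: the
#' inequalities are strict on both sides.  Excluded FOV metadata is retained
#' on the section so tumor maps can gray out the dropped footprints.
#'
#' @param section a [section_table()].
#' @param min_tumor exclude if `tumor_fraction < min_tumor` (default 0.01).
#' @param max_artifact exclude if `artifact_fraction > max_artifact`
#'   (default 0.70).
#' @return list with elements `section` (filtered [section_table()]) and
#'   `report` (data.frame of excluded `fov_id`, `reason`).
#' @export
filter_fovs <- function(section, min_tumor = 0.01, max_artifact = 0.70) {
  stopifnot(inherits(section, "section_table"),
            min_tumor >= 0, min_tumor <= 1,
            max_artifact >= 0, max_artifact <= 1)
  fovs <- section$fovs
  low_tumor <- fovs$tumor_fraction < min_tumor
  high_artifact <- fovs$artifact_fraction > max_artifact
  drop <- low_tumor | high_artifact
  reason <- ifelse(low_tumor & high_artifact, "low_tumor;high_artifact",
                   ifelse(low_tumor, "low_tumor", "high_artifact"))
  report <- data.frame(fov_id = fovs$fov_id[drop], reason = reason[drop],
                       stringsAsFactors = FALSE)
  out <- section
  out$fovs <- fovs[!drop, , drop = FALSE]
  out$cells <- section$cells[!section$cells$fov_id %in% fovs$fov_id[drop], ,
                             drop = FALSE]
  out$excluded_fovs <- rbind(section$excluded_fovs,
                             fovs[drop, , drop = FALSE])
  list(section = out, report = report)
}

#' Keep tumor-class cells only
#'
#' Percentile thresholds and the cluster index are defined over cancer cells;
#' stroma cells are removed while FOV metadata is preserved.
#'
#' @param section a [section_table()].
#' @return the section with only `tissue_class == "tumor"` cells.
#' @export
select_tumor_cells <- function(section) {
  stopifnot(inherits(section, "section_table"))
  section$cells <- section$cells[section$cells$tissue_class == "tumor", ,
                                 drop = FALSE]
  section
}
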