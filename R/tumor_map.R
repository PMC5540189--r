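#' Tile layout: global origin of every FOV
#'
#' Reconstructs each tile's origin in the whole-section coordinate system from
#' its grid position.  Grid indices are 0-based; with `overlap = 0` tiles abut
#' exactly, so a cell at local (10, 20) in grid column 1 of 1392-px-wide tiles
#' lands at global x = 1402.
#'
#' @param fovs FOV metadata data.frame (`fov_id`, `grid_row`, `grid_col`,
#'   `tile_width`, `tile_height`).
#' @param overlap tile overlap in pixels (default 0).
#' @return data.frame `fov_id`, `x0`, `y0`, `tile_width`, `tile_height`.
#' @export
tile_layout <- function(fovs, overlap = 0) {
  stopifnot(is.data.frame(fovs), overlap >= 0)
  out <- data.frame(fov_id = fovs$fov_id,
                    x0 = fovs$grid_col * (fovs$tile_width - overlap),
                    y0 = fovs$grid_row * (fovs$tile_height - overlap),
                    tile_width = fovs$tile_width,
                    tile_height = fovs$tile_height,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out[, c("x0", "y0")]))
    stop("tile origins are not unique", call. = FALSE)
  out
}

#' Stitch per-tile coordinates into a digital tumor map
#'
#' De-convolutes local (within-tile) cell coordinates into a single Cartesian
#' coordinate system for the whole section: global = tile origin + local, a
#' rigid translation per tile.  QCC labels may be attached so the map can be
#' rendered and fed to the spatial statistics.
#'
#' @param section a [section_table()].
#' @param labels optional [call_qcc()] result; matched to cells by `cell_id`.
#' @param layout optional [tile_layout()]; defaults to the layout of all FOVs
#'   (retained and QC-excluded) of the section.
#' @param overlap passed to [tile_layout()] when `layout` is `NULL`.
#' @return object of class `tumor_map`: a data.frame with `cell_id`,
#'   `fov_id`, `x`, `y`, `tissue_class`, `qcc`; attributes `section_id`,
#'   `excluded` (footprint rectangles of QC-excluded FOVs) and `field`
#'   (map extent).
#' @export
stitch <- function(section, labels = NULL, layout = NULL, overlap = 0) {
  stopifnot(inherits(section, "section_table"))
  all_fovs <- rbind(section$fovs, section$excluded_fovs)
  if (is.null(layout)) layout <- tile_layout(all_fovs, overlap = overlap)
  cells <- section$cells
  i <- match(cells$fov_id, layout$fov_id)
  if (anyNA(i))
    stop("no layout origin for tile '", cells$fov_id[which(is.na(i))[1L]],
         "'", call. = FALSE)
  qcc <- rep(NA, nrow(cells))
  if (!is.null(labels)) {
    j <- match(cells$cell_id, labels$cell_id)
    qcc <- labels$qcc_label[j]
  }
  map <- data.frame(cell_id = cells$cell_id, fov_id = cells$fov_id,
                    x = layout$x0[i] + cells$x_local,
                    y = layout$y0[i] + cells$y_local,
                    tissue_class = cells$tissue_class,
                    qcc = qcc, stringsAsFactors = FALSE)
  excl <- NULL
  if (!is.null(section$excluded_fovs) && nrow(section$excluded_fovs)) {
    k <- match(section$excluded_fovs$fov_id, layout$fov_id)
    excl <- data.frame(fov_id = section$excluded_fovs$fov_id,
                       x0 = layout$x0[k], y0 = layout$y0[k],
                       width = layout$tile_width[k],
                       height = layout$tile_height[k],
                       stringsAsFactors = FALSE)
  }
  structure(map, section_id = section$section_id, excluded = excl,
            field = c(width = max(layout$x0 + layout$tile_width),
                      height = max(layout$y0 + layout$tile_height)),
            class = c("tumor_map", "data.frame"))
}

#' Construct a tumor map directly from global coordinates
#'
#' Convenience constructor for maps not derived from a tiled section (tests,
#' simulations already in global coordinates).
#'
#' @param x,y global coordinates.
#' @param qcc logical QCC labels.
#' @param cell_id cell identifiers (default sequential).
#' @param tissue_class default all `"tumor"`.
#' @param section_id map identifier.
#' @return a `tumor_map`.
#' @export
tumor_map <- function(x, y, qcc, cell_id = seq_along(x),
                      tissue_class = rep("tumor", length(x)),
                      section_id = NA_character_) {
  stopifnot(length(x) == length(y), !anyDuplicated(cell_id))
  qcc <- rep_len(qcc, length(x))
  structure(data.frame(cell_id = cell_id, fov_id = NA_character_,
                       x = x, y = y, tissue_class = tissue_class,
                       qcc = qcc, stringsAsFactors = FALSE),
            section_id = section_id, excluded = NULL,
            field = c(width = max(x, 0), height = max(y, 0)),
            class = c("tumor_map", "data.frame"))
}

#' Arrange maps of sequential sections as an ordered 3D stack
#'
#' Maps are left untouched; each is assigned a z position equal to its rank in
#' `order` (0-based), emulating the visual stacking of sequential sections.
#'
#' @param maps list of `tumor_map` objects.
#' @param order numeric order keys (e.g. section numbers), one per map,
#'   distinct.
#' @return object of class `map_stack`: list with `maps` (sorted by `order`),
#'   `order` and `z` (0-based positions).
#' @export
stack_sections <- function(maps, order = seq_along(maps)) {
  stopifnot(is.list(maps), length(order) == length(maps))
  if (anyDuplicated(order)) stop("duplicate order values", call. = FALSE)
  idx <- base::order(order)
  structure(list(maps = maps[idx], order = order[idx],
                 z = seq_along(maps) - 1L),
            class = "map_stack")
}

#' Render a digital tumor map to SVG
#'
#' QCCs are drawn as red dots, other cancer cells as blue dots, stroma cells
#' as light gray dots, and the footprints of QC-excluded FOVs as gray
#' rectangles.  The output is plain SVG text composed deterministically: the
#' same map renders byte-identically every time, and glyph counts can be
#' audited directly.
#'
#' @param map a `tumor_map` with `qcc` labels set.
#' @param path output `.svg` path.
#' @param width canvas width in px (height follows the map aspect ratio).
#' @param point_radius dot radius in canvas px.
#' @return `path`, invisibly.
#' @export
render_map <- function(map, path, width = 1000, point_radius = 2.5) {
  stopifnot(inherits(map, "tumor_map"), nrow(map) > 0)
  field <- attr(map, "field", exact = TRUE)
  fw <- max(field[["width"]], max(map$x), 1)
  fh <- max(field[["height"]], max(map$y), 1)
  s <- width / fw
  height <- ceiling(fh * s)
  fmt <- function(v) sprintf("%.2f", v * s)
  lines <- c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                            'width="%d" height="%d" ',
                            'viewBox="0 0 %d %d">'),
                     as.integer(width), as.integer(height),
                     as.integer(width), as.integer(height)),
             '<rect width="100%" height="100%" fill="white"/>')
  excl <- attr(map, "excluded", exact = TRUE)
  if (!is.null(excl) && nrow(excl)) {
    excl <- excl[order(excl$fov_id), , drop = FALSE]
    lines <- c(lines, sprintf(
      '<rect class="excluded" x="%s" y="%s" width="%s" height="%s" fill="gray"/>',
      fmt(excl$x0), fmt(excl$y0), fmt(excl$width), fmt(excl$height)))
  }
  circ <- function(d, cls, fill) sprintf(
    '<circle class="%s" cx="%s" cy="%s" r="%.2f" fill="%s"/>',
    cls, fmt(d$x), fmt(d$y), point_radius, fill)
  ord <- order(map$cell_id)
  m <- map[ord, , drop = FALSE]
  stroma <- m$tissue_class != "tumor"
  other <- !stroma & !(m$qcc %in% TRUE)
  qcc <- !stroma & (m$qcc %in% TRUE)
  if (any(stroma)) lines <- c(lines, circ(m[stroma, ], "stroma", "#d9d9d9"))
  if (any(other)) lines <- c(lines, circ(m[other, ], "other", "blue"))
  if (any(qcc)) lines <- c(lines, circ(m[qcc, ], "qcc", "red"))
  writeLines(c(lines, "</svg>"), path)
  invisible(path)
}

#' Write / read a digital tumor map as CSV
#'
#' Lossless for coordinates and labels (the excluded-FOV mask is carried by
#' the section, not the CSV).
#'
#' @param map a `tumor_map`.
#' @param path CSV path.
#' @return `write_map`: `path` invisibly; `read_map`: a `tumor_map`.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "tumor_map"))
  out <- data.frame(section_id = attr(map, "section_id", exact = TRUE),
                    cell_id = map$cell_id, fov_id = map$fov_id,
                    x_global = map$x, y_global = map$y,
                    qcc_label = map$qcc, tissue_class = map$tissue_class,
                    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  structure(data.frame(cell_id = d$cell_id, fov_id = d$fov_id,
                       x = d$x_global, y = d$y_global,
                       tissue_class = d$tissue_class, qcc = d$qcc_label,
                       stringsAsFactors = FALSE),
            section_id = d$section_id[1L], excluded = NULL,
            field = c(width = max(d$x_global, 0), height = max(d$y_global, 0)),
            class = c("tumor_map", "data.frame"))
}
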