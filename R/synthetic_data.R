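# Class-conditional log-normal intensity model.  QCCs sit 4 sdlog units
# below the bulk for AKT and H3K9me2 and 4 above for HES1 — a strong but not
# perfectly separable shift, so percentile calling recovers most (not all)
# ground-truth QCCs.
default_intensity_model <- function() {
  list(AKT = list(other = c(meanlog = 3, sdlog = 0.5),
                  qcc = c(meanlog = 1, sdlog = 0.5)),
       H3K9me2 = list(other = c(meanlog = 3, sdlog = 0.5),
                      qcc = c(meanlog = 1, sdlog = 0.5)),
       HES1 = list(other = c(meanlog = 2, sdlog = 0.5),
                   qcc = c(meanlog = 4, sdlog = 0.5)))
}

#' Configuration of a synthetic tissue section
#'
#' Describes the generative model for one section: how many tumor cells,
#' where they sit (complete spatial randomness, or a Thomas parent-offspring
#' cluster process for the QCCs), the class-conditional log-normal intensity
#' model for the three markers, per-section multiplicative batch scaling, and
#' the FOV grid the cells are carved into.
#'
#' Defaults describe a 3x3 grid of 1392x1040 px (Vectra x20) tiles holding
#' 1000 tumor cells, 30% stroma admixture, a 5% QCC fraction, and for the
#' clustered alternative 5 cluster parents with Gaussian dispersion equal to
#' 2% of the field width (tight clusters).
#'
#' @param n_cells total tumor cells.
#' @param stroma_fraction fraction of all cells that are stroma.
#' @param qcc_fraction target ground-truth QCC fraction among tumor cells.
#' @param spatial_model `"csr"` (uniform, labels i.i.d. Bernoulli) or
#'   `"thomas"` (QCCs as Gaussian offspring of uniform parents).
#' @param n_parents Thomas parent count.
#' @param sigma Thomas offspring dispersion (coordinate units); default 2% of
#'   field width.
#' @param fov_rows,fov_cols,tile_width,tile_height FOV grid geometry.
#' @param artifact_fraction per-FOV artifact fraction (recycled).
#' @param intensity per-marker, per-class log-normal parameters.
#' @param batch_scale named per-marker multiplicative intensity factor
#'   (the section/batch effect).
#' @param panel a [marker_panel()].
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_cells = 1000, stroma_fraction = 0.3,
                         qcc_fraction = 0.05,
                         spatial_model = c("csr", "thomas"),
                         n_parents = 5, sigma = NULL,
                         fov_rows = 3, fov_cols = 3,
                         tile_width = 1392, tile_height = 1040,
                         artifact_fraction = 0,
                         intensity = default_intensity_model(),
                         batch_scale = c(AKT = 1, H3K9me2 = 1, HES1 = 1),
                         panel = marker_panel()) {
  spatial_model <- match.arg(spatial_model)
  stopifnot(n_cells >= 0, stroma_fraction >= 0, stroma_fraction < 1,
            qcc_fraction >= 0, qcc_fraction <= 1, n_parents >= 1,
            fov_rows >= 1, fov_cols >= 1, tile_width > 0, tile_height > 0,
            all(artifact_fraction >= 0 & artifact_fraction <= 1),
            all(panel$markers %in% names(intensity)),
            all(panel$markers %in% names(batch_scale)),
            all(batch_scale > 0))
  field <- c(width = fov_cols * tile_width, height = fov_rows * tile_height)
  if (is.null(sigma)) sigma <- 0.02 * field[["width"]]
  stopifnot(sigma > 0)
  structure(list(n_cells = n_cells, stroma_fraction = stroma_fraction,
                 qcc_fraction = qcc_fraction, spatial_model = spatial_model,
                 n_parents = n_parents, sigma = sigma,
                 fov_rows = fov_rows, fov_cols = fov_cols,
                 tile_width = tile_width, tile_height = tile_height,
                 artifact_fraction = artifact_fraction, field = field,
                 intensity = intensity, batch_scale = batch_scale,
                 panel = panel),
            class = "synth_config")
}

#' Simulate tumor-cell positions and ground-truth classes
#'
#' Under `csr`, positions are uniform on the field and classes are
#' independent Bernoulli(`qcc_fraction`).  Under `thomas`, non-QCC cells are
#' uniform while `round(qcc_fraction * n_cells)` QCCs are placed as
#' Gaussian-dispersed offspring (sd `sigma`) of uniformly placed parents,
#' clipped to the field.
#'
#' @param config a [synth_config()].
#' @param seed optional seed (RNG state untouched if `NULL`).
#' @param parents optional matrix of parent coordinates (columns x, y) to
#'   reuse across sections, emulating contiguous sections that share cluster
#'   positions.
#' @return data.frame `x`, `y`, `is_qcc`, `parent` (offspring's parent index,
#'   `NA` for csr / non-QCC).
#' @export
simulate_positions <- function(config, seed = NULL, parents = NULL) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(seed, {
    n <- config$n_cells
    w <- config$field[["width"]]; h <- config$field[["height"]]
    if (n == 0)
      return(data.frame(x = numeric(0), y = numeric(0), is_qcc = logical(0),
                        parent = integer(0)))
    if (config$spatial_model == "csr") {
      data.frame(x = runif(n, 0, w), y = runif(n, 0, h),
                 is_qcc = rbinom(n, 1, config$qcc_fraction) == 1,
                 parent = NA_integer_)
    } else {
      n_q <- round(config$qcc_fraction * n)
      n_o <- n - n_q
      if (is.null(parents))
        parents <- cbind(runif(config$n_parents, 0, w),
                         runif(config$n_parents, 0, h))
      assign_p <- if (n_q) sample.int(nrow(parents), n_q, replace = TRUE)
                  else integer(0)
      qx <- pmin(pmax(parents[assign_p, 1] + rnorm(n_q, 0, config$sigma), 0), w)
      qy <- pmin(pmax(parents[assign_p, 2] + rnorm(n_q, 0, config$sigma), 0), h)
      data.frame(x = c(runif(n_o, 0, w), qx), y = c(runif(n_o, 0, h), qy),
                 is_qcc = rep(c(FALSE, TRUE), c(n_o, n_q)),
                 parent = c(rep(NA_integer_, n_o), assign_p))
    }
  })
}

#' Simulate class-conditional marker intensities
#'
#' Log-normal draws per marker with QCC-class location shifted down for AKT
#' and H3K9me2 and up for HES1, then multiplied by the section's per-marker
#' batch scale.  Positivity is guaranteed by construction.
#'
#' @param is_qcc logical ground-truth class vector.
#' @param config a [synth_config()].
#' @param seed optional seed.
#' @return data.frame of intensity columns named as in the cell-table schema
#'   (e.g. `AKT_cytoplasm_mean`).
#' @export
simulate_intensities <- function(is_qcc, config, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(seed, {
    n <- length(is_qcc)
    out <- data.frame(row.names = seq_len(n))
    for (mk in config$panel$markers) {
      pr <- config$intensity[[mk]]
      v <- numeric(n)
      nq <- sum(is_qcc)
      v[!is_qcc] <- rlnorm(n - nq, pr$other[["meanlog"]], pr$other[["sdlog"]])
      v[is_qcc] <- rlnorm(nq, pr$qcc[["meanlog"]], pr$qcc[["sdlog"]])
      out[[intensity_column(config$panel, mk)]] <-
        v * config$batch_scale[[mk]]
    }
    out
  })
}

#' Simulate one complete synthetic section
#'
#' Generates tumor-cell positions and classes, adds uniformly placed stroma
#' cells, draws intensities, carves cells into the FOV grid (local
#' coordinates relative to each tile origin), and records per-FOV realized
#' tumor fractions plus the configured artifact fractions.  The output passes
#' [section_table()] validation and round-trips through the CSV I/O.
#'
#' @param config a [synth_config()].
#' @param seed integer seed controlling the whole section.
#' @param section_id,patient_id,sample_type,batch_id metadata.
#' @param parents passed to [simulate_positions()].
#' @return list with `section` (a [section_table()]) and `truth`
#'   (data.frame `cell_id`, `is_qcc`, `parent`; stroma rows are never QCC).
#' @export
simulate_section <- function(config, seed = 1, section_id = "S01",
                             patient_id = section_id,
                             sample_type = "control", batch_id = "B1",
                             parents = NULL) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(seed, {
    pos <- simulate_positions(config, seed = NULL, parents = parents)
    sf <- config$stroma_fraction
    n_s <- round(config$n_cells * sf / (1 - sf))
    w <- config$field[["width"]]; h <- config$field[["height"]]
    x <- c(pos$x, runif(n_s, 0, w))
    y <- c(pos$y, runif(n_s, 0, h))
    is_qcc <- c(pos$is_qcc, rep(FALSE, n_s))
    parent <- c(pos$parent, rep(NA_integer_, n_s))
    tissue <- rep(c("tumor", "stroma"), c(nrow(pos), n_s))
    n <- length(x)
    inten <- simulate_intensities(is_qcc, config, seed = NULL)
    col <- pmin(floor(x / config$tile_width), config$fov_cols - 1)
    row <- pmin(floor(y / config$tile_height), config$fov_rows - 1)
    fov_id <- sprintf("F%02d%02d", row, col)
    cells <- data.frame(cell_id = sprintf("C%05d", seq_len(n)),
                        fov_id = fov_id,
                        x_local = x - col * config$tile_width,
                        y_local = y - row * config$tile_height,
                        tissue_class = tissue, stringsAsFactors = FALSE)
    cells <- cbind(cells, inten)
    grid <- expand.grid(grid_row = seq_len(config$fov_rows) - 1L,
                        grid_col = seq_len(config$fov_cols) - 1L)
    gid <- sprintf("F%02d%02d", grid$grid_row, grid$grid_col)
    n_in <- vapply(gid, function(f) sum(fov_id == f), 0L)
    n_tum <- vapply(gid, function(f) sum(fov_id == f & tissue == "tumor"), 0L)
    fovs <- data.frame(fov_id = gid, grid_row = grid$grid_row,
                       grid_col = grid$grid_col,
                       tile_width = config$tile_width,
                       tile_height = config$tile_height,
                       tumor_fraction = ifelse(n_in > 0, n_tum / n_in, 0),
                       artifact_fraction = rep_len(config$artifact_fraction,
                                                   length(gid)),
                       stringsAsFactors = FALSE, row.names = NULL)
    section <- section_table(cells, fovs, section_id = section_id,
                             patient_id = patient_id,
                             sample_type = sample_type, batch_id = batch_id,
                             panel = config$panel)
    truth <- data.frame(cell_id = cells$cell_id, is_qcc = is_qcc,
                        parent = parent, stringsAsFactors = FALSE)
    list(section = section, truth = truth)
  })
}

#' Simulate a cohort of sections
#'
#' One section per entry of `seeds`, with configs, sample types and IDs
#' recycled.  If `outdir` is given, each section is written as the canonical
#' cells/FOV CSV pair plus a ground-truth CSV, together with a
#' `manifest.json` recording every seed for exact reproduction; reruns are
#' byte-identical.
#'
#' @param configs a [synth_config()] or list of them (recycled).
#' @param seeds integer vector, one per section.
#' @param sample_types recycled over sections.
#' @param section_ids default `"S01"`, `"S02"`, ...
#' @param outdir optional output directory.
#' @return list of [simulate_section()] results, invisibly when writing.
#' @export
simulate_cohort <- function(configs, seeds,
                            sample_types = "control",
                            section_ids = sprintf("S%02d", seq_along(seeds)),
                            outdir = NULL) {
  if (inherits(configs, "synth_config")) configs <- list(configs)
  n <- length(seeds)
  sims <- lapply(seq_len(n), function(i) {
    simulate_section(configs[[(i - 1L) %% length(configs) + 1L]],
                     seed = seeds[i], section_id = section_ids[i],
                     sample_type = rep_len(sample_types, n)[i])
  })
  names(sims) <- section_ids
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(n)) {
      base <- file.path(outdir, section_ids[i])
      write_cell_table(sims[[i]]$section, paste0(base, "_cells.csv"),
                       paste0(base, "_fovs.csv"))
      write.csv(sims[[i]]$truth, paste0(base, "_truth.csv"),
                row.names = FALSE)
    }
    manifest <- list(sections = data.frame(section_id = section_ids,
                                           seed = seeds,
                                           sample_type = rep_len(sample_types,
                                                                 n)))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(sims)
}
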