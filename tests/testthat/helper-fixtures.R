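# Shared fixtures and independent oracles.  Everything is built in code;
# no data files ship with the tests.

# 4-cell, single-FOV section: AKT = H3K9me2 = 1..4, HES1 = 4..1, so cell C1
# is the unique triple-qualifier at t = 0.25 and {C1, C2} qualify at t = 0.5.
tiny_section <- function() {
  cells <- data.frame(
    cell_id = paste0("C", 1:4), fov_id = "F0000",
    x_local = c(10, 20, 30, 40), y_local = c(10, 10, 10, 10),
    tissue_class = "tumor",
    AKT_cytoplasm_mean = c(1, 2, 3, 4),
    H3K9me2_nuclear_mean = c(1, 2, 3, 4),
    HES1_cytoplasm_mean = c(4, 3, 2, 1),
    stringsAsFactors = FALSE)
  fovs <- data.frame(fov_id = "F0000", grid_row = 0L, grid_col = 0L,
                     tile_width = 1392, tile_height = 1040,
                     tumor_fraction = 1, artifact_fraction = 0,
                     stringsAsFactors = FALSE)
  section_table(cells, fovs, section_id = "T1")
}

# 2x2 square map: nearest neighbours pair up within columns (distance 1 vs 10)
square_map <- function(qcc = c(TRUE, TRUE, FALSE, FALSE)) {
  tumor_map(x = c(0, 0, 10, 10), y = c(0, 1, 0, 1), qcc = qcc,
            cell_id = paste0("C", 1:4))
}

# random map in a box, labels independent of geometry
random_map <- function(n, q_frac = 0.05, extent = 2000) {
  tumor_map(x = runif(n, 0, extent), y = runif(n, 0, extent),
            qcc = seq_len(n) %in% sample.int(n, max(1, round(q_frac * n))),
            cell_id = sprintf("C%05d", seq_len(n)))
}

# Brute-force cluster index via the full pairwise distance matrix, sharing
# nothing with the package's k-NN path except the tie-break definition.
oracle_qcc_ci <- function(map, k, window) {
  tum <- which(map$tissue_class == "tumor")
  x <- map$x[tum]; y <- map$y[tum]
  is_qcc <- map$qcc[tum] %in% TRUE
  ids <- map$cell_id[tum]
  id_rank <- integer(length(tum)); id_rank[order(ids)] <- seq_along(tum)
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  fr <- vapply(which(is_qcc), function(i) {
    cand <- which(abs(x - x[i]) <= window & abs(y - y[i]) <= window)
    cand <- setdiff(cand, i)
    if (length(cand) < k) return(NA_real_)
    take <- cand[order(d2[i, cand], id_rank[cand])][seq_len(k)]
    mean(is_qcc[take])
  }, 0)
  list(fractions = fr,
       qcc_ci = if (all(is.na(fr))) NA_real_ else mean(fr, na.rm = TRUE))
}

# config with zero class separation: markers carry no information about the
# ground-truth class, so calls behave as three independent continuous markers
null_intensity_config <- function(...) {
  flat <- list(other = c(meanlog = 2, sdlog = 0.5),
               qcc = c(meanlog = 2, sdlog = 0.5))
  synth_config(intensity = list(AKT = flat, H3K9me2 = flat, HES1 = flat), ...)
}
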