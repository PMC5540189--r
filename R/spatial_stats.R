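#' Configuration for the QCC cluster index
#'
#' @param k number of nearest tumor-cell neighbors per focal QCC
#'   (default 100).
#' @param window half-width, in map coordinate units, of the box within which
#'   neighbors are sought (default 500); a focal cell with fewer than `k`
#'   tumor cells inside the +/- window box on both axes is discarded.
#' @param B number of permutation replicates (default 1000).
#' @param seed integer seed for the permutation draws, or `NULL` to use the
#'   current RNG state.
#' @return object of class `cluster_index_config`.
#' @export
cluster_index_config <- function(k = 100, window = 500, B = 1000,
                                 seed = NULL) {
  stopifnot(k >= 1, window > 0, B >= 1)
  structure(list(k = as.integer(k), window = window, B = as.integer(B),
                 seed = seed),
            class = "cluster_index_config")
}

# k-NN structure over the tumor cells of a map: indices into the tumor
# subset, NA rows for discarded cells.  Labels play no role here, so one
# precomputation serves the observed statistic and every permutation.
tumor_knn <- function(map, k, window) {
  tum <- which(map$tissue_class == "tumor")
  n <- length(tum)
  ids <- map$cell_id[tum]
  id_rank <- integer(n)
  id_rank[order(ids)] <- seq_len(n)
  nn <- if (n) knn_window_cpp(map$x[tum], map$y[tum], id_rank,
                              as.integer(k), window)
        else matrix(NA_integer_, 0, k)
  list(tumor_idx = tum, nn = nn)
}

# per-focal neighbor fractions given a k-NN structure and logical labels over
# the tumor subset; NA marks discarded focal cells
focal_fractions <- function(nn, is_qcc, focal) {
  fr <- rep(NA_real_, length(focal))
  if (!length(focal)) return(fr)
  ok <- !is.na(nn[focal, 1L])
  if (any(ok)) {
    sub <- nn[focal[ok], , drop = FALSE]
    fr[ok] <- rowMeans(array(is_qcc[sub], dim = dim(sub)))
  }
  fr
}

#' Neighbor fraction for a single focal QCC
#'
#' The cluster index of one focal QCC: the proportion of QCCs among its `k`
#' nearest tumor cells (excluding itself), where candidates are restricted to
#' the +/- `window` box on each axis.  A focal cell with fewer than `k`
#' in-window tumor neighbors is discarded.
#'
#' @param map a `tumor_map` with logical `qcc` labels.
#' @param focal_cell_id `cell_id` of a tumor cell labeled QCC.
#' @param config a [cluster_index_config()].
#' @return list with `fraction` (in \[0, 1\], or `NA` if discarded) and
#'   `discarded` (logical).
#' @export
neighbor_fraction <- function(map, focal_cell_id,
                              config = cluster_index_config()) {
  stopifnot(inherits(map, "tumor_map"))
  knn <- tumor_knn(map, config$k, config$window)
  is_qcc <- map$qcc[knn$tumor_idx] %in% TRUE
  focal <- which(map$cell_id[knn$tumor_idx] == focal_cell_id)
  if (length(focal) != 1L || !is_qcc[focal])
    stop("focal cell must be a tumor cell labeled QCC", call. = FALSE)
  fr <- focal_fractions(knn$nn, is_qcc, focal)
  list(fraction = fr, discarded = is.na(fr))
}

#' Observed QCC cluster index of a map
#'
#' Averages the per-focal neighbor fractions over all focal QCCs that survive
#' the discard rule.  A map with QCCs but no surviving focal cell yields an
#' undefined index (`NA` with `undefined = TRUE`); a map with no QCC at all
#' is an error (a distinct condition).
#'
#' @param map a `tumor_map` with logical `qcc` labels.
#' @param config a [cluster_index_config()].
#' @return list with `qcc_ci`, `fractions` (per focal QCC, `NA` = discarded),
#'   `n_focal_retained`, `n_focal_discarded`, `undefined`.
#' @export
qcc_ci <- function(map, config = cluster_index_config()) {
  stopifnot(inherits(map, "tumor_map"))
  knn <- tumor_knn(map, config$k, config$window)
  is_qcc <- map$qcc[knn$tumor_idx] %in% TRUE
  focal <- which(is_qcc)
  if (!length(focal)) stop("no QCC in map", call. = FALSE)
  fr <- focal_fractions(knn$nn, is_qcc, focal)
  ok <- !is.na(fr)
  list(qcc_ci = if (any(ok)) mean(fr[ok]) else NA_real_,
       fractions = fr,
       n_focal_retained = sum(ok),
       n_focal_discarded = sum(!ok),
       undefined = !any(ok))
}

# run one RNG-consuming expression under an optional seed without disturbing
# the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Permutation null distribution of the cluster index
#'
#' Draws `B` random sets of `n_qcc` tumor cells (uniformly, without
#' replacement, from the same section geometry) as pseudo-QCCs and computes
#' the cluster index of each under the identical discard rule.  Replicates in
#' which every pseudo-focal cell is discarded are recorded as `NA` and later
#' excluded from the p-value denominator.
#'
#' @param map a `tumor_map`.
#' @param n_qcc number of pseudo-QCCs per replicate (the observed QCC count).
#' @param config a [cluster_index_config()]; `config$seed` makes the score
#'   list reproducible.
#' @return numeric vector of `B` scores (`NA` = undefined replicate) with
#'   attribute `n_undefined`.
#' @export
permutation_null <- function(map, n_qcc, config = cluster_index_config()) {
  stopifnot(inherits(map, "tumor_map"), n_qcc >= 1)
  knn <- tumor_knn(map, config$k, config$window)
  n <- length(knn$tumor_idx)
  if (n_qcc > n)
    stop("n_qcc exceeds the number of tumor cells", call. = FALSE)
  scores <- with_seed(config$seed, {
    vapply(seq_len(config$B), function(b) {
      idx <- sample.int(n, n_qcc)
      isq <- logical(n)
      isq[idx] <- TRUE
      fr <- focal_fractions(knn$nn, isq, idx)
      if (all(is.na(fr))) NA_real_ else mean(fr, na.rm = TRUE)
    }, 0)
  })
  structure(scores, n_undefined = sum(is.na(scores)))
}

#' One-sided empirical p-value for clustering
#'
#' Add-one empirical p-value, one-sided toward clustering:
#' `p = (1 + #\{score >= observed\}) / (#defined scores + 1)`, so `p > 0`
#' always and ties count against the observation.
#'
#' @param observed observed cluster index.
#' @param scores permutation scores (`NA` entries are undefined replicates).
#' @return list with `p_value` (`NA` with `undefined = TRUE` if no score is
#'   defined), `n_defined`, `n_undefined`.
#' @export
empirical_p <- function(observed, scores) {
  defined <- scores[!is.na(scores)]
  if (!length(defined))
    return(list(p_value = NA_real_, n_defined = 0L,
                n_undefined = sum(is.na(scores)), undefined = TRUE))
  list(p_value = (1 + sum(defined >= observed)) / (length(defined) + 1),
       n_defined = length(defined), n_undefined = sum(is.na(scores)),
       undefined = FALSE)
}

#' Exhaustive permutation null (small-map oracle)
#'
#' Enumerates all `choose(N, n_qcc)` labelings of `n_qcc` pseudo-QCCs among
#' the `N` tumor cells and scores each one — the exact distribution the
#' Monte-Carlo null samples from.  Only feasible for small maps.
#'
#' @param map a `tumor_map`.
#' @param n_qcc pseudo-QCC count per labeling.
#' @param config a [cluster_index_config()].
#' @param max_labelings refuse to enumerate beyond this many combinations.
#' @return list with `scores` (one per labeling, `NA` = undefined) and
#'   `n_labelings`.
#' @export
exact_null <- function(map, n_qcc, config = cluster_index_config(),
                       max_labelings = 1e5) {
  stopifnot(inherits(map, "tumor_map"), n_qcc >= 1)
  knn <- tumor_knn(map, config$k, config$window)
  n <- length(knn$tumor_idx)
  if (n_qcc > n)
    stop("n_qcc exceeds the number of tumor cells", call. = FALSE)
  if (choose(n, n_qcc) > max_labelings)
    stop("choose(N, n_qcc) exceeds ", max_labelings,
         "; use the Monte-Carlo null (permutation_null)", call. = FALSE)
  combs <- combn(n, n_qcc)
  scores <- apply(combs, 2L, function(idx) {
    isq <- logical(n)
    isq[idx] <- TRUE
    fr <- focal_fractions(knn$nn, isq, idx)
    if (all(is.na(fr))) NA_real_ else mean(fr, na.rm = TRUE)
  })
  list(scores = scores, n_labelings = ncol(combs))
}

#' Full cluster-index analysis of one map
#'
#' Computes the observed QCC-CI, its permutation null (with `n_qcc` equal to
#' the observed QCC count) and the one-sided empirical p-value.
#'
#' @param map a `tumor_map` with logical `qcc` labels.
#' @param config a [cluster_index_config()].
#' @return object of class `cluster_index_result`: observed fields from
#'   [qcc_ci()] plus `n_qcc`, `permutation_scores`, `n_perm_undefined`,
#'   `p_value`, `k`, `window`, `B`, `seed`.
#' @export
cluster_index <- function(map, config = cluster_index_config()) {
  obs <- qcc_ci(map, config)
  n_qcc <- obs$n_focal_retained + obs$n_focal_discarded
  scores <- permutation_null(map, n_qcc, config)
  ep <- if (obs$undefined)
    list(p_value = NA_real_, n_defined = sum(!is.na(scores)),
         n_undefined = attr(scores, "n_undefined"), undefined = TRUE)
  else empirical_p(obs$qcc_ci, scores)
  structure(c(obs,
              list(n_qcc = n_qcc,
                   permutation_scores = as.numeric(scores),
                   n_perm_undefined = attr(scores, "n_undefined"),
                   p_value = ep$p_value,
                   k = config$k, window = config$window, B = config$B,
                   seed = config$seed)),
            class = "cluster_index_result")
}

#' @export
print.cluster_index_result <- function(x, ...) {
  cat(sprintf(paste0("<cluster_index_result> QCC-CI = %s over %d focal QCCs",
                     " (%d discarded)\n  k = %d, window = %g, B = %d",
                     " (%d undefined), one-sided p = %s\n"),
              format(x$qcc_ci, digits = 4), x$n_focal_retained,
              x$n_focal_discarded, x$k, x$window, x$B, x$n_perm_undefined,
              format(x$p_value, digits = 4)))
  invisible(x)
}
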