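#' QCC percentage of a section
#'
#' QCC-P: the proportion of QCCs among the tumor (cancer) cells of a section.
#'
#' @param labels a [call_qcc()] result.
#' @return fraction in \[0, 1\].
#' @export
qcc_percentage <- function(labels) {
  stopifnot(inherits(labels, "qcc_labels"))
  tum <- labels$tissue_class == "tumor"
  if (!any(tum)) stop("zero tumor cells", call. = FALSE)
  mean(labels$qcc_label[tum])
}

#' QCC density: QCC-P per field of view
#'
#' One fraction per retained FOV of the section; FOVs without tumor cells are
#' reported as `NA` (undefined), never as zero.  The cell-count-weighted mean
#' of the defined fractions equals the section-level QCC-P.
#'
#' @param labels a [call_qcc()] result.
#' @param section the [section_table()] the labels were computed on.
#' @return data.frame `fov_id`, `n_tumor`, `n_qcc`, `qcc_d`.
#' @export
qcc_density <- function(labels, section) {
  stopifnot(inherits(labels, "qcc_labels"), inherits(section, "section_table"))
  fov_ids <- section$fovs$fov_id
  tum <- labels$tissue_class == "tumor"
  n_tumor <- vapply(fov_ids, function(f) sum(tum & labels$fov_id == f), 0L)
  n_qcc <- vapply(fov_ids, function(f)
    sum(labels$qcc_label & tum & labels$fov_id == f), 0L)
  data.frame(fov_id = fov_ids, n_tumor = n_tumor, n_qcc = n_qcc,
             qcc_d = ifelse(n_tumor > 0, n_qcc / n_tumor, NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Unpaired two-sample t-test on per-section summaries
#'
#' Classical unpaired t-test with pooled variance by default (Welch by flag),
#' two-sided p.  A zero pooled variance is flagged as degenerate: identical
#' groups give t = 0, p = 1; separated constant groups give infinite t, p = 0.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @param var_equal pooled variance if `TRUE` (default), Welch otherwise.
#' @return list with `mean_diff` (a - b), `t`, `df`, `p_value`, `degenerate`.
#' @export
group_compare <- function(values_a, values_b, var_equal = TRUE) {
  n1 <- length(values_a); n2 <- length(values_b)
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 values", call. = FALSE)
  d <- mean(values_a) - mean(values_b)
  v1 <- var(values_a); v2 <- var(values_b)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  if (se == 0) {
    return(list(mean_diff = d, t = if (d == 0) 0 else sign(d) * Inf,
                df = df, p_value = if (d == 0) 1 else 0, degenerate = TRUE))
  }
  tt <- d / se
  list(mean_diff = d, t = tt, df = df, p_value = 2 * pt(-abs(tt), df),
       degenerate = FALSE)
}

#' Pearson correlation with validation
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return r in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must have equal length >= 3", call. = FALSE)
  if (var(x) == 0 || var(y) == 0)
    stop("zero variance", call. = FALSE)
  cor(x, y, method = "pearson")
}

#' Post-hoc power for a two-group mean difference
#'
#' Normal-approximation power with noncentrality `delta / se`: one-sided
#' power is `pnorm(delta/se - qnorm(1 - alpha))`; two-sided power adds both
#' rejection tails at `alpha / 2`.  `dispersion` selects whether the second
#' argument is already the standard error of the difference (`"se"`, default)
#' or a standard deviation to be scaled by `sqrt(1/n1 + 1/n2)` (`"sd"`) —
#' the two readings of a printed "difference ± spread".
#'
#' @param delta mean difference between groups.
#' @param se standard error of the difference (or SD, see `dispersion`).
#' @param n1,n2 group sizes (required when `dispersion = "sd"`; recorded
#'   otherwise).
#' @param alpha type-I error rate, in (0, 1).
#' @param sided `"one"` or `"two"`.
#' @param dispersion `"se"` or `"sd"`.
#' @return power in (0, 1).
#' @export
#' @examples
#' posthoc_power(delta = 0.567, se = 0.25, n1 = 10, n2 = 16)  # 0.73
posthoc_power <- function(delta, se, n1 = NULL, n2 = NULL, alpha = 0.05,
                          sided = c("one", "two"),
                          dispersion = c("se", "sd")) {
  sided <- match.arg(sided)
  dispersion <- match.arg(dispersion)
  stopifnot(se > 0, alpha > 0, alpha < 1)
  if (dispersion == "sd") {
    if (is.null(n1) || is.null(n2))
      stop("dispersion = 'sd' requires n1 and n2", call. = FALSE)
    se <- se * sqrt(1 / n1 + 1 / n2)
  }
  lambda <- delta / se
  if (sided == "one") {
    pnorm(lambda - qnorm(1 - alpha))
  } else {
    z <- qnorm(1 - alpha / 2)
    pnorm(lambda - z) + pnorm(-lambda - z)
  }
}

#' Summarize one section for the cohort table
#'
#' @param section a [section_table()].
#' @param labels a [call_qcc()] result for that section.
#' @param ci optional [cluster_index()] result.
#' @return one-row data.frame: `section_id`, `sample_type`, `n_tumor_cells`,
#'   `qcc_p`, `qcc_ci`, `ci_p_value`.
#' @export
section_summary <- function(section, labels, ci = NULL) {
  data.frame(section_id = section$section_id,
             sample_type = section$sample_type,
             n_tumor_cells = sum(labels$tissue_class == "tumor"),
             qcc_p = qcc_percentage(labels),
             qcc_ci = if (is.null(ci)) NA_real_ else ci$qcc_ci,
             ci_p_value = if (is.null(ci)) NA_real_ else ci$p_value,
             stringsAsFactors = FALSE)
}
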