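#' Pearson correlation with a two-sided p-value
#'
#' Product-moment correlation plus the two-sided p-value from the t
#' transform. p-values that underflow double precision are reported at the
#' 1e-300 floor (printed elsewhere as "P = 0") and are never thresholded by
#' this package.
#'
#' @param x,y numeric vectors of equal length >= 3, both non-constant.
#' @return A list with `pcc` and `p_value`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3L) abort("Pearson correlation needs at least 3 points.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation is undefined for a constant vector.")
  }
  ct <- suppressWarnings(cor.test(x, y, method = "pearson"))
  list(pcc = unname(ct$estimate), p_value = max(ct$p.value, 1e-300))
}

#' Ordinary least-squares line
#'
#' @param x,y numeric vectors of equal length >= 2; `x` non-constant.
#' @return A list with `slope` and `intercept`.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 2L) abort("A line needs at least 2 points.")
  if (sd(x) == 0) abort("OLS is undefined for constant x.")
  co <- coef(lm(y ~ x))
  list(slope = unname(co[2]), intercept = unname(co[1]))
}

.concordance_row <- function(x, y, pair_label, scale = "normalized") {
  if (scale == "normalized") {
    x <- suppressWarnings(minmax_normalize(x))
    y <- suppressWarnings(minmax_normalize(y))
  }
  pr <- pearson(x, y)
  fit <- linear_fit(x, y)
  tibble::tibble(pair_label = pair_label, pcc = pr$pcc, slope = fit$slope,
                 intercept = fit$intercept, n = length(x),
                 p_value = pr$p_value)
}

#' Concordance between two columns of a flexibility profile
#'
#' Pearson correlation and OLS line between two per-residue score columns
#' (e.g. AF2-score vs RMSF). With `scale = "normalized"` (the default,
#' matching figures drawn in arbitrary units) both columns are min-max
#' normalized before the regression; the correlation itself is affine
#' invariant, so only slope/intercept depend on this choice.
#'
#' @param profile a [flexibility_profile()] tibble.
#' @param pair character vector of two column names, `c(x, y)`; the second
#'   is the regression response.
#' @param scale `"normalized"` or `"raw"`.
#' @return A one-row tibble: `pair_label`, `pcc`, `slope`, `intercept`,
#'   `n`, `p_value`.
#' @export
profile_concordance <- function(profile, pair = c("af2_score", "rmsf"),
                                scale = c("normalized", "raw")) {
  scale <- match.arg(scale)
  if (!all(pair %in% names(profile))) {
    abort(sprintf("Profile lacks column(s): %s.",
                  paste(setdiff(pair, names(profile)), collapse = ", ")))
  }
  .concordance_row(profile[[pair[1]]], profile[[pair[2]]],
                   paste(pair[1], "vs", pair[2]), scale)
}

#' Concordance report in both sign conventions
#'
#' The AF2-score is an affine, order-reversing transform of pLDDT, so the
#' correlation of pLDDT with a flexibility measure is exactly the negative
#' of the AF2-score correlation. This reports both rows: the AF2-score
#' orientation computed directly, and the pLDDT orientation with `pcc` the
#' exact negation (its slope/intercept are fitted on the pLDDT column
#' itself).
#'
#' @param profile a [flexibility_profile()] with `plddt`, `af2_score` and
#'   the flexibility column.
#' @param flex_col flexibility column name (default `"rmsf"`).
#' @param scale `"normalized"` or `"raw"` (see [profile_concordance()]).
#' @return A two-row tibble with an `orientation` column
#'   (`"af2_score"`, `"plddt"`).
#' @export
concordance_report <- function(profile, flex_col = "rmsf",
                               scale = c("normalized", "raw")) {
  scale <- match.arg(scale)
  r_af2 <- profile_concordance(profile, c("af2_score", flex_col), scale)
  fit_p <- linear_fit(
    if (scale == "normalized") suppressWarnings(minmax_normalize(profile$plddt))
    else profile$plddt,
    if (scale == "normalized") suppressWarnings(minmax_normalize(profile[[flex_col]]))
    else profile[[flex_col]])
  r_pl <- tibble::tibble(pair_label = paste("plddt vs", flex_col),
                         pcc = -r_af2$pcc, slope = fit_p$slope,
                         intercept = fit_p$intercept, n = r_af2$n,
                         p_value = r_af2$p_value)
  dplyr::bind_rows(
    dplyr::mutate(r_af2, orientation = "af2_score"),
    dplyr::mutate(r_pl, orientation = "plddt")
  )
}

#' Matrix-level concordance between a PAE map and a DV matrix
#'
#' The PAE matrix is first symmetrized (default: mean of each transpose
#' pair, since DV is symmetric while PAE is not; `"upper_triangle_raw"`
#' uses the raw upper triangle instead), then the Pearson correlation is
#' computed over the strict upper-triangle elements — the forced-zero
#' diagonal is excluded and no element is double-counted.
#'
#' @param pae a [new_pae_matrix()] object (or plain matrix).
#' @param dv a [dv_matrix()] object (or plain matrix).
#' @param symmetrization `"mean_of_transpose_pair"` (default) or
#'   `"upper_triangle_raw"`.
#' @return A one-row tibble: `pcc`, `p_value`, `n_elements`,
#'   `symmetrization`.
#' @export
pae_dv_concordance <- function(pae, dv,
                               symmetrization = c("mean_of_transpose_pair",
                                                  "upper_triangle_raw")) {
  symmetrization <- match.arg(symmetrization)
  P <- if (inherits(pae, "pae_matrix")) pae$values else as.matrix(pae)
  D <- if (inherits(dv, "dv_matrix")) dv$values else as.matrix(dv)
  if (!all(dim(P) == dim(D))) {
    abort(sprintf("Dimension mismatch: PAE is %d x %d, DV is %d x %d.",
                  nrow(P), ncol(P), nrow(D), ncol(D)))
  }
  if (nrow(P) < 3L) abort("Matrix concordance needs at least 3 residues.")
  if (symmetrization == "mean_of_transpose_pair") P <- (P + t(P)) / 2
  ut <- upper.tri(P)
  pr <- pearson(P[ut], D[ut])
  tibble::tibble(pcc = pr$pcc, p_value = pr$p_value, n_elements = sum(ut),
                 symmetrization = symmetrization)
}

#' Near-diagonal disorder signature of a PAE or DV matrix
#'
#' The mean of all entries at sequence separation 1 to `window` (both
#' triangles, so asymmetric PAE input is handled). Large errors or distance
#' variations between close sequence neighbours are the matrix signature of
#' intrinsic disorder; globular proteins keep this band small.
#'
#' @param matrix a [new_pae_matrix()], [dv_matrix()] or plain square matrix.
#' @param window maximum sequence separation included (default 8; use
#'   `window >= 2` for freely-jointed-chain models whose bonded-neighbour
#'   distance is fixed).
#' @return Mean band value (Angstrom). If the matrix has `window` or fewer
#'   residues, all off-diagonal entries are used, with a warning.
#' @export
near_diagonal_signature <- function(matrix, window = 8L) {
  if (window < 1L) abort("`window` must be >= 1.")
  M <- if (inherits(matrix, "pae_matrix")) matrix$values
       else if (inherits(matrix, "dv_matrix")) matrix$values
       else as.matrix(matrix)
  n <- nrow(M)
  sep <- abs(row(M) - col(M))
  if (n <= window) {
    warn("Matrix no larger than the window: using all off-diagonal entries.")
    return(mean(M[sep >= 1]))
  }
  mean(M[sep >= 1 & sep <= window])
}

#' Cross-protein regression of per-protein mean scores
#'
#' Given one row per protein of mean per-residue scores (e.g. mean pLDDT
#' and mean RMSF over each protein), fits the cross-protein OLS line and
#' Pearson correlation. Row order is immaterial.
#'
#' @param means a data frame with one row per protein (>= 3 rows).
#' @param predictor,response column names; RMSF is the conventional
#'   response.
#' @return A one-row tibble: `pair_label`, `pcc`, `slope`, `intercept`,
#'   `n`, `p_value`.
#' @export
aggregate_regression <- function(means, predictor = "plddt",
                                 response = "rmsf") {
  if (!is.data.frame(means) || nrow(means) < 3L) {
    abort("Aggregate regression needs at least 3 proteins.")
  }
  if (!all(c(predictor, response) %in% names(means))) {
    abort("`means` lacks the requested columns.")
  }
  .concordance_row(means[[predictor]], means[[response]],
                   paste(predictor, "vs", response, "(per-protein means)"),
                   scale = "raw")
}
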