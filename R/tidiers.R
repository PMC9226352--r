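#' Tidy a trajectory PCA result
#'
#' @param x a [pca_ensemble()] result.
#' @param n_modes number of leading modes to report (default all).
#' @param ... unused.
#' @return A tibble with one row per mode: `mode`, `eigenvalue`,
#'   `variance_fraction`, `cumulative_fraction`.
#' @export
tidy.flex_pca <- function(x, n_modes = length(x$eigenvalues), ...) {
  n_modes <- min(n_modes, length(x$eigenvalues))
  tibble::tibble(
    mode = seq_len(n_modes),
    eigenvalue = x$eigenvalues[seq_len(n_modes)],
    variance_fraction = x$variance_fraction[seq_len(n_modes)],
    cumulative_fraction = cumsum(x$variance_fraction)[seq_len(n_modes)]
  )
}

#' @rdname tidy.flex_pca
#' @return `glance()` returns a one-row tibble: `n_modes`, `n_frames`,
#'   `total_variance`, `pc1_fraction`.
#' @export
glance.flex_pca <- function(x, ...) {
  tibble::tibble(
    n_modes = length(x$eigenvalues),
    n_frames = nrow(x$projections),
    total_variance = sum(x$eigenvalues),
    pc1_fraction = x$variance_fraction[1]
  )
}

#' Tidy a DV or PAE matrix into long form
#'
#' @param x a [dv_matrix()] or [new_pae_matrix()] object.
#' @param ... unused.
#' @return A tibble with columns `residue_i`, `residue_j`, `value`.
#' @export
tidy.dv_matrix <- function(x, ...) {
  M <- x$values
  tibble::tibble(
    residue_i = rep(seq_len(nrow(M)), times = ncol(M)),
    residue_j = rep(seq_len(ncol(M)), each = nrow(M)),
    value = as.numeric(M)
  )
}

#' @rdname tidy.dv_matrix
#' @export
tidy.pae_matrix <- function(x, ...) {
  M <- x$values
  tibble::tibble(
    residue_i = rep(seq_len(nrow(M)), times = ncol(M)),
    residue_j = rep(seq_len(ncol(M)), each = nrow(M)),
    value = as.numeric(M)
  )
}

#' Tidy a structure model into its residue table
#'
#' @param x a [read_af2_model()] result.
#' @param ... unused.
#' @return The per-residue tibble with a `score_kind` column appended.
#' @export
tidy.structure_model <- function(x, ...) {
  dplyr::mutate(x$residues, score_kind = x$score_kind)
}
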