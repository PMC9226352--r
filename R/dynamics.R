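#' Interquartile range with linear-interpolation quantiles
#'
#' Q3 minus Q1 using linearly interpolated order statistics with plotting
#' positions p(k) = (k-1)/(n-1) (`stats::quantile` type 7, the R default).
#' The IQR is the robust spread statistic behind the distance-variation
#' matrix: unlike the range it is insensitive to occasional extreme
#' C-alpha--C-alpha distances.
#'
#' @param x numeric vector with at least one value.
#' @return A non-negative scalar.
#' @export
iqr <- function(x) {
  if (length(x) < 1L) abort("`iqr()` needs at least one sample.")
  q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  q[2] - q[1]
}

#' Distance-variation (DV) matrix of an ensemble
#'
#' `DV[x, y]` is the interquartile range, over frames, of the
#' C-alpha--C-alpha distance between residues x and y — a symmetric,
#' rigid-motion-invariant per-pair flexibility statistic (the 1D analogue
#' of a PAE map, in Angstrom). The diagonal is zero by construction.
#'
#' @param ens a [new_ensemble()] object with at least 2 frames.
#' @param stride optional frame stride applied before the calculation.
#' @return An object of class `dv_matrix`: list with `values` (R x R
#'   symmetric matrix, Angstrom) and `quantile_method`.
#' @export
dv_matrix <- function(ens, stride = 1L) {
  if (stride > 1L) ens <- subsample(ens, stride)
  if (n_frames(ens) < 2L) abort("DV needs at least 2 frames.")
  ca <- select_calpha(ens)
  nf <- n_frames(ca); nr <- dim(ca$coords)[2]
  pd <- matrix(0, nf, nr * (nr - 1L) / 2L)
  for (f in seq_len(nf)) pd[f, ] <- stats::dist(ca$coords[f, , ])
  iqrs <- apply(pd, 2, iqr)
  values <- matrix(0, nr, nr)
  values[lower.tri(values)] <- iqrs
  values <- values + t(values)
  structure(list(values = values, quantile_method = "linear_type7"),
            class = "dv_matrix")
}

#' @export
print.dv_matrix <- function(x, ...) {
  cat(sprintf("<dv_matrix> %d x %d, max %.2f A (quantiles: %s)\n",
              nrow(x$values), ncol(x$values), max(x$values),
              x$quantile_method))
  invisible(x)
}

#' Dynamic cross-correlation matrix (DCCM)
#'
#' Frames are first superposed with the global fit-to-mean protocol
#' (C-alpha fit set), then for each residue pair the normalized
#' scalar-product correlation of the C-alpha positional deviations is
#' computed: `C[i, j] = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)`.
#' Residues with zero positional variance get correlation 0 (with a
#' warning) rather than NaN.
#'
#' @param ens a [new_ensemble()] object with at least 2 frames.
#' @return An R x R matrix of class `dccm_matrix`, entries in \[-1, 1\],
#'   unit diagonal for residues with positive variance.
#' @export
dccm <- function(ens) {
  if (n_frames(ens) < 2L) abort("DCCM needs at least 2 frames.")
  ca <- select_calpha(ens)
  fit <- .fit_to_mean(ca$coords, seq_len(dim(ca$coords)[2]))
  nf <- dim(fit$coords)[1]; nr <- dim(fit$coords)[2]
  S <- matrix(0, nr, nr)
  for (k in 1:3) {
    dk <- fit$coords[, , k] - matrix(fit$mean[, k], nf, nr, byrow = TRUE)
    S <- S + crossprod(dk)
  }
  v <- diag(S)
  # a residue is flagged zero-variance when its mean squared deviation is
  # below (1e-6 A)^2 — numerically immobile, not merely the least mobile
  zero_var <- v / nf <= 1e-12
  denom <- sqrt(outer(v, v))
  vals <- matrix(0, nr, nr)
  ok <- denom > 0 & !outer(zero_var, zero_var, `|`)
  vals[ok] <- S[ok] / denom[ok]
  vals <- pmin(pmax(vals, -1), 1)
  diag(vals)[!zero_var] <- 1
  if (any(zero_var)) {
    warn(sprintf(
      "%d residue(s) have zero positional variance; their correlations are set to 0.",
      sum(zero_var)))
  }
  structure(vals, class = c("dccm_matrix", "matrix", "array"))
}

#' Mass-weighted principal component analysis of an ensemble
#'
#' Frames are superposed with the global fit-to-mean protocol (C-alpha fit
#' set), each coordinate of the analyzed atoms is scaled by the square root
#' of its atomic mass, and the covariance (1/(F-1) normalization) of the
#' resulting 3A'-dimensional vectors is eigendecomposed. Hydrogens are
#' excluded from the default heavy-backbone selection.
#'
#' @param ens a [new_ensemble()] object with at least 2 frames.
#' @param atom_subset `"backbone"` (N, CA, C, O heavy atoms; the default)
#'   or `"calpha"`.
#' @param mass_weighted scale coordinates by sqrt(mass)? Default `TRUE`.
#' @return An object of class `flex_pca`: `eigenvalues` (descending,
#'   Angstrom^2 amu when mass-weighted), `modes` (orthonormal columns over
#'   the 3A' mass-weighted coordinates), `projections` (F x n_modes),
#'   `variance_fraction`, `mean_coords` (A' x 3, unweighted), `masses`,
#'   `atom_names`, `atom_residue`.
#' @export
pca_ensemble <- function(ens, atom_subset = c("backbone", "calpha"),
                         mass_weighted = TRUE) {
  atom_subset <- match.arg(atom_subset)
  if (n_frames(ens) < 2L) abort("PCA needs at least 2 frames.")
  fit_idx <- which(ens$atom_names == "CA")
  fitted <- .fit_to_mean(ens$coords, fit_idx)
  keep <- switch(atom_subset,
    backbone = which(ens$atom_names %in% c("N", "CA", "C", "O")),
    calpha = which(ens$atom_names == "CA"))
  nf <- dim(fitted$coords)[1]
  X <- matrix(0, nf, 3L * length(keep))
  for (k in 1:3) X[, seq(k, ncol(X), by = 3)] <- fitted$coords[, keep, k]
  w <- if (mass_weighted) sqrt(rep(ens$masses[keep], each = 3)) else
    rep(1, 3L * length(keep))
  Xw <- sweep(X, 2, w, `*`)
  Xc <- sweep(Xw, 2, colMeans(Xw))
  C <- crossprod(Xc) / (nf - 1)
  eig <- eigen(C, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  structure(
    list(eigenvalues = ev, modes = eig$vectors,
         projections = Xc %*% eig$vectors,
         variance_fraction = ev / sum(ev),
         mean_coords = apply(fitted$coords[, keep, , drop = FALSE],
                             c(2, 3), mean),
         masses = ens$masses[keep],
         atom_names = ens$atom_names[keep],
         atom_residue = ens$atom_residue[keep],
         mass_weighted = mass_weighted),
    class = "flex_pca")
}

#' @export
print.flex_pca <- function(x, ...) {
  cat(sprintf("<flex_pca> %d modes; PC1 variance fraction %.3f\n",
              length(x$eigenvalues), x$variance_fraction[1]))
  invisible(x)
}

#' Animate a principal component as an ensemble
#'
#' Builds an ensemble of `n_steps` frames interpolating the mean structure
#' displaced along one PCA mode from -amplitude to +amplitude (in the
#' mass-unweighted coordinate space), suitable for writing as a multi-model
#' PDB with [write_multimodel_pdb()].
#'
#' @param res a [pca_ensemble()] result.
#' @param mode 1-based mode index.
#' @param n_steps number of frames.
#' @param amplitude positive displacement amplitude (projection units).
#' @return A [new_ensemble()] object.
#' @export
pc_animation <- function(res, mode = 1L, n_steps = 21L, amplitude = 1) {
  if (amplitude <= 0) abort("`amplitude` must be positive.")
  if (mode < 1L || mode > length(res$eigenvalues)) abort("Invalid mode index.")
  v <- res$modes[, mode]
  w <- if (isTRUE(res$mass_weighted)) sqrt(rep(res$masses, each = 3)) else
    rep(1, length(v))
  disp <- v / w  # back to plain Angstrom displacements
  n_atoms <- nrow(res$mean_coords)
  coords <- array(0, dim = c(n_steps, n_atoms, 3))
  steps <- seq(-amplitude, amplitude, length.out = n_steps)
  for (f in seq_len(n_steps)) {
    # disp is ordered (x1,y1,z1,x2,...): reshape to A x 3
    d <- cbind(steps[f] * disp[seq(1, 3 * n_atoms, 3)],
               steps[f] * disp[seq(2, 3 * n_atoms, 3)],
               steps[f] * disp[seq(3, 3 * n_atoms, 3)])
    coords[f, , ] <- res$mean_coords + d
  }
  new_ensemble(coords, atom_names = res$atom_names,
               atom_residue = res$atom_residue, masses = res$masses)
}
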