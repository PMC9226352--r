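#' Optimal rigid-body (Kabsch) superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' `mobile` and `target` over the fit set, by SVD of the covariance of the
#' centered fit coordinates. Reflections are excluded by sign-flipping the
#' smallest singular direction, so the returned rotation always has
#' determinant +1.
#'
#' @param mobile,target numeric `n x 3` coordinate matrices (Angstrom).
#' @param fit_indices row indices used for the fit (default: all rows).
#'   At least three non-collinear points are required.
#' @return A list with `rotation` (3x3, det +1), `translation` (length-3),
#'   `coords` (all mobile points transformed) and `rmsd` (over the fit set).
#' @export
kabsch_superpose <- function(mobile, target, fit_indices = NULL) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (is.null(fit_indices)) fit_indices <- seq_len(nrow(mobile))
  if (length(fit_indices) < 3L) {
    abort("Kabsch fit needs at least 3 fit points.")
  }
  P <- mobile[fit_indices, , drop = FALSE]
  Q <- target[fit_indices, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv_p <- svd(Pc)$d
  if (sv_p[2] <= 1e-8 * max(sv_p[1], 1)) {
    abort("Degenerate fit: the fit points are (nearly) collinear.")
  }
  s <- svd(t(Pc) %*% Qc)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- as.numeric(cq - rot %*% cp)
  coords <- sweep(mobile %*% t(rot), 2, trans, `+`)
  dev <- coords[fit_indices, , drop = FALSE] - target[fit_indices, , drop = FALSE]
  list(rotation = rot, translation = trans, coords = coords,
       rmsd = sqrt(mean(rowSums(dev^2))))
}

# Fit every frame of a coordinate array (F x A x 3) onto `target` using
# `fit_indices`; returns the fitted array.
.fit_frames <- function(coords, target, fit_indices) {
  out <- coords
  for (f in seq_len(dim(coords)[1])) {
    out[f, , ] <- kabsch_superpose(coords[f, , ], target, fit_indices)$coords
  }
  out
}

# The fixed two-iteration mean-structure protocol: fit all frames to frame 1,
# take the mean structure, refit all frames to that mean, retake the mean.
# Returns list(coords = fitted F x A x 3 array, mean = A x 3 matrix).
.fit_to_mean <- function(coords, fit_indices) {
  fitted <- .fit_frames(coords, coords[1, , ], fit_indices)
  m <- apply(fitted, c(2, 3), mean)
  fitted <- .fit_frames(coords, m, fit_indices)
  m <- apply(fitted, c(2, 3), mean)
  list(coords = fitted, mean = m)
}

#' RMSD profile of an ensemble against a reference frame
#'
#' Each frame is optimally superposed (Kabsch, C-alpha fit set by default)
#' onto the reference frame and the RMSD over the fit set reported.
#'
#' @param ens a [new_ensemble()] object.
#' @param reference_frame 1-based frame index (default first frame).
#' @param fit_indices atom indices used for fitting and RMSD (default: all
#'   C-alpha atoms).
#' @return A tibble with columns `frame` and `rmsd` (Angstrom).
#' @export
rmsd_profile <- function(ens, reference_frame = 1L, fit_indices = NULL) {
  if (reference_frame < 1 || reference_frame > n_frames(ens)) {
    abort("`reference_frame` is out of range.")
  }
  if (is.null(fit_indices)) fit_indices <- which(ens$atom_names == "CA")
  target <- ens$coords[reference_frame, , ]
  rmsd <- vapply(seq_len(n_frames(ens)), function(f) {
    if (f == reference_frame) return(0)
    kabsch_superpose(ens$coords[f, , ], target, fit_indices)$rmsd
  }, numeric(1))
  tibble::tibble(frame = seq_len(n_frames(ens)), rmsd = rmsd)
}

.rmsf_from_fitted <- function(fitted_ca, mean_ca) {
  dev2 <- sweep(fitted_ca, c(2, 3), mean_ca)^2
  sqrt(apply(dev2, 2, sum) / dim(fitted_ca)[1])
}

#' Per-residue RMSF under global ("all-atom") superposition
#'
#' Frames are superposed on the iteratively refined mean structure (two
#' fixed fit-to-mean iterations) using the C-alpha atoms of the whole chain
#' as the fit set, then the root-mean-square fluctuation of each residue's
#' C-alpha about its mean position is reported. "All-atom" names the
#' protocol — a single global fit, as opposed to the domain-specific
#' protocol of [rmsf_domain_specific()] — while the fit set itself is the
#' C-alpha trace for robustness to sidechain noise.
#'
#' @param ens a [new_ensemble()] object with at least 2 frames.
#' @return A tibble (class `rmsf_profile`) with columns `residue` and
#'   `rmsf` (Angstrom); attributes `protocol` and `reference`.
#' @export
rmsf_all_atom <- function(ens) {
  if (n_frames(ens) < 2L) abort("RMSF needs at least 2 frames.")
  ca <- select_calpha(ens)
  fit <- .fit_to_mean(ca$coords, seq_len(dim(ca$coords)[2]))
  out <- tibble::tibble(residue = seq_len(n_residues(ens)),
                        rmsf = .rmsf_from_fitted(fit$coords, fit$mean))
  structure(out, protocol = "all_atom", reference = "mean_structure",
            class = c("rmsf_profile", class(out)))
}

#' Define a domain partition of the residue sequence
#'
#' Segments are inclusive 1-based residue ranges; linkers are ranges lying
#' strictly between two segments. Residues covered by neither are assigned
#' to the nearest segment for superposition purposes.
#'
#' @param segments named list of length-2 integer vectors `c(start, end)`.
#' @param linkers optional list of length-2 integer vectors.
#' @return An object of class `domain_partition`: list with tibbles
#'   `segments` (label, start, end) and `linkers` (start, end, flank1,
#'   flank2 — the indices of the flanking segments).
#' @export
domain_partition <- function(segments, linkers = list()) {
  if (is.null(names(segments))) {
    names(segments) <- paste0("domain", seq_along(segments))
  }
  seg <- tibble::tibble(
    label = names(segments),
    start = vapply(segments, function(s) as.integer(s[1]), integer(1)),
    end = vapply(segments, function(s) as.integer(s[2]), integer(1))
  )
  seg <- seg[order(seg$start), , drop = FALSE]
  if (any(seg$end < seg$start)) abort("Segment end precedes its start.")
  if (nrow(seg) > 1 && any(seg$start[-1] <= seg$end[-nrow(seg)])) {
    abort("Segments must be non-overlapping.")
  }
  lk <- tibble::tibble(
    start = vapply(linkers, function(s) as.integer(s[1]), integer(1)),
    end = vapply(linkers, function(s) as.integer(s[2]), integer(1)),
    flank1 = NA_integer_, flank2 = NA_integer_
  )
  if (nrow(lk) > 0) {
    for (i in seq_len(nrow(lk))) {
      f1 <- which(seg$end == lk$start[i] - 1L)
      f2 <- which(seg$start == lk$end[i] + 1L)
      if (length(f1) != 1L || length(f2) != 1L) {
        abort(sprintf(
          "Linker %d-%d is not flanked by two segments.", lk$start[i], lk$end[i]))
      }
      lk$flank1[i] <- f1; lk$flank2[i] <- f2
    }
  }
  structure(list(segments = seg, linkers = lk), class = "domain_partition")
}

# Assign every residue to a segment index: segment members to their own
# segment, everything else (linkers included) to the nearest segment edge.
.nearest_segment <- function(partition, n_res) {
  seg <- partition$segments
  assign <- integer(n_res)
  for (i in seq_len(nrow(seg))) assign[seg$start[i]:seg$end[i]] <- i
  for (r in which(assign == 0L)) {
    d <- pmin(abs(r - seg$start), abs(r - seg$end))
    assign[r] <- which.min(d)
  }
  assign
}

#' Per-residue RMSF under domain-specific superposition
#'
#' For each segment of the partition the frames are superposed on that
#' segment's C-alpha atoms only (two fixed fit-to-mean iterations) and the
#' RMSF of the segment's residues is read from that fit. Linker residues
#' receive the arithmetic mean of their RMSF under the two flanking
#' segments' fits. Residues outside all segments and linkers are reported
#' under their nearest segment's fit.
#'
#' @param ens a [new_ensemble()] object with at least 2 frames.
#' @param partition a [domain_partition()].
#' @return A tibble (class `rmsf_profile`) with columns `residue`, `rmsf`
#'   and `segment` (the segment label, or `"linker"`).
#' @export
rmsf_domain_specific <- function(ens, partition) {
  if (n_frames(ens) < 2L) abort("RMSF needs at least 2 frames.")
  ca <- select_calpha(ens)
  n_res <- n_residues(ens)
  seg <- partition$segments
  if (any(seg$end > n_res)) abort("Partition exceeds the residue count.")
  # RMSF of every residue under each segment's fit
  per_fit <- matrix(NA_real_, nrow(seg), n_res)
  for (i in seq_len(nrow(seg))) {
    fit <- .fit_to_mean(ca$coords, seg$start[i]:seg$end[i])
    per_fit[i, ] <- .rmsf_from_fitted(fit$coords, fit$mean)
  }
  assign <- .nearest_segment(partition, n_res)
  rmsf <- per_fit[cbind(assign, seq_len(n_res))]
  seg_label <- seg$label[assign]
  lk <- partition$linkers
  for (i in seq_len(nrow(lk))) {
    rng <- lk$start[i]:lk$end[i]
    rmsf[rng] <- (per_fit[lk$flank1[i], rng] + per_fit[lk$flank2[i], rng]) / 2
    seg_label[rng] <- "linker"
  }
  out <- tibble::tibble(residue = seq_len(n_res), rmsf = rmsf,
                        segment = seg_label)
  structure(out, protocol = "domain_specific", reference = "mean_structure",
            class = c("rmsf_profile", class(out)))
}

#' Interdomain centre-of-mass distance per frame
#'
#' @param ens a [new_ensemble()] object.
#' @param partition a [domain_partition()] with exactly two segments.
#' @return A tibble with columns `frame` and `distance` (Angstrom) between
#'   the mass-weighted centroids of the two segments.
#' @export
com_distance_series <- function(ens, partition) {
  seg <- partition$segments
  if (nrow(seg) != 2L) abort("COM distance needs exactly 2 segments.")
  idx <- lapply(1:2, function(i) {
    which(ens$atom_residue >= seg$start[i] & ens$atom_residue <= seg$end[i])
  })
  dist_f <- vapply(seq_len(n_frames(ens)), function(f) {
    coms <- lapply(idx, function(ii) {
      w <- ens$masses[ii]
      m <- matrix(ens$coords[f, ii, ], nrow = length(ii), ncol = 3)
      colSums(m * w) / sum(w)
    })
    sqrt(sum((coms[[1]] - coms[[2]])^2))
  }, numeric(1))
  tibble::tibble(frame = seq_len(n_frames(ens)), distance = dist_f)
}
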