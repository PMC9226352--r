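# Synthetic-ensemble generators with known ground truth.
#
# Frames are statistically independent (no autocorrelation) — unlike real
# MD — which is fine for the DV/RMSF estimators, none of which require
# temporal correlation. Geometry is C-alpha only; masses are uniform
# 12.011 amu, so mass-weighted PCA reduces to uniform weighting here.

# run `code` under `seed` without touching the caller's RNG state
.with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# ideal-helix C-alpha trace (radius/rise/turn chosen so the trace is
# non-collinear and locally alpha-helix-like); collinear traces would make
# every Kabsch fit degenerate
.helix_trace <- function(n, radius = 2.3, rise = 1.5, turn_deg = 100) {
  i <- seq_len(n) - 1
  w <- turn_deg * pi / 180
  cbind(radius * cos(w * i), radius * sin(w * i), rise * i)
}

.ca_ensemble <- function(coords, mass = 12.011) {
  n_res <- dim(coords)[2]
  new_ensemble(coords, atom_names = rep("CA", n_res),
               atom_residue = seq_len(n_res),
               masses = rep(mass, n_res))
}

#' Canonical flexible-loop fluctuation profile
#'
#' A rigid scaffold (per-coordinate SD `base`) with one flexible loop whose
#' SD ramps linearly up to `peak` at the loop centre — the baseline-with-peak
#' shape of real per-residue RMSF profiles, where flexibility is localized
#' to loops and termini. This is the canonical test profile for
#' [gaussian_chain()]: superposition-based RMSF estimation is only reliable
#' when the mobile fraction of the chain is small (the fit's translation
#' noise scales with the mean squared displacement), which is exactly the
#' regime this profile represents.
#'
#' @param n_residues chain length.
#' @param base scaffold per-coordinate SD, Angstrom.
#' @param peak loop-centre per-coordinate SD, Angstrom.
#' @param loop_start,loop_end 1-based loop bounds (default: the central
#'   tenth of the chain).
#' @return Numeric vector of per-residue SDs in `[base, peak]`.
#' @export
sigma_loop_profile <- function(n_residues, base = 0.2, peak = 2.0,
                               loop_start = NULL, loop_end = NULL) {
  if (is.null(loop_start)) loop_start <- max(1L, round(n_residues * 0.45))
  if (is.null(loop_end)) {
    loop_end <- min(n_residues,
                    max(loop_start + 2L, round(n_residues * 0.55)))
  }
  sigma <- rep(base, n_residues)
  idx <- loop_start:loop_end
  mid <- (loop_start + loop_end) / 2
  half <- max((loop_end - loop_start) / 2, 1e-9)
  sigma[idx] <- base + (peak - base) * (1 - abs(idx - mid) / half)
  sigma
}

#' Gaussian-chain ensemble with a known fluctuation profile
#'
#' The mean structure is an ideal-helix C-alpha trace (a straight extended
#' trace would be collinear, leaving the superposition's spin angle about
#' the chain axis unconstrained — the degenerate-fit case the Kabsch
#' routine rejects — and letting the fit chase noise); each frame adds
#' independent isotropic Gaussian displacements with
#' per-residue, per-coordinate standard deviation `sigma[i]`. The expected
#' RMSF of residue i is `sigma[i] * sqrt(3)` (three independent
#' coordinates), recorded in the returned truth.
#'
#' @param n_residues chain length.
#' @param n_frames number of frames (>= 2).
#' @param sigma per-coordinate displacement SD, Angstrom; scalar or one
#'   value per residue; non-negative.
#' @param seed integer seed; generation is bitwise reproducible.
#' @return A list with `ensemble` (a [new_ensemble()]) and `truth`
#'   (`sigma`, `expected_rmsf`).
#' @export
gaussian_chain <- function(n_residues, n_frames, sigma, seed) {
  sigma <- rep_len(sigma, n_residues)
  if (any(sigma < 0)) abort("`sigma` must be non-negative.")
  if (n_frames < 2L) abort("Need at least 2 frames.")
  mean_str <- .helix_trace(n_residues)
  coords <- .with_seed(seed, {
    noise <- array(rnorm(n_frames * n_residues * 3), c(n_frames, n_residues, 3))
    out <- array(0, c(n_frames, n_residues, 3))
    for (k in 1:3) {
      out[, , k] <- matrix(mean_str[, k], n_frames, n_residues, byrow = TRUE) +
        sweep(noise[, , k], 2, sigma, `*`)
    }
    out
  })
  list(ensemble = .ca_ensemble(coords),
       truth = list(sigma = sigma, expected_rmsf = sigma * sqrt(3)))
}

#' Two-domain hinge ensemble
#'
#' Two internally rigid C-alpha bodies (segments of one ideal helix trace)
#' joined at a pivot — the last residue of domain 1. Per frame, the linker
#' and domain 2 are rotated rigidly by an angle drawn from
#' Normal(0, `hinge_angle_std`) about the hinge axis: the x-axis through
#' the pivot, perpendicular to the helix (z) axis, so the two bodies bend
#' toward and away from each other and all residues of the moving body are
#' displaced coherently. Optional isotropic jitter can be added on top.
#' The truth records the sampled angles and the centre-of-mass geometry,
#' so the interdomain COM distance has the closed form
#' `d(theta) = sqrt(|u|^2 + |v|^2 - 2 (A cos(theta) + B sin(theta) + C))`
#' with `u`, `v` the COM offsets from the pivot and `A`, `B`, `C` their
#' in-plane/axial products.
#'
#' @param domain_sizes two domain lengths in residues (each >= 3).
#' @param linker_length residues between the domains (rotate with domain 2).
#' @param hinge_angle_std SD of the hinge angle, degrees (>= 0).
#' @param n_frames number of frames (>= 2).
#' @param seed integer seed.
#' @param jitter_sd per-coordinate Gaussian jitter SD, Angstrom (default 0:
#'   perfectly rigid domains).
#' @return A list with `ensemble`, `partition` (a [domain_partition()]
#'   with the two domains and the linker), and `truth` (`angles` in
#'   radians, `pivot`, `com1`, `com2_ref`, `hinge_angle_std_deg`).
#' @export
hinge_two_domain <- function(domain_sizes = c(30L, 30L), linker_length = 5L,
                             hinge_angle_std = 15, n_frames = 1000L, seed = 1L,
                             jitter_sd = 0) {
  if (length(domain_sizes) != 2L || any(domain_sizes < 3L)) {
    abort("`domain_sizes` must give two domains of at least 3 residues.")
  }
  if (hinge_angle_std < 0) abort("`hinge_angle_std` must be >= 0.")
  if (n_frames < 2L) abort("Need at least 2 frames.")
  n1 <- domain_sizes[1]; n2 <- domain_sizes[2]; lk <- linker_length
  n_res <- n1 + lk + n2
  base <- .helix_trace(n_res)
  pivot <- base[n1, ]
  moving <- (n1 + 1L):n_res
  masses <- rep(12.011, n_res)
  com1 <- colSums(base[1:n1, , drop = FALSE]) / n1
  d2 <- (n1 + lk + 1L):n_res
  com2 <- colSums(base[d2, , drop = FALSE]) / n2
  sd_rad <- hinge_angle_std * pi / 180
  res <- .with_seed(seed, {
    angles <- rnorm(n_frames, 0, sd_rad)
    coords <- array(0, c(n_frames, n_res, 3))
    for (f in seq_len(n_frames)) {
      th <- angles[f]
      # rotation about the x-axis through the pivot (the hinge axis)
      R <- matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3, 3)
      fr <- base
      fr[moving, ] <- sweep(sweep(fr[moving, , drop = FALSE], 2, pivot) %*% t(R),
                            2, pivot, `+`)
      coords[f, , ] <- fr
    }
    if (jitter_sd > 0) {
      coords <- coords + array(rnorm(length(coords), 0, jitter_sd), dim(coords))
    }
    list(angles = angles, coords = coords)
  })
  partition <- domain_partition(
    segments = list(domain1 = c(1L, n1), domain2 = c(n1 + lk + 1L, n_res)),
    linkers = if (lk > 0) list(c(n1 + 1L, n1 + lk)) else list()
  )
  list(ensemble = .ca_ensemble(res$coords), partition = partition,
       truth = list(angles = res$angles, pivot = pivot, com1 = com1,
                    com2_ref = com2, hinge_angle_std_deg = hinge_angle_std,
                    jitter_sd = jitter_sd))
}

#' Closed-form interdomain COM distance of the hinge generator
#'
#' Law-of-cosines style closed form for the centre-of-mass distance of the
#' two hinge domains as a function of the hinge angle, computed from the
#' truth geometry alone (no rotation matrices).
#'
#' @param truth the `truth` element of a [hinge_two_domain()] result.
#' @return Numeric vector of COM distances, one per frame.
#' @export
hinge_com_closed_form <- function(truth) {
  u <- truth$com1 - truth$pivot
  v <- truth$com2_ref - truth$pivot
  # rotation about x: the yz components precess, the x component is fixed
  A <- u[2] * v[2] + u[3] * v[3]
  B <- u[3] * v[2] - u[2] * v[3]
  C <- u[1] * v[1]
  th <- truth$angles
  sqrt(sum(u^2) + sum(v^2) - 2 * (A * cos(th) + B * sin(th) + C))
}

#' Freely-jointed disordered-chain ensemble
#'
#' Every frame is an independent freely-jointed chain: uniformly random
#' unit steps of fixed bond length (3.8 Angstrom by default, the C-alpha
#' virtual bond). All residues are disordered by construction; bonded
#' neighbours keep a constant distance, so the near-diagonal DV signature
#' of disorder must be read at sequence separation >= 2.
#'
#' @param n_residues chain length.
#' @param n_frames number of frames (>= 2).
#' @param bond_length step length, Angstrom (> 0).
#' @param seed integer seed.
#' @return A list with `ensemble` and `truth` (`disordered` flags,
#'   `bond_length`).
#' @export
disordered_chain <- function(n_residues, n_frames, bond_length = 3.8,
                             seed = 1L) {
  if (bond_length <= 0) abort("`bond_length` must be positive.")
  if (n_frames < 2L) abort("Need at least 2 frames.")
  coords <- .with_seed(seed, {
    out <- array(0, c(n_frames, n_residues, 3))
    for (f in seq_len(n_frames)) {
      # uniform directions on the sphere
      z <- runif(n_residues - 1, -1, 1)
      phi <- runif(n_residues - 1, 0, 2 * pi)
      r <- sqrt(1 - z^2)
      steps <- bond_length * cbind(r * cos(phi), r * sin(phi), z)
      out[f, , ] <- rbind(c(0, 0, 0), apply(steps, 2, cumsum))
    }
    out
  })
  list(ensemble = .ca_ensemble(coords),
       truth = list(disordered = rep(TRUE, n_residues),
                    bond_length = bond_length))
}

#' Emulated pLDDT profile coupled to a ground-truth flexibility profile
#'
#' Generates `pLDDT_i = clip(baseline - a (sigma_i - mean(sigma)) + eps_i,
#' 0, 100)` with Gaussian noise `eps`, choosing the gain `a` so that the
#' expected correlation between pLDDT and `sigma` equals `-coupling`:
#' `a = coupling * noise_std / (sd(sigma) * sqrt(1 - coupling^2))`. With
#' `coupling = 1` the map is deterministic (the correlation is exactly -1
#' for any positive gain; `noise_std` must then be 0). `coupling < 1` with
#' zero noise is unsatisfiable and rejected.
#'
#' @param sigma ground-truth per-residue flexibility (e.g. the Gaussian
#'   chain `sigma`); must be non-constant.
#' @param coupling target |correlation| in \[0, 1\].
#' @param noise_std SD of the additive noise, pLDDT units.
#' @param seed integer seed.
#' @param baseline centre of the emitted profile (default 60, leaving
#'   headroom so realistic gain/noise settings rarely clip).
#' @return A list with `plddt` (length of `sigma`, in \[0, 100\]) and
#'   `truth` (`target_pcc = -coupling`, `gain`).
#' @export
emulate_plddt <- function(sigma, coupling = 0.9, noise_std = 5, seed = 1L,
                          baseline = 60) {
  if (coupling < 0 || coupling > 1) abort("`coupling` must lie in [0, 1].")
  if (noise_std < 0) abort("`noise_std` must be >= 0.")
  if (sd(sigma) == 0 && coupling > 0) {
    abort("`sigma` must be non-constant to couple pLDDT to it.")
  }
  if (coupling == 1) {
    if (noise_std > 0) abort("`coupling = 1` requires `noise_std = 0`.")
    a <- 40 / diff(range(sigma))
  } else if (coupling == 0) {
    a <- 0
  } else {
    if (noise_std == 0) {
      abort("`coupling` < 1 with zero noise is unsatisfiable; give noise_std > 0.")
    }
    a <- coupling * noise_std / (sd(sigma) * sqrt(1 - coupling^2))
  }
  plddt <- .with_seed(seed, {
    eps <- if (noise_std > 0) rnorm(length(sigma), 0, noise_std) else 0
    pmin(pmax(baseline - a * (sigma - mean(sigma)) + eps, 0), 100)
  })
  list(plddt = plddt, truth = list(target_pcc = -coupling, gain = a))
}

#' Emulated PAE matrix coupled to a DV matrix
#'
#' `PAE[x, y] = clip(gain * DV[x, y] + offset + eps_xy, 0, max_pae)` with
#' independent noise per ordered pair, producing the realistic asymmetry of
#' AF2 PAE maps; the diagonal is 0. The truth records the expected
#' pre-clip correlation between the symmetrized PAE and DV over the strict
#' upper triangle: `gain * sd(DV) / sqrt(gain^2 var(DV) + noise_std^2 / 2)`
#' (transpose-pair averaging halves the noise variance).
#'
#' @param dv a [dv_matrix()] object (or plain symmetric matrix).
#' @param gain positive scale factor.
#' @param offset baseline error, Angstrom.
#' @param noise_std SD of the per-pair noise, Angstrom.
#' @param max_pae clip ceiling, Angstrom (> offset).
#' @param seed integer seed.
#' @return A list with `pae` (a [new_pae_matrix()]) and `truth`
#'   (`expected_pcc`).
#' @export
pae_emulator <- function(dv, gain = 1, offset = 2, noise_std = 0.5,
                         max_pae = 31.8, seed = 1L) {
  if (gain <= 0) abort("`gain` must be positive.")
  if (max_pae <= offset) abort("`max_pae` must exceed `offset`.")
  D <- if (inherits(dv, "dv_matrix")) dv$values else as.matrix(dv)
  n <- nrow(D)
  vals <- .with_seed(seed, {
    eps <- matrix(rnorm(n * n, 0, noise_std), n, n)
    out <- pmin(pmax(gain * D + offset + eps, 0), max_pae)
    diag(out) <- 0
    out
  })
  ut <- upper.tri(D)
  s_dv <- sd(D[ut])
  expected_pcc <- if (noise_std == 0) 1 else
    gain * s_dv / sqrt(gain^2 * s_dv^2 + noise_std^2 / 2)
  list(pae = new_pae_matrix(vals, max_pae = max_pae),
       truth = list(expected_pcc = expected_pcc))
}
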