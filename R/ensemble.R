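#' Conformational ensemble container
#'
#' A `flex_ensemble` holds an ensemble of conformations (an MD-trajectory
#' stand-in): a frames x atoms x 3 coordinate array in Angstrom plus the atom
#' table (names, residue assignment, masses). Every residue must own exactly
#' one `CA` atom; this is what all C-alpha based statistics (RMSF, DV, DCCM)
#' rely on.
#'
#' @param coords numeric array `c(n_frames, n_atoms, 3)`, Angstrom.
#' @param atom_names character vector of PDB atom names, one per atom.
#' @param atom_residue integer vector, 1-based residue index per atom.
#' @param residue_labels optional residue labels (defaults to the residue
#'   index); one per residue.
#' @param chains optional per-residue chain labels.
#' @param masses atomic masses in amu, one per atom; derived from the atom
#'   name when omitted.
#'
#' @return An object of class `flex_ensemble` with elements `coords`,
#'   `atom_names`, `atom_residue`, `residue_labels`, `chains`, `masses`.
#' @export
new_ensemble <- function(coords, atom_names, atom_residue,
                         residue_labels = NULL, chains = NULL, masses = NULL) {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    abort("`coords` must be an n_frames x n_atoms x 3 array.")
  }
  n_atoms <- dim(coords)[2]
  if (dim(coords)[1] < 1L) abort("An ensemble needs at least one frame.")
  atom_residue <- as.integer(atom_residue)
  stopifnot(length(atom_names) == n_atoms, length(atom_residue) == n_atoms)
  n_res <- max(atom_residue)
  ca_per_res <- tabulate(atom_residue[atom_names == "CA"], nbins = n_res)
  if (any(ca_per_res != 1L)) {
    bad <- which(ca_per_res != 1L)[1]
    abort(sprintf("Residue %d must own exactly one CA atom (found %d).",
                  bad, ca_per_res[bad]))
  }
  if (is.null(masses)) masses <- .mass_of(.element_from_name(atom_names))
  if (any(masses <= 0)) abort("Atomic masses must be positive.")
  if (is.null(residue_labels)) residue_labels <- seq_len(n_res)
  if (is.null(chains)) chains <- rep("A", n_res)
  structure(
    list(coords = coords, atom_names = as.character(atom_names),
         atom_residue = atom_residue, residue_labels = residue_labels,
         chains = chains, masses = as.numeric(masses)),
    class = "flex_ensemble"
  )
}

#' @export
print.flex_ensemble <- function(x, ...) {
  cat(sprintf("<flex_ensemble> %d frame(s), %d atom(s), %d residue(s)\n",
              n_frames(x), dim(x$coords)[2], n_residues(x)))
  invisible(x)
}

#' Ensemble dimensions
#' @param ens a [new_ensemble()] object.
#' @return An integer count.
#' @export
n_frames <- function(ens) dim(ens$coords)[1]

#' @rdname n_frames
#' @export
n_residues <- function(ens) max(ens$atom_residue)

#' Read a multi-model PDB file as an ensemble
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame; a file without MODEL
#' records yields a single-frame ensemble. All models must share the same
#' atom table. Masses are assigned from the element (C 12.011, N 14.007,
#' O 15.999, S 32.06, H 1.008 amu).
#'
#' @param path path to a PDB file.
#' @return A [new_ensemble()] object.
#' @export
read_multimodel_pdb <- function(path) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) abort(paste0(
      "Failed to parse multi-model PDB (models must share one atom table): ",
      conditionMessage(e)))
  )
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_atoms <- ncol(xyz) / 3L
  if (n_atoms != nrow(pdb$atom)) {
    abort("Atom count mismatch across MODEL blocks.")
  }
  at <- pdb$atom
  res_key <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert))
  res_index <- match(res_key, unique(res_key))
  el <- at$elesy
  if (is.null(el) || all(is.na(el)) || all(trimws(el) == "")) {
    el <- .element_from_name(at$elety)
  } else {
    el <- trimws(el)
    el[is.na(el) | el == ""] <- .element_from_name(at$elety[is.na(el) | el == ""])
  }
  coords <- array(0, dim = c(nrow(xyz), n_atoms, 3))
  for (k in 1:3) coords[, , k] <- xyz[, seq(k, ncol(xyz), by = 3), drop = FALSE]
  first <- !duplicated(res_index)
  new_ensemble(coords,
               atom_names = trimws(at$elety),
               atom_residue = res_index,
               residue_labels = at$resno[first],
               chains = at$chain[first],
               masses = .mass_of(el))
}

#' Write an ensemble as a multi-model PDB file
#'
#' Coordinates are written at the PDB fixed-width precision (3 decimals), so
#' a read/write round trip preserves coordinates to 1e-3 Angstrom.
#'
#' @param ens a [new_ensemble()] object.
#' @param path output path.
#' @param bfactors optional per-atom B-factor column (e.g. emulated pLDDT).
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(ens, path, bfactors = NULL) {
  n_atoms <- dim(ens$coords)[2]
  xyz <- matrix(0, n_frames(ens), 3L * n_atoms)
  for (k in 1:3) xyz[, seq(k, 3L * n_atoms, by = 3)] <- ens$coords[, , k]
  if (is.null(bfactors)) bfactors <- rep(0, n_atoms)
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = ens$residue_labels[ens$atom_residue],
                   chain = ens$chains[ens$atom_residue],
                   resid = rep("ALA", n_atoms), elety = ens$atom_names,
                   b = rep_len(bfactors, n_atoms))
  invisible(path)
}

#' Restrict an ensemble to C-alpha atoms
#'
#' @param ens a [new_ensemble()] object.
#' @return A `flex_ensemble` with one `CA` atom per residue, in residue
#'   order; idempotent on CA-only input.
#' @export
select_calpha <- function(ens) {
  idx <- which(ens$atom_names == "CA")
  idx <- idx[order(ens$atom_residue[idx])]
  new_ensemble(ens$coords[, idx, , drop = FALSE],
               atom_names = ens$atom_names[idx],
               atom_residue = seq_along(idx),
               residue_labels = ens$residue_labels,
               chains = ens$chains,
               masses = ens$masses[idx])
}

#' Subsample ensemble frames at a fixed stride
#'
#' Keeps frames 1, 1+stride, 1+2*stride, ...; a stride beyond the frame
#' count clamps to the first frame.
#'
#' @param ens a [new_ensemble()] object.
#' @param stride positive integer step.
#' @return A `flex_ensemble` with the retained frames.
#' @export
subsample <- function(ens, stride) {
  if (!is.numeric(stride) || length(stride) != 1L || stride < 1) {
    abort("`stride` must be a single integer >= 1.")
  }
  keep <- seq(1L, n_frames(ens), by = as.integer(stride))
  out <- ens
  out$coords <- ens$coords[keep, , , drop = FALSE]
  out
}
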