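# Plain-text PDB fixtures built in code.

pdb_atom_line <- function(serial, name, resname, chain, resno, xyz, b,
                          element = NULL, icode = "", altloc = "") {
  if (is.null(element)) element <- substr(gsub("[0-9]", "", name), 1, 1)
  name_f <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name_f, altloc, resname, chain, resno, icode,
          xyz[1], xyz[2], xyz[3], 1.00, b, element)
}

# a simple CA-trace model PDB with given per-residue B-factors
write_ca_model_pdb <- function(path, bfactors, chain = "A",
                               resno = seq_along(bfactors),
                               drop_ca_at = integer(0)) {
  n <- length(bfactors)
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(n)) {
    serial <- serial + 1L
    xyz <- c(3.8 * (i - 1), 0.5 * i, 0)
    nm <- if (i %in% drop_ca_at) "CB" else "CA"
    lines <- c(lines, pdb_atom_line(serial, nm, "ALA",
                                    if (length(chain) == 1) chain else chain[i],
                                    resno[i], xyz, bfactors[i], "C"))
  }
  writeLines(c(lines, "END"), path)
  path
}

# multi-model PDB text for a list of frame coordinate matrices (CA only)
write_ca_traj_pdb <- function(path, frames, bfactors = NULL) {
  n <- nrow(frames[[1]])
  if (is.null(bfactors)) bfactors <- rep(0, n)
  lines <- character(0)
  for (f in seq_along(frames)) {
    lines <- c(lines, sprintf("MODEL     %4d", f))
    for (i in seq_len(n)) {
      lines <- c(lines, pdb_atom_line(i, "CA", "ALA", "A", i,
                                      frames[[f]][i, ], bfactors[i], "C"))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

write_pae_json_v1 <- function(path, values, max_pae = max(values)) {
  n <- nrow(values)
  idx <- expand.grid(r1 = seq_len(n), r2 = seq_len(n))
  obj <- list(list(residue1 = idx$r1, residue2 = idx$r2,
                   distance = values[cbind(idx$r1, idx$r2)],
                   max_predicted_aligned_error = max_pae))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  path
}

write_pae_json_v2 <- function(path, values, max_pae = max(values)) {
  obj <- list(list(predicted_aligned_error = values,
                   max_predicted_aligned_error = max_pae))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  path
}

# a complete miniature analysis system on disk (model + trajectory + PAE)
fixture_system <- function(dir, n_res = 30L, n_frames = 60L, seed = 42L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- gaussian_chain(n_res, n_frames, sigma_loop_profile(n_res), seed = seed)
  traj <- file.path(dir, "trajectory.pdb")
  write_multimodel_pdb(g$ensemble, traj)
  pl <- emulate_plddt(g$truth$sigma, coupling = 0.9, noise_std = 5,
                      seed = seed + 1L)
  mean_ens <- g$ensemble
  mean_ens$coords <- array(apply(g$ensemble$coords, c(2, 3), mean),
                           dim = c(1, n_res, 3))
  model <- file.path(dir, "model.pdb")
  write_multimodel_pdb(mean_ens, model, bfactors = pl$plddt)
  dv <- dv_matrix(g$ensemble)
  pe <- pae_emulator(dv, seed = seed + 2L)
  pae <- file.path(dir, "pae.json")
  write_pae_json_v2(pae, pe$pae$values, pe$pae$max_pae)
  list(model = model, trajectory = traj, pae = pae,
       truth = list(chain = g$truth, plddt = pl, pae = pe$truth))
}
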