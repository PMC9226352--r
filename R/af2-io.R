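#' Read an AlphaFold2 model (or experimental structure) from PDB
#'
#' AlphaFold2 deposits the per-residue pLDDT confidence score in the PDB
#' B-factor column, so the same reader serves AF2 models
#' (`score_kind = "plddt"`) and experimental structures
#' (`score_kind = "bfactor"`). The per-residue score is taken from each
#' residue's C-alpha record. Multi-chain models are concatenated in file
#' order with chain labels retained. Only the first altLoc of an atom is
#' kept; residues with insertion codes are distinct positions in file order.
#'
#' @param path path to a PDB file.
#' @param score_kind `"plddt"` (scores validated to lie in \[0, 100\]) or
#'   `"bfactor"`.
#' @return A `structure_model`: list with `residues` (tibble: `residue`
#'   internal 1-based index, `label` original resSeq, `chain`, `score`),
#'   `atoms` (tibble of atom records), and `score_kind`.
#' @export
read_af2_model <- function(path, score_kind = c("plddt", "bfactor")) {
  score_kind <- match.arg(score_kind)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  # first altLoc only: keep the first record for each (chain, resno, icode, name)
  key <- paste(at$chain, at$resno,
               ifelse(is.na(at$insert), "", at$insert), trimws(at$elety))
  at <- at[!duplicated(key), , drop = FALSE]
  res_key <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert))
  res_index <- match(res_key, unique(res_key))
  n_res <- max(res_index)
  first <- !duplicated(res_index)
  labels <- at$resno[first]
  chains <- at$chain[first]
  for (ch in unique(chains)) {
    if (is.unsorted(labels[chains == ch])) {
      abort(sprintf("Residue numbers are not increasing within chain %s.", ch))
    }
  }
  is_ca <- trimws(at$elety) == "CA"
  ca_rows <- integer(n_res)
  for (i in seq_len(n_res)) {
    hit <- which(is_ca & res_index == i)
    if (length(hit) == 0L) {
      abort(sprintf("Residue %s (chain %s) has no CA atom.",
                    labels[i], chains[i]))
    }
    ca_rows[i] <- hit[1]
  }
  score <- at$b[ca_rows]
  if (score_kind == "plddt" && any(score < 0 | score > 100)) {
    abort("pLDDT scores must lie in [0, 100].")
  }
  structure(
    list(
      residues = tibble::tibble(residue = seq_len(n_res), label = labels,
                                chain = chains, score = score),
      atoms = tibble::tibble(name = trimws(at$elety), residue = res_index,
                             x = at$x, y = at$y, z = at$z, b = at$b),
      score_kind = score_kind
    ),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d residue(s), score: %s\n",
              nrow(x$residues), x$score_kind))
  invisible(x)
}

#' Construct a predicted-aligned-error matrix
#'
#' @param values square, non-negative numeric matrix of expected position
#'   errors in Angstrom; asymmetry is permitted (the error assigned to
#'   residue x when y is aligned need not equal the converse).
#' @param max_pae the scale maximum in Angstrom; defaults to `max(values)`.
#' @return An object of class `pae_matrix` with elements `values`, `max_pae`.
#' @export
new_pae_matrix <- function(values, max_pae = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) abort("PAE matrix must be square.")
  if (any(values < 0)) abort("PAE entries must be non-negative.")
  if (is.null(max_pae)) max_pae <- max(values)
  if (max(values) > max_pae) {
    warn("PAE entries exceed the declared max_pae; raising max_pae.")
    max_pae <- max(values)
  }
  structure(list(values = unname(values), max_pae = as.numeric(max_pae)),
            class = "pae_matrix")
}

#' @export
print.pae_matrix <- function(x, ...) {
  cat(sprintf("<pae_matrix> %d x %d, max_pae %.2f A\n",
              nrow(x$values), ncol(x$values), x$max_pae))
  invisible(x)
}

#' Read a PAE matrix from AlphaFold-DB JSON
#'
#' Both AlphaFold-DB dialects are supported: the triplet form with 1-based
#' `residue1`/`residue2` index lists and a `distance` list (plus
#' `max_predicted_aligned_error`), and the nested-list form under
#' `predicted_aligned_error` or `pae`. A top-level single-element array
#' wrapper (as AFDB emits) is unwrapped.
#'
#' @param path path to a JSON file.
#' @return A [new_pae_matrix()] object.
#' @export
read_pae_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  if (is.list(obj) && is.null(names(obj)) && length(obj) == 1L) obj <- obj[[1]]
  obj <- lapply(obj, function(x) if (is.list(x) && length(x) == 1L && is.null(names(x))) x[[1]] else x)
  max_pae <- obj[["max_predicted_aligned_error"]]
  if (!is.null(obj[["predicted_aligned_error"]]) || !is.null(obj[["pae"]])) {
    vals <- obj[["predicted_aligned_error"]]
    if (is.null(vals)) vals <- obj[["pae"]]
    if (is.list(vals)) vals <- do.call(rbind, vals)
    vals <- as.matrix(vals)
    if (nrow(vals) != ncol(vals)) {
      abort(sprintf("PAE matrix is not square (%d x %d).",
                    nrow(vals), ncol(vals)))
    }
  } else if (!is.null(obj[["residue1"]])) {
    r1 <- as.integer(unlist(obj[["residue1"]]))
    r2 <- as.integer(unlist(obj[["residue2"]]))
    d <- as.numeric(unlist(obj[["distance"]]))
    n <- max(r1, r2)
    if (length(d) != n * n || length(r1) != length(d) ||
        anyDuplicated(cbind(r1, r2))) {
      abort("Triplet PAE JSON does not cover a complete square index grid.")
    }
    vals <- matrix(NA_real_, n, n)
    vals[cbind(r1, r2)] <- d
    if (anyNA(vals)) {
      abort("Triplet PAE JSON does not cover a complete square index grid.")
    }
  } else {
    abort("Unrecognized PAE JSON dialect.")
  }
  if (any(vals < 0)) abort("PAE entries must be non-negative.")
  new_pae_matrix(vals, max_pae = if (is.null(max_pae)) NULL else as.numeric(max_pae))
}

#' Write / read a per-residue flexibility profile table
#'
#' The profile is a tibble with one row per residue (column `residue` plus
#' any of `plddt`, `af2_score`, `rmsf`, `sqrt_b`, `external_disorder`, ...).
#' Written as a tab-separated table with a header; numeric values
#' round-trip to at least six significant digits.
#'
#' @param profile a data frame, one row per residue.
#' @param path output (input) path.
#' @return `write_profile_table()` returns `path` invisibly;
#'   `read_profile_table()` returns a tibble.
#' @export
write_profile_table <- function(profile, path) {
  if (!is.data.frame(profile)) abort("`profile` must be a data frame.")
  readr::write_tsv(profile, path)
  invisible(path)
}

#' @rdname write_profile_table
#' @export
read_profile_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
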