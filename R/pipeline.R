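#' Load a pipeline run configuration
#'
#' A run configuration names the inputs and options of one analysis:
#' `model` (AF2 PDB with pLDDT in the B-factor column), `trajectory`
#' (multi-model PDB ensemble), optional `pae` (AlphaFold-DB JSON),
#' optional `experimental` (PDB with crystallographic B-factors), optional
#' `external_disorder` (TSV with columns `residue`, `score` from an
#' external disorder predictor), optional `partition`
#' (`list(segments = , linkers = )` residue ranges for the domain-specific
#' RMSF protocol), `stride` (frame stride, default 1), `symmetrization`
#' (PAE symmetrization rule), `breaks` (heatmap bin edges), `seed`, and
#' `out_dir`. Accepts a JSON file path or an R list; list/flag values
#' override nothing here — later arguments to the `run_*()` functions win.
#'
#' @param config a named list or the path of a JSON config file.
#' @return A named list with defaults filled in.
#' @export
load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) abort("`config` must be a list or a JSON file path.")
  defaults <- list(stride = 1L, symmetrization = "mean_of_transpose_pair",
                   seed = 1L, normalize = TRUE, out_dir = ".")
  out <- utils::modifyList(defaults, config)
  if (out$stride < 1L) abort("`stride` must be >= 1.")
  out
}

.config_partition <- function(config) {
  if (is.null(config$partition)) return(NULL)
  p <- config$partition
  segs <- lapply(seq_len(nrow(as.data.frame(p$segments))), function(i) {
    s <- as.data.frame(p$segments)[i, ]
    c(as.integer(s$start), as.integer(s$end))
  })
  names(segs) <- as.data.frame(p$segments)$label
  lks <- list()
  if (!is.null(p$linkers)) {
    ldf <- as.data.frame(p$linkers)
    lks <- lapply(seq_len(nrow(ldf)), function(i) {
      c(as.integer(ldf$start[i]), as.integer(ldf$end[i]))
    })
  }
  domain_partition(segs, lks)
}

.compute_profile <- function(config) {
  model <- read_af2_model(config$model, score_kind = "plddt")
  ens <- read_multimodel_pdb(config$trajectory)
  if (config$stride > 1L) ens <- subsample(ens, config$stride)
  n_model <- nrow(model$residues)
  n_traj <- n_residues(ens)
  if (n_model != n_traj) {
    abort(sprintf(
      "Residue count mismatch: model has %d residues, trajectory has %d.",
      n_model, n_traj))
  }
  partition <- .config_partition(config)
  rmsf <- if (is.null(partition)) rmsf_all_atom(ens)
          else rmsf_domain_specific(ens, partition)
  bfac <- NULL
  if (!is.null(config$experimental)) {
    exp_model <- read_af2_model(config$experimental, score_kind = "bfactor")
    if (nrow(exp_model$residues) != n_traj) {
      abort(sprintf(
        "Residue count mismatch: experimental structure has %d residues, trajectory has %d.",
        nrow(exp_model$residues), n_traj))
    }
    bfac <- exp_model$residues$score
  }
  ext <- NULL
  if (!is.null(config$external_disorder)) {
    tab <- read_profile_table(config$external_disorder)
    if (nrow(tab) != n_traj) {
      abort(sprintf(
        "Residue count mismatch: external disorder table has %d rows, trajectory has %d.",
        nrow(tab), n_traj))
    }
    ext <- tab$score
  }
  profile <- flexibility_profile(
    rmsf = rmsf, plddt = model$residues$score, bfactor = bfac,
    external_disorder = ext, residue = model$residues$label,
    normalize = isTRUE(config$normalize))
  list(profile = profile, ensemble = ens)
}

#' Run the per-residue profile stage of the pipeline
#'
#' Reads the model and trajectory named in the configuration, computes the
#' RMSF (domain-specific when a partition is configured, global
#' superposition otherwise), merges all per-residue scores into one
#' flexibility profile, and writes `profile.tsv` plus an overlay figure
#' `profile.pdf` (every figure has its numeric sidecar — no result exists
#' only as pixels). Outputs are deterministic: identical configuration and
#' seed give byte-identical tables.
#'
#' @param config a [load_run_config()] input (list or JSON path).
#' @param out_dir output directory (created if needed); overrides the
#'   config's `out_dir`.
#' @return Invisibly, a list with `profile` (tibble) and `files`.
#' @export
run_profile <- function(config, out_dir = NULL) {
  config <- load_run_config(config)
  if (!is.null(out_dir)) config$out_dir <- out_dir
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- .compute_profile(config)
  tsv <- file.path(config$out_dir, "profile.tsv")
  write_profile_table(res$profile, tsv)
  fig <- file.path(config$out_dir, "profile.pdf")
  ggplot2::ggsave(fig, plot_flexibility_profile(res$profile),
                  width = 7, height = 3.5, device = grDevices::pdf)
  invisible(list(profile = res$profile, files = c(profile = tsv, figure = fig)))
}

#' Run the concordance stage of the pipeline
#'
#' Computes the per-residue concordance report in both sign conventions
#' (AF2-score vs RMSF positive, pLDDT vs RMSF its exact negative) and — if
#' a PAE file is configured — the matrix-level PAE-vs-DV concordance.
#' Writes `concordance.tsv` and `concordance.json`.
#'
#' @inheritParams run_profile
#' @return Invisibly, a list with `report` (tibble), `matrix_concordance`
#'   (tibble or `NULL`) and `files`.
#' @export
run_concord <- function(config, out_dir = NULL) {
  config <- load_run_config(config)
  if (!is.null(out_dir)) config$out_dir <- out_dir
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- .compute_profile(config)
  report <- concordance_report(res$profile, flex_col = "rmsf")
  mat <- NULL
  if (!is.null(config$pae)) {
    pae <- read_pae_json(config$pae)
    dv <- dv_matrix(res$ensemble)
    mat <- pae_dv_concordance(pae, dv, symmetrization = config$symmetrization)
  }
  tsv <- file.path(config$out_dir, "concordance.tsv")
  write_profile_table(report, tsv)
  js <- file.path(config$out_dir, "concordance.json")
  payload <- list(profile_concordance = report)
  if (!is.null(mat)) payload$matrix_concordance <- mat
  jsonlite::write_json(payload, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(report = report, matrix_concordance = mat,
                 files = c(table = tsv, json = js)))
}

#' Write a heatmap figure with its numeric sidecar
#'
#' Renders [plot_matrix_heatmap()] to a file and writes the matrix itself
#' as TSV alongside it.
#'
#' @param matrix a [new_pae_matrix()], [dv_matrix()] or plain square
#'   matrix.
#' @param path output figure path (extension selects the device, e.g.
#'   `.pdf`).
#' @param breaks optional strictly increasing bin edges.
#' @return Invisibly, the paths of the figure and the TSV sidecar.
#' @export
run_heatmap <- function(matrix, path, breaks = NULL) {
  p <- plot_matrix_heatmap(matrix, breaks = breaks)
  ggplot2::ggsave(path, p, width = 6, height = 5)
  M <- if (inherits(matrix, "pae_matrix")) matrix$values
       else if (inherits(matrix, "dv_matrix")) matrix$values
       else as.matrix(matrix)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".tsv")
  utils::write.table(M, sidecar, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(c(figure = path, table = sidecar))
}
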