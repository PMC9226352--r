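#' AF2-score: reversed min-max normalization of pLDDT
#'
#' `(pLDDT_max - pLDDT) / (pLDDT_max - pLDDT_min)`, mapping the most
#' confident residue to 0 and the least confident to 1, so that high
#' AF2-score means high predicted flexibility. By default the extrema are
#' the profile's own max/min (so every profile spans \[0, 1\]); setting
#' `extrema = "fixed"` uses the theoretical 100/0 bounds instead.
#'
#' @param plddt numeric vector of pLDDT scores in \[0, 100\].
#' @param extrema `"profile"` (default) or `"fixed"`.
#' @return Numeric vector in \[0, 1\]; a constant profile yields all zeros
#'   with a warning (the normalization is degenerate).
#' @export
af2_score <- function(plddt, extrema = c("profile", "fixed")) {
  extrema <- match.arg(extrema)
  if (any(plddt < 0 | plddt > 100)) abort("pLDDT values must lie in [0, 100].")
  if (extrema == "fixed") return((100 - plddt) / 100)
  hi <- max(plddt); lo <- min(plddt)
  if (hi == lo) {
    warn("Constant pLDDT profile: AF2-scores set to 0.")
    return(rep(0, length(plddt)))
  }
  (hi - plddt) / (hi - lo)
}

#' Convert between RMSF and crystallographic B-factor
#'
#' `B = (8 pi^2 / 3) RMSF^2` relates the isotropic temperature factor
#' (Angstrom^2) to the root-mean-square fluctuation (Angstrom); higher B or
#' RMSF means higher flexibility.
#'
#' @param rmsf non-negative RMSF values, Angstrom.
#' @param b non-negative B-factors, Angstrom^2.
#' @return `rmsf_to_b()` returns B-factors; `b_to_rmsf()` returns RMSF.
#' @export
rmsf_to_b <- function(rmsf) {
  if (any(rmsf < 0)) abort("RMSF values must be non-negative.")
  (8 * pi^2 / 3) * rmsf^2
}

#' @rdname rmsf_to_b
#' @export
b_to_rmsf <- function(b) {
  if (any(b < 0)) abort("B-factors must be non-negative.")
  sqrt(3 * b / (8 * pi^2))
}

#' Square-root B-factor profile
#'
#' The square root of the B-factor is the RMSF-comparable per-residue
#' flexibility scale for experimental structures; optionally min-max
#' normalized to \[0, 1\].
#'
#' @param b non-negative B-factors, Angstrom^2.
#' @param normalize min-max normalize the result? Default `FALSE`.
#' @return Numeric vector.
#' @export
b_to_sqrtb_profile <- function(b, normalize = FALSE) {
  if (any(b < 0)) abort("B-factors must be non-negative.")
  out <- sqrt(b)
  if (normalize) out <- minmax_normalize(out)
  out
}

#' Min-max normalization to the unit interval
#'
#' @param values numeric vector (length >= 1).
#' @return `(values - min) / (max - min)`; a constant input yields all
#'   zeros with a warning.
#' @export
minmax_normalize <- function(values) {
  if (length(values) < 1L) abort("Need at least one value.")
  hi <- max(values); lo <- min(values)
  if (hi == lo) {
    warn("Constant input: normalized values set to 0.")
    return(rep(0, length(values)))
  }
  (values - lo) / (hi - lo)
}

#' Disorder summary of a pLDDT profile
#'
#' Residues with pLDDT below 50 are commonly taken to lie in intrinsically
#' disordered regions; this summarizes the disordered fraction of a profile
#' together with its median and interquartile range.
#'
#' @param plddt numeric vector of pLDDT scores in \[0, 100\].
#' @param threshold disorder cutoff (strict `<`); default 50.
#' @return A one-row tibble: `n`, `count` (residues strictly below the
#'   threshold), `fraction`, `median`, `iqr`, `threshold`.
#' @export
disorder_fraction <- function(plddt, threshold = 50) {
  if (any(plddt < 0 | plddt > 100)) abort("pLDDT values must lie in [0, 100].")
  cnt <- sum(plddt < threshold)
  tibble::tibble(
    n = length(plddt), count = cnt, fraction = cnt / length(plddt),
    median = unname(quantile(plddt, 0.5, type = 7)), iqr = iqr(plddt),
    threshold = threshold
  )
}

#' Assemble a per-residue flexibility profile
#'
#' Aligns the available per-residue scores — pLDDT (with its derived
#' AF2-score), RMSF, experimental B-factor (as square-root profile), and an
#' externally supplied disorder score — into one tibble, one row per
#' residue. Columns named `*_norm` hold min-max normalized versions when
#' `normalize = TRUE`.
#'
#' @param rmsf RMSF vector or an [rmsf_all_atom()] profile.
#' @param plddt optional pLDDT vector.
#' @param bfactor optional experimental B-factor vector.
#' @param external_disorder optional per-residue disorder score in \[0, 1\]
#'   from an external predictor (ingested, never computed here).
#' @param residue optional residue labels.
#' @param normalize add min-max normalized columns? Default `TRUE`.
#' @return A tibble with columns `residue` plus those supplied.
#' @export
flexibility_profile <- function(rmsf, plddt = NULL, bfactor = NULL,
                                external_disorder = NULL, residue = NULL,
                                normalize = TRUE) {
  if (is.data.frame(rmsf)) rmsf <- rmsf$rmsf
  n <- length(rmsf)
  for (v in list(plddt, bfactor, external_disorder)) {
    if (!is.null(v) && length(v) != n) {
      abort(sprintf("Profile columns disagree in length (%d vs %d residues).",
                    length(v), n))
    }
  }
  if (is.null(residue)) residue <- seq_len(n)
  out <- tibble::tibble(residue = residue, rmsf = rmsf)
  if (!is.null(plddt)) {
    out$plddt <- plddt
    out$af2_score <- af2_score(plddt)
  }
  if (!is.null(bfactor)) out$sqrt_b <- b_to_sqrtb_profile(bfactor)
  if (!is.null(external_disorder)) out$external_disorder <- external_disorder
  if (normalize) {
    out$rmsf_norm <- minmax_normalize(out$rmsf)
    if (!is.null(bfactor)) out$sqrt_b_norm <- minmax_normalize(out$sqrt_b)
  }
  out
}
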