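#' Colour palette for PAE/DV heatmaps
#'
#' Low values are dark green, high values white — the reverse of typical
#' heatmap defaults, chosen so well-ordered (low-error, low-variation)
#' regions read as solid colour.
#'
#' @param n number of colours (default 256 bins).
#' @return Character vector of colours, `[1]` dark green (lowest bin),
#'   `[n]` white (highest bin).
#' @export
heatmap_palette <- function(n = 256L) {
  grDevices::colorRampPalette(c("darkgreen", "white"))(n)
}

#' Heatmap of a PAE or DV matrix
#'
#' Values are binned into 256 equal-width bins from dark green (lowest) to
#' white (highest) by default; an explicit strictly increasing `breaks`
#' vector defines piecewise bins instead (useful to expose block structure
#' when a few large entries dominate). A marginal histogram of the matrix
#' values, aligned with the colour scale, is attached when the patchwork
#' package is available.
#'
#' @param matrix a [new_pae_matrix()], [dv_matrix()] or plain square
#'   matrix.
#' @param breaks optional strictly increasing bin edges (Angstrom).
#' @param n_bins number of equal-width bins when `breaks` is `NULL`.
#' @param with_histogram attach the value histogram panel? Default `TRUE`
#'   (silently skipped if patchwork is unavailable).
#' @param title optional plot title.
#' @return A ggplot (or patchwork) object.
#' @export
plot_matrix_heatmap <- function(matrix, breaks = NULL, n_bins = 256L,
                                with_histogram = TRUE, title = NULL) {
  M <- if (inherits(matrix, "pae_matrix")) matrix$values
       else if (inherits(matrix, "dv_matrix")) matrix$values
       else as.matrix(matrix)
  if (nrow(M) != ncol(M)) abort("Heatmap needs a square matrix.")
  if (is.null(breaks)) {
    lo <- min(M); hi <- max(M)
    if (hi == lo) hi <- lo + 1e-9
    breaks <- seq(lo, hi, length.out = n_bins + 1L)
  } else {
    if (any(diff(breaks) <= 0)) abort("`breaks` must be strictly increasing.")
    if (min(M) < breaks[1] || max(M) > breaks[length(breaks)]) {
      breaks <- unique(sort(c(min(M), breaks, max(M))))
    }
  }
  nb <- length(breaks) - 1L
  pal <- heatmap_palette(nb)
  df <- tidyr::expand_grid(i = seq_len(nrow(M)), j = seq_len(ncol(M)))
  df$value <- M[cbind(df$i, df$j)]
  df$bin <- cut(df$value, breaks = breaks, include.lowest = TRUE)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                        fill = .data$bin)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = pal, drop = FALSE, guide = "none") +
    ggplot2::scale_y_reverse(expand = c(0, 0)) +
    ggplot2::scale_x_continuous(expand = c(0, 0)) +
    ggplot2::labs(x = "residue", y = "residue", title = title) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
  if (with_histogram && requireNamespace("patchwork", quietly = TRUE)) {
    hist_df <- tibble::tibble(value = as.numeric(M))
    ph <- ggplot2::ggplot(hist_df, ggplot2::aes(x = .data$value)) +
      ggplot2::geom_histogram(bins = min(nb, 64L), fill = "darkgreen") +
      ggplot2::labs(x = "value (Å)", y = "count") +
      ggplot2::theme_minimal()
    p <- patchwork::wrap_plots(p, ph, ncol = 2, widths = c(3, 1))
  }
  p
}

#' Per-residue flexibility profile overlay
#'
#' Overlays the normalized per-residue scores of a flexibility profile —
#' AF2-score (black), RMSF (red), external disorder score (blue, dashed),
#' square-root B-factor (brown) — against residue index, all in arbitrary
#' units after min-max normalization.
#'
#' @param profile a [flexibility_profile()] tibble.
#' @return A ggplot object.
#' @export
plot_flexibility_profile <- function(profile) {
  cols <- c(af2_score = "black", rmsf_norm = "red",
            external_disorder = "blue", sqrt_b_norm = "brown")
  present <- intersect(names(cols), names(profile))
  if (length(present) == 0L) abort("No plottable score columns in profile.")
  long <- tidyr::pivot_longer(profile[, c("residue", present)],
                              -"residue", names_to = "score",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$residue, y = .data$value,
                                     colour = .data$score,
                                     linetype = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = cols[present]) +
    ggplot2::scale_linetype_manual(
      values = stats::setNames(
        ifelse(present == "external_disorder", "dashed", "solid"), present)) +
    ggplot2::labs(x = "residue", y = "score (AU)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dv_matrix <- function(object, ...) plot_matrix_heatmap(object, ...)

#' @export
autoplot.pae_matrix <- function(object, ...) plot_matrix_heatmap(object, ...)

#' @export
autoplot.dccm_matrix <- function(object, ...) {
  plot_matrix_heatmap(unclass(object),
                      breaks = seq(-1, 1, length.out = 257), ...)
}

#' @export
autoplot.rmsf_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$residue, y = .data$rmsf)) +
    ggplot2::geom_line(colour = "red") +
    ggplot2::labs(x = "residue", y = "RMSF (Å)") +
    ggplot2::theme_minimal()
}
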