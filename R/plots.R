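#' Plot the per-patient coverage summary
#'
#' Bars of the tumor coverage percentage per patient with the cohort
#' mean as a dashed reference line.
#'
#' @param object A [build_coverage_table()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.coverage_summary <- function(object, ...) {
  pts <- object$patients
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$subject_id, y = .data$coverage_percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = mean(pts$coverage_percent), linetype = 2) +
    ggplot2::labs(x = NULL, y = "Tumor coverage (%)",
                  title = "Tracer coverage of the tumor volume per patient") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot an axial slice of a phantom case
#'
#' Shows the post-minus-pre difference image for one axial slice with
#' the ground-truth distribution mask outlined, a quick visual check of
#' the phantom construction and segmentation.
#'
#' @param case A [generate_phantom()] result.
#' @param k Axial slice index (default: infusate centre slice).
#' @param vd_mask Optional recovered [binary_mask()] to overlay.
#' @return A ggplot object.
#' @export
plot_phantom_slice <- function(case, k = NULL, vd_mask = NULL) {
  stopifnot(inherits(case, "phantom_case"))
  sp <- case$spec$spacing_mm
  k <- k %||% (round(case$spec$infusate_center_mm[3] / sp[3]) + 1L)
  diff <- case$post_t1$voxels[, , k] - case$pre_t1$voxels[, , k]
  d <- dim(diff)
  df <- tidyr::expand_grid(i = seq_len(d[1]), j = seq_len(d[2]))
  df$value <- diff[cbind(df$i, df$j)]
  df$truth <- case$vd_truth$voxels[, , k][cbind(df$i, df$j)]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_viridis_c(name = "post - pre") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Phantom difference image, slice k = %d", k),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if (any(df$truth)) {
    p <- p + ggplot2::geom_contour(ggplot2::aes(z = as.numeric(.data$truth)),
                                   breaks = 0.5, colour = "white")
  }
  if (!is.null(vd_mask)) {
    df$recovered <- vd_mask$voxels[, , k][cbind(df$i, df$j)]
    if (any(df$recovered)) {
      p <- p + ggplot2::geom_contour(data = df,
                                     ggplot2::aes(z = as.numeric(.data$recovered)),
                                     breaks = 0.5, colour = "red")
    }
  }
  p
}
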