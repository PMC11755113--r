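#' Axial slice map of a voxel-weight pattern
#'
#' Renders one axial slice of a pattern's voxel weights on its common-mask
#' grid, with a diverging palette (negative weights: lower uptake associated
#' with the modeled state; positive: higher).
#'
#' @param pattern A `voxel_pattern` (or plain weight vector over the mask).
#' @param mask Logical 3-D array the weights were vectorized on.
#' @param slice Axial slice index (default: middle).
#' @return A ggplot.
#' @export
plot_pattern_slice <- function(pattern, mask, slice = NULL) {
  weights <- if (inherits(pattern, "voxel_pattern")) pattern$weights else as.numeric(pattern)
  vol <- unvectorize(weights, mask)
  slice <- slice %||% ceiling(dim(vol)[3] / 2)
  df <- expand.grid(x = seq_len(dim(vol)[1]), y = seq_len(dim(vol)[2]))
  df$weight <- as.vector(vol[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "grey95", high = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0("Pattern weights, axial slice ", slice),
                  fill = "Weight") +
    ggplot2::theme_minimal()
}
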