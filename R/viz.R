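#' Color-map a grayscale slice
#'
#' Min-max normalizes a slice and looks each pixel up in a perceptual
#' blue-to-yellow colormap (viridis by default), so low intensities render
#' blue and high intensities yellow. A constant slice renders as the
#' mid-colormap color. The mapping is rank-preserving in intensity.
#'
#' @param s an `mri_slice` or numeric matrix.
#' @param colormap a palette name accepted by [grDevices::hcl.colors()]
#'   (default `"viridis"`).
#' @param source provenance tag, `"generated"` or `"real"`.
#' @return A `color_mapped_slice`: list with `rgb` (rows x cols x 3 array in
#'   `[0, 1]`), `source` and `colormap_name`.
#' @export
color_map_slice <- function(s, colormap = "viridis",
                            source = c("generated", "real")) {
  source <- match.arg(source)
  a <- if (inherits(s, "mri_slice")) slice_data(s) else as.matrix(s)
  if (length(a) < 1L) stop("slice must be non-empty", call. = FALSE)
  lo <- min(a); hi <- max(a)
  u <- if (hi > lo) (a - lo) / (hi - lo) else array(0.5, dim = dim(a))
  ramp <- grDevices::colorRamp(grDevices::hcl.colors(256, colormap))
  cols <- ramp(as.vector(u)) / 255
  rgb <- array(0, dim = c(dim(a), 3L))
  rgb[, , 1L] <- cols[, 1L]
  rgb[, , 2L] <- cols[, 2L]
  rgb[, , 3L] <- cols[, 3L]
  structure(list(rgb = rgb, source = source, colormap_name = colormap),
            class = "color_mapped_slice")
}

#' @export
print.color_mapped_slice <- function(x, ...) {
  d <- dim(x$rgb)
  cat(sprintf("<color_mapped_slice> %d x %d (%s, colormap %s)\n",
              d[1], d[2], x$source, x$colormap_name))
  invisible(x)
}

slice_to_df <- function(a, panel) {
  data.frame(row = rep(seq_len(nrow(a)), times = ncol(a)),
             col = rep(seq_len(ncol(a)), each = nrow(a)),
             value = as.vector(a), panel = panel)
}

#' Side-by-side comparison of generated and real slices
#'
#' Renders the two slices as adjacent color-mapped panels on a single
#' shared color scale, so a given intensity displays as the same color in
#' both panels and the images are directly comparable. Panels are never
#' rescaled independently.
#'
#' @param generated,real `mri_slice`s or matrices of identical shape.
#' @param colormap palette name for [ggplot2::scale_fill_viridis_c()]-style
#'   gradient (passed to `hcl.colors`).
#' @return A ggplot object with panels "generated" and "real".
#' @export
side_by_side <- function(generated, real, colormap = "viridis") {
  g <- if (inherits(generated, "mri_slice")) slice_data(generated) else as.matrix(generated)
  r <- if (inherits(real, "mri_slice")) slice_data(real) else as.matrix(real)
  check_same_shape(g, r)
  df <- rbind(slice_to_df(g, "generated"), slice_to_df(r, "real"))
  ggplot2::ggplot(df, ggplot2::aes(x = col, y = row, fill = value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::scale_fill_gradientn(colours = grDevices::hcl.colors(256, colormap)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "intensity") +
    ggplot2::theme_minimal()
}

#' Signed intensity difference between slices
#'
#' Computes `generated - real` per pixel. Where the generation step boosts
#' regional feature intensity, the map is positive over that region.
#'
#' @param generated,real `mri_slice`s or matrices of identical shape.
#' @return An `mri_slice` of signed differences.
#' @export
intensity_difference_map <- function(generated, real) {
  g <- if (inherits(generated, "mri_slice")) slice_data(generated) else as.matrix(generated)
  r <- if (inherits(real, "mri_slice")) slice_data(real) else as.matrix(real)
  check_same_shape(g, r)
  as_slice(g - r,
           axis = attr(generated, "axis") %||% "axial",
           index = attr(generated, "index") %||% 1L)
}

#' Plot a slice or difference map
#'
#' Difference maps (slices containing negative values) use a diverging
#' blue-white-red scale centered at zero; plain slices use the blue-to-
#' yellow perceptual scale.
#'
#' @param object an `mri_slice`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mri_slice <- function(object, ...) {
  a <- slice_data(object)
  df <- slice_to_df(a, "slice")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = col, y = row, fill = value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "intensity") +
    ggplot2::theme_minimal()
  if (min(a) < 0 && max(a) > 0) {
    lim <- max(abs(a))
    p <- p + ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                           high = "#b2182b",
                                           limits = c(-lim, lim))
  } else {
    p <- p + ggplot2::scale_fill_gradientn(
      colours = grDevices::hcl.colors(256, "viridis"))
  }
  p
}
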