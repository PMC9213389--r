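#' Orthogonal-slice overlay of a class-activation map on a CT subvolume
#'
#' Renders axial, coronal and sagittal slices through a chosen voxel with
#' the Grad-CAM++ activation overlaid on the HU image, the usual way
#' volumetric attention maps are inspected.
#'
#' @param volume HU array (or normalized array) congruent with the heatmap.
#' @param heatmap A `heatmap_result` or activation array in `[0, 1]`.
#' @param centre 0-based voxel triple the three slices pass through
#'   (defaults to the grid centre).
#' @param alpha_max Maximum overlay opacity.
#' @return A ggplot object with one panel per plane.
#' @export
plot_heatmap_overlay <- function(volume, heatmap, centre = NULL,
                                 alpha_max = 0.7) {
  act <- if (inherits(heatmap, "heatmap_result")) heatmap$activation
         else heatmap
  stopifnot(identical(dim(volume)[1:3], dim(act)))
  d <- dim(act)
  if (is.null(centre)) centre <- (d - 1) %/% 2
  cx <- centre + 1
  slice_df <- function(plane) {
    sl <- switch(plane,
                 axial = list(img = volume[, , cx[3]], cam = act[, , cx[3]]),
                 coronal = list(img = volume[, cx[2], ], cam = act[, cx[2], ]),
                 sagittal = list(img = volume[cx[1], , ], cam = act[cx[1], , ]))
    g <- expand.grid(i = seq_len(nrow(sl$img)), j = seq_len(ncol(sl$img)))
    tibble(plane = plane, i = g$i, j = g$j,
           hu = as.numeric(sl$img), cam = as.numeric(sl$cam))
  }
  df <- dplyr::bind_rows(lapply(c("axial", "coronal", "sagittal"), slice_df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$hu)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::geom_raster(ggplot2::aes(alpha = .data$cam), fill = "red") +
    ggplot2::scale_alpha(range = c(0, alpha_max), guide = "none") +
    ggplot2::facet_wrap(~plane) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Grad-CAM++ class activation overlay")
}
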