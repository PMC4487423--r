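#' Plot a rocking curve
#'
#' Intensity against mid-exposure angle with one-sigma error bars and,
#' when the curve was fitted, the Gaussian model overlaid.
#'
#' @param curve A `rocking_curve` from [extract_rocking_curve()].
#' @return A ggplot object.
#' @export
plot_rocking_curve <- function(curve) {
  stopifnot(inherits(curve, "rocking_curve"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    me_stop("plotting requires the ggplot2 package", "invalid_argument")
  df <- curve$curve
  p <- ggplot2::ggplot(df, ggplot2::aes(x = phi_mid,
                                        y = intensity)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = intensity - sigma,
                                        ymax = intensity + sigma),
                           width = 0) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(phi ~ "(degrees)"),
                  y = "integrated intensity (counts)") +
    ggplot2::theme_minimal()
  if (is.finite(curve$peak_phi) && is.finite(curve$fwhm) &&
      !"single_frame" %in% curve$flags) {
    s <- curve$fwhm / (2 * sqrt(2 * log(2)))
    amp <- max(df$intensity) - min(df$intensity)
    grid <- data.frame(phi_mid = seq(min(df$phi_mid), max(df$phi_mid),
                                     length.out = 200))
    grid$intensity <- min(df$intensity) +
      amp * exp(-(grid$phi_mid - curve$peak_phi)^2 / (2 * s^2))
    p <- p + ggplot2::geom_line(data = grid, linetype = "dashed")
  }
  p
}

#' Plot found spots over a diffraction image
#'
#' @param image Pixel matrix or [smv_image()].
#' @param spots Tibble from [find_spots()].
#' @param trim Upper display quantile for the grey scale.
#' @return A ggplot object.
#' @export
plot_spots <- function(image, spots, trim = 0.999) {
  if (inherits(image, "smv_image")) image <- image$pixels
  if (!requireNamespace("ggplot2", quietly = TRUE))
    me_stop("plotting requires the ggplot2 package", "invalid_argument")
  d <- dim(image)
  df <- data.frame(x = rep(seq_len(d[1]), times = d[2]),
                   y = rep(seq_len(d[2]), each = d[1]),
                   value = pmin(as.vector(image),
                                stats::quantile(image, trim)))
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::geom_point(data = spots, shape = 1, colour = "red", size = 3) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
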