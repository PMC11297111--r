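#' Plot NCFS feature weights along the wavelength axis
#'
#' @param object an [ncfs_fit()].
#' @param thresholds threshold fractions drawn as horizontal guides.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ncfs_fit <- function(object, thresholds = c(0.5, 0.75), ...) {
  d <- tidy(object)
  x_var <- if (all(is.na(d$wavelength))) "feature" else "wavelength"
  p <- ggplot2::ggplot(d, ggplot2::aes(.data[[x_var]], .data$weight)) +
    ggplot2::geom_point(colour = "firebrick", size = 1) +
    ggplot2::geom_hline(yintercept = thresholds * max(d$weight),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = if (x_var == "wavelength") "wavelength [nm]" else "feature index",
                  y = "NCFS feature weight")
  p
}

#' Plot the feature-count / F1 trade-off curve
#'
#' @param object a [feature_curve()] tibble.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.feature_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$n_bands, .data$f1)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$fraction)), size = 2) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "retained wavelengths", y = "1-NN F1 score",
                  colour = "threshold")
}

#' Display a segmentation overlay
#'
#' Renders the pseudo-colour image with the class overlay (yellow = human,
#' blue = animal) as a raster.
#'
#' @param object a [segment_image()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.blood_segmentation <- function(object, ...) {
  ov <- object$overlay
  d <- dim(ov)
  df <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  df$fill <- grDevices::rgb(ov[, , 1], ov[, , 2], ov[, , 3])
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$fill)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Plot mean spectra by group
#'
#' @param data labelled-spectra tibble.
#' @param by grouping column name (default `"species"`).
#' @return A ggplot of group-mean spectra against wavelength.
#' @export
plot_mean_spectra <- function(data, by = "species") {
  wl <- spectra_wavelengths(data)
  m <- spectra_matrix(data)
  groups <- data[[by]]
  d <- bind_rows(lapply(unique(groups), function(g) {
    tibble(group = g, wavelength = wl,
           reflectance = colMeans(m[groups == g, , drop = FALSE]))
  }))
  ggplot2::ggplot(d, ggplot2::aes(.data$wavelength, .data$reflectance,
                                  colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength [nm]", y = "reflectance", colour = by)
}
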