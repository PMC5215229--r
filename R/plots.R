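#' Plot spectra of a data set
#'
#' Overlays up to `max_spectra` spectra against wavenumber (or channel
#' index when no axis is stored).
#'
#' @param object A [raman_dataset()].
#' @param max_spectra Upper bound on the number of spectra drawn.
#' @param alpha Line transparency.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot raman_dataset
#' @export
autoplot.raman_dataset <- function(object, max_spectra = 50, alpha = 0.4, ...) {
  m <- nrow(object$intensities)
  keep <- if (m > max_spectra)
    sort(sample.int(m, max_spectra)) else seq_len(m)
  df <- as_tibble(raman_dataset(object$intensities[keep, , drop = FALSE],
                                wavenumber = object$wavenumber))
  df$spectrum <- factor(keep[df$spectrum])
  xvar <- if (!is.null(object$wavenumber)) "wavenumber" else "channel"
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[xvar]], y = .data$intensity,
                                   group = .data$spectrum)) +
    ggplot2::geom_line(alpha = alpha, linewidth = 0.3) +
    ggplot2::labs(
      x = if (xvar == "wavenumber") expression(Wavenumber ~ (cm^-1)) else "Channel",
      y = "Intensity (counts)") +
    ggplot2::theme_minimal()
}

#' Plot an airPLS fit
#'
#' Original spectrum, fitted baseline and corrected spectrum for one
#' spectrum.
#'
#' @param object An `"airpls_fit"`.
#' @param x Optional original spectrum (`baseline + corrected` is used when
#'   omitted).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot airpls_fit
#' @export
autoplot.airpls_fit <- function(object, x = NULL, ...) {
  if (is.null(x)) x <- object$baseline + object$corrected
  df <- tibble::tibble(
    channel = rep(seq_along(x), 3),
    intensity = c(x, object$baseline, object$corrected),
    trace = rep(c("original", "baseline", "corrected"), each = length(x))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel, y = .data$intensity,
                                   colour = .data$trace)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "Channel", y = "Intensity (counts)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a despiking result
#'
#' One panel per affected spectrum (up to `max_spectra`): the input, the
#' corrected trace and the replaced zones.
#'
#' @param object A `"despike_result"`.
#' @param input The matrix that was despiked; defaults to reconstructing
#'   unaffected channels from the result (replaced channels are drawn from
#'   the corrected trace only).
#' @param max_spectra Upper bound on panels.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot despike_result
#' @export
autoplot.despike_result <- function(object, input = NULL, max_spectra = 6, ...) {
  affected <- which(rowSums(object$spike_mask) > 0)
  if (!length(affected)) affected <- 1L
  keep <- head(affected, max_spectra)
  if (is.null(input)) input <- object$corrected
  input <- as_spectra_matrix(input)
  n <- ncol(object$corrected)
  df <- dplyr::bind_rows(lapply(keep, function(i) {
    tibble::tibble(
      spectrum = i,
      channel = rep(seq_len(n), 2),
      intensity = c(input[i, ], object$corrected[i, ]),
      trace = rep(c("input", "corrected"), each = n),
      masked = rep(object$spike_mask[i, ], 2)
    )
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel, y = .data$intensity,
                                   colour = .data$trace)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_rug(data = df[df$masked & df$trace == "corrected", ],
                      sides = "b", colour = "red", alpha = 0.5) +
    ggplot2::facet_wrap(~spectrum, scales = "free_y") +
    ggplot2::labs(x = "Channel", y = "Intensity (counts)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot principal-component score maps
#'
#' @param object A `"pca_score_maps"` tibble from [pca_score_maps()].
#' @param ... Unused.
#' @return A ggplot object: one raster panel per component.
#' @method autoplot pca_score_maps
#' @export
autoplot.pca_score_maps <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$col, y = .data$row,
                                       fill = .data$score)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~component) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Column", y = "Row", fill = "Score") +
    ggplot2::theme_minimal()
}
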