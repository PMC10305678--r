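eem_long <- function(eem) {
  tibble::tibble(
    em_nm = rep(eem$em_wavelengths, times = length(eem$ex_wavelengths)),
    ex_nm = rep(eem$ex_wavelengths, each = length(eem$em_wavelengths)),
    intensity = as.vector(eem$intensity))
}

#' Plot an EEM as a filled raster
#'
#' @param object An `eem`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot eem
#' @export
autoplot.eem <- function(object, ...) {
  ggplot2::ggplot(eem_long(object),
                  ggplot2::aes(x = .data$ex_nm, y = .data$em_nm,
                               fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "intensity (a.u.)") +
    ggplot2::labs(x = "excitation (nm)", y = "emission (nm)") +
    ggplot2::theme_minimal()
}

#' Plot the real part of a Gabor kernel
#'
#' @param object A `gabor_kernel`.
#' @param part `"real"` or `"imag"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gabor_kernel
#' @export
autoplot.gabor_kernel <- function(object, part = c("real", "imag"), ...) {
  part <- match.arg(part)
  m <- object[[part]]
  h <- (object$K - 1) / 2
  df <- tibble::tibble(x = rep(-h:h, each = object$K),
                       y = rep(-h:h, times = object$K),
                       value = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(name = part) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' Plot the training history of a fitted fusion network
#'
#' @param object A `fusion_fit`.
#' @param ... Unused.
#' @return A ggplot with loss and validation R-squared panels.
#' @method autoplot fusion_fit
#' @export
autoplot.fusion_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history,
                           c("train_loss", "val_loss", "val_r2"),
                           names_to = "series")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of retrieved versus true COD
#'
#' @param predictions,truths COD values in mg/L.
#' @return A ggplot with the identity line.
#' @export
plot_retrieval <- function(predictions, truths) {
  df <- tibble::tibble(truth = truths, prediction = predictions)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$truth, y = .data$prediction)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = "true COD (mg/L)", y = "retrieved COD (mg/L)") +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
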