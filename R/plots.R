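#' Plot one or more spectra
#'
#' @param spectra A spectrum tibble or a (optionally named) list of them.
#' @param labels Optional labels overriding list names.
#' @return A ggplot object.
#' @export
plot_spectra <- function(spectra, labels = NULL) {
  if (is.data.frame(spectra)) spectra <- list(spectra)
  labels <- labels %||% names(spectra) %||%
    paste0("spectrum ", seq_along(spectra))
  df <- purrr::map2_dfr(spectra, labels, function(s, lab) {
    dplyr::mutate(as_spectrum_tbl(s), label = lab)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$wavenumber, .data$intensity,
                                   colour = .data$label)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = expression(paste("Raman shift (", cm^-1, ")")),
                  y = "Intensity", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Loss and validation-accuracy curves of a training run
#'
#' @param object A `sers_fit` from [train()].
#' @param ... Unused.
#' @return A ggplot object (faceted loss terms and accuracies by step).
#' @export
autoplot.sers_fit <- function(object, ...) {
  df <- dplyr::select(object$history, "step", "L_cls", "L_evi", "L_reg",
                      "total", "pure_val_acc", "seven_cat_val_acc")
  long <- tidyr::pivot_longer(df, -"step", names_to = "series")
  ggplot2::ggplot(long, ggplot2::aes(.data$step, .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "training step", y = NULL) +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap
#'
#' @param object A `sers_confusion` from [confusion()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sers_confusion <- function(object, ...) {
  df <- tidy.sers_confusion(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}

#' Overlay a Grad-CAM attribution map on its spectrum
#'
#' @param s Feature spectrum tibble used for the attribution.
#' @param cam Attribution tibble from [grad_cam()].
#' @return A ggplot object.
#' @export
plot_attribution <- function(s, cam) {
  s <- as_spectrum_tbl(s)
  df <- tibble(wavenumber = s$wavenumber, intensity = s$intensity,
               attribution = cam$attribution)
  ggplot2::ggplot(df, ggplot2::aes(.data$wavenumber)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = 0, ymax = .data$attribution),
      fill = "tomato", alpha = 0.3
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$intensity),
                       colour = "grey20", linewidth = 0.3) +
    ggplot2::labs(x = expression(paste("Raman shift (", cm^-1, ")")),
                  y = "normalised intensity / attribution") +
    ggplot2::theme_minimal()
}
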