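# ggplot2 visualization helpers.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

matrix_to_df <- function(m, value_name = "value") {
  tibble::tibble(
    row = rep(seq_len(nrow(m)), ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    !!value_name := as.vector(m)
  )
}

#' Plot a phantom case
#'
#' Grey-scale image of one modality with the uterus and lesion mask
#' outlines overlaid.
#'
#' @param object A `phantom_case`.
#' @param modality Image channel to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phantom_case <- function(object, modality = "T1c", ...) {
  df <- matrix_to_df(object$images[[modality]])
  du <- matrix_to_df(object$uterus_mask, "mask")
  dl <- matrix_to_df(object$lesion_mask, "mask")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::geom_contour(
      data = du, ggplot2::aes(z = .data$mask), breaks = 0.5,
      colour = "#4daf4a", linewidth = 0.4
    ) +
    ggplot2::geom_contour(
      data = dl, ggplot2::aes(z = .data$mask), breaks = 0.5,
      colour = "#e41a1c", linewidth = 0.4
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("%s (%s)", object$case_id, modality),
      subtitle = sprintf(
        "true invasion fraction %.2f, stage %s",
        object$truth$true_fraction, object$truth$true_stage
      ),
      x = NULL, y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot training curves
#'
#' Train/validation Dice loss and per-structure validation IoU by epoch,
#' with the selected checkpoint marked.
#'
#' @param object A `myo_training`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.myo_training <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$value,
                                  colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2,
                        colour = "grey50") +
    ggplot2::labs(
      title = "Training curves",
      subtitle = sprintf("checkpoint: epoch %d (min validation loss)",
                         object$best_epoch),
      y = NULL, colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Box-and-whisker plot of invasion fractions by concordance group
#'
#' Displays the distribution of estimated invasion fractions for
#' compatible IA, discrepant, and compatible IB cases - the pattern where
#' discrepancies concentrate near the 50% cutoff.
#'
#' @param staging Tibble with `fraction`, `stage`, `true_stage`.
#' @return A ggplot object.
#' @export
plot_fraction_by_concordance <- function(staging) {
  st <- staging[!is.na(staging$stage), ]
  st$group <- dplyr::case_when(
    st$stage == st$true_stage & st$true_stage == "IA" ~ "IA/IA (compatible)",
    st$stage == st$true_stage & st$true_stage == "IB" ~ "IB/IB (compatible)",
    TRUE ~ "Discrepancy"
  )
  st$group <- factor(st$group, c("IA/IA (compatible)", "Discrepancy",
                                 "IB/IB (compatible)"))
  ggplot2::ggplot(st, ggplot2::aes(.data$group, .data$fraction)) +
    ggplot2::geom_boxplot(width = 0.5, outlier.shape = 1) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::labs(
      x = NULL, y = "invasion fraction",
      title = "Invasion fraction by staging concordance"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a radial profile and junction estimate
#'
#' @param object A `ray_profile`.
#' @param r_junction_hat Optional junction estimate to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ray_profile <- function(object, r_junction_hat = NULL, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[object$valid, ],
    c("r_serosa", "r_lesion"), names_to = "curve", values_to = "radius"
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$theta, .data$radius,
                                        colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "angle (rad)", y = "radius (px)", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(r_junction_hat)) {
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(theta = object$theta, radius = r_junction_hat,
                            curve = "r_junction_hat"),
      linetype = 2
    )
  }
  p
}
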