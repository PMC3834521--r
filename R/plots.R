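sfi_levels <- c("positive", "zero", "negative")

#' Plot the developmental curves of a relational-shift simulation
#'
#' Mean accuracy by SFI type over training epochs, with the chance line at
#' 0.5.
#'
#' @param object An `analogy_sim1`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.analogy_sim1 <- function(object, ...) {
  curve <- developmental_curve(object)
  curve$sfi_label <- factor(curve$sfi_label, levels = sfi_levels)
  ggplot2::ggplot(curve, ggplot2::aes(.data$epoch, .data$accuracy,
                                      colour = .data$sfi_label)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "training epoch", y = "proportion correct",
                  colour = "SFI",
                  title = "Development of analogy performance by problem type") +
    ggplot2::theme_minimal()
}

#' @export
plot.analogy_sim1 <- function(x, ...) print(autoplot(x, ...))

#' Plot the lesion-condition accuracies of an FTLD simulation
#'
#' Grouped bars: mean accuracy per condition (control, frontal, temporal)
#' and SFI type.
#'
#' @param object An `analogy_sim2`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.analogy_sim2 <- function(object, ...) {
  df <- object$summary |>
    tidyr::pivot_longer(dplyr::all_of(paste0("accuracy_", sfi_levels)),
                        names_to = "sfi_label", values_to = "accuracy") |>
    dplyr::mutate(sfi_label = factor(sub("accuracy_", "", .data$sfi_label),
                                     levels = sfi_levels),
                  condition = factor(.data$condition,
                                     levels = c("control", "frontal",
                                                "temporal")))
  ggplot2::ggplot(df, ggplot2::aes(.data$condition, .data$accuracy,
                                   fill = .data$sfi_label)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "proportion correct", fill = "SFI",
                  title = "Analogy performance by lesion condition") +
    ggplot2::theme_minimal()
}

#' @export
plot.analogy_sim2 <- function(x, ...) print(autoplot(x, ...))
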