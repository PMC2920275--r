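# ggplot2 visualisations of fitted result objects.

#' Plot per-size cross-validation metrics
#'
#' Shows cross-validation consistency (bars) and mean prediction accuracy
#' (points/line) per model size, mirroring the tables used to pick the final
#' model.
#'
#' @param object An `mdr_cv` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mdr_cv <- function(object, ...) {
  df <- tidy(object)
  df$final <- df$k == object$final$k
  long <- tidyr::pivot_longer(
    dplyr::mutate(df, cvc = .data$cvc / object$m),
    c("cvc", "mean_pa"), names_to = "metric", values_to = "value")
  long$metric <- dplyr::recode(long$metric,
                               cvc = "CVC (fraction of folds)",
                               mean_pa = "mean prediction accuracy")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$k), y = .data$value,
                                     fill = .data$final)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey65", `TRUE` = "#2b8cbe")) +
    ggplot2::labs(x = "model size k", y = NULL,
                  title = "Cross-validation model selection") +
    ggplot2::theme_minimal()
}

#' Plot stage accuracies of a three-way-split run
#'
#' @param object An `mdr_3ws` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mdr_3ws <- function(object, ...) {
  df <- tidy(object)
  cols <- intersect(c("testing_ba", "validation_ba"), names(df))
  long <- tidyr::pivot_longer(df, dplyr::all_of(cols),
                              names_to = "stage", values_to = "ba")
  long$stage <- sub("_ba$", "", long$stage)
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$k), y = .data$ba,
                                     colour = .data$stage, group = .data$stage)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "model size k", y = "balanced accuracy",
                  title = "Three-way split stage accuracies") +
    ggplot2::theme_minimal()
}

#' Plot a power-study summary
#'
#' Conservative and liberal power with +/- 1 SE error bars.
#'
#' @param object An `mdr_power` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mdr_power <- function(object, ...) {
  s <- object$summary
  df <- tibble::tibble(
    definition = factor(c("conservative", "liberal"),
                        levels = c("conservative", "liberal")),
    power = c(s$conservative_power, s$liberal_power),
    se = c(s$se_conservative, s$se_liberal)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$definition, y = .data$power)) +
    ggplot2::geom_col(fill = "#2b8cbe", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(.data$power - .data$se, 0),
                                        ymax = pmin(.data$power + .data$se, 1)),
                           width = 0.15) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "power",
                  title = sprintf("Power over %d replicates (%s)",
                                  s$n_datasets, s$method)) +
    ggplot2::theme_minimal()
}
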