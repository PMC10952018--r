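#' Plot a Kaplan-Meier curve
#'
#' Step plot of the product-limit estimate, starting at S(0) = 1, with
#' censoring marks.
#'
#' @param object a `km_curve` from [km_estimate()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(time = 0, survival = 1),
    tibble::as_tibble(object)[, c("time", "survival")]
  )
  cens <- tibble::as_tibble(object) |> dplyr::filter(.data$n_censor > 0)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Survival probability") +
    ggplot2::theme_minimal()
  if (nrow(cens) > 0) {
    p <- p + ggplot2::geom_point(data = cens, shape = 3)
  }
  p
}

#' Plot an ROC curve with its Youden cutoff
#'
#' @param object a `roc_result` from [roc_youden()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.roc_result <- function(object, ...) {
  df <- tibble::tibble(
    fpr = c(1, 1 - object$curve$specificity, 0),
    tpr = c(1, object$curve$sensitivity, 0)
  )
  at <- which(object$curve$cutoff == object$youden_cutoff)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::annotate(
      "point",
      x = 1 - object$curve$specificity[at],
      y = object$curve$sensitivity[at], colour = "red"
    ) +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("AUC = %.3f, Youden cutoff = %.3g",
                      object$auc, object$youden_cutoff)
    ) +
    ggplot2::theme_minimal()
}

#' Plot stratified survival curves for the synergy analysis
#'
#' @param object a `synergy_result` from [synergy_analysis()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.synergy_result <- function(object, ...) {
  df <- object$curves |>
    dplyr::group_by(.data$stratum) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble::tibble(time = 0, survival = 1), .x[, c("time", "survival")]
    )) |>
    dplyr::ungroup() |>
    dplyr::mutate(stratum = factor(.data$stratum,
                                   levels = c("neither", "either", "both")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$stratum)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Survival probability",
                  colour = "Group") +
    ggplot2::theme_minimal()
}
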