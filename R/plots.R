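#' Plot a Kaplan-Meier curve
#'
#' @param object A `km_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(time = 0, surv = 1),
    tibble::as_tibble(object)[, c("time", "surv")]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Plot stratified survival curves
#'
#' @param object A `strata_result`.
#' @param ... Unused.
#' @return A ggplot with one KM step per risk group and the log-rank p.
#' @export
autoplot.strata_result <- function(object, ...) {
  df <- purrr::imap_dfr(object$km, function(km, g) {
    if (is.null(km)) return(NULL)
    dplyr::bind_rows(tibble::tibble(time = 0, surv = 1),
                     tibble::as_tibble(km)[, c("time", "surv")]) |>
      dplyr::mutate(group = g)
  })
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                        color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  color = "Risk group") +
    ggplot2::theme_minimal()
  if (!is.null(object$logrank)) {
    p <- p + ggplot2::ggtitle(sprintf("Log-rank chi2 = %.1f, p = %.2g",
                                      object$logrank$chisq,
                                      object$logrank$p.value))
  }
  p
}

#' Plot a decision curve
#'
#' @param object A `net_benefit_curve`.
#' @param ... Unused.
#' @return A ggplot of net benefit against threshold probability.
#' @export
autoplot.net_benefit_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$threshold,
                                       y = .data$net_benefit,
                                       color = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Threshold probability", y = "Net benefit") +
    ggplot2::theme_minimal()
}

#' Plot a calibration curve
#'
#' @param object A `calibration_curve`.
#' @param ... Unused.
#' @return A ggplot of observed against predicted survival with the
#'   identity diagonal.
#' @export
autoplot.calibration_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$predicted,
                                       y = .data$observed)) +
    ggplot2::geom_abline(linetype = 2, color = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Predicted survival", y = "Observed survival (KM)") +
    ggplot2::theme_minimal()
}

#' Plot per-repeat cross-validation metrics
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot of the per-repeat metric distribution.
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$runs, c("cindex", "auc", "brier", "ibs"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "Per-repeat value") +
    ggplot2::theme_minimal()
}

#' Plot global mask importance
#'
#' @param importance The `global` tibble from [aggregate_importance()].
#' @return A ggplot bar chart of per-feature attention importance.
#' @export
plot_importance <- function(importance) {
  ggplot2::ggplot(importance,
                  ggplot2::aes(x = stats::reorder(.data$feature,
                                                  .data$importance),
                               y = .data$importance)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Aggregated attention importance") +
    ggplot2::theme_minimal()
}
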