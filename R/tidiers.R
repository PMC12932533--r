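#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a linear Cox fit
#'
#' One row per term with hazard ratio, Wald confidence interval and
#' p-value, mirroring the usual clinical HR table.
#'
#' @param x A `linear_cox` from [fit_linear_coxph()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.linear_cox <- function(x, ...) x$table

#' @rdname tidy.linear_cox
#' @export
glance.linear_cox <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, n_terms = length(x$coef),
                 iter = x$iter, converged = x$converged)
}

#' Tidy a fitted risk model's training log
#'
#' @param x A `risk_model`.
#' @param ... Unused.
#' @return Tibble with per-epoch training and stopping-set losses.
#' @export
tidy.risk_model <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$log$train_loss),
                 train_loss = x$log$train_loss,
                 stop_loss = x$log$stop_loss)
}

#' @rdname tidy.risk_model
#' @export
glance.risk_model <- function(x, ...) {
  tibble::tibble(kind = x$kind,
                 n_parameters = length(flatten_params(x$par)),
                 epochs_run = x$log$epochs_run,
                 stop_epoch = x$log$stop_epoch,
                 final_stop_loss = min(x$log$stop_loss))
}

#' Tidy an evaluation report
#'
#' @param x An `eval_report` from [repeated_cv()].
#' @param ... Unused.
#' @return The per-repeat metric tibble.
#' @export
tidy.eval_report <- function(x, ...) x$runs

#' @rdname tidy.eval_report
#' @export
glance.eval_report <- function(x, ...) x$summary

#' Tidy a stratification result
#'
#' @param x A `strata_result`.
#' @param ... Unused.
#' @return Per-patient tibble with score and group.
#' @export
tidy.strata_result <- function(x, ...) {
  tibble::tibble(score = x$scores, group = x$group)
}

#' @rdname tidy.strata_result
#' @export
glance.strata_result <- function(x, ...) {
  out <- tibble::tibble(cutoff = x$cutoff, searched = x$searched,
                        n_low = sum(x$group == "low"),
                        n_high = sum(x$group == "high"))
  if (!is.null(x$logrank)) {
    out$chisq <- x$logrank$chisq
    out$p.value <- x$logrank$p.value
  }
  out
}

#' Tidy a clustering of high-risk profiles
#'
#' @param x A `highrisk_clusters`.
#' @param ... Unused.
#' @return Tibble of cluster labels per patient.
#' @export
tidy.highrisk_clusters <- function(x, ...) {
  tibble::tibble(sample = seq_along(x$labels), cluster = x$labels)
}

#' @rdname tidy.highrisk_clusters
#' @export
glance.highrisk_clusters <- function(x, ...) {
  tibble::tibble(k = x$k, n = length(x$labels))
}
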