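#' Linear Cox proportional-hazards fit (Newton-Raphson, Breslow ties)
#'
#' Maximizes the Breslow partial likelihood for the log-linear model
#' `h(x) = x' beta` by Newton-Raphson with step-halving. Standard errors
#' come from the inverse observed information; hazard ratios are
#' `exp(beta)` with Wald 95% confidence intervals and p-values.
#'
#' @param cohort A `cohort`, or a data frame accepted by [as_cohort()]
#'   already carrying `time`/`event` columns and encoded covariates.
#' @param covariates Optional character vector restricting the fit to a
#'   subset of encoded columns (default: all).
#' @param max_iter Maximum Newton iterations.
#' @param tol Convergence tolerance on the log-likelihood change.
#' @return A `linear_cox` object: list with `coef`, `se`, `loglik`,
#'   `iter`, `converged`, `baseline` (Breslow hazard at the fitted
#'   coefficients), and a `table` tibble (term, estimate, se, hr,
#'   conf.low, conf.high, p.value).
#' @export
fit_linear_coxph <- function(cohort, covariates = NULL, max_iter = 50L,
                             tol = 1e-9) {
  X <- cohort$X
  if (!is.null(covariates)) {
    missing_cov <- setdiff(covariates, colnames(X))
    if (length(missing_cov)) {
      stop("unknown covariate(s): ", paste(missing_cov, collapse = ", "),
           call. = FALSE)
    }
    X <- X[, covariates, drop = FALSE]
  }
  time <- cohort$time
  event <- cohort$event
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    stop("exact collinearity among covariates: rank ", qrX$rank, " < ", p,
         call. = FALSE)
  }
  beta <- rep(0, p)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    sc <- cox_score_info(X, time, event, beta)
    if (!all(is.finite(sc$score)) || !is.finite(sc$loglik)) {
      stop("non-finite likelihood at iteration ", iter,
           "; last beta = ", paste(signif(beta, 4), collapse = ", "),
           call. = FALSE)
    }
    step <- tryCatch(solve(sc$info, sc$score),
                     error = function(e) {
                       stop("singular information matrix at iteration ", iter,
                            call. = FALSE)
                     })
    # step-halving until the likelihood does not decrease
    sfac <- 1
    repeat {
      beta_new <- beta + sfac * step
      ll_new <- cox_score_info(X, time, event, beta_new,
                               loglik_only = TRUE)$loglik
      if (is.finite(ll_new) && ll_new >= sc$loglik - 1e-12) break
      sfac <- sfac / 2
      if (sfac < 1e-8) { beta_new <- beta; ll_new <- sc$loglik; break }
    }
    beta <- beta_new
    if (abs(ll_new - ll_old) < tol) { converged <- TRUE; ll_old <- ll_new; break }
    ll_old <- ll_new
  }
  if (!converged) {
    stop("Newton-Raphson did not converge in ", max_iter,
         " iterations; last beta = ", paste(signif(beta, 4), collapse = ", "),
         call. = FALSE)
  }
  if (any(abs(beta) > 15)) {
    warning("very large coefficient(s); possible separation: ",
            paste(colnames(X)[abs(beta) > 15], collapse = ", "))
  }
  final <- cox_score_info(X, time, event, beta)
  se <- sqrt(diag(solve(final$info)))
  z <- beta / se
  tab <- tibble::tibble(
    term = colnames(X),
    estimate = unname(beta),
    std.error = unname(se),
    hr = exp(unname(beta)),
    conf.low = exp(unname(beta - 1.959963984540054 * se)),
    conf.high = exp(unname(beta + 1.959963984540054 * se)),
    statistic = unname(z),
    p.value = 2 * stats::pnorm(-abs(unname(z)))
  )
  h <- drop(X %*% beta)
  structure(list(coef = stats::setNames(beta, colnames(X)),
                 se = stats::setNames(se, colnames(X)),
                 loglik = final$loglik, iter = iter, converged = converged,
                 table = tab,
                 baseline = breslow_baseline(h, time, event),
                 covariates = colnames(X)),
            class = "linear_cox")
}

# Breslow log partial likelihood, score and information for linear h = X beta.
# Single pass over unique times in decreasing order, accumulating
# S0 = sum e, S1 = sum e*x, S2 = sum e*x x' over the growing risk set.
cox_score_info <- function(X, time, event, beta, loglik_only = FALSE) {
  n <- nrow(X); p <- ncol(X)
  eta <- drop(X %*% beta)
  m <- max(eta)
  w <- exp(eta - m)
  ord <- order(time, decreasing = TRUE)
  ut <- unique(time[ord])
  ll <- 0
  score <- rep(0, p)
  info <- matrix(0, p, p)
  S0 <- 0; S1 <- rep(0, p); S2 <- matrix(0, p, p)
  pos <- 1L
  no <- length(ord)
  for (t in ut) {
    # absorb the tied block into the risk set
    while (pos <= no && time[ord[pos]] == t) {
      i <- ord[pos]
      S0 <- S0 + w[i]
      xi <- X[i, ]
      S1 <- S1 + w[i] * xi
      if (!loglik_only) S2 <- S2 + w[i] * tcrossprod(xi)
      pos <- pos + 1L
    }
    ev <- which(time == t & event == 1)
    d <- length(ev)
    if (d > 0L) {
      ll <- ll + sum(eta[ev]) - d * (log(S0) + m)
      if (!loglik_only) {
        mu <- S1 / S0
        score <- score + colSums(X[ev, , drop = FALSE]) - d * mu
        info <- info + d * (S2 / S0 - tcrossprod(mu))
      }
    }
  }
  list(loglik = ll, score = score, info = info)
}

#' Predict from a Newton-fitted linear Cox model
#'
#' @param object A `linear_cox`.
#' @param cohort A `cohort` or covariate matrix.
#' @param type `"risk"` (linear predictor) or `"survival"`.
#' @param times Query grid for survival predictions.
#' @param ... Unused.
#' @return Log-risks or a survival probability matrix.
#' @export
predict.linear_cox <- function(object, cohort, type = c("risk", "survival"),
                               times = NULL, ...) {
  type <- match.arg(type)
  X <- if (inherits(cohort, "cohort")) cohort$X else as.matrix(cohort)
  h <- drop(X[, object$covariates, drop = FALSE] %*% object$coef)
  if (type == "risk") return(h)
  if (is.null(times)) stop("survival prediction needs a `times` grid",
                           call. = FALSE)
  survival_from_hazard(h, object$baseline, times)
}

#' @export
print.linear_cox <- function(x, ...) {
  cat("<linear_cox> log-likelihood", signif(x$loglik, 6), "after", x$iter,
      "iterations\n")
  print(x$table)
  invisible(x)
}
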