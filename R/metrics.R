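#' Harrell's concordance index
#'
#' Over admissible pairs `(i, j)` with `t_i < t_j` and `E_i = 1`, a pair is
#' concordant when the earlier failure has the higher risk score; ties in
#' the score count 1/2. The returned value is the concordant fraction of
#' admissible pairs: 0.5 is chance, 1 perfect ranking. Invariant under any
#' strictly increasing transform of the scores.
#'
#' @param h Risk scores (higher = worse prognosis).
#' @param time Follow-up times.
#' @param event 0/1 event indicators.
#' @return Concordance in `[0, 1]`.
#' @export
concordance_index <- function(h, time, event) {
  n <- length(h)
  stopifnot(length(time) == n, length(event) == n)
  conc <- 0; tied <- 0; total <- 0
  ev <- which(event == 1)
  if (length(ev) == 0L) stop("no comparable pairs (no events)", call. = FALSE)
  for (i in ev) {
    later <- time > time[i]
    m <- sum(later)
    if (m == 0L) next
    total <- total + m
    conc <- conc + sum(h[i] > h[later])
    tied <- tied + sum(h[i] == h[later])
  }
  if (total == 0) stop("no comparable pairs", call. = FALSE)
  (conc + 0.5 * tied) / total
}

#' Kaplan-Meier survival function of the censoring distribution
#'
#' `G(t) = P(C > t)` estimated by flipping the event indicator; used for
#' inverse-probability-of-censoring weights. Returns a function evaluating
#' `G` at arbitrary times; `lag = TRUE` evaluates the left limit `G(t-)`.
#'
#' @param time Follow-up times.
#' @param event 0/1 event indicators of the *survival* outcome.
#' @return A function `G(t, lag = FALSE)`.
#' @export
censoring_survfit <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  tms <- fit$time
  srv <- fit$surv
  function(t, lag = FALSE) {
    tt <- if (lag) t - 1e-10 else t
    idx <- findInterval(tt, tms)
    c(1, srv)[idx + 1L]
  }
}

#' IPCW cumulative/dynamic AUC at a horizon
#'
#' Cases are subjects with an observed event by `tau`; controls are
#' subjects still under observation beyond `tau`. Each case is weighted by
#' `1/G(t_i-)`, each control by `1/G(tau)`, where `G` is the
#' Kaplan-Meier censoring survival function, and the AUC is the weighted
#' probability that a random case outranks a random control (score ties
#' count 1/2). With no censoring the weights are unity and this reduces to
#' the plain binary AUC for the event-by-`tau` label.
#'
#' @inheritParams concordance_index
#' @param tau Evaluation horizon.
#' @return AUC in `[0, 1]`.
#' @export
risk_auc <- function(h, time, event, tau) {
  cases <- which(time <= tau & event == 1)
  controls <- which(time > tau)
  if (length(cases) == 0L || length(controls) == 0L) {
    stop("AUC undefined: need at least one case and one control at tau",
         call. = FALSE)
  }
  G <- censoring_survfit(time, event)
  wc <- 1 / G(time[cases], lag = TRUE)
  wk <- rep(1 / G(tau), length(controls))
  hc <- h[cases]; hk <- h[controls]
  num <- 0
  for (a in seq_along(hc)) {
    num <- num + wc[a] * sum(wk * ((hc[a] > hk) + 0.5 * (hc[a] == hk)))
  }
  num / (sum(wc) * sum(wk))
}

#' IPCW Brier score at a horizon
#'
#' `BS(tau) = n^-1 sum_i [ S_i^2 1(t_i <= tau, E_i = 1)/G(t_i-) +
#' (1 - S_i)^2 1(t_i > tau)/G(tau) ]` where `S_i` is the predicted
#' survival probability at `tau` and `G` the censoring Kaplan-Meier.
#' Subjects censored before `tau` contribute zero directly (their mass is
#' carried by the weights). With no censoring this is the mean squared
#' error of `S` against the survival indicator.
#'
#' @param s_pred Predicted survival probabilities at `tau` (length n).
#' @inheritParams risk_auc
#' @return Brier score in `[0, 1]`.
#' @export
brier_ipcw <- function(s_pred, time, event, tau) {
  n <- length(time)
  stopifnot(length(s_pred) == n)
  G <- censoring_survfit(time, event)
  g_tau <- G(tau)
  died <- time <= tau & event == 1
  alive <- time > tau
  if (any(died) && any(G(time[died], lag = TRUE) == 0) ||
      (any(alive) && g_tau == 0)) {
    stop("censoring survival reaches 0 before tau; choose a smaller horizon",
         call. = FALSE)
  }
  contrib <- numeric(n)
  contrib[died] <- s_pred[died]^2 / G(time[died], lag = TRUE)
  contrib[alive] <- (1 - s_pred[alive])^2 / g_tau
  mean(contrib)
}

#' Integrated Brier score over (0, tau_max]
#'
#' Trapezoidal time-average of the IPCW Brier score over a grid.
#'
#' @param s_pred_matrix n x length(times) matrix of predicted survival
#'   probabilities.
#' @param times Increasing evaluation grid (all > 0).
#' @inheritParams risk_auc
#' @param tau_max Upper end of integration (defaults to `max(times)`).
#' @return Integrated Brier score.
#' @export
integrated_brier <- function(s_pred_matrix, times, time, event,
                             tau_max = max(times)) {
  stopifnot(ncol(s_pred_matrix) == length(times), all(diff(times) > 0))
  keep <- times <= tau_max
  ts <- times[keep]
  bs <- vapply(seq_along(ts), function(j) {
    brier_ipcw(s_pred_matrix[, which(keep)[j]], time, event, ts[j])
  }, numeric(1))
  if (length(ts) == 1L) return(bs)
  # trapezoid from 0 (where BS is taken as the first grid value) to tau_max
  grid <- c(0, ts)
  vals <- c(bs[1L], bs)
  sum(diff(grid) * (utils::head(vals, -1L) + utils::tail(vals, -1L)) / 2) /
    (tau_max - 0)
}
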