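#' Negative log Cox partial likelihood
#'
#' The relative-risk training loss: for events i (`event == 1`),
#' `-sum_i [ h_i - log sum_{j in R(t_i)} exp(h_j) ]`, where the risk set
#' `R(t)` holds all subjects with observed time `>= t`. Tied event times use
#' the Breslow convention (the full risk set, event count as multiplier).
#' The log-sum-exp is computed stably with a max shift. Adding a constant
#' to every `h` leaves the loss unchanged (the baseline hazard is
#' profiled out).
#'
#' @param h Length-n log-risk scores.
#' @param time Length-n follow-up times.
#' @param event Length-n 0/1 event indicators; at least one event required.
#' @return Scalar loss.
#' @examples
#' cox_partial_nll(c(0, 0), c(1, 2), c(1, 1))  # log(2)
#' @export
cox_partial_nll <- function(h, time, event) {
  ck <- cox_risk_structure(h, time, event)
  sum(ck$d * ck$log_denom) - sum(h[event == 1])
}

# Shared risk-set bookkeeping for the Breslow partial likelihood.
# Returns, per distinct event time (increasing): event count d, stable
# log-denominator log sum_{R(t)} exp(h), and per-subject cumulative
# hazard-style weights used by the gradient.
cox_risk_structure <- function(h, time, event) {
  n <- length(h)
  stopifnot(length(time) == n, length(event) == n)
  if (any(!is.finite(h))) stop("log-risks must be finite", call. = FALSE)
  if (sum(event == 1) == 0L) {
    stop("partial likelihood undefined with zero events", call. = FALSE)
  }
  ord <- order(time, decreasing = TRUE)  # add to risk set as time decreases
  ho <- h[ord]; to <- time[ord]; eo <- event[ord]
  m <- max(ho)
  cs <- cumsum(exp(ho - m))              # sum over {j : t_j >= to[i]} resolves below
  # positions sharing a time must all see the full tied block in the risk set
  last_of_block <- cumsum(tabulate(match(to, unique(to))))[match(to, unique(to))]
  risk_sum <- cs[last_of_block]          # sum exp(h - m) over R(to[i])
  ev_times <- unique(to[eo == 1])
  idx <- match(ev_times, to)
  d <- vapply(ev_times, function(t) sum(eo == 1 & to == t), numeric(1))
  log_denom <- m + log(risk_sum[idx])
  # order event times increasing for downstream cumulative sums
  o2 <- order(ev_times)
  list(event_times = ev_times[o2], d = d[o2], log_denom = log_denom[o2],
       ord = ord, risk_sum_shift = m)
}

#' Gradient of the Cox partial NLL with respect to the log-risks
#'
#' `d/dh_k = -E_k + exp(h_k) * sum_{event times t <= t_k} d_t / S_t` with
#' `S_t = sum_{j in R(t)} exp(h_j)`.
#'
#' @inheritParams cox_partial_nll
#' @return Length-n gradient.
#' @export
cox_partial_nll_grad <- function(h, time, event) {
  ck <- cox_risk_structure(h, time, event)
  inv_s <- ck$d / exp(ck$log_denom)      # d_t / S_t per increasing event time
  cum <- cumsum(inv_s)
  # W_k = sum over event times <= t_k
  pos <- findInterval(time, ck$event_times)
  w <- ifelse(pos == 0L, 0, cum[pmax(pos, 1L)])
  exp(h) * w - (event == 1)
}

#' Entropy sparsity penalty on attention masks
#'
#' `(1 / (n_steps * B)) * sum_steps sum_b sum_j -M log M` with natural
#' logarithm and `0 log 0 := 0`. Zero for one-hot masks, `log D` for
#' uniform masks over D features.
#'
#' @param masks List of n x D mask matrices (rows on the simplex), or a
#'   single matrix.
#' @return Scalar penalty.
#' @examples
#' entropy_sparsity(matrix(c(0.5, 0.5), 1))  # log(2)
#' @export
entropy_sparsity <- function(masks) {
  if (is.matrix(masks)) masks <- list(masks)
  n_steps <- length(masks)
  b <- nrow(masks[[1L]])
  tot <- 0
  for (M in masks) {
    if (any(M < -1e-12)) {
      stop("mask entries must be nonnegative", call. = FALSE)
    }
    pos <- M > 0
    tot <- tot + sum(-M[pos] * log(M[pos]))
  }
  tot / (n_steps * b)
}

#' Gradient of the entropy penalty with respect to each mask entry
#'
#' `-(log M + 1) / (n_steps * B)` on the support, zero elsewhere (the
#' sparsemax Jacobian vanishes off-support, so the off-support value is
#' never consumed).
#'
#' @inheritParams entropy_sparsity
#' @return List of gradient matrices matching `masks`.
#' @export
entropy_sparsity_grad <- function(masks) {
  if (is.matrix(masks)) masks <- list(masks)
  n_steps <- length(masks)
  b <- nrow(masks[[1L]])
  lapply(masks, function(M) {
    g <- matrix(0, nrow(M), ncol(M))
    pos <- M > 0
    g[pos] <- -(log(M[pos]) + 1) / (n_steps * b)
    g
  })
}

#' Total training objective: Cox partial NLL plus sparsity penalty
#'
#' `L = cox_partial_nll(h) + lambda_sparse * entropy_sparsity(masks)`.
#' With `lambda_sparse = 0` or one-hot masks it reduces to the partial
#' likelihood alone.
#'
#' @inheritParams cox_partial_nll
#' @param masks List of mask matrices (or NULL for comparators without
#'   attention).
#' @param lambda_sparse Sparsity weight.
#' @param gradient Also return analytic gradients w.r.t. `h` and `masks`.
#' @return Scalar, or (with `gradient = TRUE`) a list
#'   `list(value, d_h, d_masks)`.
#' @export
total_objective <- function(h, time, event, masks = NULL, lambda_sparse = 0,
                            gradient = FALSE) {
  val <- cox_partial_nll(h, time, event)
  if (!is.null(masks) && lambda_sparse > 0) {
    val <- val + lambda_sparse * entropy_sparsity(masks)
  }
  if (!gradient) return(val)
  d_h <- cox_partial_nll_grad(h, time, event)
  d_masks <- NULL
  if (!is.null(masks) && lambda_sparse > 0) {
    d_masks <- lapply(entropy_sparsity_grad(masks), function(g) {
      lambda_sparse * g
    })
  }
  list(value = val, d_h = d_h, d_masks = d_masks)
}

#' Breslow cumulative baseline hazard
#'
#' Given fitted log-risks on the training data, the increment at each
#' distinct event time is `d_t / sum_{j in R(t)} exp(h_j)`; the cumulative
#' sum is the step-function baseline `Lambda0(t)`. With all-zero log-risks
#' this reduces to the Nelson-Aalen estimator.
#'
#' @inheritParams cox_partial_nll
#' @return A `baseline_hazard`: tibble with `time`, `increment`,
#'   `cumhaz`, nondecreasing, zero before the first event time.
#' @export
breslow_baseline <- function(h, time, event) {
  if (sum(event == 1) == 0L) {
    warning("no events: baseline hazard is identically zero")
    out <- tibble::tibble(time = numeric(0), increment = numeric(0),
                          cumhaz = numeric(0))
    return(structure(out, class = c("baseline_hazard", class(out))))
  }
  ck <- cox_risk_structure(h, time, event)
  inc <- ck$d / exp(ck$log_denom)
  out <- tibble::tibble(time = ck$event_times, increment = inc,
                        cumhaz = cumsum(inc))
  structure(out, class = c("baseline_hazard", class(out)))
}

#' Evaluate a cumulative baseline hazard at query times
#'
#' @param bh A `baseline_hazard`.
#' @param times Nonnegative query times.
#' @return `Lambda0(times)` (right-continuous step function, zero before
#'   the first event time).
#' @export
cumhaz_at <- function(bh, times) {
  if (any(times < 0)) stop("query times must be nonnegative", call. = FALSE)
  if (nrow(bh) == 0L) return(rep(0, length(times)))
  idx <- findInterval(times, bh$time)
  c(0, bh$cumhaz)[idx + 1L]
}

#' Predicted survival probabilities
#'
#' `S(t | x) = exp(-Lambda0(t) * exp(h(x)))`: nonincreasing in `t`, in
#' `[0, 1]`, equal to 1 before the first training event time.
#'
#' @param h Log-risk scores for the rows being predicted.
#' @param bh A `baseline_hazard` fitted on training data.
#' @param times Query time grid (nonnegative).
#' @return An n x length(times) matrix of survival probabilities.
#' @export
survival_from_hazard <- function(h, bh, times) {
  lam <- cumhaz_at(bh, times)
  exp(-outer(exp(h), lam))
}
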