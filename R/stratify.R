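#' Kaplan-Meier product-limit estimator
#'
#' Thin surface over `survival::survfit`. Censoring tied with an event time
#' is handled after the event (the standard product-limit convention).
#'
#' @param time Follow-up times.
#' @param event 0/1 event indicators.
#' @return A `km_curve` tibble: `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`, with `surv` nonincreasing and S(0) = 1.
#' @export
km_estimator <- function(time, event) {
  stopifnot(length(time) >= 1L)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                        n_event = fit$n.event, n_censor = fit$n.censor,
                        surv = fit$surv)
  structure(out, class = c("km_curve", class(out)))
}

#' Evaluate a KM curve at arbitrary times
#'
#' @param km A `km_curve`.
#' @param times Query times.
#' @return Survival probabilities (right-continuous step function).
#' @export
km_at <- function(km, times) {
  ev <- km[km$n_event > 0, ]
  if (nrow(ev) == 0L) return(rep(1, length(times)))
  idx <- findInterval(times, ev$time)
  c(1, ev$surv)[idx + 1L]
}

#' Log-rank test for survival differences between groups
#'
#' Surface over `survival::survdiff` (rho = 0).
#'
#' @param time,event As in [km_estimator()].
#' @param group Group labels (>= 2 nonempty groups).
#' @return Tibble with `chisq`, `df`, `p.value`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L) {
    stop("log-rank test needs at least two nonempty groups", call. = FALSE)
  }
  fit <- survival::survdiff(survival::Surv(time, event) ~ group, rho = 0)
  df <- length(fit$n) - 1L
  tibble::tibble(chisq = fit$chisq, df = df,
                 p.value = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Map log-risks to bounded scores in [0, 1]
#'
#' Rank-preserving normalization frozen on a training reference: by default
#' the empirical CDF of the training log-risks (distribution-free,
#' clipped to `[0, 1]` outside the reference range); `method = "minmax"`
#' rescales linearly by the reference range instead. A frozen normalizer
#' applied to new data never refits. The score preserves every ranking
#' property of the raw log-risk (identical C-index).
#'
#' @param reference Training log-risks defining the mapping.
#' @param method `"ecdf"` or `"minmax"`.
#' @return A `risk_normalizer`: function `f(h)` returning scores in [0, 1].
#' @export
risk_normalizer <- function(reference, method = c("ecdf", "minmax")) {
  method <- match.arg(method)
  if (length(unique(reference)) < 2L) {
    stop("degenerate reference: constant log-risks", call. = FALSE)
  }
  f <- if (method == "ecdf") {
    ref_sorted <- sort(reference)
    n <- length(ref_sorted)
    function(h) {
      # interpolated ECDF: rank within the reference, endpoints map to 0/1
      r <- findInterval(h, ref_sorted)
      lo <- ref_sorted[pmax(r, 1L)]
      hi <- ref_sorted[pmin(r + 1L, n)]
      frac <- ifelse(hi > lo, (h - lo) / (hi - lo), 0)
      pmin(pmax((pmax(r, 0) + ifelse(r >= 1 & r < n, frac, 0) - 1) /
                  (n - 1), 0), 1)
    }
  } else {
    lo <- min(reference); hi <- max(reference)
    function(h) pmin(pmax((h - lo) / (hi - lo), 0), 1)
  }
  structure(f, class = "risk_normalizer", method = method)
}

#' @rdname risk_normalizer
#' @param h Log-risks to normalize.
#' @param normalizer A `risk_normalizer`.
#' @export
normalize_risk <- function(h, normalizer) normalizer(h)

#' Optimal risk-score cut-off by log-rank maximization
#'
#' Searches the unique observed scores between the 10th and 90th
#' percentiles (subject to a minimum group-fraction constraint) for the
#' threshold maximizing the log-rank chi-squared between the resulting
#' groups. Because the cut-off is optimized over many candidates, the
#' attached chi-squared is inflated by multiplicity and must not be read
#' as an honest test; the result carries a warning flag saying so. A
#' prespecified external cut-off (e.g. a published 0.35) can be supplied
#' via `override` and is then applied unchanged.
#'
#' @param scores Normalized risk scores in [0, 1].
#' @param time,event Survival outcome.
#' @param min_frac Minimum fraction of the cohort in each group.
#' @param override Optional fixed cut-off applied without any search.
#' @return A list with `cutoff`, `chisq`, `searched` (FALSE when
#'   overridden), and `multiplicity_warning`.
#' @export
optimal_cutoff <- function(scores, time, event, min_frac = 0.10,
                           override = NULL) {
  if (!is.null(override)) {
    grp <- scores > override
    ch <- if (length(unique(grp)) == 2L) {
      logrank_test(time, event, grp)$chisq
    } else NA_real_
    return(list(cutoff = override, chisq = ch, searched = FALSE,
                multiplicity_warning = FALSE))
  }
  qs <- stats::quantile(scores, c(0.10, 0.90), names = FALSE)
  cand <- sort(unique(scores))
  cand <- cand[cand >= qs[1L] & cand <= qs[2L]]
  n <- length(scores)
  cand <- cand[vapply(cand, function(ct) {
    k <- sum(scores > ct)
    k >= min_frac * n && (n - k) >= min_frac * n
  }, logical(1))]
  if (length(cand) == 0L) {
    stop("no admissible threshold satisfies the group-size constraint",
         call. = FALSE)
  }
  chis <- vapply(cand, function(ct) {
    logrank_test(time, event, scores > ct)$chisq
  }, numeric(1))
  best <- which.max(chis)
  list(cutoff = cand[best], chisq = chis[best], searched = TRUE,
       multiplicity_warning = TRUE)
}

#' Stratify a cohort into low- and high-risk groups
#'
#' Applies a frozen normalizer and cut-off (searched on this data or
#' supplied as an override) and returns group labels, per-group KM curves,
#' and the log-rank comparison. Deterministic: the same scores and cut-off
#' always give the same strata.
#'
#' @param h Log-risks for the cohort being stratified.
#' @param time,event Survival outcome.
#' @param normalizer A [risk_normalizer()] frozen on training log-risks.
#' @param cutoff Optional prespecified cut-off (skips the search).
#' @param min_frac Group-size constraint for the search.
#' @return A `strata_result`: list with `scores`, `cutoff`, `group`
#'   (factor low/high), `km` (named list of `km_curve`s), `logrank`
#'   (tibble), `searched`.
#' @export
stratify_risk <- function(h, time, event, normalizer, cutoff = NULL,
                          min_frac = 0.10) {
  scores <- normalizer(h)
  oc <- optimal_cutoff(scores, time, event, min_frac = min_frac,
                       override = cutoff)
  group <- factor(ifelse(scores > oc$cutoff, "high", "low"),
                  levels = c("low", "high"))
  km <- lapply(split(seq_along(scores), group), function(idx) {
    if (length(idx) == 0L) return(NULL)
    km_estimator(time[idx], event[idx])
  })
  lr <- if (all(table(group) > 0)) logrank_test(time, event, group) else NULL
  structure(list(scores = scores, cutoff = oc$cutoff, group = group,
                 km = km, logrank = lr, searched = oc$searched,
                 multiplicity_warning = isTRUE(oc$multiplicity_warning)),
            class = "strata_result")
}

#' @export
print.strata_result <- function(x, ...) {
  cat("<strata_result> cut-off", signif(x$cutoff, 4),
      if (x$searched) "(searched; chi-squared inflated by multiplicity)"
      else "(prespecified)", "\n")
  print(table(x$group))
  if (!is.null(x$logrank)) print(x$logrank)
  invisible(x)
}
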