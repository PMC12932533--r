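# Independent brute-force oracles used to validate the package's metric and
# projection implementations. Deliberately naive (pair enumeration, direct
# summation); kept free of any package internals beyond the public API they
# check.

# Harrell concordance by O(n^2) pair enumeration.
oracle_concordance <- function(h, time, event) {
  n <- length(h)
  conc <- 0; tied <- 0; total <- 0
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    for (j in seq_len(n)) {
      if (time[j] <= time[i]) next
      total <- total + 1
      if (h[i] > h[j]) conc <- conc + 1
      else if (h[i] == h[j]) tied <- tied + 1
    }
  }
  (conc + 0.5 * tied) / total
}

# Kaplan-Meier of the censoring distribution by direct product-limit,
# evaluated at t (or the left limit t-).
oracle_censor_km <- function(time, event) {
  ut <- sort(unique(time))
  surv <- 1
  tab <- data.frame(time = ut, surv = NA_real_)
  for (i in seq_along(ut)) {
    t <- ut[i]
    n_risk <- sum(time >= t)
    d_cens <- sum(time == t & event == 0)
    surv <- surv * (1 - d_cens / n_risk)
    tab$surv[i] <- surv
  }
  function(t, lag = FALSE) {
    tt <- if (lag) t - 1e-10 else t
    vapply(tt, function(q) {
      below <- tab$time <= q
      if (!any(below)) 1 else tab$surv[max(which(below))]
    }, numeric(1))
  }
}

# IPCW cumulative/dynamic AUC by direct weighted pair summation.
oracle_risk_auc <- function(h, time, event, tau) {
  G <- oracle_censor_km(time, event)
  cases <- which(time <= tau & event == 1)
  controls <- which(time > tau)
  num <- 0; den <- 0
  for (i in cases) {
    wi <- 1 / G(time[i], lag = TRUE)
    for (j in controls) {
      wj <- 1 / G(tau)
      den <- den + wi * wj
      if (h[i] > h[j]) num <- num + wi * wj
      else if (h[i] == h[j]) num <- num + 0.5 * wi * wj
    }
  }
  num / den
}

# IPCW Brier score by direct summation over subjects.
oracle_brier <- function(s_pred, time, event, tau) {
  G <- oracle_censor_km(time, event)
  n <- length(time)
  tot <- 0
  for (i in seq_len(n)) {
    if (time[i] <= tau && event[i] == 1) {
      tot <- tot + s_pred[i]^2 / G(time[i], lag = TRUE)
    } else if (time[i] > tau) {
      tot <- tot + (1 - s_pred[i])^2 / G(tau)
    }
  }
  tot / n
}

# Plain binary AUC (rank statistic), for the no-censoring reduction.
oracle_binary_auc <- function(score, label) {
  pos <- score[label == 1]; neg <- score[label == 0]
  num <- 0
  for (a in pos) num <- num + sum(a > neg) + 0.5 * sum(a == neg)
  num / (length(pos) * length(neg))
}

# Random small survival instance generator for oracle comparisons.
random_instance <- function(n, cens_prob = 0.3) {
  time <- round(rexp(n, 0.1) + 0.1, 2)
  event <- rbinom(n, 1, 1 - cens_prob)
  if (sum(event) == 0) event[sample(n, 1)] <- 1
  h <- rnorm(n)
  list(h = h, time = time, event = event)
}

# Tiny deterministic cohort data frame for ingestion tests.
tiny_cohort_df <- function() {
  data.frame(
    age = c(50, 60, 70, 55, 65),
    marker = c(1.2, 3.4, 2.2, 0.8, 5.0),
    stage = c("A_B", "C", "C", "A_B", "C"),
    time = c(12, 5, 30, 22, 8),
    event = c(1, 1, 0, 0, 1)
  )
}

tiny_schema <- function() {
  cohort_schema(
    feature_spec("age", "continuous", units = "years"),
    feature_spec("marker", "continuous"),
    feature_spec("stage", "categorical", categories = c("A_B", "C"))
  )
}
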