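#' Variance inflation factors and tolerance
#'
#' `VIF_j = 1 / (1 - R2_j)` from regressing covariate `j` on all the
#' others (with intercept); tolerance is the reciprocal. Perfect
#' collinearity is reported as infinite VIF rather than an error.
#'
#' @param X Numeric covariate matrix (n > ncol, no constant columns).
#' @return Tibble with `term`, `r.squared`, `vif`, `tolerance`.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (nrow(X) <= p) stop("need more rows than covariates", call. = FALSE)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  }
  if (p == 1L) {
    return(tibble::tibble(term = colnames(X), r.squared = 0, vif = 1,
                          tolerance = 1))
  }
  out <- purrr::map_dfr(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - rss / tss
    v <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    tibble::tibble(term = colnames(X)[j] %||% paste0("V", j),
                   r.squared = r2, vif = v, tolerance = 1 / v)
  })
  out
}

#' Univariable screening plus multivariable Cox fit
#'
#' Mirrors the standard clinical modeling procedure: every candidate is
#' fitted in a univariable Cox model; candidates with `p < alpha` are
#' checked for collinearity, the highest-VIF covariate being dropped
#' iteratively until all VIFs are at most `vif_max`; the survivors enter
#' one multivariable fit via [fit_linear_coxph()].
#'
#' @param cohort A `cohort`.
#' @param candidates Encoded covariate names to screen (default: all).
#' @param alpha Univariable significance gate.
#' @param vif_max Maximum admissible VIF.
#' @return A list with `univariable` (tibble: term, hr, CI, p, selected),
#'   `dropped_collinear`, and `multivariable` (tibble, or NULL when no
#'   candidate survives).
#' @export
cox_screen_and_fit <- function(cohort, candidates = NULL, alpha = 0.05,
                               vif_max = 5) {
  candidates <- candidates %||% colnames(cohort$X)
  missing_cov <- setdiff(candidates, colnames(cohort$X))
  if (length(missing_cov)) {
    stop("unknown candidate(s): ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  uni <- purrr::map_dfr(candidates, function(v) {
    fit <- fit_linear_coxph(cohort, covariates = v)
    fit$table
  })
  uni$selected <- uni$p.value < alpha
  keep <- uni$term[uni$selected]
  dropped <- character(0)
  while (length(keep) >= 2L) {
    vt <- vif(cohort$X[, keep, drop = FALSE])
    if (all(vt$vif <= vif_max)) break
    worst <- vt$term[which.max(vt$vif)]
    dropped <- c(dropped, worst)
    keep <- setdiff(keep, worst)
  }
  multi <- NULL
  if (length(keep) >= 1L) {
    multi <- fit_linear_coxph(cohort, covariates = keep)$table
  } else {
    message("no candidate survived screening; multivariable step skipped")
  }
  list(univariable = uni, dropped_collinear = dropped, multivariable = multi)
}

#' Decision curve analysis (net benefit)
#'
#' For each threshold probability `p_t`, patients whose predicted event
#' probability at the horizon (`1 - S_pred`) exceeds `p_t` are treated;
#' `NB(p_t) = TP/n - FP/n * p_t / (1 - p_t)`. Under right censoring the
#' true-positive and false-positive counts are IPCW-weighted: events by
#' `tau` weigh `1/G(t-)`, survivors beyond `tau` weigh `1/G(tau)`, and
#' patients censored before `tau` contribute through the weights only.
#' Curves are returned for the model, treat-all, treat-none (identically
#' zero), and optionally a reference model.
#'
#' @param s_pred Predicted survival probabilities at `tau`.
#' @param time,event Survival outcome.
#' @param tau Horizon.
#' @param thresholds Threshold grid in (0, 1).
#' @param s_ref Optional reference predictions (e.g. from a stage-only
#'   model) evaluated on the same patients.
#' @return A `net_benefit_curve` tibble: `threshold`, `strategy`,
#'   `net_benefit`.
#' @export
decision_curve <- function(s_pred, time, event, tau,
                           thresholds = seq(0.05, 0.95, by = 0.05),
                           s_ref = NULL) {
  if (any(thresholds <= 0) || any(thresholds >= 1)) {
    stop("thresholds must lie strictly inside (0, 1)", call. = FALSE)
  }
  n <- length(time)
  G <- censoring_survfit(time, event)
  w_case <- ifelse(time <= tau & event == 1, 1 / G(time, lag = TRUE), 0)
  w_ctrl <- ifelse(time > tau, 1 / G(tau), 0)
  nb <- function(p_event, p_t) {
    pos <- p_event > p_t
    tp <- sum(w_case[pos]) / n
    fp <- sum(w_ctrl[pos]) / n
    tp - fp * p_t / (1 - p_t)
  }
  prev <- sum(w_case) / n
  rows <- purrr::map_dfr(thresholds, function(p_t) {
    out <- tibble::tibble(
      threshold = p_t,
      strategy = c("model", "treat_all", "treat_none"),
      net_benefit = c(nb(1 - s_pred, p_t),
                      prev - (sum(w_ctrl) / n) * p_t / (1 - p_t),
                      0)
    )
    if (!is.null(s_ref)) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        threshold = p_t, strategy = "reference",
        net_benefit = nb(1 - s_ref, p_t)
      ))
    }
    out
  })
  structure(rows, class = c("net_benefit_curve", class(rows)),
            tau = tau, censoring_adjustment = "ipcw")
}

#' Calibration curve: predicted versus KM-observed survival
#'
#' Patients are binned by predicted survival probability at the horizon
#' (quantile bins); each bin's observed survival is the Kaplan-Meier
#' estimate at `tau` within the bin. Empty bins are merged into their
#' neighbor and noted.
#'
#' @inheritParams decision_curve
#' @param bins Number of bins (>= 2).
#' @return A `calibration_curve` tibble: `bin`, `n`, `predicted`
#'   (mean predicted survival), `observed` (KM at tau), `merged`.
#' @export
calibration_curve <- function(s_pred, time, event, tau, bins = 5L) {
  stopifnot(bins >= 2L)
  if (length(unique(s_pred)) == 1L) {
    warning("constant predictions: single degenerate calibration bin")
    km <- km_estimator(time, event)
    return(structure(
      tibble::tibble(bin = 1L, n = length(time), predicted = s_pred[1L],
                     observed = km_at(km, tau), merged = FALSE),
      class = c("calibration_curve", "tbl_df", "tbl", "data.frame")))
  }
  br <- unique(stats::quantile(s_pred, probs = seq(0, 1, length.out = bins + 1L),
                               names = FALSE))
  merged <- length(br) < bins + 1L
  grp <- cut(s_pred, breaks = br, include.lowest = TRUE, labels = FALSE)
  rows <- purrr::map_dfr(sort(unique(grp)), function(g) {
    idx <- which(grp == g)
    km <- km_estimator(time[idx], event[idx])
    tibble::tibble(bin = g, n = length(idx),
                   predicted = mean(s_pred[idx]),
                   observed = km_at(km, tau), merged = merged)
  })
  structure(rows, class = c("calibration_curve", class(rows)), tau = tau)
}

#' Coalition-sampling Shapley attributions for any risk model
#'
#' Model-agnostic Shapley-value estimates of each feature's signed
#' contribution to the log-risk, by sampling random feature permutations
#' against background rows drawn from the training data: within one
#' permutation, each feature's marginal contribution is the change in
#' model output when that feature switches from the background value to
#' the patient's value, features before it already switched. Averaging
#' over permutation/background draws gives the attribution; the
#' telescoping sum makes local accuracy exact by construction:
#' `sum_j phi_j = h(x) - phi_0` with `phi_0` the mean prediction over the
#' sampled background rows.
#'
#' @param model A `risk_model`.
#' @param X Rows to explain (preprocessed matrix or `cohort`).
#' @param background Background matrix (preprocessed training rows).
#' @param n_samples Number of permutation/background draws per row.
#' @param seed Integer seed.
#' @return A `shap_result`: list with `phi` (n x D attribution matrix),
#'   `phi0` (per-row base value), `log_risk` (model output per row), and
#'   the Monte-Carlo standard error estimate per feature.
#' @export
sampling_attribution <- function(model, X, background, n_samples = 64L,
                                 seed = 1L) {
  if (inherits(X, "cohort")) X <- X$X
  if (inherits(background, "cohort")) background <- background$X
  X <- as.matrix(X); background <- as.matrix(background)
  n <- nrow(X); d <- ncol(X)
  if (n_samples < 2L) stop("n_samples must be at least 2", call. = FALSE)
  withr::local_seed(as.integer(seed))
  perms <- replicate(n_samples, sample.int(d), simplify = FALSE)
  bg_idx <- sample.int(nrow(background), n_samples, replace = TRUE)
  predict_rows <- function(M) predict(model, M, type = "risk")
  h_x <- predict_rows(X)
  phi <- matrix(0, n, d, dimnames = list(NULL, colnames(X)))
  phi_sq <- matrix(0, n, d)
  phi0 <- rep(0, n)
  for (s in seq_len(n_samples)) {
    perm <- perms[[s]]
    b <- background[bg_idx[s], ]
    # build the d+1 coalition states for every explained row in one batch
    cur <- matrix(b, n, d, byrow = TRUE, dimnames = list(NULL, colnames(X)))
    states <- vector("list", d + 1L)
    states[[1L]] <- cur
    for (jj in seq_len(d)) {
      cur[, perm[jj]] <- X[, perm[jj]]
      states[[jj + 1L]] <- cur
    }
    big <- do.call(rbind, states)
    hs <- matrix(predict_rows(big), nrow = n)
    phi0 <- phi0 + hs[, 1L]
    contrib <- hs[, -1L, drop = FALSE] - hs[, -(d + 1L), drop = FALSE]
    contrib_f <- matrix(0, n, d)
    contrib_f[, perm] <- contrib
    phi <- phi + contrib_f
    phi_sq <- phi_sq + contrib_f^2
  }
  phi <- phi / n_samples
  phi0 <- phi0 / n_samples
  se <- sqrt(pmax(phi_sq / n_samples - phi^2, 0) / n_samples)
  if (mean(se) > 0.25 * stats::sd(h_x)) {
    warning("Monte-Carlo attribution error is large (mean SE ",
            signif(mean(se), 3), "); increase n_samples")
  }
  structure(list(phi = phi, phi0 = phi0, log_risk = h_x, se = se,
                 n_samples = n_samples),
            class = "shap_result")
}

#' Long-format tidy view of Shapley attributions
#'
#' @param x A `shap_result`.
#' @param ... Unused.
#' @return Tibble with `sample`, `feature`, `phi`.
#' @export
tidy.shap_result <- function(x, ...) {
  tibble::tibble(
    sample = rep(seq_len(nrow(x$phi)), times = ncol(x$phi)),
    feature = rep(colnames(x$phi) %||% paste0("V", seq_len(ncol(x$phi))),
                  each = nrow(x$phi)),
    phi = as.vector(x$phi)
  )
}

#' Pearson correlation matrix of cohort features
#'
#' @param X Numeric matrix (n >= 3, no constant columns).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 3L) stop("need at least 3 rows", call. = FALSE)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s) have undefined correlation: ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  }
  stats::cor(X, method = "pearson")
}

#' Hierarchical clustering of high-risk patients
#'
#' Agglomerative clustering (Ward linkage on Euclidean distance over
#' standardized features) of the high-risk subgroup, to surface clinical
#' phenotypes such as tumor-burden-dominant versus
#' liver-dysfunction-dominant profiles. When `k` is not given it is chosen
#' by maximizing the mean silhouette width over k in 2..5.
#'
#' @param X Standardized feature matrix of high-risk patients (>= 2 rows).
#' @param k Number of clusters, or NULL to select by silhouette.
#' @return A `highrisk_clusters`: list with `labels`, `k`, `merge`
#'   (the dendrogram merge table), `heights`, `centers` (cluster-wise
#'   feature means), `silhouette` (per-k mean widths when searched).
#' @export
highrisk_clustering <- function(X, k = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 high-risk patients", call. = FALSE)
  if (!is.null(k) && k > n) stop("k cannot exceed the number of patients",
                                 call. = FALSE)
  d <- stats::dist(X)
  hc <- stats::hclust(d, method = "ward.D2")
  sil <- NULL
  if (is.null(k)) {
    ks <- 2:min(5L, n - 1L)
    if (max(d) == 0) {
      k <- 1L
    } else {
      sil <- vapply(ks, function(kk) {
        lab <- stats::cutree(hc, kk)
        if (length(unique(lab)) < 2L) return(-Inf)
        mean(cluster::silhouette(lab, d)[, 3L])
      }, numeric(1))
      names(sil) <- ks
      k <- ks[which.max(sil)]
    }
  }
  labels <- if (k == 1L) rep(1L, n) else stats::cutree(hc, k)
  centers <- do.call(rbind, lapply(sort(unique(labels)), function(g) {
    colMeans(X[labels == g, , drop = FALSE])
  }))
  rownames(centers) <- paste0("cluster", sort(unique(labels)))
  structure(list(labels = labels, k = k, merge = hc$merge,
                 heights = hc$height, centers = centers, silhouette = sil),
            class = "highrisk_clusters")
}
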