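#' Declare a model to be evaluated
#'
#' Bundles an encoder kind with its hyperparameters so the resampling
#' protocol can fit it repeatedly.
#'
#' @param kind `"tabnet"`, `"mlp"`, or `"linear"`.
#' @param hp A [tabnet_hp()].
#' @param fit_fun Optional custom fitter `function(cohort, seed)` returning
#'   a `risk_model`; overrides `kind`/`hp` (used for oracle/reference
#'   models in tests).
#' @return A `model_spec`.
#' @export
model_spec <- function(kind = c("tabnet", "mlp", "linear"), hp = tabnet_hp(),
                       fit_fun = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, hp = hp, fit_fun = fit_fun),
            class = "model_spec")
}

#' Declare the resampling protocol
#'
#' Repeated K-fold cross-validation: for each repeat, folds are reshuffled
#' with that repeat's seed (event-stratified, so every fold holds events);
#' the model is trained on K-1 folds and scored on the held-out fold;
#' held-out predictions are concatenated across folds and each metric is
#' computed once per repeat. The stability index `sigma` is the sample
#' standard deviation of the per-repeat C-index.
#'
#' @param k Number of folds (>= 2).
#' @param seeds Integer seed vector, one per repeat (all distinct).
#' @param tau Metric horizon for AUC/Brier; `NULL` means the median
#'   follow-up of the evaluated cohort.
#' @param n_grid_times Grid size for the integrated Brier score.
#' @return A `cv_protocol`.
#' @export
cv_protocol <- function(k = 5L, seeds = 1:10, tau = NULL,
                        n_grid_times = 15L) {
  stopifnot(k >= 2L, length(seeds) >= 1L, !anyDuplicated(seeds))
  structure(list(k = as.integer(k), seeds = as.integer(seeds), tau = tau,
                 n_grid_times = as.integer(n_grid_times)),
            class = "cv_protocol")
}

stratified_folds <- function(event, k, seed) {
  n <- length(event)
  fold <- integer(n)
  withr::with_seed(seed, {
    for (grp in list(which(event == 1), which(event == 0))) {
      idx <- sample(grp)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

fit_spec <- function(spec, cohort, seed) {
  if (!is.null(spec$fit_fun)) return(spec$fit_fun(cohort, seed))
  fit_risk_model(cohort, kind = spec$kind, hp = spec$hp, seed = seed)
}

#' Repeated cross-validated evaluation of a survival model
#'
#' Runs the protocol of [cv_protocol()] and reports discrimination
#' (C-index, IPCW AUC at `tau`), prediction error (IPCW Brier at `tau`,
#' integrated Brier over `(0, tau]`), and the resampling stability index
#' `sigma` (SD of the per-repeat C-index). Preprocessing statistics are
#' refitted inside every training fold, never on held-out rows.
#'
#' @param spec A [model_spec()].
#' @param cohort An unpreprocessed `cohort`.
#' @param protocol A [cv_protocol()].
#' @return An `eval_report`: list with `runs` (per-repeat tibble),
#'   `summary` (one-row tibble with means and `sigma`), `protocol`.
#' @export
repeated_cv <- function(spec, cohort, protocol = cv_protocol()) {
  n <- n_cohort(cohort)
  tau <- protocol$tau %||% stats::median(cohort$time)
  runs <- purrr::map_dfr(seq_along(protocol$seeds), function(r) {
    seed <- protocol$seeds[r]
    fold <- stratified_folds(cohort$event, protocol$k, seed)
    h_out <- numeric(n)
    s_out <- matrix(NA_real_, n, protocol$n_grid_times)
    grid_times <- seq(min(cohort$time), tau, length.out = protocol$n_grid_times)
    for (f in seq_len(protocol$k)) {
      tr <- subset_cohort(cohort, which(fold != f))
      te <- subset_cohort(cohort, which(fold == f))
      if (sum(tr$event) == 0L || sum(te$event) == 0L) {
        stop("fold without events; use stratified folds or a larger cohort",
             call. = FALSE)
      }
      pp <- fit_preprocess(tr)
      model <- fit_spec(spec, apply_preprocess(tr, pp), seed = seed + 1000L * f)
      te_pp <- apply_preprocess(te, pp)
      # the Cox log-risk is identified only up to a constant, so center each
      # fold model's held-out scores before pooling across folds
      h_f <- predict(model, te_pp, type = "risk")
      h_out[fold == f] <- h_f - mean(h_f)
      s_out[fold == f, ] <- predict(model, te_pp, type = "survival",
                                    times = grid_times)
    }
    s_tau <- survival_prob_at(s_out, grid_times, tau)
    tibble::tibble(
      repeat_id = r, seed = seed,
      cindex = concordance_index(h_out, cohort$time, cohort$event),
      auc = risk_auc(h_out, cohort$time, cohort$event, tau),
      brier = brier_ipcw(s_tau, cohort$time, cohort$event, tau),
      ibs = integrated_brier(s_out, grid_times, cohort$time, cohort$event,
                             tau_max = tau)
    )
  })
  structure(list(runs = runs, summary = summarize_runs(runs, tau),
                 protocol = protocol, tau = tau),
            class = "eval_report")
}

survival_prob_at <- function(s_matrix, grid_times, tau) {
  j <- which.min(abs(grid_times - tau))
  s_matrix[, j]
}

summarize_runs <- function(runs, tau) {
  tibble::tibble(
    n_runs = nrow(runs),
    mean_cindex = mean(runs$cindex),
    mean_auc = mean(runs$auc),
    mean_brier = mean(runs$brier),
    mean_ibs = mean(runs$ibs),
    sigma = stability_sigma(runs$cindex),
    tau = tau
  )
}

#' Resampling stability index
#'
#' The sample standard deviation (n-1 denominator) of a per-run metric
#' list; zero when all runs agree. Invariant to run order.
#'
#' @param per_run Numeric vector of per-run metric values.
#' @return `sigma >= 0`.
#' @export
stability_sigma <- function(per_run) {
  if (length(per_run) < 2L) return(0)
  stats::sd(per_run)
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>", nrow(x$runs), "repeats, horizon tau =",
      signif(x$tau, 4), "\n")
  print(x$summary)
  invisible(x)
}

#' Grid search over hyperparameters under the resampling protocol
#'
#' Evaluates every lattice point with [repeated_cv()] and selects the one
#' maximizing the mean CV C-index; ties break toward lower `sigma`, then
#' toward the smaller model (fewer steps, then smaller widths).
#'
#' @param cohort An unpreprocessed `cohort`.
#' @param grid A data frame of hyperparameter columns (any subset of the
#'   [tabnet_hp()] fields, e.g. `n_steps`, `width_d`, `lambda_sparse`).
#' @param kind Encoder kind.
#' @param protocol A [cv_protocol()].
#' @param base_hp Baseline hyperparameters that grid columns override.
#' @return A `grid_search_result`: list with `best_hp`, `best_row`, and
#'   `table` (the full grid with mean C-index and sigma).
#' @export
grid_search <- function(cohort, grid, kind = "tabnet",
                        protocol = cv_protocol(seeds = 1:3),
                        base_hp = tabnet_hp()) {
  if (!is.data.frame(grid) || nrow(grid) == 0L) {
    stop("grid must be a nonempty data frame", call. = FALSE)
  }
  res <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    hp <- base_hp
    for (nm in names(grid)) hp[[nm]] <- grid[[nm]][i]
    rep <- repeated_cv(model_spec(kind, hp), cohort, protocol)
    dplyr::bind_cols(grid[i, , drop = FALSE], rep$summary)
  })
  size <- rep(0, nrow(res))
  for (nm in intersect(c("n_steps", "width_d", "width_a"), names(grid))) {
    size <- size + res[[nm]]
  }
  ord <- order(-res$mean_cindex, res$sigma, size)
  best_row <- res[ord[1L], ]
  best_hp <- base_hp
  for (nm in names(grid)) best_hp[[nm]] <- best_row[[nm]]
  structure(list(best_hp = best_hp, best_row = best_row, table = res),
            class = "grid_search_result")
}

#' Default hyperparameter lattice
#'
#' The searched grid is configuration, not code: steps in \{3, 4, 5\},
#' widths in \{8, 16, 32\} (applied to both representation sizes), and
#' sparsity weights in \{1e-4, 1e-3, 1e-2\}.
#'
#' @return A data frame lattice for [grid_search()].
#' @export
default_grid <- function() {
  g <- expand.grid(n_steps = c(3L, 4L, 5L), width_d = c(8L, 16L, 32L),
                   lambda_sparse = c(1e-4, 1e-3, 1e-2))
  g$width_a <- g$width_d
  g
}

#' Learning curve under subsampled training data
#'
#' For each training fraction, repeats of: subsample the training split
#' (event-stratified, seeded), fit, and record the C-index on the training
#' subsample and on a fixed held-out set.
#'
#' @param spec A [model_spec()].
#' @param cohort An unpreprocessed `cohort`.
#' @param fractions Training fractions in (0, 1].
#' @param seeds One seed per repeat.
#' @param holdout_frac Fraction held out once for validation.
#' @return Tibble with `fraction`, `seed`, `n_train`, `train_cindex`,
#'   `val_cindex`.
#' @export
learning_curve <- function(spec, cohort, fractions = c(0.25, 0.5, 0.75, 1),
                           seeds = 1:3, holdout_frac = 0.25) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  split <- random_split(cohort, ratio = 1 - holdout_frac, seed = 1L)
  tr_all <- split$train
  te <- split$holdout
  purrr::map_dfr(fractions, function(f) {
    purrr::map_dfr(seeds, function(s) {
      idx <- withr::with_seed(s, {
        ev <- which(tr_all$event == 1); cs <- which(tr_all$event == 0)
        c(sample(ev, max(2L, round(f * length(ev)))),
          sample(cs, max(2L, round(f * length(cs)))))
      })
      tr <- subset_cohort(tr_all, sort(idx))
      if (sum(tr$event) < 2L) {
        warning("fraction ", f, " holds too few events; skipped")
        return(NULL)
      }
      pp <- fit_preprocess(tr)
      model <- fit_spec(spec, apply_preprocess(tr, pp), seed = s)
      tibble::tibble(
        fraction = f, seed = s, n_train = n_cohort(tr),
        train_cindex = concordance_index(
          predict(model, apply_preprocess(tr, pp)), tr$time, tr$event),
        val_cindex = concordance_index(
          predict(model, apply_preprocess(te, pp)), te$time, te$event)
      )
    })
  })
}
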