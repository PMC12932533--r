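#' Adam optimizer state and update
#' @noRd
adam_init <- function(par) {
  v <- flatten_params(par)
  list(m = 0 * v, v2 = 0 * v, t = 0L)
}

adam_step <- function(state, theta, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v2 <- beta2 * state$v2 + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v2 / (1 - beta2^state$t)
  list(state = state, theta = theta - lr * mhat / (sqrt(vhat) + eps))
}

mlp_init <- function(d, hidden, seed) {
  withr::local_seed(as.integer(seed))
  par <- list(W1 = glorot(d, hidden), b1 = rep(0, hidden),
              w2 = stats::rnorm(hidden, 0, 0.1), b2 = 0)
  attr(par, "d") <- d
  par
}

mlp_forward <- function(par, X) {
  Z <- sweep(X %*% par$W1, 2L, par$b1, "+")
  H <- pmax(Z, 0)
  list(log_risk = drop(H %*% par$w2) + par$b2, Z = Z, H = H)
}

mlp_backward <- function(par, X, fw, d_log_risk) {
  dH <- outer(d_log_risk, par$w2)
  dZ <- dH * (fw$Z > 0)
  list(W1 = crossprod(X, dZ), b1 = colSums(dZ),
       w2 = drop(crossprod(fw$H, d_log_risk)), b2 = sum(d_log_risk))
}

linear_init <- function(d, seed) {
  par <- list(beta = rep(0, d))
  attr(par, "d") <- d
  par
}

#' Fit a deep or linear Cox risk model
#'
#' Trains one of three encoder kinds on a preprocessed cohort by full-batch
#' Adam on the total objective (Cox partial NLL; plus the entropy sparsity
#' penalty for the attention encoder). An early-stopping subset (default
#' 15%, seeded, event-stratified) is carved from the training rows; training
#' stops when the stopping-set partial likelihood fails to improve for
#' `patience` epochs and the best parameters are restored. The Breslow
#' baseline hazard is then fitted on the full training data with the final
#' log-risks, so absolute survival curves can be predicted.
#'
#' @param cohort A preprocessed training `cohort`.
#' @param kind `"tabnet"`, `"mlp"`, or `"linear"`.
#' @param hp A [tabnet_hp()] (its optimizer fields are shared by all kinds;
#'   `width_d` sets the MLP hidden width).
#' @param seed Integer seed controlling initialization and the stopping
#'   split; fixed seed gives bit-identical training runs.
#' @param preprocess Optional `preprocess_stats` to store in the model
#'   bundle (for applying to new raw cohorts at prediction time).
#' @return A `risk_model`: list with `kind`, `par`, `hp`, `baseline`
#'   (Breslow hazard), `preprocess`, `log` (per-epoch losses, stopping
#'   epoch), `feature_names`.
#' @export
fit_risk_model <- function(cohort, kind = c("tabnet", "mlp", "linear"),
                           hp = tabnet_hp(), seed = 1L, preprocess = NULL) {
  kind <- match.arg(kind)
  X <- cohort$X
  time <- cohort$time
  event <- cohort$event
  n <- nrow(X); d <- ncol(X)
  if (sum(event) < 2L) stop("too few events to train", call. = FALSE)

  # event-stratified early-stopping subset
  idx_stop <- withr::with_seed(as.integer(seed) + 1L, {
    ev <- which(event == 1); cs <- which(event == 0)
    c(sample(ev, max(1L, round(hp$stop_frac * length(ev)))),
      sample(cs, max(1L, round(hp$stop_frac * length(cs)))))
  })
  idx_fit <- setdiff(seq_len(n), idx_stop)

  par <- switch(kind,
                tabnet = init_tabnet(d, hp, seed),
                mlp = mlp_init(d, hp$width_d, seed),
                linear = linear_init(d, seed))
  fwd <- function(par, X, cache = FALSE) {
    switch(kind,
           tabnet = tabnet_forward(par, X, hp, keep_cache = cache),
           mlp = mlp_forward(par, X),
           linear = list(log_risk = drop(X %*% par$beta)))
  }
  Xf <- X[idx_fit, , drop = FALSE]
  tf <- time[idx_fit]; ef <- event[idx_fit]
  Xs <- X[idx_stop, , drop = FALSE]
  ts <- time[idx_stop]; es <- event[idx_stop]

  opt <- adam_init(par)
  theta <- flatten_params(par)
  best <- list(loss = Inf, theta = theta, epoch = 0L)
  log_tr <- numeric(0); log_st <- numeric(0)
  wait <- 0L
  for (epoch in seq_len(hp$max_epochs)) {
    par <- unflatten_params(par, theta)
    fw <- fwd(par, Xf, cache = TRUE)
    lam <- if (kind == "tabnet") hp$lambda_sparse else 0
    obj <- total_objective(fw$log_risk, tf, ef, masks = fw$masks,
                           lambda_sparse = lam, gradient = TRUE)
    if (!is.finite(obj$value)) {
      stop("divergent (non-finite) training loss at epoch ", epoch,
           call. = FALSE)
    }
    grad <- switch(kind,
                   tabnet = tabnet_backward(par, hp, fw, obj$d_h, obj$d_masks),
                   mlp = mlp_backward(par, Xf, fw, obj$d_h),
                   linear = list(beta = drop(crossprod(Xf, obj$d_h))))
    gv <- flatten_params(grad)
    upd <- adam_step(opt, theta, gv, hp$learning_rate)
    opt <- upd$state
    theta <- upd$theta

    par_eval <- unflatten_params(par, theta)
    h_stop <- fwd(par_eval, Xs)$log_risk
    stop_loss <- cox_partial_nll(h_stop, ts, es)
    log_tr <- c(log_tr, obj$value)
    log_st <- c(log_st, stop_loss)
    if (stop_loss < best$loss - 1e-8) {
      best <- list(loss = stop_loss, theta = theta, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= hp$patience) break
    }
  }
  par <- unflatten_params(par, best$theta)
  h_full <- fwd(par, X)$log_risk
  structure(list(kind = kind, par = par, hp = hp,
                 baseline = breslow_baseline(h_full, time, event),
                 preprocess = preprocess,
                 feature_names = colnames(X),
                 train_log_risk = h_full,
                 log = list(train_loss = log_tr, stop_loss = log_st,
                            stop_epoch = best$epoch,
                            epochs_run = length(log_tr))),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat("<risk_model>", x$kind, "encoder,",
      length(flatten_params(x$par)), "parameters; stopped at epoch",
      x$log$stop_epoch, "of", x$log$epochs_run, "\n")
  invisible(x)
}

#' Predict log-risk or survival probabilities from a fitted model
#'
#' @param object A `risk_model`.
#' @param cohort A `cohort` (already preprocessed with the training
#'   statistics) or a bare numeric matrix.
#' @param type `"risk"` for log-risk scores, `"survival"` for
#'   `S(t|x) = exp(-Lambda0(t) exp(h))` on `times`.
#' @param times Query time grid (survival only).
#' @param ... Unused.
#' @return Numeric vector of log-risks, or an n x length(times) survival
#'   matrix.
#' @export
predict.risk_model <- function(object, cohort, type = c("risk", "survival"),
                               times = NULL, ...) {
  type <- match.arg(type)
  X <- if (inherits(cohort, "cohort")) cohort$X else as.matrix(cohort)
  if (!is.null(object$feature_names) &&
      !is.null(colnames(X)) &&
      !identical(colnames(X), object$feature_names)) {
    X <- X[, object$feature_names, drop = FALSE]
  }
  h <- switch(object$kind,
              tabnet = tabnet_forward(object$par, X, object$hp)$log_risk,
              mlp = mlp_forward(object$par, X)$log_risk,
              linear = drop(X %*% object$par$beta))
  if (type == "risk") return(h)
  if (is.null(times)) stop("survival prediction needs a `times` grid",
                           call. = FALSE)
  survival_from_hazard(h, object$baseline, times)
}

#' Serialize / restore a trained model bundle
#'
#' One structured text (YAML) file holding the encoder kind,
#' hyperparameters, flattened parameters, Breslow baseline hazard,
#' preprocessing statistics, and the training log -- everything needed to
#' reproduce predictions exactly at inference time.
#'
#' @param model A `risk_model`.
#' @param path File path.
#' @return `write_model_bundle` returns `path` invisibly;
#'   `read_model_bundle` the restored `risk_model`.
#' @export
write_model_bundle <- function(model, path) {
  bundle <- list(
    kind = model$kind,
    d = attr(model$par, "d"),
    hp = unclass(model$hp),
    theta = as.list(flatten_params(model$par)),
    baseline = lapply(as.list(model$baseline), as.list),
    train_log_risk = as.list(model$train_log_risk),
    feature_names = as.list(model$feature_names),
    log = lapply(model$log, as.list),
    preprocess = if (is.null(model$preprocess)) NULL else
      list(center = as.list(model$preprocess$center),
           scale = as.list(model$preprocess$scale),
           standardized = as.list(model$preprocess$standardized))
  )
  yaml::write_yaml(bundle, path, precision = 17L)
  invisible(path)
}

#' @rdname write_model_bundle
#' @export
read_model_bundle <- function(path) {
  b <- yaml::read_yaml(path)
  hp <- do.call(tabnet_hp, b$hp)
  template <- switch(b$kind,
                     tabnet = init_tabnet(b$d, hp, seed = 0L),
                     mlp = mlp_init(b$d, hp$width_d, seed = 0L),
                     linear = linear_init(b$d, seed = 0L))
  par <- unflatten_params(template, unlist(b$theta))
  baseline <- tibble::tibble(time = unlist(b$baseline$time) %||% numeric(0),
                             increment = unlist(b$baseline$increment) %||%
                               numeric(0),
                             cumhaz = unlist(b$baseline$cumhaz) %||%
                               numeric(0))
  class(baseline) <- c("baseline_hazard", class(baseline))
  pp <- NULL
  if (!is.null(b$preprocess)) {
    pp <- structure(list(center = unlist(b$preprocess$center),
                         scale = unlist(b$preprocess$scale),
                         standardized = unlist(b$preprocess$standardized)),
                    class = "preprocess_stats")
  }
  structure(list(kind = b$kind, par = par, hp = hp, baseline = baseline,
                 preprocess = pp,
                 train_log_risk = unlist(b$train_log_risk),
                 feature_names = unlist(b$feature_names),
                 log = list(train_loss = unlist(b$log$train_loss),
                            stop_loss = unlist(b$log$stop_loss),
                            stop_epoch = b$log$stop_epoch[[1]],
                            epochs_run = b$log$epochs_run[[1]])),
            class = "risk_model")
}

#' Attention masks and importance for a fitted attention model
#'
#' @param model A `risk_model` of kind `"tabnet"`.
#' @param cohort Preprocessed `cohort` or matrix.
#' @return The [tabnet_forward()] output (log-risk, masks, step
#'   contributions).
#' @export
model_masks <- function(model, cohort) {
  if (model$kind != "tabnet") {
    stop("attention masks exist only for the tabnet encoder", call. = FALSE)
  }
  X <- if (inherits(cohort, "cohort")) cohort$X else as.matrix(cohort)
  tabnet_forward(model$par, X, model$hp)
}
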