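#' Hyperparameters of the sequential-attention encoder
#'
#' @param n_steps Number of sequential decision steps (>= 1).
#' @param width_d Size of the decision representation fed to the scalar head.
#' @param width_a Size of the attention representation fed to the next
#'   step's attentive transformer.
#' @param lambda_sparse Weight of the entropy sparsity penalty on the
#'   attention masks (>= 0). Larger values push each mask toward fewer
#'   features.
#' @param gamma Prior relaxation (>= 1). After a step uses feature `j` with
#'   mask mass `m`, the feature's attention prior is multiplied by
#'   `gamma - m`; at `gamma = 1` a fully used feature becomes unusable at
#'   later steps.
#' @param learning_rate Adam learning rate.
#' @param max_epochs Maximum full-batch training epochs.
#' @param patience Early-stopping patience, in epochs without improvement of
#'   the stopping-set partial likelihood.
#' @param stop_frac Fraction of the training data carved out (seeded) as the
#'   early-stopping set.
#' @param batch_size Minimum batch size for the partial-likelihood loss;
#'   cohorts here are fit full-batch so risk sets are exact.
#' @return A `tabnet_hp` list.
#' @export
tabnet_hp <- function(n_steps = 3L, width_d = 16L, width_a = 16L,
                      lambda_sparse = 1e-3, gamma = 1.3,
                      learning_rate = 0.01, max_epochs = 300L,
                      patience = 20L, stop_frac = 0.15, batch_size = 128L) {
  stopifnot(n_steps >= 1L, width_d >= 1L, width_a >= 1L, lambda_sparse >= 0,
            gamma >= 1, learning_rate > 0, max_epochs >= 1L, patience >= 1L,
            stop_frac > 0, stop_frac < 0.5)
  structure(list(n_steps = as.integer(n_steps), width_d = as.integer(width_d),
                 width_a = as.integer(width_a), lambda_sparse = lambda_sparse,
                 gamma = gamma, learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), stop_frac = stop_frac,
                 batch_size = as.integer(batch_size)),
            class = "tabnet_hp")
}

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

#' Initialize encoder parameters (seeded)
#'
#' Glorot-uniform weight matrices; biases zero; the initial attention
#' context `a0` is a learned vector shared across samples, so the first
#' step's mask depends only on parameters (and the attention prior), never
#' on unmasked features.
#'
#' @param d Encoded feature dimension.
#' @param hp A [tabnet_hp()].
#' @param seed Integer seed.
#' @return A parameter list.
#' @export
init_tabnet <- function(d, hp, seed = 1L) {
  withr::local_seed(as.integer(seed))
  k <- hp$width_d + hp$width_a
  par <- list(
    a0 = stats::rnorm(hp$width_a, 0, 0.1),
    att = lapply(seq_len(hp$n_steps), function(i) {
      list(W = glorot(hp$width_a, d), b = rep(0, d))
    }),
    shared = list(list(W = glorot(d, 2L * k), b = rep(0, 2L * k)),
                  list(W = glorot(k, 2L * k), b = rep(0, 2L * k))),
    step = lapply(seq_len(hp$n_steps), function(i) {
      list(list(W = glorot(k, 2L * k), b = rep(0, 2L * k)),
           list(W = glorot(k, 2L * k), b = rep(0, 2L * k)))
    }),
    head = list(w = stats::rnorm(hp$width_d, 0, 0.1), b = 0)
  )
  attr(par, "d") <- d
  par
}

glu_fwd <- function(x, W, b) {
  U <- x %*% W
  U <- sweep(U, 2L, b, "+")
  k <- ncol(U) %/% 2L
  a <- U[, seq_len(k), drop = FALSE]
  g <- stats::plogis(U[, k + seq_len(k), drop = FALSE])
  list(y = a * g, x = x, a = a, g = g)
}

glu_bwd <- function(cache, W, dy) {
  da <- dy * cache$g
  dgpre <- dy * cache$a * cache$g * (1 - cache$g)
  dU <- cbind(da, dgpre)
  list(dx = dU %*% t(W), dW = crossprod(cache$x, dU), db = colSums(dU))
}

#' One attentive-transformer step
#'
#' `mask = sparsemax(prior * (a %*% W + b))`; the updated prior is
#' `prior * (gamma - mask)`, so features attended to heavily at this step
#' are down-weighted at later steps (and excluded outright when
#' `gamma = 1`).
#'
#' @param a Attention context: length-`width_a` vector or n x width_a matrix.
#' @param prior Positive attention prior: length-D vector or n x D matrix.
#' @param W,b Linear-map parameters (width_a x D matrix, length-D bias).
#' @param gamma Prior relaxation (>= 1).
#' @return List with `mask` (simplex rows) and `prior` (updated).
#' @export
attentive_step <- function(a, prior, W, b, gamma = 1.3) {
  if (!is.matrix(a)) a <- matrix(a, nrow = 1L)
  if (!is.matrix(prior)) prior <- matrix(prior, nrow = nrow(a),
                                         ncol = length(prior), byrow = TRUE)
  if (any(prior < 0)) stop("prior entries must be nonnegative", call. = FALSE)
  Z <- sweep(a %*% W, 2L, b, "+")
  M <- sparsemax_rows(prior * Z)
  list(mask = drop(M), prior = drop(prior * (gamma - M)))
}

#' Feature transformer applied to masked covariates
#'
#' Two shared plus two step-specific gated linear (GLU) blocks with
#' `1/sqrt(2)` residual scaling; the output splits into the decision part
#' (fed, rectified, to the log-risk head) and the attention part (context
#' for the next attentive transformer). Deterministic given parameters and
#' independent across samples.
#'
#' @param masked_x Masked covariates: length-D vector or n x D matrix.
#' @param par Parameters from [init_tabnet()].
#' @param hp The matching [tabnet_hp()].
#' @param step Which step's specific blocks to use.
#' @return List with `decision` and `attention` parts.
#' @export
feature_transform <- function(masked_x, par, hp, step = 1L) {
  if (!is.matrix(masked_x)) masked_x <- matrix(masked_x, nrow = 1L)
  s <- sqrt(0.5)
  h1 <- glu_fwd(masked_x, par$shared[[1]]$W, par$shared[[1]]$b)$y
  h2 <- s * (h1 + glu_fwd(h1, par$shared[[2]]$W, par$shared[[2]]$b)$y)
  h3 <- s * (h2 + glu_fwd(h2, par$step[[step]][[1]]$W,
                          par$step[[step]][[1]]$b)$y)
  h4 <- s * (h3 + glu_fwd(h3, par$step[[step]][[2]]$W,
                          par$step[[step]][[2]]$b)$y)
  list(decision = drop(h4[, seq_len(hp$width_d), drop = FALSE]),
       attention = drop(h4[, hp$width_d + seq_len(hp$width_a),
                           drop = FALSE]))
}

#' Forward pass of the sequential-attention encoder
#'
#' At each decision step an attentive transformer maps the previous step's
#' attention context through a linear layer, multiplies by the running
#' prior, and projects with [sparsemax()] to a mask on the feature simplex.
#' The masked features pass through a feature transformer (two shared plus
#' two step-specific gated linear blocks, residual scaling `1/sqrt(2)`),
#' whose output splits into a decision part (rectified and summed across
#' steps into the scalar log-risk head) and the next attention context.
#' The prior update `prior * (gamma - mask)` discourages re-using features
#' already attended to.
#'
#' Computation is strictly per-sample: permuting or duplicating rows
#' permutes or duplicates the outputs.
#'
#' @param par Parameters from [init_tabnet()].
#' @param X Preprocessed n x D covariate matrix.
#' @param hp The [tabnet_hp()] used at initialization.
#' @param keep_cache Keep intermediate activations for the backward pass.
#' @return A list with `log_risk` (length n), `masks` (list of n x D
#'   simplex-row matrices, one per step), `eta` (n x n_steps nonnegative
#'   step contributions), and (optionally) `cache`.
#' @export
tabnet_forward <- function(par, X, hp, keep_cache = FALSE) {
  d <- attr(par, "d")
  if (ncol(X) != d) {
    stop("input has ", ncol(X), " features but parameters expect ", d,
         call. = FALSE)
  }
  n <- nrow(X)
  s <- sqrt(0.5)
  wd <- hp$width_d
  k <- hp$width_d + hp$width_a
  A <- matrix(par$a0, n, hp$width_a, byrow = TRUE)
  P <- matrix(1, n, d)
  AGG <- matrix(0, n, wd)
  masks <- vector("list", hp$n_steps)
  eta <- matrix(0, n, hp$n_steps)
  steps <- if (keep_cache) vector("list", hp$n_steps) else NULL
  for (i in seq_len(hp$n_steps)) {
    Zraw <- sweep(A %*% par$att[[i]]$W, 2L, par$att[[i]]$b, "+")
    Zp <- P * Zraw
    M <- sparsemax_rows(Zp)
    colnames(M) <- colnames(X)
    P_out <- P * (hp$gamma - M)
    MX <- M * X
    c1 <- glu_fwd(MX, par$shared[[1]]$W, par$shared[[1]]$b)
    h1 <- c1$y
    c2 <- glu_fwd(h1, par$shared[[2]]$W, par$shared[[2]]$b)
    h2 <- s * (h1 + c2$y)
    c3 <- glu_fwd(h2, par$step[[i]][[1]]$W, par$step[[i]][[1]]$b)
    h3 <- s * (h2 + c3$y)
    c4 <- glu_fwd(h3, par$step[[i]][[2]]$W, par$step[[i]][[2]]$b)
    h4 <- s * (h3 + c4$y)
    Dpart <- h4[, seq_len(wd), drop = FALSE]
    R <- pmax(Dpart, 0)
    AGG <- AGG + R
    eta[, i] <- rowSums(R)
    masks[[i]] <- M
    if (keep_cache) {
      steps[[i]] <- list(A_in = A, P_in = P, Zraw = Zraw, M = M,
                         c1 = c1, c2 = c2, c3 = c3, c4 = c4,
                         Dpart = Dpart)
    }
    A <- h4[, wd + seq_len(hp$width_a), drop = FALSE]
    P <- P_out
  }
  log_risk <- drop(AGG %*% par$head$w) + par$head$b
  out <- list(log_risk = log_risk, masks = masks, eta = eta)
  if (keep_cache) out$cache <- list(steps = steps, AGG = AGG, X = X)
  out
}

#' Backward pass: parameter gradients of a loss on (log_risk, masks)
#'
#' Pulls an upstream gradient `d_log_risk` (length n) and optional per-step
#' mask gradients `d_masks` back through the full unrolled computation,
#' including the sparsemax projections and the multiplicative prior chain.
#'
#' @param par,hp As in [tabnet_forward()].
#' @param fw Output of `tabnet_forward(..., keep_cache = TRUE)`.
#' @param d_log_risk Length-n gradient of the loss w.r.t. log-risk.
#' @param d_masks Optional list (per step) of n x D gradients w.r.t. masks.
#' @param want_dx Also return the gradient w.r.t. the input matrix.
#' @return A list of gradients with the same structure as `par` (plus `dX`
#'   if requested).
#' @export
tabnet_backward <- function(par, hp, fw, d_log_risk, d_masks = NULL,
                            want_dx = FALSE) {
  cache <- fw$cache
  if (is.null(cache)) stop("forward pass must keep_cache = TRUE", call. = FALSE)
  X <- cache$X
  n <- nrow(X); d <- ncol(X)
  s <- sqrt(0.5)
  wd <- hp$width_d
  g <- list(
    a0 = rep(0, hp$width_a),
    att = lapply(seq_len(hp$n_steps), function(i) {
      list(W = matrix(0, hp$width_a, d), b = rep(0, d))
    }),
    shared = list(list(W = 0 * par$shared[[1]]$W, b = 0 * par$shared[[1]]$b),
                  list(W = 0 * par$shared[[2]]$W, b = 0 * par$shared[[2]]$b)),
    step = lapply(seq_len(hp$n_steps), function(i) {
      list(list(W = 0 * par$step[[i]][[1]]$W, b = 0 * par$step[[i]][[1]]$b),
           list(W = 0 * par$step[[i]][[2]]$W, b = 0 * par$step[[i]][[2]]$b))
    }),
    head = list(w = drop(crossprod(cache$AGG, d_log_risk)),
                b = sum(d_log_risk))
  )
  dAGG <- outer(d_log_risk, par$head$w)
  dA_carry <- matrix(0, n, hp$width_a)
  dP_carry <- matrix(0, n, d)
  dX <- if (want_dx) matrix(0, n, d) else NULL
  for (i in rev(seq_len(hp$n_steps))) {
    st <- cache$steps[[i]]
    dD <- dAGG * (st$Dpart > 0)
    dh4 <- cbind(dD, dA_carry)
    b4 <- glu_bwd(st$c4, par$step[[i]][[2]]$W, s * dh4)
    g$step[[i]][[2]]$W <- g$step[[i]][[2]]$W + b4$dW
    g$step[[i]][[2]]$b <- g$step[[i]][[2]]$b + b4$db
    dh3 <- s * dh4 + b4$dx
    b3 <- glu_bwd(st$c3, par$step[[i]][[1]]$W, s * dh3)
    g$step[[i]][[1]]$W <- g$step[[i]][[1]]$W + b3$dW
    g$step[[i]][[1]]$b <- g$step[[i]][[1]]$b + b3$db
    dh2 <- s * dh3 + b3$dx
    b2 <- glu_bwd(st$c2, par$shared[[2]]$W, s * dh2)
    g$shared[[2]]$W <- g$shared[[2]]$W + b2$dW
    g$shared[[2]]$b <- g$shared[[2]]$b + b2$db
    dh1 <- s * dh2 + b2$dx
    b1 <- glu_bwd(st$c1, par$shared[[1]]$W, dh1)
    g$shared[[1]]$W <- g$shared[[1]]$W + b1$dW
    g$shared[[1]]$b <- g$shared[[1]]$b + b1$db
    dMX <- b1$dx
    dM <- dMX * X
    if (!is.null(d_masks) && !is.null(d_masks[[i]])) {
      dM <- dM + d_masks[[i]]
    }
    # prior update P_out = P_in * (gamma - M), consumed by later steps
    dM <- dM - dP_carry * st$P_in
    dZp <- sparsemax_backward(st$M, dM)
    dP_carry <- dP_carry * (hp$gamma - st$M) + dZp * st$Zraw
    dZraw <- dZp * st$P_in
    g$att[[i]]$W <- g$att[[i]]$W + crossprod(st$A_in, dZraw)
    g$att[[i]]$b <- g$att[[i]]$b + colSums(dZraw)
    dA_carry <- dZraw %*% t(par$att[[i]]$W)
    if (want_dx) dX <- dX + dMX * st$M
  }
  g$a0 <- colSums(dA_carry)
  if (want_dx) g$dX <- dX
  g
}

flatten_params <- function(par) {
  unlist(rapply(par, identity, how = "list"), use.names = FALSE)
}

unflatten_params <- function(template, v) {
  i <- 0L
  fill <- function(x) {
    if (is.list(x)) return(lapply(x, fill))
    len <- length(x)
    out <- v[i + seq_len(len)]
    i <<- i + len
    if (is.matrix(x)) dim(out) <- dim(x)
    out
  }
  out <- fill(template)
  attributes(out) <- attributes(template)
  out
}

#' Aggregate attention masks into feature importance
#'
#' Instance-level importance weights each step's mask by that step's
#' aggregate decision contribution `eta_i(b)` (the summed rectified
#' decision units), so steps that contribute more to the log-risk count
#' more. Global importance averages the normalized instance rows and is
#' renormalized to sum to one. A feature that no mask ever selects has
#' importance exactly zero.
#'
#' @param fw Output of [tabnet_forward()] (or a fitted model's stored
#'   forward output).
#' @return A list with `instance` (n x D matrix, rows summing to 1) and
#'   `global` (tibble of feature index and importance, sorted descending).
#' @export
aggregate_importance <- function(fw) {
  n_steps <- length(fw$masks)
  n <- nrow(fw$masks[[1L]])
  d <- ncol(fw$masks[[1L]])
  imp <- matrix(0, n, d, dimnames = list(NULL, colnames(fw$masks[[1L]])))
  for (i in seq_len(n_steps)) {
    imp <- imp + fw$eta[, i] * fw$masks[[i]]
  }
  tot <- rowSums(imp)
  if (all(tot == 0)) {
    warning("all decision contributions are zero; returning uniform importance")
    imp[] <- 1 / d
    tot <- rowSums(imp)
  }
  zero <- tot == 0
  tot[zero] <- 1
  inst <- imp / tot
  inst[zero, ] <- 1 / d
  glob <- colMeans(inst)
  glob <- glob / sum(glob)
  list(instance = inst,
       global = tibble::tibble(
         feature = colnames(fw$masks[[1L]]) %||% paste0("V", seq_len(d)),
         importance = unname(glob)
       ) |> dplyr::arrange(dplyr::desc(.data$importance)))
}

#' Export masks as a long-format table
#'
#' @param fw Output of [tabnet_forward()].
#' @return Tibble with columns `step`, `sample`, `feature`, `mass`.
#' @export
masks_long <- function(fw) {
  purrr::imap_dfr(fw$masks, function(M, i) {
    tibble::tibble(
      step = as.integer(i),
      sample = rep(seq_len(nrow(M)), times = ncol(M)),
      feature = rep(colnames(M) %||% paste0("V", seq_len(ncol(M))),
                    each = nrow(M)),
      mass = as.vector(M)
    )
  })
}
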