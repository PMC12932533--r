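small_hp <- function(...) {
  tabnet_hp(n_steps = 3, width_d = 4, width_a = 4, lambda_sparse = 1e-3,
            gamma = 1.3, ...)
}

test_that("every mask row lies on the probability simplex", {
  set.seed(12)
  hp <- small_hp()
  X <- matrix(rnorm(50 * 7), 50, 7)
  par <- init_tabnet(7, hp, seed = 4)
  fw <- tabnet_forward(par, X, hp)
  for (M in fw$masks) {
    expect_gte(min(M), 0)
    expect_lt(max(abs(rowSums(M) - 1)), 1e-6)
  }
  expect_true(all(is.finite(fw$log_risk)))
})

test_that("attentive step follows the prior update arithmetic", {
  d <- 5
  # symmetric inputs with an all-ones prior give the uniform mask
  st <- attentive_step(a = rep(0, 3), prior = rep(1, d),
                       W = matrix(0, 3, d), b = rep(0, d), gamma = 1.3)
  expect_equal(st$mask, rep(1 / d, d))
  expect_equal(st$prior, rep(1.3 - 1 / d, d))

  # a saturated mask at gamma = 1 excludes the feature thereafter
  # (competing features carry positive scores)
  b <- c(10, rep(1, d - 1))
  st1 <- attentive_step(rep(0, 3), rep(1, d), matrix(0, 3, d), b, gamma = 1)
  expect_equal(st1$mask, c(1, rep(0, d - 1)))
  expect_equal(st1$prior[1], 0)
  st2 <- attentive_step(rep(0, 3), st1$prior, matrix(0, 3, d), b, gamma = 1)
  expect_equal(st2$mask[1], 0)  # feature 1 unusable once prior hits 0

  # gamma = 1.3 with mask 1 leaves 0.3x the previous prior mass
  st3 <- attentive_step(rep(0, 3), rep(0.8, d), matrix(0, 3, d), b, gamma = 1.3)
  expect_equal(st3$prior[1], 0.8 * (1.3 - st3$mask[1]))
  expect_error(attentive_step(rep(0, 3), rep(-1, d), matrix(0, 3, d), b),
               "nonnegative")
})

test_that("prior telescoping bounds total mask mass at gamma = 1", {
  set.seed(15)
  hp <- tabnet_hp(n_steps = 4, width_d = 4, width_a = 4, gamma = 1)
  X <- matrix(rnorm(30 * 6), 30, 6)
  par <- init_tabnet(6, hp, seed = 2)
  fw <- tabnet_forward(par, X, hp)
  total <- Reduce(`+`, fw$masks)
  expect_lte(max(total), 1 + 1e-8)
})

test_that("feature transformer is deterministic and propagates nulls", {
  hp <- small_hp()
  par <- init_tabnet(5, hp, seed = 8)
  x <- rnorm(5)
  o1 <- feature_transform(x, par, hp, step = 2)
  o2 <- feature_transform(x, par, hp, step = 2)
  expect_identical(o1, o2)
  z <- feature_transform(rep(0, 5), par, hp, step = 1)
  # zero input with zero biases gives exactly zero activations
  expect_equal(z$decision, rep(0, hp$width_d))
  expect_equal(z$attention, rep(0, hp$width_a))
})

test_that("forward is sample-wise: permutation-equivariant and duplication-consistent", {
  set.seed(19)
  hp <- small_hp()
  X <- matrix(rnorm(20 * 6), 20, 6)
  par <- init_tabnet(6, hp, seed = 3)
  fw <- tabnet_forward(par, X, hp)
  perm <- sample(20)
  fwp <- tabnet_forward(par, X[perm, ], hp)
  expect_equal(fwp$log_risk, fw$log_risk[perm])
  fwd <- tabnet_forward(par, X[c(1, 1, 2), ], hp)
  expect_equal(fwd$log_risk[1], fwd$log_risk[2])
  expect_error(tabnet_forward(par, X[, 1:5], hp), "expect")

  hp1 <- tabnet_hp(n_steps = 1, width_d = 4, width_a = 4)
  par1 <- init_tabnet(6, hp1, seed = 3)
  fw1 <- tabnet_forward(par1, X, hp1)
  expect_length(fw1$masks, 1L)
  expect_length(fw1$log_risk, 20L)
})

test_that("gradient w.r.t. inputs vanishes for features never selected by any mask", {
  set.seed(44)
  hp <- tabnet_hp(n_steps = 2, width_d = 3, width_a = 3, gamma = 1.3)
  d <- 5
  par <- init_tabnet(d, hp, seed = 5)
  # force every step's attention scores to favor feature 1 overwhelmingly
  for (i in seq_len(hp$n_steps)) {
    par$att[[i]]$W[] <- 0
    par$att[[i]]$b <- c(50, rep(0, d - 1))
  }
  X <- matrix(rnorm(10 * d), 10, d)
  tm <- rexp(10) + 0.1; ev <- rep(1, 10)
  fw <- tabnet_forward(par, X, hp, keep_cache = TRUE)
  for (M in fw$masks) {
    expect_equal(unname(M[, 1]), rep(1, 10))
  }
  g <- tabnet_backward(par, hp, fw, cox_partial_nll_grad(fw$log_risk, tm, ev),
                       want_dx = TRUE)
  expect_equal(g$dX[, 2:d], matrix(0, 10, d - 1))
  expect_gt(max(abs(g$dX[, 1])), 0)
  # perturbing a masked-out feature leaves the output unchanged
  X2 <- X; X2[, 3] <- X2[, 3] + 5
  expect_equal(tabnet_forward(par, X2, hp)$log_risk, fw$log_risk)
})

test_that("analytic parameter gradients match central differences", {
  set.seed(52)
  hp <- small_hp()
  n <- 12; d <- 6
  X <- matrix(rnorm(n * d), n, d)
  tm <- rexp(n) + 0.1; ev <- rbinom(n, 1, 0.7); ev[2] <- 1
  par <- init_tabnet(d, hp, seed = 7)
  theta <- tabcox:::flatten_params(par)
  obj_of <- function(th) {
    p2 <- tabcox:::unflatten_params(par, th)
    fw <- tabnet_forward(p2, X, hp)
    total_objective(fw$log_risk, tm, ev, fw$masks, hp$lambda_sparse)
  }
  fw <- tabnet_forward(par, X, hp, keep_cache = TRUE)
  obj <- total_objective(fw$log_risk, tm, ev, fw$masks, hp$lambda_sparse,
                         gradient = TRUE)
  g <- tabcox:::flatten_params(
    tabnet_backward(par, hp, fw, obj$d_h, obj$d_masks))
  idx <- sample(length(theta), 80)
  eps <- 1e-5
  gf <- vapply(idx, function(k) {
    e <- rep(0, length(theta)); e[k] <- eps
    (obj_of(theta + e) - obj_of(theta - e)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(g[idx] - gf)) / max(abs(gf)), 1e-5)
})

test_that("aggregate importance weights masks by decision contribution", {
  set.seed(61)
  hp <- small_hp()
  X <- matrix(rnorm(40 * 5), 40, 5)
  colnames(X) <- paste0("f", 1:5)
  par <- init_tabnet(5, hp, seed = 1)
  fw <- tabnet_forward(par, X, hp)
  imp <- aggregate_importance(fw)
  expect_equal(sum(imp$global$importance), 1)
  expect_gte(min(imp$global$importance), 0)
  expect_equal(unname(rowSums(imp$instance)), rep(1, 40))

  # a feature with zero mask everywhere has importance exactly zero
  for (i in seq_len(hp$n_steps)) {
    par$att[[i]]$W[] <- 0
    par$att[[i]]$b <- c(50, rep(0, 4))
  }
  fw0 <- tabnet_forward(par, X, hp)
  imp0 <- aggregate_importance(fw0)
  g <- imp0$global
  expect_equal(g$importance[g$feature == "f1"], 1)
  expect_equal(sum(g$importance[g$feature != "f1"]), 0)

  # degenerate all-zero contributions fall back to uniform with a warning
  fw_zero <- fw
  fw_zero$eta[] <- 0
  expect_warning(impz <- aggregate_importance(fw_zero), "uniform")
  expect_equal(impz$global$importance, rep(1 / 5, 5))
})

test_that("masks export to a tidy long table", {
  hp <- small_hp()
  X <- matrix(rnorm(6 * 4), 6, 4, dimnames = list(NULL, paste0("v", 1:4)))
  par <- init_tabnet(4, hp, seed = 2)
  fw <- tabnet_forward(par, X, hp)
  long <- masks_long(fw)
  expect_equal(nrow(long), hp$n_steps * 6 * 4)
  expect_setequal(unique(long$feature), paste0("v", 1:4))
  sums <- dplyr::summarise(dplyr::group_by(long, step, sample),
                           s = sum(mass))
  expect_true(all(abs(sums$s - 1) < 1e-6))
})
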