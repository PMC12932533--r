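linear_model_stub <- function(beta, baseline = NULL) {
  # a bona fide risk_model with known linear log-risk, for closed-form checks
  par <- list(beta = beta)
  attr(par, "d") <- length(beta)
  structure(list(kind = "linear", par = par, hp = tabnet_hp(),
                 baseline = baseline, feature_names = names(beta),
                 log = list()),
            class = "risk_model")
}

test_that("VIF matches its regression definition", {
  set.seed(21)
  n <- 300
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  v <- vif(X)
  expect_equal(v$vif, rep(1, 3), tolerance = 0.1)  # independent covariates
  expect_equal(v$tolerance, 1 / v$vif)

  # x2 = x1 + small noise: VIF = 1/(1 - R^2) from the direct regression
  X2 <- cbind(x1 = rnorm(n), x2 = 0)
  X2[, "x2"] <- X2[, "x1"] + rnorm(n, sd = 0.1)
  X2 <- cbind(X2, x3 = rnorm(n))
  v2 <- vif(X2)
  r2 <- summary(lm(X2[, "x2"] ~ X2[, "x1"] + X2[, "x3"]))$r.squared
  expect_equal(v2$vif[v2$term == "x2"], 1 / (1 - r2), tolerance = 1e-8)

  Xd <- cbind(u = rnorm(n))
  Xd <- cbind(Xd, v = Xd[, "u"])
  expect_equal(vif(Xd)$vif, c(Inf, Inf))
  expect_error(vif(cbind(k = rep(1, 10))), "constant")
})

test_that("screening gates on p-value then collinearity before the joint fit", {
  sc <- simulate_cohort(sim_config(
    n = 1200, d_cont = 5, d_cat = 0, correlation = 0,
    effects = list(effect("x1", "linear", 0.8)), censor_rate = 0.25,
    seed = 17))
  res <- cox_screen_and_fit(sc$cohort)
  expect_true("x1" %in% res$univariable$term[res$univariable$selected])
  expect_true("x1" %in% res$multivariable$term)
  # permissive gates admit every candidate
  res_all <- cox_screen_and_fit(sc$cohort, alpha = 1, vif_max = Inf)
  expect_equal(sort(res_all$multivariable$term), paste0("x", 1:5))
  # a duplicated covariate cannot co-enter the joint fit
  co2 <- sc$cohort
  co2$X <- cbind(co2$X, x1copy = co2$X[, "x1"] + rnorm(1200, sd = 1e-4))
  res_dup <- cox_screen_and_fit(co2, candidates = c("x1", "x1copy"),
                                alpha = 1, vif_max = 5)
  expect_length(res_dup$multivariable$term, 1L)
  expect_length(res_dup$dropped_collinear, 1L)
})

test_that("decision curve reproduces its closed forms without censoring", {
  set.seed(5)
  n <- 500
  tm <- rexp(n, 1 / 20) + 0.1; ev <- rep(1, n)  # fully observed
  tau <- 15
  pi_prev <- mean(tm <= tau)
  ths <- seq(0.1, 0.9, by = 0.1)

  # treat-none is identically zero; treat-all matches pi - (1-pi) pt/(1-pt)
  dc <- decision_curve(runif(n), tm, ev, tau, thresholds = ths)
  tn <- dc[dc$strategy == "treat_none", ]
  expect_true(all(tn$net_benefit == 0))
  ta <- dc[dc$strategy == "treat_all", ]
  expect_equal(ta$net_benefit,
               pi_prev - (1 - pi_prev) * ths / (1 - ths), tolerance = 1e-12)

  # a perfect predictor attains NB = pi at every threshold
  s_perf <- as.numeric(tm > tau)  # S(tau) = 1 iff survives
  dcp <- decision_curve(s_perf, tm, ev, tau, thresholds = ths)
  mp <- dcp[dcp$strategy == "model", ]
  expect_equal(mp$net_benefit, rep(pi_prev, length(ths)), tolerance = 1e-12)
  # and no strategy can beat the prevalence
  expect_lte(max(dc$net_benefit), pi_prev + 1e-12)

  expect_error(decision_curve(runif(n), tm, ev, tau, thresholds = c(0.5, 1)),
               "strictly inside")
})

test_that("calibration curve recovers the diagonal for the true model", {
  cfg <- sim_config(n = 2000, d_cont = 3, d_cat = 0, correlation = 0,
                    effects = list(effect("x1", "linear", 1)),
                    baseline_shape = 1.5, baseline_scale = 24,
                    censor_rate = 0.25, seed = 33)
  sc <- simulate_cohort(cfg)
  tau <- 12
  s_true <- exp(-(tau / 24)^1.5 * exp(sc$true_log_risk))
  cal <- calibration_curve(s_true, sc$cohort$time, sc$cohort$event, tau,
                           bins = 5)
  expect_equal(nrow(cal), 5L)
  expect_lt(max(abs(cal$predicted - cal$observed)), 0.06)

  # anti-calibrated predictions produce a decreasing pattern
  anti <- calibration_curve(1 - s_true, sc$cohort$time, sc$cohort$event,
                            tau, bins = 5)
  expect_lt(cor(anti$predicted, anti$observed), 0)

  expect_warning(
    deg <- calibration_curve(rep(0.5, 100), sc$cohort$time[1:100],
                             sc$cohort$event[1:100], tau),
    "degenerate")
  expect_equal(nrow(deg), 1L)
})

test_that("attributions recover the additive closed form and are locally exact", {
  set.seed(10)
  n <- 20; d <- 4
  X <- matrix(rnorm(n * d), n, d, dimnames = list(NULL, paste0("x", 1:d)))
  bg <- matrix(rnorm(200 * d), 200, d, dimnames = list(NULL, colnames(X)))
  beta <- c(x1 = 1.5, x2 = -0.8, x3 = 0.3, x4 = 0)
  model <- linear_model_stub(beta)
  sh <- sampling_attribution(model, X, bg, n_samples = 200, seed = 2)

  # local accuracy is exact by construction
  expect_equal(rowSums(sh$phi) + sh$phi0, sh$log_risk, tolerance = 1e-10)
  # additive model: phi_j -> beta_j * (x_j - E[background x_j])
  for (j in 1:3) {
    expected <- beta[j] * (X[, j] - mean(bg[, j]))
    expect_equal(unname(sh$phi[, j]), unname(expected), tolerance = 0.15)
  }
  # an ignored feature attributes exactly zero under a linear model
  expect_equal(unname(sh$phi[, "x4"]), rep(0, n))

  td <- tidy(sh)
  expect_equal(nrow(td), n * d)
})

test_that("attributions vanish for features the attention model masks out", {
  set.seed(12)
  hp <- tabnet_hp(n_steps = 2, width_d = 4, width_a = 4)
  d <- 5
  par <- init_tabnet(d, hp, seed = 5)
  for (i in seq_len(hp$n_steps)) {
    par$att[[i]]$W[] <- 0
    par$att[[i]]$b <- c(50, rep(0, d - 1))  # only feature 1 ever selected
  }
  model <- structure(list(kind = "tabnet", par = par, hp = hp,
                          baseline = NULL, feature_names = NULL,
                          log = list()),
                     class = "risk_model")
  X <- matrix(rnorm(10 * d), 10, d)
  bg <- matrix(rnorm(50 * d), 50, d)
  sh <- sampling_attribution(model, X, bg, n_samples = 30, seed = 3)
  expect_equal(unname(sh$phi[, 2:d]), matrix(0, 10, d - 1))
  expect_equal(rowSums(sh$phi) + sh$phi0, sh$log_risk, tolerance = 1e-10)
})

test_that("Pearson matrix has the expected structure", {
  set.seed(44)
  n <- 10000
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  R <- pearson_matrix(X)
  expect_equal(diag(R), c(a = 1, b = 1, c = 1))
  expect_equal(R, t(R))
  expect_lt(max(abs(R[upper.tri(R)])), 0.05)  # independent columns

  X2 <- cbind(x = rnorm(100))
  X2 <- cbind(X2, y = X2[, "x"], z = -X2[, "x"])
  R2 <- pearson_matrix(X2)
  expect_equal(R2["x", "y"], 1)
  expect_equal(R2["x", "z"], -1)
  expect_error(pearson_matrix(cbind(k = rep(2, 10))), "constant")
})

test_that("hierarchical clustering recovers planted high-risk phenotypes", {
  set.seed(91)
  n <- 60
  # tumor-burden profile: high marker block; liver-dysfunction: low albumin
  blob1 <- cbind(matrix(rnorm(n * 2, 3), n, 2), matrix(rnorm(n * 2), n, 2))
  blob2 <- cbind(matrix(rnorm(n * 2), n, 2), matrix(rnorm(n * 2, -3), n, 2))
  X <- rbind(blob1, blob2)
  colnames(X) <- c("afp", "ggt", "alb", "lym")
  truth <- rep(1:2, each = n)
  cl <- highrisk_clustering(X, k = 2)
  # Rand index ~ 1 for well-separated blobs
  agree <- outer(cl$labels, cl$labels, "==") == outer(truth, truth, "==")
  rand <- mean(agree[upper.tri(agree)])
  expect_gt(rand, 0.95)
  # cluster means show the planted contrasts
  expect_gt(abs(cl$centers[1, "afp"] - cl$centers[2, "afp"]), 2)
  expect_gt(abs(cl$centers[1, "alb"] - cl$centers[2, "alb"]), 2)

  # silhouette-based selection also finds two groups
  cl_auto <- highrisk_clustering(X)
  expect_equal(cl_auto$k, 2L)

  # identical rows collapse to one cluster
  same <- matrix(1, 8, 3)
  cl_same <- highrisk_clustering(same)
  expect_equal(length(unique(cl_same$labels)), 1L)
  expect_error(highrisk_clustering(X, k = 500), "exceed")
  # row-order invariance up to label permutation
  perm <- sample(nrow(X))
  cl_p <- highrisk_clustering(X[perm, ], k = 2)
  agree_p <- outer(cl_p$labels, cl_p$labels, "==") ==
    outer(truth[perm], truth[perm], "==")
  expect_gt(mean(agree_p[upper.tri(agree_p)]), 0.95)
})
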