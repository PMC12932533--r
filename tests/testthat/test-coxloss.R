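test_that("Cox partial NLL matches hand-evaluated worked cases", {
  expect_equal(cox_partial_nll(c(0, 0), c(1, 2), c(1, 1)), log(2))
  expect_equal(cox_partial_nll(c(0, 0, 0), c(1, 2, 3), c(1, 1, 1)), log(6))
  expect_error(cox_partial_nll(c(0, 0), c(1, 2), c(0, 0)), "zero events")
  expect_error(cox_partial_nll(c(NA, 0), c(1, 2), c(1, 1)), "finite")
})

test_that("partial likelihood is location-invariant and tie handling is Breslow", {
  set.seed(5)
  h <- rnorm(20); tm <- sample(1:8, 20, replace = TRUE) + 0.5
  ev <- rbinom(20, 1, 0.6); ev[1] <- 1
  expect_equal(cox_partial_nll(h + 3.7, tm, ev), cox_partial_nll(h, tm, ev))
  expect_equal(cox_partial_nll_grad(h + 3.7, tm, ev),
               cox_partial_nll_grad(h, tm, ev))

  # Breslow: d tied events at one time contribute d * log(full risk-set sum)
  h2 <- c(0.3, -0.2, 0.1, 0.4)
  tm2 <- c(2, 2, 5, 7); ev2 <- c(1, 1, 1, 0)
  s1 <- sum(exp(h2)); s2 <- sum(exp(h2[3:4]))
  expect_equal(cox_partial_nll(h2, tm2, ev2),
               -(h2[1] + h2[2] + h2[3]) + 2 * log(s1) + log(s2))
})

test_that("Cox NLL gradient matches central differences", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    h <- rnorm(n); tm <- round(rexp(n), 2) + 0.1
    ev <- rbinom(n, 1, 0.7); ev[sample(n, 1)] <- 1
    g <- cox_partial_nll_grad(h, tm, ev)
    eps <- 1e-6
    gf <- vapply(seq_len(n), function(k) {
      e <- rep(0, n); e[k] <- eps
      (cox_partial_nll(h + e, tm, ev) - cox_partial_nll(h - e, tm, ev)) /
        (2 * eps)
    }, numeric(1))
    expect_equal(g, gf, tolerance = 1e-6)
  }
})

one_hot_pad <- function(d) {
  m <- matrix(0, 3, d); m[, 1] <- 1; m
}

test_that("entropy penalty matches closed forms and rejects invalid masks", {
  one_hot <- diag(4)[c(1, 3), ]
  expect_equal(entropy_sparsity(one_hot), 0)
  unif <- matrix(1 / 5, 3, 5)
  expect_equal(entropy_sparsity(unif), log(5))
  expect_equal(entropy_sparsity(matrix(c(0.5, 0.5), 1)), log(2))
  # normalization averages over steps and batch
  expect_equal(entropy_sparsity(list(unif, one_hot_pad(5))),
               (3 * log(5) + 0) / (2 * 3))
  expect_error(entropy_sparsity(matrix(c(-0.1, 1.1), 1)), "nonnegative")
})

test_that("total objective reduces to the partial NLL and its gradient is exact", {
  set.seed(77)
  n <- 15; d <- 6; steps <- 2
  h <- rnorm(n); tm <- rexp(n) + 0.1; ev <- rbinom(n, 1, 0.7); ev[1] <- 1
  # entries bounded away from 0 so central differences stay accurate
  masks <- lapply(1:steps, function(i) {
    m <- matrix(runif(n * d, 0.2, 1), n, d); m / rowSums(m)
  })
  expect_equal(total_objective(h, tm, ev, masks, lambda_sparse = 0),
               cox_partial_nll(h, tm, ev))
  oh <- lapply(1:steps, function(i) {
    m <- matrix(0, n, d); m[cbind(1:n, sample(d, n, TRUE))] <- 1; m
  })
  expect_equal(total_objective(h, tm, ev, oh, lambda_sparse = 0.5),
               cox_partial_nll(h, tm, ev))

  lam <- 0.05
  obj <- total_objective(h, tm, ev, masks, lam, gradient = TRUE)
  eps <- 1e-6
  gf_h <- vapply(seq_len(n), function(k) {
    e <- rep(0, n); e[k] <- eps
    (total_objective(h + e, tm, ev, masks, lam) -
       total_objective(h - e, tm, ev, masks, lam)) / (2 * eps)
  }, numeric(1))
  expect_equal(obj$d_h, gf_h, tolerance = 1e-6)
  for (k in sample(n * d, 10)) {
    for (i in 1:steps) {
      mp <- masks; mp[[i]][k] <- mp[[i]][k] + eps
      mm <- masks; mm[[i]][k] <- mm[[i]][k] - eps
      fd <- (total_objective(h, tm, ev, mp, lam) -
               total_objective(h, tm, ev, mm, lam)) / (2 * eps)
      expect_equal(obj$d_masks[[i]][k], fd, tolerance = 1e-5)
    }
  }
})

test_that("Breslow baseline reduces to Nelson-Aalen at h = 0 and is shift-consistent", {
  # n=2, both events, h = 0: increments 1/2 then 1/1
  bh <- breslow_baseline(c(0, 0), c(1, 2), c(1, 1))
  expect_equal(bh$increment, c(1 / 2, 1))
  expect_equal(bh$cumhaz, c(0.5, 1.5))

  set.seed(3)
  n <- 30; tm <- round(rexp(n), 1) + 0.1; ev <- rbinom(n, 1, 0.6); ev[1] <- 1
  bh0 <- breslow_baseline(rep(0, n), tm, ev)
  na_fit <- survival::survfit(survival::Surv(tm, ev) ~ 1, ctype = 1)
  na_inc <- na_fit$n.event[na_fit$n.event > 0] /
    na_fit$n.risk[na_fit$n.event > 0]
  expect_equal(bh0$increment, na_inc)

  # shifting h by c rescales Lambda0 by exp(-c)
  h <- rnorm(n)
  b1 <- breslow_baseline(h, tm, ev)
  b2 <- breslow_baseline(h + 1.3, tm, ev)
  expect_equal(b2$cumhaz, b1$cumhaz * exp(-1.3))
  expect_warning(breslow_baseline(c(0, 0), c(1, 2), c(0, 0)), "no events")
})

test_that("predicted survival is a proper nonincreasing curve", {
  set.seed(9)
  n <- 40; tm <- rexp(n) + 0.1; ev <- rbinom(n, 1, 0.7); ev[1] <- 1
  h <- rnorm(n)
  bh <- breslow_baseline(h, tm, ev)
  grid <- seq(0, max(tm), length.out = 25)
  S <- survival_from_hazard(h, bh, grid)
  expect_true(all(S >= 0 & S <= 1))
  expect_true(all(apply(S, 1, function(r) all(diff(r) <= 1e-12))))
  expect_true(all(S[, grid < min(bh$time)] == 1))
  # h = 0 matches exp(-Nelson-Aalen)
  S0 <- survival_from_hazard(0, bh, grid)
  expect_equal(as.vector(S0), exp(-cumhaz_at(bh, grid)))
  # larger h -> pointwise smaller survival
  Sa <- survival_from_hazard(c(0, 1), bh, grid)
  expect_true(all(Sa[2, bh$time[1] <= grid] <= Sa[1, bh$time[1] <= grid]))
  expect_error(survival_from_hazard(h, bh, c(-1, 2)), "nonnegative")
})
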