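test_that("simulation is seed-deterministic and structurally valid", {
  cfg <- sim_config(n = 300, d_cont = 4, d_cat = 1, correlation = 0.4,
                    effects = list(effect("x1", "linear", 1)), seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cohort$X, b$cohort$X)
  expect_identical(a$cohort$time, b$cohort$time)
  expect_identical(a$true_log_risk, b$true_log_risk)
  c2 <- simulate_cohort(sim_config(n = 300, d_cont = 4, d_cat = 1,
                                   correlation = 0.4,
                                   effects = list(effect("x1", "linear", 1)),
                                   seed = 43))
  expect_false(identical(a$cohort$time, c2$cohort$time))

  expect_equal(a$cohort$time, pmin(a$true_event_time, a$censor_time))
  expect_equal(a$cohort$event,
               as.integer(a$true_event_time <= a$censor_time))
  expect_true(all(a$cohort$time > 0))
})

test_that("effect forms assemble the declared ground-truth log-risk", {
  cfg <- sim_config(n = 200, d_cont = 3, d_cat = 1, correlation = 0,
                    effects = list(effect("x1", "linear", 0.5),
                                   effect("x2", "threshold", 1, at = 0.3),
                                   effect(c("x1", "x3"), "interaction", -0.4),
                                   effect("z1", "null")),
                    seed = 11)
  sc <- simulate_cohort(cfg)
  X <- sc$cohort$X
  manual <- 0.5 * X[, "x1"] + 1 * (X[, "x2"] > 0.3) -
    0.4 * X[, "x1"] * X[, "x3"]
  expect_equal(sc$true_log_risk, unname(manual))
})

test_that("near-null effects give chance-level oracle concordance", {
  cfg <- sim_config(n = 4000, d_cont = 3, d_cat = 0,
                    effects = list(effect("x1", "linear", 1e-12)),
                    censor_rate = 0.2, seed = 5)
  sc <- simulate_cohort(cfg)
  expect_lt(max(abs(sc$true_log_risk)), 1e-8)
  # break exact ties in the scores for a meaningful concordance
  expect_equal(concordance_index(rnorm(4000), sc$cohort$time,
                                 sc$cohort$event), 0.5, tolerance = 0.02)
})

test_that("the censoring rate calibration hits its target", {
  for (s in 1:5) {
    cfg <- sim_config(n = 2000, d_cont = 4, d_cat = 0,
                      effects = list(effect("x1", "linear", 1)),
                      censor_rate = 0.3, seed = s)
    sc <- simulate_cohort(cfg)
    expect_lt(abs(mean(sc$cohort$event == 0) - 0.3), 0.03)
  }
  cfg2 <- sim_config(n = 1000, d_cont = 2, d_cat = 0,
                     effects = list(effect("x1", "linear", 0.5)),
                     censor_rate = 0.7, seed = 2)
  expect_lt(abs(mean(simulate_cohort(cfg2)$cohort$event == 0) - 0.7), 0.04)
})

test_that("event times follow the Weibull proportional-hazards model", {
  # with k = 1 (exponential baseline), scaling exp(h) by 2 halves the
  # median event time
  base <- list(n = 5000L, d_cont = 1L, d_cat = 0L, correlation = 0,
               baseline_shape = 1, baseline_scale = 10, censor_rate = 0.1)
  mk <- function(beta, seed) {
    cfg <- do.call(sim_config, c(base, list(
      effects = list(effect("x1", "threshold", beta, at = -Inf)),
      seed = seed)))
    simulate_cohort(cfg)
  }
  s0 <- mk(1e-12, 21)   # h ~ 0
  s1 <- mk(log(2), 21)  # h = log 2 for everyone
  ratio <- median(s1$true_event_time) / median(s0$true_event_time)
  expect_equal(ratio, 0.5, tolerance = 0.03)

  # marginal KM at h = 0 converges to the closed-form Weibull survival
  cfg <- sim_config(n = 5000, d_cont = 1, d_cat = 0,
                    effects = list(effect("x1", "linear", 1e-12)),
                    baseline_shape = 1.5, baseline_scale = 24,
                    censor_rate = 0.2, seed = 8)
  sc <- simulate_cohort(cfg)
  km <- km_estimator(sc$cohort$time, sc$cohort$event)
  q <- km$time[km$time <= quantile(sc$cohort$time, 0.95)]
  s_true <- exp(-(q / 24)^1.5)
  expect_lt(max(abs(km_at(km, q) - s_true)), 0.03)
})

test_that("censoring is independent of the ground-truth risk", {
  cfg <- sim_config(n = 5000, d_cont = 3, d_cat = 0, correlation = 0.3,
                    effects = list(effect("x1", "linear", 1)),
                    censor_rate = 0.35, seed = 13)
  sc <- simulate_cohort(cfg)
  expect_lt(abs(cor(sc$censor_time, sc$true_log_risk)), 0.04)
})

test_that("oracle concordance is a strong-signal upper reference", {
  cfg <- sim_config(n = 3000, d_cont = 2, d_cat = 0,
                    effects = list(effect("x1", "linear", 2)),
                    censor_rate = 0.1, seed = 3)
  sc <- simulate_cohort(cfg)
  expect_gt(oracle_cindex(sc), 0.75)
  # degenerate two-subject cohort with one event
  tiny <- sc
  tiny$cohort <- tabcox:::subset_cohort(sc$cohort, 1:2)
  tiny$true_log_risk <- sc$true_log_risk[1:2]
  tiny$cohort$event <- c(1L, 0L)
  tiny$cohort$time <- c(1, 2)
  expect_true(oracle_cindex(tiny) %in% c(0, 0.5, 1))
})

test_that("cohort and ground truth round-trip through the sidecar files", {
  cfg <- sim_config(n = 50, d_cont = 2, d_cat = 1,
                    effects = list(effect("x1", "linear", 1)), seed = 77)
  sc <- simulate_cohort(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sim_cohort(sc, path)
  sch <- cohort_schema(feature_spec("x1", "continuous"),
                       feature_spec("x2", "continuous"),
                       feature_spec("z1", "categorical", c("0", "1")))
  back <- load_cohort(path, sch)
  expect_equal(back$X, sc$cohort$X, tolerance = 1e-12)
  truth <- readr::read_csv(paste0(path, ".truth.csv"),
                           show_col_types = FALSE)
  expect_equal(truth$true_log_risk, sc$true_log_risk, tolerance = 1e-12)
})
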