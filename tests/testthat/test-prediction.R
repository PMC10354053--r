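test_that("conditional survival is 1 at the landmark and matches the exponential closed form", {
  frozen <- freeze_fit(shared_cv_fit()$fit, log_h0 = log(0.25), alpha_value = 0)
  hist <- data.frame(time = c(0.5, 1.5, 2.5), y = c(0.1, 0.2, 0.1))
  pr <- conditional_survival(frozen, hist, t = 3, u = c(3, 4, 5.5, 7),
                             n_mc = 400, seed = 1)
  expect_equal(pr$surv$mean[1], 1)
  expect_lt(max(abs(pr$surv$mean - exp(-0.25 * (pr$surv$u - 3)))), 1e-8)
  # bands contain the mean and survival is non-increasing in the horizon
  expect_true(all(pr$surv$lo <= pr$surv$mean + 1e-12 &
                    pr$surv$mean <= pr$surv$hi + 1e-12))
  expect_true(all(diff(pr$surv$mean) <= 1e-12))
  expect_error(conditional_survival(frozen, hist[0, ], 3, 4), "history")
  expect_error(conditional_survival(frozen, hist, 3, 2), "u >= t")
})

test_that("Monte-Carlo conditional survival agrees with direct quadrature under fixed effects", {
  sh <- shared_cv_fit()
  frozen <- freeze_fit(sh$fit, log_h0 = log(0.15), alpha_value = 0.8)
  # near-noiseless history pins the subject's random effects
  tms <- seq(0.5, 4, by = 0.5)
  X <- msjoint:::ncs_design(tms, frozen$spline, 0)
  bfix <- c(0.4, 0.1, -0.05, 0.02)
  hist <- data.frame(time = tms, y = drop(X %*% (frozen$theta + bfix)))
  pr <- conditional_survival(frozen, hist, t = 4, u = c(4, 6), n_mc = 3000, seed = 2)
  # oracle: E over b-posterior is concentrated; integrate hazard on dense grid
  pm <- frozen$traj_means
  V <- solve(crossprod(X) / pm$sigma^2 + solve(pm$D))
  mu_b <- drop(V %*% crossprod(X, hist$y - drop(X %*% frozen$theta))) / pm$sigma^2
  grid <- seq(4, 6, length.out = 20001)
  mgrid <- drop(msjoint:::ncs_design(grid, frozen$spline, 0) %*% (frozen$theta + mu_b))
  H <- sum(0.15 * exp(0.8 * mgrid[-1])) * diff(grid[1:2])
  expect_lt(abs(pr$surv$mean[2] - exp(-H)), 0.02)
})

test_that("the dynamic AUC estimator reproduces hand-enumerated concordance", {
  # perfect ordering
  perf <- data.frame(pi = c(0.2, 0.4, 0.7, 0.9), omega = c(1, 1, 0, 0))
  expect_equal(dynamic_auc(NULL, NULL, 2.5, 2.5, predictions = perf), 1.0)
  # swapping one pair gives 3 of 4 concordant pairs
  swap <- data.frame(pi = c(0.2, 0.7, 0.4, 0.9), omega = c(1, 1, 0, 0))
  expect_equal(dynamic_auc(NULL, NULL, 2.5, 2.5, predictions = swap), 0.75)
  # ties count one half
  ties <- data.frame(pi = c(0.5, 0.5), omega = c(1, 0))
  expect_equal(dynamic_auc(NULL, NULL, 2.5, 2.5, predictions = ties), 0.5)
  # censored subjects enter both sides weighted by omega
  cens <- data.frame(pi = c(0.2, 0.6, 0.9), omega = c(1, 0.5, 0))
  num <- 1 * 0.5 * 1 + 1 * 1 * 1 + 0.5 * 1 * 1
  den <- 0.5 + 1 + 0.5 * 1 + 0.5 * 0.5 * 0  # pairs (1,2),(1,3),(2,3)
  expect_equal(dynamic_auc(NULL, NULL, 2.5, 2.5, predictions = cens),
               num / (0.5 + 1 + 0.5))
  # no comparable pairs
  expect_true(is.na(suppressMessages(
    dynamic_auc(NULL, NULL, 2.5, 2.5,
                predictions = data.frame(pi = 0.4, omega = 1)))))
})

test_that("outcome-independent predictions give AUC near one half", {
  set.seed(9)
  n <- 500
  pr <- data.frame(pi = stats::runif(n), omega = stats::rbinom(n, 1, 0.4))
  auc <- dynamic_auc(NULL, NULL, 2.5, 2.5, predictions = pr)
  expect_lt(abs(auc - 0.5), 3 / sqrt(n))
})

test_that("prediction error reproduces Brier closed cases", {
  perf <- data.frame(pi = c(0, 0, 1, 1), omega = c(1, 1, 0, 0))
  expect_equal(prediction_error(NULL, NULL, 2.5, 2.5, predictions = perf), 0)
  half <- data.frame(pi = rep(0.5, 10), omega = stats::rbinom(10, 1, 0.5))
  expect_equal(prediction_error(NULL, NULL, 2.5, 2.5, predictions = half), 0.25)
  toy <- data.frame(pi = c(0.3, 0.8, 0.6), omega = c(1, 0, 0.5))
  expect_equal(prediction_error(NULL, NULL, 2.5, 2.5, predictions = toy),
               mean(c(0.09, 0.04, 0.5 * 0.36 + 0.5 * 0.16)))
})

test_that("rising marker histories lower the updated event-free probabilities", {
  frozen <- freeze_fit(shared_cv_fit()$fit, log_h0 = log(0.1), alpha_value = 1)
  rising <- function(t) 0.5 * t - 1
  p_at <- function(t) {
    tms <- seq(0.5, t, by = 0.5)
    conditional_survival(frozen, data.frame(time = tms, y = rising(tms)),
                         t = t, u = t + 2, n_mc = 800, seed = 5)$surv$mean[1]
  }
  probs <- c(p_at(2), p_at(4), p_at(6))
  expect_true(all(diff(probs) < 0))
})

test_that("model comparison tabulates metrics per landmark and flags a preference", {
  sh <- shared_cv_fit()
  data <- list(surv = sh$sim$surv, long = sh$sim$long)
  tab <- compare_models(list(cv = sh$fit), data, t_grid = c(2.5, 5, 7.5),
                        dt = 2.5, n_mc = 60, seed = 3)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$model, rep("cv", 3))
  expect_true(all(tab$auc >= 0 & tab$auc <= 1, na.rm = TRUE))
  expect_true(all(tab$pe >= 0, na.rm = TRUE))
  expect_equal(length(unique(tab$dic)), 1L)
  expect_equal(attr(tab, "preferred"), "cv")
  # identical fits give identical metrics
  tab2 <- compare_models(list(a = sh$fit, b = sh$fit), data, t_grid = 5,
                         dt = 2.5, n_mc = 40, seed = 4)
  expect_equal(tab2$auc[1], tab2$auc[2])
  expect_equal(tab2$pe[1], tab2$pe[2])
})

test_that("model-discriminating subjects: AUC above chance on associated data", {
  sh <- shared_cv_fit()
  data <- list(surv = sh$sim$surv, long = sh$sim$long)
  auc <- dynamic_auc(sh$fit, data, t = 2.5, dt = 2.5, n_mc = 80, seed = 6)
  expect_gt(auc, 0.5)
})
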