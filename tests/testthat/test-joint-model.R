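test_that("association terms follow the CV/CVS/CE hypotheses", {
  cv <- jm_spec("relapse", "CV", confounders = character(0))
  expect_equal(association_term(cv, list(value = 0.919), m = 1), 0.919)
  cvs <- jm_spec("relapse", "CVS", confounders = character(0))
  expect_equal(association_term(cvs, list(value = 0.5, slope = -2), m = 2,
                                m_slope = 0.25), 0.5)
  # cumulative effect of a constant marker m over (0, t] is alpha * m * t
  ce <- jm_spec("relapse", "CE", confounders = character(0))
  m <- 0.7; t <- 4.5; a <- 1.3
  expect_equal(association_term(ce, list(value = a), m = m, m_cum = m * t),
               a * m * t)
  # DMT interactions add duration-weighted marker terms
  dmt <- jm_spec("relapse", "CV", confounders = character(0),
                 dmt_interactions = TRUE)
  out <- association_term(dmt, list(value = 1,
                                    dmt_value = c(cat1 = -0.4, cat3 = -1)),
                          m = 2, dmt_durations = list(cat1 = 3, cat3 = 0.5))
  expect_equal(out, 2 - 0.4 * 3 * 2 - 1 * 0.5 * 2)
  expect_error(jm_spec("relapse", "CE", lag = 3), "lag")
})

test_that("a constant-coefficient VCJM reproduces the CCJM likelihood", {
  intervals <- data.frame(start = c(0, 1.2, 0), stop = c(1.2, 3.8, 2.5),
                          event = c(1L, 0L, 1L))
  marker <- list(value = function(t) 0.3 + 0.1 * t,
                 slope = function(t) rep(0.1, length(t)))
  base <- list(log_h0 = function(t) -1 + 0.05 * t, gamma = numeric(0))
  ccjm <- jm_spec("relapse", "CVS", confounders = character(0),
                  baseline = pspline_config(range = c(0, 10)))
  vcjm <- jm_spec("relapse", "CVS", confounders = character(0),
                  varying_coefficient = TRUE, vc_df = 4,
                  baseline = pspline_config(range = c(0, 10)))
  ll_c <- subject_log_likelihood(intervals, marker,
                                 c(base, list(alpha = list(value = 0.8, slope = -0.3))),
                                 ccjm)
  ll_v <- subject_log_likelihood(intervals, marker,
                                 c(base, list(alpha = list(value = rep(0.8, 4),
                                                           slope = rep(-0.3, 4)))),
                                 vcjm)
  expect_lt(abs(ll_c - ll_v), 1e-10)
})

test_that("survival log-likelihood matches exponential closed forms", {
  spec <- jm_spec("relapse", "CV", confounders = character(0))
  lam <- 0.37; T <- 4.2
  marker <- list(value = function(t) rep(0, length(t)))
  params <- list(log_h0 = function(t) rep(log(lam), length(t)),
                 gamma = numeric(0), alpha = list(value = 0))
  cens <- data.frame(start = 0, stop = T, event = 0L)
  expect_equal(subject_log_likelihood(cens, marker, params, spec), -lam * T,
               tolerance = 1e-10)
  ev <- data.frame(start = 0, stop = T, event = 1L)
  expect_equal(subject_log_likelihood(ev, marker, params, spec),
               log(lam) - lam * T, tolerance = 1e-10)
})

test_that("Gauss-Legendre integrals match a dense Riemann sum", {
  spec <- jm_spec("relapse", "CV", confounders = character(0))
  marker <- list(value = function(t) sin(t / 2))
  params <- list(log_h0 = function(t) -1 + 0.3 * t - 0.02 * t^2,
                 gamma = numeric(0), alpha = list(value = 0.6))
  iv <- data.frame(start = 0.4, stop = 6.3, event = 1L)
  ll <- subject_log_likelihood(iv, marker, params, spec)
  h <- function(t) exp(params$log_h0(t) + 0.6 * marker$value(t))
  grid <- seq(0.4, 6.3, length.out = 1e6 + 1)
  riemann <- sum(h((grid[-1] + grid[-length(grid)]) / 2)) * diff(grid[1:2])
  direct <- log(h(6.3)) - riemann
  expect_lt(abs(ll - direct) / abs(direct), 1e-6)
})

test_that("splitting an event-free interval leaves the likelihood unchanged", {
  spec <- jm_spec("relapse", "CVS", confounders = character(0))
  marker <- list(value = function(t) 0.2 * t, slope = function(t) rep(0.2, length(t)))
  params <- list(log_h0 = function(t) -0.5 - 0.1 * t, gamma = numeric(0),
                 alpha = list(value = 0.5, slope = 0.3))
  whole <- data.frame(start = 1, stop = 5, event = 0L)
  split3 <- data.frame(start = c(1, 2.2, 3.7), stop = c(2.2, 3.7, 5), event = 0L)
  expect_lt(abs(subject_log_likelihood(whole, marker, params, spec) -
                  subject_log_likelihood(split3, marker, params, spec)), 1e-8)
})

test_that("with alpha = 0 the likelihood reduces to an independent Cox-with-offset evaluation", {
  spec <- jm_spec("relapse", "CV", confounders = c("bmi"))
  iv <- data.frame(start = c(0, 1, 0), stop = c(1, 2.5, 1.8),
                   event = c(0L, 1L, 1L), bmi = c(27, 27, 31))
  params <- list(log_h0 = function(t) -1.2 + 0.1 * t,
                 gamma = c(bmi = 0.05), alpha = list(value = 0))
  marker <- list(value = function(t) 5 + t)  # must be irrelevant
  ll <- subject_log_likelihood(iv, marker, params, spec)
  # independent evaluation: piecewise exponential-type integration on a grid
  indep <- 0
  for (r in 1:3) {
    h <- function(t) exp(params$log_h0(t) + 0.05 * iv$bmi[r])
    indep <- indep - stats::integrate(h, iv$start[r], iv$stop[r],
                                      rel.tol = 1e-12)$value
    if (iv$event[r] == 1) indep <- indep + log(h(iv$stop[r]))
  }
  expect_equal(ll, indep, tolerance = 1e-8)
})

test_that("joint-model fits are bit-reproducible under a fixed seed", {
  truth <- recovery_truth(assoc_value = 0.8, assoc_slope = 0)
  sim <- simulate_joint_model_data(truth, 60, obs_times = c(0.5, 2, 4, 6, 8, 10),
                                   censor_time = 11, seed = 21)
  ser <- data.frame(subject_id = sim$long$subject_id, time = sim$long$time,
                    gpi = sim$long$y)
  tf <- fit_trajectory_model(ser, spline = truth$spline,
                             mcmc = mcmc_control(300, 150, 1, seed = 2))
  spec <- jm_spec("relapse", "CV", confounders = character(0),
                  baseline = pspline_config(n_basis = 8, range = c(0, 11)))
  f1 <- fit_joint_model(sim$surv, tf, spec, mcmc_control(400, 200, 2, seed = 7))
  f2 <- fit_joint_model(sim$surv, tf, spec, mcmc_control(400, 200, 2, seed = 7))
  expect_identical(jm_draws(f1), jm_draws(f2))
  expect_identical(f1$dic, f2$dic)
})

test_that("the Gelman-Rubin factor obeys its closed forms", {
  n <- 400
  x <- stats::rnorm(n)
  expect_equal(unname(gelman_rubin(list(x, x))), sqrt((n - 1) / n))
  set.seed(1)
  iid <- lapply(1:4, function(i) stats::rnorm(5000))
  expect_true(gelman_rubin(iid) > 0.99 && gelman_rubin(iid) < 1.02)
  set.seed(2)
  sep <- list(stats::rnorm(500, 0), stats::rnorm(500, 5))
  expect_gt(gelman_rubin(sep), 1.5)
  const <- list(rep(1, 100), rep(1, 100))
  expect_true(is.nan(gelman_rubin(const)))
})

test_that("DIC reduces to its closed forms", {
  # degenerate posterior: all draws identical
  d0 <- dic_from_deviance(rep(12.5, 100), 12.5)
  expect_equal(d0$pD, 0)
  expect_equal(d0$dic, 12.5)
  # normal mean model with known sigma: pD approaches 1
  set.seed(3)
  n <- 50; sigma <- 1
  y <- stats::rnorm(n, 2, sigma)
  mu_draws <- stats::rnorm(20000, mean(y), sigma / sqrt(n))
  dev <- vapply(mu_draws, function(m) sum((y - m)^2) / sigma^2, numeric(1))
  dd <- dic_from_deviance(dev, sum((y - mean(y))^2) / sigma^2)
  expect_lt(abs(dd$pD - 1), 0.05)
})

test_that("posterior summaries exponentiate to the reported hazard-ratio scale", {
  expect_equal(to_hazard_ratio(c(1.086, 1.068, 1.104)), c(2.96, 2.91, 3.02))
  expect_equal(to_hazard_ratio(c(0, 0, 0)), c(1, 1, 1))
  expect_equal(to_hazard_ratio(c(-0.387, -0.542, -0.233)), c(0.68, 0.58, 0.79))
  df <- to_hazard_ratio(data.frame(param = "a", mean = -1.580, lo = -1.880,
                                   hi = -1.280))
  expect_equal(unlist(df[, c("mean", "lo", "hi")], use.names = FALSE),
               c(0.21, 0.15, 0.28))
})
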