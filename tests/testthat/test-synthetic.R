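test_that("genotype simulation follows Hardy-Weinberg proportions", {
  G <- simulate_genotypes(400, 3, c(0.5, 0.5), seed = 1)
  expect_true(all(G %in% 0:2))
  # expected mean dosage 1 per SNP at MAF 0.5; SE = sqrt(0.5/400)
  expect_true(all(abs(colMeans(G) - 1) < 3 * sqrt(0.5 / 400)))

  rare <- simulate_genotypes(100, 4, c(1e-4, 1e-4), seed = 2)
  expect_gt(mean(rare == 0), 0.995)

  G2 <- simulate_genotypes(2000, 6, c(0.2, 0.2), seed = 3)
  hw <- c(0.64, 0.32, 0.04)
  for (g in 0:2) {
    p <- hw[g + 1L]
    se <- sqrt(p * (1 - p) / 2000)
    expect_true(all(abs(colMeans(G2 == g) - p) < 3 * se))
  }

  expect_identical(simulate_genotypes(50, 5, seed = 9),
                   simulate_genotypes(50, 5, seed = 9))
  expect_error(simulate_genotypes(10, 2, c(0, 0.6)), "maf_range")
  expect_error(simulate_genotypes(0, 2), "at least one")
})

test_that("disease course reproduces the base relapse rate under a null truth", {
  truth <- sim_truth(seed = 1, assoc_value = 0, relapse_rate = 0.3,
                     dmt_log_rr = c(cat1 = 0, cat3 = 0),
                     confounder_effects = c(sex = 0, log_age = 0, bmi = 0,
                                            relapse_count = 0, t2l = 0, vitd = 0))
  truth$snp_effects[, c("beta_main", "beta_time", "beta_lat")] <- 0
  G <- simulate_genotypes(500, 5, c(0.2, 0.4), seed = 4)
  co <- simulate_disease_course(G, truth, schedule = seq(0, 10, by = 1), seed = 5)
  per_subj <- tapply(co$visits$n_relapses, co$visits$subject_id, sum)
  se <- sqrt(3 / 500)   # Poisson mean 3 over 10 years
  expect_lt(abs(mean(per_subj) - 3), 3 * se)
})

test_that("zero move intensities freeze the EDSS series", {
  truth <- sim_truth(seed = 1, edss_up_rate = 0, edss_down_rate = 0)
  G <- simulate_genotypes(40, 10, c(0.1, 0.5), seed = 6)
  co <- simulate_disease_course(G, truth, seed = 7)
  rng <- tapply(co$visits$edss, co$visits$subject_id, function(e) diff(range(e)))
  expect_true(all(rng == 0))
})

test_that("a positive GPI-hazard association separates extreme GPI deciles", {
  truth <- sim_truth(seed = 3, assoc_value = 0.6)
  G <- simulate_genotypes(1000, 40, c(0.1, 0.5), seed = 8)
  co <- simulate_disease_course(G, truth, seed = 9)
  tr <- build_transitions(co$visits)
  # true GPI at mid follow-up
  eff <- truth$snp_effects
  gpi <- drop(G %*% (eff$beta_main + eff$beta_time * log(7.5)))
  qs <- stats::quantile(gpi, c(0.1, 0.9))
  rate <- function(ids) {
    s <- tr[tr$subject_id %in% ids, ]
    sum(s$event) / sum(s$stop - s$start)
  }
  top <- rownames(G)[gpi >= qs[2]]
  bottom <- rownames(G)[gpi <= qs[1]]
  expect_gt(rate(top), rate(bottom))
})

test_that("cohort generation is reproducible and respects the visit schedule", {
  truth <- sim_truth(seed = 2)
  G <- simulate_genotypes(30, 8, c(0.1, 0.5), seed = 10)
  a <- simulate_disease_course(G, truth, seed = 11)
  b <- simulate_disease_course(G, truth, seed = 11)
  expect_identical(a$visits, b$visits)
  expect_true(all(a$visits$edss * 2 == round(a$visits$edss * 2)))
  expect_true(all(tapply(a$visits$time, a$visits$subject_id,
                         function(t) all(diff(t) > 0))))
  expect_error(simulate_disease_course(G, truth, schedule = c(0, 20)), "15")
})

test_that("event times from the joint-model simulator match closed-form survival", {
  truth <- sim_truth(seed = 1, assoc_value = 0, assoc_slope = 0,
                     baseline_hazard = list(type = "constant", rate = 0.2))
  sim <- simulate_joint_model_data(truth, 2000, censor_time = 12, seed = 3)
  tev <- sim$surv$stop[sim$surv$event == 1]
  ks <- stats::ks.test(tev, function(t) stats::pexp(t, 0.2) / stats::pexp(12, 0.2))
  expect_gt(ks$p.value, 0.01)
})

test_that("noiseless markers equal the true subject trajectories", {
  truth <- sim_truth(seed = 1, resid_sd = 0)
  sim <- simulate_joint_model_data(truth, 25, seed = 4)
  X <- msjoint:::ncs_design(sim$long$time, truth$spline, 0)
  idx <- match(sim$long$subject_id, sprintf("S%04d", seq_len(25)))
  coefs <- sweep(sim$b, 2, truth$traj_fixed, "+")
  expect_equal(sim$long$y, rowSums(X * coefs[idx, ]), tolerance = 1e-12)
})

test_that("a unit marker shift under alpha = 1 multiplies the hazard by e", {
  base <- sim_truth(seed = 1, assoc_value = 1, assoc_slope = 0, resid_sd = 0,
                    re_cov = diag(1e-8, 4),
                    traj_fixed = c(0, 0, 0, 0),
                    baseline_hazard = list(type = "constant", rate = 0.1))
  shifted <- base
  shifted$traj_fixed <- c(1, 0, 0, 0)
  s0 <- simulate_joint_model_data(base, 800, censor_time = 6, seed = 5)
  s1 <- simulate_joint_model_data(shifted, 800, censor_time = 6, seed = 6)
  df <- rbind(data.frame(stop = s0$surv$stop, ev = s0$surv$event, g = 0),
              data.frame(stop = s1$surv$stop, ev = s1$surv$event, g = 1))
  cf <- survival::coxph(survival::Surv(stop, ev) ~ g, data = df)
  expect_lt(abs(unname(stats::coef(cf)) - 1), 3 * sqrt(diag(stats::vcov(cf))))
})

test_that("invalid random-effects covariances are rejected", {
  expect_error(sim_truth(re_cov = matrix(c(1, 2, 2, 1), 2),
                         traj_fixed = c(0, 0)), "positive definite")
  expect_error(simulate_joint_model_data(sim_truth(seed = 1), 5,
                                         obs_times = c(5, 6), censor_time = 4),
               "censor_time")
})
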