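# shared fixtures and independent oracles for the test suite

# hand-checkable EDSS visit fixture: 3 subjects, 7 reported relapses of which
# exactly 4 coincide with an absolute EDSS change >= 1 point at the stop visit
toy_visits <- function() {
  data.frame(
    subject_id = rep(c("A", "B", "C"), times = c(5, 4, 4)),
    time = c(0, 1, 2, 3, 4,   0, 1.5, 3, 4.5,   0, 2, 3, 5),
    edss = c(2, 3, 3, 2, 3.5, 1, 1.5, 3, 3,     4, 3, 4.5, 4.5),
    relapse_flag = c(FALSE, TRUE, TRUE, FALSE, TRUE,   # A: +1 (yes), 0 (no), +1.5 (yes)
                     FALSE, TRUE, TRUE, FALSE,         # B: +0.5 (no), +1.5 (yes)
                     FALSE, TRUE, FALSE, TRUE),        # C: -1 (yes), 0 (no)
    stringsAsFactors = FALSE)
}

# independent Breslow partial-likelihood oracle: direct risk-set enumeration
# on counting-process data with a single covariate, maximised by optimize()
breslow_loglik <- function(beta, start, stop, event, x) {
  ev_t <- stop[event == 1]
  ll <- 0
  for (k in seq_along(ev_t)) {
    t <- ev_t[k]
    i <- which(event == 1 & stop == t)[1L]
    risk <- which(start < t & stop >= t)
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

bf_breslow_coef <- function(start, stop, event, x, interval = c(-5, 5)) {
  stats::optimize(function(b) breslow_loglik(b, start, stop, event, x),
                  interval = interval, maximum = TRUE, tol = 1e-9)$maximum
}

# study conditions of the joint-model parameter-recovery design
recovery_truth <- function(assoc_value = 1.0, assoc_slope = 0.5) {
  sim_truth(seed = 1, assoc_value = assoc_value, assoc_slope = assoc_slope,
            baseline_hazard = list(type = "constant", rate = 0.08),
            re_cov = diag(c(0.5, 0.3, 0.15, 0.15)), resid_sd = 0.1)
}

recovery_obs_times <- function() seq(0.25, 11, by = 0.75)

fit_recovery_replicate <- function(truth, r, association = "CVS",
                                   n_subjects = 300,
                                   mcmc = mcmc_control(2000, 1000, 3, seed = 300 + r)) {
  sim <- simulate_joint_model_data(truth, n_subjects,
                                   obs_times = recovery_obs_times(),
                                   censor_time = 12, seed = 100 + r)
  ser <- data.frame(subject_id = sim$long$subject_id, time = sim$long$time,
                    gpi = sim$long$y)
  tf <- fit_trajectory_model(ser, spline = truth$spline,
                             mcmc = mcmc_control(800, 400, 1, seed = 200 + r))
  fit <- fit_joint_model(sim$surv, tf,
                         spec = jm_spec("relapse", association,
                                        confounders = character(0),
                                        baseline = pspline_config(range = c(0, 12))),
                         mcmc = mcmc)
  list(sim = sim, traj = tf, fit = fit)
}

# one moderate CV joint-model fit, built once per session and reused by the
# prediction tests
.shared <- new.env(parent = emptyenv())
shared_cv_fit <- function() {
  if (is.null(.shared$cv)) {
    truth <- recovery_truth(assoc_value = 1.0, assoc_slope = 0)
    .shared$cv <- fit_recovery_replicate(truth, r = 1, association = "CV",
                                         n_subjects = 120,
                                         mcmc = mcmc_control(1200, 600, 2, seed = 42))
  }
  .shared$cv
}

# turn a fitted CV joint model into one with fixed, known parameters
# (constant baseline log-hazard and fixed association), used to compare the
# Monte-Carlo prediction machinery against closed forms
freeze_fit <- function(fit, log_h0, alpha_value) {
  for (c in seq_along(fit$chains)) {
    fit$chains[[c]]$kappa[] <- log_h0     # partition of unity => constant h0
    fit$chains[[c]]$alpha[] <- alpha_value
    if (ncol(fit$chains[[c]]$gamma)) fit$chains[[c]]$gamma[] <- 0
  }
  fit
}
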