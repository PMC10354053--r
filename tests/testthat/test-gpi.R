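# single-interval exponential survival data with per-SNP log-HR effects,
# shaped like transition intervals
sim_cox_data <- function(n, betas, maf = 0.3, rate = 0.25, censor = 5, seed = 1) {
  msjoint:::.with_seed(seed, {
    G <- matrix(stats::rbinom(n * length(betas), 2, maf), n,
                dimnames = list(sprintf("S%04d", 1:n),
                                sprintf("snp%02d", seq_along(betas))))
    lp <- drop(G %*% betas)
    t <- stats::rexp(n, rate * exp(lp))
    ev <- as.integer(t <= censor)
    tr <- data.frame(subject_id = rownames(G), start = 0, stop = pmin(t, censor),
                     prev_edss = NA_real_, cur_edss = NA_real_,
                     relapse_reported = FALSE,
                     status = ifelse(ev == 1, "worsening", "stable"),
                     event = ev, relapse_event = ev == 1,
                     relapse_count = 0, latitude = 0, stringsAsFactors = FALSE)
    class(tr) <- c("transition_intervals", "data.frame")
    list(tr = tr, G = G)
  })
}

test_that("penalized selection honours the penalty limits", {
  d <- sim_cox_data(150, betas = rep(0, 8), seed = 2)
  expect_equal(select_variants(d$tr, d$G, "worsening", penalty = 10), character(0))
  expect_setequal(select_variants(d$tr, d$G, "worsening", penalty = 0),
                  colnames(d$G))
  expect_error(select_variants(d$tr[d$tr$event == 0, ][1:5, ], d$G, "worsening"),
               "events")
})

test_that("cross-validated selection finds a strong causal SNP among nulls", {
  hits <- 0L
  for (r in 1:20) {
    d <- sim_cox_data(500, betas = c(log(3), rep(0, 20)), rate = 0.35,
                      censor = 6, seed = 100 + r)
    sel <- select_variants(d$tr, d$G, "worsening", seed = r)
    hits <- hits + ("snp01" %in% sel)
  }
  expect_gte(hits, 18L)  # >= 90% of replicates
})

test_that("stage-1 coefficients match the brute-force Breslow partial likelihood", {
  # 6 subjects, 4 events in both genotype groups; risk sets enumerable by hand
  tr <- data.frame(subject_id = letters[1:6], start = 0,
                   stop = c(1, 2, 3, 4, 5, 6),
                   prev_edss = NA_real_, cur_edss = NA_real_,
                   relapse_reported = FALSE,
                   status = "stable",
                   event = c(1L, 1L, 0L, 1L, 0L, 1L),
                   relapse_event = FALSE, relapse_count = 0,
                   stringsAsFactors = FALSE)
  class(tr) <- c("transition_intervals", "data.frame")
  G <- matrix(c(1, 0, 1, 1, 0, 0), 6, 1,
              dimnames = list(letters[1:6], "snp01"))
  m <- fit_gpi_cox(tr, G, "snp01", outcome = "worsening",
                   time_interactions = FALSE, lat_interactions = FALSE,
                   frailty = FALSE, adjust = FALSE)
  oracle <- bf_breslow_coef(tr$start, tr$stop, tr$event, G[, 1])
  expect_equal(m$snp_terms$beta_main, oracle, tolerance = 1e-6)
})

test_that("an empty SNP set yields a null model with zero linear predictor", {
  m <- fit_gpi_cox(NULL, NULL, character(0), outcome = "relapse")
  expect_s3_class(m, "gpi_model")
  expect_equal(evaluate_gpi(m, c(snpX = 2), latitude = 1, time = 5), 0)
})

test_that("stage-1 confidence intervals cover a known log hazard ratio", {
  covered <- 0L
  for (r in 1:40) {
    d <- sim_cox_data(200, betas = log(2), rate = 0.2, censor = 8, seed = 500 + r)
    df <- data.frame(stop = d$tr$stop, ev = d$tr$event, g = d$G[, 1])
    cf <- survival::coxph(survival::Surv(stop, ev) ~ g, data = df, ties = "breslow")
    ci <- stats::confint(cf)
    covered <- covered + (ci[1] <= log(2) && ci[2] >= log(2))
  }
  expect_gte(covered, 33L)  # nominal 95%: P(<33 of 40) < 0.003
})

test_that("the GPI evaluates as a linear predictor of dosage, log-time and latitude", {
  m <- structure(list(outcome = "worsening",
                      snp_terms = data.frame(snp = c("a", "b"),
                                             beta_main = c(0.5, 0),
                                             beta_time = c(0, 0.1),
                                             beta_lat = c(0.2, 0)),
                      frailty_sd = 0,
                      adjustment = c(log_time = 9, latitude = 9)),
                 class = "gpi_model")
  # all coefficients zero
  m0 <- m; m0$snp_terms[, 2:4] <- 0
  expect_equal(evaluate_gpi(m0, c(a = 2, b = 1), 0.3, 4), 0)
  # g = 2 on beta_main 0.5 only
  expect_equal(evaluate_gpi(m, c(a = 2, b = 0), latitude = 0, time = 1), 1.0)
  # log-time interaction at t = e
  expect_equal(evaluate_gpi(m, c(a = 0, b = 1), latitude = 0, time = exp(1)), 0.1)
  # latitude interaction and linearity in dosage
  g1 <- c(a = 1, b = 2); g2 <- c(a = 2, b = 0)
  expect_equal(evaluate_gpi(m, g1 + g2, 0.7, 3),
               evaluate_gpi(m, g1, 0.7, 3) + evaluate_gpi(m, g2, 0.7, 3))
  expect_error(evaluate_gpi(m, c(a = 1, b = 1), 0, 0), "positive")
})

test_that("GPI series are constant in time iff all time interactions vanish", {
  G <- simulate_genotypes(20, 6, c(0.2, 0.5), seed = 3)
  visits <- data.frame(subject_id = rep(rownames(G), each = 3),
                       time = rep(c(1, 4, 9), 20),
                       latitude = rep(stats::rnorm(20), each = 3))
  m <- structure(list(outcome = "worsening",
                      snp_terms = data.frame(snp = colnames(G),
                                             beta_main = stats::rnorm(6, 0, 0.2),
                                             beta_time = 0,
                                             beta_lat = stats::rnorm(6, 0, 0.1)),
                      frailty_sd = 0, adjustment = c(log_time = 0, latitude = 0)),
                 class = "gpi_model")
  s <- compute_gpi_series(m, visits, G)
  expect_true(all(abs(tapply(s$gpi, s$subject_id, function(x) diff(range(x)))) < 1e-12))
  m$snp_terms$beta_time <- 0.2
  s2 <- compute_gpi_series(m, visits, G)
  drift <- tapply(seq_len(nrow(s2)), s2$subject_id,
                  function(i) diff(range(s2$gpi[i])))
  expect_true(any(drift > 1e-6))
})
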