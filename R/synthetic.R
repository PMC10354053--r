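#' Generative truth for synthetic cohorts
#'
#' Bundles every parameter the generators need: per-SNP log-hazard effects
#' (main, x log-time, x latitude), the association between the true genetic
#' prognostic index (GPI) and the hazards, DMT-duration interactions, the
#' baseline hazard, the longitudinal trajectory model (natural-spline fixed
#' effects, random-effects covariance, residual SD), confounder effects, and
#' the clinical-course intensities (relapse rate, EDSS up/down move rates and
#' step-size distribution).
#'
#' Defaults mirror the cohort the analysis targets: ~0.3 relapses per
#' subject-year, 4 recruitment sites at distinct latitudes, ~40 causal SNPs
#' with a minority carrying time- and latitude-interactions.
#'
#' @param snp_effects Data frame with columns `snp`, `beta_main`,
#'   `beta_time`, `beta_lat` (log-HR scale), or NULL to draw a default set.
#' @param n_snps Number of causal SNPs for the default draw.
#' @param assoc_value,assoc_slope Association of the current GPI value/slope
#'   with the log-hazard.
#' @param assoc_relapse,assoc_worsening Optional outcome-specific overrides of
#'   `assoc_value` for the clinical-course generator (GPI effect on the
#'   relapse intensity and on the EDSS worsening intensity respectively);
#'   both default to `assoc_value`.
#' @param dmt_interactions Named numeric `c(cat1 = ..., cat3 = ...)`:
#'   log-HR per GPI unit per year of DMT exposure.
#' @param baseline_hazard List: `list(type = "constant", rate = )`,
#'   `list(type = "weibull", shape = , scale = )`, or
#'   `list(type = "spline", coefs = , n_basis = , range = )`.
#' @param traj_fixed Fixed-effect coefficients (intercept + natural-spline
#'   terms) of the marker trajectory.
#' @param re_cov Random-effects covariance (symmetric positive definite,
#'   same dimension as `traj_fixed`).
#' @param resid_sd Measurement-noise SD (> 0).
#' @param confounder_effects Named log-HRs for sex (male), log(age at onset),
#'   BMI, relapse count, T2 lesion load, vitamin-D supplementation.
#' @param relapse_rate Baseline relapse intensity per subject-year.
#' @param edss_up_rate,edss_down_rate Baseline intensities (per year) of
#'   upward/downward EDSS moves in the first-order Markov kernel.
#' @param step_probs Probabilities of a 0.5 / 1.0 / 1.5-point move given a move.
#' @param spline [spline_config()] for the trajectory.
#' @param dmt_log_rr Named log rate-ratios of being on DMT category 1/3 for
#'   the clinical event intensities.
#' @param seed Seed for the default SNP-effect draw.
#' @return An object of class `sim_truth`.
#' @export
sim_truth <- function(snp_effects = NULL,
                      n_snps = 40,
                      assoc_value = 0.35,
                      assoc_slope = 0,
                      assoc_relapse = NULL,
                      assoc_worsening = NULL,
                      dmt_interactions = c(cat1 = 0, cat3 = 0),
                      baseline_hazard = list(type = "constant", rate = 0.2),
                      traj_fixed = c(0.2, 0.05, -0.1, 0.05),
                      re_cov = diag(c(0.4, 0.05, 0.05, 0.05)),
                      resid_sd = 0.25,
                      confounder_effects = c(sex = 0, log_age = 0, bmi = 0,
                                             relapse_count = 0, t2l = 0, vitd = 0),
                      relapse_rate = 0.3,
                      edss_up_rate = 0.35,
                      edss_down_rate = 0.20,
                      step_probs = c(0.40, 0.45, 0.15),
                      spline = spline_config(),
                      dmt_log_rr = c(cat1 = -0.25, cat3 = -0.5),
                      seed = 20260101) {
  if (is.null(snp_effects)) {
    snp_effects <- .with_seed(seed, data.frame(
      snp = sprintf("snp%02d", seq_len(n_snps)),
      beta_main = stats::rnorm(n_snps, 0, 0.15),
      beta_time = stats::rnorm(n_snps, 0, 0.08) * stats::rbinom(n_snps, 1, 0.4),
      beta_lat = stats::rnorm(n_snps, 0, 0.04) * stats::rbinom(n_snps, 1, 0.4),
      stringsAsFactors = FALSE
    ))
  }
  stopifnot(all(c("snp", "beta_main", "beta_time", "beta_lat") %in% names(snp_effects)))
  re_cov <- as.matrix(re_cov)
  if (!isSymmetric(re_cov, tol = 1e-8) ||
      min(eigen(re_cov, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("re_cov must be symmetric positive definite", call. = FALSE)
  if (length(traj_fixed) != nrow(re_cov))
    stop("traj_fixed and re_cov dimensions differ", call. = FALSE)
  if (resid_sd < 0) stop("resid_sd must be non-negative", call. = FALSE)
  if (abs(sum(step_probs) - 1) > 1e-8 || any(step_probs < 0))
    stop("step_probs must be a probability vector over steps 0.5/1.0/1.5",
         call. = FALSE)
  structure(list(snp_effects = snp_effects, assoc_value = assoc_value,
                 assoc_slope = assoc_slope,
                 assoc_relapse = assoc_relapse %||% assoc_value,
                 assoc_worsening = assoc_worsening %||% assoc_value,
                 dmt_interactions = dmt_interactions,
                 baseline_hazard = baseline_hazard, traj_fixed = traj_fixed,
                 re_cov = re_cov, resid_sd = resid_sd,
                 confounder_effects = confounder_effects,
                 relapse_rate = relapse_rate, edss_up_rate = edss_up_rate,
                 edss_down_rate = edss_down_rate, step_probs = step_probs,
                 spline = spline, dmt_log_rr = dmt_log_rr),
            class = "sim_truth")
}

# evaluate expr under its own seed, restoring the caller's RNG state after
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Baseline hazard function from its specification
#'
#' @param spec Baseline hazard spec (see [sim_truth()]).
#' @return A vectorized function `h0(t)`.
#' @export
baseline_hazard_fn <- function(spec) {
  switch(spec$type,
         constant = function(t) rep(spec$rate, length(t)),
         weibull = function(t)
           (spec$shape / spec$scale) * (pmax(t, 1e-12) / spec$scale)^(spec$shape - 1),
         spline = function(t)
           exp(drop(bspline_basis(t, spec$n_basis, spec$range) %*% spec$coefs)),
         stop("unknown baseline hazard type: ", spec$type, call. = FALSE))
}

#' Simulate a genotype dosage matrix
#'
#' Draws per-SNP allele frequencies uniformly from `maf_range` and genotypes
#' under Hardy-Weinberg equilibrium (dosage ~ Binomial(2, MAF)).
#'
#' @param n_subjects,n_snps Dimensions (>= 1).
#' @param maf_range Interval in (0, 0.5] for the minor-allele frequency.
#' @param seed Integer seed.
#' @return Integer matrix (subjects x SNPs) with entries in 0/1/2, subject
#'   ids as row names, SNP ids as column names, and the drawn MAFs as the
#'   `"maf"` attribute.
#' @export
simulate_genotypes <- function(n_subjects, n_snps, maf_range = c(0.05, 0.5),
                               seed = 1) {
  if (n_subjects < 1 || n_snps < 1) stop("need at least one subject and SNP",
                                         call. = FALSE)
  if (length(maf_range) != 2L || maf_range[1L] > maf_range[2L] ||
      maf_range[1L] <= 0 || maf_range[2L] > 0.5)
    stop("maf_range must be an interval within (0, 0.5]", call. = FALSE)
  .with_seed(seed, {
    maf <- stats::runif(n_snps, maf_range[1L], maf_range[2L])
    G <- matrix(stats::rbinom(n_subjects * n_snps, 2L,
                              rep(maf, each = n_subjects)),
                n_subjects, n_snps)
    dimnames(G) <- list(sprintf("S%04d", seq_len(n_subjects)),
                        sprintf("snp%02d", seq_len(n_snps)))
    attr(G, "maf") <- maf
    G
  })
}

# standardized latitudes of the four recruitment sites (southern hemisphere,
# Brisbane / Newcastle / Geelong / Tasmania), mean 0 SD 1 across sites
.site_latitudes <- function() {
  lat <- c(-27.5, -32.9, -38.1, -42.9)
  as.numeric(scale(lat))
}

# true time-dependent GPI for all subjects at one time (log-time floored at
# the first trajectory boundary knot to keep log() finite at onset)
.true_gpi <- function(G, truth, latitude, time) {
  eff <- truth$snp_effects[truth$snp_effects$snp %in% colnames(G), , drop = FALSE]
  G <- G[, eff$snp, drop = FALSE]
  if (!nrow(eff)) return(rep(0, nrow(G)))
  tfl <- pmax(time, truth$spline$boundary_knots[1L])
  b <- eff$beta_main + eff$beta_time * log(tfl)
  drop(G %*% b) + drop(G %*% eff$beta_lat) * latitude
}

#' Simulate a clinical-style synthetic cohort
#'
#' Generates visit records on a fixed schedule for the subjects in a
#' genotype matrix. Relapses arise from a subject-specific inhomogeneous
#' Poisson process whose log-rate includes the subject's true
#' time-dependent GPI and DMT exposure; EDSS evolves as a first-order Markov
#' chain on the 0.5-point grid whose per-interval move probabilities scale
#' with interval length and with the same true hazard multiplier. The two
#' processes are coupled only through the shared true GPI and covariates.
#'
#' @param genotypes Dosage matrix from [simulate_genotypes()].
#' @param truth A [sim_truth()].
#' @param schedule Visit times in years since onset, within \[0, 15\];
#'   defaults to assessments at 0, 2.5, 5 then annually to 15.
#' @param seed Integer seed.
#' @return A list of class `synthetic_cohort` with elements `visits` (data
#'   frame of visit records), `genotypes`, `truth`, `seed`.
#' @export
simulate_disease_course <- function(genotypes, truth,
                                    schedule = c(0, 2.5, 5:15), seed = 1) {
  stopifnot(inherits(truth, "sim_truth"))
  if (any(schedule < 0 | schedule > 15)) stop("schedule times must lie in [0, 15]",
                                              call. = FALSE)
  schedule <- sort(unique(schedule))
  n <- nrow(genotypes)
  ids <- rownames(genotypes)
  lat4 <- .site_latitudes()
  .with_seed(seed, {
    site <- sample.int(4L, n, replace = TRUE)
    latitude <- lat4[site]
    sex <- stats::rbinom(n, 1L, 57 / 253)               # 1 = male
    age_at_onset <- stats::rnorm(n, 37, 9)
    bmi <- stats::rnorm(n, 27.7, 4.5)
    t2l_count <- stats::rpois(n, 8.3)
    vitd_status <- stats::rbinom(n, 1L, 0.5)
    # DMT exposure windows: category 1 (first-line) then possibly category 3
    on1 <- stats::rbinom(n, 1L, 0.6) == 1L
    s1 <- ifelse(on1, stats::runif(n, 0.5, 5), Inf)
    on3 <- stats::rbinom(n, 1L, 0.3) == 1L
    s3 <- ifelse(on3, pmax(stats::runif(n, 5, 12), s1 + 0.5), Inf)
    e1 <- pmin(s3, 15)

    edss0 <- sample(seq(1, 3.5, by = 0.5), n, replace = TRUE,
                    prob = c(1, 1, 2, 3, 2, 1))
    conf_lp <- truth$confounder_effects["sex"] * sex +
      truth$confounder_effects["log_age"] * log(age_at_onset) +
      truth$confounder_effects["bmi"] * bmi +
      truth$confounder_effects["t2l"] * t2l_count +
      truth$confounder_effects["vitd"] * vitd_status

    rows <- vector("list", length(schedule))
    edss <- edss0
    for (k in seq_along(schedule)) {
      tk <- schedule[k]
      dur1 <- pmin(pmax(tk - s1, 0), pmax(e1 - s1, 0))
      dur3 <- pmin(pmax(tk - s3, 0), 15)
      cat_now <- ifelse(tk >= s3, "3", ifelse(tk >= s1 & tk < e1, "1", "none"))
      if (k > 1L) {
        t0 <- schedule[k - 1L]
        dt <- tk - t0
        tm <- (t0 + tk) / 2
        gpi_mid <- .true_gpi(genotypes, truth, latitude, tm)
        on_dmt1 <- tm >= s1 & tm < e1
        on_dmt3 <- tm >= s3
        dmt_lp <- truth$dmt_log_rr["cat1"] * on_dmt1 +
          truth$dmt_log_rr["cat3"] * on_dmt3
        mult_rel <- exp(truth$assoc_relapse * gpi_mid + conf_lp + dmt_lp)
        mult_wor <- exp(truth$assoc_worsening * gpi_mid + conf_lp + dmt_lp)
        n_rel <- stats::rpois(n, truth$relapse_rate * dt * mult_rel)
        p_up <- 1 - exp(-truth$edss_up_rate * dt * mult_wor)
        p_down <- 1 - exp(-truth$edss_down_rate * dt)
        u <- stats::runif(n)
        move <- ifelse(u < p_up, 1L, ifelse(u < p_up + (1 - p_up) * p_down, -1L, 0L))
        step <- sample(c(0.5, 1, 1.5), n, replace = TRUE, prob = truth$step_probs)
        edss <- pmin(pmax(edss + move * step, 0), 10)
        relapse_flag <- n_rel > 0
      } else {
        n_rel <- rep(0L, n)
        relapse_flag <- rep(FALSE, n)
      }
      rows[[k]] <- data.frame(
        subject_id = ids, time = tk, edss = edss, relapse_flag = relapse_flag,
        n_relapses = n_rel,
        sex = sex, age_at_onset = age_at_onset, bmi = bmi,
        t2l_count = t2l_count, vitd_status = vitd_status, site = site,
        latitude = latitude, dmt_category = cat_now,
        dur_dmt1 = dur1, dur_dmt3 = dur3, stringsAsFactors = FALSE)
    }
    visits <- do.call(rbind, rows)
    visits <- visits[order(visits$subject_id, visits$time), , drop = FALSE]
    rownames(visits) <- NULL
    structure(list(visits = visits, genotypes = genotypes, truth = truth,
                   seed = seed), class = "synthetic_cohort")
  })
}

#' Simulate data directly from the joint model
#'
#' Parameter-recovery harness: the longitudinal marker is
#' `y_i(t) = x(t)'(theta + b_i) + e`, and each subject's event time is drawn
#' by inverse-transform sampling from the hazard
#' `h_i(t) = h0(t) exp(w_i'beta_u + a1 m_i(t) + a2 m_i'(t))` via bracketed
#' root-finding on the numerically integrated cumulative hazard
#' (time tolerance 1e-8), with administrative censoring at `censor_time`.
#'
#' @param truth A [sim_truth()]; uses `traj_fixed`, `re_cov`, `resid_sd`,
#'   `assoc_value`, `assoc_slope`, `baseline_hazard`, `spline` and (when any
#'   are nonzero) `confounder_effects`.
#' @param n_subjects Number of subjects.
#' @param obs_times Scheduled marker observation times (years).
#' @param censor_time Administrative censoring time (> min obs time).
#' @param seed Integer seed.
#' @return List with `long` (subject_id, time, y), `surv` (a
#'   `transition_intervals` frame with one (0, T\] row per subject),
#'   `b` (true random effects), `truth`.
#' @export
simulate_joint_model_data <- function(truth, n_subjects,
                                      obs_times = c(0.5, 1, 2, 3, 5, 7, 9, 11),
                                      censor_time = 12, seed = 1) {
  stopifnot(inherits(truth, "sim_truth"))
  if (censor_time <= min(obs_times)) stop("censor_time must exceed the first observation time",
                                          call. = FALSE)
  p <- length(truth$traj_fixed)
  h0 <- baseline_hazard_fn(truth$baseline_hazard)
  gl <- pracma::gaussLegendre(15, -1, 1)
  .with_seed(seed, {
    b <- MASS::mvrnorm(n_subjects, mu = rep(0, p), Sigma = truth$re_cov)
    if (n_subjects == 1L) b <- matrix(b, 1L)
    coefs <- sweep(b, 2L, truth$traj_fixed, "+")   # theta + b_i, rows = subjects
    use_conf <- any(truth$confounder_effects != 0)
    if (use_conf) {
      W <- cbind(sex = stats::rbinom(n_subjects, 1, 57 / 253),
                 log_age = log(stats::rnorm(n_subjects, 37, 9)),
                 bmi = stats::rnorm(n_subjects, 27.7, 4.5),
                 relapse_count = stats::rpois(n_subjects, 2),
                 t2l = stats::rpois(n_subjects, 8.3),
                 vitd = stats::rbinom(n_subjects, 1, 0.5))
      wlp <- drop(W %*% truth$confounder_effects[colnames(W)])
    } else {
      W <- NULL
      wlp <- rep(0, n_subjects)
    }

    loghaz_i <- function(i, t) {
      X <- ncs_design(t, truth$spline, 0)
      Xd <- ncs_design(t, truth$spline, 1)
      m <- drop(X %*% coefs[i, ])
      md <- drop(Xd %*% coefs[i, ])
      log(h0(t)) + wlp[i] + truth$assoc_value * m + truth$assoc_slope * md
    }
    # panel-wise cumulative hazard, vectorised across subjects: 15-point
    # Gauss-Legendre on each 1-year panel, then bracketed root-finding
    # (time tolerance 1e-8) inside the panel containing the event
    brks <- unique(c(seq(0, censor_time, by = 1), censor_time))
    npan <- length(brks) - 1L
    Hpan <- matrix(0, n_subjects, npan)
    for (k in seq_len(npan)) {
      a <- brks[k]; bb <- brks[k + 1L]
      u <- (bb - a) / 2 * gl$x + (a + bb) / 2
      X <- ncs_design(u, truth$spline, 0)
      Xd <- ncs_design(u, truth$spline, 1)
      lh <- matrix(log(h0(u)), n_subjects, length(u), byrow = TRUE) + wlp +
        truth$assoc_value * (coefs %*% t(X)) +
        truth$assoc_slope * (coefs %*% t(Xd))
      Hpan[, k] <- (bb - a) / 2 * drop(exp(lh) %*% gl$w)
    }
    Hcum <- cbind(0, t(apply(Hpan, 1L, cumsum)))
    ev_time <- rep(censor_time, n_subjects)
    status <- integer(n_subjects)
    E <- stats::rexp(n_subjects)
    cumhaz_panel <- function(i, k, t) {
      # integral over [brks[k], t] within panel k
      a <- brks[k]
      if (t <= a) return(0)
      u <- (t - a) / 2 * gl$x + (a + t) / 2
      (t - a) / 2 * sum(gl$w * exp(loghaz_i(i, u)))
    }
    hit <- which(Hcum[, npan + 1L] > E)
    for (i in hit) {
      k <- findInterval(E[i], Hcum[i, ], rightmost.closed = TRUE)
      ev_time[i] <- stats::uniroot(
        function(t) Hcum[i, k] + cumhaz_panel(i, k, t) - E[i],
        lower = brks[k], upper = brks[k + 1L], tol = 1e-8, extendInt = "upX")$root
      status[i] <- 1L
    }
    ids <- sprintf("S%04d", seq_len(n_subjects))
    # the marker schedule runs to administrative censoring: the survival side
    # emulates recurrent events (relapses / worsening transitions), under
    # which subjects remain in follow-up after an event
    keep <- obs_times[obs_times <= censor_time]
    long <- data.frame(
      subject_id = rep(ids, each = length(keep)),
      time = rep(keep, n_subjects), stringsAsFactors = FALSE)
    Xl <- ncs_design(long$time, truth$spline, 0)
    idx <- match(long$subject_id, ids)
    long$y <- rowSums(Xl * coefs[idx, , drop = FALSE]) +
      stats::rnorm(nrow(long), 0, truth$resid_sd)

    surv <- data.frame(subject_id = ids, start = 0, stop = ev_time,
                       prev_edss = NA_real_, cur_edss = NA_real_,
                       relapse_reported = FALSE,
                       status = ifelse(status == 1L, "worsening", "stable"),
                       event = status, relapse_event = FALSE,
                       relapse_count = 0, stringsAsFactors = FALSE)
    if (use_conf) surv <- cbind(surv, as.data.frame(W))
    class(surv) <- c("transition_intervals", "data.frame")
    list(long = long, surv = surv, b = b, truth = truth)
  })
}

#' Write a synthetic cohort to disk
#'
#' Writes the visit table and genotype dosage matrix as CSV.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vp <- file.path(dir, "visits.csv")
  gp <- file.path(dir, "genotypes.csv")
  utils::write.csv(cohort$visits, vp, row.names = FALSE)
  utils::write.csv(data.frame(subject_id = rownames(cohort$genotypes),
                              cohort$genotypes, check.names = FALSE),
                   gp, row.names = FALSE)
  invisible(c(visits = vp, genotypes = gp))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic MS cohort:", length(unique(x$visits$subject_id)), "subjects,",
      nrow(x$visits), "visits,", ncol(x$genotypes), "SNPs (seed", x$seed, ")\n")
  invisible(x)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Simulation truth:", nrow(x$snp_effects), "causal SNPs; assoc value/slope =",
      x$assoc_value, "/", x$assoc_slope, "; baseline:", x$baseline_hazard$type, "\n")
  invisible(x)
}
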