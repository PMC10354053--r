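#' Baseline-hazard P-spline configuration
#'
#' @param n_basis Number of cubic B-spline basis functions (default 12).
#' @param range Support `c(0, max follow-up)`.
#' @param penalty_order Difference order of the smoothness penalty (default 2).
#' @return List of class `pspline_config`.
#' @export
pspline_config <- function(n_basis = 12, range = c(0, 15), penalty_order = 2L) {
  structure(list(n_basis = n_basis, range = range,
                 penalty_order = as.integer(penalty_order)),
            class = "pspline_config")
}

#' P-spline log baseline hazard
#'
#' Evaluates `log h0(t)` as a cubic B-spline expansion on an equidistant
#' knot grid. The smoothness penalty used in estimation is the second-order
#' difference penalty on the coefficients with a gamma hyperprior on the
#' inverse smoothing variance.
#'
#' @param coeffs Spline coefficients (length `config$n_basis`).
#' @param time Evaluation times within `config$range`.
#' @param config A [pspline_config()].
#' @return Numeric vector of log baseline-hazard values.
#' @export
pspline_log_baseline <- function(coeffs, time, config = pspline_config()) {
  drop(bspline_basis(time, config$n_basis, config$range) %*% coeffs)
}

#' Joint model specification
#'
#' @param outcome `"relapse"` or `"worsening"` (the survival side).
#' @param association `"CV"` (current value), `"CVS"` (current value and
#'   slope) or `"CE"` (cumulative effects).
#' @param lag Survival-time lag in months (0, 3 or 6); cannot be combined
#'   with `"CE"`.
#' @param varying_coefficient Fit the varying-coefficient model (VCJM) with
#'   B-spline association coefficients of dimension `vc_df` (>= 2).
#' @param vc_df Spline dimension for the VCJM association function.
#' @param confounders Character vector among `sex`, `log_age`, `bmi`,
#'   `relapse_count`, `t2l`, `vitd` (default: all six).
#' @param dmt_interactions Include GPI x DMT-duration interaction terms.
#' @param baseline A [pspline_config()].
#' @return Object of class `jm_spec`.
#' @export
jm_spec <- function(outcome = c("relapse", "worsening"),
                    association = c("CV", "CVS", "CE"),
                    lag = 0, varying_coefficient = FALSE, vc_df = 4,
                    confounders = c("sex", "log_age", "bmi", "relapse_count",
                                    "t2l", "vitd"),
                    dmt_interactions = FALSE,
                    baseline = pspline_config()) {
  outcome <- match.arg(outcome)
  association <- match.arg(association)
  if (association == "CE" && lag > 0)
    stop("cumulative-effects association cannot be combined with a lag", call. = FALSE)
  if (varying_coefficient && vc_df < 2)
    stop("varying-coefficient model requires vc_df >= 2", call. = FALSE)
  if (!lag %in% c(0, 3, 6))
    stop("lag must be 0, 3 or 6 months", call. = FALSE)
  structure(list(outcome = outcome, association = association, lag = lag,
                 varying_coefficient = varying_coefficient, vc_df = vc_df,
                 confounders = confounders, dmt_interactions = dmt_interactions,
                 baseline = baseline),
            class = "jm_spec")
}

#' Association contribution to the log hazard
#'
#' Computes the marker contribution under the chosen hypothesis:
#' CV `a1 * m`, CVS `a1 * m + a2 * m'`, CE `a1 * integral of m`, plus
#' DMT-duration interaction terms `sum_c d_c * m * dur_c` (and slope
#' analogues under CVS). In the VCJM, `a1` (and `a2`) are B-spline functions
#' of time evaluated from coefficient vectors.
#'
#' @param spec A [jm_spec()].
#' @param alpha Named list: `value` (scalar, or coefficient vector under the
#'   VCJM), `slope` (CVS only), `dmt_value` and `dmt_slope` (named
#'   `c(cat1=, cat3=)`, when `spec$dmt_interactions`).
#' @param m,m_slope,m_cum Marker value, slope and running integral at `time`.
#' @param dmt_durations List or data frame with elements `cat1`, `cat3`
#'   (years of exposure at `time`); defaults to zero exposure.
#' @param time Evaluation times (needed for the VCJM).
#' @return Numeric log-hazard contribution, one per element of `m`.
#' @export
association_term <- function(spec, alpha, m, m_slope = 0, m_cum = 0,
                             dmt_durations = list(cat1 = 0, cat3 = 0),
                             time = NULL) {
  a1 <- .alpha_at(spec, alpha$value, time)
  out <- switch(spec$association,
                CV = a1 * m,
                CVS = a1 * m + .alpha_at(spec, alpha$slope, time) * m_slope,
                CE = a1 * m_cum)
  if (isTRUE(spec$dmt_interactions)) {
    d1 <- dmt_durations$cat1; d3 <- dmt_durations$cat3
    out <- out + (alpha$dmt_value["cat1"] * d1 + alpha$dmt_value["cat3"] * d3) * m
    if (spec$association == "CVS")
      out <- out + (alpha$dmt_slope["cat1"] * d1 + alpha$dmt_slope["cat3"] * d3) * m_slope
  }
  unname(out)
}

.alpha_at <- function(spec, a, time) {
  if (!spec$varying_coefficient || length(a) == 1L) return(a)
  if (is.null(time)) stop("VCJM association needs evaluation times", call. = FALSE)
  drop(bspline_basis(time, spec$vc_df, spec$baseline$range) %*% a)
}

#' Survival log-likelihood of one or more subjects
#'
#' Counting-process log-likelihood
#' `sum_events log h(stop) - sum_intervals int_start^stop h(s) ds` with
#' `h(s) = exp(log h0(s) + x'gamma + association(s))`; each interval's
#' integral uses 15-point Gauss-Legendre quadrature.
#'
#' @param intervals Data frame with `start`, `stop`, `event` (and covariate
#'   columns when `gamma` is non-empty).
#' @param marker List of functions `value(t)`, and optionally `slope(t)` and
#'   `cum(t)`, giving the subject's marker trajectory.
#' @param params List: `log_h0` (vectorized function of time), `gamma`
#'   (named log-HRs matched to interval columns; may be empty), `alpha`
#'   (association parameters, see [association_term()]).
#' @param spec A [jm_spec()].
#' @param quadrature Number of Gauss-Legendre nodes per interval.
#' @return Scalar log-likelihood.
#' @export
subject_log_likelihood <- function(intervals, marker, params, spec,
                                   quadrature = 15) {
  gl <- pracma::gaussLegendre(quadrature, -1, 1)
  mk <- function(t) {
    m <- marker$value(t)
    ms <- if (!is.null(marker$slope)) marker$slope(t) else 0
    mc <- if (!is.null(marker$cum)) marker$cum(t) else 0
    association_term(spec, params$alpha, m, ms, mc,
                     dmt_durations = .dur_at(intervals, t), time = t)
  }
  covlp <- function(rows) {
    if (!length(params$gamma)) return(rep(0, length(rows)))
    X <- as.matrix(intervals[rows, names(params$gamma), drop = FALSE])
    drop(X %*% params$gamma)
  }
  logh <- function(t, rows) params$log_h0(t) + covlp(rows) + mk(t)
  total <- 0
  for (r in seq_len(nrow(intervals))) {
    a <- intervals$start[r]; b <- intervals$stop[r]
    u <- (b - a) / 2 * gl$x + (a + b) / 2
    total <- total - (b - a) / 2 * sum(gl$w * exp(logh(u, rep(r, quadrature))))
    if (intervals$event[r] == 1) total <- total + logh(b, r)
  }
  unname(total)
}

# DMT durations at arbitrary times: nearest interval's start duration grown
# linearly while the category is active (0 when columns absent)
.dur_at <- function(intervals, t) {
  if (!all(c("dur_dmt1", "dur_dmt3") %in% names(intervals)))
    return(list(cat1 = rep(0, length(t)), cat3 = rep(0, length(t))))
  r <- findInterval(t, intervals$start, all.inside = TRUE)
  act <- as.character(intervals$dmt_category[r])
  dt <- pmax(t - intervals$start[r], 0)
  list(cat1 = intervals$dur_dmt1[r] + dt * (act == "1"),
       cat3 = intervals$dur_dmt3[r] + dt * (act == "3"))
}

# ---------------------------------------------------------------------------
# internal fitting machinery

.confounder_design <- function(surv, confounders) {
  if (!length(confounders)) return(NULL)
  col <- function(nm) {
    switch(nm,
           sex = surv$sex,
           log_age = if (!is.null(surv$log_age)) surv$log_age else log(surv$age_at_onset),
           bmi = surv$bmi,
           relapse_count = surv$relapse_count,
           t2l = if (!is.null(surv$t2l)) surv$t2l else surv$t2l_count,
           vitd = if (!is.null(surv$vitd)) surv$vitd else surv$vitd_status,
           stop("unknown confounder: ", nm, call. = FALSE))
  }
  X <- vapply(confounders, function(nm) {
    v <- col(nm)
    if (is.null(v)) stop("confounder '", nm, "' not found in the survival data",
                         call. = FALSE)
    as.numeric(v)
  }, numeric(nrow(surv)))
  X <- matrix(X, nrow = nrow(surv), dimnames = list(NULL, confounders))
  X
}

# precompute every design matrix the sampler needs
.jm_design <- function(surv, long, spec, spline, quadrature = 15) {
  bl <- spec$baseline
  if (is.null(bl$range)) bl$range <- c(0, max(surv$stop))
  gl <- pracma::gaussLegendre(quadrature, -1, 1)
  ni <- nrow(surv)
  subj <- factor(surv$subject_id)
  subjects <- levels(subj)
  n <- length(subjects)

  half <- (surv$stop - surv$start) / 2
  mid <- (surv$stop + surv$start) / 2
  tq <- as.vector(outer(gl$x, half) + matrix(mid, quadrature, ni, byrow = TRUE))
  wq <- as.vector(outer(gl$w, half))
  row_q <- rep(seq_len(ni), each = quadrature)
  si_q <- as.integer(subj)[row_q]

  ev <- which(surv$event == 1)
  tev <- surv$stop[ev]
  si_ev <- as.integer(subj)[ev]

  Xc <- .confounder_design(surv, spec$confounders)
  Xc_q <- if (is.null(Xc)) NULL else Xc[row_q, , drop = FALSE]
  Xc_ev <- if (is.null(Xc)) NULL else Xc[ev, , drop = FALSE]

  B0_q <- bspline_basis(tq, bl$n_basis, bl$range)
  B0_ev <- bspline_basis(tev, bl$n_basis, bl$range)

  Nv_q <- ncs_design(tq, spline, 0); Nv_ev <- ncs_design(tev, spline, 0)
  Ns_q <- ncs_design(tq, spline, 1); Ns_ev <- ncs_design(tev, spline, 1)
  Ni_q <- ncs_design(tq, spline, -1); Ni_ev <- ncs_design(tev, spline, -1)

  # DMT durations grown from the interval-start values along each row
  dur_row <- function(rows, t) {
    if (!all(c("dur_dmt1", "dur_dmt3") %in% names(surv)))
      return(list(cat1 = rep(0, length(t)), cat3 = rep(0, length(t))))
    act <- as.character(surv$dmt_category[rows])
    dt <- pmax(t - surv$start[rows], 0)
    list(cat1 = surv$dur_dmt1[rows] + dt * (act == "1"),
         cat3 = surv$dur_dmt3[rows] + dt * (act == "3"))
  }
  dur_q <- dur_row(row_q, tq)
  dur_ev <- dur_row(ev, tev)

  Ba_q <- Ba_ev <- NULL
  if (spec$varying_coefficient) {
    Ba_q <- bspline_basis(tq, spec$vc_df, bl$range)
    Ba_ev <- bspline_basis(tev, spec$vc_df, bl$range)
  }

  # longitudinal data mapped to the same subject indexing
  li <- match(as.character(long$subject_id), subjects)
  Xl <- ncs_design(long$time, spline, 0)

  list(spec = spec, baseline = bl, spline = spline, quadrature = quadrature,
       subjects = subjects, n = n, ni = ni,
       tq = tq, wq = wq, row_q = row_q, si_q = si_q,
       ev = ev, tev = tev, si_ev = si_ev,
       Xc_q = Xc_q, Xc_ev = Xc_ev, B0_q = B0_q, B0_ev = B0_ev,
       Nv_q = Nv_q, Nv_ev = Nv_ev, Ns_q = Ns_q, Ns_ev = Ns_ev,
       Ni_q = Ni_q, Ni_ev = Ni_ev, dur_q = dur_q, dur_ev = dur_ev,
       Ba_q = Ba_q, Ba_ev = Ba_ev,
       long_idx = li, Xl = Xl, yl = long$y)
}

# association parameter bookkeeping: a flat vector with a descriptor
.alpha_layout <- function(spec) {
  k <- if (spec$varying_coefficient) spec$vc_df else 1L
  nm <- character(0)
  nm <- c(nm, if (k == 1L) "alpha_value" else paste0("alpha_value_bs", 1:k))
  if (spec$association == "CVS")
    nm <- c(nm, if (k == 1L) "alpha_slope" else paste0("alpha_slope_bs", 1:k))
  if (spec$dmt_interactions) {
    nm <- c(nm, "alpha_value_dmt1", "alpha_value_dmt3")
    if (spec$association == "CVS") nm <- c(nm, "alpha_slope_dmt1", "alpha_slope_dmt3")
  }
  nm
}

.alpha_unflatten <- function(spec, a) {
  k <- if (spec$varying_coefficient) spec$vc_df else 1L
  out <- list(value = a[seq_len(k)])
  at <- k
  if (spec$association == "CVS") { out$slope <- a[at + seq_len(k)]; at <- at + k }
  if (spec$dmt_interactions) {
    out$dmt_value <- c(cat1 = a[[at + 1L]], cat3 = a[[at + 2L]]); at <- at + 2L
    if (spec$association == "CVS") {
      out$dmt_slope <- c(cat1 = a[[at + 1L]], cat3 = a[[at + 2L]])
    }
  }
  out
}

# marker value/slope/integral at quadrature and event rows for coefficient
# matrix `coefs` (n x p, theta + b_i)
.marker_parts <- function(d, coefs) {
  list(mq = rowSums(d$Nv_q * coefs[d$si_q, , drop = FALSE]),
       mev = rowSums(d$Nv_ev * coefs[d$si_ev, , drop = FALSE]),
       sq = rowSums(d$Ns_q * coefs[d$si_q, , drop = FALSE]),
       sev = rowSums(d$Ns_ev * coefs[d$si_ev, , drop = FALSE]),
       iq = rowSums(d$Ni_q * coefs[d$si_q, , drop = FALSE]),
       iev = rowSums(d$Ni_ev * coefs[d$si_ev, , drop = FALSE]))
}

.assoc_rows <- function(d, alpha, mp) {
  spec <- d$spec
  al <- .alpha_unflatten(spec, alpha)
  a1q <- if (spec$varying_coefficient) drop(d$Ba_q %*% al$value) else al$value
  a1e <- if (spec$varying_coefficient) drop(d$Ba_ev %*% al$value) else al$value
  if (spec$association == "CE") {
    aq <- a1q * mp$iq; ae <- a1e * mp$iev
  } else {
    aq <- a1q * mp$mq; ae <- a1e * mp$mev
    if (spec$association == "CVS") {
      a2q <- if (spec$varying_coefficient) drop(d$Ba_q %*% al$slope) else al$slope
      a2e <- if (spec$varying_coefficient) drop(d$Ba_ev %*% al$slope) else al$slope
      aq <- aq + a2q * mp$sq; ae <- ae + a2e * mp$sev
    }
  }
  if (spec$dmt_interactions) {
    aq <- aq + (al$dmt_value["cat1"] * d$dur_q$cat1 +
                  al$dmt_value["cat3"] * d$dur_q$cat3) * mp$mq
    ae <- ae + (al$dmt_value["cat1"] * d$dur_ev$cat1 +
                  al$dmt_value["cat3"] * d$dur_ev$cat3) * mp$mev
    if (spec$association == "CVS") {
      aq <- aq + (al$dmt_slope["cat1"] * d$dur_q$cat1 +
                    al$dmt_slope["cat3"] * d$dur_q$cat3) * mp$sq
      ae <- ae + (al$dmt_slope["cat1"] * d$dur_ev$cat1 +
                    al$dmt_slope["cat3"] * d$dur_ev$cat3) * mp$sev
    }
  }
  list(q = aq, ev = ae)
}

# survival log-likelihood, totalled and by subject
.jm_loglik <- function(d, kappa, gamma, alpha, coefs, by_subject = FALSE) {
  mp <- .marker_parts(d, coefs)
  as <- .assoc_rows(d, alpha, mp)
  lq <- drop(d$B0_q %*% kappa) + as$q
  le <- drop(d$B0_ev %*% kappa) + as$ev
  if (!is.null(d$Xc_q)) {
    lq <- lq + drop(d$Xc_q %*% gamma)
    le <- le + drop(d$Xc_ev %*% gamma)
  }
  hq <- d$wq * exp(lq)
  if (!by_subject) return(sum(le) - sum(hq))
  bys <- rep(0, d$n)
  cum <- rowsum(hq, d$si_q, reorder = FALSE)
  bys[as.integer(rownames(cum))] <- -cum
  if (length(le)) {
    evs <- rowsum(le, d$si_ev, reorder = FALSE)
    bys[as.integer(rownames(evs))] <- bys[as.integer(rownames(evs))] + evs
  }
  bys
}

#' Fit a Bayesian joint model (stage 3)
#'
#' Metropolis-within-Gibbs sampler for the joint model linking the stage-2
#' GPI trajectory to the counting-process hazard. The baseline log hazard is
#' a penalized P-spline (gamma hyperprior on the inverse smoothing
#' variance, conjugate update); the confounder and association blocks use
#' adaptive random-walk Metropolis tuned to 20-30% acceptance during
#' burn-in. Population trajectory parameters (fixed spline effects, the
#' random-effects covariance and residual SD) are plugged in at their
#' stage-2 posterior means; subject random effects are re-sampled inside the
#' survival model by default (`resample_re = FALSE` fixes them at their
#' stage-2 means).
#'
#' @param surv Transition intervals with an `event` column (the modelled
#'   outcome), covariates, and `subject_id`.
#' @param traj A `trajectory_fit` from [fit_trajectory_model()] on the same
#'   subjects.
#' @param spec A [jm_spec()].
#' @param mcmc An [mcmc_control()].
#' @param resample_re Re-sample subject random effects inside stage 3.
#' @param quadrature Gauss-Legendre nodes per interval (default 15).
#' @param prior_sd Normal prior SD for fixed effects and associations.
#' @return Object of class `jm_fit` with per-chain draws, split by parameter
#'   block, convergence diagnostics (`rhat`), `dic`, and posterior summaries.
#' @export
fit_joint_model <- function(surv, traj, spec = jm_spec(),
                            mcmc = mcmc_control(2000, 1000, 3, seed = 1),
                            resample_re = TRUE, quadrature = 15,
                            prior_sd = 10) {
  stopifnot(inherits(traj, "trajectory_fit"))
  if (sum(surv$event) < 10) stop("need at least 10 events to fit the joint model",
                                 call. = FALSE)
  if (spec$lag > 0) surv <- lag_survival_times(surv, spec$lag)
  spec$confounders <- intersect(spec$confounders, .available_confounders(surv))
  pm <- trajectory_posterior_means(traj)
  theta <- pm$theta; Dhat <- pm$D; sig <- max(pm$sigma, 1e-6)
  Dinv <- solve(Dhat)

  long <- traj$data
  d <- .jm_design(surv, long, spec, traj$spline, quadrature)
  # sample on standardized confounders (shared proposal scale, baseline
  # decorrelated from covariate levels); draws are stored back on the raw
  # scale, with the constant re-absorbed into the baseline coefficients
  cmu <- csd <- NULL
  if (!is.null(d$Xc_q)) {
    cmu <- colMeans(d$Xc_q)
    csd <- apply(d$Xc_q, 2L, stats::sd)
    csd[csd < 1e-12] <- 1
    d$Xc_q <- sweep(sweep(d$Xc_q, 2L, cmu), 2L, csd, "/")
    d$Xc_ev <- sweep(sweep(d$Xc_ev, 2L, cmu), 2L, csd, "/")
  }
  # align random effects with design subject order
  bhat <- apply(.pool_b(traj), c(2L, 3L), mean)
  tri <- match(d$subjects, traj$subjects)
  if (anyNA(tri)) stop("survival data contains subjects absent from the trajectory fit",
                       call. = FALSE)
  bhat <- bhat[tri, , drop = FALSE]
  p <- length(theta)
  full_b <- traj$random == "spline"
  expand_b <- function(b) if (full_b) b else cbind(b, matrix(0, nrow(b), p - 2L))

  nb <- d$baseline$n_basis
  P <- pspline_penalty(nb, d$baseline$penalty_order)
  rkP <- nb - d$baseline$penalty_order
  qg <- length(spec$confounders)
  anames <- .alpha_layout(spec)
  na <- length(anames)

  # longitudinal sufficient stats per subject for b updates; for the
  # intercept+slope restriction the first two columns of the NCS design are
  # exactly [1, t], so padding b with zeros reuses the same marker algebra
  Zl <- if (full_b) d$Xl else cbind(d$Xl[, 1L], long$time)
  qb <- ncol(Zl)
  stopifnot(qb == ncol(bhat))
  li <- match(as.character(long$subject_id), d$subjects)
  Dinv_b <- Dinv
  resid_fix <- d$yl - drop(d$Xl %*% theta)
  ZtR <- rowsum(Zl * resid_fix, li, reorder = FALSE)
  ZtR_full <- matrix(0, d$n, qb)
  ZtR_full[as.integer(rownames(ZtR)), ] <- ZtR
  ZtZ <- array(0, c(qb, qb, d$n))
  for (i in seq_len(d$n)) {
    Zi <- Zl[li == i, , drop = FALSE]
    if (nrow(Zi)) ZtZ[, , i] <- crossprod(Zi)
  }

  n_keep <- mcmc$n_iter - mcmc$burnin
  events_total <- sum(surv$event)
  ptime <- sum(surv$stop - surv$start)
  kappa0 <- rep(log(max(events_total, 1) / max(ptime, 1e-8)), nb)

  # sparse support of each baseline basis column (coordinate-wise updates
  # only touch the rows where the B-spline is nonzero)
  nzq <- lapply(seq_len(nb), function(j) which(d$B0_q[, j] != 0))
  nzev <- lapply(seq_len(nb), function(j) which(d$B0_ev[, j] != 0))
  nev_total <- length(d$tev)
  tiltv <- (seq_len(nb) - (nb + 1) / 2) / nb
  tilt_q <- drop(d$B0_q %*% tiltv)
  tilt_ev <- drop(d$B0_ev %*% tiltv)
  need_slope <- spec$association == "CVS"
  need_int <- spec$association == "CE"
  mk_parts <- function(coefs) {
    mp <- list(mq = rowSums(d$Nv_q * coefs[d$si_q, , drop = FALSE]),
               mev = rowSums(d$Nv_ev * coefs[d$si_ev, , drop = FALSE]))
    if (need_slope) {
      mp$sq <- rowSums(d$Ns_q * coefs[d$si_q, , drop = FALSE])
      mp$sev <- rowSums(d$Ns_ev * coefs[d$si_ev, , drop = FALSE])
    }
    if (need_int) {
      mp$iq <- rowSums(d$Ni_q * coefs[d$si_q, , drop = FALSE])
      mp$iev <- rowSums(d$Ni_ev * coefs[d$si_ev, , drop = FALSE])
    }
    mp
  }
  ZZmat <- matrix(ZtZ, nrow = qb * qb)  # (r,c) stacked per subject
  # per-coordinate proposal shape for the b updates from the average
  # longitudinal conditional precision (the marker series can pin b tightly)
  Pb <- apply(ZtZ, c(1L, 2L), mean) / sig^2 + Dinv
  sbcol <- sqrt(diag(solve(Pb)))
  rowwise_matvec <- function(V) {
    # returns n x qb matrix with rows A_i V_i using the stacked ZtZ
    out <- matrix(0, d$n, qb)
    for (r in seq_len(qb)) for (cc in seq_len(qb))
      out[, r] <- out[, r] + ZZmat[(cc - 1L) * qb + r, ] * V[, cc]
    out
  }
  rowsum_full <- function(x, g) {
    out <- rep(0, d$n)
    if (!length(x)) return(out)
    rs <- rowsum(x, g, reorder = FALSE)
    out[as.integer(rownames(rs))] <- rs
    out
  }
  quad_D <- function(B, Dinv) rowSums((B %*% Dinv) * B)

  run_chain <- function(cseed) .with_seed(cseed, {
    kappa <- kappa0
    gamma <- rep(0, qg)
    alpha <- rep(0, na)
    tau2 <- 1
    b <- bhat
    coefs <- sweep(expand_b(b), 2L, theta, "+")
    mp <- mk_parts(coefs)
    as_cur <- .assoc_rows(d, alpha, mp)
    b0q <- drop(d$B0_q %*% kappa); b0e <- drop(d$B0_ev %*% kappa)
    xgq <- if (qg > 0) drop(d$Xc_q %*% gamma) else 0
    xge <- if (qg > 0) drop(d$Xc_ev %*% gamma) else 0
    lq <- b0q + xgq + as_cur$q
    le <- b0e + xge + as_cur$ev
    hq <- d$wq * exp(lq)
    ll <- sum(le) - sum(hq)
    Pk <- drop(P %*% kappa)
    kPk <- sum(kappa * Pk)

    sck <- rep(0.1, nb)
    sck_shift <- 0.2
    sck_tilt <- 0.1
    sc <- c(gamma = 0.1, alpha = 0.1, b = 1.2)
    acck <- wink <- rep(0, nb)
    acc2 <- win2 <- c(shift = 0, tilt = 0)
    acc <- win <- c(gamma = 0, alpha = 0, b = 0)
    kd <- matrix(NA_real_, n_keep, nb)
    gd <- matrix(NA_real_, n_keep, qg)
    ad <- matrix(NA_real_, n_keep, na)
    td <- numeric(n_keep)
    lld <- numeric(n_keep)
    bsum <- matrix(0, d$n, qb)

    for (it in seq_len(mcmc$n_iter)) {
      # baseline: coordinate-wise Metropolis on the P-spline coefficients
      dk <- stats::rnorm(nb, 0, sck)
      lu <- log(stats::runif(nb))
      for (j in seq_len(nb)) {
        Sq <- nzq[[j]]; Se <- nzev[[j]]
        lq_new <- lq[Sq] + d$B0_q[Sq, j] * dk[j]
        h_new <- d$wq[Sq] * exp(lq_new)
        dll <- sum(d$B0_ev[Se, j]) * dk[j] - (sum(h_new) - sum(hq[Sq]))
        dpr <- -(2 * dk[j] * Pk[j] + dk[j]^2 * P[j, j]) / (2 * tau2) -
          (2 * kappa[j] * dk[j] + dk[j]^2) / (2 * 100^2)
        if (lu[j] < dll + dpr) {
          kPk <- kPk + 2 * dk[j] * Pk[j] + dk[j]^2 * P[j, j]
          Pk <- Pk + dk[j] * P[, j]
          kappa[j] <- kappa[j] + dk[j]
          lq[Sq] <- lq_new; hq[Sq] <- h_new
          if (length(Se)) le[Se] <- le[Se] + d$B0_ev[Se, j] * dk[j]
          ll <- ll + dll
          acck[j] <- acck[j] + 1
        }
      }
      # global level move: adding a constant to every coefficient shifts the
      # whole log baseline; it lies in the difference-penalty null space, and
      # by partition of unity the cumulative hazard simply rescales
      cs <- stats::rnorm(1, 0, sck_shift)
      dll <- nev_total * cs - (exp(cs) - 1) * sum(hq)
      dpr <- -(2 * cs * sum(kappa) + nb * cs^2) / (2 * 100^2)
      if (log(stats::runif(1)) < dll + dpr) {
        kappa <- kappa + cs
        Pk <- drop(P %*% kappa)           # unchanged in exact arithmetic
        lq <- lq + cs; hq <- hq * exp(cs); le <- le + cs
        ll <- ll + dll
        acc2["shift"] <- acc2["shift"] + 1
      }
      # global tilt move along the linear (penalty-free) direction
      ct <- stats::rnorm(1, 0, sck_tilt)
      kprop <- kappa + ct * tiltv
      lq2 <- lq + ct * tilt_q
      le2 <- le + ct * tilt_ev
      hq2 <- d$wq * exp(lq2)
      llp <- sum(le2) - sum(hq2)
      dpr <- -(sum(kprop^2) - sum(kappa^2)) / (2 * 100^2)
      if (log(stats::runif(1)) < llp - ll + dpr) {
        kappa <- kprop
        Pk <- drop(P %*% kappa)
        kPk <- sum(kappa * Pk)
        lq <- lq2; hq <- hq2; le <- le2; ll <- llp
        acc2["tilt"] <- acc2["tilt"] + 1
      }
      # smoothing variance (conjugate given the penalty quadratic form)
      tau2 <- 1 / stats::rgamma(1, 1 + rkP / 2, 0.005 + kPk / 2)
      # confounder block
      if (qg > 0) {
        prop <- gamma + stats::rnorm(qg, 0, sc["gamma"])
        dxq <- drop(d$Xc_q %*% (prop - gamma))
        dxe <- drop(d$Xc_ev %*% (prop - gamma))
        lq2 <- lq + dxq
        hq2 <- d$wq * exp(lq2)
        llp <- sum(le + dxe) - sum(hq2)
        if (log(stats::runif(1)) < llp - ll + sum(gamma^2 - prop^2) / (2 * prior_sd^2)) {
          gamma <- prop; xgq <- xgq + dxq; xge <- xge + dxe
          lq <- lq2; hq <- hq2; le <- le + dxe; ll <- llp
          acc["gamma"] <- acc["gamma"] + 1
        }
      }
      # association block
      if (na > 0) {
        prop <- alpha + stats::rnorm(na, 0, sc["alpha"])
        as2 <- .assoc_rows(d, prop, mp)
        lq2 <- lq - as_cur$q + as2$q
        le2 <- le - as_cur$ev + as2$ev
        hq2 <- d$wq * exp(lq2)
        llp <- sum(le2) - sum(hq2)
        if (log(stats::runif(1)) < llp - ll + sum(alpha^2 - prop^2) / (2 * prior_sd^2)) {
          alpha <- prop; as_cur <- as2
          lq <- lq2; hq <- hq2; le <- le2; ll <- llp
          acc["alpha"] <- acc["alpha"] + 1
        }
      }
      # subject random effects (vectorised per-subject Metropolis)
      if (resample_re) {
        bprop <- b + matrix(stats::rnorm(d$n * qb, 0, sc["b"] * rep(sbcol, each = d$n)),
                            d$n, qb)
        coefs_p <- sweep(expand_b(bprop), 2L, theta, "+")
        mp_p <- mk_parts(coefs_p)
        as_p <- .assoc_rows(d, alpha, mp_p)
        lq_p <- lq - as_cur$q + as_p$q
        le_p <- le - as_cur$ev + as_p$ev
        hq_p <- d$wq * exp(lq_p)
        dsurv <- (rowsum_full(le_p, d$si_ev) - rowsum_full(hq_p, d$si_q)) -
          (rowsum_full(le, d$si_ev) - rowsum_full(hq, d$si_q))
        db <- bprop - b
        dlong <- (rowSums(db * ZtR_full) -
                    rowSums(db * rowwise_matvec(b + bprop)) / 2) / sig^2
        dprior <- -(quad_D(bprop, Dinv_b) - quad_D(b, Dinv_b)) / 2
        accept <- log(stats::runif(d$n)) < (dsurv + dlong + dprior)
        if (any(accept)) {
          b[accept, ] <- bprop[accept, , drop = FALSE]
          rq <- accept[d$si_q]; re <- accept[d$si_ev]
          lq[rq] <- lq_p[rq]; hq[rq] <- hq_p[rq]; le[re] <- le_p[re]
          for (nmp in names(mp)) {
            rows <- if (grepl("q$", nmp)) rq else re
            mp[[nmp]][rows] <- mp_p[[nmp]][rows]
          }
          as_cur$q[rq] <- as_p$q[rq]; as_cur$ev[re] <- as_p$ev[re]
          ll <- sum(le) - sum(hq)
        }
        acc["b"] <- acc["b"] + mean(accept)
      }
      win <- win + 1
      wink <- wink + 1
      win2 <- win2 + 1
      if (it <= mcmc$burnin && it %% 50 == 0) {
        sck <- sck * exp(acck / wink - 0.35)
        sck_shift <- sck_shift * exp(acc2[["shift"]] / win2[["shift"]] - 0.35)
        sck_tilt <- sck_tilt * exp(acc2[["tilt"]] / win2[["tilt"]] - 0.35)
        sc <- sc * exp(acc / win - 0.25)
        acck[] <- 0; wink[] <- 0; acc[] <- 0; win[] <- 0; acc2[] <- 0; win2[] <- 0
      }
      if (it > mcmc$burnin) {
        k <- it - mcmc$burnin
        if (qg > 0) {
          kd[k, ] <- kappa - sum((cmu / csd) * gamma)
          gd[k, ] <- gamma / csd
        } else kd[k, ] <- kappa
        if (na > 0) ad[k, ] <- alpha
        td[k] <- tau2
        lld[k] <- ll
        bsum <- bsum + b
      }
    }
    colnames(kd) <- paste0("baseline_bs", seq_len(nb))
    if (qg > 0) colnames(gd) <- spec$confounders
    if (na > 0) colnames(ad) <- anames
    list(kappa = kd, gamma = gd, alpha = ad, tau2 = td, loglik = lld,
         b_mean = bsum / n_keep,
         accept = c(kappa = mean(acck / pmax(wink, 1)), acc / pmax(win, 1)))
  })

  chains <- lapply(mcmc$chain_seeds, run_chain)
  draw_mat <- function(ch) cbind(ch$alpha, ch$gamma, ch$kappa, tau2 = ch$tau2)
  rhat <- if (length(chains) >= 2L) gelman_rubin(lapply(chains, draw_mat))
          else stats::setNames(rep(NA_real_, ncol(draw_mat(chains[[1L]]))),
                               colnames(draw_mat(chains[[1L]])))
  b_mean <- Reduce(`+`, lapply(chains, `[[`, "b_mean")) / length(chains)
  pooled <- do.call(rbind, lapply(chains, draw_mat))
  means <- colMeans(pooled)
  coefs_bar <- sweep(expand_b(b_mean), 2L, theta, "+")
  kap_bar <- means[colnames(chains[[1L]]$kappa)]
  gam_bar <- if (qg > 0) means[spec$confounders] else numeric(0)
  if (qg > 0) {   # back onto the standardized parameterization of `d`
    kap_bar <- kap_bar + sum(cmu * gam_bar)
    gam_bar <- gam_bar * csd
  }
  ll_bar <- .jm_loglik(d, kap_bar, gam_bar,
                       if (na > 0) means[anames] else numeric(0), coefs_bar)
  dbar <- mean(-2 * unlist(lapply(chains, `[[`, "loglik")))
  dic <- list(dic = dbar + (dbar - (-2 * ll_bar)), pD = dbar - (-2 * ll_bar),
              Dbar = dbar, Dhat = -2 * ll_bar)
  rh_fin <- rhat[is.finite(rhat)]
  conv_fail <- length(rh_fin) > 0 && all(rh_fin > 1.5)
  if (conv_fail) warning("all split R-hat exceed 1.5: convergence failure flagged")
  structure(list(spec = spec, chains = chains, design = d, traj_means = pm,
                 theta = theta, b_mean = b_mean, full_b = full_b,
                 spline = traj$spline, subjects = d$subjects,
                 alpha_names = anames, rhat = rhat, dic = dic,
                 mcmc = mcmc, converged = !conv_fail,
                 accept = lapply(chains, `[[`, "accept")),
            class = "jm_fit")
}

.available_confounders <- function(surv) {
  have <- names(surv)
  out <- character(0)
  if ("sex" %in% have) out <- c(out, "sex")
  if (any(c("log_age", "age_at_onset") %in% have)) out <- c(out, "log_age")
  if ("bmi" %in% have) out <- c(out, "bmi")
  if ("relapse_count" %in% have) out <- c(out, "relapse_count")
  if (any(c("t2l", "t2l_count") %in% have)) out <- c(out, "t2l")
  if (any(c("vitd", "vitd_status") %in% have)) out <- c(out, "vitd")
  out
}

#' Pooled posterior draws of a joint-model fit
#'
#' @param fit A `jm_fit`.
#' @return Matrix of pooled draws (associations, confounders, baseline,
#'   smoothing variance).
#' @export
jm_draws <- function(fit) {
  do.call(rbind, lapply(fit$chains, function(ch)
    cbind(ch$alpha, ch$gamma, ch$kappa, tau2 = ch$tau2)))
}

#' Posterior summaries (mean and central 95% interval)
#'
#' @param fit A `jm_fit` (or a draws matrix).
#' @param params Optional subset of parameter names.
#' @return Data frame with `param`, `mean`, `lo`, `hi`.
#' @export
posterior_summary <- function(fit, params = NULL) {
  M <- if (inherits(fit, "jm_fit")) jm_draws(fit) else as.matrix(fit)
  if (!is.null(params)) M <- M[, params, drop = FALSE]
  out <- data.frame(param = colnames(M), mean = colMeans(M),
                    lo = apply(M, 2L, stats::quantile, 0.025),
                    hi = apply(M, 2L, stats::quantile, 0.975),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic PSRF `R = sqrt(((n-1)/n W + B/n) / W)` across chains; with
#' `split = TRUE` each chain is first split in half. Two identical chains of
#' length n give exactly `sqrt((n-1)/n)`; well-separated chains give values
#' far above 1.
#'
#' @param chains List of per-chain draw vectors or matrices (equal lengths).
#' @param split Split each chain in half before computing the factor.
#' @return Named numeric vector of R-hat values (NaN where the within-chain
#'   variance is zero).
#' @export
gelman_rubin <- function(chains, split = FALSE) {
  if (length(chains) < 2L && !split) stop("need at least 2 chains", call. = FALSE)
  chains <- lapply(chains, function(x) {
    x <- as.matrix(x)
    if (is.null(colnames(x))) colnames(x) <- paste0("par", seq_len(ncol(x)))
    x
  })
  if (split) {
    chains <- unlist(lapply(chains, function(x) {
      h <- floor(nrow(x) / 2)
      list(x[seq_len(h), , drop = FALSE], x[h + seq_len(h), , drop = FALSE])
    }), recursive = FALSE)
  }
  n <- nrow(chains[[1L]])
  apply_par <- function(j) {
    xs <- vapply(chains, function(x) x[, j], numeric(n))
    W <- mean(apply(xs, 2L, stats::var))
    B_over_n <- stats::var(colMeans(xs))
    if (W == 0) return(NaN)
    sqrt(((n - 1) / n * W + B_over_n) / W)
  }
  out <- vapply(seq_len(ncol(chains[[1L]])), apply_par, numeric(1))
  names(out) <- colnames(chains[[1L]])
  out
}

#' Deviance information criterion of a joint-model fit
#'
#' `DIC = Dbar + pD` with `pD = Dbar - D(posterior means)`, using the
#' survival-part deviance conditional on the subject random effects (the
#' longitudinal part is common to the association structures being
#' compared).
#'
#' @param fit A `jm_fit`.
#' @return The DIC value, with components as attributes.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "jm_fit"))
  structure(fit$dic$dic, pD = fit$dic$pD, Dbar = fit$dic$Dbar,
            Dhat = fit$dic$Dhat)
}

#' DIC from deviance draws
#'
#' Building block used when the deviance of a model is available directly:
#' `DIC = Dbar + (Dbar - D_at_mean)`.
#'
#' @param deviance_draws Vector of deviance evaluations over posterior draws.
#' @param deviance_at_mean Deviance at the posterior mean.
#' @return List with `dic`, `pD`, `Dbar`.
#' @export
dic_from_deviance <- function(deviance_draws, deviance_at_mean) {
  dbar <- mean(deviance_draws)
  list(dic = 2 * dbar - deviance_at_mean, pD = dbar - deviance_at_mean,
       Dbar = dbar)
}

#' Hazard-ratio scale summaries
#'
#' Exponentiates a posterior summary (mean, lower, upper) componentwise and
#' rounds to 2 decimals, the reporting convention for the association and
#' interaction parameters.
#'
#' @param s Numeric vector `c(mean, lo, hi)` on the log-hazard scale, or a
#'   data frame with columns `mean`, `lo`, `hi`.
#' @return Same shape on the HR scale, rounded to 2 decimals.
#' @export
to_hazard_ratio <- function(s) {
  if (is.data.frame(s)) {
    out <- s
    out$mean <- round(exp(s$mean), 2)
    out$lo <- round(exp(s$lo), 2)
    out$hi <- round(exp(s$hi), 2)
    return(out)
  }
  round(exp(s), 2)
}

#' @export
print.jm_fit <- function(x, ...) {
  cat("Bayesian joint model (", x$spec$outcome, ", ", x$spec$association,
      if (x$spec$varying_coefficient) ", VCJM" else ", CCJM",
      if (x$spec$lag > 0) paste0(", lag ", x$spec$lag, "m") else "",
      "): ", length(x$chains), " chain(s), DIC = ", round(x$dic$dic, 1),
      ", max R-hat = ", round(max(x$rhat, na.rm = TRUE), 3), "\n", sep = "")
  print(posterior_summary(x, params = x$alpha_names), digits = 3)
  invisible(x)
}
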