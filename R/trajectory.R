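#' MCMC settings
#'
#' @param n_iter Iterations per chain (post burn-in draws = `n_iter - burnin`).
#' @param burnin Burn-in iterations discarded from each chain.
#' @param chains Number of chains.
#' @param seed Base seed; chain `c` runs under `seed + 1000 * (c - 1)` unless
#'   `chain_seeds` is given explicitly (chains sharing a seed are identical).
#' @param chain_seeds Optional integer vector of per-chain seeds.
#' @return List of class `mcmc_control`.
#' @export
mcmc_control <- function(n_iter = 10000, burnin = 5000, chains = 3, seed = 1,
                         chain_seeds = NULL) {
  if (burnin >= n_iter) stop("burnin must be smaller than n_iter", call. = FALSE)
  if (is.null(chain_seeds)) chain_seeds <- seed + 1000L * (seq_len(chains) - 1L)
  if (length(chain_seeds) != chains) stop("need one seed per chain", call. = FALSE)
  structure(list(n_iter = n_iter, burnin = burnin, chains = chains,
                 seed = seed, chain_seeds = chain_seeds),
            class = "mcmc_control")
}

#' Fit the Bayesian spline trajectory model (stage 2)
#'
#' Gibbs sampler for the longitudinal GPI sub-model
#' `y_ij = x(t_ij)'theta + x(t_ij)'b_i + e_ij`, with `x(t)` the intercept plus
#' natural cubic spline basis of time, `b_i ~ MVN(0, D)` and
#' `e ~ N(0, sigma^2)`. All full conditionals are conjugate: normal updates
#' for `theta` and each `b_i`, a Wishart update for `D^-1`, and a gamma
#' update for the residual precision. Priors: `theta ~ N(0, 10^2 I)`,
#' `sigma^-2 ~ Gamma(0.01, 0.01)`, `D^-1 ~ Wishart(p + 2, (0.1 I)^-1)`.
#'
#' @param series A `gpi_series` data frame (`subject_id`, `time`, and the
#'   response column `gpi` or `y`).
#' @param spline A [spline_config()]; by default knots are placed from the
#'   observed times via [spline_config_from_times()].
#' @param mcmc An [mcmc_control()].
#' @param random Either `"spline"` (random coefficients on the full basis,
#'   default) or `"intercept_slope"` (random intercept + linear time only).
#' @param prior_theta_sd,prior_gamma_a,prior_gamma_b Prior hyper-parameters.
#' @return Object of class `trajectory_fit`: per-chain draws of the fixed
#'   effects, residual SD, `D`, and subject random effects, plus the frozen
#'   spline configuration.
#' @export
fit_trajectory_model <- function(series, spline = NULL,
                                 mcmc = mcmc_control(2000, 1000, 1, seed = 1),
                                 random = c("spline", "intercept_slope"),
                                 prior_theta_sd = 10, prior_gamma_a = 0.01,
                                 prior_gamma_b = 0.01) {
  random <- match.arg(random)
  ycol <- if ("gpi" %in% names(series)) "gpi" else "y"
  y <- series[[ycol]]
  if (is.null(spline)) spline <- spline_config_from_times(series$time)
  X <- ncs_design(series$time, spline, 0)
  p <- ncol(X)
  Z <- if (random == "spline") X else cbind(X[, 1L], series$time)
  q <- ncol(Z)
  subj <- factor(series$subject_id)
  n <- nlevels(subj)
  idx <- as.integer(subj)
  if (qr(X)$rank < p)
    warning("trajectory design is rank deficient; the regularising prior carries the fit")

  # per-subject sufficient statistics (fixed across iterations)
  ZtZ <- array(0, c(q, q, n))
  XtZ_theta_part <- NULL
  for (i in seq_len(n)) {
    Zi <- Z[idx == i, , drop = FALSE]
    ZtZ[, , i] <- crossprod(Zi)
  }
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  N <- length(y)
  S0 <- diag(0.1, q)
  nu0 <- q + 2

  n_keep <- mcmc$n_iter - mcmc$burnin
  run_chain <- function(cseed) {
    .with_seed(cseed, {
      theta <- rep(0, p)
      b <- matrix(0, n, q)
      Dinv <- diag(1, q)
      prec_e <- 1
      th_d <- matrix(NA_real_, n_keep, p)
      sg_d <- numeric(n_keep)
      D_d <- matrix(NA_real_, n_keep, q * q)
      b_d <- array(NA_real_, c(n_keep, n, q))
      prior_prec_theta <- diag(1 / prior_theta_sd^2, p)
      for (it in seq_len(mcmc$n_iter)) {
        # theta | b, sigma
        rb <- rowSums(Z * b[idx, , drop = FALSE])
        P <- prec_e * XtX + prior_prec_theta
        m <- prec_e * crossprod(X, y - rb)
        ch <- chol(P)
        theta <- drop(backsolve(ch, backsolve(ch, m, transpose = TRUE) +
                                  stats::rnorm(p)))
        # b_i | theta, sigma, D
        r <- y - drop(X %*% theta)
        Ztr <- rowsum(Z * r, idx)          # n x q
        for (i in seq_len(n)) {
          Pi <- prec_e * ZtZ[, , i] + Dinv
          chi <- chol(Pi)
          b[i, ] <- backsolve(chi, backsolve(chi, prec_e * Ztr[i, ],
                                             transpose = TRUE) + stats::rnorm(q))
        }
        # D^-1 | b  (Wishart)
        Sn <- S0 + crossprod(b)
        Dinv <- stats::rWishart(1, nu0 + n, solve(Sn))[, , 1L]
        # sigma^-2 | rest
        resid <- r - rowSums(Z * b[idx, , drop = FALSE])
        prec_e <- stats::rgamma(1, prior_gamma_a + N / 2,
                                prior_gamma_b + sum(resid^2) / 2)
        if (it > mcmc$burnin) {
          k <- it - mcmc$burnin
          th_d[k, ] <- theta
          sg_d[k] <- 1 / sqrt(prec_e)
          D_d[k, ] <- solve(Dinv)
          b_d[k, , ] <- b
        }
      }
      list(theta = th_d, sigma = sg_d, D = D_d, b = b_d)
    })
  }
  chains <- lapply(mcmc$chain_seeds, run_chain)
  structure(list(chains = chains, spline = spline, basis_dim = p,
                 random = random, q = q, subjects = levels(subj),
                 mcmc = mcmc, n_obs = N,
                 data = data.frame(subject_id = as.character(series$subject_id),
                                   time = series$time, y = y,
                                   stringsAsFactors = FALSE)),
            class = "trajectory_fit")
}

# pooled draws across chains
.pool <- function(fit, what) {
  do.call(rbind, lapply(fit$chains, `[[`, what))
}

.pool_b <- function(fit) {
  arrs <- lapply(fit$chains, `[[`, "b")
  do.call(abind3, arrs)
}

# minimal 3-d array bind along dim 1
abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1L]])
  out <- array(NA_real_, c(sum(vapply(xs, function(a) dim(a)[1L], 1L)), d[2L], d[3L]))
  at <- 0L
  for (a in xs) {
    out[at + seq_len(dim(a)[1L]), , ] <- a
    at <- at + dim(a)[1L]
  }
  out
}

#' Posterior summaries of trajectory parameters
#'
#' @param fit A `trajectory_fit`.
#' @return List with posterior means `theta`, `sigma`, `D`.
#' @export
trajectory_posterior_means <- function(fit) {
  q <- fit$q
  list(theta = colMeans(.pool(fit, "theta")),
       sigma = mean(.pool(fit, "sigma")),
       D = matrix(colMeans(.pool(fit, "D")), q, q))
}

#' Subject-specific predicted value and slope
#'
#' Per posterior draw, the predicted marker value is `x(t)'(theta + b_i)` and
#' the slope is the exact analytic derivative `x'(t)'(theta + b_i)`;
#' summaries are the posterior mean and central 95% interval.
#'
#' @param fit A `trajectory_fit`.
#' @param subject_id Subject identifier present in the fit.
#' @param time Evaluation time(s) in years.
#' @return List with data frames `value` and `slope` (columns `time`,
#'   `mean`, `lo`, `hi`).
#' @export
predict_trajectory <- function(fit, subject_id, time) {
  stopifnot(inherits(fit, "trajectory_fit"))
  i <- match(as.character(subject_id), fit$subjects)
  if (is.na(i)) stop("unknown subject: ", subject_id, call. = FALSE)
  th <- .pool(fit, "theta")
  bb <- .pool_b(fit)[, i, , drop = FALSE]
  dim(bb) <- c(dim(bb)[1L], dim(bb)[3L])
  X <- ncs_design(time, fit$spline, 0)
  Xd <- ncs_design(time, fit$spline, 1)
  coefs <- th
  if (fit$random == "spline") {
    coefs <- th + bb
    val <- coefs %*% t(X)
    slp <- coefs %*% t(Xd)
  } else {
    val <- th %*% t(X) + bb %*% t(cbind(1, time))
    slp <- th %*% t(Xd) + bb %*% t(cbind(0, rep(1, length(time))))
  }
  summ <- function(M) data.frame(
    time = time, mean = colMeans(M),
    lo = apply(M, 2L, stats::quantile, 0.025),
    hi = apply(M, 2L, stats::quantile, 0.975))
  list(value = summ(val), slope = summ(slp))
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat("Bayesian spline trajectory fit:", length(x$subjects), "subjects,",
      x$n_obs, "observations;", length(x$chains), "chain(s) x",
      x$mcmc$n_iter - x$mcmc$burnin, "kept draws\n")
  invisible(x)
}
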