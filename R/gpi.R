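#' Penalized Cox variant selection
#'
#' Stage 1 screening: an elastic-net-penalized Cox partial likelihood is
#' maximised over a penalty path on the counting-process data, with the
#' penalty chosen by k-fold cross-validated partial-likelihood deviance.
#' Folds are grouped by subject so correlated intervals never straddle a
#' fold boundary. SNPs with nonzero main-effect coefficients at the chosen
#' penalty are returned.
#'
#' @param transitions A `transition_intervals` frame; the modelled event is
#'   `event` for the worsening outcome or `relapse_event` for relapses.
#' @param genotypes Dosage matrix whose rows (named by subject id) cover all
#'   subjects in `transitions`.
#' @param outcome `"worsening"` or `"relapse"`.
#' @param alpha Elastic-net mixing parameter (1 = lasso, default).
#' @param nfolds Cross-validation folds (default 5).
#' @param rule `"1se"` (default) or `"min"` penalty choice.
#' @param nlambda Length of the penalty path (default 50).
#' @param penalty Optional fixed penalty; bypasses cross-validation
#'   (`penalty = 0` retains every SNP).
#' @param seed Seed for the fold assignment.
#' @return Character vector of selected SNP ids (possibly empty).
#' @export
select_variants <- function(transitions, genotypes, outcome = c("worsening", "relapse"),
                            alpha = 1, nfolds = 5, rule = c("1se", "min"),
                            nlambda = 50, penalty = NULL, seed = 1) {
  outcome <- match.arg(outcome)
  rule <- match.arg(rule)
  ev <- .event_vector(transitions, outcome)
  if (sum(ev) < 2) stop("fewer than 2 events; cannot select variants", call. = FALSE)
  G <- .genotype_rows(genotypes, transitions$subject_id)
  y <- survival::Surv(transitions$start, transitions$stop, ev)
  if (!is.null(penalty)) {
    if (penalty == 0) return(colnames(G))
    fit <- glmnet::glmnet(G, y, family = "cox", alpha = alpha,
                          nlambda = nlambda, lambda.min.ratio = 0.01)
    beta <- as.numeric(stats::coef(fit, s = penalty))
    return(colnames(G)[beta != 0])
  }
  subj <- factor(transitions$subject_id)
  foldid <- .with_seed(seed, {
    fs <- sample(rep_len(seq_len(nfolds), nlevels(subj)))
    fs[as.integer(subj)]
  })
  cv <- glmnet::cv.glmnet(G, y, family = "cox", alpha = alpha,
                          foldid = foldid, nlambda = nlambda,
                          lambda.min.ratio = 0.05)
  lam <- if (rule == "1se") cv$lambda.1se else cv$lambda.min
  beta <- as.numeric(stats::coef(cv, s = lam))
  colnames(G)[beta != 0]
}

.event_vector <- function(transitions, outcome) {
  if (outcome == "worsening") as.integer(transitions$event)
  else as.integer(transitions$relapse_event)
}

.genotype_rows <- function(genotypes, subject_id) {
  idx <- match(as.character(subject_id), rownames(genotypes))
  if (anyNA(idx)) stop("genotype rows do not cover all subjects in transitions",
                       call. = FALSE)
  genotypes[idx, , drop = FALSE]
}

#' Fit the stage-1 mixed-effects Cox GPI model
#'
#' Fits a Cox model with a subject-level Gaussian frailty (random intercept
#' on the log hazard) including, for every selected SNP, a main effect, an
#' interaction with log time since onset, and an interaction with
#' standardised latitude; adjusted for log disease duration and latitude
#' main effects. Ties are handled by Breslow's method. The tag SNP for the
#' primary HLA-DRB1 signal, when supplied, is always force-included.
#'
#' @param transitions A `transition_intervals` frame with a `latitude` column.
#' @param genotypes Dosage matrix.
#' @param snps Character vector of SNP ids to include (from
#'   [select_variants()]); may be empty, in which case the returned model has
#'   a linear predictor identically zero.
#' @param outcome `"worsening"` or `"relapse"`.
#' @param hla_snp Optional id of the force-included HLA tag SNP.
#' @param time_interactions,lat_interactions Logical: include SNP x log(time)
#'   and SNP x latitude terms (default TRUE).
#' @param frailty Include the subject-level Gaussian frailty (default TRUE).
#' @param adjust Include the log-time and latitude main-effect adjustments
#'   (default TRUE).
#' @return An object of class `gpi_model` with the per-SNP coefficient table
#'   (`beta_main`, `beta_time`, `beta_lat`), the frailty SD, the adjustment
#'   coefficients, and the outcome label.
#' @export
fit_gpi_cox <- function(transitions, genotypes, snps,
                        outcome = c("worsening", "relapse"), hla_snp = NULL,
                        time_interactions = TRUE, lat_interactions = TRUE,
                        frailty = TRUE, adjust = TRUE) {
  outcome <- match.arg(outcome)
  snps <- union(snps, hla_snp)
  if (!length(snps)) {
    return(structure(list(outcome = outcome,
                          snp_terms = data.frame(snp = character(0),
                                                 beta_main = numeric(0),
                                                 beta_time = numeric(0),
                                                 beta_lat = numeric(0)),
                          frailty_sd = 0, adjustment = c(log_time = 0, latitude = 0),
                          converged = TRUE),
                     class = "gpi_model"))
  }
  ev <- .event_vector(transitions, outcome)
  G <- .genotype_rows(genotypes, transitions$subject_id)[, snps, drop = FALSE]
  logt <- log(pmax(transitions$stop, 1e-8))
  lat <- transitions$latitude
  if (is.null(lat)) {
    if (lat_interactions || adjust)
      stop("transitions must carry a latitude column", call. = FALSE)
    lat <- rep(0, nrow(transitions))
  }

  # syntactic internal column names (SNP ids are often chr:pos strings)
  sid <- paste0("x", seq_along(snps))
  X <- G
  cn <- paste0(sid, "_main")
  if (time_interactions) { X <- cbind(X, G * logt); cn <- c(cn, paste0(sid, "_time")) }
  if (lat_interactions) { X <- cbind(X, G * lat); cn <- c(cn, paste0(sid, "_lat")) }
  colnames(X) <- cn
  df <- data.frame(start = transitions$start, stop = transitions$stop, ev = ev,
                   id = factor(transitions$subject_id), logt = logt, lat = lat)
  df <- cbind(df, as.data.frame(X, check.names = FALSE))
  fml <- stats::as.formula(paste(
    "survival::Surv(start, stop, ev) ~",
    paste(cn, collapse = " + "),
    if (adjust) "+ logt + lat" else "",
    if (frailty) "+ survival::frailty(id, distribution = 'gaussian')" else ""))
  fit <- tryCatch(
    survival::coxph(fml, data = df, ties = "breslow"),
    error = function(e) stop("stage-1 Cox fit failed: ", conditionMessage(e),
                             call. = FALSE))
  cf <- stats::coef(fit)
  pick <- function(kind) {
    v <- cf[paste0(sid, "_", kind)]
    v[is.na(v)] <- 0
    unname(v)
  }
  terms <- data.frame(snp = snps,
                      beta_main = pick("main"),
                      beta_time = if (time_interactions) pick("time") else 0,
                      beta_lat = if (lat_interactions) pick("lat") else 0,
                      stringsAsFactors = FALSE)
  fr_var <- if (frailty) tryCatch(fit$history[[1]]$theta, error = function(e) NULL)
            else NULL
  adj <- if (adjust) c(log_time = unname(cf["logt"]), latitude = unname(cf["lat"]))
         else c(log_time = 0, latitude = 0)
  structure(list(outcome = outcome, snp_terms = terms,
                 frailty_sd = if (is.null(fr_var)) 0 else sqrt(fr_var),
                 adjustment = adj,
                 converged = TRUE),
            class = "gpi_model")
}

#' Evaluate the genetic prognostic index
#'
#' The GPI is the genetic part of the stage-1 linear predictor:
#' `sum_j g_j * (beta_main_j + beta_time_j * log(t) + beta_lat_j * latitude)`.
#' Frailty and the non-genetic adjustment terms are excluded: the index is
#' purely genetic. Linear in the dosage vector.
#'
#' @param model A `gpi_model`.
#' @param genotype Dosage vector named by SNP id (extra SNPs ignored).
#' @param latitude Standardised latitude of the subject's site.
#' @param time Time since onset in years (> 0; log-time interactions).
#' @return Numeric GPI value(s), one per `time`.
#' @export
evaluate_gpi <- function(model, genotype, latitude, time) {
  stopifnot(inherits(model, "gpi_model"))
  if (any(time <= 0)) stop("time must be positive (log-time interactions)",
                           call. = FALSE)
  tt <- model$snp_terms
  if (!nrow(tt)) return(rep(0, length(time)))
  g <- genotype[tt$snp]
  if (anyNA(g)) stop("genotype vector lacks SNPs required by the model",
                     call. = FALSE)
  const <- sum(g * (tt$beta_main + tt$beta_lat * latitude))
  tcoef <- sum(g * tt$beta_time)
  const + tcoef * log(time)
}

#' Per-subject GPI series at visit times
#'
#' Evaluates the GPI at every visit of every subject; this longitudinal
#' series is what the stage-2 trajectory model smooths.
#'
#' @param model A `gpi_model`.
#' @param visits Visit table with `subject_id`, `time`, `latitude`.
#' @param genotypes Dosage matrix.
#' @param min_time Times below this are floored before taking logs
#'   (default 0.25 years; the baseline visit sits at t = 0).
#' @return Data frame of class `gpi_series`: `subject_id`, `time`, `gpi`.
#' @export
compute_gpi_series <- function(model, visits, genotypes, min_time = 0.25) {
  tt <- model$snp_terms
  G <- .genotype_rows(genotypes, visits$subject_id)
  tm <- pmax(visits$time, min_time)
  if (nrow(tt)) {
    Gs <- G[, tt$snp, drop = FALSE]
    gpi <- drop(Gs %*% tt$beta_main) +
      drop(Gs %*% tt$beta_time) * log(tm) +
      drop(Gs %*% tt$beta_lat) * visits$latitude
  } else gpi <- rep(0, nrow(visits))
  out <- data.frame(subject_id = visits$subject_id, time = visits$time,
                    gpi = gpi, stringsAsFactors = FALSE)
  class(out) <- c("gpi_series", "data.frame")
  out
}

#' Serialise a GPI model to JSON
#'
#' @param model A `gpi_model`.
#' @param path Output path.
#' @export
write_gpi_model <- function(model, path) {
  jsonlite::write_json(
    list(outcome = model$outcome, snp_terms = model$snp_terms,
         frailty_sd = model$frailty_sd, adjustment = as.list(model$adjustment)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.gpi_model <- function(x, ...) {
  cat("Stage-1 GPI model (", x$outcome, "): ", nrow(x$snp_terms),
      " SNPs, frailty SD = ", signif(x$frailty_sd, 3), "\n", sep = "")
  invisible(x)
}
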