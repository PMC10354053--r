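#' Run configuration for the three-stage analysis
#'
#' Exactly one of `visits`/`genotypes` (data frames or CSV paths) or a
#' `simulation` block must be given. Seeds are mandatory.
#'
#' @param visits,genotypes Input data (data frame / matrix) or CSV paths.
#' @param simulation List with `n_subjects`, `n_snps`, and optionally any
#'   [sim_truth()] arguments under `truth`.
#' @param directions Analysis directions: `"worsening_to_relapse"`
#'   (WS-GPI -> relapse hazard) and/or `"relapse_to_worsening"`.
#' @param associations Association hypotheses to fit (`"CV"`, `"CVS"`, `"CE"`).
#' @param lags Survival-time lags in months (subset of 0/3/6).
#' @param dmt_adjusted Also fit the DMT-duration-adjusted model.
#' @param mcmc [mcmc_control()] for the stage-3 joint models.
#' @param traj_mcmc [mcmc_control()] for the stage-2 trajectory model.
#' @param selection List of [select_variants()] options (e.g. `penalty`).
#' @param confounders Confounders for stage 3 (default: the six clinical and
#'   environmental effects; smoking is deliberately not among them).
#' @param seed Master seed.
#' @param out_dir Optional output directory for the report bundle.
#' @return List of class `run_config`.
#' @export
run_config <- function(visits = NULL, genotypes = NULL, simulation = NULL,
                       directions = c("worsening_to_relapse", "relapse_to_worsening"),
                       associations = c("CV", "CVS"), lags = 0,
                       dmt_adjusted = FALSE,
                       mcmc = mcmc_control(2000, 1000, 3, seed = 1),
                       traj_mcmc = mcmc_control(1500, 500, 1, seed = 1),
                       selection = list(penalty = NULL),
                       confounders = c("sex", "log_age", "bmi",
                                       "relapse_count", "t2l", "vitd"),
                       seed = 1, out_dir = NULL) {
  has_data <- !is.null(visits) && !is.null(genotypes)
  if (has_data == !is.null(simulation))
    stop("provide exactly one of (visits + genotypes) or a simulation block",
         call. = FALSE)
  if (is.null(seed)) stop("a seed is mandatory", call. = FALSE)
  directions <- match.arg(directions, several.ok = TRUE)
  structure(list(visits = visits, genotypes = genotypes, simulation = simulation,
                 directions = directions, associations = associations,
                 lags = lags, dmt_adjusted = dmt_adjusted, mcmc = mcmc,
                 traj_mcmc = traj_mcmc, selection = selection,
                 confounders = confounders, seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror the [run_config()]
#'   arguments (`mcmc`/`traj_mcmc` as lists of [mcmc_control()] arguments).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$mcmc)) y$mcmc <- do.call(mcmc_control, y$mcmc)
  if (!is.null(y$traj_mcmc)) y$traj_mcmc <- do.call(mcmc_control, y$traj_mcmc)
  do.call(run_config, y)
}

.load_inputs <- function(config) {
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    truth <- if (!is.null(sim$truth)) do.call(sim_truth, sim$truth) else sim_truth()
    G <- simulate_genotypes(sim$n_subjects, n_snps = sim$n_snps %||% nrow(truth$snp_effects),
                            maf_range = sim$maf_range %||% c(0.1, 0.5),
                            seed = config$seed)
    cohort <- simulate_disease_course(G, truth, seed = config$seed + 1L)
    list(visits = cohort$visits, genotypes = G, truth = truth)
  } else {
    v <- config$visits
    g <- config$genotypes
    if (is.character(v)) v <- read_visits(v)
    if (is.character(g)) {
      gd <- utils::read.csv(g, check.names = FALSE)
      g <- as.matrix(gd[, -1L, drop = FALSE])
      rownames(g) <- gd[[1L]]
    }
    list(visits = v, genotypes = g, truth = NULL)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full three-stage analysis
#'
#' Orchestrates event construction, stage-1 GPI fitting, the stage-2
#' trajectory model and the stage-3 joint models for every requested
#' direction, association hypothesis and lag; produces a Table-3-style
#' summary on the log-hazard and hazard-ratio scales and a machine-readable
#' manifest of seeds and event counts.
#'
#' @param config A [run_config()].
#' @return List of class `three_stage_run`: per-direction results (`gpi`,
#'   `trajectory`, `fits`, `tables`), the transitions, and the `manifest`.
#' @export
run_three_stage <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inp <- .load_inputs(config)
  visits <- inp$visits
  transitions <- confirm_relapses(visits, build_transitions(visits))
  d1 <- sum(transitions$event)
  d2 <- sum(transitions$relapse_event)
  results <- list()
  for (dir in config$directions) {
    gpi_outcome <- if (dir == "worsening_to_relapse") "worsening" else "relapse"
    surv_outcome <- if (dir == "worsening_to_relapse") "relapse" else "worsening"
    sel_args <- c(list(transitions = transitions, genotypes = inp$genotypes,
                       outcome = gpi_outcome, seed = config$seed + 11L),
                  config$selection)
    snps <- do.call(select_variants, sel_args)
    gpi <- fit_gpi_cox(transitions, inp$genotypes, snps, outcome = gpi_outcome)
    series <- compute_gpi_series(gpi, visits, inp$genotypes)
    spl <- spline_config_from_times(pmax(series$time, 0.25))
    traj <- fit_trajectory_model(series, spline = spl, mcmc = config$traj_mcmc)

    surv <- transitions
    surv$event <- if (surv_outcome == "relapse") as.integer(surv$relapse_event)
                  else as.integer(surv$event)
    bl <- pspline_config(range = c(0, max(surv$stop)))
    fits <- list()
    for (assoc in config$associations) for (lag in config$lags) {
      if (assoc == "CE" && lag > 0) next
      key <- paste0(assoc, if (lag > 0) paste0("_lag", lag))
      fits[[key]] <- fit_joint_model(
        surv, traj,
        spec = jm_spec(surv_outcome, assoc, lag = lag,
                       confounders = config$confounders, baseline = bl),
        mcmc = config$mcmc)
      if (config$dmt_adjusted) {
        fits[[paste0(key, "_dmt")]] <- fit_joint_model(
          surv, traj,
          spec = jm_spec(surv_outcome, assoc, lag = lag,
                         confounders = config$confounders,
                         dmt_interactions = TRUE, baseline = bl),
          mcmc = config$mcmc)
      }
    }
    first <- config$associations[1L]
    tables <- report_table3(fits[[first]],
                            adjusted = fits[[paste0(first, "_dmt")]],
                            gpi_label = if (gpi_outcome == "worsening") "WS-GPI" else "RS-GPI")
    results[[dir]] <- list(snps = snps, gpi = gpi, trajectory = traj,
                           fits = fits, tables = tables)
  }
  manifest <- list(
    package = "msjoint", version = as.character(utils::packageVersion("msjoint")),
    seed = config$seed,
    chain_seeds = config$mcmc$chain_seeds,
    traj_chain_seeds = config$traj_mcmc$chain_seeds,
    selection_seed = config$seed + 11L,
    n_subjects = length(unique(visits$subject_id)),
    n_visits = nrow(visits), n_transitions = nrow(transitions),
    worsening_events = d1, relapse_events = d2,
    directions = config$directions, associations = config$associations,
    lags = config$lags)
  out <- structure(list(directions = results, transitions = transitions,
                        visits = visits, genotypes = inp$genotypes,
                        truth = inp$truth, manifest = manifest),
                   class = "three_stage_run")
  if (!is.null(config$out_dir)) .write_bundle(out, config$out_dir)
  out
}

.write_bundle <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_transitions(run$transitions, file.path(dir, "transitions.csv"))
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  summ <- lapply(run$directions, function(r) {
    lapply(r$fits, function(f) {
      s <- posterior_summary(f, params = f$alpha_names)
      list(association = s, rhat_max = max(f$rhat, na.rm = TRUE),
           dic = unclass(dic(f)))
    })
  })
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  for (nm in names(run$directions)) {
    tb <- run$directions[[nm]]$tables
    utils::write.csv(tb$log_scale, file.path(dir, paste0("table3_", nm, "_log.csv")),
                     row.names = FALSE)
    utils::write.csv(tb$hazard_ratio, file.path(dir, paste0("table3_", nm, "_hr.csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

.fit_summary_df <- function(fit) {
  if (inherits(fit, "jm_fit")) {
    posterior_summary(fit, params = c(fit$spec$confounders, fit$alpha_names))
  } else as.data.frame(fit)
}

#' Table-3-style summary of joint-model fits
#'
#' Formats confounder effects, association parameters and DMT-duration
#' interactions of an unadjusted and (optionally) DMT-adjusted fit, on the
#' log-hazard scale and, via [to_hazard_ratio()], on the hazard-ratio scale
#' rounded to two decimals.
#'
#' @param unadjusted A `jm_fit`, or a data frame with columns `param`,
#'   `mean`, `lo`, `hi`.
#' @param adjusted Optional DMT-adjusted counterpart.
#' @param gpi_label Label of the index ("WS-GPI" or "RS-GPI").
#' @return List with data frames `log_scale` and `hazard_ratio`; the latter
#'   carries a formatted `hr` column like `"2.96 (2.91; 3.02)"`.
#' @export
report_table3 <- function(unadjusted, adjusted = NULL, gpi_label = "GPI") {
  lab <- function(param) {
    param <- sub("^alpha_value_dmt([13])$", paste0(gpi_label, " [value] x DDMT (Cat. \\1)"), param)
    param <- sub("^alpha_slope_dmt([13])$", paste0(gpi_label, " [slope] x DDMT (Cat. \\1)"), param)
    param <- sub("^alpha_value$", paste0(gpi_label, " [value]"), param)
    param <- sub("^alpha_slope$", paste0(gpi_label, " [slope]"), param)
    param
  }
  u <- .fit_summary_df(unadjusted)
  u$component <- ifelse(grepl("^alpha", u$param), "Association parameters",
                        "Clinical and environmental effects")
  u$effect <- lab(u$param)
  out <- data.frame(component = u$component, effect = u$effect,
                    est_unadjusted = u$mean, lo_unadjusted = u$lo,
                    hi_unadjusted = u$hi, stringsAsFactors = FALSE)
  if (!is.null(adjusted)) {
    a <- .fit_summary_df(adjusted)
    a$effect <- lab(a$param)
    m <- match(out$effect, a$effect)
    out$est_adjusted <- a$mean[m]
    out$lo_adjusted <- a$lo[m]
    out$hi_adjusted <- a$hi[m]
    extra <- a[!a$effect %in% out$effect, , drop = FALSE]
    if (nrow(extra)) {
      out <- rbind(out, data.frame(
        component = "Association parameters", effect = extra$effect,
        est_unadjusted = NA_real_, lo_unadjusted = NA_real_,
        hi_unadjusted = NA_real_, est_adjusted = extra$mean,
        lo_adjusted = extra$lo, hi_adjusted = extra$hi,
        stringsAsFactors = FALSE))
    }
  }
  hr <- out
  for (cc in grep("^(est|lo|hi)_", names(hr), value = TRUE))
    hr[[cc]] <- round(exp(out[[cc]]), 2)
  hr$hr <- sprintf("%.2f (%.2f; %.2f)",
                   if (is.null(hr$est_adjusted)) hr$est_unadjusted else
                     ifelse(is.na(hr$est_adjusted), hr$est_unadjusted, hr$est_adjusted),
                   if (is.null(hr$lo_adjusted)) hr$lo_unadjusted else
                     ifelse(is.na(hr$lo_adjusted), hr$lo_unadjusted, hr$lo_adjusted),
                   if (is.null(hr$hi_adjusted)) hr$hi_unadjusted else
                     ifelse(is.na(hr$hi_adjusted), hr$hi_unadjusted, hr$hi_adjusted))
  list(log_scale = out, hazard_ratio = hr)
}

#' @export
print.three_stage_run <- function(x, ...) {
  m <- x$manifest
  cat("Three-stage joint-model run:", m$n_subjects, "subjects,",
      m$n_transitions, "transitions (", m$worsening_events, "worsening /",
      m$relapse_events, "relapse events )\n")
  for (nm in names(x$directions))
    cat("  ", nm, ": fits =", paste(names(x$directions[[nm]]$fits), collapse = ", "), "\n")
  invisible(x)
}
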