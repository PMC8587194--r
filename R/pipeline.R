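# End-to-end orchestration: simulate a market, link quality information,
# build choice sets, fit, post-estimate, and optionally refit the four
# robustness variants -- all from one declarative configuration, with
# every artifact regenerable from (config, seed) alone.

#' Default pipeline configuration
#'
#' @return a nested list of defaults; see [run_pipeline()].
#' @export
default_run_config <- function() {
  list(
    market = list(),  # overrides for market_config()
    truth = list(),   # overrides for true_parameters() (mu/sigma/gamma)
    choice_seed = NULL,  # defaults to market seed + 1
    radius_mode = "fixed_50",  # fixed_50 | variable_90 | custom
    radius_miles = 50,
    coverage = 0.90,
    filters = list(exclude_exited = FALSE, nonemergency_only = FALSE,
                   nonreferral_only = FALSE),
    estimation = list(draws = 300, draw_method = "halton", seed = 1,
                      tol = 1e-8, max_iter = 400, se_method = "hessian",
                      interactions = FALSE),
    post = list(n_boot = 200, ame_draws = 300,
                ame_attribute = "high_online"),
    robustness = FALSE,
    out_dir = NULL
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the full study pipeline from one configuration
#'
#' Stages: simulate the market and its choices, restrict choice sets by
#' the configured market definition, apply sample filters, fit the mixed
#' logit, and compute post-estimation statistics.  With
#' `robustness = TRUE` the four robustness variants (exited surgeons
#' removed; variable-radius markets; nonemergency only; nonreferral only)
#' are refit as well.  All artifacts (CSV/JSON) are written under
#' `out_dir` when given, and every file is regenerable from the
#' configuration and seeds alone.
#'
#' @param config a nested list of overrides over
#'   [default_run_config()], or the path of a YAML file holding one.
#' @param out_dir output directory; overrides `config$out_dir`.  `NULL`
#'   skips writing.
#' @return (invisibly) a list with the market, the simulated and
#'   restricted datasets, descriptive statistics, fits, post-estimation
#'   results, and the audit trail.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(default_run_config(), config)
  out_dir <- out_dir %||% cfg$out_dir
  wr <- !is.null(out_dir)
  if (wr) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(x, f) if (wr) jsonlite::write_json(
    x, file.path(out_dir, f), auto_unbox = TRUE, digits = NA)
  log_stage <- function(stage, ...)
    message(sprintf("[%s] %s", stage, sprintf(...)))

  if (wr) emit(cfg, "config.json")

  # --- simulate -------------------------------------------------------
  mcfg <- do.call(market_config, cfg$market)
  market <- generate_market(mcfg)
  panel <- build_quality_panel(market$reviews, market$report_cards,
                               market$surgeons$surgeon_id,
                               seq_len(mcfg$study_quarters))
  sets <- build_choice_sets(market, Inf)
  long <- assemble_long_dataset(sets, panel, market)
  tr_args <- cfg$truth
  for (nm in c("mu", "sigma", "gamma"))
    if (!is.null(tr_args[[nm]])) tr_args[[nm]] <- unlist(tr_args[[nm]])
  truth <- do.call(true_parameters,
                   c(tr_args, list(surgeon_ids = market$surgeons$surgeon_id,
                                   seed = mcfg$seed)))
  choice_seed <- cfg$choice_seed %||% (mcfg$seed + 1L)
  data <- simulate_choices(long, truth, seed = choice_seed)
  log_stage("simulate", "%d patients, %d rows",
            length(unique(data$patient_id)), nrow(data))
  if (wr) {
    write_market(market, file.path(out_dir, "market"))
    write_long_dataset(data, file.path(out_dir, "discharges_long.csv"))
    write_true_parameters(truth, file.path(out_dir, "true_parameters.json"))
  }

  # --- build (market definition + filters) ----------------------------
  est <- switch(cfg$radius_mode,
    fixed_50 = fixed_radius_choice_sets(data, 50),
    variable_90 = variable_radius_choice_sets(data, coverage = cfg$coverage),
    custom = fixed_radius_choice_sets(data, cfg$radius_miles),
    stop("run_pipeline: unknown radius_mode `", cfg$radius_mode, "`"))
  audit <- list(radius = exclusion_audit(est))
  est <- do.call(apply_filters, c(list(est), cfg$filters))
  audit$filters <- exclusion_audit(est)
  log_stage("build", "%d patients retained (%d rows)",
            audit$filters$n_patients_out, nrow(est))
  desc <- list(unrestricted = descriptive_stats(data),
               restricted = descriptive_stats(est))
  if (wr) {
    write_long_dataset(est, file.path(out_dir, "estimation_long.csv"))
    emit(audit, "exclusion_audit.json")
    .write_csv_exact(desc$unrestricted,
                     file.path(out_dir, "descriptives_unrestricted.csv"))
    .write_csv_exact(desc$restricted,
                     file.path(out_dir, "descriptives_restricted.csv"))
  }

  # --- fit -------------------------------------------------------------
  e <- cfg$estimation
  spec <- model_spec(interactions = if (isTRUE(e$interactions))
    c("high_online", "no_online", "high_report", "no_report") else NULL)
  fit <- fit_mixed_logit(est, spec, draws = e$draws,
                         draw_method = e$draw_method, seed = e$seed,
                         tol = e$tol, max_iter = e$max_iter,
                         se_method = e$se_method)
  log_stage("fit", "loglik %.2f, converged %s", fit$loglik, fit$converged)
  if (wr) {
    write_fit(fit, file.path(out_dir, "fit_main.json"))
    .write_csv_exact(format_fit_table(fit),
                     file.path(out_dir, "fit_main_table.csv"))
  }

  # --- post-estimation --------------------------------------------------
  shares <- lapply(c(no_online = "no_online", no_report = "no_report"),
                   function(a) {
                     s <- share_preferring(fit$mu[[a]], fit$sigma[[a]])
                     list(share_pct = 100 * s$share,
                          complement_pct = 100 * s$complement)
                   })
  wtt <- lapply(c(high_online = "high_online", high_report = "high_report"),
                function(a) {
                  w <- willingness_to_travel(fit, a)
                  list(miles = as.numeric(w), se = attr(w, "se"))
                })
  ame <- ame_bootstrap(fit, est, cfg$post$ame_attribute,
                       n_boot = cfg$post$n_boot, seed = choice_seed,
                       n_draws = cfg$post$ame_draws)
  post <- list(shares = shares, wtt = wtt,
               baseline = baseline_choice_probability(est),
               ame = list(attribute = ame$attribute, ame_pp = ame$ame,
                          relative = ame$relative, ci = ame$ci,
                          n_boot = ame$n_boot))
  yearfx <- NULL
  if (isTRUE(e$interactions)) {
    yearfx <- lapply(c(high_online = "high_online",
                       high_report = "high_report"),
                     function(a) year_effects(fit, a))
    if (wr) .write_csv_exact(
      cbind(attribute = rep(names(yearfx),
                            vapply(yearfx, nrow, 0L)),
            do.call(rbind, yearfx)),
      file.path(out_dir, "year_effects.csv"))
  }
  if (wr) emit(post, "postestimation.json")

  # --- robustness -------------------------------------------------------
  robust <- NULL
  if (isTRUE(cfg$robustness)) {
    variants <- list(
      exclude_exited = apply_filters(fixed_radius_choice_sets(data, 50),
                                     exclude_exited = TRUE),
      variable_radius = variable_radius_choice_sets(data,
                                                    coverage = cfg$coverage),
      nonemergency = apply_filters(fixed_radius_choice_sets(data, 50),
                                   nonemergency_only = TRUE),
      nonreferral = apply_filters(fixed_radius_choice_sets(data, 50),
                                  nonreferral_only = TRUE))
    robust <- lapply(names(variants), function(nm) {
      f <- fit_mixed_logit(variants[[nm]], model_spec(), draws = e$draws,
                           draw_method = e$draw_method, seed = e$seed,
                           tol = e$tol, max_iter = e$max_iter,
                           se_method = e$se_method)
      log_stage("robustness", "%s: loglik %.2f", nm, f$loglik)
      if (wr) write_fit(f, file.path(out_dir,
                                     paste0("fit_robust_", nm, ".json")))
      f
    })
    names(robust) <- names(variants)
  }

  invisible(list(config = cfg, market = market, truth = truth,
                 data = data, estimation = est, descriptives = desc,
                 fit = fit, post = post, year_effects = yearfx,
                 robustness = robust, audit = audit,
                 out_dir = out_dir))
}

#' Descriptive statistics of the realized (chosen) alternatives
#'
#' Means and SDs over chosen rows.  Binary variables are reported in
#' percent (mean and SD both scaled by 100); SDs use the population
#' convention `sqrt(mean((x - mean)^2))`, so a binary column with mean
#' `p` has SD `sqrt(p (1 - p))` (times 100).
#'
#' @param data long-format dataset; rows with `chosen == 1` are used if a
#'   `chosen` column is present, otherwise all rows.
#' @return data frame: `variable`, `mean`, `sd`, `n`.
#' @export
descriptive_stats <- function(data) {
  ch <- if ("chosen" %in% names(data)) data[data$chosen == 1, , drop = FALSE]
        else data
  binary <- c("high_online", "no_online", "high_report", "no_report",
              "teaching", "cicu", "emergency", "referral")
  contin <- c("distance", "bed_size")
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  rows <- list()
  for (v in c(contin, binary)) {
    if (!v %in% names(ch)) next
    x <- as.numeric(ch[[v]])
    scale <- if (v %in% binary) 100 else 1
    rows[[v]] <- data.frame(variable = if (v %in% binary)
                              paste0(v, "_pct") else v,
                            mean = scale * mean(x), sd = scale * pop_sd(x),
                            n = length(x), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
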