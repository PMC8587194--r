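# Plain-text readers/writers for the package's data contracts.  Numeric
# columns are serialized with 17 significant digits so every file
# round-trips through its reader bit-exactly.

.write_csv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- .fmt_num(out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

.int_cols <- c("quarter", "pub_quarter", "chosen", "high_online",
               "no_online", "high_report", "no_report", "teaching", "cicu",
               "emergency", "referral", "bed_size", "stars", "exit_quarter")

# always-double columns (grid-snapped coordinates and distances can take
# integer values, which read.csv would otherwise type as integer)
.dbl_cols <- c("x", "y", "distance", "bed_size_100", "mortality_pctile",
               "mean_volume", "avg_rating")

.coerce_cols <- function(x) {
  for (nm in intersect(.int_cols, names(x))) x[[nm]] <- as.integer(x[[nm]])
  for (nm in intersect(.dbl_cols, names(x))) x[[nm]] <- as.numeric(x[[nm]])
  if ("active" %in% names(x)) x$active <- as.logical(x$active)
  x
}

#' Write / read the long-format estimation dataset
#'
#' One row per patient-alternative; doubles are written with enough
#' digits to round-trip exactly.
#'
#' @param data long-format data frame.
#' @param path CSV file path.
#' @return `read_long_dataset` returns the data frame.
#' @export
write_long_dataset <- function(data, path) {
  .write_csv_exact(data, path)
  invisible(path)
}

#' @rdname write_long_dataset
#' @export
read_long_dataset <- function(path) {
  .coerce_cols(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write / read a synthetic market as a directory of CSVs plus a JSON
#' configuration sidecar
#'
#' @param market a `synthetic_market`.
#' @param dir output directory (created if needed).
#' @return `read_market` returns the reconstructed `synthetic_market`.
#' @export
write_market <- function(market, dir) {
  stopifnot(inherits(market, "synthetic_market"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_csv_exact(market$hospitals, file.path(dir, "hospitals.csv"))
  .write_csv_exact(market$surgeons, file.path(dir, "surgeons.csv"))
  .write_csv_exact(market$surgeon_hospitals,
                   file.path(dir, "surgeon_hospitals.csv"))
  .write_csv_exact(market$patients, file.path(dir, "patients.csv"))
  .write_csv_exact(market$reviews, file.path(dir, "reviews.csv"))
  .write_csv_exact(market$report_cards, file.path(dir, "report_cards.csv"))
  cfg <- unclass(market$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_market
#' @export
read_market <- function(dir) {
  cfg <- jsonlite::fromJSON(file.path(dir, "config.json"))
  cfg$star_distribution <- as.numeric(cfg$star_distribution)
  cfg$report_card_quarters <- as.integer(cfg$report_card_quarters)
  config <- do.call(market_config, cfg)
  rd <- function(f) .coerce_cols(utils::read.csv(file.path(dir, f),
                                                stringsAsFactors = FALSE))
  structure(list(config = config,
                 hospitals = rd("hospitals.csv"),
                 surgeons = rd("surgeons.csv"),
                 surgeon_hospitals = rd("surgeon_hospitals.csv"),
                 patients = rd("patients.csv"),
                 reviews = rd("reviews.csv"),
                 report_cards = rd("report_cards.csv")),
            class = "synthetic_market")
}

#' Write / read generating parameters as JSON
#' @param truth a [true_parameters()] object.
#' @param path JSON file path.
#' @return `read_true_parameters` returns the `true_parameters` object.
#' @export
write_true_parameters <- function(truth, path) {
  stopifnot(inherits(truth, "true_parameters"))
  jsonlite::write_json(lapply(unclass(truth), as.list), path,
                       auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_true_parameters
#' @export
read_true_parameters <- function(path) {
  x <- jsonlite::fromJSON(path)
  unl <- function(v) if (length(v) == 0) NULL else unlist(v)
  true_parameters(mu = unl(x$mu), sigma = unl(x$sigma),
                  gamma = unl(x$gamma), fe = unl(x$fe))
}

#' Write a fit (estimates, SEs, log-likelihood, options) as JSON
#' @param fit a `mixl_fit`.
#' @param path JSON file path.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "mixl_fit"))
  out <- list(model = fit$model,
              coefficients = as.list(fit$coefficients),
              se = as.list(fit$se),
              loglik = fit$loglik,
              converged = fit$converged,
              n_obs = fit$n_obs,
              n_patients = fit$n_patients,
              n_draws = fit$n_draws,
              draw_method = fit$draw_method,
              se_method = fit$se_method,
              spec = list(random = fit$spec$random, fixed = fit$spec$fixed,
                          fe = fit$spec$fe,
                          interactions = fit$spec$interactions,
                          trend_origin = fit$spec$trend_origin))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
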