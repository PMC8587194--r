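# Synthetic surgical market: geography, providers, review streams,
# report-card issues, and choices drawn from the utility model with known
# parameters, so every downstream stage is testable without external data.

#' Configuration of a synthetic surgical market
#'
#' Study conditions for [generate_market()].  Defaults emulate a 40-quarter
#' (10-year) statewide CABG market: reviews arrive per surgeon-quarter as a
#' Poisson stream with stars skewed toward five, seven report-card issues
#' appear at irregular intervals, and report cards rate only surgeons whose
#' per-issue case volume reaches the threshold.
#'
#' @param n_patients number of discharges to simulate.
#' @param n_hospitals,n_surgeons provider counts.
#' @param study_quarters number of study quarters (default 40).
#' @param region_extent_miles side of the square region; patients and
#'   hospitals are placed uniformly inside it.
#' @param grid_miles coordinates are snapped to a grid of this cell size,
#'   emulating zip-code-level distance granularity.
#' @param review_arrival_rate expected reviews per surgeon-quarter.
#' @param star_distribution probability vector over 1..5 stars.
#' @param report_card_quarters strictly increasing publication quarters.
#' @param rating_volume_threshold minimum per-issue case volume for a
#'   surgeon to be rated (default 30).
#' @param mean_case_volume mean per-issue case volume across surgeons.
#' @param rc_low_pctile,rc_high_pctile latent mortality-percentile cut
#'   points: below `rc_low_pctile` scores lower-than-expected mortality
#'   (the favorable category), above `rc_high_pctile` greater-than-expected.
#' @param emergency_share,referral_share,attrition_share probabilities of
#'   an emergency admission, a referral admission, and of a surgeon
#'   leaving the market mid-window.
#' @param seed integer RNG seed; the whole market is deterministic in it.
#' @return a validated `market_config` list.
#' @export
market_config <- function(n_patients = 5000, n_hospitals = 12,
                          n_surgeons = 20, study_quarters = 40,
                          region_extent_miles = 120, grid_miles = 5,
                          review_arrival_rate = 0.15,
                          star_distribution = c(0.10, 0.05, 0.05, 0.20, 0.60),
                          report_card_quarters = c(2, 8, 14, 20, 26, 32, 38),
                          rating_volume_threshold = 30,
                          mean_case_volume = 38,
                          rc_low_pctile = 0.10, rc_high_pctile = 0.90,
                          emergency_share = 0.3152, referral_share = 0.30,
                          attrition_share = 0.15, seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_hospitals = as.integer(n_hospitals),
              n_surgeons = as.integer(n_surgeons),
              study_quarters = as.integer(study_quarters),
              region_extent_miles = as.numeric(region_extent_miles),
              grid_miles = as.numeric(grid_miles),
              review_arrival_rate = as.numeric(review_arrival_rate),
              star_distribution = as.numeric(star_distribution),
              report_card_quarters = as.integer(report_card_quarters),
              rating_volume_threshold = as.numeric(rating_volume_threshold),
              mean_case_volume = as.numeric(mean_case_volume),
              rc_low_pctile = as.numeric(rc_low_pctile),
              rc_high_pctile = as.numeric(rc_high_pctile),
              emergency_share = as.numeric(emergency_share),
              referral_share = as.numeric(referral_share),
              attrition_share = as.numeric(attrition_share),
              seed = as.integer(seed))
  validate_market_config(cfg)
  class(cfg) <- "market_config"
  cfg
}

validate_market_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!ok) stop("market_config: invalid `", field, "`: ", why, call. = FALSE)
  }
  for (f in c("n_patients", "n_hospitals", "n_surgeons", "study_quarters"))
    chk(length(cfg[[f]]) == 1 && is.finite(cfg[[f]]) && cfg[[f]] > 0,
        f, "must be a positive count")
  for (f in c("region_extent_miles", "grid_miles", "review_arrival_rate",
              "rating_volume_threshold", "mean_case_volume"))
    chk(length(cfg[[f]]) == 1 && is.finite(cfg[[f]]) && cfg[[f]] >= 0,
        f, "must be finite and non-negative")
  chk(cfg$region_extent_miles > 0, "region_extent_miles", "must be positive")
  sd <- cfg$star_distribution
  chk(length(sd) == 5 && all(is.finite(sd)) && all(sd >= 0) &&
        abs(sum(sd) - 1) < 1e-8,
      "star_distribution", "must be 5 non-negative probabilities summing to 1")
  rq <- cfg$report_card_quarters
  chk(all(diff(rq) > 0), "report_card_quarters", "must be strictly increasing")
  chk(all(rq >= 1 & rq <= cfg$study_quarters), "report_card_quarters",
      "must lie within the study window")
  for (f in c("rc_low_pctile", "rc_high_pctile", "emergency_share",
              "referral_share", "attrition_share"))
    chk(length(cfg[[f]]) == 1 && is.finite(cfg[[f]]) &&
          cfg[[f]] >= 0 && cfg[[f]] <= 1, f, "must be a probability in [0, 1]")
  chk(cfg$rc_low_pctile <= cfg$rc_high_pctile, "rc_low_pctile",
      "must not exceed rc_high_pctile")
  invisible(cfg)
}

#' Generating (true) preference parameters of a synthetic market
#'
#' Means and standard deviations of the normal random coefficients on the
#' quality-information dummies and distance, fixed coefficients on the
#' hospital attributes, and surgeon fixed effects (first surgeon pinned to
#' zero as the reference).  Defaults carry magnitudes typical of a
#' statewide CABG choice study: small positive utility of a high online
#' rating, heterogeneous response to missing information, and a distance
#' coefficient of about -0.28 per mile.
#'
#' @param mu named means for `high_online`, `no_online`, `high_report`,
#'   `no_report`, `distance`.
#' @param sigma named non-negative SDs for the same attributes.
#' @param gamma named fixed coefficients for `bed_size_100` (hundreds of
#'   beds), `teaching`, `cicu`; may be an empty numeric vector.
#' @param fe named surgeon fixed effects with the first (reference) entry
#'   equal to 0, or `NULL` to draw them.
#' @param surgeon_ids surgeon ids used when drawing `fe`.
#' @param fe_sd SD of drawn fixed effects.
#' @param seed seed used only when drawing `fe`.
#' @return a `true_parameters` list.
#' @export
true_parameters <- function(mu = c(high_online = 0.317, no_online = 0.536,
                                   high_report = -0.057, no_report = -0.516,
                                   distance = -0.278),
                            sigma = c(high_online = 0.064, no_online = 1.015,
                                      high_report = 0.326, no_report = 0.828,
                                      distance = 0.122),
                            gamma = c(bed_size_100 = 0.05, teaching = 0.10,
                                      cicu = 0.30),
                            fe = NULL, surgeon_ids = NULL, fe_sd = 0.5,
                            seed = 1L) {
  if (is.null(names(mu)) || is.null(names(sigma)))
    stop("true_parameters: mu and sigma must be named")
  if (!identical(sort(names(mu)), sort(names(sigma))))
    stop("true_parameters: mu and sigma must cover the same attributes")
  sigma <- sigma[names(mu)]
  if (any(sigma < 0)) stop("true_parameters: sigma must be non-negative")
  if (is.null(gamma)) gamma <- setNames(numeric(0), character(0))
  if (length(gamma) > 0 && is.null(names(gamma)))
    stop("true_parameters: gamma must be named")
  if (is.null(fe) && !is.null(surgeon_ids)) {
    set.seed(seed)
    fe <- setNames(c(0, rnorm(length(surgeon_ids) - 1, 0, fe_sd)),
                   as.character(surgeon_ids))
  }
  if (!is.null(fe)) {
    if (is.null(names(fe))) stop("true_parameters: fe must be named")
    if (abs(fe[[1]]) > 1e-12)
      stop("true_parameters: reference surgeon (first fe entry) must be 0")
  }
  structure(list(mu = mu, sigma = sigma, gamma = gamma, fe = fe),
            class = "true_parameters")
}

#' Generate a synthetic market (geography, providers, information streams)
#'
#' Places hospitals and patients uniformly on a grid-snapped square,
#' affiliates each surgeon with one or two hospitals, draws the review
#' stream as a per-surgeon-quarter Poisson arrival process with stars from
#' the configured distribution, and publishes report-card issues at the
#' configured quarters: surgeons below the per-issue case-volume threshold
#' are unrated, the rest are categorized from their latent mortality
#' percentile.  A share of surgeons exits the market (performs no
#' surgeries after the exit quarter).  Deterministic given the seed.
#'
#' @param config a [market_config()].
#' @return a `synthetic_market` list with elements `config`, `hospitals`,
#'   `surgeons`, `surgeon_hospitals`, `patients`, `reviews`,
#'   `report_cards`.
#' @export
generate_market <- function(config) {
  validate_market_config(config)
  set.seed(config$seed)
  snap <- function(v) round(v / config$grid_miles) * config$grid_miles
  ext <- config$region_extent_miles
  Qn <- config$study_quarters

  hospitals <- data.frame(
    hospital_id = sprintf("H%02d", seq_len(config$n_hospitals)),
    x = snap(runif(config$n_hospitals, 0, ext)),
    y = snap(runif(config$n_hospitals, 0, ext)),
    bed_size = as.integer(pmax(50, round(rgamma(config$n_hospitals,
                                                shape = 2.2, scale = 250)))),
    teaching = rbinom(config$n_hospitals, 1, 0.5),
    cicu = rbinom(config$n_hospitals, 1, 0.9),
    stringsAsFactors = FALSE
  )

  sid <- sprintf("S%03d", seq_len(config$n_surgeons))
  exited <- runif(config$n_surgeons) < config$attrition_share
  exit_q <- rep(NA_integer_, config$n_surgeons)
  lo <- max(2L, Qn %/% 2L)
  hi <- max(lo, Qn - 4L)
  exit_q[exited] <- sample(seq.int(lo, hi), sum(exited), replace = TRUE)
  surgeons <- data.frame(
    surgeon_id = sid,
    mortality_pctile = runif(config$n_surgeons),
    # volumes concentrate near the rating threshold so a surgeon's rated
    # status genuinely varies across issues (identification of the
    # no-score effect separately from surgeon fixed effects)
    mean_volume = rgamma(config$n_surgeons, shape = 9,
                         rate = 9 / config$mean_case_volume),
    exit_quarter = exit_q,
    stringsAsFactors = FALSE
  )

  primary <- sample(hospitals$hospital_id, config$n_surgeons, replace = TRUE)
  second <- ifelse(runif(config$n_surgeons) < 0.4,
                   vapply(primary, function(h)
                     sample(setdiff(hospitals$hospital_id, h), 1), ""),
                   NA_character_)
  sh <- rbind(
    data.frame(surgeon_id = sid, hospital_id = primary,
               stringsAsFactors = FALSE),
    data.frame(surgeon_id = sid[!is.na(second)],
               hospital_id = second[!is.na(second)],
               stringsAsFactors = FALSE)
  )
  sh <- sh[order(sh$surgeon_id, sh$hospital_id), , drop = FALSE]
  rownames(sh) <- NULL

  patients <- data.frame(
    patient_id = sprintf("P%05d", seq_len(config$n_patients)),
    x = snap(runif(config$n_patients, 0, ext)),
    y = snap(runif(config$n_patients, 0, ext)),
    quarter = sample.int(Qn, config$n_patients, replace = TRUE),
    emergency = rbinom(config$n_patients, 1, config$emergency_share),
    referral = rbinom(config$n_patients, 1, config$referral_share),
    stringsAsFactors = FALSE
  )

  # review stream: Poisson arrivals per surgeon-quarter
  grid <- expand.grid(surgeon_id = sid, quarter = seq_len(Qn),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  nrev <- rpois(nrow(grid), config$review_arrival_rate)
  reviews <- data.frame(
    surgeon_id = rep(grid$surgeon_id, nrev),
    quarter = rep(grid$quarter, nrev),
    stars = if (sum(nrev) > 0)
      sample.int(5, sum(nrev), replace = TRUE,
                 prob = config$star_distribution)
    else integer(0),
    stringsAsFactors = FALSE
  )

  # report-card issues: rate surgeons above the case-volume threshold;
  # categories from the rank of latent mortality among rated surgeons, so
  # each issue carries both tails whenever enough surgeons are rated
  rc <- list()
  for (pq in config$report_card_quarters) {
    vol <- rpois(config$n_surgeons, surgeons$mean_volume)
    rated <- vol >= config$rating_volume_threshold
    if (!any(rated)) next
    pr <- rank(surgeons$mortality_pctile[rated]) / sum(rated)
    lo_cut <- max(config$rc_low_pctile, 1 / sum(rated))
    cat_ <- ifelse(pr <= lo_cut, "lower_than_expected",
                   ifelse(pr > config$rc_high_pctile,
                          "greater_than_expected", "as_expected"))
    rc[[length(rc) + 1]] <- data.frame(
      pub_quarter = pq, surgeon_id = sid[rated], category = cat_,
      stringsAsFactors = FALSE)
  }
  report_cards <- if (length(rc) > 0) do.call(rbind, rc)
    else data.frame(pub_quarter = integer(0), surgeon_id = character(0),
                    category = character(0), stringsAsFactors = FALSE)
  rownames(report_cards) <- NULL

  structure(list(config = config, hospitals = hospitals, surgeons = surgeons,
                 surgeon_hospitals = sh, patients = patients,
                 reviews = reviews, report_cards = report_cards),
            class = "synthetic_market")
}

#' Simulate patient choices from the utility model
#'
#' For each patient, draws patient-level coefficients from the normal
#' mixing distribution, adds type-1 extreme value (Gumbel) shocks via
#' inverse-CDF sampling, and records the utility-maximizing alternative as
#' chosen.  Rows whose `active` flag is `FALSE` (surgeon already exited at
#' the patient's admission quarter) cannot be chosen.  Patients with no
#' feasible alternative are dropped, with the count reported in the
#' attached audit.
#'
#' @param data long-format dataset (one row per patient-alternative) with
#'   the covariate columns named in `truth`, e.g. from
#'   [assemble_long_dataset()].
#' @param truth a [true_parameters()] object.
#' @param seed RNG seed for coefficient and shock draws.
#' @return `data` with a `chosen` column (0/1, exactly one 1 per retained
#'   patient); audit attached via [exclusion_audit()].
#' @export
simulate_choices <- function(data, truth, seed = 1L) {
  stopifnot(inherits(truth, "true_parameters"), "patient_id" %in% names(data))
  attrs <- names(truth$mu)
  miss <- setdiff(c(attrs, names(truth$gamma)), names(data))
  if (length(miss) > 0)
    stop("simulate_choices: data lacks covariate column(s): ",
         paste(miss, collapse = ", "))
  set.seed(seed)

  pid_levels <- unique(data$patient_id)
  pid <- match(data$patient_id, pid_levels)
  P <- length(pid_levels)
  K <- length(attrs)

  z <- matrix(rnorm(P * K), P, K)
  beta <- sweep(z, 2, truth$sigma[attrs], "*")
  beta <- sweep(beta, 2, truth$mu[attrs], "+")

  Q <- as.matrix(data[attrs])
  u <- rowSums(Q * beta[pid, , drop = FALSE])
  for (g in names(truth$gamma)) u <- u + truth$gamma[[g]] * data[[g]]
  if (!is.null(truth$fe)) {
    fidx <- match(as.character(data$surgeon_id), names(truth$fe))
    if (any(is.na(fidx)))
      stop("simulate_choices: surgeon without a fixed effect in truth$fe")
    u <- u + unname(truth$fe[fidx])
  }
  u <- u - log(-log(runif(nrow(data))))  # EV1 shock, inverse CDF

  feasible <- if ("active" %in% names(data)) as.logical(data$active)
              else rep(TRUE, nrow(data))
  u[!feasible] <- -Inf

  # argmax per patient (ties have measure zero); -Inf-only patients are empty
  ord <- order(pid, -u)
  first <- ord[!duplicated(pid[ord])]
  best <- rep(-Inf, P)
  best[pid[first]] <- u[first]
  empty <- !is.finite(best)
  chosen <- integer(nrow(data))
  chosen[first[is.finite(u[first])]] <- 1L

  out <- data
  out$chosen <- chosen
  if (any(empty)) {
    drop_pid <- pid_levels[empty]
    out <- out[!out$patient_id %in% drop_pid, , drop = FALSE]
    message("simulate_choices: dropped ", sum(empty),
            " patient(s) with no feasible alternative")
  }
  rownames(out) <- NULL
  attr(out, "audit") <- list(n_patients_in = P,
                             n_patients_empty = sum(empty),
                             n_patients_out = P - sum(empty),
                             seed = seed)
  out
}
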