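# Shared fixtures: all synthetic, built in code at test time.

# A complete small market run: market -> panel -> long data -> simulated
# choices -> 50-mile estimation sample.
make_study <- function(n_patients = 300, n_hospitals = 6, n_surgeons = 8,
                       seed = 42, region = 120, radius = 50,
                       mu = c(high_online = 0.3, no_online = 0.5,
                              high_report = -0.057, no_report = -0.516,
                              distance = -0.28),
                       sigma = c(high_online = 0.064, no_online = 1.015,
                                 high_report = 0.326, no_report = 0.828,
                                 distance = 0.122),
                       ...) {
  cfg <- market_config(n_patients = n_patients, n_hospitals = n_hospitals,
                       n_surgeons = n_surgeons, seed = seed,
                       region_extent_miles = region, ...)
  mk <- generate_market(cfg)
  panel <- build_quality_panel(mk$reviews, mk$report_cards,
                               mk$surgeons$surgeon_id,
                               seq_len(cfg$study_quarters))
  long <- assemble_long_dataset(build_choice_sets(mk, Inf), panel, mk)
  truth <- true_parameters(mu = mu, sigma = sigma,
                           surgeon_ids = mk$surgeons$surgeon_id,
                           seed = seed + 1000)
  dat <- suppressMessages(simulate_choices(long, truth, seed = seed + 2000))
  est <- fixed_radius_choice_sets(dat, radius)
  list(config = cfg, market = mk, panel = panel, truth = truth,
       data = dat, est = est)
}

# A hand-built long dataset: P patients who share one choice set of J
# alternatives with the given attribute columns (each a length-J vector).
make_shared_set <- function(P, attrs, surgeon_ids = NULL) {
  J <- length(attrs[[1]])
  if (is.null(surgeon_ids)) surgeon_ids <- sprintf("S%02d", seq_len(J))
  d <- data.frame(
    patient_id = rep(sprintf("P%04d", seq_len(P)), each = J),
    surgeon_id = rep(surgeon_ids, P),
    hospital_id = "H1",
    quarter = 1L,
    stringsAsFactors = FALSE)
  for (nm in names(attrs)) d[[nm]] <- rep(attrs[[nm]], P)
  d
}

# A minimal fitted-model object for post-estimation algebra tests.
fake_fit <- function(mu, sigma, gamma = setNames(numeric(0), character(0)),
                     fe = c(S1 = 0), spec = NULL, vcov = NULL) {
  if (is.null(spec))
    spec <- model_spec(random = names(mu), fixed = names(gamma),
                       interactions = NULL)
  structure(list(mu = mu, sigma = sigma, gamma = gamma, fe = fe,
                 vcov = vcov, spec = spec, model = "mixed_logit",
                 se = NULL, loglik = NA_real_, converged = TRUE),
            class = "mixl_fit")
}
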