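# Geographic choice sets: distances, fixed- and variable-radius market
# definitions, sample filters, and assembly of the long-format estimation
# dataset (one row per patient-alternative, exactly one chosen row per
# patient).

#' Distance between coordinate pairs, in miles
#'
#' Planar mode takes Euclidean distance on synthetic `(x, y)` mile
#' coordinates; great-circle mode takes the haversine distance between
#' `(lon, lat)` degree coordinates (via \pkg{geosphere}).
#'
#' @param a,b two-column matrices (or length-2 vectors) of coordinates:
#'   `(x, y)` miles for planar, `(lon, lat)` degrees for great-circle.
#' @param mode `"planar"` or `"greatcircle"`.
#' @return numeric vector of distances in miles.
#' @export
distance_miles <- function(a, b, mode = c("planar", "greatcircle")) {
  mode <- match.arg(mode)
  if (is.null(dim(a))) a <- matrix(a, ncol = 2)
  if (is.null(dim(b))) b <- matrix(b, ncol = 2)
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("distance_miles: coordinates must be finite")
  if (mode == "planar") {
    sqrt((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2)
  } else {
    geosphere::distHaversine(a, b) / 1609.344
  }
}

#' Build patient choice sets from market geography
#'
#' Crosses every patient with every surgeon-hospital pair and keeps pairs
#' whose hospital lies within `radius_miles` of the patient's residence.
#' With the default infinite radius this is the unrestricted roster, the
#' feasible set from which synthetic choices are simulated; estimation
#' samples are then restricted with [fixed_radius_choice_sets()] or
#' [variable_radius_choice_sets()].
#'
#' @param market a [generate_market()] result.
#' @param radius_miles inclusion radius (default `Inf`).
#' @return skeleton data frame: `patient_id`, `quarter`, `surgeon_id`,
#'   `hospital_id`, `distance`; patients left with no alternative are
#'   dropped and counted in the attached audit.
#' @export
build_choice_sets <- function(market, radius_miles = Inf) {
  stopifnot(inherits(market, "synthetic_market"))
  pairs <- merge(market$surgeon_hospitals,
                 market$hospitals[c("hospital_id", "x", "y")],
                 by = "hospital_id")
  pairs <- pairs[order(pairs$surgeon_id, pairs$hospital_id), , drop = FALSE]
  np <- nrow(market$patients)
  nA <- nrow(pairs)
  # distance of every patient to every pair's hospital
  d <- sqrt(outer(market$patients$x, pairs$x, "-")^2 +
              outer(market$patients$y, pairs$y, "-")^2)
  keep <- d <= radius_miles
  idx_p <- rep(seq_len(np), times = nA)[as.vector(keep)]
  idx_a <- rep(seq_len(nA), each = np)[as.vector(keep)]
  out <- data.frame(
    patient_id = market$patients$patient_id[idx_p],
    quarter = market$patients$quarter[idx_p],
    surgeon_id = pairs$surgeon_id[idx_a],
    hospital_id = pairs$hospital_id[idx_a],
    distance = d[keep],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$patient_id, out$surgeon_id, out$hospital_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  n_empty <- np - length(unique(out$patient_id))
  attr(out, "audit") <- list(radius_miles = radius_miles,
                             n_patients_in = np,
                             n_patients_empty = n_empty,
                             n_patients_out = np - n_empty)
  out
}

#' Assemble the long-format estimation dataset
#'
#' Joins quality-panel states (as the mutually exclusive indicator blocks
#' `high_online`/`no_online` and `high_report`/`no_report`), hospital
#' attributes (`bed_size`, `bed_size_100` = beds/100, `teaching`,
#' `cicu`), patient admission flags, and surgeon activity (`active` is
#' `FALSE` once the surgeon's exit quarter has passed) onto a choice-set
#' skeleton.
#'
#' @param sets skeleton from [build_choice_sets()] (or any data frame with
#'   `patient_id`, `quarter`, `surgeon_id`, `hospital_id`, `distance`).
#' @param panel quality panel from [build_quality_panel()]; must cover
#'   every (surgeon, quarter) referenced.
#' @param market the generating [generate_market()] object (source of
#'   hospital attributes and patient flags).
#' @return long-format data frame ordered by (patient, surgeon, hospital).
#' @export
assemble_long_dataset <- function(sets, panel, market) {
  key <- paste(sets$surgeon_id, sets$quarter, sep = "\r")
  pkey <- paste(panel$surgeon_id, panel$quarter, sep = "\r")
  m <- match(key, pkey)
  if (any(is.na(m)))
    stop("assemble_long_dataset: quality panel misses ",
         sum(is.na(m)), " (surgeon, quarter) cell(s)")
  out <- sets
  out$high_online <- as.integer(panel$online_state[m] == "high")
  out$no_online <- as.integer(panel$online_state[m] == "none")
  out$high_report <- as.integer(panel$report_state[m] == "high")
  out$no_report <- as.integer(panel$report_state[m] == "none")

  hm <- match(out$hospital_id, market$hospitals$hospital_id)
  if (any(is.na(hm)))
    stop("assemble_long_dataset: unknown hospital in choice sets")
  out$bed_size <- market$hospitals$bed_size[hm]
  out$bed_size_100 <- out$bed_size / 100
  out$teaching <- market$hospitals$teaching[hm]
  out$cicu <- market$hospitals$cicu[hm]

  pm <- match(out$patient_id, market$patients$patient_id)
  out$emergency <- market$patients$emergency[pm]
  out$referral <- market$patients$referral[pm]

  sm <- match(out$surgeon_id, market$surgeons$surgeon_id)
  exq <- market$surgeons$exit_quarter[sm]
  out$active <- is.na(exq) | out$quarter <= exq

  out <- out[order(out$patient_id, out$surgeon_id, out$hospital_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# drop patients listed in `bad`, preserving/merging the audit
.drop_patients <- function(data, bad, audit) {
  out <- data[!data$patient_id %in% bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "audit") <- audit
  out
}

#' Restrict choice sets to a fixed travel radius
#'
#' Drops alternatives farther than `radius_miles` from the patient, and
#' excludes patients whose realized (chosen) alternative lies beyond the
#' radius -- the standard fixed-radius market definition.  Counts of both
#' exclusions are attached as the audit.
#'
#' @param data long-format dataset; if a `chosen` column is present the
#'   realized-choice exclusion rule is applied.
#' @param radius_miles cutoff (default 50).
#' @return the restricted dataset with an exclusion audit.
#' @export
fixed_radius_choice_sets <- function(data, radius_miles = 50) {
  stopifnot("distance" %in% names(data))
  n_pat_in <- length(unique(data$patient_id))
  beyond <- character(0)
  if ("chosen" %in% names(data)) {
    ch <- data[data$chosen == 1, , drop = FALSE]
    beyond <- unique(ch$patient_id[ch$distance > radius_miles])
  }
  out <- data[data$distance <= radius_miles &
                !data$patient_id %in% beyond, , drop = FALSE]
  n_pat_out <- length(unique(out$patient_id))
  rownames(out) <- NULL
  attr(out, "audit") <- list(
    rule = "fixed_radius", radius_miles = radius_miles,
    n_patients_in = n_pat_in,
    n_patients_beyond_radius = length(beyond),
    n_patients_empty = n_pat_in - length(beyond) - n_pat_out,
    n_patients_out = n_pat_out,
    share_excluded_pct = pct_share(n_pat_in - n_pat_out, n_pat_in),
    n_rows_out = nrow(out))
  out
}

#' Market radius of each hospital
#'
#' The radius needed to encompass a coverage share (default 90%) of the
#' patients who realized surgery at the hospital: the `coverage` quantile
#' of their patient-to-hospital distances, using the linear-interpolation
#' percentile definition (R quantile type 7).
#'
#' @param data long-format dataset with a `chosen` column.
#' @param coverage quantile level in (0, 1]; 1 gives the maximum distance.
#' @return named numeric vector of radii; hospitals with no realized
#'   discharge are absent.
#' @export
hospital_market_radius <- function(data, coverage = 0.90) {
  stopifnot(all(c("chosen", "hospital_id", "distance") %in% names(data)),
            coverage > 0, coverage <= 1)
  ch <- data[data$chosen == 1, , drop = FALSE]
  if (nrow(ch) == 0) return(setNames(numeric(0), character(0)))
  vapply(split(ch$distance, ch$hospital_id), quantile, numeric(1),
         probs = coverage, type = 7, names = FALSE)
}

#' Restrict choice sets to each hospital's actual market
#'
#' Keeps a surgeon-hospital pair for a patient only when the hospital's
#' market radius (see [hospital_market_radius()]) reaches the patient's
#' residence.  Patients left with no alternative, or whose chosen
#' alternative is removed, are excluded and counted.
#'
#' @param data long-format dataset.
#' @param market_radii named radii; computed from `data` when `NULL`.
#' @param coverage passed to [hospital_market_radius()] when computing.
#' @return the restricted dataset with an exclusion audit.
#' @export
variable_radius_choice_sets <- function(data, market_radii = NULL,
                                        coverage = 0.90) {
  if (is.null(market_radii)) market_radii <- hospital_market_radius(data, coverage)
  n_pat_in <- length(unique(data$patient_id))
  rad <- market_radii[as.character(data$hospital_id)]
  keep <- !is.na(rad) & data$distance <= rad
  out <- data[keep, , drop = FALSE]
  lost_choice <- character(0)
  if ("chosen" %in% names(data)) {
    kept_choosers <- unique(out$patient_id[out$chosen == 1])
    lost_choice <- setdiff(unique(data$patient_id[data$chosen == 1]),
                           kept_choosers)
    out <- out[!out$patient_id %in% lost_choice, , drop = FALSE]
  }
  n_pat_out <- length(unique(out$patient_id))
  rownames(out) <- NULL
  attr(out, "audit") <- list(
    rule = "variable_radius", coverage = coverage,
    n_patients_in = n_pat_in,
    n_patients_chosen_outside = length(lost_choice),
    n_patients_empty = n_pat_in - length(lost_choice) - n_pat_out,
    n_patients_out = n_pat_out,
    n_rows_out = nrow(out))
  out
}

#' Apply robustness-sample filters
#'
#' Three filters mirror the usual robustness designs: `exclude_exited`
#' removes alternatives whose surgeon has exited the market (no realized
#' surgery in the patient's admission quarter nor in any later quarter of
#' the window, judged from the dataset's own chosen rows); patients whose
#' own surgeon would be removed this way cannot occur (their surgery is in
#' that quarter), but patients left with an empty set are dropped.
#' `nonemergency_only` and `nonreferral_only` drop flagged patients
#' entirely.  Patient-level filters commute.
#'
#' @param data long-format dataset with `chosen` (and `emergency`,
#'   `referral` flags as needed).
#' @param exclude_exited,nonemergency_only,nonreferral_only logical flags.
#' @return the filtered dataset with per-rule counts in the audit.
#' @export
apply_filters <- function(data, exclude_exited = FALSE,
                          nonemergency_only = FALSE,
                          nonreferral_only = FALSE) {
  n_pat_in <- length(unique(data$patient_id))
  audit <- list(rule = "filters", n_patients_in = n_pat_in)
  out <- data

  if (nonemergency_only) {
    stopifnot("emergency" %in% names(out))
    drop <- unique(out$patient_id[out$emergency == 1])
    audit$n_patients_emergency <- length(drop)
    out <- out[!out$patient_id %in% drop, , drop = FALSE]
  }
  if (nonreferral_only) {
    stopifnot("referral" %in% names(out))
    drop <- unique(out$patient_id[out$referral == 1])
    audit$n_patients_referral <- length(drop)
    out <- out[!out$patient_id %in% drop, , drop = FALSE]
  }
  if (exclude_exited) {
    stopifnot("chosen" %in% names(out))
    ch <- data[data$chosen == 1, , drop = FALSE]
    last_q <- tapply(ch$quarter, ch$surgeon_id, max)
    lq <- last_q[as.character(out$surgeon_id)]
    exited_row <- is.na(lq) | out$quarter > lq
    audit$n_rows_exited <- sum(exited_row)
    out <- out[!exited_row, , drop = FALSE]
    kept_choosers <- unique(out$patient_id[out$chosen == 1])
    bad <- setdiff(unique(out$patient_id), kept_choosers)
    audit$n_patients_lost_choice <- length(bad)
    out <- out[!out$patient_id %in% bad, , drop = FALSE]
  }

  audit$n_patients_out <- length(unique(out$patient_id))
  audit$n_rows_out <- nrow(out)
  rownames(out) <- NULL
  attr(out, "audit") <- audit
  out
}
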