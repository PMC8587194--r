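# Geographic choice sets, market radii, filters, dataset assembly.

test_that("planar and great-circle distances are correct", {
  expect_equal(distance_miles(c(2, 3), c(2, 3)), 0)
  expect_equal(distance_miles(c(0, 0), c(3, 4)), 5)
  # dual-formula oracle: haversine vs an independently coded spherical law
  # of cosines, on a few city-scale lon/lat pairs
  slc <- function(a, b) {
    r <- pi / 180
    d <- acos(sin(a[2] * r) * sin(b[2] * r) +
                cos(a[2] * r) * cos(b[2] * r) * cos((b[1] - a[1]) * r))
    d * 6378137 / 1609.344
  }
  pairs <- list(list(c(-75.16, 39.95), c(-79.99, 40.44)),
                list(c(-76.88, 40.27), c(-75.16, 39.95)),
                list(c(-80.0, 42.1), c(-75.5, 41.4)))
  for (p in pairs) {
    hv <- distance_miles(p[[1]], p[[2]], mode = "greatcircle")
    expect_equal(hv, slc(p[[1]], p[[2]]), tolerance = 1e-3)
  }
  expect_error(distance_miles(c(NA, 1), c(0, 0)), "finite")
})

test_that("fixed-radius restriction drops far alternatives and far choosers", {
  d <- data.frame(
    patient_id = rep(c("P1", "P2"), each = 2),
    surgeon_id = rep(c("S1", "S2"), 2),
    hospital_id = "H1", quarter = 1L,
    distance = c(10, 60, 20, 30),
    chosen = c(0L, 1L, 1L, 0L))
  out <- fixed_radius_choice_sets(d, 50)
  # P1 chose at 60 miles -> excluded entirely; P2 keeps both alternatives
  expect_setequal(unique(out$patient_id), "P2")
  a <- exclusion_audit(out)
  expect_equal(a$n_patients_beyond_radius, 1)
  expect_equal(a$share_excluded_pct, 50)
  # infinite radius is the identity
  inf <- fixed_radius_choice_sets(d, Inf)
  expect_equal(nrow(inf), nrow(d))
  expect_equal(exclusion_audit(inf)$n_patients_out, 2)
})

test_that("market radius follows the linear-interpolation percentile", {
  d <- data.frame(patient_id = sprintf("P%02d", 1:10),
                  surgeon_id = "S1", hospital_id = "H1", quarter = 1L,
                  distance = 1:10, chosen = 1L)
  expect_equal(unname(hospital_market_radius(d, 0.90)), 9.1)
  expect_equal(unname(hospital_market_radius(d, 1.00)), 10)
  one <- d[3, ]
  expect_equal(unname(hospital_market_radius(one)), 3)
})

test_that("variable-radius sets need not nest the fixed-radius sets", {
  # H1's realized patients are all nearby -> small market; H2's are spread
  # far -> market wider than 50 miles
  hist <- data.frame(
    patient_id = sprintf("P%02d", 1:8),
    surgeon_id = rep(c("S1", "S2"), each = 4),
    hospital_id = rep(c("H1", "H2"), each = 4),
    quarter = 1L,
    distance = c(2, 3, 4, 5, 55, 60, 65, 70),
    chosen = 1L)
  radii <- hospital_market_radius(hist, 1.0)
  target <- data.frame(
    patient_id = "P99",
    surgeon_id = c("S1", "S2"), hospital_id = c("H1", "H2"),
    quarter = 1L, distance = c(20, 60))
  vr <- variable_radius_choice_sets(target, radii)
  fx <- fixed_radius_choice_sets(target, 50)
  # the 20-mile pair is inside the 50-mile circle but outside H1's market;
  # the 60-mile pair is outside the circle but inside H2's market
  expect_setequal(vr$hospital_id, "H2")
  expect_setequal(fx$hospital_id, "H1")
})

test_that("a patient outside every market is excluded and counted", {
  hist <- data.frame(patient_id = "P01", surgeon_id = "S1",
                     hospital_id = "H1", quarter = 1L, distance = 5,
                     chosen = 1L)
  far <- data.frame(patient_id = "P02", surgeon_id = "S1",
                    hospital_id = "H1", quarter = 1L, distance = 40,
                    chosen = 1L)
  out <- variable_radius_choice_sets(far, hospital_market_radius(hist, 0.9))
  expect_equal(nrow(out), 0)
  expect_equal(exclusion_audit(out)$n_patients_out, 0)
})

test_that("filters drop what they say and nothing else", {
  st <- make_study(n_patients = 300, seed = 31, attrition_share = 0.4)
  est <- st$est

  # no flags -> identity
  id <- apply_filters(est)
  expect_equal(nrow(id), nrow(est))

  # nonemergency drops exactly the flagged patients
  ne <- apply_filters(est, nonemergency_only = TRUE)
  flagged <- unique(est$patient_id[est$emergency == 1])
  expect_equal(exclusion_audit(ne)$n_patients_emergency, length(flagged))
  expect_setequal(unique(ne$patient_id),
                  setdiff(unique(est$patient_id), flagged))
  expect_true(all(ne$emergency == 0))

  # patient-level filters commute
  ab <- apply_filters(apply_filters(est, nonemergency_only = TRUE),
                      nonreferral_only = TRUE)
  ba <- apply_filters(apply_filters(est, nonreferral_only = TRUE),
                      nonemergency_only = TRUE)
  expect_equal(ab[order(ab$patient_id, ab$surgeon_id, ab$hospital_id),
                  names(ab)],
               ba[order(ba$patient_id, ba$surgeon_id, ba$hospital_id),
                  names(ab)],
               ignore_attr = TRUE)
})

test_that("the attrition filter removes exited surgeons from later quarters", {
  # surgeon S2's last realized surgery is in quarter 20
  d <- data.frame(
    patient_id = rep(c("P1", "P2", "P3"), each = 2),
    surgeon_id = rep(c("S1", "S2"), 3),
    hospital_id = "H1",
    quarter = rep(c(18L, 20L, 25L), each = 2),
    distance = 5,
    chosen = c(1L, 0L, 0L, 1L, 1L, 0L))
  out <- apply_filters(d, exclude_exited = TRUE)
  # P3 admitted in quarter 25: S2 performed no surgery in or after 25
  expect_false(any(out$surgeon_id == "S2" & out$quarter == 25))
  # S2 stays in P1's and P2's sets (still operating then)
  expect_true(any(out$surgeon_id == "S2" & out$quarter == 20))
  expect_true(any(out$surgeon_id == "S2" & out$quarter == 18))
  expect_equal(exclusion_audit(out)$n_rows_exited, 1)
})

test_that("assembly produces one row per alternative with exclusive indicators", {
  st <- make_study(n_patients = 40, seed = 13)
  long <- st$data
  # counting: one chosen row per patient
  expect_equal(sum(long$chosen), length(unique(long$patient_id)))
  # indicator exclusivity for both information blocks
  expect_true(all(long$high_online + long$no_online <= 1))
  expect_true(all(long$high_report + long$no_report <= 1))
  # unreviewed surgeon rows carry high = 0, none = 1
  panel <- st$panel
  none_cells <- panel[panel$online_state == "none", ]
  key <- paste(long$surgeon_id, long$quarter)
  is_none <- key %in% paste(none_cells$surgeon_id, none_cells$quarter)
  expect_true(all(long$no_online[is_none] == 1))
  expect_true(all(long$high_online[is_none] == 0))
  # states identical across hospitals for the same surgeon-quarter
  agg <- tapply(long$high_online, key, function(x) length(unique(x)))
  expect_true(all(agg == 1))
})

test_that("missing panel cells are a hard failure", {
  st <- make_study(n_patients = 20, seed = 13)
  short_panel <- st$panel[st$panel$quarter <= 10, ]
  expect_error(
    assemble_long_dataset(build_choice_sets(st$market, Inf), short_panel,
                          st$market),
    "panel misses")
})

test_that("long datasets and markets round-trip through disk bit-exactly", {
  st <- make_study(n_patients = 30, seed = 5)
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "long.csv")
  write_long_dataset(st$est, f)
  back <- read_long_dataset(f)
  expect_identical(back, st$est, ignore_attr = TRUE)
  expect_true(all(back$distance == st$est$distance))  # exact doubles

  mdir <- file.path(tmp, "market")
  write_market(st$market, mdir)
  mk2 <- read_market(mdir)
  for (nm in c("hospitals", "surgeons", "surgeon_hospitals", "patients",
               "reviews", "report_cards"))
    expect_identical(mk2[[nm]], st$market[[nm]], ignore_attr = TRUE)
  expect_identical(unclass(mk2$config), unclass(st$market$config))

  tf <- file.path(tmp, "truth.json")
  write_true_parameters(st$truth, tf)
  tr2 <- read_true_parameters(tf)
  expect_identical(tr2$mu, st$truth$mu)
  expect_identical(tr2$sigma, st$truth$sigma)
  expect_identical(tr2$fe, st$truth$fe)
})
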