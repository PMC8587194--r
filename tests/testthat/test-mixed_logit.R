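# The simulated-maximum-likelihood estimator and its oracles.

test_that("conditional choice probabilities are a stabilized softmax", {
  expect_equal(conditional_choice_prob(3.7), 1)
  expect_equal(conditional_choice_prob(c(0, log(3))), c(0.25, 0.75))
  u <- c(-1, 0.5, 2, 700)  # survives would-be overflow
  expect_equal(sum(conditional_choice_prob(u)), 1)
  expect_equal(conditional_choice_prob(u), conditional_choice_prob(u + 123))
  expect_error(conditional_choice_prob(numeric(0)), "empty")
  expect_error(conditional_choice_prob(c(1, NA)), "finite")
})

test_that("with all sigma zero the simulated loglik is the conditional logit's", {
  st <- make_study(n_patients = 120, seed = 8)
  spec <- model_spec()
  cl <- suppressMessages(fit_conditional_logit(st$est, spec,
                                               se_method = "none"))
  K <- length(spec$random)
  p0 <- list(mu = cl$mu, sigma = setNames(rep(0, K), spec$random),
             gamma = cl$gamma, fe = cl$fe)
  for (ds in list(draw_set(cl$n_patients, 64, K, method = "halton"),
                  draw_set(cl$n_patients, 33, K, method = "pseudo",
                           seed = 4))) {
    sl <- suppressMessages(simulated_loglik(p0, st$est, spec, ds))
    expect_equal(as.numeric(sl), cl$loglik, tolerance = 1e-12)
  }
})

test_that("conditional logit matches survival::clogit on a fixture", {
  skip_if_not_installed("survival")
  withr::local_package("survival")
  st <- make_study(n_patients = 200, seed = 12)
  spec <- model_spec()
  ours <- suppressMessages(fit_conditional_logit(st$est, spec))
  dd <- st$est
  dd$surgeon_id <- factor(dd$surgeon_id)
  ref <- survival::clogit(
    chosen ~ high_online + no_online + high_report + no_report + distance +
      bed_size_100 + teaching + cicu + surgeon_id + strata(patient_id),
    data = dd)
  expect_equal(ours$loglik, ref$loglik[2], tolerance = 1e-8)
  rc <- coef(ref)
  expect_equal(unname(ours$mu),
               unname(rc[c("high_online", "no_online", "high_report",
                           "no_report", "distance")]),
               tolerance = 1e-4)
  # hospital attributes are identified only through multi-hospital
  # surgeons; compare the two that are well determined in this market
  # (cicu sits on a near-flat direction here and both optimizers stop
  # at different points along it)
  expect_equal(unname(ours$gamma[c("bed_size_100", "teaching")]),
               unname(rc[c("bed_size_100", "teaching")]),
               tolerance = 1e-4)
  # SEs agree too
  expect_equal(unname(ours$se[paste0("mu.", names(ours$mu))]),
               unname(sqrt(diag(vcov(ref)))[1:5]), tolerance = 1e-3)
})

test_that("a perfectly separating covariate is rejected by name", {
  st <- make_study(n_patients = 60, seed = 14)
  d <- st$est
  d$winner <- as.numeric(d$chosen)  # equals the outcome: infinite MLE
  spec <- model_spec(random = c("high_online", "no_online", "distance"),
                     fixed = c("winner", "teaching"))
  expect_error(suppressMessages(fit_conditional_logit(d, spec)),
               "winner")
})

test_that("the quadrature oracle agrees with independent estimates", {
  # two-random-attribute fixture
  set.seed(3)
  P <- 60
  d <- make_shared_set(P, list(high_online = c(1, 0, 1, 0),
                               distance = c(2, 5, 14, 9)))
  d$high_online <- rbinom(nrow(d), 1, 0.5)  # vary sets across patients
  d$distance <- runif(nrow(d), 0, 25)
  spec <- model_spec(random = c("high_online", "distance"),
                     fixed = character(0))
  truth <- true_parameters(mu = c(high_online = 0.5, distance = -0.15),
                           sigma = c(high_online = 0.9, distance = 0.06),
                           gamma = NULL)
  d <- simulate_choices(d, truth, seed = 6)
  pars <- list(mu = truth$mu, sigma = truth$sigma)

  gh64 <- gh_loglik(pars, d, spec, 64)
  gh32 <- gh_loglik(pars, d, spec, 32)
  gh128 <- gh_loglik(pars, d, spec, 128)
  # the quadrature ladder has converged at 64 nodes
  expect_equal(gh64, gh128, tolerance = 1e-10)
  expect_equal(gh32, gh64, tolerance = 1e-8)

  sml <- as.numeric(simulated_loglik(pars, d, spec,
                                     draw_set(P, 2000, 2)))
  expect_equal(sml, gh64, tolerance = 1e-3)
  # doubling nodes moves gh far less than the simulation error
  expect_lt(abs(gh128 - gh64), abs(sml - gh64) + 1e-12)

  # second, independent oracle: brute-force pseudo Monte Carlo
  mc <- as.numeric(simulated_loglik(pars, d, spec,
                                    draw_set(P, 2e5, 2, method = "pseudo",
                                             seed = 77)))
  expect_equal(mc, gh64, tolerance = 2e-3)

  # sigma = 0 collapses the oracle to the conditional logit too
  p0 <- list(mu = truth$mu, sigma = c(high_online = 0, distance = 0))
  cl <- as.numeric(simulated_loglik(p0, d, spec, draw_set(P, 1, 2)))
  expect_equal(gh_loglik(p0, d, spec, 16), cl, tolerance = 1e-10)
})

test_that("the simulated loglik is invariant to patient order", {
  st <- make_study(n_patients = 50, seed = 26)
  spec <- model_spec(fixed = "teaching")
  pars <- list(mu = st$truth$mu, sigma = st$truth$sigma,
               gamma = c(teaching = 0.1),
               fe = st$truth$fe)
  ds <- draw_set(50, 40, 5)
  a <- simulated_loglik(pars, st$est, spec, ds)
  shuf <- st$est[rev(seq_len(nrow(st$est))), ]
  b <- simulated_loglik(pars, shuf, spec, ds)
  expect_identical(as.numeric(a), as.numeric(b))
})

test_that("the analytic score matches finite differences", {
  st <- make_study(n_patients = 40, seed = 33)
  spec <- model_spec(random = c("high_online", "no_online", "distance"),
                     fixed = c("teaching"))
  prep <- surgchoice:::.prepare_mixl(st$est, spec)
  ds <- draw_set(prep$P, 30, prep$K)
  zv <- surgchoice:::.z_vector(ds, prep$P, prep$K)
  theta <- c(0.2, 0.4, -0.2, 0.3, 0.15, 0.05, 0.1,
             rnorm(prep$nFe, 0, 0.2))
  ev <- function(th, wg) {
    K <- prep$K
    surgchoice:::mixl_eval_cpp(
      th[1:K], th[K + 1:K],
      if (prep$F > 0) th[2 * K + seq_len(prep$F)] else numeric(0),
      if (prep$nFe > 0) th[2 * K + prep$F + seq_len(prep$nFe)]
      else numeric(0),
      prep$Qt, prep$Xt, prep$feIdx, prep$patPtr, prep$chosenRow, zv,
      ds$n_draws, wg, FALSE, 1e-300)
  }
  g <- ev(theta, TRUE)$grad
  h <- 1e-6
  for (j in seq_along(theta)) {
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    fd <- (ev(tp, FALSE)$loglik - ev(tm, FALSE)$loglik) / (2 * h)
    expect_equal(g[j], fd, tolerance = 1e-5)
  }
})

test_that("mixing strictly relaxes the conditional logit", {
  st <- make_study(n_patients = 150, seed = 44)
  spec <- model_spec(random = c("no_online", "distance"),
                     fixed = c("teaching", "cicu"))
  cl <- suppressMessages(fit_conditional_logit(st$est, spec,
                                               se_method = "none"))
  mx <- suppressMessages(fit_mixed_logit(st$est, spec, draws = 100,
                                         se_method = "none"))
  expect_gte(mx$loglik, cl$loglik - 1e-6)
  expect_true(all(mx$sigma >= 0))  # reported as magnitudes
})

test_that("Halton estimates ignore the seed; pseudo estimates vary slightly", {
  st <- make_study(n_patients = 120, seed = 55)
  spec <- model_spec(random = c("no_online", "distance"),
                     fixed = c("teaching"))
  f1 <- suppressMessages(fit_mixed_logit(st$est, spec, draws = 60,
                                         seed = 1, se_method = "none"))
  f2 <- suppressMessages(fit_mixed_logit(st$est, spec, draws = 60,
                                         seed = 2, se_method = "none"))
  expect_identical(f1$coefficients, f2$coefficients)
  p1 <- suppressMessages(fit_mixed_logit(st$est, spec, draws = 60,
                                         draw_method = "pseudo", seed = 1,
                                         se_method = "none"))
  p2 <- suppressMessages(fit_mixed_logit(st$est, spec, draws = 60,
                                         draw_method = "pseudo", seed = 2,
                                         se_method = "none"))
  expect_false(identical(p1$coefficients, p2$coefficients))
  expect_equal(p1$mu, p2$mu, tolerance = 0.25)  # simulation noise only
})

test_that("duplicating every patient keeps estimates, shrinks SEs by sqrt 2", {
  st <- make_study(n_patients = 100, seed = 66)
  spec <- model_spec(random = c("no_online", "distance"),
                     fixed = c("teaching"))
  d1 <- st$est
  d2 <- d1
  d2$patient_id <- paste0(d2$patient_id, "_dup")
  dd <- rbind(d1, d2)
  P <- length(unique(d1$patient_id))
  ds1 <- draw_set(P, 80, 2)
  # duplicated patients sort right after their originals; give each copy
  # its original's draw block so the likelihood scales exactly by 2
  z2 <- ds1$z[, , rep(seq_len(P), each = 2), drop = FALSE]
  ds2 <- ds1
  ds2$z <- z2
  ds2$n_patients <- 2L * P
  f1 <- suppressMessages(fit_mixed_logit(d1, spec, draws = ds1, tol = 1e-12,
                                         se_method = "opg"))
  f2 <- suppressMessages(fit_mixed_logit(dd, spec, draws = ds2, tol = 1e-12,
                                         se_method = "opg"))
  expect_equal(f1$mu, f2$mu, tolerance = 1e-4)
  expect_equal(f2$loglik, 2 * f1$loglik, tolerance = 1e-6)
  ratio <- f2$se[paste0("mu.", spec$random)] /
    f1$se[paste0("mu.", spec$random)]
  expect_equal(unname(ratio), rep(1 / sqrt(2), 2), tolerance = 1e-3)
})

test_that("draw sets are reproducible and well-formed", {
  a <- draw_set(7, 11, 3)
  b <- draw_set(7, 11, 3)
  expect_identical(a$z, b$z)
  expect_equal(dim(a$z), c(3, 11, 7))
  expect_true(all(is.finite(a$z)))
  # Halton marginals are standard-normal-ish
  expect_equal(mean(a$z), 0, tolerance = 0.05)
  expect_equal(sd(a$z), 1, tolerance = 0.05)
  p1 <- draw_set(4, 9, 2, method = "pseudo", seed = 3)
  p2 <- draw_set(4, 9, 2, method = "pseudo", seed = 3)
  expect_identical(p1$z, p2$z)
})
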