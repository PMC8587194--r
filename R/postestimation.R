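# Derived statistics reported from a fitted choice model: heterogeneity
# shares of the coefficient distributions, willingness to travel,
# bootstrap average marginal effects, the baseline choice probability,
# and year-by-year marginal utilities from trend interactions.

#' Share of a normal coefficient distribution lying above zero
#'
#' For a coefficient distributed `N(mean, sd^2)`, the share of patients
#' with a positive coefficient is `pnorm(mean / sd)`.  Used to summarize
#' preference heterogeneity, e.g. the share of patients who consider a
#' missing rating better than a low one.
#'
#' @param mean estimated mean of the coefficient.
#' @param sd estimated SD; must be non-negative.  A zero SD is degenerate
#'   (everyone on one side) and is returned with a `degenerate` flag.
#' @return a `pref_share` list: `share`, `complement`, `mean`, `sd`,
#'   `degenerate`.
#' @examples
#' share_preferring(0.536, 1.015)  # 70.13% above zero
#' @export
share_preferring <- function(mean, sd) {
  stopifnot(length(mean) == 1, length(sd) == 1, is.finite(mean),
            is.finite(sd))
  if (sd < 0) stop("share_preferring: sd must be non-negative")
  if (sd == 0) {
    share <- as.numeric(mean > 0)
    degenerate <- TRUE
  } else {
    share <- pnorm(mean / sd)
    degenerate <- FALSE
  }
  structure(list(share = share, complement = 1 - share, mean = mean,
                 sd = sd, degenerate = degenerate), class = "pref_share")
}

#' @export
print.pref_share <- function(x, ...) {
  cat(sprintf(
    "%.2f%% of the coefficient distribution lies above zero (%.2f%% below)%s\n",
    100 * x$share, 100 * x$complement,
    if (x$degenerate) " [degenerate: sd = 0]" else ""))
  invisible(x)
}

#' Willingness to travel for an attribute
#'
#' Miles of extra travel the average patient accepts for a unit
#' improvement in the attribute: the negative ratio of the attribute's
#' mean coefficient to the distance mean coefficient.  A delta-method SE
#' is attached when the fit carries a covariance matrix.
#'
#' @param fit a `mixl_fit`, or a named numeric vector of mean
#'   coefficients containing `attribute` and `distance`.
#' @param attribute attribute name (e.g. `"high_online"`).
#' @param distance name of the distance coefficient.
#' @return willingness to travel in miles, with attribute `"se"` when
#'   available.
#' @export
willingness_to_travel <- function(fit, attribute, distance = "distance") {
  mu <- if (inherits(fit, "mixl_fit")) fit$mu else fit
  if (!all(c(attribute, distance) %in% names(mu)))
    stop("willingness_to_travel: need mean coefficients for `", attribute,
         "` and `", distance, "`")
  a <- mu[[attribute]]
  d <- mu[[distance]]
  if (d == 0)
    stop("willingness_to_travel: distance mean coefficient is zero")
  wtt <- -a / d
  se <- NA_real_
  if (inherits(fit, "mixl_fit") && !is.null(fit$vcov)) {
    na <- paste0("mu.", attribute)
    nd <- paste0("mu.", distance)
    if (all(c(na, nd) %in% rownames(fit$vcov))) {
      g <- c(-1 / d, a / d^2)
      V <- fit$vcov[c(na, nd), c(na, nd)]
      se <- sqrt(drop(t(g) %*% V %*% g))
    }
  }
  structure(wtt, se = se)
}

#' Baseline probability of a surgeon being chosen
#'
#' The mean over patients of one over their choice-set size: the chance a
#' uniformly picked alternative is the chosen one, the baseline against
#' which average marginal effects are expressed.
#'
#' @param data long-format dataset.
#' @return a probability in (0, 1].
#' @export
baseline_choice_probability <- function(data) {
  stopifnot(nrow(data) > 0, "patient_id" %in% names(data))
  sizes <- as.vector(table(data$patient_id))
  mean(1 / sizes)
}

# Integrated predicted probability of every row being chosen, under the
# observed covariates (p_obs) and under the attribute toggled high (p1)
# versus not high (p0), with the companion "none" dummy forced to 0 in
# both counterfactual arms.  Integration over the fitted mixing
# distribution uses a fresh Halton draw set (offset burn-in).
.predict_probs_toggle <- function(fit, data, attribute, n_draws = 1000,
                                  integrate = TRUE) {
  spec <- fit$spec
  comp_map <- c(high_online = "no_online", high_report = "no_report")
  if (!attribute %in% names(comp_map))
    stop("attribute must be one of: ",
         paste(names(comp_map), collapse = ", "))
  comp <- comp_map[[attribute]]
  if (!all(c(attribute, comp) %in% spec$random))
    stop("attribute `", attribute, "` (or its companion `", comp,
         "`) is not in the model's random block")
  prep <- .prepare_mixl(data, spec, require_chosen = FALSE)
  mu <- unname(fit$mu[spec$random])
  sigma <- unname((fit$sigma %||%
                     setNames(rep(0, prep$K), spec$random))[spec$random])
  gamma <- if (prep$F > 0) unname(fit$gamma[prep$xnames]) else numeric(0)
  if (prep$F > 0 && any(is.na(gamma)))
    stop("fit lacks coefficients for fixed column(s) of the data")
  base <- if (prep$F > 0) as.vector(prep$X %*% gamma) else rep(0, nrow(prep$d))
  fev <- fit$fe[as.character(prep$d[[spec$fe]])]
  if (any(is.na(fev))) stop("fit lacks fixed effects for some surgeons")
  base <- base + unname(fev)

  K <- prep$K
  P <- prep$P
  pid <- prep$pid
  kA <- match(attribute, spec$random)
  kC <- match(comp, spec$random)
  R <- if (integrate) n_draws else 1L
  ds <- if (integrate) draw_set(P, R, K, method = "halton", burn = 4096L)
        else NULL

  p0 <- p1 <- pobs <- numeric(nrow(prep$d))
  Q <- prep$Q
  for (r in seq_len(R)) {
    z <- if (integrate) t(ds$z[, r, , drop = TRUE]) else matrix(0, P, K)
    if (K == 1) z <- matrix(z, P, K)
    beta <- sweep(sweep(z, 2, sigma, "*"), 2, mu, "+")
    brow <- beta[pid, , drop = FALSE]
    u <- base + rowSums(Q * brow)
    um <- u - max(u)
    e <- exp(um)
    den <- rowsum(e, pid)[, 1]
    rest <- pmax(den[pid] - e, 0)  # other alternatives' mass
    bA <- brow[, kA]
    bC <- brow[, kC]
    d1 <- (1 - Q[, kA]) * bA - Q[, kC] * bC  # toggle to high, none -> 0
    d0 <- (0 - Q[, kA]) * bA - Q[, kC] * bC  # toggle to not high, none -> 0
    # own probability in logistic form: robust to extreme utility shifts
    # (a lone alternative has rest = 0 and probability 1)
    pown <- function(delta) {
      w <- rest * exp(-(um + delta))
      ifelse(rest == 0, 1, 1 / (1 + w))
    }
    pobs <- pobs + pown(0)
    p1 <- p1 + pown(d1)
    p0 <- p0 + pown(d0)
  }
  list(p_obs = pobs / R, p1 = p1 / R, p0 = p0 / R, prep = prep)
}

#' Bootstrap average marginal effect of a quality attribute
#'
#' Per replicate, one alternative is picked uniformly at random from each
#' patient's choice set; the replicate's marginal effect is the mean
#' change in that alternative's predicted choice probability when the
#' attribute is set high versus not high (the companion "no information"
#' dummy forced to 0 in both arms).  Predicted probabilities integrate
#' over the fitted mixing distribution with a fresh Halton draw set fixed
#' for the whole result (set `integrate = FALSE` to evaluate at the mean
#' coefficients instead).  The reported AME is the replicate average, in
#' percentage points.
#'
#' @param fit a `mixl_fit`.
#' @param data the long-format dataset the effect is evaluated on.
#' @param attribute `"high_online"` or `"high_report"`.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the per-patient alternative picks.
#' @param n_draws draws for the probability integration.
#' @param integrate integrate over the mixing distribution (default) or
#'   evaluate at the mean coefficients.
#' @return an `ame_result`: `ame` (percentage points), `baseline`
#'   probability, `relative` = (`ame`/100)/`baseline`, percentile CI, and
#'   the replicate values.
#' @export
ame_bootstrap <- function(fit, data, attribute, n_boot = 1000, seed = 1L,
                          n_draws = 1000, integrate = TRUE) {
  stopifnot(inherits(fit, "mixl_fit"), n_boot >= 1)
  pp <- .predict_probs_toggle(fit, data, attribute, n_draws, integrate)
  prep <- pp$prep
  starts <- prep$patPtr[-length(prep$patPtr)]
  sizes <- diff(prep$patPtr)
  diffs <- pp$p1 - pp$p0

  set.seed(seed)
  reps <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    rows <- starts + floor(runif(prep$P) * sizes) + 1
    reps[b] <- mean(diffs[rows])
  }
  ame <- mean(reps) * 100
  baseline <- baseline_choice_probability(prep$d)
  structure(list(
    attribute = attribute, ame = ame, baseline = baseline,
    relative = (ame / 100) / baseline,
    ci = quantile(reps, c(0.025, 0.975), names = FALSE) * 100,
    n_boot = n_boot, seed = seed, n_draws = n_draws,
    integrate = integrate, replicates = reps * 100),
    class = "ame_result")
}

#' @export
print.ame_result <- function(x, ...) {
  cat(sprintf(
    "AME of %s: %.4f percentage points (95%% CI %.4f to %.4f)\n",
    x$attribute, x$ame, x$ci[1], x$ci[2]))
  cat(sprintf("baseline choice probability: %.4f; relative change: %.2f%%\n",
              x$baseline, 100 * x$relative))
  invisible(x)
}

#' Year-by-year marginal utility of an attribute from a trend interaction
#'
#' For a fit estimated with an attribute-by-year-trend interaction, the
#' marginal utility in year `y` (years from the study start) is
#' `mu_main + theta_interaction * t_y`, with `t_y = y - trend_origin`.
#' SEs follow from the delta method on the fit's covariance; 95% CIs are
#' `estimate +/- 1.96 * SE`.
#'
#' @param fit a `mixl_fit` estimated with the interaction term.
#' @param attribute the attribute name.
#' @param years integer years from study start (default `0:9`).
#' @return data frame: `year`, `trend`, `effect`, `se`, `lo`, `hi`.
#' @export
year_effects <- function(fit, attribute, years = 0:9) {
  stopifnot(inherits(fit, "mixl_fit"))
  int_name <- .interaction_name(attribute)
  if (!int_name %in% names(fit$gamma))
    stop("year_effects: fit has no `", int_name, "` interaction term")
  mu_name <- paste0("mu.", attribute)
  if (!attribute %in% fit$spec$random)
    stop("year_effects: `", attribute, "` is not a random attribute")
  m <- fit$mu[[attribute]]
  th <- fit$gamma[[int_name]]
  t_y <- years - fit$spec$trend_origin
  est <- m + th * t_y
  se <- rep(NA_real_, length(years))
  if (!is.null(fit$vcov) &&
      all(c(mu_name, int_name) %in% rownames(fit$vcov))) {
    V <- fit$vcov[c(mu_name, int_name), c(mu_name, int_name)]
    se <- sqrt(V[1, 1] + t_y^2 * V[2, 2] + 2 * t_y * V[1, 2])
  }
  data.frame(year = years, trend = t_y, effect = est, se = se,
             lo = est - 1.96 * se, hi = est + 1.96 * se)
}
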