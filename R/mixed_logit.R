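# Random-coefficient (mixed) logit with surgeon fixed effects, estimated
# by simulated maximum likelihood.  The per-patient likelihood integrates
# the conditional logit probability over independent normal coefficient
# distributions; the integral is approximated by averaging over Halton or
# pseudo-random standard-normal draws (C++ core in src/mixl.cpp), with an
# exact Gauss-Hermite quadrature oracle for small models.

#' Model specification for the choice model
#'
#' @param random attributes with normally distributed random coefficients
#'   (means and SDs estimated); by default the four quality-information
#'   dummies and distance.
#' @param fixed alternative attributes with nonrandom coefficients
#'   (hospital characteristics by default).
#' @param fe column naming the surgeon identity whose alternative-specific
#'   constants (fixed effects) are estimated, first level as reference.
#' @param interactions attributes to interact with a linear year trend;
#'   the interaction coefficients are nonrandom.
#' @param trend_origin year (in years from the study start) subtracted
#'   from the trend, so the main effect is the marginal utility at this
#'   origin.  Default 0 = first study year.
#' @param quarters_per_year trend scaling: the trend value of quarter `q`
#'   is `(q - 1) / quarters_per_year - trend_origin`.
#' @return a `model_spec` list.
#' @export
model_spec <- function(random = c("high_online", "no_online", "high_report",
                                  "no_report", "distance"),
                       fixed = c("bed_size_100", "teaching", "cicu"),
                       fe = "surgeon_id", interactions = NULL,
                       trend_origin = 0, quarters_per_year = 4) {
  all_names <- c(random, fixed)
  if (anyDuplicated(all_names))
    stop("model_spec: attribute names must be disjoint across blocks")
  if (!all(interactions %in% c(random, fixed)))
    stop("model_spec: interactions must name attributes in the model")
  structure(list(random = random, fixed = fixed, fe = fe,
                 interactions = interactions, trend_origin = trend_origin,
                 quarters_per_year = quarters_per_year),
            class = "model_spec")
}

.trend_value <- function(quarter, spec) {
  (quarter - 1) / spec$quarters_per_year - spec$trend_origin
}

.interaction_name <- function(attr) paste0(attr, "_x_trend")

# append attribute-by-trend interaction columns; returns list(data, xnames)
.add_interactions <- function(data, spec) {
  xnames <- spec$fixed
  if (length(spec$interactions) > 0) {
    if (!"quarter" %in% names(data))
      stop("interactions need a `quarter` column for the year trend")
    tv <- .trend_value(data$quarter, spec)
    for (a in spec$interactions) {
      cn <- .interaction_name(a)
      data[[cn]] <- data[[a]] * tv
      xnames <- c(xnames, cn)
    }
  }
  list(data = data, xnames = xnames)
}

# order rows by patient, build matrices/indices for the likelihood core
.prepare_mixl <- function(data, spec, require_chosen = TRUE) {
  need <- c("patient_id", spec$random, spec$fixed, spec$fe)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop("data lacks column(s): ", paste(miss, collapse = ", "))
  ord <- order(data$patient_id, data[[spec$fe]],
               if ("hospital_id" %in% names(data)) data$hospital_id
               else seq_len(nrow(data)))
  d <- data[ord, , drop = FALSE]
  ai <- .add_interactions(d, spec)
  d <- ai$data
  xnames <- ai$xnames

  Q <- as.matrix(d[spec$random])
  X <- if (length(xnames) > 0) as.matrix(d[xnames])
       else matrix(0, nrow(d), 0)
  if (!all(is.finite(Q)) || !all(is.finite(X)))
    stop("covariates must be finite")

  pid_levels <- unique(d$patient_id)
  pid <- match(d$patient_id, pid_levels)
  P <- length(pid_levels)
  patPtr <- c(0L, cumsum(tabulate(pid, P)))

  chosenRow <- NULL
  if (require_chosen) {
    if (!"chosen" %in% names(d)) stop("data lacks a `chosen` column")
    ch <- which(d$chosen == 1)
    if (length(ch) != P || !identical(pid[ch], seq_len(P)))
      stop("each patient must have exactly one chosen row")
    chosenRow <- ch - 1L
  }

  fe_levels <- sort(unique(as.character(d[[spec$fe]])))
  feIdx <- match(as.character(d[[spec$fe]]), fe_levels) - 2L  # ref -> -1

  # identification: every coefficient needs within-choice-set variation.
  # Random attributes without variation are a hard error; fixed attributes
  # without variation (e.g. every hospital teaching) are dropped with a
  # message.  Collinearity among the survivors is rejected by name.
  cnts <- patPtr[-1] - patPtr[-length(patPtr)]
  within_var <- function(M) {
    means <- rowsum(M, pid) / cnts
    M - means[pid, , drop = FALSE]
  }
  demQ <- within_var(Q)
  novarQ <- apply(abs(demQ), 2, max) < 1e-10
  if (any(novarQ))
    stop("random attribute(s) with no within-choice-set variation: ",
         paste(colnames(Q)[novarQ], collapse = ", "))
  if (ncol(X) > 0) {
    novarX <- apply(abs(within_var(X)), 2, max) < 1e-10
    if (any(novarX)) {
      message("dropping fixed attribute(s) with no within-choice-set ",
              "variation: ", paste(xnames[novarX], collapse = ", "))
      X <- X[, !novarX, drop = FALSE]
      xnames <- xnames[!novarX]
    }
  }
  M <- cbind(demQ, if (ncol(X) > 0) within_var(X))
  qr_ <- qr(M)
  if (qr_$rank < ncol(M)) {
    bad <- colnames(M)[qr_$pivot[(qr_$rank + 1):ncol(M)]]
    stop("collinear covariate(s): ", paste(bad, collapse = ", "))
  }

  list(d = d, Q = Q, X = X, Qt = t(Q), Xt = t(X), xnames = xnames,
       pid = pid, pid_levels = pid_levels, P = P, patPtr = patPtr,
       chosenRow = chosenRow, fe_levels = fe_levels, feIdx = feIdx,
       K = ncol(Q), F = ncol(X), nFe = length(fe_levels) - 1L)
}

.param_names <- function(prep, spec, with_sigma = TRUE) {
  c(paste0("mu.", spec$random),
    if (with_sigma) paste0("sd.", spec$random),
    prep$xnames,
    if (prep$nFe > 0) paste0("fe.", prep$fe_levels[-1]))
}

# split a params list into the vectors the C++ core expects
.coerce_params <- function(params, prep, spec) {
  mu <- params$mu[spec$random]
  if (any(is.na(mu))) stop("params$mu must name every random attribute")
  sigma <- if (is.null(params$sigma)) setNames(rep(0, prep$K), spec$random)
           else params$sigma[spec$random]
  if (any(is.na(sigma))) stop("params$sigma must name every random attribute")
  gamma <- if (prep$F > 0) params$gamma[prep$xnames] else numeric(0)
  if (prep$F > 0 && any(is.na(gamma)))
    stop("params$gamma must name every fixed attribute (including ",
         "interaction terms)")
  fe <- rep(0, prep$nFe)
  if (!is.null(params$fe) && prep$nFe > 0) {
    fef <- params$fe[prep$fe_levels]
    if (any(is.na(fef))) stop("params$fe must cover every surgeon")
    if (abs(fef[[1]]) > 1e-12)
      stop("params$fe reference surgeon (first level) must be 0")
    fe <- unname(fef[-1])
  }
  list(mu = unname(mu), sigma = unname(sigma), gamma = unname(gamma),
       fe = fe)
}

#' Standard-normal draw set for simulated likelihood
#'
#' Halton draws use one prime base per random attribute with a burn-in,
#' transformed by the normal quantile function; patient `i` uses the
#' `n_draws` consecutive sequence elements starting at
#' `burn + (i-1) * n_draws + 1`, so the draw set is reproducible from
#' `(method, seed, shape)` and independent of the seed for Halton.
#'
#' @param n_patients,n_draws,k draw-array shape (patients, draws per
#'   patient, random attributes).
#' @param method `"halton"` (default) or `"pseudo"`.
#' @param seed RNG seed (pseudo draws only).
#' @param primes Halton bases, one per attribute.
#' @param burn Halton burn-in length.
#' @return a `draw_set` whose `z` array is laid out
#'   `(attribute, draw, patient)` as consumed by the likelihood core.
#' @export
draw_set <- function(n_patients, n_draws, k,
                     method = c("halton", "pseudo"), seed = 1L,
                     primes = c(2, 3, 5, 7, 11, 13, 17), burn = 100L) {
  method <- match.arg(method)
  stopifnot(n_patients > 0, n_draws > 0, k > 0)
  if (method == "halton") {
    if (k > length(primes))
      stop("draw_set: need ", k, " distinct primes, have ", length(primes))
    z <- array(0, c(k, n_draws, n_patients))
    idx <- burn + seq_len(as.numeric(n_draws) * n_patients)
    for (kk in seq_len(k)) z[kk, , ] <- qnorm(.halton_radical(idx, primes[kk]))
  } else {
    set.seed(seed)
    z <- array(rnorm(k * n_draws * n_patients), c(k, n_draws, n_patients))
  }
  structure(list(method = method, n_draws = as.integer(n_draws),
                 n_patients = as.integer(n_patients), k = as.integer(k),
                 seed = seed, burn = burn, z = z),
            class = "draw_set")
}

# radical-inverse (van der Corput) values of `idx` in the given base
.halton_radical <- function(idx, base) {
  h <- numeric(length(idx))
  f <- 1 / base
  ix <- idx
  while (any(ix > 0)) {
    h <- h + (ix %% base) * f
    ix <- ix %/% base
    f <- f / base
  }
  h
}

# slice a draw set's z for the first P patients, flattened for the core
.z_vector <- function(draws, P, K) {
  if (!inherits(draws, "draw_set")) stop("draws must be a draw_set")
  if (draws$k != K)
    stop("draw set has ", draws$k, " attribute dimensions, model needs ", K)
  if (draws$n_patients < P)
    stop("draw set covers ", draws$n_patients, " patients, data has ", P)
  z <- if (draws$n_patients == P) draws$z
       else draws$z[, , seq_len(P), drop = FALSE]
  as.vector(z)
}

#' Conditional (logit) choice probabilities over one choice set
#'
#' Numerically stabilized softmax: subtracts the maximum utility before
#' exponentiating, so a constant added to all utilities leaves the
#' probabilities unchanged.
#'
#' @param utilities finite numeric vector of alternative utilities.
#' @return probability vector summing to 1.
#' @export
conditional_choice_prob <- function(utilities) {
  if (length(utilities) == 0)
    stop("conditional_choice_prob: empty choice set")
  if (!all(is.finite(utilities)))
    stop("conditional_choice_prob: utilities must be finite")
  e <- exp(utilities - max(utilities))
  e / sum(e)
}

#' Simulated log-likelihood of the mixed logit
#'
#' `sum_i log( (1/R) sum_r P_i(chosen | beta_ir) )` where
#' `beta_ir = mu + sigma * z_ir` and the fixed coefficients and surgeon
#' effects enter every draw identically.  With all `sigma = 0` this
#' equals the plain conditional-logit log-likelihood for any draw set.
#'
#' @param params list with named vectors `mu`, `sigma` (over the random
#'   attributes), `gamma` (fixed attributes, including any interaction
#'   columns), and optionally `fe` (all surgeons, reference first at 0).
#' @param data long-format dataset with a `chosen` column.
#' @param spec a [model_spec()].
#' @param draws a [draw_set()] covering the data's patients.
#' @param prob_floor simulated probabilities below this are floored before
#'   the log; the floored count is attached as attribute `n_floor`.
#' @return the log-likelihood (scalar).
#' @export
simulated_loglik <- function(params, data, spec = model_spec(), draws,
                             prob_floor = 1e-300) {
  prep <- .prepare_mixl(data, spec)
  pv <- .coerce_params(params, prep, spec)
  zv <- .z_vector(draws, prep$P, prep$K)
  res <- mixl_eval_cpp(pv$mu, pv$sigma, pv$gamma, pv$fe, prep$Qt, prep$Xt,
                       prep$feIdx, prep$patPtr, prep$chosenRow, zv,
                       draws$n_draws, FALSE, FALSE, prob_floor)
  if (res$n_floor > 0)
    warning("simulated_loglik: ", res$n_floor,
            " patient probabilities floored at ", prob_floor)
  structure(res$loglik, n_floor = res$n_floor)
}

#' Gauss-Hermite quadrature log-likelihood (oracle)
#'
#' Deterministic tensor-product quadrature of the mixture integral,
#' limited to models with at most two random attributes.  Implemented in
#' plain R, independently of the simulated-likelihood core, to serve as
#' its oracle on small instances.
#'
#' @inheritParams simulated_loglik
#' @param n_nodes quadrature nodes per dimension.
#' @return the log-likelihood (scalar).
#' @export
gh_loglik <- function(params, data, spec = model_spec(), n_nodes = 64) {
  if (length(spec$random) > 2)
    stop("gh_loglik: oracle supports at most two random attributes")
  d <- data[order(data$patient_id), , drop = FALSE]
  ai <- .add_interactions(d, spec)
  d <- ai$data
  Q <- as.matrix(d[spec$random])
  X <- if (length(ai$xnames) > 0) as.matrix(d[ai$xnames])
       else matrix(0, nrow(d), 0)
  mu <- unname(params$mu[spec$random])
  sigma <- if (is.null(params$sigma)) rep(0, ncol(Q))
           else unname(params$sigma[spec$random])
  gamma <- if (ncol(X) > 0) unname(params$gamma[ai$xnames]) else numeric(0)
  stopifnot(!any(is.na(mu)), !any(is.na(sigma)), !any(is.na(gamma)))
  base <- if (ncol(X) > 0) as.vector(X %*% gamma) else rep(0, nrow(d))
  if (!is.null(params$fe)) {
    fev <- params$fe[as.character(d[[spec$fe]])]
    if (any(is.na(fev))) stop("gh_loglik: params$fe must cover every surgeon")
    base <- base + unname(fev)
  }
  pid <- match(d$patient_id, unique(d$patient_id))
  chosen <- d$chosen == 1
  P <- max(pid)

  gh <- pracma::gaussHermite(n_nodes)
  K <- ncol(Q)
  if (K == 1) {
    nodes <- matrix(gh$x, ncol = 1)
    wts <- gh$w / sqrt(pi)
  } else {
    g <- expand.grid(a = seq_len(n_nodes), b = seq_len(n_nodes))
    nodes <- cbind(gh$x[g$a], gh$x[g$b])
    wts <- gh$w[g$a] * gh$w[g$b] / pi
  }

  prob <- numeric(P)
  for (t in seq_len(nrow(nodes))) {
    coef <- mu + sqrt(2) * sigma * nodes[t, ]
    u <- base + as.vector(Q %*% coef)
    mx <- stats::ave(u, pid, FUN = max)
    e <- exp(u - mx)
    den <- stats::ave(e, pid, FUN = sum)
    prob <- prob + wts[t] * (e / den)[chosen]
  }
  sum(log(prob))
}

# shared quasi-Newton driver over the C++ evaluator; `free` masks theta
.mixl_optim <- function(prep, theta0, zvec, n_draws, sigma_mask,
                        max_iter, tol, prob_floor) {
  K <- prep$K
  split_theta <- function(theta) {
    list(mu = theta[seq_len(K)],
         sigma = if (sigma_mask) theta[K + seq_len(K)] else rep(0, K),
         gamma = if (prep$F > 0)
           theta[(if (sigma_mask) 2 * K else K) + seq_len(prep$F)]
           else numeric(0),
         fe = if (prep$nFe > 0) theta[length(theta) - prep$nFe +
                                        seq_len(prep$nFe)]
              else numeric(0))
  }
  grad_sel <- c(seq_len(K), if (sigma_mask) K + seq_len(K),
                2 * K + seq_len(prep$F + prep$nFe))
  cache <- new.env(parent = emptyenv())
  evalf <- function(theta, want_grad) {
    key <- if (want_grad) "g" else "f"
    if (!is.null(cache$theta) && identical(theta, cache$theta) &&
        (!want_grad || !is.null(cache$grad)))
      return(invisible(NULL))
    pv <- split_theta(theta)
    res <- mixl_eval_cpp(pv$mu, pv$sigma, pv$gamma, pv$fe, prep$Qt, prep$Xt,
                         prep$feIdx, prep$patPtr, prep$chosenRow, zvec,
                         n_draws, want_grad, FALSE, prob_floor)
    cache$theta <- theta
    cache$ll <- res$loglik
    cache$grad <- if (want_grad) res$grad[grad_sel] else NULL
    cache$n_floor <- res$n_floor
    invisible(NULL)
  }
  fn <- function(theta) { evalf(theta, FALSE); -cache$ll }
  gr <- function(theta) { evalf(theta, TRUE); -cache$grad }
  opt <- stats::optim(theta0, fn, gr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = tol))
  evalf(opt$par, TRUE)
  list(opt = opt, theta = opt$par, loglik = -opt$value,
       grad = cache$grad, n_floor = cache$n_floor,
       split_theta = split_theta,
       gradfun = function(theta) { evalf(theta, TRUE); cache$grad },
       scorefun = function(theta) {
         pv <- split_theta(theta)
         res <- mixl_eval_cpp(pv$mu, pv$sigma, pv$gamma, pv$fe, prep$Qt,
                              prep$Xt, prep$feIdx, prep$patPtr,
                              prep$chosenRow, zvec, n_draws, TRUE, TRUE,
                              prob_floor)
         res$scores[, grad_sel, drop = FALSE]
       })
}

# finite differences of an analytic gradient; central (2p evaluations) or
# forward (p+1, adequate for standard errors)
.hessian_from_grad <- function(gradfun, theta, h_rel = 1e-5,
                               diff = c("central", "forward")) {
  diff <- match.arg(diff)
  p <- length(theta)
  H <- matrix(0, p, p)
  h <- h_rel * pmax(1, abs(theta))
  g0 <- if (diff == "forward") gradfun(theta)
  for (j in seq_len(p)) {
    tp <- theta; tp[j] <- tp[j] + h[j]
    if (diff == "central") {
      tm <- theta; tm[j] <- tm[j] - h[j]
      H[, j] <- (gradfun(tp) - gradfun(tm)) / (2 * h[j])
    } else {
      H[, j] <- (gradfun(tp) - g0) / h[j]
    }
  }
  (H + t(H)) / 2
}

.safe_solve <- function(A) {
  tryCatch(solve(A), error = function(e) MASS::ginv(A))
}

.build_fit <- function(run, prep, spec, with_sigma, se_method, extra,
                       hessian_diff = "central") {
  theta <- run$theta
  pn <- .param_names(prep, spec, with_sigma = with_sigma)
  names(theta) <- pn
  K <- prep$K

  vcov <- NULL
  if (se_method == "hessian") {
    H <- .hessian_from_grad(run$gradfun, unname(theta), diff = hessian_diff)
    vcov <- .safe_solve(-H)
  } else if (se_method == "opg") {
    S <- run$scorefun(unname(theta))
    vcov <- .safe_solve(crossprod(S))
  }
  if (with_sigma) {
    # report |sigma|; flip vcov rows/cols where the raw draw-scale was
    # negative so covariances refer to the reported magnitude
    sg <- sign(theta[K + seq_len(K)])
    sg[sg == 0] <- 1
    flip <- rep(1, length(theta))
    flip[K + seq_len(K)] <- sg
    theta[K + seq_len(K)] <- abs(theta[K + seq_len(K)])
    if (!is.null(vcov)) vcov <- vcov * (flip %o% flip)
  }
  se <- if (is.null(vcov)) setNames(rep(NA_real_, length(theta)), pn)
        else setNames(sqrt(pmax(diag(vcov), 0)), pn)
  if (!is.null(vcov)) dimnames(vcov) <- list(pn, pn)

  fe_full <- setNames(rep(0, length(prep$fe_levels)), prep$fe_levels)
  if (prep$nFe > 0)
    fe_full[prep$fe_levels[-1]] <- theta[length(theta) - prep$nFe +
                                           seq_len(prep$nFe)]

  structure(c(list(
    coefficients = theta,
    mu = setNames(theta[seq_len(K)], spec$random),
    sigma = if (with_sigma) setNames(theta[K + seq_len(K)], spec$random)
            else NULL,
    gamma = if (prep$F > 0)
      setNames(theta[(if (with_sigma) 2 * K else K) + seq_len(prep$F)],
               prep$xnames)
      else setNames(numeric(0), character(0)),
    fe = fe_full,
    se = se, vcov = vcov, loglik = run$loglik,
    converged = run$opt$convergence == 0,
    grad_max = max(abs(run$grad)),
    n_obs = nrow(prep$d), n_patients = prep$P,
    n_floor = run$n_floor, spec = spec, se_method = se_method,
    counts = run$opt$counts), extra),
    class = "mixl_fit")
}

#' Conditional logit (all coefficients fixed) by exact maximum likelihood
#'
#' Used as the warm start for [fit_mixed_logit()] and as the degenerate
#' (`sigma = 0`) oracle of the simulated likelihood.
#'
#' @param data long-format dataset with a `chosen` column.
#' @param spec a [model_spec()].
#' @param tol,max_iter optimizer control.
#' @param se_method `"hessian"` (default), `"opg"`, or `"none"`.
#' @return a `mixl_fit` with `model = "conditional_logit"` and no sigma.
#' @export
fit_conditional_logit <- function(data, spec = model_spec(), tol = 1e-10,
                                  max_iter = 500,
                                  se_method = c("hessian", "opg", "none")) {
  se_method <- match.arg(se_method)
  prep <- .prepare_mixl(data, spec)
  zvec <- rep(0, prep$P * prep$K)  # one zero draw
  theta0 <- rep(0, prep$K + prep$F + prep$nFe)
  run <- .mixl_optim(prep, theta0, zvec, 1L, sigma_mask = FALSE,
                     max_iter = max_iter, tol = tol, prob_floor = 1e-300)
  big <- abs(run$theta[seq_len(prep$K + prep$F)]) > 15
  if (any(big))
    stop("fit_conditional_logit: coefficient diverging (possible perfect ",
         "separation) for: ",
         paste(c(spec$random, prep$xnames)[big], collapse = ", "))
  .build_fit(run, prep, spec, with_sigma = FALSE, se_method = se_method,
             extra = list(model = "conditional_logit"))
}

#' Fit the mixed logit by simulated maximum likelihood
#'
#' Quasi-Newton (BFGS) maximization of [simulated_loglik()] with its
#' analytic score, warm-started from the conditional logit.  The
#' draw-scale parameters are unconstrained internally (their sign is not
#' identified since only `sigma^2` enters the mixture) and reported as
#' absolute values.  Standard errors come from the inverse of the
#' numerical Hessian (central differences of the analytic score) or from
#' the outer product of per-patient scores (`"opg"`).
#'
#' @param data long-format dataset with a `chosen` column.
#' @param spec a [model_spec()].
#' @param draws draws per patient (default 1000), or a prebuilt
#'   [draw_set()].
#' @param draw_method `"halton"` or `"pseudo"`.
#' @param seed seed for pseudo draws (Halton draws are seed-invariant).
#' @param tol,max_iter optimizer control (relative tolerance).
#' @param se_method `"hessian"` (default), `"opg"`, or `"none"`.
#' @param hessian_diff finite-difference scheme for the numerical Hessian:
#'   `"central"` (default, 2p score evaluations) or `"forward"` (p+1,
#'   cheaper, adequate for standard errors in replication studies).
#' @param start optional named start values (list with `mu`, `sigma`,
#'   `gamma`, `fe`).
#' @param sigma_start starting value for each draw-scale parameter.
#' @param prob_floor floor for simulated probabilities.
#' @return a `mixl_fit`: estimates, SEs, `vcov`, `loglik`, convergence
#'   flag, and bookkeeping (`n_obs`, `n_patients`, draw settings).
#' @export
fit_mixed_logit <- function(data, spec = model_spec(), draws = 1000,
                            draw_method = c("halton", "pseudo"), seed = 1L,
                            tol = 1e-8, max_iter = 400,
                            se_method = c("hessian", "opg", "none"),
                            hessian_diff = c("central", "forward"),
                            start = NULL, sigma_start = 0.1,
                            prob_floor = 1e-300) {
  draw_method <- match.arg(draw_method)
  se_method <- match.arg(se_method)
  prep <- .prepare_mixl(data, spec)
  ds <- if (inherits(draws, "draw_set")) draws
        else draw_set(prep$P, draws, prep$K, method = draw_method,
                      seed = seed)
  zvec <- .z_vector(ds, prep$P, prep$K)

  if (is.null(start)) {
    warm <- tryCatch(
      fit_conditional_logit(data, spec, se_method = "none"),
      error = function(e) NULL)
    theta0 <- c(if (is.null(warm)) rep(0, prep$K)
                else unname(warm$mu),
                rep(sigma_start, prep$K),
                if (is.null(warm)) rep(0, prep$F + prep$nFe)
                else unname(c(warm$gamma,
                              warm$fe[prep$fe_levels[-1]])))
  } else {
    pv <- .coerce_params(start, prep, spec)
    theta0 <- c(pv$mu, pv$sigma, pv$gamma, pv$fe)
  }

  run <- .mixl_optim(prep, theta0, zvec, ds$n_draws, sigma_mask = TRUE,
                     max_iter = max_iter, tol = tol,
                     prob_floor = prob_floor)
  .build_fit(run, prep, spec, with_sigma = TRUE, se_method = se_method,
             hessian_diff = match.arg(hessian_diff),
             extra = list(model = "mixed_logit", n_draws = ds$n_draws,
                          draw_method = ds$method, seed = seed))
}

#' Parameters of a fit in the list format used by the likelihood functions
#' @param fit a `mixl_fit`.
#' @return list with `mu`, `sigma`, `gamma`, `fe`.
#' @export
fit_params <- function(fit) {
  stopifnot(inherits(fit, "mixl_fit"))
  list(mu = fit$mu,
       sigma = fit$sigma %||% setNames(rep(0, length(fit$mu)),
                                       names(fit$mu)),
       gamma = fit$gamma, fe = fit$fe)
}

#' @export
logLik.mixl_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n_obs, class = "logLik")
}

#' @export
vcov.mixl_fit <- function(object, ...) object$vcov

#' Format a fit as a report table (mean, SE, SD, SE per random attribute)
#' @param fit a `mixl_fit`.
#' @param digits digits for rounding.
#' @return a data frame, one row per attribute.
#' @export
format_fit_table <- function(fit, digits = 3) {
  stopifnot(inherits(fit, "mixl_fit"))
  rn <- fit$spec$random
  tab <- data.frame(
    variable = rn,
    mean = round(unname(fit$mu), digits),
    mean_se = round(unname(fit$se[paste0("mu.", rn)]), digits),
    sd = if (is.null(fit$sigma)) NA_real_
         else round(unname(fit$sigma), digits),
    sd_se = if (is.null(fit$sigma)) NA_real_
            else round(unname(fit$se[paste0("sd.", rn)]), digits),
    stringsAsFactors = FALSE
  )
  if (length(fit$gamma) > 0)
    tab <- rbind(tab, data.frame(
      variable = names(fit$gamma),
      mean = round(unname(fit$gamma), digits),
      mean_se = round(unname(fit$se[names(fit$gamma)]), digits),
      sd = NA_real_, sd_se = NA_real_, stringsAsFactors = FALSE))
  tab
}

#' @export
print.mixl_fit <- function(x, ...) {
  cat(sprintf("%s fit: %d patients, %d patient-alternative rows\n",
              x$model, x$n_patients, x$n_obs))
  if (!is.null(x$n_draws))
    cat(sprintf("draws: %d (%s)\n", x$n_draws, x$draw_method))
  print(format_fit_table(x), row.names = FALSE)
  cat(sprintf("surgeon fixed effects: %d (reference %s)\n",
              length(x$fe) - 1, names(x$fe)[1]))
  cat(sprintf("log-likelihood: %.4f   converged: %s\n",
              x$loglik, x$converged))
  invisible(x)
}
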