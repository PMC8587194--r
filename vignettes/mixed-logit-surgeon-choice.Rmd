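---
title: "Modelling patient choice of surgeon from online ratings and report cards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling patient choice of surgeon from online ratings and report cards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

When a patient needs coronary artery bypass graft (CABG) surgery, two
public quality signals about candidate surgeons may be available:
crowd-sourced star ratings on physician review platforms, and state
report cards that grade each surgeon's risk-adjusted surgical mortality
as lower than, as, or greater than expected.  The two differ in kind —
one is subjective, prompt and easy to read; the other is objective,
slow and effortful to obtain — and a patient population will differ in
how much weight it places on each.

`surgchoice` models the choice of a surgeon–hospital pair with a
random-coefficient (mixed) logit.  Patient $i$'s utility for pair
$(j, k)$ at admission quarter $t$ is

$$U_{ijkt} = Q_{jkt}'\beta_i + X_{ijk}'\gamma + \lambda_k +
\varepsilon_{ijkt},$$

with $Q$ the quality-information state of the surgeon in that quarter
(four mutually referenced dummies: high online rating, no online rating
yet, high report-card score, no report-card score), $X$ the hospital
attributes (beds in hundreds, teaching status, cardiac ICU) plus travel
distance in miles, $\lambda_k$ surgeon fixed effects with one reference
surgeon pinned at zero, and $\varepsilon$ iid type-1 extreme value.
The coefficients on the quality dummies and on distance are random
across patients, $\beta_i \sim N(\mu, \mathrm{diag}(\sigma^2))$,
independent across attributes; the hospital-attribute coefficients
$\gamma$ are nonrandom (a switchable choice — the estimator accepts any
split of attributes between the random and fixed blocks).

Conditional on $\beta_i$ the choice probability over patient $i$'s
choice set is the logit softmax; the unconditional probability
integrates it over the mixing density.  The log-likelihood is maximized
by simulated maximum likelihood: the integral is replaced by an average
over $R$ draws $\beta_{ir} = \mu + \sigma \odot z_{ir}$, with the
analytic score computed alongside and a BFGS quasi-Newton update.  The
reference-card conventions for what a patient "saw" follow the
information actually available at admission:

* the running average star rating counts reviews posted **strictly
  before** the admission quarter (an inclusive variant is available by
  flag; the two differ only on same-quarter reviews);
* an average of at least 4.0 stars is a *high* online rating (the
  boundary is inclusive); an unreviewed surgeon is *none*;
* a report-card issue is effective from its publication quarter
  (inclusive) until the next issue's publication quarter (exclusive);
  *lower-than-expected* mortality is a high score, the other two
  categories pool into the reference, and surgeons unrated in the
  effective issue (below the per-issue case-volume threshold) carry the
  *no score* dummy.

All dates are integer study quarters; finer publication dates in real
data should be floored to the quarter start.

## Tunable parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `draws` | draws/patient | 1000 | simulation error of the likelihood falls as $1/\sqrt{R}$ with Halton draws performing far better than pseudo-random; 1000 is a conventional production setting, and replicate studies in the tests use 100–300 (stated below) |
| draw method | — | Halton, primes 2,3,5,7,11, burn-in 100 | low-discrepancy coverage of the 5-dimensional mixing space; estimates are seed-invariant |
| `radius_miles` | miles | 50 | the fixed-radius market definition; patients whose realized choice lies beyond it are excluded |
| `coverage` | share | 0.90 | the variable-radius definition: each hospital's market is the 90th percentile (linear-interpolation definition, R type 7) of its realized patient distances |
| `sigma_start` | coefficient scale | 0.1 | starting value of each draw-scale parameter after the conditional-logit warm start |
| `tol` | relative | 1e-8 | BFGS relative-tolerance stop |
| `trend_origin` | years | 0 | year-trend interactions use trend $(q-1)/4 - \text{origin}$, so the main effect is the marginal utility in the origin year (first study year by default) |

Standard errors come from the inverse numerical Hessian of the
simulated log-likelihood (central finite differences of the analytic
score; a forward-difference variant costs half as much and is adequate
for replication studies), or from the outer product of per-patient
scores (`"opg"`).  The draw-scale parameters enter the likelihood only
through $\sigma^2$, so their sign is unidentified; estimates are
reported as $|\hat\sigma|$.

## The synthetic market generator

`generate_market()` builds a complete synthetic study so that every
stage of the pipeline is testable without any restricted data:

* **Geography.** Patients and hospitals are placed uniformly in a
  square region (default side 120 miles), with coordinates snapped to a
  5-mile grid to emulate zip-code-level distance granularity.  Distance
  is Euclidean on these planar coordinates; real latitude/longitude
  inputs use the haversine great-circle distance.
* **Providers.** Each surgeon practices at one hospital, or at two with
  probability 0.4 (the same surgeon at two hospitals is two distinct
  alternatives sharing quality states).  A configurable share of
  surgeons exits the market mid-window and performs no surgeries after
  the exit quarter.
* **Reviews.** A per-surgeon-quarter Poisson stream (default rate 0.15,
  matching roughly one review per surgeon-year) with stars drawn iid
  from a distribution skewed high (default 0.10/0.05/0.05/0.20/0.60),
  emulating the documented under-representation of low ratings on
  review platforms.
* **Report cards.** Seven issues published at irregular quarters.  Per
  issue, each surgeon's case volume is Poisson around a surgeon-level
  mean; surgeons below 30 cases are unrated.  Rated surgeons are
  categorized by the rank of their latent mortality among that issue's
  rated set: the bottom decile (at least one surgeon) is
  lower-than-expected, the top decile greater-than-expected.  The
  surgeon-level volume means are drawn with most mass near the
  threshold (Gamma with shape 9, mean 38), so rated status genuinely
  varies across issues — with only a few dozen surgeons at desk scale,
  a more persistent rated status would be nearly collinear with the
  surgeon fixed effects and would leave the no-score coefficient weakly
  identified.
* **Choices.** Patient coefficients are drawn from the generating
  normal distributions and Gumbel shocks added by inverse-CDF sampling;
  the utility-maximizing feasible alternative is recorded as chosen.
  Simulation uses the unrestricted roster, so the 50-mile rule excludes
  a realistic share of realized choices afterwards.

Default generating coefficients carry the magnitudes typical of this
setting (e.g. a high online rating worth about 0.32 utility units with
little dispersion, a no-rating coefficient of 0.54 with SD about 1.0,
distance −0.28 per mile with SD 0.12), and the default admission-flag
shares (31.5% emergency, 30% referral) match the descriptive scale of a
statewide fee-for-service CABG population.

What the generator does **not** emulate: real zip-centroid geography,
insurance-network feasibility, review-posting selection bias (reviews
arrive independently of outcomes), or any correlation between the
random coefficients.  Passing tests therefore demonstrate correctness
of the estimator and pipeline under the stated data-generating process,
not robustness to those real-world complications.

## Numerical choices

* Softmax probabilities are stabilized by max-subtraction per choice
  set; simulated probabilities are floored at `1e-300` before logging
  (floored patients are counted and reported).
* The conditional logit (all coefficients fixed) is fitted first and
  warm-starts the mixed logit; it also serves as the exact degenerate
  case — with all $\sigma = 0$ the simulated likelihood equals the
  conditional-logit likelihood for any draw set, which the tests assert
  to 1e-10.
* A Gauss–Hermite tensor-product quadrature oracle (`gh_loglik`,
  pure R, at most two random attributes) provides a deterministic check
  of the mixture integral; at 64 nodes per dimension it agrees with the
  simulated likelihood at 2000 Halton draws to better than 1e-3
  relative error on the test fixtures.
* The analytic score is verified against central finite differences of
  the likelihood at 1e-5 relative tolerance.
* Identification guards: random attributes must vary within at least
  one choice set (error), fixed attributes that never vary within a
  choice set are dropped with a message (e.g. a market where every
  hospital has a cardiac ICU), collinear covariates and separating
  covariates are rejected by name.
* Ties in simulated utilities have probability zero; the first
  maximizing row would win.  Patients with an empty feasible set are
  dropped and counted.

## Counterfactual and reporting conventions

* The AME bootstrap toggles the selected alternative's attribute to
  *high* versus *not high* with the companion "no information" dummy
  forced to 0 in both arms (the counterfactual surgeon is rated in both
  scenarios).  Predicted probabilities integrate over the fitted mixing
  distribution with a fresh 1000-draw Halton set held fixed for the
  whole result; a point-evaluation variant at the mean coefficients is
  available by flag.  AMEs are reported in percentage points, and the
  relative effect is exactly AME divided by the baseline choice
  probability (the mean inverse choice-set size).
* Heterogeneity shares are $\Phi(\mu/\sigma)$; the degenerate
  $\sigma = 0$ case returns the 0/1 share with an explicit flag rather
  than an error.
* Willingness to travel is $-\mu_a/\mu_{distance}$ in miles with an
  optional delta-method SE.  Note this is a ratio of *means* of two
  random coefficients, a summary of the average patient rather than the
  mean of the patient-level ratio.
* Descriptive tables report binary variables in percent with the
  population-SD convention $100\sqrt{p(1-p)}$.

## Problem sizes used in the shipped tests

The replicated parameter-recovery study in the test suite simulates
markets of 5,000 patients, 12 hospitals and 20 surgeons on a 90-mile
region (about 15 alternatives per patient after the 50-mile rule), fits
with 100 Halton draws and forward-difference Hessian standard errors,
and repeats over 20 market replicates; the oracle-agreement and
degenerate-case checks run on fixtures of 60–200 patients.  These sizes
were chosen so the whole suite runs comfortably on a single CPU while
keeping the recovery study's sampling error well inside the tested
3-standard-error and 90%-coverage bands.

Two conditions of the recovery study deserve a note.  First, it runs
with surgeon attrition switched off: with attrition on, exited
surgeons' alternatives remain in the analyst's choice sets although
they can never be chosen, which is precisely the misspecification the
exit-filter robustness design addresses — a recovery study must
evaluate the estimator on model-matched data.  Second, it uses a review
arrival rate of 0.3 per surgeon-quarter, about one review per surgeon
every ten months.  A market of only 20 surgeons carries far fewer
online-state transitions than a 184-surgeon statewide sample at the
same per-surgeon rate, and because the rating states are
surgeon-persistent between transitions, too sparse a stream leaves the
online-rating coefficients weakly separated from the surgeon fixed
effects (we verified directly that the resulting finite-sample bias is
unchanged at 600 draws, i.e. it is an identification property of the
information stream, not a simulation artifact).  The denser stream
restores per-surgeon information comparable to the full-scale design.

## Known limitations

* Random coefficients are independent normals; correlated mixing and
  non-normal distributions are out of scope.
* Each patient chooses once — there is no panel structure.
* The exit-surgeon robustness filter infers exits from the dataset's
  own realized surgeries, so a surgeon with a long late-window gap in a
  small sample can be classified as exited even if active elsewhere.
* Willingness-to-travel is reported from the ratio of estimated means;
  with a heterogeneous distance coefficient, other summaries (e.g. the
  distribution of patient-level ratios) can differ substantially.
* The variable-radius market definition excludes patients whose
  realized choice falls outside every reconstructed market; the count
  is logged in the exclusion audit.
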