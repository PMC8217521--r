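---
title: "Estimating abundance of aggregated animals from per-minute resighting histories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating abundance of aggregated animals from per-minute resighting histories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbcmr)
```

## The problem

Counting animals that aggregate in turbid water is hard: individuals dive
and resurface, only part of the body shows, and at any instant many animals
are simply unavailable to be seen.  A stationary aerial camera hovering over
an aggregation site for a few minutes turns this into a tractable statistical
problem.  If individuals can be told apart within the hover — by position
and orientation rather than natural markings — then scoring each individual
as seen/not seen in each one-minute interval produces a *capture history*,
and a closed-population capture–mark–recapture (CMR) model can estimate how
many animals were present but never surfaced while the camera watched.

`bbcmr` implements that model for study designs with repeated visits to a
set of sites (for instance, winter surveys of thermal refuges), fits it by
Markov chain Monte Carlo, and ships the surrounding machinery: data
containers and file formats for the annotation exports, a synthetic survey
generator with the exact statistical structure the model assumes, derived
estimates (site and visit abundance, per-minute and cumulative detection,
survey-duration comparisons), and an exact enumeration oracle used to
validate the sampler.

## The model

For visit $v$, site $l$, minute $t$ and individual $i$:

$$
y_{v,l,t,i} \sim \mathrm{Bern}(z_{v,l,i}\, p_{v,l,t}), \qquad
p_{v,l,t} \sim \mathrm{Beta}(\alpha_v, \beta_v).
$$

Each minute draws a *single* detection probability shared by every
individual present.  Animals in a group often surface in a correlated way —
a minute that reveals one animal tends to reveal others — and sharing
$p_{v,l,t}$ within the minute is exactly what encodes that: integrating over
$p$ makes any two detection indicators in the same minute correlated with

$$
\bar p_v = \frac{\alpha_v}{\alpha_v + \beta_v}, \qquad
\rho_v = \frac{1}{\alpha_v + \beta_v + 1}.
$$

The package parameterizes each visit by the interpretable pair
$(\bar p_v, \rho_v) \in (0,1)^2$; `beta_from_mean_corr()` and
`mean_corr_from_beta()` are exact inverses of each other.  No additional
autocorrelation *across* minutes is modeled: given the hyperparameters, the
minute-level probabilities are exchangeable.

Abundance uses parameter-expanded data augmentation.  Every observed
capture history is padded with all-zero pseudo-individual rows to a fixed
cap of $A$ rows (default 100), and each row carries a latent inclusion
indicator

$$
z_{v,l,i} \sim \mathrm{Bern}(\Omega), \qquad
N_{v,l} = \sum_{i=1}^{A} z_{v,l,i}.
$$

Rows with at least one detection have $z = 1$ with certainty.  An all-zero
row is included with conditional probability
$\Omega q / (\Omega q + 1 - \Omega)$ where $q = \prod_t (1 - p_{v,l,t})$ is
the probability a present animal is never seen.  $\Omega$ is a single global
scalar shared by all site/visit combinations, matching how the augmentation
is usually written for this design; the cap $A$ must comfortably exceed any
plausible site abundance, and the fit warns whenever more than 1% of the
posterior mass of any $N_{v,l}$ sits at $A$.

Visit totals $M_v$ are computed per posterior draw as the sum of the included
sites' $N_{v,l}$ draws, so their intervals come from the joint posterior and
not from adding site-level intervals.  Sites surveyed in only some visits can
be excluded from every total to keep the totals comparable across visits
(`visit_totals(fit, exclude = ...)`).

## Priors

The model family is usually fitted with flat priors on the interpretable
scales, and that is the default here:
$\Omega \sim \mathrm{Beta}(1,1)$, $\bar p_v \sim \mathrm{Beta}(1,1)$,
$\rho_v \sim \mathrm{Beta}(1,1)$, all configurable through
`bbcmr_priors()`.  Flat priors on $(\bar p_v, \rho_v)$ are *not* flat on
$(\alpha_v, \beta_v)$; the sampler works on the interpretable scale
throughout, so what you specify is what the model uses.

## Sampling

`bbcmr()` runs a Metropolis-within-Gibbs sampler with a fixed scan order,
chosen so a run replays deterministically from its master seed (per-chain
seeds are derived from it):

1. every $p_{v,l,t}$ from its conjugate full conditional
   $\mathrm{Beta}(\alpha_v + k_t, \beta_v + s - k_t)$, where $k_t$ counts
   detections in the minute and $s$ the currently included individuals;
2. the included all-zero rows.  Because those rows are exchangeable, the
   number included per site is drawn directly as
   $\mathrm{Binomial}(A - n_{\mathrm{obs}}, c)$ with $c$ the common
   conditional inclusion probability — distributionally identical to
   flipping each row separately, and nothing downstream depends on row
   identity.  Observed rows are never touched;
3. $\Omega$ from its conjugate beta full conditional over all rows;
4. per visit, a joint random-walk Metropolis proposal on
   $(\mathrm{logit}\,\bar p_v, \mathrm{logit}\,\rho_v)$, accepted by the
   beta log density of the realized $p$'s plus priors plus the logit
   Jacobians.

The proposal scale starts at 0.4 and adapts in batches of 50 iterations
during burn-in only (Robbins–Monro on the log scale, targeting an
acceptance rate of about 0.3, with diminishing steps $1/\sqrt{\text{batch}}$);
it is frozen at the end of burn-in so the post-burn-in kernel leaves the
posterior invariant.  Defaults mirror common practice for this model family:
3 chains, 120,000 retained iterations after 60,000 burn-in, thinning 1.
At the package's problem sizes memory is trivial, so thinning exists mainly
for storage control when minute-level draws are kept.

Numerical choices worth knowing about:

* sampled $p$'s are clamped to $[10^{-12}, 1 - 10^{-12}]$ so logs stay
  finite; $q$ is accumulated as $\exp(\sum \log(1-p))$;
* a hyperparameter proposal that overflows the logit scale (a mapped value
  of exactly 0 or 1) is rejected, counted, and reported once as a warning;
* the enumeration oracle works entirely in log space with a log-sum-exp
  normalization, since ratios of beta functions underflow quickly;
* a visit surveyed for very few minutes identifies $\rho_v$ weakly; the
  sampler still runs, and the summary flags any parameter whose effective
  sample size falls below 100.

## Convergence diagnostics

`gelman_rubin()` implements the split-chain potential scale reduction
factor: each chain is halved and $\hat R = \sqrt{((n-1)W/n + B/n)/W}$ is
computed across the halves, so a single wandering chain is caught even when
the between-chain means agree.  The fit summary reports $\hat R$ and an
effective sample size (Geyer's initial positive sequence, summed over
chains) for every monitored scalar.  There is no universally agreed
threshold; the package warns at $\hat R > 1.1$ as a conventional level.
Effective sample sizes use autocorrelations up to lag 200, ample for the
mixing rates this sampler exhibits.

## The synthetic survey generator

Because annotation data of this kind are rarely deposited, the generator is
first-class, tested code rather than a fixture.  `simulate_survey()` runs
the model generatively: per visit the shapes come from
`beta_from_mean_corr()`; each (site, minute) draws one $p_t$; every
individual present is a Bernoulli draw with that shared $p_t$; individuals
never detected are recorded in the truth but absent from the observed
histories, whose labels are anonymized and shuffled so nothing can exploit
generation order.  True abundances may be fixed directly (best for recovery
experiments, and the default) or drawn through $\Omega$ and the cap $A$
(model-faithful).

`refuge_preset()` pins down a realistic study layout for a winter
aggregation survey: 4 visits over 15 site labels (12 canals, a set of
mitigation pools, a pond, and a preserve site surveyed only on the last
visit, hence excluded from visit totals), visit-level $\bar p_v$ drawn
uniformly in $[0.29, 0.54]$ and $\rho_v$ in $[0.11, 0.28]$, site/visit
abundances between 0 and 47 with one heavily used canal, structural zeros,
and pools that stay nearly empty until the final visit.  Sites with nothing
present are surveyed for 6 minutes — emulating an operator cutting the
hover short when nothing is seen — and all others for 10.

What the generator deliberately does *not* emulate: misidentification
(split or merged individuals), arrivals during the hover, minute-to-minute
autocorrelation in surfacing, or observer-specific annotation error.
Passing recovery tests on these simulations therefore demonstrates that the
implementation estimates the model it claims to estimate — not that the
model is robust to those violations in real footage.  One violation is
available as a hook: `inject_closure_violation()` lets each true individual
depart at a uniformly drawn minute with a configurable probability, erasing
its later detections, which is useful for directional robustness
experiments (departures drain detections, so estimates drop).  Arrivals are
noted as future work.

## Truncation and the duration trade-off

`truncate_minutes()` keeps the leading minutes of every history and removes
individuals first seen after the cut, exactly what re-annotating a shorter
hover would produce.  It is idempotent and can only reduce observed counts.
`compare_durations()` then compares two fits of the same survey — posterior
means, CI widths, and their aggregates — to quantify what a shorter hover
costs: with fewer minutes the cumulative detection
$p^* = 1 - \prod_t (1 - p_{v,l,t})$ drops, intervals widen, but point
estimates should move little when $p^*$ remains high.

Cumulative detection is computed from the realized per-minute draws, not
from the closed form $1 - (1-\bar p_v)^T$; the realized-$p$ definition is
what makes $p^*$ differ between sites within a visit.  (`predict()` exposes
it at any duration.)  Site-level mean detection pools minutes across visits
weighted by surveyed-minute counts — whether such a summary should pool
across visits is genuinely ambiguous, so the per-(visit, site, minute) table
is always emitted alongside and the pooled version is simply the default.

## Validation strategy

Two independent routes check the sampler.  First, with the hyperparameters
and $\Omega$ held fixed, the posterior of $N$ for a single history is
available exactly: all-zero augmented rows are exchangeable, so
`enumerate_posterior_N()` sums over the number of included pseudo-rows
$m$ with closed-form beta-binomial weights (the test suite additionally
checks this collapsed formula against a naive enumeration of all
$2^{A-n}$ inclusion configurations).  `oracle_vs_mcmc()` reports the
total-variation distance between the sampler's empirical pmf of $N$ and the
exact one.  Second, on data simulated from the model at the preset's scale,
the suite checks frequentist operating characteristics: coverage of the 95%
intervals for $N_{v,l}$, the error of the $\bar p_v$ point estimates, and
the duration trade-off direction.

The suite's experiment sizes are a deliberate compromise kept small enough
to run routinely: oracle comparisons use 200,000 retained sweeps on
instances with $A \le 10$ and $T \le 4$; the recovery experiment uses 30
replicate preset surveys fitted with 3 chains of 10,000 retained iterations
after 10,000 burn-in, at both the full and the 6-minute duration.  For real
analyses the defaults (120,000 after 60,000) are recommended.

## Edge cases and conventions

* Minutes are 1-based; detection matrices are dense 0/1 with one column per
  minute (the largest realistic size, $100 \times 10$, makes sparsity
  pointless).
* Zero-row histories (nothing observed at a declared site) are valid and
  flow through augmentation, fitting, and reporting.
* An individual annotated but never scored detected is dropped with a
  warning, counted, rather than treated as an error — annotation slips
  happen, and an all-zero observed row is not a valid capture history.
* Ragged designs are first-class: a site absent from a visit is simply not
  imputed.
* Declared durations are recommended; inferring a site's duration from its
  largest recorded minute is unsafe when nothing was detected there, and the
  package says so when it infers.
* The augmentation update rejects immediately if the cap is below the
  observed count, with a message to raise `A`.

## Limitations

Abundance and detection correlation are only weakly separated by data of
this shape.  A capture history with clumped detections can be explained
either by the true abundance with moderate detection, or by more
never-detected individuals combined with a larger $\rho_v$ and a smaller
$\bar p_v$ — and with flat priors the posterior sometimes spreads well into
the second regime even when every chain mixes cleanly ($\hat R \approx 1$).
In recovery experiments at the package's preset regime this occasionally
produces replicates whose posterior means understate $\bar p_v$ and
overstate $N$ substantially; the identical behavior is obtained when the
same data are fitted with an independent general-purpose Gibbs sampler (see
the cross-check in the test suite), so it is a property of the model and
priors, not of this implementation.  When external knowledge bounds the
surfacing correlation, an informative `bbcmr_priors(rho = ...)` is the
remedy.

The closure assumption (no movement in or out during the hover) is the
model's main vulnerability; departures bias estimates toward the observed
count side, and only the departure half of the violation is simulated.
Identification is positional, so extreme within-hover movement or
misidentification violates the individual-identity assumption in ways the
model cannot detect from the data alone.  $\Omega$ is global by default; a
per-visit inclusion probability is a straightforward extension but is not
the default because the augmentation is usually written with a single
$\Omega$.  Finally, the hierarchical posterior has no closed form — the
enumeration oracle fixes the hyperparameters, so the Metropolis step is
validated separately through its log-density arithmetic rather than by
exact enumeration.
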