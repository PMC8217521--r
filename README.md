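# bbcmr

Bayesian beta-binomial capture–mark–recapture for repeated-count surveys of
aggregated wildlife.

## What problem this solves, and for whom

Ecologists monitoring animals that gather in tight aggregations — manatees
in winter thermal refuges, hippos in pools, hauled-out pinnipeds — face a
detection problem: at any instant many individuals are submerged or hidden,
so a raw count underestimates the group. A stationary camera (for example a
drone hovering over a site for 6–10 minutes) turns the count into a
capture–mark–recapture problem: score each distinguishable individual as
seen/not seen in each one-minute interval, and estimate how many animals
were present but never surfaced.

`bbcmr` is for analysts with that kind of data: per-minute
detection/non-detection histories for each site and visit, possibly ragged
(sites surveyed only on some visits, hovers of different lengths). It
estimates site- and visit-level abundance with honest uncertainty, while
accounting for imperfect and *correlated* detection.

## The model

For visit $v$, site $l$, minute $t$, individual $i$:

$$
y_{v,l,t,i} \sim \mathrm{Bern}(z_{v,l,i}\,p_{v,l,t}),\qquad
p_{v,l,t} \sim \mathrm{Beta}(\alpha_v,\beta_v)
$$

One detection probability per minute is shared by all individuals present,
which induces a within-minute correlation among detections. The visit-level
shapes are parameterized by the mean detection probability and that
correlation:

$$
\bar p_v = \frac{\alpha_v}{\alpha_v+\beta_v},\qquad
\rho_v = \frac{1}{\alpha_v+\beta_v+1}.
$$

Abundance uses parameter-expanded data augmentation: each history is padded
with all-zero rows to $A$ rows (default 100), each row has a latent
inclusion indicator $z_{v,l,i} \sim \mathrm{Bern}(\Omega)$, and

$$
N_{v,l} = \sum_{i=1}^{A} z_{v,l,i},
$$

with visit totals $M_v$ accumulated per posterior draw across sites.
Fitting is by a Metropolis-within-Gibbs sampler (conjugate updates for the
$p$'s and $\Omega$, a joint logit-scale random walk for
$(\bar p_v, \rho_v)$), with split-chain $\hat R$ and effective-sample-size
diagnostics. An exact enumeration oracle validates the sampler on small
instances, and a synthetic survey generator reproduces the model's exact
statistical structure for recovery experiments. See the vignette
(`vignettes/beta-binomial-cmr.Rmd`) for the full methods account.

## Worked example

Simulate a two-visit survey of three sites with known truth, then fit:

```r
library(bbcmr)

sim <- simulate_survey(
  survey_design(rep(c("jan2018", "feb2019"), each = 3),
                rep(c("canal_2", "canal_7", "pond"), 2), duration = 10, A = 100),
  mean_p = c(0.29, 0.5), rho = c(0.2, 0.15),
  N = c(42, 11, 8, 35, 14, 6), seed = 11)

fit <- bbcmr(sim, A = 100, chains = 3, iter = 5000, burnin = 5000, seed = 11)
fit
#> Beta-binomial capture-mark-recapture fit
#>   2 visits, 6 site/visit combinations, A = 100
#>   3 chain(s) x 5000 retained (burn-in 5000, thin 1), seed 11
#>   inclusion probability Omega: 0.196 (0.166-0.229)
#>   visit jan2018: mean_p 0.315 (0.224-0.421), rho 0.284 (0.181-0.417)
#>   visit feb2019: mean_p 0.481 (0.408-0.554), rho 0.101 (0.048-0.183)
```

The visit-level detection parameters recover the simulating values (0.29
and 0.5 for $\bar p$). Site-level abundance, with the raw count `n_obs`
alongside the posterior mean and 95% credible interval:

```r
site_abundance(fit)
#>                    visit    site n_obs      mean q2.5 q97.5      rhat       ess
#> jan2018::canal_2 jan2018 canal_2    42 42.650000   42    45 0.9998576 12511.469
#> jan2018::canal_7 jan2018 canal_7    11 11.221000   11    13 0.9999767 10314.199
#> jan2018::pond    jan2018    pond     8  8.106733    8     9 1.0004554  9431.198
#> feb2019::canal_2 feb2019 canal_2    35 35.034600   35    36 1.0000263 14961.927
#> feb2019::canal_7 feb2019 canal_7    14 14.011200   14    14 0.9998371 13697.295
#> feb2019::pond    feb2019    pond     6  6.039333    6     7 0.9999319 11617.551

visit_totals(fit)
#>     visit count     mean q2.5 q97.5     rhat      ess
#> 1 jan2018    61 61.97773   61    65 1.000084 10653.54
#> 2 feb2019    55 55.08513   55    56 1.000062 12348.73
```

After ten minutes of observation cumulative detection is high, so the
estimates sit close to the counts — e.g. 42.7 (CI 42–45) estimated against
42 counted where the truth was 42 — while the lower-detection January visit
gets the larger upward correction. Analyzing only the first six minutes of
the same footage costs precision, not accuracy:

```r
fit6 <- bbcmr(truncate_minutes(sim$histories, 6), A = 100,
              chains = 3, iter = 5000, burnin = 5000, seed = 11)
cmp <- compare_durations(fit6, fit)
cmp$mean_abs_diff   # 0.51 animals mean shift in the point estimates
cmp$ci_width_ratio  # 2.38: 6-min credible intervals are ~2.4x wider
```

Other entry points: `read_annotations()` / `build_history_set()` for
long-format annotation CSVs, `cumulative_detection()`, `detection_means()`,
`count_vs_estimate()`, `predict()` for detection at any duration,
`plot()` for the abundance figure, `refuge_preset()` for a realistic
multi-site study simulation, `enumerate_posterior_N()` /
`oracle_vs_mcmc()` for exact validation, and `run_simulation()` /
`run_fit()` / `run_report()` (plus the thin CLI in `inst/cli/`) for
file-driven pipelines.

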