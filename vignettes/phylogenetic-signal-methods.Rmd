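---
title: "Measuring phylogenetic signal over posterior tree samples: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring phylogenetic signal over posterior tree samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treesignal)
```

Phylogenetic signal is the tendency of related species to resemble each
other more than species drawn at random from the same tree. This package
measures it for continuous and binary species traits, and — because a
Bayesian phylogenetic analysis returns a posterior *sample* of trees, not
one tree — repeats every test across that sample so the output is a
distribution of statistics and p-values rather than a single number. This
vignette explains the models, the tunable parameters, the numerical
choices, and what the simulation-based tests do and do not establish.

## The Brownian-motion backbone

All continuous-trait machinery rests on the Brownian-motion (BM) model:
a trait evolves as a random walk with rate $\sigma^2$ along the branches
of an ultrametric tree, so tip values are jointly normal with covariance

$$\operatorname{cov}(x_i, x_j) = \sigma^2 C_{ij},$$

where $C_{ij}$ is the root-to-MRCA path length shared by tips $i$ and $j$
(`tree_to_covariance()`). Trees must be ultrametric (all tips equidistant
from the root, relative tolerance $10^{-6}$ by default in
`check_ultrametric()`) because the statistics compare trait divergence
against *time available for divergence*; branch lengths are treated as
relative time, and every simulator normalises tree height to 1 so rates
($\sigma^2$, the Mk rate $q$) are per total tree depth.

## Blomberg's K

`blomberg_K()` computes

$$K \;=\; \frac{\text{observed MSE}_0/\text{MSE}}
             {\text{expected MSE}_0/\text{MSE}}
   \;=\; \frac{(x-\hat a)^{\!\top}(x-\hat a)\,\big/\,(x-\hat a)^{\!\top}C^{-1}(x-\hat a)}
             {\left[\operatorname{tr}(C) - n\big/\mathbf 1^{\!\top}C^{-1}\mathbf 1\right]/(n-1)},$$

with $\hat a$ the GLS (phylogenetically weighted) mean. K is
scale-invariant in both the trait and the covariance, equals 1 exactly on
a star phylogeny for *any* non-constant trait (both ratios reduce to the
tree height — this analytic identity is a test anchor), is near 1 on
average under BM on the true tree, below 1 when relatives resemble each
other less than BM predicts, and above 1 when they resemble each other
more. Significance comes from `K_randomization_test()`: trait values are
shuffled across tips and the one-sided add-one estimate
$p = (1 + \#\{K_{\text{perm}} \ge K_{\text{obs}}\})/(n_{\text{perm}}+1)$
is reported, so $p$ is never exactly 0 and ties count against the
observed statistic (floating-point ties within $10^{-9}$ relative are
counted as ties, which is what makes the star-tree case return exactly
$p = 1$).

Measurement error in trait means is handled by
`blomberg_K_with_SE()` with the working covariance
$V = \hat\sigma^2 C + \operatorname{diag}(\text{SE}^2)$, $\hat\sigma^2$
fit by maximum likelihood with the GLS mean profiled out, and the K ratio
evaluated under $V$. Two properties are worth knowing. With all SEs zero
the computation reduces *exactly* to the plain statistic (the code
delegates, so the reduction is bit-for-bit). And as SEs grow much larger
than the trait variance, $V$ tends to a scalar matrix, for which the K
ratio is identically 1: huge measurement error does not push K toward 0,
it collapses it onto the uninformative star value. The randomization test
in that regime compares noise in the fourth decimal and should not be
interpreted. Because each randomization refits $\hat\sigma^2$, the SE
variant costs roughly two orders of magnitude more than the plain test;
the analysis scripts therefore run the main distributions on means and
demonstrate on a subsample that small SEs move K by well under 1%.

## Pagel's lambda, continuous traits

`lambda_transform_cov()` multiplies the off-diagonal of $C$ by
$\lambda$; `lambda_transform_tree()` does the equivalent surgery on the
tree (internal branches scaled by $\lambda$, terminal branches stretched
to preserve tip depths), and the two commute with
`tree_to_covariance()` to $10^{-10}$ — a property test, because the
discrete machinery relies on the tree form. `fit_lambda_continuous()`
maximises the profile log-likelihood over $\lambda \in [0,1]$: for each
$\lambda$ the mean is the GLS mean under $C(\lambda)$ and
$\hat\sigma^2(\lambda)$ is the ML variance (divisor $n$, not $n-1$ — ML
rather than REML, the simplest likelihood that makes the subsequent LRT
internally consistent). The search domain stops at 1 because values
above 1 can break positive-definiteness; a 17-point grid pre-scan
brackets the bounded scalar search so a local optimum cannot hide the
global one, and the grid maximum is never allowed to exceed the returned
optimum by more than $10^{-6}$ log-units. The test against no signal is a
likelihood-ratio test of $\lambda = \hat\lambda$ versus $\lambda = 0$ on
one degree of freedom (`lrt_pvalue()`). When $\hat\lambda$ sits on the
boundary at 0 this plain $\chi^2_1$ tail is conservative; we use it
anyway because it is the standard reported test, and document rather than
"correct" it. On an exact star tree the likelihood is flat in $\lambda$;
the fit is then flagged `degenerate` with $\hat\lambda = 0$, $p = 1$.

## Pagel's lambda, binary traits

Binary traits use the equal-rates Mk model: a two-state continuous-time
chain with symmetric rate $q$, transition probabilities
$P(\text{stay}) = \tfrac12(1+e^{-2qt})$ over a branch of length $t$
(`mk_transition_prob()`). `mk_loglik()` evaluates the likelihood by
Felsenstein pruning — a post-order pass combining per-child partial
likelihoods, with per-node rescaling to avoid underflow — and is verified
against brute-force summation over all interior-state assignments on
trees of up to 5 tips (relative error below $10^{-10}$ on 100 random
instances). The root prior is the uniform $(\tfrac12,\tfrac12)$, which is
also the stationary distribution under symmetric rates; the source
analyses this package emulates do not state a root treatment, so the
stationary choice is ours. `fit_lambda_discrete()` maximises jointly over
$\lambda \in [0,1]$ (via the tree transform) and $q$ (log-scale, searched
in $[10^{-4}, 10^{3}]$ per unit tree height for conditioning, reported on
the original scale), seeded by a $9\times 9$ grid pre-scan, with the LRT
against the $\lambda = 0$ star tree (whose own $q$ is re-optimised).
Monomorphic traits are returned flagged rather than as errors —
$\hat\lambda = 0$, $p = 1$ — so a run over a full trait panel completes.
Note that $\hat\lambda = 1$ with $p \approx 1$ is a real and common
outcome on small species pools: the fitted value and its statistical
support are different quantities and are reported separately.

## From raw experiments to traits

Two derivation pipelines produce traits from raw records.

**Temperature tolerance** (`temperature_tolerance_trait()`): the trait is
the mean reduction in survival time under the elevated-temperature arm,
with deaths recorded at 12 h intervals up to a 96 h bound. Censored
replicates enter the mean at 96 h — a restricted-mean convention; the
design (fixed observation window, mean effect on time to death) admits no
other consistent treatment, but it is our convention and is flagged in
the trait's provenance. Species whose log-rank test
(`logrank_test()`, computed by `survival::survdiff` and verified against
direct hypergeometric tabulation) gives $p > \alpha$ are set to 0; the
default $\alpha = 0.05$ is exposed as a parameter rather than
multiplicity-adjusted.

**Feeding rates** (`adjust_feeding_records()` →
`fit_feeding_model()` → `feeding_rate_trait()`): consumption in each cup
is the start amount adjusted by the mean per-cup percent change of the
matching no-grazer controls (food × trial), minus the end amount, scaled
to per individual per 24 h. Negative values pass through to the model
stage. Rates are estimated per food by a REML mixed model — species as
fixed effect (cell means), trial as random intercept — with Satterthwaite
denominator degrees of freedom via `lmerTest` (a simpler approximation
than Kenward–Roger; for these balanced designs the difference is
immaterial and our acceptance checks are property-based, not
value-matching). Estimates whose $p \ge \alpha$ are zeroed; significant
*negative* estimates are retained with a warning, because the zeroing
rule concerns significance, not sign. `per_mg_rates()` divides by mean
dry biomass to separate size-driven from size-independent signal;
epiphyte rates live in chlorophyll units and are never converted.

One identifiability point matters for interpreting the recovery tests:
with trial a random effect, species fixed effects are estimable only up
to the realized mean trial effect of the dataset (a common offset with
standard deviation $\sigma_{\text{trial}}/\sqrt{n_{\text{trials}}}$).
Recovery is therefore assessed on centered species effects
(equivalently, species contrasts), which are exact to machine precision
when the residual noise is zero.

## Propagating phylogenetic uncertainty

`signal_over_sample()` repeats one trait × one test over every tree in a
posterior sample, pruning each tree to the trait's species first, and
summarises the per-tree statistics and p-values (mean, median, 2.5/97.5%
quantiles), keeping the raw per-tree values so any other summary is
recomputable. Each tree's randomizations get their own seed derived by a
fixed hash of (master seed, tree index), so results are independent of
execution order. Per-tree failures (e.g. a singular covariance after
pruning) are recorded with their tree index and excluded from summaries
with counts reported, never silently dropped.
`burnin_and_combine()` and `subsample_trees()` do the standard
post-MCMC bookkeeping (drop the first $b$ trees of each run, combine,
subsample uniformly *without* replacement — the without-replacement
choice is ours). `rank_traits_by_signal()` orders traits by mean p-value
(ties: mean statistic, then name); "most to least evidence" has no
canonical formalisation, and mean p is our documented choice.
`subset_analysis()` reruns everything on a species subset; with the full
pool it reproduces the full analysis exactly, and pools under 10 species
trigger a reduced-power warning.

## What the simulators emulate — and what they do not

`simulate_yule_tree()` grows a pure-birth tree forward in time (checked
against the Yule root-split law) and rescales to height 1.
`simulate_bm_trait()` draws from the exact multivariate normal
$\mathcal N(\mu \mathbf 1, \sigma^2 C(\lambda))$;
`simulate_mk_trait()` walks states down the tree.
`perturb_tree_sample()` emulates posterior uncertainty by multiplying
internal node *ages* by lognormal factors (clamped to keep parents older
than children, renormalised to height 1), optionally with a
nearest-neighbour interchange at the shallowest internal node. Jittering
ages rather than depths matters: depth jitter lets deep cherry nodes
collide with the tips, collapsing terminal branches and degenerating K;
age jitter perturbs every node in proportion to its distance from the
present. The survival simulator uses exponential death times — the
simplest hazard consistent with an interval-recorded design — rounded up
to the next 12 h mark; the feeding simulator embeds known rates, trial
effects and control drift so the adjustment step is exactly invertible in
the noise-free case.

Default study conditions follow the emulated design throughout: 16
species; 15 replicates × 3 treatment arms × 16 species = 720 survival
records; 5 feeding trials, 6–10 cups per species per food split over at
least two trials, 10 controls per food per trial; posterior bookkeeping
of 20,000/15,000/15,000-tree runs with 2,000-tree burn-ins combining to
44,000 trees, subsampled to 1,000 for analysis. Where the design is
silent we chose once: age-jitter SD 0.05 and NNI probability 0.1 for the
fixture tree sample (visible but moderate posterior spread), trial SD
0.2 and residual SD 0.5 in consumption units for the feeding fixtures.

What passing tests do *not* show: the perturbed sample has no MCMC
autocorrelation or model-based topology uncertainty; real posterior
samples disagree most exactly where the data are least informative,
which jitter does not emulate. Exponential hazards have no
age-dependence. And all Monte-Carlo acceptance bands (mean K in
$[0.85, 1.15]$ under BM at 32 tips and 200 replicates, mean
$\hat\lambda \le 0.1$ for i.i.d. traits, binomial bands on rejection
rates) quantify behaviour under the generators' assumptions, not
performance on real data.

## Problem sizes

The shipped test suite and scripts run at desk scale, chosen as the
smallest sizes at which the Monte-Carlo bands above are tight enough to
be meaningful: 32-tip trees with 200 trait replicates for the limit
checks, 199–999 randomizations per K test, 100-tree samples (50 for the
pool sensitivity stage), 100 simulated feeding datasets for the
recovery check. The full-scale analysis (1,000 trees, 1,000
randomizations) uses the same code paths; only the loop counts differ.
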