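---
title: "Two-sample MR with two-step mediation: models, defaults and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample MR with two-step mediation: models, defaults and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The problem

Two-sample Mendelian randomisation (MR) estimates the causal effect of an
exposure on an outcome from GWAS summary statistics alone: per-SNP effects
on the exposure ($\hat\beta_{Xj}, \sigma_{Xj}$) from one study and on the
outcome ($\hat\beta_{Yj}, \sigma_{Yj}$) from an independent study. The
genetic variants act as instrumental variables under the three IV
assumptions — relevance (the SNP associates with the exposure),
independence (no confounding of the SNP-outcome relation) and exclusion
restriction (no effect on the outcome except through the exposure).

`mrmediate` implements the full workflow around that idea, up to and
including **two-step MR mediation**: given an exposure, a candidate
mediator and an outcome, it estimates the total effect $\beta_c$
(exposure → outcome), the step-1 effect $\beta_a$ (exposure → mediator), the
mediator's effect adjusted for the exposure $\beta_b$ (multivariable MR),
the indirect effect $\beta_a\beta_b$ and the proportion of the total effect
that the mediator explains. The motivating application is of the
sleep-traits → depression → cardiovascular-disease type, where all traits
are measured in large biobank-scale GWAS and effects are on the log-odds
scale for binary traits, but nothing in the package is specific to those
phenotypes.

## Data model and harmonisation

Summary statistics are plain tibbles (`snp`, `chr`, `pos`, `effect_allele`,
`other_allele`, `eaf`, `beta`, `se`, `pval`, `n`), read from TSV with
remappable column names. Instruments are selected at $p < 5\times10^{-8}$
and greedily clumped (smallest $p$ first) at $r^2 < 0.01$ when an LD matrix
is available, else within a closed 1 Mb window on the same chromosome;
`strict = TRUE` switches to $r^2 < 0.001$ / 10 Mb for replication runs.
These clumping parameters are deliberate package defaults in the
conventional GWAS range — the analysis they support is robust to the exact
choice, and both regimes are exposed through `mr_settings()`.

Exclusions happen in a fixed precedence order — confounder blacklist,
missing in the outcome study, ambiguous palindrome — so that the attached
`ExclusionReport` is deterministic and each SNP is counted exactly once.
Confounder screening is a user-supplied SNP blacklist file; the package
performs no online lookups, so a run is reproducible offline.

Harmonisation aligns every study to the exposure's effect allele: matching
alleles copy, swapped alleles negate the outcome beta and reflect the
frequency, and allele pairs that match only after strand complementation
are complemented first. Palindromic SNPs (A/T, C/G) cannot be resolved from
alleles; they are resolved by effect-allele-frequency concordance and
dropped when either frequency is missing or inside the ambiguity band,
default $(0.42, 0.58)$ — the conventional "ambiguous" window. Irreconcilable
alleles drop the SNP with a flag rather than failing the run.

## Univariable estimators

With ratio weights $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$:

* **IVW** — weighted least squares of $\hat\beta_Y$ on $\hat\beta_X$
  through the origin. Fixed-effect SE $1/\sqrt{\sum w_j}$; random-effects
  uses multiplicative overdispersion, scaling the SE by
  $\max(1,\sqrt{Q/\mathrm{df}})$. The multiplicative form is the common
  two-sample-MR convention and guarantees the random SE never undercuts the
  fixed one.
* **Cochran's Q / $I^2$** — $Q=\sum_j w_j(\hat\beta_{Yj}/\hat\beta_{Xj} -
  \hat\theta)^2$, $I^2=\max(0,(Q-\mathrm{df})/Q)$. The heterogeneity
  trigger in the decision tree is the literal reading $I^2 > 25\%$
  *and* $p_Q < 0.05$.
* **MR-Egger** — the same regression with an intercept after orienting all
  SNPs to non-negative exposure effects (done internally and recorded); the
  intercept is the directional-pleiotropy test, the slope the adjusted
  effect. Requires the InSIDE assumption.
* **Weighted / penalised weighted median** — the inverse-variance-weighted
  50th percentile of the ordered Wald ratios (midpoint rule with linear
  interpolation), consistent when valid instruments carry $\ge 50\%$ of the
  weight. Ratio variances are first-order ($\sigma_Y^2/\beta_X^2$); the
  penalised variant multiplies weights by $\min(1, 20\,q_j)$ with $q_j$ the
  $\chi^2_1$ tail of each SNP's Q contribution — the established
  penalisation constant. SEs are parametric bootstrap (default 500 draws).
* **Maximum likelihood** — bivariate normal model per SNP with means
  $(\xi_j, \theta\xi_j)$; $\xi_j$ profiles out analytically, leaving a 1-d
  optimisation; SE from the observed profile information. Reduces to the
  Wald ratio at one SNP and to fixed-effect IVW as $\sigma_X \to 0$.
* **Radial IVW** — modified second-order weights
  $w_j = (\sigma^2_{Yj}/\hat\beta_{Xj}^2 +
  \hat\beta_{Yj}^2\sigma^2_{Xj}/\hat\beta_{Xj}^4)^{-1}$, acknowledging
  exposure-side noise; equals first-order IVW when $\sigma_X \to 0$.
* **IVW-SIMEX** — simulation-extrapolation against the NOME violation:
  noise $\sqrt\lambda\,\sigma_{Xj}$ is added to the exposure effects over a
  grid $\lambda\in\{0, 0.5, 1, 1.5, 2\}$ (200 inner replicates), a
  quadratic in $\lambda$ extrapolated to $\lambda=-1$, SE by nonparametric
  bootstrap over SNPs. SIMEX is most often attached to Egger; here it is
  applied to the IVW slope as named, and the same machinery applies to
  Egger via the scatter of the data, which we deliberately left out of
  scope as a separate estimator.
* **MR-PRESSO** — leave-one-out residual-sum-of-squares global test against
  a parametric null (default 1000 simulations), per-SNP outlier tests with
  Bonferroni-adjusted level applied when the global test rejects, a
  distortion test against random same-size SNP removals, and a corrected
  IVW on the retained set. The outlier p-values are raw empirical
  proportions (no $+1$ continuity term) so that a gross outlier can reach
  the Bonferroni threshold at moderate simulation counts; the global p
  keeps the $+1$ correction. The reference distribution of the original
  distortion test is not fully specified in the literature we follow, so
  the random-removal form documented above is used, fully seeded.
* **Power** — normal-approximation power for a binary outcome with
  non-centrality $\sqrt{n\,r^2_{GX}\,cf(1-cf)}\,|\log \mathrm{OR}|$.

All confidence intervals in the package are Wald-type,
$\hat\beta \pm 1.96\,\mathrm{SE}$, matching how MR consortia print them;
p-values are two-sided normal except Q (upper-tail $\chi^2$).

## Multivariable MR and QHET

`mvmr_ivw()` regresses the outcome effects on all exposures' SNP-effect
columns (no intercept, weights $1/\sigma_Y^2$), with the overdispersion
floor on SEs; `mvmr_egger()` adds the intercept after orienting SNPs to
the chosen exposure. "QHET" — named but not defined in the applied
literature this package follows — is implemented as the natural
heterogeneity-minimising estimator: it minimises
$Q(\theta)=\sum_j (\hat\beta_{Yj}-\sum_k\theta_k\hat\beta_{Xjk})^2 /
(\sigma^2_{Yj}+\sum_k\theta_k^2\sigma^2_{Xjk})$, whose denominator
propagates exposure-effect uncertainty (weak-instrument-robust weights),
from the MV-IVW start point, with nonparametric bootstrap CIs over SNPs
(default 1000 resamples, seeded). Conditional F statistics are reported as
a diagnostic but never used as a hard filter, since no threshold is part
of the design.

A design corner: an exposure column that is identically zero (the
degenerate reduction used to check MV-IVW against univariable IVW) is
dropped from the fit and reported with a zero coefficient and `NA` SE,
while genuine collinearity among non-zero columns raises an error naming
the exposures.

## Two-step mediation

The indirect effect is the product $\beta_a\beta_b$ with delta-method SE
$\sqrt{\beta_b^2 se_a^2 + \beta_a^2 se_b^2}$ — note the square root, which
reproduces published mediation CIs computed this way — Wald CI, and Sobel
test $z = \beta_a\beta_b/\mathrm{SE}$. The proportion mediated is
$100\,\beta_a\beta_b/\beta_c$ (percent) with a delta-method CI for the
ratio under independence of numerator and denominator (`"delta-ratio"`,
recorded in the output, since published tables of this kind do not state
their interval method and their proportion CIs are not recoverable from
rounded inputs). Proportions outside $[0,100]$ are legal and flagged, not
errors. SEs recovered from printed CIs use width$/3.92$ throughout.

## Decision trees and FDR tiers

The univariable primary method is chosen by pleiotropy first, then
heterogeneity: Egger intercept $p<0.05$ → MR-Egger; else $I^2>25\%$ and
$p_Q<0.05$ → random-effects IVW; else fixed-effect IVW. The multivariable
tree mirrors it with MV-Egger / QHET / MV-IVW. Both return the full rule
trace so a report can show *why* a method was used.

`run_grid()` analyses every exposure × outcome pair, controls the family of
total-effect p-values by Benjamini–Hochberg, and tiers evidence as
significant ($q<0.05$), suggestive ($p<0.05$, $q\ge0.05$) or null. The FDR
family is the whole grid of total-effect tests in one run; the Sobel tests
of the mediated pairs form a separate family. Mediation is triggered for
pairs with uncorrected $p<0.05$ on the total effect (configurable via
`mr_settings(mediation_trigger_p=)`), i.e. the significant-or-suggestive
pairs that a two-step analysis would follow up.

## The synthetic-data generator

`simulate_mediation_dag()` emulates three independent GWAS (no sample
overlap, matching a genuine two-sample design) under
exposure → mediator → outcome with a direct path. Exposure instruments
carry effects $\xi_j$; their mediator and outcome associations are
$\beta_a\xi_j$ and $(\theta_{direct}+\beta_a\beta_b)\xi_j$. A configurable
fraction of SNPs (`prop_mediator_snp`, default 0.5) instead instrument the
mediator directly with effects $\eta_j$ (outcome association
$\beta_b\eta_j$) — without them the multivariable design matrix is
collinear in expectation and the mediator coefficient is unidentified, so
a mediation DAG generator must include them, exactly as a real two-step
analysis combines the exposure's and the mediator's own instrument lists.
Standard errors are the analytic per-allele form
$1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,n}$ (tested exactly); observed
effects add independent study noise. Instrument scale is set so the mean F
statistic in the instrumented study hits `f_mean_target` (default 30 — the
"adequate power" regime). Binary-trait effects are generated directly on
the log-odds scale; summary-level fidelity is what the estimators consume,
so no liability-scale individual simulation is performed.

Pleiotropy modes: `NONE`, `BALANCED` (zero-mean) and `DIRECTIONAL`.
Pleiotropic effects are attached to the *trait-increasing* allele
orientation; with symmetric instrument signs a per-allele directional
effect would average out and silently become balanced, which is why the
orientation convention matters for testing Egger against IVW bias.

Discovery ascertainment: the exposure and mediator studies are filtered at
`selection_p` (default $5\times10^{-8}$) on their own instruments while
retaining lookup rows for the other study's instruments — mirroring how
real analyses look instruments up in full summary files. Selection induces
winner's curse (tested as $\mathbb{E}|\hat\beta_X| > \mathbb{E}|\xi|$),
which is a *feature* of the default regime; calibration suites that need
homogeneous unbiased draws disable it with `selection_p = 1`.

What the generator does **not** emulate: LD between instruments (draws are
independent, so clumping behaviour must be tested with explicit LD
matrices), sample overlap, allele-frequency differences between studies,
and liability-scale case-control ascertainment. Passing calibration on
these simulations therefore demonstrates correctness of the estimators and
plumbing under the stated model, not robustness to every artefact of real
consortium data.

## Validation regimes and numerical choices

The package's standard validation problem sizes, chosen to make
Monte-Carlo error small relative to the quantities checked:

* IVW CI coverage and null rejection: 1000 replicates of 50-SNP
  homogeneous draws at mean F 30 with selection disabled; coverage is
  expected in $[93\%, 97\%]$.
* Sobel-test calibration: 500 replicates of a zero-mediation DAG
  ($\beta_b = 0$, $\beta_a = 0.5$) at mean F 100.
* Mediation recovery: the 50%-mediated DAG
  ($\theta_{direct} = 0.1, \beta_a = 0.5, \beta_b = 0.2$) at 100 SNPs,
  studies of $10^6$ and mean F 500 — the strong-instrument, large-sample
  regime in which the proportion's delta SE is about 2.6 percentage
  points (matching its empirical SD), so recovery within $\pm 5$ points
  is a $\approx 1.9\sigma$ event per seed and the per-run recovery rate
  over 50 seeds is expected near 94% with a Monte-Carlo spread of a few
  points.

Numerical corner cases handled deliberately: two-sided p-values are clamped
at the smallest positive double so underflow at extreme z never produces a
zero that the FDR step-up (defined on $(0,1]$) would reject; Q-based $I^2$
is defined as 0 when $Q=0$; the ML optimiser errors if the optimum pins to
its search-interval boundary, naming the tolerance; QHET bootstrap SDs of
exact fits are floored at machine epsilon; Egger and MV-Egger flip SNPs
with zero exposure effect to the positive orientation.

## Known limitations

One mediator at a time (no multi-mediator decomposition or
exposure-mediator interaction); no mode-based or contamination-mixture
estimators, Steiger filtering, or bidirectional MR; no LD estimation from
genotypes, proxy search or build liftover. The proportion-mediated CI
assumes independence of the indirect and total estimates, which share
instruments in practice; treat those intervals as approximate, as their
published counterparts are.
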