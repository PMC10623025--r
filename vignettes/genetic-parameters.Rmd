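---
title: "Two-track genetic parameter estimation for dairy herds"
author: "herdgibbs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-track genetic parameter estimation for dairy herds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Breeding decisions in a dairy herd rest on three quantities: the
heritability of each economic trait, the genetic correlations among traits
(can we improve lifetime performance by selecting on something expressed
early, like age at first calving?), and the ranking of sires by estimated
breeding value. `herdgibbs` estimates all three by two parallel routes for
a zebu-type herd recording eight traits — age at first calving (AFC, days),
first service period (FSP, days), first-lactation milk / fat / solids-not-fat
yield (FLMY, FLFY, FLSNFY, kg), lifetime milk yield (LTMY, kg), productive
life (PL, days) and herd life (HL, days):

* a **frequentist half-sib track**: fixed-effect least-squares models with
  a random sire term, sire variance components by Henderson's Method III,
  heritability as four times the paternal half-sib intraclass correlation,
  and sire-component genetic/phenotypic correlations;
* a **Bayesian track**: a single- or multi-trait animal model sampled by
  Gibbs, with the pedigree numerator relationship matrix structuring the
  breeding values, inverse-Wishart full conditionals for the genetic and
  residual covariance matrices, and posterior summaries of every derived
  parameter.

Both tracks feed BLUP sire evaluation through Henderson's mixed-model
equations, and the two sire rankings are compared with a Spearman
rank-correlation t test.

## Models

### The animal model

For a trait vector $y$ ($n$ records),

$$y = X\beta + Zu + e, \qquad u \sim N(0, G_0 \otimes A), \qquad
  e \sim N(0, R_0 \otimes I_n),$$

where $X$ carries the fixed effects, $Z$ maps records to the $q$ animals of
the *full* pedigree, $A$ is the numerator relationship matrix and $G_0$,
$R_0$ are the $t \times t$ genetic and residual covariance matrices.
Heritability per trait is $h^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_e)$;
the genetic correlation for a pair is
$r_g = \mathrm{cov}_g / \sqrt{\sigma^2_{g,1}\sigma^2_{g,2}}$ and the
phenotypic one comes from $P_0 = G_0 + R_0$.

Fixed-effect templates follow the herd's recording rules. Calendar months
map to four seasons (summer April–June, rainy July–September, autumn
October–November, winter December–March); years are grouped in five-year
periods (six calving periods from 1990, seven birth periods from 1986, the
final class absorbing the overhang); and AFC enters every model as a linear
covariate except when AFC itself is the response (its model uses birth-basis
period and season and no covariate). The AFC covariate is additionally
binned into Sturges classes, $k = \mathrm{round}(1 + 3.322\log_{10}n)$
($k = 11$ at $n = 964$), for reporting only — the fitted models use the
linear covariate, which is what the model equations specify. The printed
form of the Sturges rule in the source material garbles the formula
(dividing the range by the class count is the class *width*); we implement
the standard class count, which reproduces the eleven classes.

### Pedigree machinery

`renumber_pedigree()` assigns consecutive codes with every parent before
its offspring (ties broken by first appearance, so output is deterministic),
adds animals referenced only as parents, and rejects cycles and identifiers
used as both sire and dam. `build_relationship_matrix()` is the tabular
method; `build_A_inverse()` applies Henderson's rules directly, by default
with inbreeding in the Mendelian-sampling variances
($\delta_i = 1/(0.5 - 0.25(F_s + F_d))$, a missing parent contributing
$F = -1$). Whether the emulated software runs accounted for inbreeding is
not documented; both modes are supported and the flag is recorded on the
returned matrix. Unknown parents are treated as unrelated base animals — no
unknown-parent groups.

### The Gibbs sampler

Location effects are sampled single-site (a Gauss–Seidel sweep over the
mixed-model equations): each fixed-effect coefficient and each animal's
breeding value, trait by trait, from its scalar normal full conditional
given the current $G_0$, $R_0$. Then

$$G_0 \mid u \sim \mathrm{IW}(S_g + U' A^{-1} U,\ \nu_g + q), \qquad
  R_0 \mid e \sim \mathrm{IW}(S_r + E'E,\ \nu_r + n).$$

Block updating of location effects is deliberately out of scope — the
single-site sweep is what the reference implementations of this model
family use, and it keeps the per-iteration cost linear in the number of
equations. The sweep is implemented in compiled code (RcppArmadillo) with
all randomness drawn from R's RNG, so `set.seed()` makes chains
bit-identical.

Defaults, all tunable through `chain_config()` and `prior_spec()`:

* chain: 30,000 iterations, 1,000 burn-in, thinning 10 — 2,900 stored
  draws (`floor((total - burn_in)/thin)`);
* prior: weakly informative inverse-Wishart, $\nu = t + 2$ and scale
  $(\nu - t - 1)\,\mathrm{diag}$(half the phenotypic variances), so the
  prior mean sits at half the observed phenotypic (co)variance — the
  "initial mean values as prior" idea made concrete. A flat-prior mode
  exists but warns, since the posterior is then proper only when the data
  dominate;
* starting values: $G_0 = R_0 = $ half the phenotypic covariance;
* guard rails: the chain aborts with the iteration index if a conditional
  covariance loses positive definiteness or a sampled variance exceeds
  $10^{12}$ times its starting value (divergence);
* missing data: a multi-trait run uses the complete cases of its trait
  set; there is no data augmentation. This mirrors how the emulated
  analyses dropped a non-converging trait (LTMY) rather than impute.

### Post-Gibbs summaries

`summarize_chain()` reports mean, mode, median, SD ($N-1$ denominator),
the shortest 95% HPD interval, effective sample size, Monte-Carlo error
and the Geweke diagnostic. Numerical choices, made where the emulated
tools do not document theirs:

* **HPD**: exact shortest window over the sorted draws (ties resolved to
  the lowest lower bound) — verified in the tests against a brute-force
  enumeration of all order-statistic pairs;
* **mode**: midpoint of the modal bin of a Freedman–Diaconis histogram.
  Any histogram mode is binning-sensitive; with the FD rule the bin width
  shrinks as $n^{-1/3}$, and for the 2,900-draw default the mode moves by
  less than the Monte-Carlo error when the bin count is halved or doubled;
* **ESS**: Geyer's initial monotone sequence truncation of the
  autocovariance sum, capped at $N$; a zero-variance chain returns $N$
  with a warning;
* **MCE**: defined as $\mathrm{SD}/\sqrt{\mathrm{ESS}}$ — the SD-scaled
  convention, which is the convention behind the reported "±" values on
  posterior means in this literature. Both SD and MCE are emitted so
  either reading is available;
* **Geweke**: $z$ test of equal means between the first 10% and last 50%
  of the chain, window variances by overlapping batch means with batch
  length $\approx\sqrt{n_{window}}$. The batch-means estimator has finite
  degrees of freedom, so the nominal 5% rate is only approached on long
  chains; the calibration test uses 6,000-draw chains, where the empirical
  rate sits inside [3%, 7%].

`derive_parameters()` applies the $h^2$, $r_g$, $r_p$, $\sigma^2_p$
transforms draw by draw (so posterior means of derived parameters are means
of ratios, not ratios of means — both conventions are recoverable from the
emitted chains) and excludes indefinite draws with a count; draws on the
PSD boundary are kept, so a degenerate perfectly-correlated pair yields
$r_g = 1$ rather than an exclusion.

### Frequentist track

The analysis model the half-sib track fits is fixed effects plus a random
sire; the historical "Model 8" internals are not documented in the source
material, so the package uses the textbook form of that estimator family:
Henderson's Method III. $\sigma^2_e$ comes from the full-model residual
mean square; $\sigma^2_s$ from the reduction $R(\mathrm{sire}\mid
\mathrm{fixed})$ equated to its expectation ($\hat\sigma^2_s$ can be
negative; it is truncated at zero for derived statistics with the raw value
and a flag retained). Heritability is $h^2 = 4t$ with Swiger's large-sample
standard error; trait-pair sire and residual covariances use the analogous
cross-product forms on common records, and correlations outside $[-1, 1]$
(possible with Method III) are clipped for reporting with the raw value
logged. Type III F tests and population-marginal least-squares means come
from `lm()` + `car::Anova()` + `emmeans` under a set-to-zero constraint on
the last factor level; LS means are constraint-invariant (verified in the
tests), which is why the constraint choice is free. Significance codes
follow the herd-book convention (`***` p<0.01, `**` p<0.05, `*` not
significant).

### Sire evaluation

`evaluate_sires()` solves Henderson's MME with a Jacobi-preconditioned
conjugate gradient (relative tolerance $10^{-12}$) and a sparse direct
fallback for up to 2,000 random levels. The frequentist route is sire-model
BLUP with $\lambda = (4 - h^2)/h^2$ from the half-sib $h^2$ and EBV = 2 ×
sire solution; the Bayesian route is animal-model BLUP at the posterior
means of $G_0$ and $R_0$, the sire's EBV being its own solution. Only sires
with more than three recorded progeny are ranked (ties broken by sire code
for determinism). `spearman_t()` compares rankings with
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n - 2$ degrees of freedom, $n$ being the
number of evaluated sires; $|r| = 1$ is flagged unbounded rather than
raising an error.

## The synthetic herd

No field records ship with the package; `simulate_herd()` generates herds
with known architecture so every claim is testable. The generative model is
the animal model itself: founders draw $u \sim N(0, G_0)$, non-founders
$u = \tfrac12(u_s + u_d) + m$ with Mendelian sampling $m \sim N(0,
\tfrac12 G_0)$ (inbreeding is ignored *in the generator*; the analysis-side
$A$ is exact), and phenotypes add trait means, period/season effects, the
AFC covariate term and $e \sim N(0, R_0)$.

Default conditions emulate the herd the package is scaled to: 8 founder
sires and 482 founder dams with one recorded daughter each — 964 recorded
cows, eight traits, birth cohorts 1986–2014 so that the birth/calving
period scales are exercised. Trait means and phenotypic SDs follow the
herd's descriptive statistics (AFC 1227.73 ± 179.45 d, FLMY 1765.44 ±
697.26 kg, ...). $G_0$ and $R_0$ are assembled from the reported
heritabilities and genetic/phenotypic correlation structure; because the
reported posterior variance *magnitudes* are mutually inconsistent with the
descriptive SDs for the production traits, the generator keeps the
heritability ratios and correlations and rescales each trait to the
descriptive phenotypic variance. The correlation tables omit LTMY (it was
dropped from the multi-trait analysis for non-convergence), so its rows
come from the half-sib-track estimates, and the assembled matrices are
projected to positive definiteness by eigenvalue clipping with the
diagonal preserved. Fixed-effect magnitudes are not reported at all; the
defaults (season offsets of ±0.25 phenotypic SD, a 0.1 SD-per-period trend,
a 0.1 SD-per-SD AFC slope) are moderate values chosen once as typical of
period/season effects in tropical dairy records.

What the generator does **not** emulate: non-Gaussian trait distributions
(real FSP is right-skewed; simulated traits are Gaussian and can stray
outside biological bounds), censoring of longevity traits, selection over
time, heterogeneous variances across periods, and the editing artifacts
that the `apply_edit_filters()` thresholds (<100 d lactation, <500 kg
yield, <3.5% fat) exist to remove. Passing recovery tests therefore shows
the estimators are correct under the stated model, not that real records
meet the model.

One printed inconsistency is deliberately preserved: the descriptive table
the defaults emulate lists a first-lactation fat yield *mean* larger than
the milk yield mean, which is not biologically possible for a component
trait. The generator reproduces the printed scale rather than silently
correcting it; analyses in the package are unaffected (nothing assumes
FLFY < FLMY).

## Problem sizes used in the checks

The test suite and the acceptance script re-derive everything at desk
scale, chosen as the smallest sizes at which the asymptotic claims hold
comfortably: pedigrees up to q = 50 for exact A⁻¹ checks; a bivariate
recovery study with q = 400 animals, 390 records, true $h^2 = 0.5$ and
$r_g = 0.6$, twenty replicates at 6,000/500/5 chain settings (truth inside
the 95% HPD in ≥ 90% of replicates); 1,000 null replicates for the F-test
size; 200 replicates of 200 sires × 20 progeny for half-sib recovery; and
the full default herd (964 cows) with the standard 30,000/1,000/10 chain
for the acceptance run.

## Known limitations

* Multi-trait runs share one record set (complete cases); traits observed
  on disjoint cows cannot be analysed jointly.
* The MME solver and sire evaluation are univariate per trait; multi-trait
  BLUP is available only through per-trait solves at the posterior-mean
  components.
* Method III with few sires is very noisy — with 8 sire families the
  half-sib $h^2$ routinely truncates at 0 or 1, with standard errors to
  match (0.3–0.7). That is a property of the estimator at this design
  size, and is the reason the Bayesian track exists.
* No maternal effects, no unknown-parent groups, no genomic relationships.
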