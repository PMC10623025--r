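# herdgibbs

Pedigree-based genetic parameter estimation for dairy herds, by two
parallel routes. `herdgibbs` is aimed at animal breeders working with
modest field herds (hundreds of recorded cows, a handful of sires) who
need heritabilities, genetic/phenotypic correlations and sire rankings for
reproduction traits (age at first calving AFC, first service period FSP),
production traits (first-lactation milk, fat and solids-not-fat yields)
and lifetime traits (lifetime milk yield, productive life, herd life).

The core model is the animal model

    y = Xβ + Zu + e,   u ~ N(0, G0 ⊗ A),   e ~ N(0, R0 ⊗ I),

with A the pedigree numerator relationship matrix. The package provides:

* **pedigree machinery** — renumbering with parents before offspring, the
  tabular A with inbreeding, and Henderson's direct rules for A⁻¹;
* **a frequentist half-sib track** — fixed-effect models (five-year
  period, four-season, AFC covariate templates) with a random sire term,
  Henderson Method III variance components, paternal half-sib heritability
  h² = 4σ²ₛ/(σ²ₛ+σ²ₑ) with Swiger standard errors, and sire-component
  correlations;
* **a Bayesian track** — single- and multi-trait Gibbs sampling of G0 and
  R0 under the animal model (compiled single-site sampler, inverse-Wishart
  full conditionals), with posterior mean/mode/median/SD, shortest 95% HPD
  intervals, Geyer effective sample sizes, Monte-Carlo errors SD/√ESS and
  Geweke diagnostics, plus per-draw heritabilities and correlations;
* **BLUP sire evaluation** by both routes (sire-model BLUP with λ =
  (4−h²)/h², animal-model BLUP at posterior-mean components) and a
  Spearman rank-correlation t test comparing the rankings;
* **a synthetic-herd generator** with known genetic architecture, whose
  defaults emulate a 964-cow zebu herd, so the whole pipeline is testable
  without field records;
* **a command-line pipeline** (`exec/herdgibbs`) with `simulate`,
  `describe`, `lsml`, `gibbs`, `postgibbs`, `blup` and `compare-sires`
  subcommands over plain CSV/TOML files.

## Worked example

```r
library(herdgibbs)

params <- sim_params(traits = c("afc", "pl"), n_sires = 8, n_dams = 120,
                     seed = 42)
herd <- simulate_herd(params)
descriptive_statistics(herd$phenotypes)
#>   trait   n mean    se    cv    sd    min  max
#> 1   afc 240 1200 11.81 15.24 182.9  766.2 1769
#> 2    pl 240 1312 40.11 47.35 621.3 -214.5 2955

Ainv <- build_A_inverse(herd$pedigree)
res <- run_chain(lapply(c("afc", "pl"), model_spec), herd$phenotypes,
                 Ainv, chain_config(6000, 500, 5), seed = 43)
post <- derive_parameters(res)
subset(post$summary, parameter %in% c("h2_afc", "h2_pl", "rg_pl_afc"))
#>  parameter  mean    sd hpd_lower hpd_upper  ess    mce geweke_z
#>     h2_afc 0.767 0.118    0.5596     0.954 68.9 0.0142    0.349
#>      h2_pl 0.304 0.138    0.0607     0.570 44.8 0.0207   -5.685
#>  rg_pl_afc 0.222 0.364   -0.5003     0.837 40.0 0.0576   -1.978
```

The posterior mean heritability of AFC in this 240-cow herd is 0.77 with a
shortest 95% credible interval of (0.56, 0.95); its Monte-Carlo error
(SD/√ESS) is 0.014, and the Geweke z of 0.35 flags no drift between the
early and late chain. The PL chain's z of −5.7 says 6,000 iterations were
*not* enough for that trait — exactly the situation the diagnostic exists
to catch. The genetic correlation between AFC and productive life is still
very uncertain (HPD spans zero) at this herd size.

The frequentist track on the same herd:

```r
spec <- model_spec("afc", random = "sire")
comp <- henderson3_components(spec, herd$phenotypes)
phs_heritability(comp$sigma2_s, comp$sigma2_e, comp$k, comp$n_sires, comp$n)
#> Paternal half-sib h2 = 0.241 +/- 0.256 (t = 0.060, 8 sires, N = 120)
```

With eight sire families the half-sib estimate carries a standard error of
the same order as the estimate — the small-sample weakness the Bayesian
track addresses. Finally, the two sire rankings:

```r
freq  <- evaluate_sires(spec, herd$phenotypes, method = "sire_model", h2 = 0.24)
s <- setNames(post$summary$mean, post$summary$parameter)
bayes <- evaluate_sires(model_spec("afc"), herd$phenotypes,
                        method = "animal_model", sigma2_g = s["s2_g_afc"],
                        sigma2_e = s["s2_e_afc"], Ainv = Ainv)
compare_sire_rankings(freq, bayes)
#> Spearman r = 0.881, t = 4.56, df = 6: significant
```

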