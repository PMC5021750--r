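# monodmix

Size-dependent saturation thresholds for dietary EPA in *Daphnia*
juvenile growth experiments.

## What it is for

Eicosapentaenoic acid (EPA, 20:5ω3) is an essential dietary fatty acid for
*Daphnia*: on EPA-free food, juvenile somatic growth rises with dietary
EPA supplementation up to saturation. Whether the EPA *demand* — the
dietary concentration needed to approach that saturation — scales with
body size across species is an ecological question with consequences for
the dominance of small-bodied cladocerans in warm, cyanobacteria-rich
waters. `monodmix` provides the full inference pipeline for such
experiments, for ecologists and ecophysiologists analysing dose–response
growth data grouped by clonal lineages.

## The model

Beaker-level juvenile growth rate, g = (ln Wt − ln W0)/t (day⁻¹), is
modelled as a Monod-type saturation curve of the dietary EPA concentration
S (µg EPA mg C⁻¹) with a baseline shift:

    g(S) = g0 + (g∞ − g0) · S / (S + K_S)

with clone-level Gaussian random effects on a nested subset of
(g0, g∞, K_S) and, in the size-dependent model family, a linear body-size
law K_S = K0 + K_L·L. The package fits the six-model series A1…B3 by
maximum likelihood (Laplace-approximated marginal likelihood; the
per-clone inner problem runs in compiled code), ranks it by AIC with
pairwise likelihood-ratio tests of the size law, obtains standard errors
by residual bootstrap, and reports EPA demands as saturation thresholds
S_p = K_S·p/(1−p) (so S₇₅ = 3·K_S). Companion modules analyse clutch
sizes (arcsine-square-root transformed after rescaling) and fatty-acid
tissue quotas (totals, newly-built-biomass contents, species means,
Kruskal–Wallis tests). A synthetic-data generator reproduces the
experimental design — 12 clones of three species, 7 EPA levels spanning
0–10 µg EPA mg C⁻¹, 3 replicate beakers, 6 days — so the whole pipeline is
testable without laboratory data.

## Worked example

```r
library(monodmix)

cfg    <- default_config()                 # the 12-clone study design
growth <- simulate_growth(cfg, seed = 1)   # 252 beaker observations
sel    <- run_model_series(growth, cfg$clones)
sel
```

```
Model selection across the A/B Monod mixed-model series

 model    fixed_effects random_effects Df     AIC logLik converged
    A1     g0, ginf, KS             g0  5 -1029.3  519.6      TRUE
    A2     g0, ginf, KS       g0, ginf  6 -1081.7  546.8      TRUE
    A3     g0, ginf, KS   g0, ginf, KS  7 -1164.1  589.0      TRUE
    B1 g0, ginf, K0, KL             g0  6 -1212.3  612.1      TRUE
    B2 g0, ginf, K0, KL       g0, ginf  7 -1210.4  612.2      TRUE
    B3 g0, ginf, K0, KL   g0, ginf, KS  8 -1208.4  612.2      TRUE

Pairwise likelihood-ratio tests (A_k vs B_k):
 null_model alt_model  chisq chi_df p_value
         A1        B1 185.01      1       0
         A2        B2 130.68      1       0
         A3        B3  46.30      1       0

Best model (min AIC): B1
```

Every size-dependent model (family B) beats its size-free counterpart, and
B1 — a clonal random effect on g0 plus the body-size law for K_S — wins
the AIC ranking: on these data the half-saturation constant genuinely
scales with body size (the generator's truth). Bootstrap uncertainty and
the 75% saturation thresholds:

```r
best <- sel$fits[[sel$best_model]]
boot <- residual_bootstrap(best, n_boot = 200, seed = 1000004)
threshold_table(data.frame(clone_id = boot$summary$clone_id,
                           ks = boot$summary$ks,
                           ks_se = boot$summary$ks_se), p_frac = 0.75)
```

```
  clone_id   ks ks_se  s_p s_p_se
       DlE 0.23  0.02 0.68   0.05
       Dl4 0.29  0.02 0.87   0.05
        Dh 0.40  0.02 1.19   0.06
        Dg 0.59  0.03 1.76   0.10
    DpBrA3 0.72  0.05 2.17   0.14
     DpBrS 0.92  0.06 2.77   0.19
     DpGr8 1.13  0.08 3.38   0.25
    DpGr49 1.16  0.08 3.47   0.25
  IL-M1-12 1.95  0.16 5.85   0.47
   IL-M1-8 2.08  0.17 6.23   0.51
 FI-N26-8c 2.24  0.18 6.71   0.55
 FI-N47-20 2.46  0.21 7.38   0.62
```

Small *D. longispina*-complex clones saturate their EPA-dependent growth
below ~1.8 µg EPA mg C⁻¹ while large *D. magna* clones need 6–7.4; the
fitted size law is K0 = −1.288 (SE 0.147), K_L = 1.059 (SE 0.099)
µg EPA mg C⁻¹ mm⁻¹. The single call

```r
bundle <- reproduce_paper_shape(pipeline_config(seed = 1))
```

runs simulate → fit → select → bootstrap → thresholds → fatty-acid
statistics end to end and writes the selection, threshold, species-mean
and rank-test CSVs plus a JSON summary.

See `vignettes/monodmix-methods.Rmd` for the model, the estimation
algorithm, every tunable default and the design decisions behind the
synthetic-data generator.

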