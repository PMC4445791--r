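# mlgrm — multilevel graded response models for nested ordinal survey data

`mlgrm` implements a two-step multilevel item response theory (MLIRT)
analysis for health surveys in which persons are nested in dwellings and
health is measured twice through ordinal difficulty items: *biological
health* (difficulty without technical aids or personal assistance) and
*lived health* (difficulty with whatever aids and assistance are actually
used). It is aimed at biostatisticians and epidemiologists analysing
ICF-style functioning surveys who want latent health scores and
environmental-factor effects estimated jointly, with the nesting respected
and ability uncertainty propagated, rather than regressions on frozen sum
scores.

## The model

The measurement model is a graded response model: for item *k* with
discrimination `a_k` and ordered thresholds `kappa_k,c`,

    P(Y_ik >= c | theta_i) = F(a_k (theta_i - kappa_k,c)),

with `F` probit (default) or logistic, and higher `theta` meaning worse
health. The structural model is a two-level regression of the latent trait
on person-level covariates `x`, dwelling-level covariates `w`, and a
dwelling random effect:

    theta_ij = beta0 + x_ij' beta + w_j' gamma + u_j + e_ij,
    u_j ~ N(0, tau2),  e_ij ~ N(0, sigma2).

Estimation is by MCMC with data augmentation; each iteration the ability
scale is identified by rescaling the sampled abilities to mean 0 and
variance 1. The analysis proceeds in two steps: (1) score biological
health from the biological items (intercept + dwelling random effects
only); (2) regress lived health on environmental covariates with the
step-1 score entered as a known, error-free predictor. IRT assumption
diagnostics (bifactor unidimensionality, residual-correlation local
dependence at 0.25, rest-score monotonicity), HPD posterior summaries,
Geweke convergence checks, DIC model comparison, the intraclass
correlation `tau2 / (tau2 + sigma2)` and empty-vs-full variance
decompositions are included, together with a synthetic generator of
complete nested survey bundles with known ground truth.

## Worked example

```r
library(mlgrm)

# a synthetic survey: ~2270 adults in 2000 dwellings, 15 items per trait
bundle <- simulate_survey(generator_config(seed = 7, n_dwellings = 2000))

res <- run_pipeline(bundle, mcmc_config(n_iter = 2000, burn_in = 700, seed = 7))
print(res)
```

```
<pipeline_result>
  persons kept: 1979 of 2266
  ICC: 0.044
  variance explained: person 0.874, dwelling 0.398
  DIC: empty 40020.9, full 39388.0, no biological control 40011.0
```

Reading the output: 1,979 of 2,266 generated adults report difficulty on
at least one biological item and enter the analysis. The empty-model ICC
puts ~4% of the lived-health variance between dwellings on this replicate
(the near-singleton household structure makes this quantity noisy). The
covariates explain ~87% of the person-level and ~40% of the
dwelling-level variance, and the DIC ordering — full model below the
no-biological-control model below the empty model — shows that the
environmental covariates improve prediction and that biological health is
the strongest single control, the qualitative pattern such surveys
report. The step-2 coefficient table recovers the generating effects,
e.g. biological health 0.898 (95% HPD [0.878, 0.916]) for a generating
0.902, male -0.093 [-0.135, -0.046], age over 65 0.103 [0.058, 0.145] —
the weaker environmental coefficients are attenuated relative to their
generating values because lived health is equated with biological health
for non-aid users, exactly as in the survey construction.
`res$step2$summary` holds the full table (posterior mean, SD, 95% HPD per
covariate); `res$step1$scores` the standardized biological scores;
`res$diagnostics` the assumption-check reports.

A command-line wrapper is installed as `exec/mlgrm` with subcommands
`simulate`, `check`, `fit` and `pipeline`, each driven by a YAML config:

```sh
mlgrm simulate --config gen.yaml      # writes the CSV bundle + truth.json
mlgrm pipeline --config run.yaml      # writes report.json + summary CSVs
```

## Scope notes

The one-step joint model (biological health as a latent regressor) is out
of scope, as is survey-weighted model estimation: weights enter the
descriptive tables only. The methods vignette
(`vignettes/mlirt-methods.Rmd`) documents the model, priors, sampler
design, diagnostics, generator calibration and known limitations.
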