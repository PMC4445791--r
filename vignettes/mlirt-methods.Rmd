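---
title: "Multilevel graded response modelling of biological and lived health"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel graded response modelling of biological and lived health}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`mlgrm` implements a two-step multilevel item response theory (MLIRT)
analysis for health surveys that measure functioning twice: *biological
health* (difficulty carrying out activities without technical aids or
personal assistance — the ICF notion of capacity) and *lived health*
(difficulty with whatever aids and assistance the person actually uses —
the ICF notion of performance). Both are latent traits measured by ordinal
difficulty items, and persons are nested in dwellings.

The measurement side is a graded response model (GRM). For item $k$ with
discrimination $a_k > 0$ and strictly increasing thresholds
$\kappa_{k,1} < \dots < \kappa_{k,C-1}$,

$$P(Y_{ik} \ge c \mid \theta_i) = F\!\big(a_k(\theta_i - \kappa_{k,c})\big),$$

with $F$ the probit or logistic response function and category
probabilities obtained by adjacent differencing. Higher $\theta$ means
*worse* health throughout. The structural side is a two-level linear model
for the trait of person $i$ in dwelling $j$:

$$\theta_{ij} = \beta_0 + x_{ij}'\beta + w_j'\gamma + u_j + e_{ij},
\qquad u_j \sim N(0, \tau^2),\ e_{ij} \sim N(0, \sigma^2).$$

Both parts are estimated simultaneously by MCMC, so the uncertainty of the
abilities propagates into the regression instead of being frozen into a
point-score outcome.

The analysis has two steps because the two traits are modelled separately:
step 1 fits the biological items with an intercept-and-random-effect-only
structural model and extracts standardized posterior-mean biological
scores; step 2 fits the lived items with the step-1 score entered as a
*known* person-level predictor (error fixed to zero) next to demographic
and environmental covariates and a dwelling-level block. Treating the
estimated score as error-free is the acknowledged limitation of the
two-step design: measurement error in the score attenuates its
coefficient, and a joint one-step model would be preferable where software
permits. The package deliberately implements the two-step variant.

Before fitting, the survey preprocessing mirrors common practice for
ICF-based disability surveys: sparse middle categories are collapsed
("moderate" and "severe" pooled, leaving three ordered options), only
respondents reporting difficulty on at least one biological item are kept,
and lived-health items — answered only by users of aids or assistance in a
domain — are equated with the corresponding biological item for everyone
else.

## Estimation

The default sampler uses the probit link with truncated-normal data
augmentation. Per iteration it updates, in order: the item cutpoints (a
random-walk Metropolis step evaluated against the *observed-data* ordinal
likelihood, i.e. with the augmented data collapsed out — the classical
uniform full conditionals shrink to a width of order $1/n$ and effectively
freeze the thresholds at survey sample sizes), the latent cell variables
(truncated normal), the discriminations (conjugate, truncated to be
positive), the abilities (conjugate normal combining measurement
information and the structural prediction), the fixed effects (conjugate
multivariate normal), the dwelling effects, the dwelling variance, and the
person residual variance. The logit link is available through adaptive
random-walk Metropolis updates for item parameters and abilities; the
structural machinery is shared.

Two numerical choices deserve emphasis:

* **Collapsed dwelling-variance update.** With an average of ~1.13 persons
  per dwelling, almost all clusters are singletons and the element-wise
  $u_j$ / $\tau^2$ scan mixes pathologically (the $\tau^2$ trace still
  trends after thousands of iterations). $\tau^2$ is therefore updated by a
  Metropolis step on its *collapsed* conditional, with the dwelling
  effects integrated out analytically ($O(J)$ per evaluation), after which
  the $u_j$ are redrawn. Against a REML oracle on the true abilities this
  removes the ridge entirely.
* **Half-Cauchy prior on the dwelling SD.** Under near-singleton
  clustering the $\tau^2$ likelihood is weak, and the conventional vague
  inverse-gamma prior piles mass at zero, pulling the posterior-mean ICC
  well below its generating value even with the abilities clamped at
  truth and a REML fit as reference. The default prior is therefore
  half-Cauchy(0, 1) on $\tau$ — the standard weakly-informative choice
  for hierarchical scale parameters — under which the ICC-recovery checks
  in the test suite pass across generating values of 0, 0.15 and 0.5; the
  inverse-gamma remains available via `prior_tau = "inverse_gamma"`. The
  person residual variance, which is well identified, keeps its vague
  inverse-gamma prior.

**Identification.** The latent scale is fixed the way the original MLIRT
estimation scheme fixes it: after every iteration the sampled abilities are
standardized to mean 0 and variance 1, and the compensating transform is
applied to all other parameters ($a \to a s$, $\kappa \to (\kappa - m)/s$,
coefficients and random effects divided by $s$, variances by $s^2$). The
transform leaves the observed-data likelihood invariant; the fit records
the worst log-likelihood drift across the rescaling at every stored
iteration (the test suite asserts it stays below $10^{-8}$) so the
invariance is continuously verified rather than assumed.

**Priors and defaults.** $a_k \sim N(1, 10)$ truncated positive; cutpoints
flat subject to ordering; coefficients $N(0, 100)$;
$\sigma^2 \sim \mathrm{IG}(0.001, 0.001)$; $\tau \sim$ half-Cauchy(0, 1).
Default run length is 5000 iterations with 1000 burn-in and no thinning,
single chain; proposal scales adapt only during burn-in, so the retained
chain is a fixed-kernel Markov chain. Initialization is deterministic:
$a = 1$, cutpoints at transformed empirical category proportions,
abilities at standardized rest-scores, coefficients at zero, variances at
0.5. Convergence is monitored with Geweke z-scores (first 10% vs last
50%); the deviance information criterion uses the conditional
(given-$\theta$) measurement deviance, matching the original software
family, with $p_D = \bar D - D(\hat\theta, \hat a, \hat\kappa)$.

Posterior summaries report means, SDs, and 95% highest posterior density
intervals computed by the Chen–Shao shortest-window rule on the sorted
draws.

## Assumption diagnostics

The three standard IRT assumptions are checked per item set:

* **Unidimensionality** — minres factor extraction from the polychoric
  correlation matrix followed by an orthogonal analytic bifactor rotation
  (gradient projection on the bi-quartimin criterion). A domain is flagged
  when its items load higher on their group factor than on the general
  factor; flags warn and suggest a sensitivity re-fit rather than forcing
  removal, since a domain can be both locally multidimensional and a
  legitimate part of overall health.
* **Local independence** — residual correlations after a single-factor fit
  to the polychoric matrix; pairs with $|r| > 0.25$ are flagged, connected
  flagged subsets are reduced to their most discriminating member (the
  retention rule within a dependent subset is not dictated by any
  published convention; highest provisional discrimination is this
  package's explicit choice), and a robustness comparison of person scores
  with and without the dropped items is reported.
* **Monotonicity** — rest-score curves (mean item score by binned mean of
  the other items, deciles merged to at least 50 persons). An item fails
  only when a decrease between adjacent bins exceeds the tolerance (0.03)
  *plus twice the standard error of the difference*: the tolerance alone
  describes a systematic violation, and without the noise allowance
  ordinary bin-mean sampling error fails most monotone items at a few
  hundred persons — a false alarm a human reading the graph would never
  raise.

The polychoric correlations are pairwise two-step ML estimates (thresholds
from the margins, $\rho$ by likelihood maximization over the bivariate
normal rectangle probabilities, themselves computed by a 48-node
Gauss–Legendre reduction of the bivariate normal CDF, accurate to ~1e-12
and verified against an independent implementation in the tests).

## The synthetic survey generator

Because the motivating survey's microdata are not redistributable, the
package ships a generator whose defaults encode the study conditions the
analysis assumes:

* ~1.134 persons per dwelling (cluster sizes $1 + \mathrm{Poisson}(0.134)$,
  matching 17,303 adults in 15,263 dwellings);
* 15 items per role in three domains with 3 ordered categories,
  discriminations uniform on [0.865, 3.218] (the published span) and
  ordered thresholds on [-0.5, 2.5];
* person-level covariates with published marginal frequencies (62.4%
  female, 40.4% aged 65 or younger) and published coefficient defaults
  (biological health 0.902, male -0.172, older age 0.101, feeling
  discriminated -0.103, occupation change 0.269, work-activity change
  0.148);
* a continuous standard-normal biological-health trait that both drives
  the biological items and enters the lived-health structural model;
* aid use per domain following a logistic model in lived health (base
  probability 0.5, slope 1 — the survey reports no aid-use prevalence, so
  this is a modelling choice, not a reproduced value), with lived items
  observed only for aid users;
* item responses missing completely at random at rate 0.05.

Two generator defaults are package choices calibrated to the *variance
structure* the published analysis reports rather than to its printed
coefficients: the dwelling-level coefficient is 0.6 (the published
dwelling covariate is essentially null, but a generator with no real
dwelling-level signal could never exercise the between-dwelling part of
the variance decomposition), and the residual variance is 0.235 with a
residual ICC of 0.15, so that covariates explain roughly three quarters of
the trait variance at both levels — the reported 77%/74% pattern. The
generator standardizes the simulated abilities empirically before
generating responses, so the stored truth (including coefficients and
variances) lives on the identified scale a fitted model reports, which is
what makes recovery comparisons well-defined.

What the generator does *not* emulate: proxy interviews, the screening
instrument, informative missingness, covariate dependence beyond
independent draws, and realistic within-household correlation of person
covariates. Passing recovery tests therefore show the estimator is correct
under its own assumptions at realistic sizes — not that those assumptions
hold in any particular survey.

## Verification strategy and problem sizes

The test suite recomputes every layer against an independent oracle where
one exists: brute-force summation for the GRM likelihood, `mvtnorm` for
the bivariate normal CDF, a closed-form conjugate posterior for the
structural block (with abilities clamped), an exhaustive window scan for
the HPD rule, and `coda` as a cross-check for interval and convergence
summaries. The deeper simulation checks run at reduced sizes chosen to
keep the full suite in the tens of minutes: measurement recovery at ~1000
persons, structural recovery over five replicates at ~4000 persons in
3500 dwellings, ICC recovery at 2000 dwellings across generating values
{0, 0.15, 0.5}, DIC model-ordering over 20 replicates at ~380 persons,
and the end-to-end pipeline (twice, for bit-reproducibility) at the
generator defaults. The two-step pipeline's weaker coefficients are
checked for sign rather than magnitude: the equating construction mixes
the two latent traits for non-aid users and the error-free treatment of
the step-1 score attenuates its coefficient, so magnitudes are not
comparable to the one-step ideal — the same caveat the two-step design
carries on real data.

## Known limitations

* The one-step joint model (biological health as a latent regressor) is
  intentionally out of scope.
* Sampling weights enter descriptive tables only; the MLIRT fits are
  unweighted, as in the motivating analysis.
* The DIC is conditional on the abilities; marginal DIC variants are not
  computed.
* Single-chain estimation with Geweke monitoring; multi-chain potential
  scale reduction is not orchestrated.
* Heterogeneous category counts across items must be resolved (collapsed)
  before fitting.
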