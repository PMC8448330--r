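---
title: "Hierarchical models for epiphytic lichen diversity in managed boreal forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical models for epiphytic lichen diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lichendiv` analyses complete tree-level presence/absence surveys of
epiphytic lichens. The survey design it targets is a set of forest subplots
("stands") in which every living tree above 10 cm diameter at breast height
(DBH) is searched for every lichen species, on the trunk and branches
separately. Two questions drive the analysis: which host tree species does
each lichen prefer, and how do stand-level tree-species richness and
composition shape the lichen diversity of the whole stand?

Two Bayesian hierarchical models answer them. Both merge the trunk and
branch records into a single presence per (lichen, tree) before modelling.

## The tree-level model

Occurrence of lichen species $k$ on tree $i$ in subplot $p$ is Bernoulli
with

$$\operatorname{logit} P_{k,i,p} = \alpha_{k,t(i)} + b_k\, z_i + u_{k,p},$$

where $t(i)$ is the host tree species (spruce, pine, birch, aspen, alder,
oak), $z_i$ the Z-scored DBH and $u_{k,p}$ a subplot random effect. This is
a multi-species occupancy model with complete detection: the survey design
(exhaustive search of the lowest 2 m of every tree) justifies treating
observed presence as true occurrence, so no detection submodel is fitted.

Host-species intercepts use **cell-means coding** — one intercept per host
species, no reference level — because the quantities of interest are
per-host predictions and an "average tree", both of which are then direct
transformations of the coefficients.

The hierarchy supplies Bayesian shrinkage: $\alpha_{k,t} \sim
N(\mu_t, \sigma_t)$ and $b_k \sim N(\mu_b, \sigma_b)$ pool species toward
community means, which stabilises the 30-plus species in a typical survey
that are seen only a handful of times. All observed species enter the
model; there is no occurrence-count filter, shrinkage being precisely the
mechanism that handles the rare ones. Hyperpriors are vague on the logit
scale: $N(0, 10)$ for means, half-Cauchy(5) for SDs. Subplot-effect SDs
$\tau_k$ are species-specific with a half-Cauchy prior whose scale has a
Uniform(0, 5) hyperprior (`subplot_effect = "shared"` switches to a single
subplot effect common to all species, for the reading of the design in
which the group effect is not species-specific).

Post-processing follows from the fitted object:

* `predict_occurrence()` — occurrence probability per lichen per host
  species at the mean DBH and zero subplot effect. The "average tree"
  averages the six linear predictors per draw on the logit scale before
  the inverse logit; averaging on the probability scale instead is exposed
  via `average_scale = "probability"`. The logit-scale default is declared
  rather than derived: with cell means and equal weights it is the natural
  "average host effect", and the option documents the sensitivity.
* `predict_richness()` — expected lichen richness per tree as the sum of
  the occurrence probabilities across species, per draw.
* `pairwise_richness()` — draw-matched differences and exceedance
  probabilities between host species, the Bayesian analogue of ANOVA
  contrasts. Exactly tied draws count 1/2 so the exceedance matrix is
  always antisymmetric.

## The stand-level model

Richness cannot be compared across subplots directly because they contain
different numbers of trees. The package therefore builds, per subplot, a
species accumulation curve: trees are virtually reordered `s = 100` times
and the accumulated number of distinct species is averaged,
$U_{i,p} = \mathrm{mean}_s(U_{i,p,s})$. An exact mode computes the average
over *all* orderings in closed form through the hypergeometric rarefaction
identity $E[U_i] = \sum_s \left(1 - \binom{n - n_s}{i}/\binom{n}{i}\right)$
— identical to the permutation mean, with no Monte-Carlo noise, and
available for any subplot size. Each subplot draws its permutations from
its own seed stream, so curves do not change when other subplots are added
or dropped.

The curve is modelled with a modified Michaelis–Menten function in which
the half-saturation constant is replaced by true (Whittaker,
multiplicative) beta diversity:

$$U_{i,p} \sim N\!\left(\frac{\gamma_p\, i}{\beta_p - 1 + i},\ \sigma_p\right).$$

$\gamma_p$ is the asymptote — stand gamma diversity — and the curve at one
tree gives alpha diversity $\gamma_p/\beta_p$, so the three Whittaker
components are carried by two parameters. Half-saturation falls at
$i = \beta_p - 1$ trees.

Subplot diversities are regressed on stand covariates *inside the same
model* (no two-stage plug-in):

$$\gamma_p \sim N(\mathbf{x}_p'\mathbf{g},\ \sigma_\gamma), \qquad
  \beta_p \sim \mathrm{Gamma}\big(\text{mean} = e^{\mathbf{x}_p'\mathbf{h}},\ \text{sd} = \sigma_\beta\big),$$

with the Gamma law in its moment parameterisation (shape
$\mu^2/\sigma^2$, rate $\mu/\sigma^2$). The log link keeps the
beta-diversity mean positive; because true beta diversity cannot fall
below one, the default parameterisation is **shifted**:
$\beta_p = 1 + \delta_p$ with $\delta_p$ Gamma-distributed with mean
$e^{\mathbf{x}_p'\mathbf{h}} - 1$. The literal unshifted Gamma law on
$\beta_p$ is available via `beta_model = "unshifted"` (draws below one are
then flagged, not hidden).

Four model variants share this structure: tree-species richness
(cell means over the levels 1–4) and quadratic functions of the percentage
of spruce, pine, or deciduous trees (birch + aspen + alder + oak), each
with a mean-DBH slope. Percentages are computed from surveyed trees only
and Z-scaled across subplots. Priors: vague Gamma(0.01, 0.01) on positive
intercept-type coefficients, $N(0,10)$ on slopes, half-Cauchy(5) on all SD
parameters, with $\sigma_p$ independent per subplot.

`optimal_composition()` converts the quadratic coefficients, per draw,
into the percentage maximising the predictor: the vertex $-b_1/(2 b_2)$
when the quadratic is concave, otherwise the better boundary, clipped to
[0, 100]. `posterior_predictive_check()` draws replicated curves from the
fitted observation law and reports 95% envelope coverage;
`composition_surface()` exports the per-subplot ternary coordinates with
posterior median diversities.

## Sampling and diagnostics

Both models are fitted with a self-contained adaptive
Metropolis-within-Gibbs sampler. Proposal SDs adapt per parameter in
batches of 50 during a dedicated adaptation phase (target acceptance
0.44), then stay fixed. The stand model runs on a generic block engine
(`amwg_sample()`); the tree model uses the same update rules with
incremental linear-predictor bookkeeping, vectorised across species —
species are conditionally independent given the hyperparameters, so whole
coefficient matrices update in one Metropolis step with per-element
acceptance, and community means use conjugate Gibbs draws.

Defaults mirror the study design: three chains from over-dispersed
starting points, 50,000 post-burn-in iterations thinned to every 40th
draw, convergence declared when every monitored Gelman–Rubin PSRF is below
1.1 (classic, non-rank-normalised, computed on retained draws). Because
"visual inspection of mixing" is not automatable, an effective-sample-size
floor (default 100 per parameter, Geyer initial-sequence estimator) is
reported as a screen alongside the PSRF gate. The study design fixes total
draws and thinning but not warm-up; the defaults (10,000 adaptation +
5,000 burn-in) are ordinary practice and configurable — the PSRF gate is
the operative check. Every run is exactly reproducible from its master
seed; per-chain seeds derive from it deterministically.

Numerical choices worth knowing:

* Occurrence probabilities are clamped to $[10^{-12}, 1 - 10^{-12}]$ in
  likelihood evaluations, so log-likelihoods stay finite.
* Per-subplot observation SDs have a floor of $10^{-6}$: exactly noiseless
  synthetic curves otherwise drive the Normal likelihood into its
  degenerate spike at $\sigma = 0$. On real (noisy) data the floor is
  never active.
* Chain starting points: hyper-means offset by the `init_dispersion`
  setting per chain (tree model); per-subplot curve heuristics
  (a Lineweaver–Burk regression of $1/U$ on $1/i$) scaled per chain
  (stand model).
* Half-Cauchy draws in the generators use the closed form
  $|c \tan(\pi u / 2)|$, matching the prior family used in fitting.

## The synthetic-data generators

`simulate_community()` mirrors the tree-level model's generative
structure; its defaults emulate the study system: 117 lichen species, 59
subplots of about 19 trees (roughly 1,100 trees), host-tree frequencies
matching the surveyed stands (spruce and pine dominant, oak marginal), a
mostly-rare community (logit intercepts $N(-4, 2)$, overall occupancy near
10%), a weak positive community DBH effect (0.08 on the logit scale), and
DBH near 20 cm truncated at the 10 cm survey threshold. The truncated
Normal for DBH is a fixture choice — the models condition on DBH and make
no claim about its distribution in real forests. The trunk/branch split of
each simulated presence is uniform over {trunk, branches, both}; it is
cosmetic, since both models merge substrates.

`simulate_stand_curves()` mirrors the stand-level hierarchy. By default it
truncates each accumulated count at its running maximum, because real
accumulation counts are non-decreasing by construction. That truncation is
a deliberate misspecification relative to the model's plain Normal
observation law — it biases points near the asymptote upward — so the
calibration and recovery experiments in the test suite generate from the
exact law (`monotone = FALSE`): credible-interval coverage is a property
of the model's own generative distribution, and only under it is the
nominal 95% meaningful. Passing those checks therefore demonstrates that
the machinery is correct and calibrated under its assumptions; it does not
demonstrate robustness to the monotonicity (or any other) violation in
real data.

`simulate_full_stand()` varies the host-species mixture per subplot under
one shared lichen community, producing end-to-end fixtures where stand
composition genuinely drives the diversity gradient the stand model
estimates.

What the generators do not emulate: spatial autocorrelation between
subplots, tree age, dead-wood substrates, and any lichen–lichen
interaction. Conclusions from synthetic experiments transfer to real
surveys only to the extent those features do not matter.

## Problem sizes and verification

The test-suite experiments use desk-scale versions of the study
conditions, chosen so that each recovery experiment is decisive yet the
whole suite runs in minutes: occupancy-model recovery at 40 species x 30
subplots x 15 trees with 3 chains of 2,000 retained-iteration runs
(thin 2), stand-model recovery at 20–30 subplots of 20–25 trees with 3
chains x 5,000 (thin 5). At these reduced draws the PSRF gate is not
always met for every nuisance parameter — fits warn rather than fail — but
posterior medians and interval coverage, which the experiments score, are
stable. The verification ladder is:

1. exact identities (modified-MMf algebra, Gamma moment conversions,
   Z-scaling round trips) to $10^{-12}$;
2. independent oracles (all-permutations accumulation means; an external
   Gibbs-sampler fit of the identical occupancy model in JAGS; closed-form
   targets for the generic sampler);
3. parameter-recovery and calibration experiments on synthetic data with
   known truth (hyper-mean CrI coverage, subplot diversity recovery,
   composition-optimum recovery, posterior-predictive envelope coverage).

## Known limitations

* Complete detection is assumed, not tested; surveys with imperfect
  detection need an occupancy model with a detection submodel, which this
  package deliberately does not provide.
* The three composition variants are separate univariate models, so their
  predictions cannot be combined into a joint composition surface; the
  ternary export shows subplot-level estimates, not a fitted surface.
* The random-walk sampler is robust but not fast for very large
  communities; full-scale runs (hundreds of species, 50,000-draw chains)
  take hours, not seconds.
* Accumulation curves treat trees as exchangeable sampling units; there is
  no individual-based or coverage-based rarefaction, and no richness
  extrapolation beyond the Michaelis–Menten asymptote.

## A minimal worked example

```{r, eval = FALSE}
library(lichendiv)

tr <- community_truth(n_species = 30, n_subplots = 12,
                      trees_per_subplot = 12)
sim <- simulate_community(tr, seed = 1)

ctrl <- sampler_control(n_iter = 4000, thin = 4, adapt = 1500,
                        burnin = 500, seed = 1)
fit <- msom(sim$survey, control = ctrl)
summary(fit)
pairwise_richness(fit)$prob_col_exceeds_row

acc <- accumulation_table(sim$survey, s = 100, seed = 1)
des <- build_stand_design(sim$survey)
sfit <- stand_sac(acc, des, variant = "n_tree_species", control = ctrl)
diversity_levels(sfit)$gamma$summary
posterior_predictive_check(sfit)$coverage
```
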