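# lichendiv

Bayesian hierarchical models for complete tree-level surveys of epiphytic
lichens in managed boreal forests.

Structurally simple production forests dominate Fennoscandia, and what
little structural variety they retain — which tree species are present, at
what frequencies, at what stem diameters — is what shapes their epiphyte
communities. Given a survey in which every tree above 10 cm DBH on a set
of subplots is searched exhaustively for every lichen species (trunk and
branches recorded separately), `lichendiv` answers two questions:

1. **Tree level** — which host tree species does each lichen prefer, and
   how many lichen species does a tree of each host species carry?
2. **Stand level** — how do a stand's tree-species richness and
   composition drive its gamma (total) and beta (between-tree turnover)
   lichen diversity, and is there a composition that maximises them?

## The models

**Multi-species occupancy model with complete detection.** Occurrence of
lichen *k* on tree *i* in subplot *p* is Bernoulli with

    logit P[k,i,p] = alpha[k, t(i)] + b[k] * dbh_z(i) + u[k, p]

— a host-species intercept per lichen (cell-means coding), a DBH slope and
a subplot random effect. Species-level coefficients shrink toward
community means through Normal priors with vague Normal/half-Cauchy
hyperpriors, which is what makes estimates for rarely observed species
usable. Post-processing gives per-host occurrence probabilities, expected
richness per tree, and draw-matched pairwise richness contrasts with
exceedance probabilities.

**Hierarchical species-accumulation model.** Per subplot, trees are
virtually reordered (s = 100 times, or exactly via the hypergeometric
rarefaction identity) to build the mean accumulation curve U_i, modelled
with a modified Michaelis–Menten function in which the half-saturation
constant is true Whittaker beta diversity:

    U[i,p] ~ Normal( gamma[p] * i / (beta[p] - 1 + i), sigma[p] )
    gamma[p] ~ Normal( x[p]' g, sigma_gamma )          # identity link
    beta[p]  ~ Gamma( mean = exp(x[p]' h), sd = sigma_beta )   # log link

fitted jointly (no two-stage plug-in) with stand covariates: tree-species
richness (1–4, cell means) or quadratic tree-species percentages, plus
mean DBH. The quadratic variants yield a posterior for the composition
percentage that maximises diversity.

Both models are sampled by a self-contained adaptive
Metropolis-within-Gibbs engine (3 chains, over-dispersed starts, thinned
draws, Gelman–Rubin PSRF < 1.1 gate plus an effective-sample-size screen),
exactly reproducible from one master seed. A synthetic-data module
generates surveys and accumulation curves with known ground truth for
every stage.

## A worked example

```r
library(lichendiv)

# a synthetic survey with known truth: 30 lichen species, 12 subplots
tr  <- community_truth(n_species = 30, n_subplots = 12, trees_per_subplot = 12)
sim <- simulate_community(tr, seed = 1)
descriptive_counts(sim$survey)

ctrl <- sampler_control(n_iter = 4000, thin = 4, adapt = 1500,
                        burnin = 500, seed = 1)
fit <- msom(sim$survey, control = ctrl)
fit
#> Multi-species occupancy model (complete detection)
#>   30 lichen species, 144 trees, 12 subplots
#>   3 chains x 1000 retained draws (thin 4)
#>   Convergence: FAIL (max PSRF 1.402)   # short demo chains; lengthen n_iter

predict_richness(fit, "spruce")$summary
#>   median    lower    upper
#> 3.338272 2.953242 3.729237

round(pairwise_richness(fit)$prob_col_exceeds_row["pine", "spruce"], 3)
#> [1] 0.962     # Pr(richness on spruce > richness on pine)

acc  <- accumulation_table(sim$survey, s = 100, seed = 1)
des  <- build_stand_design(sim$survey)
sfit <- stand_sac(acc, des, variant = "n_tree_species", control = ctrl)
diversity_levels(sfit)$gamma$summary
#>   parameter   median     lower    upper
#> 1    level2 22.16954  4.837684 33.80342
#> 2    level3 24.90967 20.381158 28.87988
#> 3    level4 28.19400 22.058672 34.04382
posterior_predictive_check(sfit)$coverage
#> [1] 0.9930556
```

(Numbers above are from this exact script; your platform reproduces them
bit-for-bit with the same seeds. This particular simulated landscape has
no subplot with a single tree species, so the richness levels start at 2;
gamma diversity rises with tree-species richness, as the host-preference
structure of the simulated community predicts. The convergence FAIL is
expected at these short demonstration chains — the per-species
coefficients of rare lichens mix slowly — and disappears at the default
run lengths.)

Key summaries: `predict_occurrence()` (per-lichen occurrence probability
per host species with 95% credible intervals), `predict_richness()` and
`pairwise_richness()` (tree-level richness and its host contrasts),
`diversity_levels()` (gamma/beta by tree-species richness),
`optimal_composition()` (diversity-maximising composition percentage),
`posterior_predictive_check()` (envelope coverage of the accumulation
data), `composition_surface()` (ternary-plot export), and
`run_pipeline()` for the whole chain with a JSON run manifest.

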