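# Shared fixture builders. Everything is generated in code; no data files.

toy_survey_csv <- function(path = tempfile(fileext = ".csv")) {
  writeLines(c(
    "subplot,tree_id,tree_species,dbh_cm,A_trunk,A_branch,B_trunk,B_branch",
    "P1,t1,spruce,20,1,0,0,0",
    "P1,t2,Pine,15,1,1,1,0",
    "P2,t1,birch,30,0,0,0,1"
  ), path)
  path
}

# Brute-force oracle: mean accumulation over all n! permutations.
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(all_perms(v[-i]), function(p) c(v[i], p))))
}

perm_mean_accumulation <- function(sets) {
  ps <- all_perms(seq_along(sets))
  Reduce(`+`, lapply(ps, accumulate_once, species_sets = sets)) / length(ps)
}

# A small simulated survey shared by several tests.
small_survey <- function(seed = 3, K = 12, P = 5, npp = 8) {
  tr <- community_truth(n_species = K, n_subplots = P,
                        trees_per_subplot = npp,
                        tree_species_probs = rep(1 / 6, 6),
                        hyper_mean = c(rep(-0.5, 6), 0.2),
                        hyper_sd = c(rep(1, 6), 0.2),
                        subplot_sd_scale = 0.3)
  simulate_community(tr, seed = seed)$survey
}

fast_control <- function(seed = 1, n_iter = 400L, thin = 4L) {
  sampler_control(n_chains = 3L, n_iter = n_iter, thin = thin,
                  adapt = 300L, burnin = 100L, seed = seed)
}

# msom-shaped object with externally supplied degenerate draws:
# every alpha (and b) draw equals `alpha_value`.
fake_msom <- function(K, alpha_value = 0, n_draws = 4) {
  nms <- c(sprintf("alpha[%d,%d]", rep(seq_len(K), 6), rep(1:6, each = K)),
           sprintf("b[%d]", seq_len(K)))
  m <- matrix(alpha_value, n_draws, length(nms), dimnames = list(NULL, nms))
  structure(list(chains = list(m), parameters = nms,
                 data = list(y = matrix(0L, K, 2),
                             species = sprintf("sp%03d", seq_len(K)),
                             subplots = c("P1", "P2"))),
            class = "msom")
}

# stand_sac-shaped object with externally supplied draws for the columns
# the post-processing helpers consume.
fake_stand <- function(draws, subplots, variant = "pct_spruce",
                       scaling = list(), beta_model = "shifted",
                       design = NULL, acc = NULL) {
  structure(list(chains = list(draws), parameters = colnames(draws),
                 subplots = subplots, variant = variant,
                 beta_model = beta_model, scaling = scaling,
                 design = design, acc = acc),
            class = "stand_sac")
}
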