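test_that("the Bernoulli-logit likelihood matches hand calculations", {
  tens <- structure(list(
    y = matrix(0L, 1, 4), subplot_index = rep(1L, 4),
    tree_species_index = rep(1L, 4), dbh_scaled = rep(0, 4),
    subplots = "P1", species = "spA"), class = "occurrence_tensor")
  zero <- list(alpha = matrix(0, 1, 6), b = 0)
  expect_equal(tree_log_likelihood(zero, tens), 4 * log(0.5))

  tens1 <- tens
  tens1$y <- matrix(1L, 1, 1)
  tens1$subplot_index <- 1L
  tens1$tree_species_index <- 1L
  tens1$dbh_scaled <- 0
  a1 <- list(alpha = matrix(c(1, 0, 0, 0, 0, 0), 1, 6), b = 0)
  expect_equal(tree_log_likelihood(a1, tens1), log(1 / (1 + exp(-1))),
               tolerance = 1e-6)
  expect_equal(tree_log_likelihood(a1, tens1), -0.3132617, tolerance = 1e-6)

  # clamping guard: P -> 0 with y = 1 is hugely unlikely but finite
  a_far <- list(alpha = matrix(c(-200, 0, 0, 0, 0, 0), 1, 6), b = 0)
  ll <- tree_log_likelihood(a_far, tens1)
  expect_true(is.finite(ll))
  expect_lt(ll, -20)

  expect_error(tree_log_likelihood(list(alpha = matrix(0, 2, 6), b = 0),
                                   tens1), "matrix")
})

test_that("degenerate all-zero posteriors predict 0.5 everywhere", {
  f <- fake_msom(K = 10, alpha_value = 0)
  occ <- predict_occurrence(f, "spruce")
  expect_equal(occ$median, rep(0.5, 10))
  occ_avg <- predict_occurrence(f, "average")
  expect_equal(occ_avg$median, rep(0.5, 10))
  expect_equal(predict_occurrence(f, "average",
                                  average_scale = "probability")$median,
               rep(0.5, 10))
  r <- predict_richness(f, "pine")
  expect_equal(unname(r$summary["median"]), 5)   # K/2 exactly
  expect_error(predict_occurrence(f, "eucalyptus"), "unknown tree species")
  pw <- pairwise_richness(f)
  pr <- pw$prob_col_exceeds_row
  expect_equal(pr["spruce", "pine"], 0.5)
  expect_true(all(pr[upper.tri(pr)] + t(pr)[upper.tri(pr)] == 1))
})

test_that("a small fit is deterministic and respects basic ranges", {
  d <- small_survey(seed = 13, K = 6, P = 4, npp = 6)
  ctrl <- fast_control(seed = 2, n_iter = 200L, thin = 2L)
  f1 <- suppressWarnings(msom(d, control = ctrl))
  f2 <- suppressWarnings(msom(d, control = ctrl))
  expect_identical(f1$chains, f2$chains)
  f3 <- suppressWarnings(msom(d, control = fast_control(seed = 3,
                                                        n_iter = 200L,
                                                        thin = 2L)))
  expect_false(identical(f1$chains, f3$chains))

  occ <- predict_occurrence(f1, "spruce")
  expect_true(all(occ$median > 0 & occ$median < 1))
  expect_true(all(occ$lower <= occ$median & occ$median <= occ$upper))
  r <- predict_richness(f1, "spruce")
  expect_true(all(r$draws > 0 & r$draws < 6))
  # shared-subplot-effect variant runs and monitors a single tau
  fs <- suppressWarnings(msom(d, control = ctrl, subplot_effect = "shared"))
  expect_true("tau" %in% fs$parameters)
  expect_false("tau[1]" %in% fs$parameters)
})

test_that("rare species shrink toward the community mean", {
  # identical data for a rare species (2 presences on 48 trees), embedded
  # in two different communities. Partial pooling must pull its intercept
  # toward the community: higher in the common community than in the
  # sparse one, and never past the community mean.
  set.seed(8)
  n <- 48
  rare <- as.integer(seq_len(n) %in% c(5, 29))
  make_tens <- function(p_others) {
    y <- rbind(matrix(rbinom(4 * n, 1, p_others), 4, n), rare)
    structure(list(
      y = y, subplot_index = rep(1:4, each = 12),
      tree_species_index = rep(1L, n), dbh_scaled = rep(0, n),
      subplots = paste0("P", 1:4), species = paste0("sp", 1:5),
      tree_species_levels = TREE_SPECIES,
      scaling = c(mean = 20, sd = 5), dbh_cm = rep(20, n)),
      class = "occurrence_tensor")
  }
  ctrl <- sampler_control(n_chains = 3, n_iter = 1500, thin = 3,
                          adapt = 600, burnin = 300, seed = 4)
  fit_hi <- suppressWarnings(msom(make_tens(0.8), control = ctrl,
                                  store_subplot = FALSE))
  fit_lo <- suppressWarnings(msom(make_tens(0.05), control = ctrl,
                                  store_subplot = FALSE))
  a5_hi <- mean(lichendiv:::msom_pooled(fit_hi, "alpha[5,1]"))
  a5_lo <- mean(lichendiv:::msom_pooled(fit_lo, "alpha[5,1]"))
  mu_hi <- mean(lichendiv:::msom_pooled(fit_hi, "mu_alpha[1]"))
  expect_gt(a5_hi, a5_lo)  # same data, richer community, higher estimate
  expect_lt(a5_hi, mu_hi)  # pooling stops short of the community mean
})

test_that("the occupancy posterior agrees with an independent JAGS fit", {
  library(rjags)
  tr <- community_truth(n_species = 8, n_subplots = 3,
                        trees_per_subplot = 30,
                        tree_species_probs = rep(1 / 6, 6),
                        hyper_mean = c(-1, 0, 1, -0.5, 0.5, 0, 0.4),
                        hyper_sd = c(rep(0.8, 6), 0.2),
                        subplot_sd_scale = 0.3)
  sim <- simulate_community(tr, seed = 41)
  tens <- merge_trunk_branch(sim$survey)

  ctrl <- sampler_control(n_chains = 3, n_iter = 4000, thin = 4,
                          adapt = 1500, burnin = 500, seed = 6)
  fit <- suppressWarnings(msom(tens, control = ctrl, store_subplot = FALSE))
  hy <- c(sprintf("mu_alpha[%d]", 1:6), "mu_b")
  ours <- colMeans(lichendiv:::msom_pooled(fit, hy))

  model_str <- "model {
    for (k in 1:K) {
      for (t in 1:6) { alpha[k, t] ~ dnorm(mu[t], pow(sigma[t], -2)) }
      b[k] ~ dnorm(mu_b, pow(sigma_b, -2))
      tau[k] ~ dt(0, pow(c_tau, -2), 1) T(0,)
      for (p in 1:P) { u[k, p] ~ dnorm(0, pow(tau[k], -2)) }
    }
    for (t in 1:6) {
      mu[t] ~ dnorm(0, 0.01)
      sigma[t] ~ dt(0, pow(5, -2), 1) T(0,)
    }
    mu_b ~ dnorm(0, 0.01)
    sigma_b ~ dt(0, pow(5, -2), 1) T(0,)
    c_tau ~ dunif(0, 5)
    for (i in 1:N) { for (k in 1:K) {
      logit(pp[k, i]) <- alpha[k, tidx[i]] + b[k] * z[i] + u[k, pidx[i]]
      y[k, i] ~ dbern(pp[k, i])
    } }
  }"
  jd <- list(y = tens$y, K = nrow(tens$y), N = ncol(tens$y),
             P = length(tens$subplots), tidx = tens$tree_species_index,
             pidx = tens$subplot_index, z = tens$dbh_scaled)
  jm <- jags.model(textConnection(model_str), data = jd, n.chains = 3,
                   n.adapt = 1500, quiet = TRUE,
                   inits = list(.RNG.name = "base::Mersenne-Twister",
                                .RNG.seed = 7))
  update(jm, 1000, progress.bar = "none")
  js <- coda.samples(jm, c("mu", "mu_b"), n.iter = 4000, thin = 4,
                     progress.bar = "none")
  jmeans <- colMeans(do.call(rbind, js))
  theirs <- c(jmeans[sprintf("mu[%d]", 1:6)], jmeans["mu_b"])
  expect_lt(max(abs(unname(ours) - unname(theirs))), 0.25)
})
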