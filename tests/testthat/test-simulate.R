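test_that("community simulation is reproducible and validates its config", {
  tr <- community_truth(n_species = 6, n_subplots = 3, trees_per_subplot = 5,
                        tree_species_probs = rep(1 / 6, 6))
  a <- simulate_community(tr, seed = 99)
  b <- simulate_community(tr, seed = 99)
  expect_identical(a$survey$trunk, b$survey$trunk)
  expect_identical(a$survey$branch, b$survey$branch)
  expect_identical(a$truth$alpha, b$truth$alpha)
  c <- simulate_community(tr, seed = 100)
  expect_false(identical(a$survey$trunk, c$survey$trunk))

  expect_error(community_truth(n_species = 0), ">= 1")
  expect_error(community_truth(tree_species_probs = rep(0.2, 6)), "summing to 1")
  expect_error(community_truth(hyper_mean = 0), "length 7")
})

test_that("a null community occupies half the trees", {
  tr <- community_truth(n_species = 1, n_subplots = 2,
                        trees_per_subplot = 5000,
                        tree_species_probs = rep(1 / 6, 6),
                        hyper_mean = rep(0, 7), hyper_sd = rep(0, 7),
                        subplot_sd_scale = 0)
  sim <- simulate_community(tr, seed = 17)
  occ <- mean(merge_trunk_branch(sim$survey)$y)
  expect_lt(abs(occ - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("a unit DBH slope shifts occupancy as the inverse logit predicts", {
  tr <- community_truth(n_species = 1, n_subplots = 2,
                        trees_per_subplot = 10000,
                        tree_species_probs = rep(1 / 6, 6),
                        hyper_mean = c(rep(0, 6), 1), hyper_sd = rep(0, 7),
                        subplot_sd_scale = 0)
  sim <- simulate_community(tr, seed = 23)
  tens <- merge_trunk_branch(sim$survey)
  sel <- abs(tens$dbh_scaled - 1) < 0.1
  phat <- mean(tens$y[1, sel])
  p_exp <- 1 / (1 + exp(-1))  # 0.731
  expect_lt(abs(phat - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / sum(sel)))
  # and the logistic slope is recovered
  fit <- suppressWarnings(glm(tens$y[1, ] ~ tens$dbh_scaled,
                              family = binomial))
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.1)
})

test_that("empirical logit occupancy regresses on truth with unit slope", {
  tr <- community_truth(n_species = 30, n_subplots = 2,
                        trees_per_subplot = 2000,
                        tree_species_probs = rep(1 / 6, 6),
                        hyper_mean = c(rep(-1, 6), 0),
                        hyper_sd = c(rep(1, 6), 0),
                        subplot_sd_scale = 0)
  sim <- simulate_community(tr, seed = 31)
  tens <- merge_trunk_branch(sim$survey)
  # with zero DBH/subplot effects, per-(species, host) occupancy is
  # inv-logit(alpha); compare on the logit scale where counts allow
  truth_logit <- as.numeric(sim$truth$alpha)
  emp <- unlist(lapply(1:6, function(t) {
    idx <- tens$tree_species_index == t
    rowMeans(tens$y[, idx, drop = FALSE])
  }))
  keep <- emp > 0.02 & emp < 0.98
  fit <- lm(log(emp[keep] / (1 - emp[keep])) ~ truth_logit[keep])
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.1)
})

test_that("stand-curve simulation honours the modified MMf in the noiseless limit", {
  tt <- stand_truth(i_max = c(10, 10), gamma_coeffs = 10,
                    beta_coeffs = log(2), sigma_p = 0)
  sim <- simulate_stand_curves(tt, seed = 1)
  u1 <- sim$acc$U_mean[sim$acc$subplot == "P01"]
  expect_equal(u1[1], 5)                      # gamma / beta at i = 1
  expect_equal(u1[1], mmf(1, 10, 2))
  expect_equal(mmf(1e9, 10, 2), 10, tolerance = 1e-6)  # asymptote
  tt2 <- stand_truth(i_max = 5, gamma_coeffs = 20, beta_coeffs = log(3),
                     sigma_p = 0)
  sim2 <- simulate_stand_curves(tt2, seed = 1)
  expect_equal(sim2$acc$U_mean[2], 10)        # 20 * 2 / (3 - 1 + 2)
  # half-saturation identity U(i = beta - 1) = gamma / 2
  expect_equal(mmf(3 - 1, 20, 3), 10)
})

test_that("stand-curve simulation enforces its support constraints", {
  expect_error(stand_truth(i_max = 5, gamma_coeffs = 10,
                           beta_coeffs = log(0.9)),
               "exceed 1")
  tt <- stand_truth(i_max = c(8, 8, 8), gamma_coeffs = 15,
                    beta_coeffs = log(1.2), sigma_beta = 3, sigma_p = 1)
  sim <- simulate_stand_curves(tt, seed = 2)
  expect_true(all(sim$beta > 1))
  expect_true(all(sim$gamma > 0))
  # monotone by default; exact law when monotone = FALSE
  for (pp in unique(sim$acc$subplot))
    expect_true(all(diff(sim$acc$U_mean[sim$acc$subplot == pp]) >= 0))
  sim_raw <- simulate_stand_curves(tt, seed = 2, monotone = FALSE)
  expect_identical(sim_raw$gamma, sim$gamma)
})

test_that("composition-varying subplots develop richer pooled species sets", {
  # a host-specialist community: wide between-host variance in preference,
  # so each lichen is common on a few hosts and near-absent on the rest;
  # a mixed stand covers more species' preferred hosts than a monoculture
  tr <- community_truth(n_species = 30, n_subplots = 2,
                        trees_per_subplot = 12,
                        tree_species_probs = rep(1 / 6, 6),
                        hyper_mean = c(rep(-3, 6), 0),
                        hyper_sd = c(rep(3, 6), 0),
                        subplot_sd_scale = 0)
  mix <- rbind(c(1, 0, 0, 0, 0, 0),                    # spruce monoculture
               c(0.25, 0.25, 0.25, 0.25, 0, 0))        # 4-species mixture
  diffs <- vapply(1:100, function(r) {
    sim <- simulate_full_stand(tr, mix, seed = 1000 + r)
    tens <- merge_trunk_branch(sim$survey)
    pooled <- vapply(1:2, function(p)
      sum(rowSums(tens$y[, tens$subplot_index == p, drop = FALSE]) > 0),
      numeric(1))
    pooled[2] - pooled[1]
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs) / (sd(diffs) / sqrt(length(diffs))), 2)

  # single-tree subplots produce curves of length one
  tr1 <- community_truth(n_species = 4, n_subplots = 3,
                         trees_per_subplot = 1,
                         tree_species_probs = rep(1 / 6, 6))
  s1 <- simulate_community(tr1, seed = 5)
  tab <- accumulation_table(s1$survey, s = 5, seed = 1)
  expect_true(all(table(tab$subplot) == 1))

  expect_error(simulate_full_stand(tr1, mix, seed = 1), "n_subplots x 6")
})
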