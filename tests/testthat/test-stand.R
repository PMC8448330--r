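test_that("stand design covariates are counted and scaled correctly", {
  p <- tempfile(fileext = ".csv")
  hdr <- "subplot,tree_id,tree_species,dbh_cm,A_trunk,A_branch"
  rows <- c(
    sprintf("P1,t%d,spruce,20,1,0", 1:5),
    sprintf("P1,t%d,pine,22,0,0", 6:8),
    sprintf("P1,t%d,birch,18,0,1", 9:10),
    "P2,t1,oak,30,1,1")
  writeLines(c(hdr, rows), p)
  d <- read_survey(p)
  des <- build_stand_design(d)
  r1 <- des[des$subplot == "P1", ]
  expect_equal(r1$n_tree_species, 3)
  expect_equal(r1$pct_spruce, 50)
  expect_equal(r1$pct_pine, 30)
  expect_equal(r1$pct_deciduous, 20)
  expect_equal(r1$n_trees, 10)
  r2 <- des[des$subplot == "P2", ]
  expect_equal(r2$n_tree_species, 1)
  expect_equal(r2$pct_deciduous, 100)
  expect_equal(r1$pct_spruce + r1$pct_pine + r1$pct_deciduous, 100)
  # scaled covariates carry their back-transformation
  sc <- attr(des, "scaling")
  expect_equal(des$mean_dbh_z * sc$mean_dbh["sd"] + sc$mean_dbh["mean"],
               des$mean_dbh, ignore_attr = TRUE)
  # a subplot with no trees is rejected
  d2 <- d
  d2$subplots <- c(d2$subplots, "P9")
  expect_error(build_stand_design(d2), "P9")
})

test_that("Gamma moment parameterisation converts and round-trips", {
  p <- gamma_params_from_mean_sd(2, 1)
  expect_equal(p$shape, 4)
  expect_equal(p$rate, 2)
  p2 <- gamma_params_from_mean_sd(1, 1)
  expect_equal(p2$shape, 1)   # Exponential(1)
  expect_equal(p2$rate, 1)
  set.seed(5)
  for (r in 1:10) {
    shape <- runif(1, 0.1, 20)
    rate <- runif(1, 0.1, 20)
    ms <- gamma_mean_sd(shape, rate)
    back <- gamma_params_from_mean_sd(ms$mu, ms$sd)
    expect_equal(back$shape, shape, tolerance = 1e-12)
    expect_equal(back$rate, rate, tolerance = 1e-12)
  }
  expect_error(gamma_params_from_mean_sd(-1, 1), "> 0")
  expect_error(gamma_mean_sd(0, 1), "> 0")
})

test_that("optimal composition follows the vertex algebra", {
  nm <- c("g:x", "g:x2", "h:x", "h:x2")
  draws <- matrix(rep(c(2, -1, 2, -1), each = 3), 3, 4,
                  dimnames = list(NULL, nm))
  f <- fake_stand(draws, subplots = "P1",
                  scaling = list(pct_spruce = c(mean = 40, sd = 20)))
  opt <- optimal_composition(f)
  expect_equal(unname(opt$gamma$summary["median"]), 60)  # vertex at +1 sd
  expect_equal(unname(opt$beta$summary["median"]), 60)

  # convex case: boundary maximum
  draws2 <- matrix(rep(c(0, 0.5, 0, 0.5), each = 3), 3, 4,
                   dimnames = list(NULL, nm))
  f2 <- fake_stand(draws2, subplots = "P1",
                   scaling = list(pct_spruce = c(mean = 40, sd = 20)))
  opt2 <- optimal_composition(f2)
  expect_true(unname(opt2$gamma$summary["median"]) %in% c(0, 100))
  # vertex outside [0, 100] is clipped
  draws3 <- matrix(rep(c(20, -1, 20, -1), each = 3), 3, 4,
                   dimnames = list(NULL, nm))
  f3 <- fake_stand(draws3, subplots = "P1",
                   scaling = list(pct_spruce = c(mean = 40, sd = 20)))
  expect_equal(unname(optimal_composition(f3)$gamma$summary["median"]), 100)

  f$variant <- "n_tree_species"
  expect_error(optimal_composition(f), "quadratic")
})

test_that("posterior predictive envelopes collapse and detect corruption", {
  # degenerate posterior pinned at known curve parameters
  P <- 2
  gam <- c(10, 20); bet <- c(2, 3)
  acc <- do.call(rbind, lapply(1:P, function(p)
    data.frame(subplot = sprintf("P%02d", p), i = 1:6,
               U_mean = mmf(1:6, gam[p], bet[p]))))
  acc <- structure(acc, class = c("accumulation_table", "data.frame"))
  nm <- c(sprintf("gamma[%d]", 1:P), sprintf("bpar[%d]", 1:P),
          sprintf("sigma[%d]", 1:P))
  draws <- matrix(rep(c(gam, bet - 1, 0, 0), each = 4), 4,
                  dimnames = list(NULL, nm))
  f <- fake_stand(draws, subplots = sprintf("P%02d", 1:P), acc = acc)
  ppc <- posterior_predictive_check(f)
  expect_equal(ppc$coverage, 1)
  expect_equal(ppc$table$pred_median, acc$U_mean, tolerance = 1e-6)
  expect_lt(max(ppc$table$pred_upper - ppc$table$pred_lower), 1e-6)

  # corrupt one subplot: its observations leave the collapsed envelope
  acc_bad <- acc
  acc_bad$U_mean[acc_bad$subplot == "P02"] <-
    acc_bad$U_mean[acc_bad$subplot == "P02"] + 10
  ppc2 <- posterior_predictive_check(f, acc = acc_bad)
  expect_lt(ppc2$coverage_by_subplot[["P02"]], 0.5)
  expect_equal(ppc2$coverage_by_subplot[["P01"]], 1)
})

test_that("the joint fit runs, is deterministic and supports its summaries", {
  set.seed(10)
  P <- 6
  gam <- runif(P, 12, 25); bet <- runif(P, 1.5, 3)
  acc <- do.call(rbind, lapply(1:P, function(p)
    data.frame(subplot = sprintf("P%02d", p), i = 1:8,
               U_mean = cummax(rnorm(8, mmf(1:8, gam[p], bet[p]), 0.5)))))
  acc <- structure(acc, class = c("accumulation_table", "data.frame"))
  design <- data.frame(subplot = sprintf("P%02d", 1:P), n_trees = 8,
                       n_tree_species = rep(1:3, 2),
                       pct_spruce = seq(10, 90, length.out = P),
                       pct_pine = 100 - seq(10, 90, length.out = P),
                       pct_deciduous = 0,
                       mean_dbh = rnorm(P, 20, 2))
  for (v in c("pct_spruce", "pct_pine", "mean_dbh"))
    design[[paste0(v, "_z")]] <- zscale(design[[v]])$scaled
  design$pct_deciduous_z <- NA_real_
  attr(design, "scaling") <- lapply(
    stats::setNames(nm = c("pct_spruce", "pct_pine", "mean_dbh")),
    function(v) c(mean = mean(design[[v]]), sd = sd(design[[v]])))

  ctrl <- fast_control(seed = 12, n_iter = 400L, thin = 4L)
  f1 <- suppressWarnings(stand_sac(acc, design, "n_tree_species",
                                   control = ctrl))
  f2 <- suppressWarnings(stand_sac(acc, design, "n_tree_species",
                                   control = ctrl))
  expect_identical(f1$chains, f2$chains)
  expect_true(all(gamma_draws(f1) > 0))
  expect_true(all(beta_draws(f1) > 1))   # shifted parameterisation

  dl <- diversity_levels(f1)
  expect_equal(nrow(dl$gamma$summary), 3)
  expect_true(all(dl$beta$summary$median > 1))

  surf <- composition_surface(f1)
  expect_equal(surf$pct_spruce + surf$pct_pine + surf$pct_deciduous,
               rep(100, P), tolerance = 1e-9)
  expect_true(all(is.finite(surf$gamma_median)))

  fit_line <- predict(f1, subplot = "P01")
  expect_equal(nrow(fit_line), 8)
  expect_true(all(diff(fit_line$fitted) > 0))
  res <- residuals(f1)
  expect_length(res, nrow(acc))

  # constant covariate for the requested variant is a collinearity error
  expect_error(suppressWarnings(stand_sac(acc, design, "pct_deciduous",
                                          control = ctrl)), "constant")
  # mismatched design rows are rejected
  expect_error(stand_sac(acc, design[-1, ], "n_tree_species",
                         control = ctrl), "match")
  expect_error(stand_sac(acc[acc$subplot %in% sprintf("P%02d", 1:4), ],
                         design, "n_tree_species", control = ctrl),
               "at least 5|match")
})

test_that("unshifted beta parameterisation also fits", {
  set.seed(11)
  P <- 5
  acc <- do.call(rbind, lapply(1:P, function(p)
    data.frame(subplot = sprintf("P%02d", p), i = 1:8,
               U_mean = cummax(rnorm(8, mmf(1:8, 15, 2.5), 0.5)))))
  acc <- structure(acc, class = c("accumulation_table", "data.frame"))
  design <- data.frame(subplot = sprintf("P%02d", 1:P), n_trees = 8,
                       n_tree_species = c(1, 2, 2, 3, 3),
                       pct_spruce = seq(20, 80, length.out = P),
                       pct_pine = 100 - seq(20, 80, length.out = P),
                       pct_deciduous = 0, mean_dbh = rnorm(P, 20, 2))
  for (v in c("pct_spruce", "pct_pine", "mean_dbh"))
    design[[paste0(v, "_z")]] <- zscale(design[[v]])$scaled
  design$pct_deciduous_z <- NA_real_
  attr(design, "scaling") <- lapply(
    stats::setNames(nm = c("pct_spruce", "pct_pine", "mean_dbh")),
    function(v) c(mean = mean(design[[v]]), sd = sd(design[[v]])))
  ctrl <- fast_control(seed = 14, n_iter = 200L, thin = 2L)
  f <- suppressWarnings(suppressMessages(
    stand_sac(acc, design, "pct_spruce", control = ctrl,
              beta_model = "unshifted")))
  expect_true(all(beta_draws(f) > 0))
  expect_s3_class(summary(f), "summary.stand_sac")
})

test_that("the joint fit beats independent two-stage curve fitting", {
  # short noisy curves (6 trees per subplot): hierarchical shrinkage should
  # estimate subplot gamma diversity at least as well as independent
  # per-subplot nonlinear least-squares fits
  set.seed(6)
  P <- 20
  gam <- rnorm(P, 20, 3)
  bet <- runif(P, 1.5, 3)
  set.seed(60)
  rows <- do.call(rbind, lapply(seq_len(P), function(p)
    data.frame(subplot = sprintf("P%02d", p), i = 1:6,
               U_mean = rnorm(6, mmf(1:6, gam[p], bet[p]), 1.5))))
  acc <- structure(rows, class = c("accumulation_table", "data.frame"))
  design <- data.frame(subplot = sprintf("P%02d", 1:P), n_trees = 6,
                       n_tree_species = sample(1:4, P, TRUE),
                       pct_spruce = runif(P, 0, 100), pct_pine = 0,
                       pct_deciduous = 0, mean_dbh = rnorm(P, 20, 3))
  design$pct_spruce_z <- zscale(design$pct_spruce)$scaled
  design$mean_dbh_z <- zscale(design$mean_dbh)$scaled
  attr(design, "scaling") <- list(pct_spruce = c(mean = 50, sd = 25),
                                  mean_dbh = c(mean = 20, sd = 3))
  ctrl <- sampler_control(n_chains = 3, n_iter = 3000, thin = 3,
                          adapt = 1000, burnin = 500, seed = 61)
  fit <- suppressWarnings(stand_sac(acc, design, "n_tree_species",
                                    control = ctrl))
  gm <- apply(gamma_draws(fit), 2, median)
  g2 <- vapply(seq_len(P), function(p) {
    d <- rows[rows$subplot == sprintf("P%02d", p), ]
    f <- tryCatch(nls(U_mean ~ g * i / (d0 + i), data = d,
                      start = list(g = max(d$U_mean) * 1.2, d0 = 1),
                      control = nls.control(warnOnly = TRUE)),
                  error = function(e) NULL)
    if (is.null(f)) max(d$U_mean) else coef(f)[["g"]]
  }, numeric(1))
  expect_lte(sqrt(mean((gm - gam)^2)), sqrt(mean((g2 - gam)^2)))
})
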