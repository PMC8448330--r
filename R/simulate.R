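#' Ground truth for a synthetic lichen community
#'
#' Parameter bundle for [simulate_community()], mirroring the generative
#' structure the tree-level occupancy model assumes: species-level
#' host-tree-species intercepts and a DBH slope drawn from community
#' (hyper)distributions on the logit scale, and per-species subplot random
#' effects with species-specific SDs drawn from a half-Cauchy distribution.
#'
#' Defaults emulate the study system: 117 lichen species across 59 subplots
#' of ~19 surveyed trees each (about 1,100 trees), host-tree frequencies
#' matching the surveyed stand composition (spruce and pine dominant, oak
#' very rare), a mostly-rare community (logit-scale intercept mean -4, SD 2,
#' giving an overall occupancy near 10%), a weak positive community DBH
#' effect, and stem diameters near 20 cm truncated at the 10 cm survey
#' threshold.
#'
#' @param n_species,n_subplots community dimensions (>= 1).
#' @param trees_per_subplot integer, or vector of length `n_subplots`.
#' @param tree_species_probs probabilities of the six host species in
#'   [TREE_SPECIES] order; must sum to 1.
#' @param hyper_mean,hyper_sd length-7 community mean/SD vectors (six host
#'   species intercepts then the DBH slope), logit scale; SDs may be 0.
#' @param subplot_sd_scale half-Cauchy scale of the per-species subplot
#'   effect SDs; 0 disables subplot effects.
#' @param dbh_mean,dbh_sd stem diameter distribution (cm), truncated below
#'   at 10 cm.
#' @return List of class `community_truth`.
#' @export
community_truth <- function(n_species = 117L, n_subplots = 59L,
                            trees_per_subplot = 19L,
                            tree_species_probs = c(381, 555, 116, 27, 19, 3) / 1101,
                            hyper_mean = c(rep(-4, 6), 0.08),
                            hyper_sd = c(rep(2, 6), 0.25),
                            subplot_sd_scale = 0.5,
                            dbh_mean = 20, dbh_sd = 6) {
  if (n_species < 1L || n_subplots < 1L || any(trees_per_subplot < 1L))
    stop("n_species, n_subplots and trees_per_subplot must all be >= 1")
  if (length(tree_species_probs) != 6L ||
      abs(sum(tree_species_probs) - 1) > 1e-12)
    stop("tree_species_probs must have 6 entries summing to 1")
  if (length(hyper_mean) != 7L || length(hyper_sd) != 7L)
    stop("hyper_mean and hyper_sd must have length 7 (6 intercepts + DBH slope)")
  if (any(hyper_sd < 0) || subplot_sd_scale < 0 || dbh_sd <= 0)
    stop("scale parameters must be non-negative (dbh_sd > 0)")
  structure(list(n_species = as.integer(n_species),
                 n_subplots = as.integer(n_subplots),
                 trees_per_subplot = as.integer(trees_per_subplot),
                 tree_species_probs = tree_species_probs,
                 hyper_mean = hyper_mean, hyper_sd = hyper_sd,
                 subplot_sd_scale = subplot_sd_scale,
                 dbh_mean = dbh_mean, dbh_sd = dbh_sd),
            class = "community_truth")
}

rtrunc_norm_low <- function(n, mean, sd, lower) {
  p0 <- stats::pnorm((lower - mean) / sd)
  mean + sd * stats::qnorm(p0 + stats::runif(n) * (1 - p0))
}

# Shared generative engine: `mixtures` is an n_subplots x 6 matrix of
# per-subplot host-tree-species probabilities.
simulate_survey_engine <- function(truth, mixtures, seed) {
  set.seed(seed)
  K <- truth$n_species
  P <- truth$n_subplots
  npp <- rep(truth$trees_per_subplot, length.out = P)
  N <- sum(npp)
  pidx <- rep.int(seq_len(P), npp)

  tidx <- integer(N)
  for (p in seq_len(P))
    tidx[pidx == p] <- sample.int(6L, npp[p], replace = TRUE,
                                  prob = mixtures[p, ])
  dbh <- rtrunc_norm_low(N, truth$dbh_mean, truth$dbh_sd, 10)
  z <- zscale(dbh)$scaled

  A <- matrix(stats::rnorm(K * 6, rep(truth$hyper_mean[1:6], each = K),
                           rep(truth$hyper_sd[1:6], each = K)), K, 6)
  b <- stats::rnorm(K, truth$hyper_mean[7], truth$hyper_sd[7])
  tau <- if (truth$subplot_sd_scale > 0)
    rhalfcauchy(K, truth$subplot_sd_scale) else numeric(K)
  U <- matrix(stats::rnorm(K * P, 0, rep(tau, P)), K, P)

  eta <- A[, tidx, drop = FALSE] + outer(b, z) + U[, pidx, drop = FALSE]
  prob <- inv_logit(eta)
  y <- matrix(stats::rbinom(K * N, 1L, prob), K, N)

  # Substrate split is cosmetic (models merge trunk and branches): each
  # presence lands on the trunk, the branches, or both with equal chance.
  split <- matrix(sample.int(3L, K * N, replace = TRUE), K, N)
  trunk <- t(y * (split != 2L))
  branch <- t(y * (split != 1L))
  species <- sprintf("sp%03d", seq_len(K))
  colnames(trunk) <- colnames(branch) <- species
  subplots <- sprintf("P%02d", seq_len(P))
  trees <- data.frame(
    subplot = subplots[pidx],
    tree_id = unlist(lapply(npp, function(n) sprintf("t%03d", seq_len(n)))),
    tree_species = factor(TREE_SPECIES[tidx], levels = TREE_SPECIES),
    dbh_cm = dbh, stringsAsFactors = FALSE)

  survey <- new_lichen_survey(trees, trunk, branch, species, subplots)
  validate_survey(survey)
  list(survey = survey,
       truth = list(alpha = A, b = b, tau = tau, subplot_effect = U,
                    hyper_mean = truth$hyper_mean,
                    hyper_sd = truth$hyper_sd,
                    prob = prob, tree_species_index = tidx,
                    subplot_index = pidx, dbh_scaled = z))
}

#' Simulate a lichen survey from known community parameters
#'
#' Draws species-level coefficients from the community distributions in a
#' [community_truth()], per-species subplot effects from
#' Normal(0, tau_k) with tau_k half-Cauchy distributed, stem diameters from
#' a truncated Normal, and occurrences from Bernoulli(inverse-logit(linear
#' predictor)), with the DBH covariate entering Z-scaled as in the fitted
#' model. A fixed seed yields bit-identical output.
#'
#' @param truth a [community_truth()].
#' @param seed integer seed.
#' @return List with `$survey` (a `lichen_survey`) and `$truth` (the drawn
#'   species-level parameters: `alpha` (K x 6), `b`, `tau`,
#'   `subplot_effect`, plus the occurrence probability matrix and aligned
#'   covariate indices).
#' @export
simulate_community <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "community_truth"))
  mixtures <- matrix(truth$tree_species_probs, truth$n_subplots, 6,
                     byrow = TRUE)
  simulate_survey_engine(truth, mixtures, seed)
}

#' Simulate a survey whose subplots differ in tree-species mixture
#'
#' End-to-end fixture for the full ingest -> accumulate -> stand-model
#' pipeline: the community parameters are shared, but each subplot draws its
#' trees from its own host-species mixture, so per-subplot species pools
#' (and hence gamma/beta diversity) vary with composition.
#'
#' @param truth a [community_truth()].
#' @param mixtures `n_subplots` x 6 matrix of per-subplot host-species
#'   probabilities (rows sum to 1, [TREE_SPECIES] order).
#' @param seed integer seed.
#' @return As [simulate_community()].
#' @export
simulate_full_stand <- function(truth, mixtures, seed = 1L) {
  stopifnot(inherits(truth, "community_truth"))
  mixtures <- as.matrix(mixtures)
  if (nrow(mixtures) != truth$n_subplots || ncol(mixtures) != 6L)
    stop("mixtures must be n_subplots x 6")
  if (any(abs(rowSums(mixtures) - 1) > 1e-9))
    stop("each mixture row must sum to 1")
  simulate_survey_engine(truth, mixtures, seed)
}

#' Ground truth for synthetic stand-level accumulation curves
#'
#' Parameter bundle for [simulate_stand_curves()], mirroring the stand-level
#' hierarchy: per-subplot gamma diversity Normal around a linear predictor
#' (identity link), per-subplot beta diversity Gamma distributed around a
#' log-linear predictor, and Normal observation noise around the modified
#' Michaelis-Menten curve.
#'
#' @param i_max per-subplot tree counts (vector; length = number of
#'   subplots).
#' @param gamma_coeffs,beta_coeffs coefficient vectors for the gamma
#'   (identity link) and beta (log link) linear predictors.
#' @param X_gamma,X_beta design matrices (subplots x coefficients); default
#'   intercept-only.
#' @param sigma_gamma,sigma_beta between-subplot SDs of gamma and beta
#'   (0 = deterministic regression means).
#' @param sigma_p observation noise SD of the accumulated counts; scalar or
#'   per subplot (0 = noiseless curves).
#' @return List of class `stand_truth`.
#' @export
stand_truth <- function(i_max, gamma_coeffs, beta_coeffs,
                        X_gamma = NULL, X_beta = NULL,
                        sigma_gamma = 0, sigma_beta = 0, sigma_p = 1) {
  P <- length(i_max)
  if (P < 1L || any(i_max < 1L)) stop("i_max must be >= 1 per subplot")
  X_gamma <- X_gamma %||% matrix(1, P, 1)
  X_beta <- X_beta %||% matrix(1, P, 1)
  stopifnot(nrow(X_gamma) == P, nrow(X_beta) == P,
            ncol(X_gamma) == length(gamma_coeffs),
            ncol(X_beta) == length(beta_coeffs))
  if (sigma_gamma < 0 || sigma_beta < 0 || any(sigma_p < 0))
    stop("sd parameters must be >= 0")
  mu_beta <- exp(drop(X_beta %*% beta_coeffs))
  if (any(mu_beta <= 1))
    stop("implied beta-diversity means must exceed 1 across the design")
  structure(list(i_max = as.integer(i_max), gamma_coeffs = gamma_coeffs,
                 beta_coeffs = beta_coeffs, X_gamma = X_gamma,
                 X_beta = X_beta, sigma_gamma = sigma_gamma,
                 sigma_beta = sigma_beta,
                 sigma_p = rep(sigma_p, length.out = P)),
            class = "stand_truth")
}

#' Simulate per-subplot accumulation curves from known diversity parameters
#'
#' Draws gamma_p from Normal(X gamma_coeffs, sigma_gamma), beta_p from a
#' Gamma distribution with mean exp(X beta_coeffs) and SD sigma_beta
#' (resampling any draw <= 1, since true beta diversity cannot fall below
#' one), and accumulated counts U_i from Normal(mmf(i, gamma_p, beta_p),
#' sigma_p) truncated below at the running maximum so the synthetic curves
#' are non-decreasing, as accumulation counts are by construction.
#'
#' @param truth a [stand_truth()].
#' @param seed integer seed.
#' @param max_retries resampling cap for gamma_p <= 0 or beta_p <= 1 draws.
#' @param monotone enforce non-decreasing curves by truncating each draw at
#'   the running maximum (default TRUE, matching real accumulation counts).
#'   Set FALSE to draw from the model's exact Normal observation law, e.g.
#'   for calibration experiments, where the truncation would act as a
#'   deliberate misspecification.
#' @return List with `$acc` (an `accumulation_table` data.frame: subplot,
#'   i, U_mean), `$gamma`, `$beta` (the true per-subplot diversities).
#' @export
simulate_stand_curves <- function(truth, seed = 1L, max_retries = 100L,
                                  monotone = TRUE) {
  stopifnot(inherits(truth, "stand_truth"))
  set.seed(seed)
  P <- length(truth$i_max)
  mu_g <- drop(truth$X_gamma %*% truth$gamma_coeffs)
  mu_b <- exp(drop(truth$X_beta %*% truth$beta_coeffs))

  draw_until <- function(draw1, ok) {
    x <- draw1()
    tries <- 0L
    while (any(!ok(x))) {
      tries <- tries + 1L
      if (tries > max_retries)
        stop("could not draw valid diversity parameters within retry cap")
      bad <- !ok(x)
      x[bad] <- draw1()[bad]
    }
    x
  }
  gamma <- if (truth$sigma_gamma > 0)
    draw_until(function() stats::rnorm(P, mu_g, truth$sigma_gamma),
               function(x) x > 0)
  else mu_g
  beta <- if (truth$sigma_beta > 0) {
    shp <- gamma_params_from_mean_sd(mu_b, truth$sigma_beta)
    draw_until(function() stats::rgamma(P, shape = shp$shape, rate = shp$rate),
               function(x) x > 1)
  } else mu_b

  rows <- lapply(seq_len(P), function(p) {
    i <- seq_len(truth$i_max[p])
    mu <- mmf(i, gamma[p], beta[p])
    U <- stats::rnorm(length(i), mu, truth$sigma_p[p])
    if (monotone) U <- cummax(U)
    data.frame(subplot = sprintf("P%02d", p), i = i, U_mean = U,
               stringsAsFactors = FALSE)
  })
  acc <- do.call(rbind, rows)
  rownames(acc) <- NULL
  acc <- structure(acc, s = NA_integer_, seed = seed, method = "simulated",
                   i_max = stats::setNames(truth$i_max,
                                           sprintf("P%02d", seq_len(P))),
                   class = c("accumulation_table", "data.frame"))
  list(acc = acc, gamma = gamma, beta = beta)
}
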