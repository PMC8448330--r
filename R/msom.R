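#' Prior settings for the tree-level occupancy model
#'
#' Vague priors on the logit scale: Normal(0, `hyper_mean_sd`) hyperpriors
#' for the community means, half-Cauchy(`hyper_sd_scale`) hyperpriors for
#' the community SDs, and a Uniform(0, `tau_scale_upper`) hyperprior for the
#' scale of the half-Cauchy prior on the subplot-effect SDs.
#'
#' @param hyper_mean_sd SD of the Normal hyperprior on community means.
#' @param hyper_sd_scale scale of the half-Cauchy hyperprior on community
#'   SDs.
#' @param tau_scale_upper upper limit of the Uniform hyperprior on the
#'   subplot-effect half-Cauchy scale.
#' @return List of class `msom_priors`.
#' @export
msom_priors <- function(hyper_mean_sd = 10, hyper_sd_scale = 5,
                        tau_scale_upper = 5) {
  stopifnot(hyper_mean_sd > 0, hyper_sd_scale > 0, tau_scale_upper > 0)
  structure(list(hyper_mean_sd = hyper_mean_sd,
                 hyper_sd_scale = hyper_sd_scale,
                 tau_scale_upper = tau_scale_upper),
            class = "msom_priors")
}

#' Bernoulli log-likelihood of the tree-level occupancy model
#'
#' Complete-detection likelihood: occurrence of lichen species k on tree i
#' is Bernoulli with logit(P) = alpha[k, t(i)] + b[k] * dbh_scaled(i) +
#' u[k, p(i)] (host-tree-species intercept in cell-means coding, DBH slope,
#' subplot effect). Probabilities are clamped to [1e-12, 1 - 1e-12] so the
#' result is always finite.
#'
#' @param params list with `alpha` (K x 6 matrix), `b` (length K), and
#'   optionally `subplot_effect` (K x P matrix; defaults to 0).
#' @param data an `occurrence_tensor`.
#' @return The summed log-likelihood (scalar).
#' @export
tree_log_likelihood <- function(params, data) {
  K <- nrow(data$y)
  N <- ncol(data$y)
  P <- length(data$subplots)
  if (!is.matrix(params$alpha) || !all(dim(params$alpha) == c(K, 6)))
    stop("alpha must be a ", K, " x 6 matrix")
  if (length(params$b) != K) stop("b must have length ", K)
  U <- params$subplot_effect %||% matrix(0, K, P)
  if (!all(dim(U) == c(K, P))) stop("subplot_effect must be ", K, " x ", P)
  eta <- params$alpha[, data$tree_species_index, drop = FALSE] +
    outer(params$b, data$dbh_scaled) +
    U[, data$subplot_index, drop = FALSE]
  p <- clamp_prob(inv_logit(eta))
  sum(data$y * log(p) + (1 - data$y) * log1p(-p))
}

# --- one chain of the specialised adaptive MWG sampler ---------------------
msom_chain <- function(tens, control, priors, chain_seed, mu_offset,
                       subplot_effect, store_subplot) {
  set.seed(chain_seed)
  y <- tens$y
  K <- nrow(y); N <- ncol(y); P <- length(tens$subplots)
  tidx <- tens$tree_species_index
  pidx <- tens$subplot_index
  z <- tens$dbh_scaled
  Tind <- matrix(0, N, 6); Tind[cbind(seq_len(N), tidx)] <- 1
  Pind <- matrix(0, N, P); Pind[cbind(seq_len(N), pidx)] <- 1
  S_yz <- drop(y %*% z)
  species_specific <- subplot_effect == "species"

  # dispersed initials: community means offset per chain
  mu_a <- rep(mu_offset, 6)
  sg_a <- rep(1, 6)
  mu_b <- 0; sg_b <- 1
  A <- matrix(stats::rnorm(K * 6, mu_a[1], 0.25), K, 6)
  b <- stats::rnorm(K, 0, 0.1)
  if (species_specific) {
    tau <- rep(0.2, K); U <- matrix(0, K, P)
  } else {
    tau <- 0.2; u_shared <- numeric(P); U <- matrix(0, K, P)
  }
  c_tau <- 1
  v_ctau <- logit(c_tau / priors$tau_scale_upper)

  eta <- A[, tidx, drop = FALSE] + outer(b, z) + U[, pidx, drop = FALSE]
  Leta <- log1pexp(eta)

  # adaptive log proposal scales
  lsA <- matrix(log(0.5), K, 6); lsb <- rep(log(0.3), K)
  lsU <- if (species_specific) matrix(log(0.3), K, P) else rep(log(0.3), P)
  lstau <- if (species_specific) rep(log(0.5), K) else log(0.5)
  lssg <- rep(log(0.3), 7)   # 6 sigma_alpha + sigma_b
  lsc <- log(0.5)
  aA <- matrix(0, K, 6); ab <- numeric(K)
  aU <- if (species_specific) matrix(0, K, P) else numeric(P)
  atau <- numeric(length(lstau)); asg <- numeric(7); ac <- 0

  monitor_u <- store_subplot && species_specific
  n_mon <- K * 6 + K + length(tau) + 6 + 6 + 2 + 1 +
    if (monitor_u) K * P else 0
  n_keep <- control$n_iter %/% control$thin
  keep <- matrix(NA_real_, n_keep, n_mon)
  kept <- 0L
  total <- control$adapt + control$burnin + control$n_iter
  batch_len <- 50L; batch_no <- 0L
  s0sq <- priors$hyper_mean_sd^2

  for (iter in seq_len(total)) {
    # -- host-tree-species intercepts alpha[k, t], vectorised over (k, t) --
    dA <- matrix(stats::rnorm(K * 6, 0, exp(lsA)), K, 6)
    eta1 <- eta + dA[, tidx, drop = FALSE]
    Leta1 <- log1pexp(eta1)
    Dll <- (y * dA[, tidx, drop = FALSE] - (Leta1 - Leta)) %*% Tind
    MU <- matrix(mu_a, K, 6, byrow = TRUE)
    SG <- matrix(sg_a, K, 6, byrow = TRUE)
    dpr <- ((A - MU)^2 - (A + dA - MU)^2) / (2 * SG^2)
    acc <- matrix(log(stats::runif(K * 6)), K, 6) < Dll + dpr
    if (any(acc)) {
      dAacc <- dA * acc
      A <- A + dAacc
      eta <- eta + dAacc[, tidx, drop = FALSE]
      Leta <- log1pexp(eta)
    }
    aA <- aA + acc

    # -- DBH slopes b[k] --
    db <- stats::rnorm(K, 0, exp(lsb))
    eta1 <- eta + outer(db, z)
    Leta1 <- log1pexp(eta1)
    Dll <- db * S_yz - rowSums(Leta1 - Leta)
    dpr <- ((b - mu_b)^2 - (b + db - mu_b)^2) / (2 * sg_b^2)
    accb <- log(stats::runif(K)) < Dll + dpr
    if (any(accb)) {
      b[accb] <- b[accb] + db[accb]
      eta <- eta + outer(db * accb, z)
      Leta <- log1pexp(eta)
    }
    ab <- ab + accb

    # -- subplot effects --
    if (species_specific) {
      dU <- matrix(stats::rnorm(K * P, 0, exp(lsU)), K, P)
      eta1 <- eta + dU[, pidx, drop = FALSE]
      Leta1 <- log1pexp(eta1)
      Dll <- (y * dU[, pidx, drop = FALSE] - (Leta1 - Leta)) %*% Pind
      TAU <- matrix(tau, K, P)
      dpr <- (U^2 - (U + dU)^2) / (2 * TAU^2)
      accU <- matrix(log(stats::runif(K * P)), K, P) < Dll + dpr
      if (any(accU)) {
        dUacc <- dU * accU
        U <- U + dUacc
        eta <- eta + dUacc[, pidx, drop = FALSE]
        Leta <- log1pexp(eta)
      }
      aU <- aU + accU
    } else {
      du <- stats::rnorm(P, 0, exp(lsU))
      eta1 <- eta + matrix(du[pidx], K, N, byrow = TRUE)
      Leta1 <- log1pexp(eta1)
      ccol <- colSums(y) * du[pidx] - colSums(Leta1 - Leta)
      Dll <- drop(rowsum(ccol, pidx, reorder = TRUE))
      dpr <- (u_shared^2 - (u_shared + du)^2) / (2 * tau^2)
      accu <- log(stats::runif(P)) < Dll + dpr
      if (any(accu)) {
        u_shared[accu] <- u_shared[accu] + du[accu]
        eta <- eta + matrix((du * accu)[pidx], K, N, byrow = TRUE)
        Leta <- log1pexp(eta)
      }
      U <- matrix(u_shared, K, P, byrow = TRUE)
      aU <- aU + accu
    }

    # -- subplot-effect SDs tau (log-scale RW) --
    if (species_specific) {
      SSU <- rowSums(U^2)
      tau1 <- tau * exp(stats::rnorm(K, 0, exp(lstau)))
      lt0 <- -P * log(tau) - SSU / (2 * tau^2) + dhalfcauchy_log(tau, c_tau)
      lt1 <- -P * log(tau1) - SSU / (2 * tau1^2) + dhalfcauchy_log(tau1, c_tau)
      acct <- log(stats::runif(K)) < lt1 - lt0 + log(tau1) - log(tau)
      tau[acct] <- tau1[acct]
      atau <- atau + acct
    } else {
      SSU <- sum(u_shared^2)
      tau1 <- tau * exp(stats::rnorm(1, 0, exp(lstau)))
      lt0 <- -P * log(tau) - SSU / (2 * tau^2) + dhalfcauchy_log(tau, c_tau)
      lt1 <- -P * log(tau1) - SSU / (2 * tau1^2) + dhalfcauchy_log(tau1, c_tau)
      if (log(stats::runif(1)) < lt1 - lt0 + log(tau1) - log(tau)) {
        tau <- tau1; atau <- atau + 1
      }
    }

    # -- community means (conjugate Gibbs given sigmas) --
    prec <- K / sg_a^2 + 1 / s0sq
    mu_a <- stats::rnorm(6, (colSums(A) / sg_a^2) / prec, sqrt(1 / prec))
    precb <- K / sg_b^2 + 1 / s0sq
    mu_b <- stats::rnorm(1, (sum(b) / sg_b^2) / precb, sqrt(1 / precb))

    # -- community SDs (log-scale RW, half-Cauchy prior) --
    SSa <- colSums(sweep(A, 2, mu_a)^2)
    sg1 <- sg_a * exp(stats::rnorm(6, 0, exp(lssg[1:6])))
    l0 <- -K * log(sg_a) - SSa / (2 * sg_a^2) +
      dhalfcauchy_log(sg_a, priors$hyper_sd_scale)
    l1 <- -K * log(sg1) - SSa / (2 * sg1^2) +
      dhalfcauchy_log(sg1, priors$hyper_sd_scale)
    accs <- log(stats::runif(6)) < l1 - l0 + log(sg1) - log(sg_a)
    sg_a[accs] <- sg1[accs]
    asg[1:6] <- asg[1:6] + accs

    SSb <- sum((b - mu_b)^2)
    sgb1 <- sg_b * exp(stats::rnorm(1, 0, exp(lssg[7])))
    l0 <- -K * log(sg_b) - SSb / (2 * sg_b^2) +
      dhalfcauchy_log(sg_b, priors$hyper_sd_scale)
    l1 <- -K * log(sgb1) - SSb / (2 * sgb1^2) +
      dhalfcauchy_log(sgb1, priors$hyper_sd_scale)
    if (log(stats::runif(1)) < l1 - l0 + log(sgb1) - log(sg_b)) {
      sg_b <- sgb1; asg[7] <- asg[7] + 1
    }

    # -- half-Cauchy scale of tau, Uniform(0, upper) hyperprior, logit RW --
    v1 <- v_ctau + stats::rnorm(1, 0, exp(lsc))
    c1 <- priors$tau_scale_upper * inv_logit(v1)
    jac <- function(cc) log(cc * (priors$tau_scale_upper - cc) /
                              priors$tau_scale_upper)
    l0 <- sum(dhalfcauchy_log(tau, c_tau)) + jac(c_tau)
    l1 <- sum(dhalfcauchy_log(tau, c1)) + jac(c1)
    if (log(stats::runif(1)) < l1 - l0) {
      c_tau <- c1; v_ctau <- v1; ac <- ac + 1
    }

    # -- proposal-scale adaptation (adaptation phase only) --
    if (iter <= control$adapt && iter %% batch_len == 0L) {
      batch_no <- batch_no + 1L
      lsA <- adapt_scale(lsA, aA / batch_len, batch_no); aA[] <- 0
      lsb <- adapt_scale(lsb, ab / batch_len, batch_no); ab[] <- 0
      lsU <- adapt_scale(lsU, aU / batch_len, batch_no); aU[] <- 0
      lstau <- adapt_scale(lstau, atau / batch_len, batch_no); atau[] <- 0
      lssg <- adapt_scale(lssg, asg / batch_len, batch_no); asg[] <- 0
      lsc <- adapt_scale(lsc, ac / batch_len, batch_no); ac <- 0
    }

    post <- iter - control$adapt - control$burnin
    if (post > 0L && post %% control$thin == 0L) {
      kept <- kept + 1L
      keep[kept, ] <- c(A, b, tau, mu_a, sg_a, mu_b, sg_b, c_tau,
                        if (monitor_u) U)
    }
  }
  keep
}

msom_param_names <- function(K, P, n_tau, monitor_u) {
  c(sprintf("alpha[%d,%d]", rep(seq_len(K), 6), rep(1:6, each = K)),
    sprintf("b[%d]", seq_len(K)),
    if (n_tau > 1) sprintf("tau[%d]", seq_len(K)) else "tau",
    sprintf("mu_alpha[%d]", 1:6), sprintf("sigma_alpha[%d]", 1:6),
    "mu_b", "sigma_b", "c_tau",
    if (monitor_u) sprintf("u[%d,%d]", rep(seq_len(K), P),
                           rep(seq_len(P), each = K)))
}

#' Fit the tree-level multi-species occupancy model
#'
#' Complete-detection multi-species occupancy model: occurrence of lichen
#' species k on tree i in subplot p is Bernoulli with
#' logit(P) = alpha[k, t(i)] + b[k] * dbh + u[k, p]. Host-tree-species
#' intercepts use cell-means coding (one intercept per host species, no
#' reference level). Species-level coefficients shrink toward community
#' means through Normal priors whose means and SDs carry vague Normal and
#' half-Cauchy hyperpriors; subplot-effect SDs carry a half-Cauchy prior
#' whose scale has a Uniform(0, 5) hyperprior. Sampling uses a specialised
#' adaptive Metropolis-within-Gibbs sweep (vectorised over species) with
#' conjugate Gibbs updates for the community means, run as multiple chains
#' from over-dispersed starting points, and attaches a Gelman-Rubin
#' convergence report.
#'
#' @param data an `occurrence_tensor` (or a `lichen_survey`, merged
#'   automatically with [merge_trunk_branch()]).
#' @param control a [sampler_control()].
#' @param priors an [msom_priors()].
#' @param subplot_effect `"species"` (default: species-specific subplot
#'   effects with species-specific SDs) or `"shared"` (one subplot effect
#'   shared by all species).
#' @param store_subplot also record the subplot-effect draws (default TRUE;
#'   they are not needed for occurrence or richness prediction).
#' @return An object of class `msom`: per-chain draw matrices (`$chains`),
#'   the convergence report (`$convergence`), data, control and prior
#'   settings.
#' @seealso [predict_occurrence()], [predict_richness()],
#'   [pairwise_richness()]
#' @export
msom <- function(data, control = sampler_control(),
                 priors = msom_priors(),
                 subplot_effect = c("species", "shared"),
                 store_subplot = TRUE) {
  subplot_effect <- match.arg(subplot_effect)
  tens <- if (inherits(data, "lichen_survey")) merge_trunk_branch(data)
          else data
  stopifnot(inherits(tens, "occurrence_tensor"))
  if (length(tens$subplots) < 2L) stop("need at least 2 subplots")
  K <- nrow(tens$y); P <- length(tens$subplots)

  seeds <- chain_seeds(control$seed, control$n_chains)
  offsets <- control$init_dispersion *
    (seq_len(control$n_chains) - (control$n_chains + 1) / 2)
  monitor_u <- store_subplot && subplot_effect == "species"
  nms <- msom_param_names(K, P,
                          n_tau = if (subplot_effect == "species") K else 1L,
                          monitor_u = monitor_u)
  chains <- vector("list", control$n_chains)
  for (ch in seq_len(control$n_chains)) {
    m <- msom_chain(tens, control, priors, seeds[ch], offsets[ch],
                    subplot_effect, store_subplot)
    colnames(m) <- nms
    chains[[ch]] <- m
  }

  # converge gate on the structural parameters (subplot effects excluded)
  core <- nms[!startsWith(nms, "u[")]
  conv <- if (control$n_chains >= 2L)
    convergence_report(lapply(chains, function(m) m[, core, drop = FALSE]),
                       control$psrf_threshold, control$ess_floor)
  else NULL
  if (!is.null(conv) && !conv$pass)
    warning("MSOM did not meet the PSRF < ", control$psrf_threshold,
            " gate for ", length(conv$flagged), " parameter(s)")

  structure(list(chains = chains, parameters = nms, data = tens,
                 control = control, priors = priors,
                 subplot_effect = subplot_effect,
                 convergence = conv, seeds = seeds),
            class = "msom")
}

# Pooled draws (all chains stacked) for a parameter-name prefix.
msom_pooled <- function(object, cols) {
  do.call(rbind, lapply(object$chains, function(m) m[, cols, drop = FALSE]))
}

# Draws of alpha as a [draw, species, tree-species] array.
msom_alpha_draws <- function(object) {
  K <- nrow(object$data$y)
  cols <- sprintf("alpha[%d,%d]", rep(seq_len(K), 6), rep(1:6, each = K))
  d <- msom_pooled(object, cols)
  array(d, dim = c(nrow(d), K, 6))
}

#' Posterior occurrence probabilities per lichen species and host tree
#'
#' Evaluates, for each retained draw, the occurrence probability of every
#' lichen species on a tree of the requested host species with DBH at the
#' survey mean (dbh_scaled = 0) and subplot effect 0, and summarises as
#' median and equal-tailed 95% credible interval. `"average"` gives the
#' probability for an average tree: by default the six host-species linear
#' predictors are averaged per draw on the logit scale before the inverse
#' logit; `average_scale = "probability"` averages the six probabilities
#' instead.
#'
#' @param object a fitted [msom()].
#' @param tree_species one of [TREE_SPECIES] or `"average"`.
#' @param average_scale `"logit"` (default) or `"probability"`.
#' @return data.frame with `species`, `median`, `lower`, `upper`.
#' @export
predict_occurrence <- function(object, tree_species = "average",
                               average_scale = c("logit", "probability")) {
  average_scale <- match.arg(average_scale)
  stopifnot(inherits(object, "msom"))
  a <- msom_alpha_draws(object)
  p <- occurrence_prob_draws(a, tree_species, average_scale)
  s <- posterior_summary(p)
  data.frame(species = object$data$species,
             median = s$median, lower = s$lower, upper = s$upper,
             stringsAsFactors = FALSE)
}

occurrence_prob_draws <- function(alpha_array, tree_species, average_scale) {
  if (tree_species == "average") {
    if (average_scale == "logit")
      inv_logit(apply(alpha_array, c(1, 2), mean))
    else apply(inv_logit(alpha_array), c(1, 2), mean)
  } else {
    t_i <- match(tree_species, TREE_SPECIES)
    if (is.na(t_i)) stop("unknown tree species: ", tree_species)
    inv_logit(alpha_array[, , t_i, drop = TRUE])
  }
}

#' Posterior expected lichen richness on a tree of a given host species
#'
#' Per retained draw, richness is the sum over all lichen species of the
#' occurrence probability on the requested host species (DBH at the survey
#' mean, subplot effect 0).
#'
#' @inheritParams predict_occurrence
#' @return List with `draws` (numeric vector, one per retained draw) and
#'   `summary` (median, lower, upper).
#' @export
predict_richness <- function(object, tree_species = "average",
                             average_scale = c("logit", "probability")) {
  average_scale <- match.arg(average_scale)
  stopifnot(inherits(object, "msom"))
  a <- msom_alpha_draws(object)
  p <- occurrence_prob_draws(a, tree_species, average_scale)
  if (is.null(dim(p))) p <- matrix(p, ncol = 1)
  r <- rowSums(p)
  list(draws = r, summary = posterior_summary(r))
}

#' Pairwise comparison of tree-level lichen richness across host species
#'
#' Draw-matched differences in expected lichen richness between every pair
#' of host tree species: 95% credible intervals of the differences and the
#' exceedance probability that the column species hosts more lichen species
#' than the row species (the Bayesian analogue of an ANOVA's pairwise
#' contrasts).
#'
#' @param object a fitted [msom()].
#' @return As [pairwise_comparison()], with host tree species as groups,
#'   plus a `richness` element holding the per-species richness summaries.
#' @export
pairwise_richness <- function(object) {
  stopifnot(inherits(object, "msom"))
  a <- msom_alpha_draws(object)
  r <- vapply(TREE_SPECIES, function(sp)
    rowSums(inv_logit(a[, , match(sp, TREE_SPECIES), drop = TRUE])),
    numeric(dim(a)[1]))
  if (is.null(dim(r))) r <- matrix(r, nrow = 1,
                                   dimnames = list(NULL, TREE_SPECIES))
  out <- pairwise_comparison(r)
  out$richness <- posterior_summary(r)
  out
}

#' @export
print.msom <- function(x, ...) {
  K <- nrow(x$data$y)
  cat("Multi-species occupancy model (complete detection)\n")
  cat(sprintf("  %d lichen species, %d trees, %d subplots\n",
              K, ncol(x$data$y), length(x$data$subplots)))
  cat(sprintf("  %d chains x %d retained draws (thin %d)\n",
              x$control$n_chains, nrow(x$chains[[1]]), x$control$thin))
  if (!is.null(x$convergence))
    cat(sprintf("  Convergence: %s (max PSRF %.3f)\n",
                if (x$convergence$pass) "PASS" else "FAIL",
                max(x$convergence$psrf)))
  invisible(x)
}

#' @export
summary.msom <- function(object, ...) {
  hy <- c(sprintf("mu_alpha[%d]", 1:6), sprintf("sigma_alpha[%d]", 1:6),
          "mu_b", "sigma_b", "c_tau")
  s <- posterior_summary(msom_pooled(object, hy))
  s$parameter <- c(paste0("community mean: ", TREE_SPECIES),
                   paste0("community sd: ", TREE_SPECIES),
                   "community mean: dbh", "community sd: dbh",
                   "subplot-sd scale")
  structure(list(hyper = s, convergence = object$convergence),
            class = "summary.msom")
}

#' @export
print.summary.msom <- function(x, ...) {
  cat("Community hyperparameters (logit scale):\n")
  print(x$hyper, digits = 3)
  if (!is.null(x$convergence)) print(x$convergence)
  invisible(x)
}

#' @export
coef.msom <- function(object, ...) {
  hy <- c(sprintf("mu_alpha[%d]", 1:6), "mu_b")
  m <- colMeans(msom_pooled(object, hy))
  stats::setNames(m, c(paste0("mu_", TREE_SPECIES), "mu_dbh"))
}

#' @export
plot.msom <- function(x, ...) {
  r <- lapply(TREE_SPECIES, function(sp) predict_richness(x, sp)$summary)
  med <- vapply(r, `[[`, numeric(1), "median")
  lo <- vapply(r, `[[`, numeric(1), "lower")
  hi <- vapply(r, `[[`, numeric(1), "upper")
  ord <- order(med)
  graphics::plot(seq_along(ord), med[ord], ylim = range(lo, hi), pch = 19,
                 xaxt = "n", xlab = "", ylab = "Expected lichen richness",
                 main = "Tree-level lichen richness by host species", ...)
  graphics::axis(1, at = seq_along(ord), labels = TREE_SPECIES[ord], las = 2)
  graphics::segments(seq_along(ord), lo[ord], seq_along(ord), hi[ord])
  invisible(x)
}
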