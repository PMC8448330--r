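#' Moment parameterisation of the Gamma distribution
#'
#' The stand-level model specifies Gamma distributions by mean and SD;
#' these helpers convert to and from the shape/rate parameterisation:
#' shape = mean^2/sd^2, rate = mean/sd^2 (implied mean `mu`, variance
#' `sd^2`).
#'
#' @param mu,sd mean and standard deviation, both > 0.
#' @return `gamma_params_from_mean_sd`: list with `shape` and `rate`;
#'   `gamma_mean_sd`: list with `mu` and `sd`.
#' @export
gamma_params_from_mean_sd <- function(mu, sd) {
  if (any(mu <= 0) || any(sd <= 0)) stop("mu and sd must be > 0")
  list(shape = mu^2 / sd^2, rate = mu / sd^2)
}

#' @rdname gamma_params_from_mean_sd
#' @param shape,rate Gamma parameters, both > 0.
#' @export
gamma_mean_sd <- function(shape, rate) {
  if (any(shape <= 0) || any(rate <= 0)) stop("shape and rate must be > 0")
  list(mu = shape / rate, sd = sqrt(shape) / rate)
}

dgamma_meansd_log <- function(x, mu, sd) {
  out <- rep(-Inf, length(x))
  ok <- mu > 0 & x > 0
  if (any(ok)) {
    sh <- (mu^2 / sd^2)[ok] * 1
    ra <- (mu / sd^2)[ok] * 1
    out[ok] <- stats::dgamma(x[ok], shape = sh, rate = ra, log = TRUE)
  }
  out
}

#' Per-subplot covariates for the stand-level model
#'
#' Computes, from the surveyed trees only, each subplot's tree-species
#' richness (number of distinct host species), the percentage of spruce,
#' pine and deciduous trees (birch + aspen + alder + oak; the three
#' percentages sum to 100), and the mean stem DBH. Continuous covariates
#' are Z-scaled across subplots; the scaling parameters are kept as the
#' `"scaling"` attribute for back-transformation. A covariate that is
#' constant across subplots cannot be scaled and is recorded as such (a fit
#' using it will fail with a collinearity error).
#'
#' @param d a `lichen_survey`.
#' @return data.frame with one row per subplot: `subplot`, `n_trees`,
#'   `n_tree_species`, `pct_spruce`, `pct_pine`, `pct_deciduous`,
#'   `mean_dbh`, and Z-scaled columns suffixed `_z`.
#' @export
build_stand_design <- function(d) {
  validate_survey(d)
  tally <- table(factor(d$trees$subplot, levels = d$subplots))
  if (any(tally == 0))
    stop("subplot(s) without trees: ",
         paste(names(tally)[tally == 0], collapse = ", "))
  sp <- as.character(d$trees$tree_species)
  rows <- lapply(d$subplots, function(pp) {
    idx <- d$trees$subplot == pp
    n <- sum(idx)
    spp <- sp[idx]
    data.frame(subplot = pp, n_trees = n,
               n_tree_species = length(unique(spp)),
               pct_spruce = 100 * mean(spp == "spruce"),
               pct_pine = 100 * mean(spp == "pine"),
               pct_deciduous = 100 * mean(spp %in% DECIDUOUS_SPECIES),
               mean_dbh = mean(d$trees$dbh_cm[idx]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  scaling <- list()
  for (v in c("pct_spruce", "pct_pine", "pct_deciduous", "mean_dbh")) {
    z <- tryCatch(zscale(out[[v]]), error = function(e) NULL)
    if (is.null(z)) {
      out[[paste0(v, "_z")]] <- NA_real_
      scaling[[v]] <- c(mean = NA_real_, sd = NA_real_)
    } else {
      out[[paste0(v, "_z")]] <- z$scaled
      scaling[[v]] <- c(mean = z$mean, sd = z$sd)
    }
  }
  attr(out, "scaling") <- scaling
  out
}

#' Prior settings for the stand-level model
#'
#' Vague Gamma(`intercept_shape`, `intercept_rate`) priors for intercepts
#' (and richness-level means, which are intercepts under cell-means
#' coding), Normal(0, `slope_sd`) priors for slopes and half-Cauchy
#' (`sd_scale`) priors for all SD parameters. `sigma_floor` is a numerical
#' guard: the observation SDs are bounded below so that exactly noiseless
#' accumulation curves (zero residuals) do not drive the Normal likelihood
#' into a degenerate spike at sigma = 0.
#'
#' @param intercept_shape,intercept_rate Gamma prior for positive
#'   intercept-type coefficients.
#' @param slope_sd Normal prior SD for slope coefficients.
#' @param sd_scale half-Cauchy scale for SD parameters.
#' @param sigma_floor lower bound on per-subplot observation SDs.
#' @return List of class `stand_priors`.
#' @export
stand_priors <- function(intercept_shape = 0.01, intercept_rate = 0.01,
                         slope_sd = 10, sd_scale = 5, sigma_floor = 1e-6) {
  structure(list(intercept_shape = intercept_shape,
                 intercept_rate = intercept_rate,
                 slope_sd = slope_sd, sd_scale = sd_scale,
                 sigma_floor = sigma_floor),
            class = "stand_priors")
}

# Design matrices and coefficient typing for a model variant.
stand_design_matrices <- function(design, variant) {
  P <- nrow(design)
  dbh <- design$mean_dbh_z
  if (anyNA(dbh)) stop("mean DBH is constant across subplots (collinear design)")
  if (variant == "n_tree_species") {
    lev <- sort(unique(design$n_tree_species))
    X <- vapply(lev, function(l) as.numeric(design$n_tree_species == l),
                numeric(P))
    X <- cbind(X, dbh)
    colnames(X) <- c(paste0("level", lev), "dbh")
    positive <- c(rep(TRUE, length(lev)), FALSE)
  } else {
    x <- design[[paste0(variant, "_z")]]
    if (anyNA(x))
      stop("covariate '", variant, "' is constant across subplots ",
           "(collinear design)")
    X <- cbind(1, x, x^2, dbh)
    colnames(X) <- c("intercept", "x", "x2", "dbh")
    positive <- c(TRUE, FALSE, FALSE, FALSE)
  }
  list(X = X, positive = positive)
}

# Lineweaver-Burk style starting values for one subplot's curve.
sac_inits <- function(U, i) {
  g0 <- max(U) * 1.05 + 0.1
  pos <- U > 0
  d0 <- 1
  if (sum(pos) >= 2) {
    fit <- stats::lm(I(1 / U[pos]) ~ I(1 / i[pos]))
    cf <- stats::coef(fit)
    if (is.finite(cf[1]) && cf[1] > 0) g0 <- max(g0, 1 / cf[1] * 0.9)
    if (is.finite(cf[2]) && cf[2] > 0) d0 <- max(cf[2] / max(cf[1], 1e-6), 0.1)
  }
  s0 <- max(stats::sd(U - mmf(i, g0, d0 + 1)), 0.05)
  c(gamma = g0, delta = d0, sigma = s0)
}

#' Fit the hierarchical species-accumulation (stand-level) model
#'
#' Jointly fits, per subplot, the modified Michaelis-Menten accumulation
#' curve U_i ~ Normal(gamma_p * i / (beta_p - 1 + i), sigma_p) and the
#' stand-level regressions: gamma_p ~ Normal(X g, sigma_gamma) with an
#' identity link, and beta_p Gamma-distributed with mean exp(X h) (log
#' link) and SD sigma_beta. There is no two-stage plug-in: subplot
#' diversities and regression coefficients are sampled from the joint
#' posterior, so stand-level information shrinks poorly determined subplot
#' curves. The default `beta_model = "shifted"` parameterises
#' beta_p = 1 + delta_p with delta_p Gamma-distributed with mean
#' exp(X h) - 1, honouring the constraint that true beta diversity cannot
#' fall below one; `"unshifted"` fits the literal Gamma law on beta_p
#' (draws below 1 are flagged).
#'
#' @param acc an `accumulation_table` (from [accumulation_table()] or
#'   [simulate_stand_curves()]).
#' @param design per-subplot covariates from [build_stand_design()]; rows
#'   must match the subplots of `acc`.
#' @param variant `"n_tree_species"` (cell-means on tree-species richness
#'   levels) or one of `"pct_spruce"`, `"pct_pine"`, `"pct_deciduous"`
#'   (linear + quadratic in the scaled percentage). All variants include a
#'   mean-DBH slope.
#' @param control a [sampler_control()].
#' @param priors a [stand_priors()].
#' @param beta_model `"shifted"` (default) or `"unshifted"`.
#' @return Object of class `stand_sac` with per-chain draw matrices,
#'   convergence report, design and scaling metadata.
#' @export
stand_sac <- function(acc, design,
                      variant = c("n_tree_species", "pct_spruce",
                                  "pct_pine", "pct_deciduous"),
                      control = sampler_control(),
                      priors = stand_priors(),
                      beta_model = c("shifted", "unshifted")) {
  variant <- match.arg(variant)
  beta_model <- match.arg(beta_model)
  stopifnot(inherits(acc, "accumulation_table") || is.data.frame(acc))
  subplots <- unique(acc$subplot)
  P <- length(subplots)
  if (P < 5L) stop("need at least 5 subplots")
  if (!identical(sort(design$subplot), sort(subplots)))
    stop("design rows do not match the subplots of the accumulation table")
  design <- design[match(subplots, design$subplot), , drop = FALSE]

  dm <- stand_design_matrices(design, variant)
  X <- dm$X
  qn <- colnames(X)
  shifted <- beta_model == "shifted"

  pi_idx <- match(acc$subplot, subplots)
  Uv <- acc$U_mean
  iv <- acc$i

  # parameter layout
  nms <- c(sprintf("gamma[%d]", seq_len(P)),
           sprintf("bpar[%d]", seq_len(P)),
           sprintf("sigma[%d]", seq_len(P)),
           paste0("g:", qn), paste0("h:", qn),
           "sigma_gamma", "sigma_beta")
  ig <- seq_len(P); ib <- P + ig; is_ <- 2L * P + ig
  iG <- 3L * P + seq_along(qn)
  iH <- 3L * P + length(qn) + seq_along(qn)
  isg <- 3L * P + 2L * length(qn) + 1L
  isb <- isg + 1L

  loglik_by_p <- function(state) {
    gamma <- state[ig]
    delta <- if (shifted) state[ib] else state[ib] - 1
    sigma <- state[is_]
    mu <- gamma[pi_idx] * iv / (delta[pi_idx] + iv)
    drop(rowsum(stats::dnorm(Uv, mu, sigma[pi_idx], log = TRUE), pi_idx,
                reorder = TRUE))
  }
  mu_gamma <- function(state) drop(X %*% state[iG])
  mu_beta <- function(state) exp(drop(X %*% state[iH]))
  bpar_prior_by_p <- function(state) {
    m <- if (shifted) mu_beta(state) - 1 else mu_beta(state)
    dgamma_meansd_log(state[ib], m, state[isb])
  }
  coef_prior <- function(val, pos) {
    if (pos) stats::dgamma(val, shape = priors$intercept_shape,
                           rate = priors$intercept_rate, log = TRUE)
    else stats::dnorm(val, 0, priors$slope_sd, log = TRUE)
  }

  blocks <- list(
    list(pars = nms[ig], indep = TRUE, transform = "identity",
         lp = function(state) {
           out <- loglik_by_p(state) +
             stats::dnorm(state[ig], mu_gamma(state), state[isg], log = TRUE)
           out[state[ig] <= 0] <- -Inf
           out
         }),
    list(pars = nms[ib], indep = TRUE, transform = "log",
         lp = function(state) loglik_by_p(state) + bpar_prior_by_p(state)),
    list(pars = nms[is_], indep = TRUE, transform = "log",
         lp = function(state) {
           out <- loglik_by_p(state) +
             dhalfcauchy_log(state[is_], priors$sd_scale)
           out[state[is_] < priors$sigma_floor] <- -Inf
           out
         })
  )
  for (j in seq_along(qn)) {
    local({
      jj <- j
      blocks[[length(blocks) + 1L]] <<- list(
        pars = nms[iG[jj]],
        transform = if (dm$positive[jj]) "log" else "identity",
        lp = function(state)
          sum(stats::dnorm(state[ig], mu_gamma(state), state[isg],
                           log = TRUE)) +
          coef_prior(state[iG[jj]], dm$positive[jj]))
      blocks[[length(blocks) + 1L]] <<- list(
        pars = nms[iH[jj]],
        transform = if (dm$positive[jj]) "log" else "identity",
        lp = function(state)
          sum(bpar_prior_by_p(state)) +
          coef_prior(state[iH[jj]], dm$positive[jj]))
    })
  }
  blocks[[length(blocks) + 1L]] <- list(
    pars = nms[isg], transform = "log",
    lp = function(state)
      sum(stats::dnorm(state[ig], mu_gamma(state), state[isg], log = TRUE)) +
      dhalfcauchy_log(state[isg], priors$sd_scale))
  blocks[[length(blocks) + 1L]] <- list(
    pars = nms[isb], transform = "log",
    lp = function(state)
      sum(bpar_prior_by_p(state)) +
      dhalfcauchy_log(state[isb], priors$sd_scale))

  # starting values from per-subplot curve heuristics
  ini <- t(vapply(seq_len(P), function(p) {
    r <- pi_idx == p
    sac_inits(Uv[r], iv[r])
  }, numeric(3)))
  seeds <- chain_seeds(control$seed, control$n_chains)
  offsets <- control$init_dispersion *
    (seq_len(control$n_chains) - (control$n_chains + 1) / 2)

  chains <- vector("list", control$n_chains)
  for (ch in seq_len(control$n_chains)) {
    f <- exp(0.1 * offsets[ch])
    g0 <- ini[, 1] * f
    d0 <- pmax(ini[, 2] * f, 0.05)
    s0 <- pmax(ini[, 3], priors$sigma_floor * 10)
    init <- numeric(length(nms))
    names(init) <- nms
    init[ig] <- g0
    init[ib] <- if (shifted) d0 else d0 + 1
    init[is_] <- s0
    gcoef <- numeric(length(qn))
    hcoef <- numeric(length(qn))
    if (variant == "n_tree_species") {
      lev_cols <- seq_len(length(qn) - 1L)
      for (l in lev_cols) {
        sel <- X[, l] == 1
        gcoef[l] <- max(mean(g0[sel]), 0.5)
        hcoef[l] <- max(log(mean(d0[sel] + 1)), 0.01)
      }
    } else {
      gcoef[1] <- max(mean(g0), 0.5)
      hcoef[1] <- max(log(mean(d0 + 1)), 0.01)
    }
    init[iG] <- gcoef
    init[iH] <- hcoef
    init[isg] <- max(stats::sd(g0), 0.5)
    init[isb] <- max(stats::sd(d0 + 1), 0.25)
    chains[[ch]] <- amwg_sample(init, blocks, n_iter = control$n_iter,
                                adapt = control$adapt,
                                burnin = control$burnin,
                                thin = control$thin, seed = seeds[ch],
                                init_scale = 0.3)
  }

  conv <- if (control$n_chains >= 2L)
    convergence_report(chains, control$psrf_threshold, control$ess_floor)
  else NULL
  if (!is.null(conv) && !conv$pass)
    warning("stand model did not meet the PSRF < ",
            control$psrf_threshold, " gate for ",
            length(conv$flagged), " parameter(s)")

  beta_pool <- do.call(rbind, lapply(chains, function(m)
    m[, nms[ib], drop = FALSE]))
  beta_pool <- if (shifted) beta_pool + 1 else beta_pool
  if (any(beta_pool < 1))
    message("note: ", sum(beta_pool < 1),
            " beta-diversity draw(s) below 1 (unshifted Gamma law)")

  structure(list(chains = chains, parameters = nms, subplots = subplots,
                 acc = acc, design = design, variant = variant,
                 beta_model = beta_model, X = X, coef_names = qn,
                 positive = dm$positive,
                 scaling = attr(design, "scaling"),
                 control = control, priors = priors,
                 convergence = conv, seeds = seeds),
            class = "stand_sac")
}

stand_pooled <- function(object, cols) {
  do.call(rbind, lapply(object$chains, function(m) m[, cols, drop = FALSE]))
}

#' Posterior draws of per-subplot gamma and beta diversity
#'
#' @param object a fitted [stand_sac()].
#' @return Matrix of pooled draws (rows) by subplot (columns).
#' @export
gamma_draws <- function(object) {
  d <- stand_pooled(object, sprintf("gamma[%d]", seq_along(object$subplots)))
  colnames(d) <- object$subplots
  d
}

#' @rdname gamma_draws
#' @export
beta_draws <- function(object) {
  d <- stand_pooled(object, sprintf("bpar[%d]", seq_along(object$subplots)))
  if (object$beta_model == "shifted") d <- d + 1
  colnames(d) <- object$subplots
  d
}

#' Diversity by tree-species-richness level
#'
#' For the `n_tree_species` variant: posterior summaries of the gamma- and
#' beta-diversity level means (at the mean stand DBH) and draw-matched
#' pairwise comparisons across levels. The beta-diversity level mean is
#' exp(level coefficient), i.e. the expected beta diversity at that level.
#'
#' @param object a fitted [stand_sac()] with `variant = "n_tree_species"`.
#' @return List with `gamma` and `beta`, each holding `summary` (per level)
#'   and `pairwise` ([pairwise_comparison()] output).
#' @export
diversity_levels <- function(object) {
  stopifnot(inherits(object, "stand_sac"))
  if (object$variant != "n_tree_species")
    stop("diversity_levels applies to the n_tree_species variant")
  lev <- grep("^level", object$coef_names, value = TRUE)
  gd <- stand_pooled(object, paste0("g:", lev))
  bd <- exp(stand_pooled(object, paste0("h:", lev)))
  colnames(gd) <- colnames(bd) <- lev
  list(gamma = list(summary = posterior_summary(gd),
                    pairwise = pairwise_comparison(gd)),
       beta = list(summary = posterior_summary(bd),
                   pairwise = pairwise_comparison(bd)))
}

#' Tree-species percentage maximising stand lichen diversity
#'
#' For a composition variant, computes per posterior draw the percentage at
#' which the quadratic linear predictor peaks: the vertex -b1/(2 b2) on the
#' scaled axis when the quadratic coefficient is negative (concave), else
#' whichever boundary (0% or 100%) maximises the predictor; back-transforms
#' to raw percentage and clips to [0, 100]. Computed separately for the
#' gamma (identity link) and beta (log link; the log is monotone so the
#' maximiser is unchanged) predictors.
#'
#' @param object a fitted [stand_sac()] with a composition variant.
#' @return List of class `composition_optimum` with elements `gamma` and
#'   `beta`, each a list of `draws` and `summary`, plus `variant`.
#' @export
optimal_composition <- function(object) {
  stopifnot(inherits(object, "stand_sac"))
  if (object$variant == "n_tree_species")
    stop("the richness variant has no quadratic composition term")
  sc <- object$scaling[[object$variant]]
  lo <- (0 - sc["mean"]) / sc["sd"]
  hi <- (100 - sc["mean"]) / sc["sd"]
  per_pred <- function(prefix) {
    b1 <- stand_pooled(object, paste0(prefix, ":x"))[, 1]
    b2 <- stand_pooled(object, paste0(prefix, ":x2"))[, 1]
    v <- ifelse(b2 < 0, -b1 / (2 * b2),
                ifelse(b1 * hi + b2 * hi^2 >= b1 * lo + b2 * lo^2, hi, lo))
    raw <- pmin(pmax(v * sc["sd"] + sc["mean"], 0), 100)
    list(draws = unname(raw), summary = posterior_summary(unname(raw)))
  }
  structure(list(gamma = per_pred("g"), beta = per_pred("h"),
                 variant = object$variant),
            class = "composition_optimum")
}

#' @export
print.composition_optimum <- function(x, ...) {
  cat("Optimal", sub("pct_", "", x$variant), "percentage:\n")
  cat(sprintf("  gamma diversity: %.1f%% (95%% CrI %.1f-%.1f)\n",
              x$gamma$summary["median"], x$gamma$summary["lower"],
              x$gamma$summary["upper"]))
  cat(sprintf("  beta diversity:  %.1f%% (95%% CrI %.1f-%.1f)\n",
              x$beta$summary["median"], x$beta$summary["lower"],
              x$beta$summary["upper"]))
  invisible(x)
}

#' Posterior predictive check of the accumulation model
#'
#' Draws replicated accumulation curves U.pred from
#' Normal(mmf(i, gamma_p, beta_p), sigma_p) for every retained posterior
#' draw and reports, per observation, the central 95% predictive envelope
#' and whether the observed value falls inside it.
#'
#' @param object a fitted [stand_sac()].
#' @param acc accumulation table to check against (default: the fitted
#'   data).
#' @param seed seed for the predictive noise draws.
#' @param level central envelope probability (default 0.95).
#' @return List with `table` (subplot, i, observed, predictive median and
#'   envelope, `inside`), `coverage` (overall fraction inside) and
#'   `coverage_by_subplot`.
#' @export
posterior_predictive_check <- function(object, acc = object$acc,
                                       seed = 1L, level = 0.95) {
  stopifnot(inherits(object, "stand_sac"))
  set.seed(seed)
  gam <- gamma_draws(object)
  bet <- beta_draws(object)
  sig <- stand_pooled(object,
                      sprintf("sigma[%d]", seq_along(object$subplots)))
  pi_idx <- match(acc$subplot, object$subplots)
  D <- nrow(gam)
  n <- nrow(acc)
  iv <- acc$i
  mu <- gam[, pi_idx, drop = FALSE] *
    matrix(iv, D, n, byrow = TRUE) /
    (bet[, pi_idx, drop = FALSE] - 1 + matrix(iv, D, n, byrow = TRUE))
  pred <- mu + matrix(stats::rnorm(D * n), D, n) * sig[, pi_idx, drop = FALSE]
  a <- (1 - level) / 2
  qs <- apply(pred, 2, stats::quantile, probs = c(a, 0.5, 1 - a), type = 7)
  inside <- acc$U_mean >= qs[1, ] & acc$U_mean <= qs[3, ]
  tab <- data.frame(subplot = acc$subplot, i = iv, observed = acc$U_mean,
                    pred_median = qs[2, ], pred_lower = qs[1, ],
                    pred_upper = qs[3, ], inside = inside,
                    stringsAsFactors = FALSE)
  list(table = tab, coverage = mean(inside),
       coverage_by_subplot = tapply(inside, acc$subplot, mean))
}

#' Ternary composition table of subplot diversity estimates
#'
#' One row per subplot with its observed tree-species composition
#' (percent spruce / pine / deciduous, summing to 100) and the subplot's
#' posterior median gamma and beta diversity — the data behind a ternary
#' diversity plot.
#'
#' @param object a fitted [stand_sac()].
#' @return data.frame with `subplot`, the three percentages,
#'   `gamma_median`, `beta_median`.
#' @export
composition_surface <- function(object) {
  stopifnot(inherits(object, "stand_sac"))
  gm <- apply(gamma_draws(object), 2, stats::median)
  bm <- apply(beta_draws(object), 2, stats::median)
  data.frame(subplot = object$design$subplot,
             pct_spruce = object$design$pct_spruce,
             pct_pine = object$design$pct_pine,
             pct_deciduous = object$design$pct_deciduous,
             gamma_median = unname(gm), beta_median = unname(bm),
             stringsAsFactors = FALSE)
}

#' @export
print.stand_sac <- function(x, ...) {
  cat("Hierarchical species-accumulation model (variant:", x$variant,
      "; beta:", x$beta_model, ")\n")
  cat(sprintf("  %d subplots, %d accumulation points\n",
              length(x$subplots), nrow(x$acc)))
  cat(sprintf("  %d chains x %d retained draws (thin %d)\n",
              x$control$n_chains, nrow(x$chains[[1]]), x$control$thin))
  if (!is.null(x$convergence))
    cat(sprintf("  Convergence: %s (max PSRF %.3f)\n",
                if (x$convergence$pass) "PASS" else "FAIL",
                max(x$convergence$psrf)))
  invisible(x)
}

#' @export
coef.stand_sac <- function(object, ...) {
  cols <- c(paste0("g:", object$coef_names), paste0("h:", object$coef_names),
            "sigma_gamma", "sigma_beta")
  apply(stand_pooled(object, cols), 2, stats::median)
}

#' @export
summary.stand_sac <- function(object, ...) {
  cols <- c(paste0("g:", object$coef_names), paste0("h:", object$coef_names),
            "sigma_gamma", "sigma_beta")
  s <- posterior_summary(stand_pooled(object, cols))
  structure(list(coefficients = s, variant = object$variant,
                 convergence = object$convergence),
            class = "summary.stand_sac")
}

#' @export
print.summary.stand_sac <- function(x, ...) {
  cat("Stand-level regression coefficients (g: gamma, identity link;",
      "h: beta, log link):\n")
  print(x$coefficients, digits = 3)
  if (!is.null(x$convergence)) print(x$convergence)
  invisible(x)
}

#' @export
predict.stand_sac <- function(object, subplot = NULL, i = NULL, ...) {
  subplot <- subplot %||% object$subplots
  gm <- apply(gamma_draws(object), 2, stats::median)
  bm <- apply(beta_draws(object), 2, stats::median)
  out <- lapply(subplot, function(pp) {
    k <- match(pp, object$subplots)
    if (is.na(k)) stop("unknown subplot: ", pp)
    ii <- i %||% seq_len(max(object$acc$i[object$acc$subplot == pp]))
    data.frame(subplot = pp, i = ii, fitted = mmf(ii, gm[k], bm[k]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
residuals.stand_sac <- function(object, ...) {
  fit <- predict(object)
  key <- paste(object$acc$subplot, object$acc$i)
  object$acc$U_mean - fit$fitted[match(key, paste(fit$subplot, fit$i))]
}

#' @export
plot.stand_sac <- function(x, max_subplots = 12, ...) {
  pp <- utils::head(x$subplots, max_subplots)
  fit <- predict(x, subplot = pp)
  graphics::plot(x$acc$i[x$acc$subplot %in% pp],
                 x$acc$U_mean[x$acc$subplot %in% pp],
                 pch = 1, col = "grey40", xlab = "Trees sampled",
                 ylab = "Accumulated lichen species",
                 main = "Species accumulation: observed and fitted", ...)
  for (p in pp) {
    f <- fit[fit$subplot == p, ]
    graphics::lines(f$i, f$fitted, col = "steelblue")
  }
  invisible(x)
}
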