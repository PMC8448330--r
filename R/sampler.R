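#' MCMC sampler configuration
#'
#' Settings shared by both model fitters. Defaults follow the study design:
#' three chains, 50,000 post-burn-in iterations per chain retained at every
#' 40th step (1,250 draws per chain), convergence declared when every
#' monitored potential scale reduction factor (PSRF) is below 1.1. The
#' adaptation and burn-in lengths are not part of the study design and are
#' configurable; mixing is additionally screened by a bulk effective sample
#' size floor in place of visual trace inspection.
#'
#' @param n_chains number of chains (>= 2 for PSRF; default 3).
#' @param n_iter post-burn-in iterations per chain (default 50000).
#' @param thin retain every `thin`-th post-burn-in draw; must divide
#'   `n_iter` (default 40).
#' @param adapt adaptive-tuning iterations per chain before burn-in.
#' @param burnin discarded iterations after adaptation.
#' @param seed master integer seed; per-chain seeds derive from it.
#' @param psrf_threshold convergence gate on PSRF (default 1.1).
#' @param ess_floor minimum effective sample size per monitored parameter.
#' @param init_dispersion spread of the chain starting points (model
#'   specific units; larger = more over-dispersed initials).
#' @return A list of class `sampler_control`.
#' @export
sampler_control <- function(n_chains = 3L, n_iter = 50000L, thin = 40L,
                            adapt = 10000L, burnin = 5000L, seed = 1L,
                            psrf_threshold = 1.1, ess_floor = 100,
                            init_dispersion = 2) {
  if (thin < 1L) stop("thin must be >= 1")
  if (n_iter %% thin != 0L)
    stop("n_iter (", n_iter, ") must be divisible by thin (", thin, ")")
  if (n_chains < 1L) stop("n_chains must be >= 1")
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 thin = as.integer(thin), adapt = as.integer(adapt),
                 burnin = as.integer(burnin), seed = as.integer(seed),
                 psrf_threshold = psrf_threshold, ess_floor = ess_floor,
                 init_dispersion = init_dispersion),
            class = "sampler_control")
}

# Robbins-Monro style batch adaptation of a log proposal scale toward the
# 0.44 scalar-optimal acceptance rate.
adapt_scale <- function(log_scale, accept_rate, batch) {
  step <- min(0.1, 1 / sqrt(batch))
  log_scale + ifelse(accept_rate > 0.44, step, -step)
}

#' Generic adaptive Metropolis-within-Gibbs sampler
#'
#' Runs one chain of componentwise random-walk Metropolis over a named
#' parameter vector, organised in blocks. Each block supplies the log of its
#' full conditional target (up to a constant). Blocks whose parameters are
#' conditionally independent given the rest of the state may declare
#' `indep = TRUE` and return per-parameter log-target contributions; all
#' their parameters are then proposed and accepted simultaneously in a
#' single vectorised step. Positive parameters may declare
#' `transform = "log"`, in which case proposals are made on the log scale
#' with the Jacobian handled internally.
#'
#' This engine is the sampler backend for the stand-level model; the
#' tree-level occupancy model uses a specialised sweep with the same update
#' rules but incremental likelihood bookkeeping (see [msom()]).
#'
#' @param init named numeric starting vector.
#' @param blocks list of blocks; each a list with elements `pars`
#'   (character), `lp` (`function(state)`), and optionally
#'   `transform` (`"identity"` or `"log"`) and `indep` (logical).
#' @param n_iter,adapt,burnin,thin see [sampler_control()].
#' @param seed integer seed for this chain.
#' @param monitor names of parameters to record (default: all).
#' @param init_scale initial random-walk SD on the (possibly transformed)
#'   scale.
#' @return Matrix of retained draws (`n_iter / thin` rows) with monitored
#'   parameter names as columns.
#' @export
amwg_sample <- function(init, blocks, n_iter, adapt = 1000L, burnin = 500L,
                        thin = 1L, seed = 1L, monitor = names(init),
                        init_scale = 0.5) {
  stopifnot(!is.null(names(init)), all(monitor %in% names(init)))
  set.seed(seed)
  state <- init
  for (b in seq_along(blocks)) {
    blocks[[b]]$transform <- blocks[[b]]$transform %||% "identity"
    blocks[[b]]$indep <- blocks[[b]]$indep %||% FALSE
    stopifnot(all(blocks[[b]]$pars %in% names(init)))
  }
  log_scale <- lapply(blocks, function(b)
    rep(log(init_scale), length(b$pars)))
  acc_count <- lapply(blocks, function(b) numeric(length(b$pars)))
  batch_len <- 50L
  total <- adapt + burnin + n_iter
  keep <- matrix(NA_real_, n_iter %/% thin, length(monitor),
                 dimnames = list(NULL, monitor))
  kept <- 0L
  batch_no <- 0L

  for (iter in seq_len(total)) {
    for (b in seq_along(blocks)) {
      blk <- blocks[[b]]
      pars <- blk$pars
      np <- length(pars)
      if (blk$indep) {
        cur <- state[pars]
        lp0 <- blk$lp(state)
        eps <- stats::rnorm(np, 0, exp(log_scale[[b]]))
        prop <- if (blk$transform == "log") cur * exp(eps) else cur + eps
        st1 <- state
        st1[pars] <- prop
        lp1 <- blk$lp(st1)
        lr <- lp1 - lp0
        if (blk$transform == "log") lr <- lr + log(prop) - log(cur)
        acc <- log(stats::runif(np)) < lr & is.finite(lp1)
        state[pars][acc] <- prop[acc]
        acc_count[[b]] <- acc_count[[b]] + acc
      } else {
        for (j in seq_len(np)) {
          pj <- pars[j]
          cur <- state[pj]
          lp0 <- blk$lp(state)
          eps <- stats::rnorm(1, 0, exp(log_scale[[b]][j]))
          prop <- if (blk$transform == "log") cur * exp(eps) else cur + eps
          st1 <- state
          st1[pj] <- prop
          lp1 <- blk$lp(st1)
          lr <- lp1 - lp0
          if (blk$transform == "log") lr <- lr + log(prop) - log(cur)
          if (is.finite(lp1) && log(stats::runif(1)) < lr) {
            state[pj] <- prop
            acc_count[[b]][j] <- acc_count[[b]][j] + 1
          }
        }
      }
    }
    if (iter <= adapt && iter %% batch_len == 0L) {
      batch_no <- batch_no + 1L
      for (b in seq_along(blocks)) {
        rate <- acc_count[[b]] / batch_len
        log_scale[[b]] <- adapt_scale(log_scale[[b]], rate, batch_no)
        acc_count[[b]][] <- 0
      }
    }
    post <- iter - adapt - burnin
    if (post > 0L && post %% thin == 0L) {
      kept <- kept + 1L
      keep[kept, ] <- state[monitor]
    }
  }
  keep
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-rank-normalised) PSRF on retained draws:
#' \deqn{\sqrt{((n-1)/n \; W + B/n) / W}}
#' with `B = n * var(chain means)` and `W` the mean within-chain variance.
#' Values near 1 indicate the chains agree; the study's convergence gate is
#' PSRF < 1.1.
#'
#' @param chains a matrix with one row per chain, a list of equal-length
#'   numeric vectors, or a matrix with chains in columns if
#'   `chains_in_rows = FALSE`.
#' @param chains_in_rows interpret matrix rows as chains (default TRUE).
#' @return The PSRF (scalar).
#' @export
psrf <- function(chains, chains_in_rows = TRUE) {
  if (is.list(chains)) chains <- do.call(rbind, chains)
  if (!chains_in_rows) chains <- t(chains)
  m <- nrow(chains)
  n <- ncol(chains)
  if (m < 2L) stop("PSRF needs at least 2 chains")
  if (n < 2L) stop("PSRF needs at least 2 draws per chain")
  W <- mean(apply(chains, 1, stats::var))
  if (!is.finite(W) || W <= 0)
    stop("degenerate chains: zero within-chain variance")
  B <- n * stats::var(rowMeans(chains))
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Effective sample size via Geyer's initial positive sequence, summed over
# chains. Conservative, sufficient as a mixing screen.
ess_geyer <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(0)
  rho <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE,
                    demean = TRUE)$acf[-1]
  s <- 0
  k <- 1L
  while (k < length(rho)) {
    pair <- rho[k] + rho[k + 1L]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2L
  }
  n / (1 + 2 * s)
}

#' Effective sample size of MCMC draws
#'
#' @param chains as in [psrf()]; a single vector is treated as one chain.
#' @return Estimated effective number of independent draws, summed over
#'   chains.
#' @export
ess <- function(chains) {
  if (is.list(chains)) return(sum(vapply(chains, ess_geyer, numeric(1))))
  if (is.matrix(chains)) return(sum(apply(chains, 1, ess_geyer)))
  ess_geyer(chains)
}

#' Posterior median and equal-tailed 95% credible interval
#'
#' Quantiles use linear interpolation (R's default type 7 rule) so summaries
#' are deterministic and reproducible.
#'
#' @param draws numeric vector of posterior draws, or a matrix with draws in
#'   rows and parameters in columns.
#' @param probs interval probabilities (default 2.5% and 97.5%).
#' @return For a vector, named numeric `c(median, lower, upper)`; for a
#'   matrix, a data.frame with one row per column.
#' @export
posterior_summary <- function(draws, probs = c(0.025, 0.975)) {
  if (is.matrix(draws)) {
    out <- t(apply(draws, 2, posterior_summary, probs = probs))
    return(data.frame(parameter = colnames(draws) %||%
                        paste0("par", seq_len(ncol(draws))),
                      median = out[, 1], lower = out[, 2], upper = out[, 3],
                      row.names = NULL, stringsAsFactors = FALSE))
  }
  if (length(draws) < 2L) stop("need at least 2 draws to summarise")
  c(median = stats::median(draws),
    lower = unname(stats::quantile(draws, probs[1], type = 7)),
    upper = unname(stats::quantile(draws, probs[2], type = 7)))
}

#' Convergence report over monitored parameters
#'
#' Computes per-parameter PSRF and effective sample size from a list of
#' per-chain draw matrices and applies the convergence gate: pass iff all
#' monitored PSRF are below the threshold (an ESS floor is reported
#' separately as a mixing screen).
#'
#' @param chains list of matrices (retained draws x parameters), one per
#'   chain, identical column names.
#' @param threshold PSRF gate (default 1.1).
#' @param ess_floor minimum ESS per parameter for the mixing screen.
#' @return List of class `convergence_report`: `$psrf`, `$ess` (named
#'   vectors), `$flagged` (parameters at or above the threshold),
#'   `$low_ess`, `$pass` (logical, PSRF gate), `$mixing_ok`.
#' @export
convergence_report <- function(chains, threshold = 1.1, ess_floor = 100) {
  stopifnot(is.list(chains), length(chains) >= 2L)
  pars <- colnames(chains[[1]])
  r <- vapply(pars, function(p) {
    draws <- lapply(chains, function(ch) ch[, p])
    W <- mean(vapply(draws, stats::var, numeric(1)))
    if (!is.finite(W) || W <= 1e-300) return(c(1, Inf))  # pinned parameter
    c(psrf(draws), ess(draws))
  }, numeric(2))
  ps <- r[1, ]
  es <- r[2, ]
  structure(list(psrf = ps, ess = es,
                 flagged = pars[ps >= threshold],
                 low_ess = pars[es < ess_floor],
                 threshold = threshold, ess_floor = ess_floor,
                 pass = all(ps < threshold),
                 mixing_ok = all(es >= ess_floor)),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("Convergence:", if (x$pass) "PASS" else "FAIL",
      sprintf("(max PSRF %.4f, threshold %.2f)\n",
              max(x$psrf), x$threshold))
  if (length(x$flagged))
    cat("  Flagged:", paste(utils::head(x$flagged, 10), collapse = ", "),
        if (length(x$flagged) > 10) "..." else "", "\n")
  cat("  Min ESS:", round(min(x$ess)),
      if (x$mixing_ok) "(mixing screen ok)\n" else
        paste0("(below floor ", x$ess_floor, ")\n"))
  invisible(x)
}

#' Draw-matched pairwise comparison of posterior quantities
#'
#' For a matrix of draw-matched posterior samples (one column per group,
#' e.g. expected lichen richness per host tree species), computes the 95%
#' credible interval of every pairwise difference and the exceedance
#' probability that the column group exceeds the row group. This is the
#' Bayesian analogue of an ANOVA's pairwise contrasts.
#'
#' @param draws matrix, draws x groups, with column names.
#' @return List with matrices `diff_lower`, `diff_upper` (CrI of column
#'   minus row) and `prob_col_exceeds_row`. Exactly tied draws contribute
#'   1/2 to the exceedance probability, so `p[a,b] + p[b,a] = 1` always.
#' @export
pairwise_comparison <- function(draws) {
  g <- colnames(draws) %||% paste0("g", seq_len(ncol(draws)))
  k <- ncol(draws)
  lo <- hi <- pr <- matrix(NA_real_, k, k, dimnames = list(g, g))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a == b) next
    d <- draws[, b] - draws[, a]
    q <- stats::quantile(d, c(0.025, 0.975), type = 7)
    lo[a, b] <- q[1]
    hi[a, b] <- q[2]
    pr[a, b] <- mean(d > 0) + 0.5 * mean(d == 0)
  }
  list(diff_lower = lo, diff_upper = hi, prob_col_exceeds_row = pr)
}
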