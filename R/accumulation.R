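#' Modified Michaelis-Menten species-accumulation function
#'
#' Expected accumulated lichen richness after sampling `i` trees in a stand
#' with gamma diversity `gamma` (the asymptote: expected total richness were
#' all trees sampled) and true (Whittaker, multiplicative) beta diversity
#' `beta`:
#' \deqn{\mu(i) = \gamma i / (\beta - 1 + i).}
#' Compared with the classical Michaelis-Menten curve, the half-saturation
#' constant is replaced by `beta - 1`, so that the curve evaluated at one
#' tree gives alpha diversity `gamma / beta` (Whittaker's relation) and
#' half-saturation occurs at `i = beta - 1` trees.
#'
#' @param i number of trees sampled (positive; may be non-integer).
#' @param gamma stand gamma diversity, > 0.
#' @param beta true beta diversity, >= 1 (`beta = 1` gives the constant
#'   `gamma`: no between-tree turnover).
#' @return Expected accumulated richness, recycled over the longest argument.
#' @export
mmf <- function(i, gamma, beta) {
  if (any(gamma <= 0)) stop("gamma must be > 0")
  if (any(beta < 1)) stop("beta must be >= 1")
  if (any(i <= 0)) stop("i must be > 0")
  gamma * i / (beta - 1 + i)
}

#' Accumulated unique-species counts along one tree ordering
#'
#' @param order integer permutation of `seq_along(species_sets)` giving the
#'   virtual sampling order of the trees.
#' @param species_sets list with one integer (or character) vector of lichen
#'   species per tree; empty vectors are legal (a lichen-free tree adds no
#'   species).
#' @return Integer vector `U` with `U[i]` = number of distinct species on the
#'   first `i` trees of the ordering.
#' @export
accumulate_once <- function(order, species_sets) {
  n <- length(species_sets)
  if (length(order) != n || !setequal(order, seq_len(n)))
    stop("'order' must be a permutation of seq_along(species_sets)")
  seen <- NULL
  U <- integer(n)
  for (j in seq_len(n)) {
    seen <- union(seen, species_sets[[order[j]]])
    U[j] <- length(seen)
  }
  U
}

# Exact expected accumulation via the hypergeometric rarefaction identity:
# E[U_i] = sum_species (1 - choose(n - n_s, i) / choose(n, i)), where n_s is
# the number of trees carrying species s. Identical to the mean over all n!
# permutations, with no Monte-Carlo noise, for any n.
exact_mean_accumulation <- function(species_sets) {
  n <- length(species_sets)
  all_sp <- unique(unlist(species_sets))
  if (length(all_sp) == 0L) return(numeric(n))
  n_s <- vapply(all_sp, function(sp) {
    sum(vapply(species_sets, function(set) sp %in% set, logical(1)))
  }, numeric(1))
  vapply(seq_len(n), function(i) {
    # lchoose is stable for large n; choose(n - n_s, i) = 0 when i > n - n_s
    miss <- ifelse(i > n - n_s, 0, exp(lchoose(n - n_s, i) - lchoose(n, i)))
    sum(1 - miss)
  }, numeric(1))
}

#' Mean species accumulation over random tree reorderings
#'
#' Virtually reorders the trees of a subplot `s` times (uniform independent
#' permutations) and averages the accumulated unique-species counts, giving
#' the mean accumulation curve \eqn{U_i = mean_s(U_{i,s})}. With
#' `method = "exact"` the average over all permutations is computed in closed
#' form instead (no Monte-Carlo noise).
#'
#' @param species_sets list of per-tree species vectors (see
#'   [accumulate_once()]).
#' @param s number of random reorderings (default 100).
#' @param seed optional integer seed for the permutation stream.
#' @param method `"resample"` (default) or `"exact"`.
#' @return Numeric vector of mean accumulated richness per tree index.
#' @export
mean_accumulation <- function(species_sets, s = 100, seed = NULL,
                              method = c("resample", "exact")) {
  method <- match.arg(method)
  n <- length(species_sets)
  if (n < 1L) stop("need at least one tree")
  if (method == "exact") return(exact_mean_accumulation(species_sets))
  if (s < 1L) stop("s must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  acc <- numeric(n)
  for (rep in seq_len(s)) {
    ord <- if (n == 1L) 1L else sample.int(n)
    acc <- acc + accumulate_once(ord, species_sets)
  }
  acc / s
}

#' Per-tree lichen species sets grouped by subplot
#'
#' @param d a `lichen_survey` or `occurrence_tensor`.
#' @return Named list (one element per subplot) of lists of per-tree integer
#'   species-index vectors, in the tree order of the data.
#' @export
subplot_species_sets <- function(d) {
  tens <- if (inherits(d, "occurrence_tensor")) d else merge_trunk_branch(d)
  out <- lapply(seq_along(tens$subplots), function(p) {
    idx <- which(tens$subplot_index == p)
    lapply(idx, function(i) which(tens$y[, i] == 1L))
  })
  names(out) <- tens$subplots
  out
}

#' Build the per-subplot mean accumulation table
#'
#' Applies [mean_accumulation()] to every subplot of a survey. Each subplot
#' gets its own deterministic permutation stream derived from the master
#' seed and its position, so adding or dropping other subplots does not
#' change a subplot's curve.
#'
#' @param d a `lichen_survey` or `occurrence_tensor`.
#' @param s number of reorderings per subplot (default 100, ignored for
#'   `method = "exact"`).
#' @param seed master integer seed.
#' @param method `"resample"` (default) or `"exact"`.
#' @return A data.frame of class `accumulation_table` with columns
#'   `subplot`, `i` (tree index) and `U_mean`, plus attributes `s`, `seed`,
#'   `method` and `i_max` (named per-subplot tree counts).
#' @export
accumulation_table <- function(d, s = 100, seed = 1L,
                               method = c("resample", "exact")) {
  method <- match.arg(method)
  sets <- subplot_species_sets(d)
  rows <- lapply(seq_along(sets), function(p) {
    sub_seed <- (as.integer(seed) + 7919L * p) %% (.Machine$integer.max - 1L)
    U <- mean_accumulation(sets[[p]], s = s, seed = sub_seed, method = method)
    data.frame(subplot = names(sets)[p], i = seq_along(U), U_mean = U,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, s = s, seed = seed, method = method,
            i_max = vapply(sets, length, integer(1)),
            class = c("accumulation_table", "data.frame"))
}
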