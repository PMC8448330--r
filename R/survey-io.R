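#' Host tree species recognised by the survey models
#'
#' The six host tree species of the boreal study system, in the fixed order
#' used throughout the package. The deciduous group comprises birch, aspen,
#' alder and oak.
#'
#' @format Character vector of length 6.
#' @export
TREE_SPECIES <- c("spruce", "pine", "birch", "aspen", "alder", "oak")

#' @rdname TREE_SPECIES
#' @export
DECIDUOUS_SPECIES <- c("birch", "aspen", "alder", "oak")

#' Column-naming configuration for survey tables
#'
#' Describes how a CSV survey table maps onto the fields the package needs:
#' tree metadata columns and the per-lichen-species presence columns for the
#' trunk and branch substrates. The default dialect expects one column per
#' lichen species per substrate, named `<species><trunk_suffix>` and
#' `<species><branch_suffix>`. Other dialects (e.g. a published deposit with
#' different headers) are adapted by supplying the actual column names here
#' rather than by editing data files.
#'
#' @param subplot,tree_id,tree_species,dbh names of the metadata columns.
#' @param trunk_suffix,branch_suffix suffixes identifying substrate columns.
#' @param species optional character vector restricting/ordering the lichen
#'   species; default derives species from the header.
#' @return A list of class `survey_format`.
#' @export
survey_format <- function(subplot = "subplot", tree_id = "tree_id",
                          tree_species = "tree_species", dbh = "dbh_cm",
                          trunk_suffix = "_trunk", branch_suffix = "_branch",
                          species = NULL) {
  structure(list(subplot = subplot, tree_id = tree_id,
                 tree_species = tree_species, dbh = dbh,
                 trunk_suffix = trunk_suffix, branch_suffix = branch_suffix,
                 species = species),
            class = "survey_format")
}

new_lichen_survey <- function(trees, trunk, branch, species, subplots) {
  stopifnot(is.data.frame(trees), is.matrix(trunk), is.matrix(branch))
  structure(list(trees = trees, trunk = trunk, branch = branch,
                 lichen_species = species, subplots = subplots),
            class = "lichen_survey")
}

validate_survey <- function(d) {
  trees <- d$trees
  if (nrow(trees) < 1L) stop("survey contains no trees")
  if (length(d$lichen_species) < 1L) stop("survey contains no lichen species")
  if (length(d$subplots) < 1L) stop("survey contains no subplots")
  if (!all(trees$subplot %in% d$subplots))
    stop("tree records reference subplots absent from the subplot list")
  key <- paste(trees$subplot, trees$tree_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop("duplicate (subplot, tree_id) pairs at rows: ",
         paste(dup, collapse = ", "))
  }
  if (!all(as.character(trees$tree_species) %in% TREE_SPECIES)) {
    bad <- setdiff(unique(as.character(trees$tree_species)), TREE_SPECIES)
    stop("unknown tree species label(s): ", paste(bad, collapse = ", "))
  }
  if (ncol(d$trunk) != length(d$lichen_species) ||
      ncol(d$branch) != length(d$lichen_species))
    stop("trunk/branch matrices must have one column per lichen species")
  if (nrow(d$trunk) != nrow(trees) || nrow(d$branch) != nrow(trees))
    stop("trunk/branch matrices must have one row per tree")
  invisible(d)
}

#' Read and validate a tree-level lichen survey table
#'
#' Reads a CSV with one row per surveyed tree: subplot id, tree id, host tree
#' species (one of [TREE_SPECIES], case-insensitive), DBH in cm, and 0/1
#' presence columns per lichen species, recorded separately for trunk and
#' branches. Validation rejects unknown tree species, non-positive or
#' non-numeric DBH (naming the offending rows), and duplicate
#' (subplot, tree id) pairs. Trees at or below the 10 cm DBH survey inclusion
#' threshold raise a warning.
#'
#' @param path path to the CSV file.
#' @param format a [survey_format()] describing the column naming.
#' @return A `lichen_survey` object: tree metadata (`$trees`), logical
#'   presence matrices `$trunk` and `$branch` (trees x species),
#'   `$lichen_species` and `$subplots`. Row order of the file is preserved.
#' @export
read_survey <- function(path, format = survey_format()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c(format$subplot, format$tree_id, format$tree_species, format$dbh))
    if (!col %in% names(raw))
      stop("required column '", col, "' missing from ", path)

  tn <- grep(paste0(gsub("([._])", "\\\\\\1", format$trunk_suffix), "$"),
             names(raw), value = TRUE)
  species_trunk <- sub(paste0(gsub("([._])", "\\\\\\1", format$trunk_suffix), "$"),
                       "", tn)
  bn <- grep(paste0(gsub("([._])", "\\\\\\1", format$branch_suffix), "$"),
             names(raw), value = TRUE)
  species_branch <- sub(paste0(gsub("([._])", "\\\\\\1", format$branch_suffix), "$"),
                        "", bn)
  species <- format$species %||% species_trunk
  if (length(species) == 0L)
    stop("no lichen species columns found (suffix '", format$trunk_suffix, "')")
  missing_t <- setdiff(species, species_trunk)
  missing_b <- setdiff(species, species_branch)
  if (length(missing_t) || length(missing_b))
    stop("species lacking trunk or branch column: ",
         paste(unique(c(missing_t, missing_b)), collapse = ", "))

  dbh_raw <- raw[[format$dbh]]
  dbh <- suppressWarnings(as.numeric(dbh_raw))
  bad <- which(is.na(dbh) | dbh <= 0)
  if (length(bad))
    stop("non-numeric or non-positive DBH at row(s): ",
         paste(bad, collapse = ", "))
  if (any(dbh <= 10))
    warning("DBH <= 10 cm at row(s) ",
            paste(which(dbh <= 10), collapse = ", "),
            "; the survey protocol includes only trees with DBH > 10 cm")

  sp_label <- tolower(trimws(raw[[format$tree_species]]))
  trees <- data.frame(
    subplot = as.character(raw[[format$subplot]]),
    tree_id = as.character(raw[[format$tree_id]]),
    tree_species = factor(sp_label, levels = TREE_SPECIES),
    dbh_cm = dbh,
    stringsAsFactors = FALSE
  )
  if (anyNA(trees$tree_species)) {
    bad <- setdiff(unique(sp_label), TREE_SPECIES)
    stop("unknown tree species label(s): ", paste(bad, collapse = ", "))
  }

  to_mat <- function(cols) {
    m <- as.matrix(raw[cols])
    if (!all(m %in% c(0, 1, NA)) || anyNA(m))
      stop("presence columns must be 0/1 with no missing values")
    storage.mode(m) <- "integer"
    colnames(m) <- species
    m
  }
  trunk <- to_mat(paste0(species, format$trunk_suffix))
  branch <- to_mat(paste0(species, format$branch_suffix))

  d <- new_lichen_survey(trees, trunk, branch, species,
                         unique(trees$subplot))
  validate_survey(d)
  d
}

#' Write a survey dataset back to the standard CSV dialect
#'
#' @param d a `lichen_survey`.
#' @param path output CSV path.
#' @param format a [survey_format()].
#' @return `path`, invisibly.
#' @export
write_survey <- function(d, path, format = survey_format()) {
  trunk <- d$trunk
  branch <- d$branch
  colnames(trunk) <- paste0(d$lichen_species, format$trunk_suffix)
  colnames(branch) <- paste0(d$lichen_species, format$branch_suffix)
  out <- cbind(
    stats::setNames(
      data.frame(d$trees$subplot, d$trees$tree_id,
                 as.character(d$trees$tree_species), d$trees$dbh_cm,
                 stringsAsFactors = FALSE),
      c(format$subplot, format$tree_id, format$tree_species, format$dbh)),
    as.data.frame(trunk), as.data.frame(branch))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.lichen_survey <- function(x, ...) {
  cat("Lichen survey:", nrow(x$trees), "trees,",
      length(x$lichen_species), "lichen species,",
      length(x$subplots), "subplots\n")
  tab <- table(x$trees$tree_species)
  cat("Trees per host species:\n")
  print(tab)
  invisible(x)
}

#' Z-score scale a numeric vector
#'
#' Centres and scales with the sample (n-1 denominator) standard deviation,
#' returning the parameters needed to invert the transformation.
#'
#' @param x numeric vector, length >= 2.
#' @return List with `scaled`, `mean`, `sd`.
#' @seealso [zscale_inverse()]
#' @export
zscale <- function(x) {
  if (length(x) < 2L) stop("zscale needs at least 2 values")
  m <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s <= 0)
    stop("cannot Z-scale a constant (zero-variance) vector")
  list(scaled = (x - m) / s, mean = m, sd = s)
}

#' @rdname zscale
#' @param scaled a Z-scaled vector.
#' @param mean,sd the scaling parameters returned by `zscale()`.
#' @export
zscale_inverse <- function(scaled, mean, sd) scaled * sd + mean

#' Merge trunk and branch presences into the model-ready occurrence tensor
#'
#' A lichen species is scored present on a tree if it occurs on the trunk or
#' the branches (both models use the merged substrate). Returns the binary
#' species x tree matrix together with aligned covariates: subplot index,
#' host-tree-species index and Z-scaled DBH.
#'
#' @param d a `lichen_survey`.
#' @return An `occurrence_tensor`: `$y` (integer matrix, species k x tree i),
#'   `$subplot_index`, `$tree_species_index`, `$dbh_scaled`, `$dbh_cm`,
#'   `$scaling` (mean, sd of raw DBH), `$species`, `$subplots`,
#'   `$tree_species_levels`.
#' @export
merge_trunk_branch <- function(d) {
  validate_survey(d)
  y <- t((d$trunk | d$branch) * 1L)
  storage.mode(y) <- "integer"
  rownames(y) <- d$lichen_species
  z <- zscale(d$trees$dbh_cm)
  structure(list(
    y = y,
    subplot_index = match(d$trees$subplot, d$subplots),
    tree_species_index = as.integer(d$trees$tree_species),
    dbh_scaled = z$scaled,
    dbh_cm = d$trees$dbh_cm,
    scaling = c(mean = z$mean, sd = z$sd),
    species = d$lichen_species,
    subplots = d$subplots,
    tree_species_levels = TREE_SPECIES
  ), class = "occurrence_tensor")
}

#' @export
print.occurrence_tensor <- function(x, ...) {
  cat("Occurrence tensor:", nrow(x$y), "lichen species x", ncol(x$y),
      "trees on", length(x$subplots), "subplots\n")
  cat("Overall occupancy:", round(mean(x$y), 4), "\n")
  invisible(x)
}

#' Per-host-tree-species descriptive summary
#'
#' Counts, after merging trunk and branch records, the number of surveyed
#' trees, lichen occurrences (species x tree presences) and distinct lichen
#' species per host tree species, with a grand-total row.
#'
#' @param d a `lichen_survey`.
#' @return A data.frame with columns `tree_species`, `n_trees`,
#'   `n_occurrences`, `n_lichen_species`; the final row is the total.
#' @export
descriptive_counts <- function(d) {
  validate_survey(d)
  merged <- (d$trunk | d$branch)
  rows <- lapply(TREE_SPECIES, function(sp) {
    idx <- which(as.character(d$trees$tree_species) == sp)
    m <- merged[idx, , drop = FALSE]
    data.frame(tree_species = sp,
               n_trees = length(idx),
               n_occurrences = sum(m),
               n_lichen_species = sum(colSums(m) > 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  total <- data.frame(tree_species = "total",
                      n_trees = nrow(d$trees),
                      n_occurrences = sum(merged),
                      n_lichen_species = sum(colSums(merged) > 0),
                      stringsAsFactors = FALSE)
  rbind(out, total)
}
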