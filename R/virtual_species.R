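#' Define a virtual species by its Gaussian environmental response
#'
#' A virtual species has a suitability of 1 at its environmental optimum and
#' declines as a product of independent Gaussian responses along each axis:
#' `prod_j exp(-(x_j - opt_j)^2 / (2 * breadth_j^2))`. The response is
#' truncated to exactly 0 beyond a Mahalanobis radius of 6 breadth units, so
#' "cells with positive suitability" is a well-defined finite set.
#'
#' @param optimum named numeric vector of environmental optima; names must
#'   match layer names of the stack the species will be evaluated on.
#' @param breadth positive niche breadth per axis (recycled).
#' @param max_prevalence fraction in (0, 1] scaling expected occupancy when
#'   sampling occurrences.
#' @return An object of class `virtual_species`.
#' @export
virtual_species <- function(optimum, breadth, max_prevalence = 1) {
  if (is.null(names(optimum)) || any(!nzchar(names(optimum)))) {
    stop_ns("optimum must be a named vector (layer names)")
  }
  breadth <- rep_len(breadth, length(optimum))
  if (any(breadth <= 0)) stop_ns("breadth must be strictly positive")
  if (max_prevalence <= 0 || max_prevalence > 1) {
    stop_ns("max_prevalence must be in (0, 1]")
  }
  structure(list(optimum = optimum, breadth = breadth,
                 max_prevalence = max_prevalence),
            class = "virtual_species")
}

#' @export
print.virtual_species <- function(x, ...) {
  cat("virtual_species on", length(x$optimum), "axes:",
      paste(names(x$optimum), collapse = ", "), "\n")
  cat("  optimum:", paste(signif(x$optimum, 4), collapse = ", "),
      "| breadth:", paste(signif(x$breadth, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a virtual species' suitability over a climate stack
#'
#' @param vs a [virtual_species()].
#' @param stack a [climate_stack()] containing every layer named in
#'   `vs$optimum`.
#' @return Matrix of suitabilities in `[0, 1]` (1 at the optimum), `NA` on
#'   nodata cells, exact 0 beyond 6 breadth units from the optimum.
#' @export
suitability_map <- function(vs, stack) {
  miss <- setdiff(names(vs$optimum), names(stack$layers))
  if (length(miss)) {
    stop_ns("stack lacks layers used by the species: ",
            paste(miss, collapse = ", "))
  }
  d2 <- 0
  for (j in seq_along(vs$optimum)) {
    L <- stack$layers[[names(vs$optimum)[j]]]
    d2 <- d2 + ((L - vs$optimum[j]) / vs$breadth[j])^2
  }
  s <- exp(-d2 / 2)
  s[d2 > 36] <- 0  # truncate beyond 6 breadth units
  s
}

#' Sample presence records for a virtual species
#'
#' Draws `n` cells without replacement from the eligible cells of
#' `region_mask` (valid climate, suitability > 0), with selection probability
#' proportional to suitability, then jitters each point uniformly within its
#' cell.
#'
#' @param vs a [virtual_species()].
#' @param stack a [climate_stack()].
#' @param region_mask logical matrix delimiting the sampling region.
#' @param n number of presence points.
#' @param seed integer seed.
#' @param species,range_label strings stored with every record.
#' @return An occurrence data frame (columns `species`, `longitude`,
#'   `latitude`, `range`), see [occurrence_set()].
#' @export
sample_occurrences <- function(vs, stack, region_mask, n, seed,
                               species = "virtual species",
                               range_label = "native") {
  stopifnot(is.logical(region_mask), identical(dim(region_mask), dim(stack)))
  if (n == 0) {
    return(occurrence_set(data.frame(species = character(), longitude = numeric(),
                                     latitude = numeric(), range = character())))
  }
  suit <- suitability_map(vs, stack)
  eligible <- which(region_mask & !is.na(suit) & suit > 0)
  if (length(eligible) < n) {
    stop_ns("only ", length(eligible),
            " eligible cells with positive suitability; need ", n)
  }
  with_seed(seed, {
    cells <- sample(eligible, n, prob = suit[eligible])
    d <- dim(stack)
    row <- (cells - 1L) %% d[1L] + 1L
    col <- (cells - 1L) %/% d[1L] + 1L
    xy <- cell_xy(stack, row, col)
    occurrence_set(data.frame(
      species = species,
      longitude = xy[, "lon"] + stats::runif(n, -0.5, 0.5) * stack$cellsize,
      latitude = xy[, "lat"] + stats::runif(n, -0.5, 0.5) * stack$cellsize,
      range = range_label
    ))
  })
}

# Numeric truth for a scenario: integrate the two Gaussian occupancies over
# each region's valid cells, with niche support delimited at 3 breadth units
# (suitability >= exp(-4.5)), mirroring the 3-bandwidth kernel truncation of
# the empirical occupancy grids.
scenario_truth <- function(native, invaded, stack, mask_nat, mask_inv) {
  cutoff <- exp(-4.5)
  s_nat <- suitability_map(native, stack)
  s_inv <- suitability_map(invaded, stack)
  inv_cells <- mask_inv & !is.na(s_inv)
  nat_cells <- mask_nat & !is.na(s_nat)
  denom_e <- sum(s_inv[inv_cells])
  denom_u <- sum(s_nat[nat_cells])
  expansion <- sum(s_inv[inv_cells & s_nat < cutoff]) / denom_e
  unfilling <- sum(s_nat[nat_cells & s_inv < cutoff]) / denom_u
  list(expansion = expansion, unfilling = unfilling)
}

#' Build a controlled niche-shift scenario with paired occurrence sets
#'
#' Places two disjoint geographic regions (west and east column bands of the
#' same stack, hence sharing their environmental distribution), defines a
#' native virtual species at the pooled environmental centroid of the first
#' two layers, derives the invaded-range species according to `kind`, samples
#' occurrences in each region, and records the analytically integrated truth
#' for the expansion/stability/unfilling decomposition.
#'
#' Scenario kinds (`b` = niche breadth):
#' \describe{
#'   \item{conservatism}{identical optima; expected expansion = unfilling = 0.}
#'   \item{expansion}{invaded optimum shifted `magnitude * b` along axis 1.}
#'   \item{unfilling}{optimum shifted `magnitude * b`, invaded breadth halved,
#'     so the invader occupies a subset of native conditions.}
#'   \item{full_shift}{optima separated by `max(6, magnitude) * b`: disjoint
#'     niches, expected D = 0, expansion = unfilling = 1.}
#'   \item{mixed}{diagonal shift of `magnitude * b` split over both axes.}
#' }
#'
#' @param kind scenario kind (see Details).
#' @param stack a [climate_stack()]; the first two layers define the niche
#'   axes. Two-layer stacks are recommended for scenario studies so the
#'   PC1--PC2 plane is a rotation of the generating environment space.
#' @param magnitude shift size in breadth units.
#' @param seed integer seed.
#' @param n_native,n_invaded occurrences sampled per region.
#' @param breadth_frac niche breadth as a fraction of the pooled environmental
#'   standard deviation per axis.
#' @return An object of class `shift_scenario` with elements `native`,
#'   `invaded` (occurrence sets), `native_species`, `invaded_species`,
#'   `region_masks`, `expected_D_class`, and the truth proportions
#'   `expected_expansion`, `expected_stability`, `expected_unfilling` with
#'   `tolerance`.
#' @export
make_scenario <- function(kind = c("conservatism", "expansion", "unfilling",
                                   "full_shift", "mixed"),
                          stack, magnitude = 1.5, seed = 1,
                          n_native = 300, n_invaded = 300,
                          breadth_frac = 0.4) {
  kind <- match.arg(kind)
  d <- dim(stack)
  wband <- max(1L, floor(0.45 * d[2L]))
  mask_nat <- matrix(FALSE, d[1L], d[2L]); mask_nat[, seq_len(wband)] <- TRUE
  mask_inv <- matrix(FALSE, d[1L], d[2L])
  mask_inv[, (d[2L] - wband + 1L):d[2L]] <- TRUE
  valid <- stack_mask(stack)
  mask_nat <- mask_nat & valid
  mask_inv <- mask_inv & valid

  axes <- names(stack$layers)[1:2]
  pooled <- mask_nat | mask_inv
  mu <- vapply(axes, function(a) mean(stack$layers[[a]][pooled]), 0)
  sdv <- vapply(axes, function(a) stats::sd(stack$layers[[a]][pooled]), 0)
  b <- breadth_frac * sdv

  native_sp <- virtual_species(stats::setNames(mu, axes), b)
  shift <- switch(kind,
    conservatism = c(0, 0),
    expansion    = c(magnitude, 0),
    unfilling    = c(magnitude, 0),
    full_shift   = c(max(6, magnitude), 0),
    mixed        = rep(magnitude / sqrt(2), 2)
  )
  inv_breadth <- if (kind == "unfilling") b / 2 else b
  invaded_sp <- virtual_species(stats::setNames(mu + shift * b, axes),
                                inv_breadth)

  seeds <- split_seeds(seed, 2L)
  occ_nat <- sample_occurrences(native_sp, stack, mask_nat, n_native,
                                seeds[1L], range_label = "native")
  occ_inv <- sample_occurrences(invaded_sp, stack, mask_inv, n_invaded,
                                seeds[2L], range_label = "invaded")

  truth <- switch(kind,
    conservatism = list(expansion = 0, unfilling = 0),
    full_shift   = list(expansion = 1, unfilling = 1),
    scenario_truth(native_sp, invaded_sp, stack, mask_nat, mask_inv)
  )
  d_class <- if (kind == "conservatism") "high"
             else if (kind == "full_shift") "zero" else "low"

  structure(list(
    kind = kind, magnitude = magnitude, seed = seed,
    native_species = native_sp, invaded_species = invaded_sp,
    native = occ_nat, invaded = occ_inv,
    region_masks = list(native = mask_nat, invaded = mask_inv),
    expected_D_class = d_class,
    expected_expansion = truth$expansion,
    expected_stability = 1 - truth$expansion,
    expected_unfilling = truth$unfilling,
    tolerance = 0.10
  ), class = "shift_scenario")
}

#' @export
print.shift_scenario <- function(x, ...) {
  cat("shift_scenario:", x$kind, "(magnitude", x$magnitude, ")\n")
  cat(sprintf("  expected: expansion %.3f  stability %.3f  unfilling %.3f  (D %s)\n",
              x$expected_expansion, x$expected_stability,
              x$expected_unfilling, x$expected_D_class))
  cat("  occurrences:", nrow(x$native), "native /", nrow(x$invaded),
      "invaded\n")
  invisible(x)
}

#' Write scenario truth values to JSON
#' @param scenario a `shift_scenario`.
#' @param path output file.
#' @export
write_scenario_truth <- function(scenario, path) {
  jsonlite::write_json(
    scenario[c("kind", "magnitude", "seed", "expected_D_class",
               "expected_expansion", "expected_stability",
               "expected_unfilling", "tolerance")],
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
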