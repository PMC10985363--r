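#' Occurrence record table
#'
#' Occurrence sets are plain data frames with columns `species`, `longitude`,
#' `latitude` (decimal degrees WGS84) and `range` (native or a named invaded
#' region), carrying class `occurrence_set`. The constructor validates column
#' presence only; coordinate validity and duplication are the business of
#' [clean_occurrences()].
#'
#' @param df data frame with the four required columns.
#' @return The data frame with class `occurrence_set` prepended.
#' @export
occurrence_set <- function(df) {
  need <- c("species", "longitude", "latitude", "range")
  if (!all(need %in% names(df))) {
    stop_ns("occurrence table needs columns: ", paste(need, collapse = ", "))
  }
  df <- as.data.frame(df)[, c(need, setdiff(names(df), need)), drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("occurrence_set", "data.frame")
  df
}

#' @rdname occurrence_set
#' @param path CSV file with header `species,longitude,latitude,range`.
#' @export
read_occurrences <- function(path) {
  occurrence_set(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname occurrence_set
#' @param occ an `occurrence_set`.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ), path, row.names = FALSE)
  invisible(path)
}

# canonical record order, so randomized algorithms are independent of the
# caller's row order
canonical_order <- function(occ) {
  occ[order(occ$species, occ$range, occ$longitude, occ$latitude), ,
      drop = FALSE]
}

#' Clean raw occurrence records
#'
#' Removes records with missing or non-numeric coordinates, coordinates
#' outside valid lon/lat bounds, exact duplicates of
#' (species, longitude, latitude, range), and records falling on nodata
#' ("ocean") cells or outside the extent of the climate stack.
#'
#' @param raw an [occurrence_set()] (coordinates may be character).
#' @param stack a [climate_stack()] supplying the land mask.
#' @return The cleaned `occurrence_set`, with a rejection report in
#'   `attr(, "report")`: counts for `missing`, `out_of_bounds`, `duplicate`,
#'   `ocean`, and `total`.
#' @export
clean_occurrences <- function(raw, stack) {
  df <- as.data.frame(raw)
  rep_counts <- c(missing = 0L, out_of_bounds = 0L, duplicate = 0L, ocean = 0L)
  if (nrow(df)) {
    lon <- suppressWarnings(as.numeric(df$longitude))
    lat <- suppressWarnings(as.numeric(df$latitude))
    df$longitude <- lon
    df$latitude <- lat

    bad_missing <- !is.finite(lon) | !is.finite(lat) | is.na(df$species) |
      is.na(df$range)
    rep_counts["missing"] <- sum(bad_missing)
    df <- df[!bad_missing, , drop = FALSE]

    oob <- df$longitude < -180 | df$longitude > 180 |
      df$latitude < -90 | df$latitude > 90
    rep_counts["out_of_bounds"] <- sum(oob)
    df <- df[!oob, , drop = FALSE]

    dup <- duplicated(df[, c("species", "longitude", "latitude", "range")])
    rep_counts["duplicate"] <- sum(dup)
    df <- df[!dup, , drop = FALSE]

    rc <- xy_cell(stack, df$longitude, df$latitude)
    on_land <- !is.na(rc[, "row"]) &
      !is.na(stack$layers[[1L]][rc])
    rep_counts["ocean"] <- sum(!on_land)
    df <- df[on_land, , drop = FALSE]
  }
  out <- occurrence_set(df)
  attr(out, "report") <- as.list(c(rep_counts, total = sum(rep_counts)))
  out
}

# all-pairs haversine distance (km) on a 6371-km sphere
haversine_km <- function(lon, lat) {
  n <- length(lon)
  if (n < 2L) return(matrix(0, n, n))
  m <- geosphere::distm(cbind(lon, lat),
                        fun = function(p1, p2) {
                          geosphere::distHaversine(p1, p2, r = 6371000)
                        })
  m / 1000
}

# one spThin-style elimination pass: repeatedly drop the record with the most
# conflicts (ties broken at random) until no pair is closer than radius_km
thin_pass <- function(conflict) {
  keep <- rep(TRUE, nrow(conflict))
  deg <- rowSums(conflict)
  while (any(deg[keep] > 0)) {
    idx <- which(keep)
    worst <- idx[deg[idx] == max(deg[idx])]
    drop <- if (length(worst) == 1L) worst else sample(worst, 1L)
    keep[drop] <- FALSE
    hit <- which(conflict[drop, ] & keep)
    deg[hit] <- deg[hit] - 1L
    deg[drop] <- 0L
  }
  keep
}

#' Spatially thin occurrence records to a minimum separation
#'
#' Randomized elimination thinning in the style of spThin: records closer
#' than `radius_km` (great-circle haversine distance, 6371-km sphere) are in
#' conflict; each pass repeatedly drops the record with most conflicts (ties
#' at random) until none remain. Among `reps` passes the one retaining the
#' most records wins, ties broken by lowest pass index. Thinning is applied
#' independently within each species x range group.
#'
#' @param occ an [occurrence_set()].
#' @param radius_km minimum pairwise distance to enforce (default 5 km).
#' @param reps number of randomized passes.
#' @param seed integer seed.
#' @return The thinned `occurrence_set` (a subset of the input rows).
#' @export
thin_occurrences <- function(occ, radius_km = 5, reps = 10, seed = 1) {
  stopifnot(radius_km > 0, reps >= 1)
  occ <- canonical_order(occurrence_set(occ))
  if (nrow(occ) < 2L) return(occ)
  groups <- interaction(occ$species, occ$range, drop = TRUE)
  seeds <- split_seeds(seed, nlevels(groups))
  kept <- logical(nrow(occ))
  for (g in seq_len(nlevels(groups))) {
    rows <- which(groups == levels(groups)[g])
    if (length(rows) < 2L) { kept[rows] <- TRUE; next }
    dmat <- haversine_km(occ$longitude[rows], occ$latitude[rows])
    conflict <- dmat < radius_km
    diag(conflict) <- FALSE
    if (!any(conflict)) { kept[rows] <- TRUE; next }
    keep_best <- NULL
    with_seed(seeds[g], {
      for (r in seq_len(reps)) {
        k <- thin_pass(conflict)
        if (is.null(keep_best) || sum(k) > sum(keep_best)) keep_best <- k
      }
    })
    kept[rows[keep_best]] <- TRUE
  }
  out <- occ[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Thin occurrences to one record per raster cell
#'
#' The CELLSIZE rule used before distribution modelling: at most one record
#' is kept in each cell of the climate grid. The retained record per cell is
#' the first in a seed-stable shuffle of the canonically ordered records.
#'
#' @param occ an [occurrence_set()].
#' @param stack a [climate_stack()] defining the cell grid.
#' @param seed integer seed for the shuffle.
#' @return The thinned `occurrence_set`; records outside the raster extent
#'   are rejected and counted in `attr(, "report")$outside`.
#' @export
thin_by_cell <- function(occ, stack, seed = 1) {
  occ <- canonical_order(occurrence_set(occ))
  if (!nrow(occ)) {
    attr(occ, "report") <- list(outside = 0L)
    return(occ)
  }
  rc <- xy_cell(stack, occ$longitude, occ$latitude)
  outside <- is.na(rc[, "row"])
  occ <- occ[!outside, , drop = FALSE]
  rc <- rc[!outside, , drop = FALSE]
  perm <- with_seed(seed, sample.int(nrow(occ)))
  cell <- (rc[, "col"] - 1L) * dim(stack)[1L] + rc[, "row"]
  keep_perm <- !duplicated(cell[perm])
  keep <- sort(perm[keep_perm])
  out <- occ[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- list(outside = sum(outside))
  out
}
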