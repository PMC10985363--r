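#' Multilayer gridded climate stack
#'
#' A `climate_stack` holds an ordered list of named 2-D grids (bioclimatic
#' layers, e.g. `Bio1`..`Bio19`) that share a common shape, affine
#' georeference (WGS84 lon/lat, square cells) and nodata mask. Matrices follow
#' raster convention: row 1 is the northernmost row, column 1 the westernmost
#' column; missing (sea) cells are `NA` in every layer.
#'
#' @param layers named list of numeric matrices with identical dimensions and
#'   identical `NA` pattern.
#' @param xmin,ymin coordinates (decimal degrees) of the lower-left corner of
#'   the grid extent.
#' @param cellsize cell edge length in degrees.
#' @return An object of class `climate_stack`.
#' @examples
#' st <- generate_climate_stack(seed = 1, shape = c(40, 40), n_layers = 3)
#' dim(st)
#' @export
climate_stack <- function(layers, xmin = 0, ymin = 0, cellsize = 0.1) {
  if (!is.list(layers) || length(layers) < 2L) {
    stop_ns("a climate stack needs at least 2 layers")
  }
  nms <- names(layers)
  if (is.null(nms) || anyDuplicated(nms) || any(!nzchar(nms))) {
    stop_ns("layers must carry unique non-empty names")
  }
  if (!all(vapply(layers, is.matrix, logical(1)))) {
    stop_ns("every layer must be a numeric matrix")
  }
  d <- dim(layers[[1L]])
  same_dim <- vapply(layers, function(m) identical(dim(m), d), logical(1))
  if (!all(same_dim)) stop_ns("all layers must share the same shape")
  m0 <- is.na(layers[[1L]])
  same_mask <- vapply(layers, function(m) identical(is.na(m), m0), logical(1))
  if (!all(same_mask)) stop_ns("all layers must share the same nodata mask")
  structure(
    list(layers = layers, xmin = xmin, ymin = ymin, cellsize = cellsize,
         crs = "EPSG:4326", nodata = -9999),
    class = "climate_stack"
  )
}

#' @export
dim.climate_stack <- function(x) dim(x$layers[[1L]])

#' @export
print.climate_stack <- function(x, ...) {
  d <- dim(x)
  cat("climate_stack:", length(x$layers), "layers,", d[1L], "x", d[2L],
      "cells @", x$cellsize, "deg\n")
  cat("  layers:", paste(utils::head(names(x$layers), 6L), collapse = ", "),
      if (length(x$layers) > 6L) "...\n" else "\n")
  cat("  extent: lon [", x$xmin, ",", x$xmin + d[2L] * x$cellsize,
      "] lat [", x$ymin, ",", x$ymin + d[1L] * x$cellsize, "]\n")
  cat("  nodata cells:", sum(is.na(x$layers[[1L]])), "of", prod(d), "\n")
  invisible(x)
}

#' Logical mask of cells with valid climate data
#' @param stack a `climate_stack`.
#' @return Logical matrix, `TRUE` where all layers carry data.
#' @export
stack_mask <- function(stack) !is.na(stack$layers[[1L]])

# centre coordinates of cells given (row, col) matrix indices
cell_xy <- function(stack, row, col) {
  d <- dim(stack)
  cbind(lon = stack$xmin + (col - 0.5) * stack$cellsize,
        lat = stack$ymin + (d[1L] - row + 0.5) * stack$cellsize)
}

# (row, col) of the cell containing each lon/lat point; NA outside the extent
xy_cell <- function(stack, lon, lat) {
  d <- dim(stack)
  col <- floor((lon - stack$xmin) / stack$cellsize) + 1
  row <- d[1L] - floor((lat - stack$ymin) / stack$cellsize)
  bad <- col < 1 | col > d[2L] | row < 1 | row > d[1L] |
    !is.finite(lon) | !is.finite(lat)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Extract layer values at point locations
#'
#' @param stack a `climate_stack`.
#' @param lon,lat point coordinates in decimal degrees.
#' @return Numeric matrix, one row per point, one column per layer; rows are
#'   `NA` for points outside the extent or on nodata cells.
#' @export
extract_env <- function(stack, lon, lat) {
  rc <- xy_cell(stack, lon, lat)
  out <- sapply(stack$layers, function(L) L[rc])
  if (length(lon) == 1L) out <- matrix(out, nrow = 1L,
                                       dimnames = list(NULL, names(stack$layers)))
  out
}

# Gaussian smoothing of a matrix, separable, kernel sd = range cells,
# truncated at 3 sd. Edge rows/columns are renormalised (kernel mass inside
# the grid sums to one), done via row-stochastic band matrices.
smooth_field <- function(m, range) {
  if (range < 1) return(m)
  half <- max(1L, ceiling(3 * range))
  k <- stats::dnorm(seq(-half, half), sd = range)
  band <- function(n) {
    B <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1L, i - half):min(n, i + half)
      B[i, j] <- k[j - i + half + 1L]
    }
    B / rowSums(B)
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

# symmetric PSD factor A with A %*% t(A) = C (eigen-based; tolerates
# semi-definite C where chol() would fail)
psd_factor <- function(C, tol = 1e-8) {
  e <- eigen(C, symmetric = TRUE)
  if (any(e$values < -tol * max(abs(e$values)))) {
    stop_ns("cross_corr must be positive semi-definite")
  }
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(C))
}

#' Generate a synthetic spatially autocorrelated climate stack
#'
#' Builds `n_layers` gridded pseudo-bioclimatic layers by smoothing seeded
#' Gaussian noise fields over `autocorr_range` cells and linearly mixing them
#' to impose a target inter-layer correlation structure. Layers `Bio1..Bio11`
#' are scaled to temperature-like units, the remainder to precipitation-like
#' units (linear scaling, so the imposed correlations are preserved exactly).
#' A smoothed threshold field supplies a shared land/sea nodata mask covering
#' 10--30% of cells.
#'
#' @param seed integer; the single source of randomness.
#' @param shape integer vector `c(nrow, ncol)`.
#' @param n_layers number of layers (>= 2).
#' @param autocorr_range smoothing kernel standard deviation in cells (>= 1);
#'   larger values give longer-range spatial autocorrelation. The grid must
#'   satisfy `min(shape) >= 4 * autocorr_range`.
#' @param cross_corr target inter-layer correlation matrix
#'   (`n_layers x n_layers`, positive semi-definite, unit diagonal), or
#'   `"random"` to draw one, or `NULL` for independent layers.
#' @param xmin,ymin,cellsize georeference passed to [climate_stack()].
#' @return A [climate_stack()].
#' @examples
#' st <- generate_climate_stack(1, shape = c(60, 60), n_layers = 4,
#'                              autocorr_range = 5)
#' @export
generate_climate_stack <- function(seed, shape = c(200, 200), n_layers = 19,
                                   autocorr_range = 10, cross_corr = "random",
                                   xmin = -20, ymin = -20, cellsize = 0.1) {
  stopifnot(length(shape) == 2L)
  if (n_layers < 2L) stop_ns("n_layers must be >= 2")
  if (autocorr_range < 1) stop_ns("autocorr_range must be >= 1")
  if (min(shape) < 4 * autocorr_range) {
    stop_ns("shape too small for autocorr_range (need min(shape) >= 4 * range)")
  }
  seeds <- split_seeds(seed, n_layers + 2L)
  ncell <- prod(shape)

  Z <- matrix(0, ncell, n_layers)
  for (i in seq_len(n_layers)) {
    f <- with_seed(seeds[i], matrix(stats::rnorm(ncell), shape[1L], shape[2L]))
    f <- smooth_field(f, autocorr_range)
    Z[, i] <- (f - mean(f)) / stats::sd(f)
  }

  if (identical(cross_corr, "random")) {
    cross_corr <- with_seed(seeds[n_layers + 1L], {
      A <- matrix(stats::rnorm(n_layers^2), n_layers)
      stats::cov2cor(crossprod(A) + diag(0.5, n_layers))
    })
  }
  if (!is.null(cross_corr)) {
    cross_corr <- as.matrix(cross_corr)
    if (!identical(dim(cross_corr), c(n_layers, n_layers)) &&
        !identical(dim(cross_corr), as.integer(c(n_layers, n_layers)))) {
      stop_ns("cross_corr must be n_layers x n_layers")
    }
    if (max(abs(diag(cross_corr) - 1)) > 1e-6) {
      stop_ns("cross_corr must have unit diagonal (a correlation matrix)")
    }
    Z <- Z %*% t(psd_factor(cross_corr))
  }

  mask_field <- with_seed(seeds[n_layers + 2L], {
    f <- smooth_field(matrix(stats::rnorm(ncell), shape[1L], shape[2L]),
                      autocorr_range)
    sea_frac <- stats::runif(1, 0.10, 0.30)
    list(field = f, frac = sea_frac)
  })
  sea <- mask_field$field < qtile(mask_field$field, mask_field$frac)

  layers <- vector("list", n_layers)
  names(layers) <- paste0("Bio", seq_len(n_layers))
  for (i in seq_len(n_layers)) {
    v <- Z[, i]
    # Bio1..Bio11 temperature-like (degC), the rest precipitation-like (mm)
    v <- if (i <= 11L) 12 + 7 * v else 800 + 350 * v
    L <- matrix(v, shape[1L], shape[2L])
    L[sea] <- NA_real_
    layers[[i]] <- L
  }
  climate_stack(layers, xmin = xmin, ymin = ymin, cellsize = cellsize)
}

#' Write/read a climate stack as ESRI ASCII grids
#'
#' Each layer is written as `<name>.asc` (plain-text ESRI ASCII grid with a
#' `nodata_value` header) next to a `stack.json` sidecar recording layer order
#' and the CRS, so round-trips preserve band order exactly.
#'
#' @param stack a `climate_stack`.
#' @param dir output directory (created if needed).
#' @return `write_stack` returns `dir` invisibly; `read_stack` returns a
#'   [climate_stack()].
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(stack)
  for (nm in names(stack$layers)) {
    L <- stack$layers[[nm]]
    L[is.na(L)] <- stack$nodata
    con <- file(file.path(dir, paste0(nm, ".asc")), "w")
    writeLines(c(
      paste("ncols", d[2L]), paste("nrows", d[1L]),
      paste("xllcorner", stack$xmin), paste("yllcorner", stack$ymin),
      paste("cellsize", stack$cellsize), paste("nodata_value", stack$nodata)
    ), con)
    utils::write.table(format(L, trim = TRUE, digits = 10), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    close(con)
  }
  jsonlite::write_json(
    list(layers = names(stack$layers), crs = stack$crs, nodata = stack$nodata),
    file.path(dir, "stack.json"), auto_unbox = TRUE
  )
  invisible(dir)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack.json"),
                              simplifyVector = TRUE)
  layers <- list()
  hdr <- NULL
  for (nm in meta$layers) {
    lines <- readLines(file.path(dir, paste0(nm, ".asc")))
    kv <- strsplit(lines[1:6], "\\s+")
    h <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                         tolower(vapply(kv, `[`, "", 1L)))
    vals <- scan(text = lines[-(1:6)], quiet = TRUE)
    M <- matrix(vals, nrow = h[["nrows"]], ncol = h[["ncols"]], byrow = TRUE)
    M[M == h[["nodata_value"]]] <- NA_real_
    layers[[nm]] <- M
    hdr <- h
  }
  climate_stack(layers, xmin = hdr[["xllcorner"]], ymin = hdr[["yllcorner"]],
                cellsize = hdr[["cellsize"]])
}
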