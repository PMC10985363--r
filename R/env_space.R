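# Environmental-space (PCA-env) machinery: accessible-area backgrounds,
# climate standardization, pooled-background PCA, and kernel-smoothed
# occupancy grids on the PC1-PC2 plane.

# minimum distance (degrees, planar) from points to a polygon boundary;
# 0 for points inside. poly is a closed-ring matrix of (x, y) vertices.
dist_to_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1L]; ys <- poly[, 2L]
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ys[j] > py)) &
      (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  dmin <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    ex <- xs[i] - xs[j]; ey <- ys[i] - ys[j]
    len2 <- ex^2 + ey^2
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - xs[j]) * ex + (py - ys[j]) * ey) / len2))
    dx <- px - (xs[j] + t * ex); dy <- py - (ys[j] + t * ey)
    dmin <- pmin(dmin, sqrt(dx^2 + dy^2))
    j <- i
  }
  dmin[inside] <- 0
  dmin
}

#' Build the accessible-area background of a region
#'
#' The background is the minimum convex polygon around the region's
#' occurrence records, buffered by `buffer_deg` degrees, intersected with the
#' cells holding valid climate data. It delimits the environment considered
#' geographically accessible by dispersal and defines the availability
#' density of the niche grids.
#'
#' @param occ_region an [occurrence_set()] with the region's records only.
#' @param stack a [climate_stack()].
#' @param buffer_deg buffer width in degrees around the convex hull.
#' @param min_occurrences regions with fewer records are flagged `excluded`
#'   (too little environmental information for a niche comparison).
#' @param label region label stored in the result.
#' @return An object of class `background_region`: `label`, logical cell
#'   `mask`, hull `polygon` (NULL on the point-buffer fallback), `excluded`
#'   flag, and `n_occ`.
#' @export
build_background <- function(occ_region, stack, buffer_deg = 1,
                             min_occurrences = 20, label = NULL) {
  occ_region <- occurrence_set(occ_region)
  label <- label %||% (if (nrow(occ_region)) occ_region$range[1L] else "region")
  n <- nrow(occ_region)
  valid <- stack_mask(stack)
  d <- dim(stack)
  ctr <- cell_xy(stack, row = rep(seq_len(d[1L]), d[2L]),
                 col = rep(seq_len(d[2L]), each = d[1L]))
  px <- occ_region$longitude
  py <- occ_region$latitude

  collinear <- FALSE
  if (n >= 3L) {
    hull <- grDevices::chull(px, py)
    collinear <- length(hull) < 3L
  }
  if (n >= 3L && !collinear) {
    poly <- cbind(px[hull], py[hull])
    dist <- dist_to_polygon(ctr[, "lon"], ctr[, "lat"], poly)
  } else {
    if (n == 0L) stop_ns("cannot build a background from zero occurrences")
    warn_ns("fewer than 3 non-collinear points; buffering points directly")
    poly <- NULL
    dist <- rep(Inf, nrow(ctr))
    for (i in seq_len(n)) {
      dist <- pmin(dist, sqrt((ctr[, "lon"] - px[i])^2 +
                                (ctr[, "lat"] - py[i])^2))
    }
  }
  mask <- matrix(dist <= buffer_deg, d[1L], d[2L]) & valid
  structure(list(label = label, mask = mask, polygon = poly,
                 buffer_deg = buffer_deg, excluded = n < min_occurrences,
                 n_occ = n),
            class = "background_region")
}

#' @export
print.background_region <- function(x, ...) {
  cat("background_region '", x$label, "': ", sum(x$mask), " cells, ",
      x$n_occ, " occurrences", if (x$excluded) " [EXCLUDED]", "\n", sep = "")
  invisible(x)
}

#' Standardize climate layers over a cell mask
#'
#' z-transforms each layer over the masked cells: subtract the mean, divide
#' by the standard deviation (n - 1 denominator), so every variable has mean
#' 0 and unit spread on the mask. Zero-variance layers are dropped with a
#' warning.
#'
#' @param stack a [climate_stack()].
#' @param pooled_mask logical matrix of cells to standardize over.
#' @return An object of class `std_env`: `values` (cells x variables matrix),
#'   `cells` (linear indices into the grid), `center`, `scale`, `dropped`,
#'   and the grid `dim`.
#' @export
ztransform <- function(stack, pooled_mask) {
  stopifnot(is.logical(pooled_mask))
  cells <- which(pooled_mask & stack_mask(stack))
  if (!length(cells)) stop_ns("pooled_mask selects no valid cells")
  X <- vapply(stack$layers, function(L) L[cells], numeric(length(cells)))
  if (length(cells) == 1L) X <- matrix(X, nrow = 1L,
                                       dimnames = list(NULL, names(stack$layers)))
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  degen <- !is.finite(scl) | scl < 1e-12
  if (any(degen)) {
    warn_ns("dropping zero-variance variable(s): ",
            paste(colnames(X)[degen], collapse = ", "))
  }
  X <- sweep(sweep(X[, !degen, drop = FALSE], 2L, ctr[!degen]), 2L,
             scl[!degen], "/")
  structure(list(values = X, cells = cells, center = ctr[!degen],
                 scale = scl[!degen], dropped = names(stack$layers)[degen],
                 dim = dim(stack)),
            class = "std_env")
}

# standardize raw env values (points x layers) with a std_env's center/scale
apply_ztransform <- function(std, env) {
  env <- env[, names(std$center), drop = FALSE]
  sweep(sweep(env, 2L, std$center), 2L, std$scale, "/")
}

#' Calibrate PCA-env on two regions' pooled backgrounds
#'
#' Runs a covariance PCA on the z-transformed climate of the union of the
#' two backgrounds (each cell one observation, equal weight), then projects
#' both regions' background cells and occurrence records onto the component
#' axes. Loadings signs are canonicalized (largest-magnitude loading of each
#' component made positive) for reproducibility.
#'
#' @param stack a [climate_stack()].
#' @param bg_native,bg_invaded [build_background()] results.
#' @param occ_native,occ_invaded the two regions' occurrence sets.
#' @return An object of class `env_scores`: `loadings` (variables x
#'   components, orthonormal columns), `variance_explained`, per-region
#'   background and occurrence score matrices (first two components), and the
#'   shared grid `bounds` (pooled background score range plus a 5% margin).
#' @export
fit_pca_env <- function(stack, bg_native, bg_invaded, occ_native, occ_invaded) {
  pooled_mask <- bg_native$mask | bg_invaded$mask
  std <- ztransform(stack, pooled_mask)
  if (nrow(std$values) < ncol(std$values)) {
    stop_ns("fewer pooled background cells (", nrow(std$values),
            ") than variables (", ncol(std$values), ")")
  }
  pca <- stats::prcomp(std$values, center = FALSE, scale. = FALSE)
  # canonical sign: dominant loading of each component positive
  for (j in seq_len(ncol(pca$rotation))) {
    i <- which.max(abs(pca$rotation[, j]))
    if (pca$rotation[i, j] < 0) {
      pca$rotation[, j] <- -pca$rotation[, j]
      pca$x[, j] <- -pca$x[, j]
    }
  }
  ve <- pca$sdev^2 / sum(pca$sdev^2)

  in_nat <- bg_native$mask[std$cells]
  in_inv <- bg_invaded$mask[std$cells]
  bg_scores <- list(native = pca$x[in_nat, 1:2, drop = FALSE],
                    invaded = pca$x[in_inv, 1:2, drop = FALSE])

  project_occ <- function(occ) {
    if (!nrow(occ)) return(matrix(numeric(), 0L, 2L))
    env <- extract_env(stack, occ$longitude, occ$latitude)
    ok <- stats::complete.cases(env)
    if (!all(ok)) warn_ns(sum(!ok), " occurrence(s) on nodata cells dropped ",
                          "during projection")
    z <- apply_ztransform(std, env[ok, , drop = FALSE])
    (z %*% pca$rotation)[, 1:2, drop = FALSE]
  }
  occ_scores <- list(native = project_occ(occ_native),
                     invaded = project_occ(occ_invaded))

  pooled <- rbind(bg_scores$native, bg_scores$invaded)
  rng <- apply(pooled, 2L, range)
  margin <- 0.05 * (rng[2L, ] - rng[1L, ])
  bounds <- rbind(lower = rng[1L, ] - margin, upper = rng[2L, ] + margin)

  structure(list(loadings = pca$rotation, variance_explained = ve,
                 bg_scores = bg_scores, occ_scores = occ_scores,
                 bounds = bounds, std = std,
                 labels = c(native = bg_native$label,
                            invaded = bg_invaded$label)),
            class = "env_scores")
}

#' @export
print.env_scores <- function(x, ...) {
  cat("env_scores (PCA-env):", ncol(x$loadings), "components over",
      nrow(x$loadings), "variables\n")
  cat(sprintf("  PC1 %.1f%% + PC2 %.1f%% = %.1f%% of variance\n",
              100 * x$variance_explained[1L], 100 * x$variance_explained[2L],
              100 * sum(x$variance_explained[1:2])))
  invisible(x)
}

# Separable 2-D Gaussian KDE on a fixed grid, kernel truncated at 3
# bandwidths (exact zeros outside the data envelope) and renormalized for
# the truncation. Returns a grid integrating to 1 (sum * dx * dy).
kde_grid <- function(pts, gx, gy, bw) {
  trunc_mass <- 2 * stats::pnorm(3) - 1
  K <- function(g, x, h) {
    u <- outer(g, x, "-") / h
    k <- stats::dnorm(u) / (h * trunc_mass)
    k[abs(u) > 3] <- 0
    k
  }
  n <- nrow(pts)
  dens <- (K(gx, pts[, 1L], bw[1L]) %*% t(K(gy, pts[, 2L], bw[2L]))) / n
  dx <- gx[2L] - gx[1L]; dy <- gy[2L] - gy[1L]
  tot <- sum(dens) * dx * dy
  if (tot > 0) dens / tot else dens
}

silverman_bw <- function(x, fallback) {
  bw <- if (length(x) >= 2L) stats::bw.nrd0(x) else NA_real_
  if (!is.finite(bw) || bw <= 0) bw <- fallback  # singleton / zero-spread set
  bw
}

#' Kernel-smoothed occupancy grid of one region in environmental space
#'
#' Grids the PC1-PC2 plane (shared bounds for both regions, so grids are
#' directly comparable) and estimates the occurrence density `o` and the
#' availability density `e` (background cells) with a truncated-Gaussian
#' kernel, bandwidth by Silverman's rule per axis on the point set being
#' smoothed. Occupancy `z` is the availability-corrected ratio `o / e`
#' (0 where no environment exists) rescaled to maximum 1; with
#' `correction = FALSE` the rescaled raw density is used instead.
#'
#' @param scores an [fit_pca_env()] result.
#' @param region `"native"` or `"invaded"`.
#' @param R grid resolution per axis (>= 10).
#' @param correction use availability-corrected occupancy (default on).
#' @return An object of class `niche_grid` with fields `R`, axis vectors
#'   `x`, `y`, cell sizes `dx`, `dy`, densities `o`, `e`, occupancy `z`,
#'   `z_uncor`, and bookkeeping (`region`, `n_occ`, `bw`, `corrected`).
#' @export
occupancy_grid <- function(scores, region = c("native", "invaded"), R = 100,
                           correction = TRUE) {
  region <- match.arg(region)
  if (R < 10) stop_ns("R must be >= 10")
  occ <- scores$occ_scores[[region]]
  bgp <- scores$bg_scores[[region]]
  if (!nrow(occ)) stop_ns("region '", region, "' has no projected occurrences")

  b <- scores$bounds
  gx <- seq(b["lower", 1L], b["upper", 1L], length.out = R)
  gy <- seq(b["lower", 2L], b["upper", 2L], length.out = R)

  clamp <- function(p) {
    out <- p[, 1L] < b["lower", 1L] | p[, 1L] > b["upper", 1L] |
      p[, 2L] < b["lower", 2L] | p[, 2L] > b["upper", 2L]
    if (any(out)) {
      warn_ns(sum(out), " occurrence score(s) outside grid bounds clamped")
      p[, 1L] <- pmin(pmax(p[, 1L], b["lower", 1L]), b["upper", 1L])
      p[, 2L] <- pmin(pmax(p[, 2L], b["lower", 2L]), b["upper", 2L])
    }
    p
  }
  occ <- clamp(occ)

  fb <- c(diff(range(gx)), diff(range(gy))) / 50
  bw_o <- c(silverman_bw(occ[, 1L], fb[1L]), silverman_bw(occ[, 2L], fb[2L]))
  bw_e <- c(silverman_bw(bgp[, 1L], fb[1L]), silverman_bw(bgp[, 2L], fb[2L]))
  o <- kde_grid(occ, gx, gy, bw_o)
  e <- kde_grid(bgp, gx, gy, bw_e)

  z_cor <- ifelse(e > 0, o / e, 0)
  if (max(z_cor) > 0) z_cor <- z_cor / max(z_cor)
  z_unc <- if (max(o) > 0) o / max(o) else o
  z_unc[e == 0] <- 0  # no occupancy where no environment exists

  structure(list(R = R, x = gx, y = gy,
                 dx = gx[2L] - gx[1L], dy = gy[2L] - gy[1L],
                 bounds = b, o = o, e = e,
                 z = if (correction) z_cor else z_unc,
                 z_uncor = z_unc, corrected = correction,
                 region = region, n_occ = nrow(occ),
                 bw = list(occurrence = bw_o, background = bw_e)),
            class = "niche_grid")
}

#' @export
print.niche_grid <- function(x, ...) {
  cat("niche_grid (", x$region, "): ", x$R, "x", x$R, " cells, ",
      x$n_occ, " occurrences, correction ",
      if (x$corrected) "on" else "off", "\n", sep = "")
  cat(sprintf("  PC1 [%.2f, %.2f]  PC2 [%.2f, %.2f]  occupied cells %d\n",
              x$bounds[1L, 1L], x$bounds[2L, 1L], x$bounds[1L, 2L],
              x$bounds[2L, 2L], sum(x$z > 0)))
  invisible(x)
}

#' Serialize a niche grid to JSON
#' @param grid a `niche_grid`.
#' @param path output file.
#' @export
write_niche_grid <- function(grid, path) {
  jsonlite::write_json(
    list(R = grid$R, x = grid$x, y = grid$y,
         o = as.vector(grid$o), e = as.vector(grid$e), z = as.vector(grid$z),
         corrected = grid$corrected, region = grid$region),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}
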