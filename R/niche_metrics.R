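# Niche overlap, similarity permutation test, and the
# expansion/stability/unfilling decomposition.

check_comparable <- function(g1, g2) {
  if (!inherits(g1, "niche_grid") || !inherits(g2, "niche_grid")) {
    stop_ns("both arguments must be niche_grid objects")
  }
  if (g1$R != g2$R || !isTRUE(all.equal(g1$bounds, g2$bounds))) {
    stop_ns("niche grids are not comparable (different bounds or resolution)")
  }
}

#' Schoener's D niche overlap
#'
#' Normalizes each occupancy grid to sum 1 and returns
#' `D = 1 - 0.5 * sum(|z1 - z2|)`: 0 for disjoint niches, 1 for identical
#' ones.
#'
#' @param g1,g2 comparable [occupancy_grid()] results (same bounds and
#'   resolution).
#' @return Scalar overlap in `[0, 1]`.
#' @export
schoener_d <- function(g1, g2) {
  check_comparable(g1, g2)
  s1 <- sum(g1$z); s2 <- sum(g2$z)
  if (s1 == 0 || s2 == 0) stop_ns("cannot compute overlap of an empty niche")
  1 - 0.5 * sum(abs(g1$z / s1 - g2$z / s2))
}

# displace a density grid by whole-cell offsets, dropping mass shifted
# outside the grid
shift_grid <- function(m, di, dj) {
  R <- nrow(m)
  out <- matrix(0, R, ncol(m))
  src_i <- seq_len(R) - di
  src_j <- seq_len(ncol(m)) - dj
  ok_i <- src_i >= 1L & src_i <= R
  ok_j <- src_j >= 1L & src_j <= ncol(m)
  out[ok_i, ok_j] <- m[src_i[ok_i], src_j[ok_j]]
  out
}

#' Niche similarity permutation test
#'
#' Tests whether the observed native-invaded overlap exceeds the overlap
#' expected if the invaded niche sat at random within the invaded range's
#' available environment. Each iteration displaces the invaded occurrence
#' density (shape preserved) so its centre of mass lands on a uniformly
#' drawn cell of the invaded background (`e > 0`), re-truncates it to the
#' available environment, rebuilds the occupancy, and recomputes D against
#' the observed native grid. One-tailed for similarity; ties count toward
#' the null, so `p = (count(D_null >= D_obs) + 1) / (n_iter + 1)`.
#'
#' @param native,invaded comparable [occupancy_grid()] results.
#' @param n_iter permutation count (the conventional choice is 100, giving a
#'   p-value floor of 1/101).
#' @param seed integer seed.
#' @return An object of class `niche_similarity`: `p_value`, `D_obs`,
#'   `null` (vector of D under displacement), `n_iter`.
#' @export
similarity_test <- function(native, invaded, n_iter = 100, seed = 1) {
  check_comparable(native, invaded)
  stopifnot(n_iter >= 1)
  D_obs <- schoener_d(native, invaded)
  avail <- which(invaded$e > 0, arr.ind = TRUE)
  if (nrow(avail) < 2L) stop_ns("degenerate invaded background (single cell)")

  w <- invaded$o
  ci <- sum(row(w) * w) / sum(w)
  cj <- sum(col(w) * w) / sum(w)
  null <- with_seed(seed, {
    vapply(seq_len(n_iter), function(it) {
      repeat {
        tgt <- avail[sample.int(nrow(avail), 1L), ]
        o_null <- shift_grid(w, round(tgt[1L] - ci), round(tgt[2L] - cj))
        o_null[invaded$e == 0] <- 0
        if (sum(o_null) > 0) break
      }
      z_null <- if (invaded$corrected) {
        ifelse(invaded$e > 0, o_null / invaded$e, 0)
      } else {
        o_null
      }
      g_null <- invaded
      g_null$z <- z_null
      schoener_d(native, g_null)
    }, numeric(1))
  })
  p <- (sum(null >= D_obs) + 1) / (n_iter + 1)
  structure(list(p_value = p, D_obs = D_obs, null = null, n_iter = n_iter),
            class = "niche_similarity")
}

#' @export
print.niche_similarity <- function(x, ...) {
  cat(sprintf("niche similarity test: D_obs = %.3f, p = %.3f (%d iterations)\n",
              x$D_obs, x$p_value, x$n_iter))
  invisible(x)
}

#' Expansion / stability / unfilling decomposition
#'
#' Restricts both occupancy grids to the analog climate (cells where both
#' availability densities exceed their own `analog_quantile` quantile of
#' positive values) and decomposes the invaded niche into the proportion of
#' occupancy on conditions novel to the native niche (expansion) versus
#' shared conditions (stability = 1 - expansion), and the native niche into
#' the proportion not re-occupied when invading (unfilling). Proportions are
#' density-weighted by default; `binary = TRUE` weights every occupied cell
#' equally.
#'
#' @param native,invaded comparable [occupancy_grid()] results.
#' @param analog_quantile envelope threshold in `[0, 0.5)`.
#' @param binary use binarized occupancy (`z > 0`) instead of densities.
#' @return List with `expansion`, `stability`, `unfilling` (all `NA` with an
#'   explanatory `"reason"` attribute when the analog region or either niche
#'   is empty there), plus `analog_quantile`, `binary`, `analog_cells`.
#' @export
esu_decomposition <- function(native, invaded, analog_quantile = 0.10,
                              binary = FALSE) {
  check_comparable(native, invaded)
  if (analog_quantile < 0 || analog_quantile >= 0.5) {
    stop_ns("analog_quantile must be in [0, 0.5)")
  }
  thr_n <- qtile(native$e[native$e > 0], analog_quantile)
  thr_i <- qtile(invaded$e[invaded$e > 0], analog_quantile)
  analog <- native$e >= thr_n & invaded$e >= thr_i

  z1 <- native$z
  z2 <- invaded$z
  if (binary) { z1 <- (z1 > 0) * 1; z2 <- (z2 > 0) * 1 }

  undefined <- function(reason) {
    warn_ns("E/S/U undefined: ", reason)
    structure(list(expansion = NA_real_, stability = NA_real_,
                   unfilling = NA_real_, analog_quantile = analog_quantile,
                   binary = binary, analog_cells = sum(analog)),
              reason = reason)
  }
  if (!any(analog)) return(undefined("empty analog climate region"))
  tot2 <- sum(z2[analog])
  tot1 <- sum(z1[analog])
  if (tot2 == 0) return(undefined("invaded niche empty in analog region"))
  if (tot1 == 0) return(undefined("native niche empty in analog region"))

  expansion <- sum(z2[analog & z1 == 0]) / tot2
  unfilling <- sum(z1[analog & z2 == 0]) / tot1
  list(expansion = expansion, stability = 1 - expansion,
       unfilling = unfilling, analog_quantile = analog_quantile,
       binary = binary, analog_cells = sum(analog))
}

#' Compare a native and an invaded range end to end
#'
#' Orchestrates the full niche comparison for one native-invaded pair:
#' accessible-area backgrounds, pooled-background PCA-env, occupancy grids,
#' Schoener's D, the similarity permutation test, and the
#' expansion/stability/unfilling decomposition. Regions failing the
#' minimum-occurrence rule yield a skip record rather than an error.
#'
#' @param occ_native,occ_invaded occurrence sets of the two ranges.
#' @param stack a [climate_stack()].
#' @param buffer_deg background buffer width in degrees.
#' @param R occupancy grid resolution.
#' @param n_iter similarity-test permutations.
#' @param analog_quantile analog-climate envelope threshold.
#' @param correction availability-corrected occupancy (default on).
#' @param min_occurrences minimum records per region.
#' @param seed integer seed (similarity test).
#' @param species species name used in reports.
#' @return An object of class `niche_comparison` with the overlap `D`,
#'   `p_similarity`, the decomposition `expansion`, `stability`,
#'   `unfilling`, the underlying `grids` and `scores`, and a `skipped` flag
#'   (with `skip_reason`) for excluded regions.
#' @examples
#' st <- generate_climate_stack(1, shape = c(80, 80), n_layers = 2,
#'                              autocorr_range = 6)
#' sc <- make_scenario("conservatism", st, seed = 1, n_native = 80,
#'                     n_invaded = 80)
#' nc <- niche_compare(sc$native, sc$invaded, st, n_iter = 20, seed = 1)
#' nc
#' @export
niche_compare <- function(occ_native, occ_invaded, stack, buffer_deg = 1,
                          R = 100, n_iter = 100, analog_quantile = 0.10,
                          correction = TRUE, min_occurrences = 20, seed = 1,
                          species = NULL) {
  occ_native <- occurrence_set(occ_native)
  occ_invaded <- occurrence_set(occ_invaded)
  species <- species %||%
    (if (nrow(occ_native)) occ_native$species[1L] else "species")
  labels <- c(native = if (nrow(occ_native)) occ_native$range[1L] else "native",
              invaded = if (nrow(occ_invaded)) occ_invaded$range[1L] else "invaded")

  skip <- function(reason) {
    structure(list(species = species, labels = labels, skipped = TRUE,
                   skip_reason = reason,
                   n_occ = c(native = nrow(occ_native),
                             invaded = nrow(occ_invaded))),
              class = "niche_comparison")
  }
  if (nrow(occ_native) < min_occurrences) {
    return(skip(sprintf("native range has %d < %d occurrences",
                        nrow(occ_native), min_occurrences)))
  }
  if (nrow(occ_invaded) < min_occurrences) {
    return(skip(sprintf("invaded range has %d < %d occurrences",
                        nrow(occ_invaded), min_occurrences)))
  }

  bg_n <- build_background(occ_native, stack, buffer_deg,
                           min_occurrences, label = labels["native"])
  bg_i <- build_background(occ_invaded, stack, buffer_deg,
                           min_occurrences, label = labels["invaded"])
  scores <- fit_pca_env(stack, bg_n, bg_i, occ_native, occ_invaded)
  g_n <- occupancy_grid(scores, "native", R = R, correction = correction)
  g_i <- occupancy_grid(scores, "invaded", R = R, correction = correction)

  D <- schoener_d(g_n, g_i)
  sim <- similarity_test(g_n, g_i, n_iter = n_iter, seed = seed)
  esu <- esu_decomposition(g_n, g_i, analog_quantile = analog_quantile)

  structure(list(
    species = species, labels = labels, skipped = FALSE, skip_reason = NULL,
    D = D, p_similarity = sim$p_value, n_iter = n_iter, similarity = sim,
    expansion = esu$expansion, stability = esu$stability,
    unfilling = esu$unfilling, analog_quantile = analog_quantile,
    esu = esu, grids = list(native = g_n, invaded = g_i), scores = scores,
    backgrounds = list(native = bg_n, invaded = bg_i),
    n_occ = c(native = nrow(occ_native), invaded = nrow(occ_invaded)),
    config = list(buffer_deg = buffer_deg, R = R, correction = correction,
                  min_occurrences = min_occurrences, seed = seed)
  ), class = "niche_comparison")
}

#' @export
print.niche_comparison <- function(x, ...) {
  cat("niche_comparison:", x$species, "|", x$labels["native"], "->",
      x$labels["invaded"], "\n")
  if (x$skipped) {
    cat("  SKIPPED:", x$skip_reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("  D = %.3f   similarity p = %.3f (%d iter)\n",
              x$D, x$p_similarity, x$n_iter))
  cat(sprintf("  unfilling %.3f   stability %.3f   expansion %.3f\n",
              x$unfilling, x$stability, x$expansion))
  invisible(x)
}

#' @export
summary.niche_comparison <- function(object, ...) {
  print(object)
  if (!object$skipped) {
    ve <- object$scores$variance_explained
    cat(sprintf("  PCA-env: PC1 %.1f%%, PC2 %.1f%% (joint %.1f%%)\n",
                100 * ve[1L], 100 * ve[2L], 100 * sum(ve[1:2])))
    cat("  occurrences:", object$n_occ["native"], "native /",
        object$n_occ["invaded"], "invaded\n")
    cat("  analog cells:", object$esu$analog_cells, "of",
        object$grids$native$R^2, "\n")
  }
  invisible(object)
}

#' @export
as.data.frame.niche_comparison <- function(x, ...) {
  data.frame(species = x$species,
             region = unname(x$labels["invaded"]),
             D = if (x$skipped) NA_real_ else x$D,
             p_similarity = if (x$skipped) NA_real_ else x$p_similarity,
             unfilling = if (x$skipped) NA_real_ else x$unfilling,
             stability = if (x$skipped) NA_real_ else x$stability,
             expansion = if (x$skipped) NA_real_ else x$expansion,
             skipped = x$skipped)
}

#' Plot the occupancy grids of a niche comparison
#'
#' Draws the native and invaded occupancy surfaces side by side in the
#' shared PC1-PC2 plane, with the analog-climate envelope contours.
#'
#' @param x a `niche_comparison`.
#' @param ... passed to [graphics::image()].
#' @export
plot.niche_comparison <- function(x, ...) {
  if (x$skipped) {
    stop_ns("comparison was skipped (", x$skip_reason, "); nothing to plot")
  }
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  for (r in c("native", "invaded")) {
    g <- x$grids[[r]]
    graphics::image(g$x, g$y, g$z, col = grDevices::hcl.colors(32, "YlGnBu",
                                                               rev = TRUE),
                    xlab = "PC1", ylab = "PC2",
                    main = paste0(r, " (", x$labels[r], ")"), ...)
    graphics::contour(g$x, g$y, g$e, levels = qtile(g$e[g$e > 0],
                                                    x$analog_quantile),
                      add = TRUE, drawlabels = FALSE, lty = 2)
  }
  invisible(x)
}
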