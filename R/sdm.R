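# Ensemble species-distribution pipeline: principal-component predictors,
# bioclim-envelope pseudo-absence placement, spatial BLOCK cross-validation,
# four model backends, Jaccard evaluation, Jaccard-weighted ensembling and
# the a-posteriori occurrence-based spatial constraint.

#' Select principal-component predictors at a cumulative-variance target
#'
#' PCA of a standardized climate table; keeps the minimal number of leading
#' components whose cumulative explained variance reaches `variance_target`
#' (the conventional choice is 95%).
#'
#' @param std a [ztransform()] result over the modelling domain.
#' @param variance_target fraction in (0, 1].
#' @return An object of class `predictor_stack`: `scores` (cells x k),
#'   `grids` (list of k component matrices), `k`, `cumulative_variance`,
#'   `loadings`, `cells`, `dim`.
#' @export
select_pcs <- function(std, variance_target = 0.95) {
  if (variance_target <= 0 || variance_target > 1) {
    stop_ns("variance_target must be in (0, 1]")
  }
  pca <- stats::prcomp(std$values, center = FALSE, scale. = FALSE)
  ve <- pca$sdev^2 / sum(pca$sdev^2)
  k <- which(cumsum(ve) >= variance_target - 1e-12)[1L]
  grids <- lapply(seq_len(k), function(j) {
    G <- matrix(NA_real_, std$dim[1L], std$dim[2L])
    G[std$cells] <- pca$x[, j]
    G
  })
  names(grids) <- paste0("PC", seq_len(k))
  structure(list(scores = pca$x[, seq_len(k), drop = FALSE], grids = grids,
                 k = k, cumulative_variance = sum(ve[seq_len(k)]),
                 variance_explained = ve,
                 loadings = pca$rotation[, seq_len(k), drop = FALSE],
                 cells = std$cells, dim = std$dim),
            class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf("predictor_stack: %d components, %.1f%% cumulative variance, %d cells\n",
              x$k, 100 * x$cumulative_variance, nrow(x$scores)))
  invisible(x)
}

#' Bioclim envelope suitability
#'
#' Classic percentile-depth envelope: per predictor, a cell at the presence
#' median scores 1 and the score declines linearly to 0 at (and beyond) the
#' presence range limits, `1 - 2 * |F(x) - 0.5|` with `F` the presence
#' empirical CDF; the cell score is the minimum across predictors.
#'
#' @param presence_values matrix (presences x predictors).
#' @param predictor_values matrix (cells x predictors) to score.
#' @return Numeric vector of envelope scores in `[0, 1]`, one per cell.
#' @export
bioclim_envelope <- function(presence_values, predictor_values) {
  presence_values <- as.matrix(presence_values)
  predictor_values <- as.matrix(predictor_values)
  if (nrow(presence_values) < 5L) stop_ns("need >= 5 presences for an envelope")
  score <- rep(Inf, nrow(predictor_values))
  used <- 0L
  for (j in seq_len(ncol(presence_values))) {
    pv <- presence_values[, j]
    if (stats::sd(pv) < 1e-12) {
      warn_ns("degenerate predictor ", j, " skipped in envelope")
      next
    }
    used <- used + 1L
    F <- stats::ecdf(pv)(predictor_values[, j])
    score <- pmin(score, 1 - 2 * abs(F - 0.5))
  }
  if (!used) stop_ns("all predictors degenerate; envelope undefined")
  pmax(score, 0)
}

#' Sample environmentally constrained pseudo-absences
#'
#' Draws pseudo-absence cells uniformly without replacement from the
#' low-suitability stratum: cells whose envelope score falls strictly below
#' the `low_quantile` quantile of the presence-cell scores, at least
#' `min_distance_cells` (Euclidean, cell units) from any presence cell.
#'
#' @param envelope numeric vector of envelope scores per domain cell.
#' @param cells linear cell indices matching `envelope`.
#' @param dim grid dimensions.
#' @param presence_cells linear indices of presence cells.
#' @param n number of pseudo-absences (default policy is 1 per presence).
#' @param low_quantile quantile of presence-cell suitability delimiting "low".
#' @param min_distance_cells exclusion radius around presences.
#' @param seed integer seed.
#' @return Integer vector of pseudo-absence cell indices.
#' @export
sample_pseudoabsences <- function(envelope, cells, dim, presence_cells, n,
                                  low_quantile = 0.5, min_distance_cells = 2,
                                  seed = 1) {
  pres_score <- envelope[match(presence_cells, cells)]
  thr <- qtile(pres_score[!is.na(pres_score)], low_quantile)
  eligible <- envelope < thr
  if (!any(eligible)) {
    stop_ns("no low-suitability stratum: no cell scores below the presence ",
            "quantile threshold ", signif(thr, 4))
  }
  er <- (cells - 1L) %% dim[1L] + 1L
  ec <- (cells - 1L) %/% dim[1L] + 1L
  pr <- (presence_cells - 1L) %% dim[1L] + 1L
  pc <- (presence_cells - 1L) %/% dim[1L] + 1L
  mind2 <- rep(Inf, length(cells))
  for (i in seq_along(presence_cells)) {
    mind2 <- pmin(mind2, (er - pr[i])^2 + (ec - pc[i])^2)
  }
  eligible <- eligible & mind2 >= min_distance_cells^2
  pool <- cells[eligible]
  if (length(pool) < n) {
    stop_ns("only ", length(pool), " eligible low-suitability cells; ",
            "cannot draw ", n, " pseudo-absences")
  }
  with_seed(seed, sample(pool, n))
}

#' Spatial BLOCK partition of presence/pseudo-absence points
#'
#' Tiles the bounding box of the points into square blocks and assigns
#' blocks to folds in a checkerboard cycle (a 2 x 2 chequer for 4 folds,
#' diagonal striping otherwise), so held-out points are geographically
#' separated from training points. When `blocks_per_side = "auto"` the
#' smallest tiling for which every fold holds at least 5% of presences (and
#' at least one point of each class) is used.
#'
#' @param lon,lat point coordinates.
#' @param is_presence logical vector, `TRUE` for presences.
#' @param n_folds number of folds (>= 2).
#' @param blocks_per_side `"auto"` or an integer number of blocks per axis.
#' @return Integer fold id per point, with the chosen `blocks_per_side` as
#'   attribute `"blocks_per_side"`.
#' @export
block_partition <- function(lon, lat, is_presence, n_folds = 4,
                            blocks_per_side = "auto") {
  stopifnot(n_folds >= 2, length(lon) == length(lat),
            length(lon) == length(is_presence))
  assign_folds <- function(nb) {
    bx <- pmin(nb, findInterval(lon, seq(min(lon), max(lon),
                                         length.out = nb + 1L),
                                rightmost.closed = TRUE))
    by <- pmin(nb, findInterval(lat, seq(min(lat), max(lat),
                                         length.out = nb + 1L),
                                rightmost.closed = TRUE))
    if (n_folds == 4L) {
      ((bx - 1L) %% 2L) * 2L + ((by - 1L) %% 2L) + 1L
    } else {
      (bx + by) %% n_folds + 1L
    }
  }
  balanced <- function(fold) {
    tab_p <- tabulate(fold[is_presence], n_folds)
    tab_a <- tabulate(fold[!is_presence], n_folds)
    all(tab_p >= max(1, 0.05 * sum(is_presence))) && all(tab_a >= 1)
  }
  candidates <- if (identical(blocks_per_side, "auto")) 2:20 else
    as.integer(blocks_per_side)
  for (nb in candidates) {
    fold <- assign_folds(nb)
    if (balanced(fold)) {
      attr(fold, "blocks_per_side") <- nb
      return(fold)
    }
  }
  fold <- assign_folds(utils::tail(candidates, 1L))
  stop_ns("no block tiling balances the folds (tried ",
          paste(range(candidates), collapse = "-"), " blocks per side; ",
          "last attempt presence counts: ",
          paste(tabulate(fold[is_presence], n_folds), collapse = ", "), ")")
}

# ---- model backends --------------------------------------------------------
# Uniform contract: fit_backend(algo, X, y, seed) returns function(newX) in
# [0, 1]. X is the (already standardized) PC score matrix; y is 0/1.

quad_expand <- function(X) cbind(X, X^2)

fit_backend <- function(algo, X, y, seed) {
  if (length(unique(y)) < 2L) stop_ns("training fold has a single class")
  if (all(apply(X, 2L, stats::sd) < 1e-12)) {
    stop_ns("constant predictors: model would be uninformative")
  }
  switch(algo,
    MXS = ,
    MXL = {
      # maximum-entropy-equivalent ridge logistic model; MXS uses the default
      # linear + quadratic feature expansion, MXL the linear features only
      # (comparison variant). Penalty chosen by internal cross-validation.
      expand <- if (algo == "MXS") quad_expand else identity
      foldid <- with_seed(seed, sample(rep_len(1:5, length(y))))
      fit <- glmnet::cv.glmnet(expand(X), y, family = "binomial", alpha = 0,
                               foldid = foldid, nlambda = 50)
      function(newX) {
        as.numeric(stats::predict(fit, expand(newX), s = "lambda.min",
                                  type = "response"))
      }
    },
    SVM = {
      fit <- with_seed(seed, e1071::svm(X, factor(y), probability = TRUE,
                                        kernel = "radial"))
      function(newX) {
        pr <- stats::predict(fit, newX, probability = TRUE)
        attr(pr, "probabilities")[, "1"]
      }
    },
    RDF = {
      fit <- with_seed(seed, randomForest::randomForest(X, factor(y),
                                                        ntree = 500))
      function(newX) stats::predict(fit, newX, type = "prob")[, "1"]
    },
    BRT = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y)
      fit <- with_seed(seed, xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = 0.1, max_depth = 3,
                      nthread = 1),
        data = dtrain, nrounds = 150, verbose = 0
      ))
      function(newX) stats::predict(fit, xgboost::xgb.DMatrix(newX))
    },
    stop_ns("unknown algorithm: ", algo)
  )
}

#' Fit the SDM algorithm backends on a training set
#'
#' Uniform train/predict contract over the four supported algorithms: MXS
#' (penalized maximum-entropy model: ridge logistic regression on linear +
#' quadratic feature expansions), SVM (radial support vector machine), RDF
#' (random forest), BRT (boosted regression trees). Outputs are suitability
#' values in `[0, 1]`.
#'
#' @param X predictor matrix (points x components).
#' @param y 0/1 response (presence / pseudo-absence).
#' @param algorithms subset of `c("MXS", "SVM", "RDF", "BRT")`; the extra
#'   value `"MXL"` selects a linear-features-only maximum-entropy variant,
#'   useful for feature-set comparisons.
#' @param seed integer seed.
#' @return Named list of prediction closures, one per algorithm.
#' @export
fit_models <- function(X, y, algorithms = c("BRT", "MXS", "RDF", "SVM"),
                       seed = 1) {
  stopifnot(length(algorithms) >= 1L)
  seeds <- split_seeds(seed, length(algorithms))
  out <- lapply(seq_along(algorithms), function(i) {
    fit_backend(algorithms[i], X, y, seeds[i])
  })
  names(out) <- algorithms
  out
}

jaccard_score <- function(pred_bin, truth) {
  tp <- sum(pred_bin & truth)
  fp <- sum(pred_bin & !truth)
  fn <- sum(!pred_bin & truth)
  if (tp + fp + fn == 0) return(NA_real_)
  tp / (tp + fp + fn)
}

#' Jaccard evaluation of a suitability prediction
#'
#' Binarizes predictions at the threshold maximizing the Jaccard index
#' (`TP / (TP + FP + FN)`) on the training points, then scores the held-out
#' points at that threshold.
#'
#' @param pred_test,truth_test held-out predictions and 0/1 truth.
#' @param pred_train,truth_train training-fold predictions and truth used to
#'   pick the threshold; defaults to the test set (resubstitution) when
#'   omitted.
#' @return List with `jaccard` and the `threshold` used.
#' @export
evaluate_jaccard <- function(pred_test, truth_test,
                             pred_train = pred_test,
                             truth_train = truth_test) {
  stopifnot(length(pred_test) == length(truth_test), length(truth_test) > 0)
  cand <- sort(unique(pred_train))
  train_scores <- vapply(cand, function(t) {
    jaccard_score(pred_train >= t, truth_train == 1)
  }, numeric(1))
  if (all(is.na(train_scores))) {
    warn_ns("no positive predictions at any threshold; score 0")
    return(list(jaccard = 0, threshold = NA_real_))
  }
  thr <- cand[which.max(train_scores)]
  j <- jaccard_score(pred_test >= thr, truth_test == 1)
  if (is.na(j)) {
    warn_ns("no positive predictions at the selected threshold; score 0")
    j <- 0
  }
  list(jaccard = j, threshold = thr)
}

#' Jaccard-weighted ensemble of suitability grids
#'
#' Cell-wise weighted mean with weights proportional to each algorithm's
#' evaluation score (weights normalized to sum 1). All-zero scores fall back
#' to an unweighted mean with a warning.
#'
#' @param grids list of >= 2 suitability matrices (same shape).
#' @param scores numeric vector of evaluation scores, one per grid.
#' @return List with the `ensemble` matrix and the normalized `weights`.
#' @export
ensemble_weighted <- function(grids, scores) {
  stopifnot(length(grids) >= 2L, length(scores) == length(grids))
  if (all(scores == 0)) {
    warn_ns("all evaluation scores are zero; using an unweighted mean")
    scores <- rep(1, length(scores))
  }
  w <- scores / sum(scores)
  ens <- Reduce(`+`, Map(function(g, wi) g * wi, grids, w))
  list(ensemble = ens, weights = stats::setNames(w, names(grids)))
}

#' Occurrence-based spatial constraint
#'
#' Labels the rook-adjacent connected components of the suitable cells of a
#' binary map and retains only components containing at least one presence
#' cell, removing suitable patches the species has never been recorded in.
#'
#' @param binary logical (or 0/1) matrix of suitable cells (`NA` allowed).
#' @param presence_cells linear indices of presence cells.
#' @return Logical matrix of the constrained map (same `NA` pattern).
#' @export
occurrence_constraint <- function(binary, presence_cells) {
  bin <- !is.na(binary) & binary > 0
  suit <- which(bin)
  if (!length(suit)) return(bin)
  d <- dim(bin)
  id <- match(seq_len(prod(d)), suit)  # cell -> vertex id
  edges <- integer(0)
  r <- (suit - 1L) %% d[1L] + 1L
  co <- (suit - 1L) %/% d[1L] + 1L
  down_ok <- r < d[1L] & !is.na(id[suit + 1L])
  right_ok <- co < d[2L] & !is.na(id[suit + d[1L]])
  edges <- c(rbind(id[suit[down_ok]], id[suit[down_ok] + 1L]),
             rbind(id[suit[right_ok]], id[suit[right_ok] + d[1L]]))
  g <- igraph::make_graph(edges, n = length(suit), directed = FALSE)
  comp <- igraph::components(g)$membership
  keep_comp <- unique(comp[id[presence_cells][!is.na(id[presence_cells])]])
  out <- matrix(FALSE, d[1L], d[2L])
  out[suit[comp %in% keep_comp]] <- TRUE
  out[is.na(binary)] <- NA
  out
}

#' Fit the full ensemble species-distribution pipeline
#'
#' End-to-end modelling for one species over the valid cells of a climate
#' stack: cell-level thinning, z-transformed climate, principal-component
#' predictors at the cumulative-variance target, bioclim-envelope
#' environmentally constrained pseudo-absences (1:1 with presences by
#' default), spatial BLOCK cross-validation, per-fold model evaluation with
#' the Jaccard index, per-algorithm full-data suitability maps, the
#' Jaccard-weighted ensemble, and the occurrence-constrained binary map.
#'
#' @param occ an [occurrence_set()] of presences.
#' @param stack a [climate_stack()].
#' @param algorithms subset of `c("BRT", "MXS", "RDF", "SVM")`.
#' @param variance_target cumulative variance for [select_pcs()].
#' @param pa_ratio pseudo-absences per presence.
#' @param n_folds BLOCK folds.
#' @param low_quantile,min_distance_cells pseudo-absence constraints, see
#'   [sample_pseudoabsences()]. The exclusion radius defaults to 10 cells,
#'   the spatial autocorrelation scale of typical climate grids: a
#'   pseudo-absence inside the correlated neighbourhood of a presence is an
#'   environmental near-duplicate of it and would carry a contradictory
#'   label.
#' @param seed integer seed governing all randomness.
#' @return An object of class `sdm_result`: per-algorithm suitability
#'   `maps`, fold-wise `jaccard` matrix (algorithms x folds), the fold-wise
#'   `ensemble_jaccard` of the weighted ensemble prediction, normalized
#'   ensemble `weights`, `ensemble` grid, `binary` and `constrained` maps,
#'   the `threshold` used, fold assignment and training bookkeeping.
#' @export
sdm_ensemble <- function(occ, stack, algorithms = c("BRT", "MXS", "RDF", "SVM"),
                         variance_target = 0.95, pa_ratio = 1, n_folds = 4,
                         low_quantile = 0.5, min_distance_cells = 10,
                         seed = 1) {
  occ <- occurrence_set(occ)
  seeds <- split_seeds(seed, 3L)
  occ <- thin_by_cell(occ, stack, seed = seeds[1L])

  valid <- stack_mask(stack)
  std <- ztransform(stack, valid)
  pred <- select_pcs(std, variance_target)

  rc <- xy_cell(stack, occ$longitude, occ$latitude)
  pres_cells <- unique((rc[, "col"] - 1L) * dim(stack)[1L] + rc[, "row"])
  pres_cells <- pres_cells[pres_cells %in% pred$cells]
  if (length(pres_cells) < 5L) stop_ns("fewer than 5 usable presence cells")

  row_of <- match(pres_cells, pred$cells)
  X_pres <- pred$scores[row_of, , drop = FALSE]

  env <- bioclim_envelope(X_pres, pred$scores)
  n_pa <- round(pa_ratio * length(pres_cells))
  pa_cells <- sample_pseudoabsences(env, pred$cells, dim(stack), pres_cells,
                                    n_pa, low_quantile, min_distance_cells,
                                    seed = seeds[2L])
  X_pa <- pred$scores[match(pa_cells, pred$cells), , drop = FALSE]

  cells_all <- c(pres_cells, pa_cells)
  X <- rbind(X_pres, X_pa)
  y <- c(rep(1L, length(pres_cells)), rep(0L, length(pa_cells)))
  d <- dim(stack)
  rr <- (cells_all - 1L) %% d[1L] + 1L
  cc <- (cells_all - 1L) %/% d[1L] + 1L
  xy <- cell_xy(stack, rr, cc)
  fold <- block_partition(xy[, "lon"], xy[, "lat"], y == 1L, n_folds)

  algo_seeds <- split_seeds(seeds[3L], n_folds + 1L)
  jac <- matrix(NA_real_, length(algorithms), n_folds,
                dimnames = list(algorithms, paste0("fold", seq_len(n_folds))))
  thresholds <- jac
  train_folds <- vector("list", n_folds)
  fold_pred <- vector("list", n_folds)  # per-fold train/test predictions
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    train_folds[[f]] <- sort(unique(fold[tr]))
    models <- fit_models(X[tr, , drop = FALSE], y[tr], algorithms,
                         seed = algo_seeds[f])
    p_tr <- sapply(algorithms, function(a) models[[a]](X[tr, , drop = FALSE]))
    p_te <- sapply(algorithms, function(a) models[[a]](X[!tr, , drop = FALSE]))
    for (a in algorithms) {
      ev <- evaluate_jaccard(p_te[, a], y[!tr], p_tr[, a], y[tr])
      jac[a, f] <- ev$jaccard
      thresholds[a, f] <- ev$threshold
    }
    fold_pred[[f]] <- list(train = p_tr, test = p_te, y_train = y[tr],
                           y_test = y[!tr])
  }

  final <- fit_models(X, y, algorithms, seed = algo_seeds[n_folds + 1L])
  maps <- lapply(final, function(m) {
    G <- matrix(NA_real_, d[1L], d[2L])
    G[pred$cells] <- m(pred$scores)
    G
  })

  mean_jac <- rowMeans(jac)
  ens <- ensemble_weighted(maps, mean_jac)
  ens_jac <- vapply(fold_pred, function(fp) {
    evaluate_jaccard(drop(fp$test %*% ens$weights), fp$y_test,
                     drop(fp$train %*% ens$weights), fp$y_train)$jaccard
  }, numeric(1))
  ens_pts <- ens$ensemble[cells_all]
  thr <- evaluate_jaccard(ens_pts, y)$threshold
  binary <- !is.na(ens$ensemble) & ens$ensemble >= thr
  binary[is.na(ens$ensemble)] <- NA
  constrained <- occurrence_constraint(binary, pres_cells)

  structure(list(
    maps = maps, jaccard = jac, fold_thresholds = thresholds,
    mean_jaccard = mean_jac, ensemble_jaccard = ens_jac,
    mean_ensemble_jaccard = mean(ens_jac), weights = ens$weights,
    ensemble = ens$ensemble, threshold = thr,
    binary = binary, constrained = constrained,
    predictors = pred, envelope = env,
    points = data.frame(cell = cells_all, lon = xy[, "lon"],
                        lat = xy[, "lat"], presence = y, fold = fold),
    train_folds = train_folds, algorithms = algorithms,
    config = list(variance_target = variance_target, pa_ratio = pa_ratio,
                  n_folds = n_folds, low_quantile = low_quantile,
                  min_distance_cells = min_distance_cells, seed = seed)
  ), class = "sdm_result")
}

#' @export
print.sdm_result <- function(x, ...) {
  cat("sdm_result:", length(x$algorithms), "algorithms,",
      x$config$n_folds, "BLOCK folds,", x$predictors$k, "PC predictors\n")
  for (a in x$algorithms) {
    cat(sprintf("  %-4s mean fold Jaccard %.3f (weight %.3f)\n",
                a, x$mean_jaccard[a], x$weights[a]))
  }
  cat(sprintf("  WMEA mean fold Jaccard %.3f\n", x$mean_ensemble_jaccard))
  cat(sprintf("  ensemble threshold %.3f; suitable cells %d -> %d after ",
              x$threshold, sum(x$binary, na.rm = TRUE),
              sum(x$constrained, na.rm = TRUE)))
  cat("occurrence constraint\n")
  invisible(x)
}

#' @export
summary.sdm_result <- function(object, ...) {
  print(object)
  cat("  fold-wise Jaccard:\n")
  print(round(object$jaccard, 3))
  cat(sprintf("  cumulative predictor variance: %.1f%%\n",
              100 * object$predictors$cumulative_variance))
  invisible(object)
}

#' Evaluation table of an SDM run (one row per species)
#' @param x an `sdm_result`.
#' @param species species name for the row.
#' @return Data frame with per-algorithm mean Jaccard and the weighted
#'   ensemble score (`WMEA`).
#' @export
sdm_evaluation_table <- function(x, species = "species") {
  row <- as.list(round(x$mean_jaccard, 2))
  row$WMEA <- round(x$mean_ensemble_jaccard, 2)
  cbind(data.frame(species = species), as.data.frame(row))
}

#' Plot an SDM ensemble map
#' @param x an `sdm_result`.
#' @param which one of `"ensemble"`, `"binary"`, `"constrained"`.
#' @param ... passed to [graphics::image()].
#' @export
plot.sdm_result <- function(x, which = c("ensemble", "binary", "constrained"),
                            ...) {
  which <- match.arg(which)
  M <- x[[which]]
  # transpose to geographic orientation (x = lon, y = lat)
  graphics::image(t(M)[, nrow(M):1, drop = FALSE],
                  col = grDevices::hcl.colors(32, "viridis"),
                  main = paste("SDM", which), ...)
  invisible(x)
}
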