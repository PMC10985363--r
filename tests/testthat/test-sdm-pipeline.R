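# Predictor selection, pseudo-absences, BLOCK folds, model backends,
# Jaccard evaluation, ensembling and the occurrence constraint.

std_from_matrix <- function(X, dim = c(nrow(X), 1L)) {
  # minimal std_env wrapper for tables built directly in tests
  structure(list(values = scale(X), cells = seq_len(nrow(X)),
                 center = colMeans(X), scale = apply(X, 2, sd),
                 dropped = character(), dim = dim),
            class = "std_env")
}

test_that("PC retention reaches the variance target and finds true rank", {
  set.seed(1)
  n <- 400
  base <- matrix(rnorm(n * 3), n)
  X <- cbind(base, base %*% matrix(rnorm(9), 3)) +
    matrix(rnorm(n * 6, sd = 1e-4), n)
  colnames(X) <- paste0("Bio", 1:6)
  ps <- select_pcs(std_from_matrix(X), 0.95)
  expect_equal(ps$k, 3)
  expect_gte(ps$cumulative_variance, 0.95)
  # target 1 keeps every non-degenerate axis
  ps_all <- select_pcs(std_from_matrix(X), 1.0)
  expect_equal(ps_all$k, 6)
  expect_error(select_pcs(std_from_matrix(X), 1.2), "variance_target")
})

test_that("a 19-layer synthetic stack meets the 95% rule by construction", {
  st <- fixture_stack(3, shape = c(100, 100), n_layers = 19,
                      autocorr_range = 6)
  std <- ztransform(st, stack_mask(st))
  ps <- select_pcs(std, 0.95)
  expect_gte(ps$cumulative_variance, 0.95)
  expect_lte(ps$k, 19)
  expect_length(ps$grids, ps$k)
})

test_that("bioclim envelope follows the percentile-depth closed form", {
  pres <- cbind(a = 1:100, b = rep(50, 100))  # b degenerate
  cells <- cbind(a = c(50, 25, 0, 100, 150), b = rep(50, 5))
  expect_warning(s <- bioclim_envelope(pres, cells), "degenerate")
  expect_equal(s[1], 1.0)        # at the median
  expect_equal(s[2], 0.5)        # 25th percentile
  expect_equal(s[3], 0.0)        # below the range
  expect_equal(s[5], 0.0)        # above the range
  expect_error(bioclim_envelope(pres[1:3, ], cells), ">= 5")
  expect_error(suppressWarnings(
    bioclim_envelope(cbind(rep(1, 9)), cbind(1))), "degenerate")
})

test_that("pseudo-absences respect the low-suitability stratum and distances", {
  set.seed(7)
  dim <- c(40L, 40L)
  cells <- seq_len(prod(dim))
  # envelope high inside a box, zero outside
  env <- rep(0, length(cells))
  r <- (cells - 1) %% 40 + 1; cc <- (cells - 1) %/% 40 + 1
  inbox <- r > 10 & r < 25 & cc > 10 & cc < 25
  env[inbox] <- runif(sum(inbox), 0.5, 1)
  pres <- sample(cells[inbox], 30)
  pa <- sample_pseudoabsences(env, cells, dim, pres, n = 30,
                              min_distance_cells = 3, seed = 2)
  expect_length(pa, 30)
  expect_true(all(!inbox[pa]))   # outside the box
  dmin <- sapply(pa, function(p) {
    min(sqrt(((p - 1) %% 40 - (pres - 1) %% 40)^2 +
               ((p - 1) %/% 40 - (pres - 1) %/% 40)^2))
  })
  expect_true(all(dmin >= 3))
  # uniform envelope: no stratum below the presence quantile
  expect_error(sample_pseudoabsences(rep(0.7, length(cells)), cells, dim,
                                     pres, 10, seed = 1), "stratum")
  # infeasible draw reports the achievable maximum
  expect_error(sample_pseudoabsences(env, cells, dim, pres, n = 100000,
                                     seed = 1), "eligible")
})

test_that("BLOCK partition balances folds and is deterministic", {
  set.seed(9)
  lon <- runif(400); lat <- runif(400)
  pres <- rep(c(TRUE, FALSE), 200)
  f1 <- block_partition(lon, lat, pres, n_folds = 4)
  f2 <- block_partition(lon, lat, pres, n_folds = 4)
  expect_identical(f1, f2)
  expect_equal(sort(unique(f1)), 1:4)
  expect_true(all(tabulate(f1[pres], 4) >= 0.05 * sum(pres)))
  expect_true(all(tabulate(f1[!pres], 4) >= 1))

  # uniform 2x2 blocks with 4 folds: one quadrant per fold
  qx <- rep(c(0.2, 0.8), each = 50); qy <- rep(c(0.2, 0.8, 0.2, 0.8), 25)
  fq <- block_partition(qx, qy, rep(c(TRUE, TRUE, FALSE, FALSE), 25),
                        n_folds = 4, blocks_per_side = 2)
  expect_equal(length(unique(fq)), 4)
  expect_equal(length(unique(paste(fq, qx, qy))), 4)  # fold <-> quadrant

  # all points in one spot cannot balance
  expect_error(block_partition(rep(0, 40), rep(0, 40), rep(c(TRUE, FALSE), 20),
                               n_folds = 4), "tiling")
})

test_that("model backends honour the train/predict contract", {
  set.seed(3)
  X <- matrix(rnorm(600), 300, 2)
  y <- as.integer(X[, 1] + X[, 2] + rnorm(300, sd = 0.3) > 0)
  models <- fit_models(X, y, c("BRT", "MXS", "RDF", "SVM"), seed = 1)
  for (a in names(models)) {
    p <- models[[a]](X)
    expect_length(p, 300)
    expect_true(all(p >= 0 & p <= 1), info = a)
    # separable problem: good resubstitution skill
    expect_gt(evaluate_jaccard(p, y)$jaccard, 0.8, label = a)
  }
  expect_error(fit_models(X, rep(1, 300), "RDF", seed = 1), "single class")
  expect_error(fit_models(matrix(1, 50, 2), rep(c(0, 1), 25), "RDF",
                          seed = 1), "constant")
  expect_error(fit_models(X, y, "GLM", seed = 1), "unknown")
})

test_that("quadratic maxent features beat linear-only on a quadratic niche", {
  # species with an interior optimum: presence iff close to it; a linear
  # logit cannot carve out an interior ellipse
  wins <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    X <- matrix(rnorm(500 * 2), 500)
    suit <- exp(-rowSums(X^2) / (2 * 0.7^2))
    y <- as.integer(runif(500) < suit)
    if (sum(y) < 20) return(NA)
    tr <- seq_len(500) <= 350
    m2 <- fit_models(X[tr, ], y[tr], c("MXS", "MXL"), seed = s)
    j_q <- evaluate_jaccard(m2$MXS(X[!tr, ]), y[!tr],
                            m2$MXS(X[tr, ]), y[tr])$jaccard
    j_l <- evaluate_jaccard(m2$MXL(X[!tr, ]), y[!tr],
                            m2$MXL(X[tr, ]), y[tr])$jaccard
    j_q - j_l
  }, numeric(1))
  expect_gt(mean(wins, na.rm = TRUE), 0)
  expect_gt(stats::median(wins, na.rm = TRUE), 0)
})

test_that("Jaccard arithmetic matches hand computation", {
  expect_equal(evaluate_jaccard(rep(1, 10), rep(1, 10))$jaccard, 1.0)
  # a binary prediction disjoint from the truth scores 0
  expect_equal(nicheshift:::jaccard_score(c(TRUE, TRUE, FALSE, FALSE),
                                          c(FALSE, FALSE, TRUE, TRUE)), 0)
  # TP=8, FP=2, FN=2 -> 8/12
  pred <- c(rep(0.9, 8), rep(0.9, 2), rep(0.1, 2), rep(0.1, 8))
  truth <- c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 8))
  ev <- evaluate_jaccard(pred, truth)
  expect_equal(ev$jaccard, 8 / 12, tolerance = 1e-12)
})

test_that("weighted ensembling normalizes weights and respects bounds", {
  g1 <- matrix(runif(25), 5); g2 <- matrix(runif(25), 5)
  g3 <- matrix(runif(25), 5)
  ew <- ensemble_weighted(list(a = g1, b = g2, c = g3), c(0.5, 0.3, 0.2))
  expect_equal(sum(ew$weights), 1)
  expect_true(all(ew$ensemble <= pmax(g1, pmax(g2, g3)) + 1e-12))
  expect_true(all(ew$ensemble >= pmin(g1, pmin(g2, g3)) - 1e-12))
  # equal scores = plain mean; a lone positive score selects its grid
  expect_equal(ensemble_weighted(list(g1, g2), c(1, 1))$ensemble,
               (g1 + g2) / 2)
  expect_equal(ensemble_weighted(list(g1, g2), c(1, 0))$ensemble, g1)
  expect_warning(ensemble_weighted(list(g1, g2), c(0, 0)), "zero")
  # near-tied scores: the lower-scoring grid gets strictly the least weight
  ew4 <- ensemble_weighted(list(g1, g2, g3, g1), c(0.96, 0.96, 0.94, 0.96))
  expect_equal(sum(ew4$weights), 1)
  expect_true(all(ew4$weights[c(1, 2, 4)] > ew4$weights[3]))
})

test_that("occurrence constraint keeps only occupied patches (flood-fill oracle)", {
  bin <- matrix(FALSE, 10, 10)
  bin[1:3, 1:3] <- TRUE          # patch A: 9 cells
  bin[6:9, 2:4] <- TRUE          # patch B: 12 cells
  bin[2:4, 7:9] <- TRUE          # patch C: 9 cells
  pres <- c(which(matrix(seq_len(100), 10) == 22),  # inside A (row 2, col 3)
            which(matrix(seq_len(100), 10) == 73))  # inside C (row 3, col 8)
  out <- occurrence_constraint(bin, pres)
  expect_equal(sum(out), 9 + 9)
  expect_true(all(out[1:3, 1:3]) && all(out[2:4, 7:9]))
  expect_false(any(out[6:9, 2:4]))
  # presences in every patch: identity
  pres_all <- c(pres, 27)  # row 7, col 3: inside B
  expect_equal(occurrence_constraint(bin, pres_all), bin)
  # empty suitable set passes through
  expect_equal(sum(occurrence_constraint(matrix(FALSE, 5, 5), 1)), 0)
  # diagonal-only contact does not merge patches (rook adjacency)
  diagm <- matrix(FALSE, 4, 4); diagm[1:2, 1:2] <- TRUE; diagm[3:4, 3:4] <- TRUE
  outd <- occurrence_constraint(diagm, 1)
  expect_equal(sum(outd), 4)
})

test_that("the full pipeline holds fold hygiene and contracts together", {
  st <- fixture_stack(5, shape = c(120, 120), n_layers = 2,
                      autocorr_range = 8)
  vs <- strong_signal_species(st)
  occ <- sample_occurrences(vs, st, stack_mask(st), 120, seed = 6)
  res <- sdm_ensemble(occ, st, seed = 7)
  # leakage assertion: a fold's model never trains on its own points
  for (f in seq_along(res$train_folds)) {
    expect_false(f %in% res$train_folds[[f]])
  }
  expect_equal(sum(res$weights), 1)
  rng <- range(res$ensemble, na.rm = TRUE)
  expect_gte(rng[1], 0); expect_lte(rng[2], 1)
  # ensemble bounded cell-wise by member maps
  mx <- Reduce(pmax, res$maps); mn <- Reduce(pmin, res$maps)
  expect_true(all(res$ensemble <= mx + 1e-9, na.rm = TRUE))
  expect_true(all(res$ensemble >= mn - 1e-9, na.rm = TRUE))
  # constrained map is a monotone contraction of the binary map
  expect_lte(sum(res$constrained, na.rm = TRUE), sum(res$binary, na.rm = TRUE))
  expect_true(all(res$binary[which(res$constrained)]))
  # every training point has complete predictors and a fold with both classes
  expect_false(anyNA(res$points))
  tab <- table(res$points$fold, res$points$presence)
  expect_true(all(tab > 0))
  # determinism of the whole fit
  res2 <- sdm_ensemble(occ, st, seed = 7)
  expect_identical(res$ensemble, res2$ensemble)
  expect_identical(res$jaccard, res2$jaccard)
})

test_that("algorithm subsetting flows through to the evaluation table", {
  st <- fixture_stack(5, shape = c(120, 120), n_layers = 2,
                      autocorr_range = 8)
  vs <- strong_signal_species(st)
  occ <- sample_occurrences(vs, st, stack_mask(st), 80, seed = 10)
  res <- sdm_ensemble(occ, st, algorithms = c("RDF", "MXS"), seed = 3)
  tab <- sdm_evaluation_table(res, species = "virtual species")
  expect_named(tab, c("species", "RDF", "MXS", "WMEA"))
  expect_true(all(unlist(tab[-1]) >= 0 & unlist(tab[-1]) <= 1))
})
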