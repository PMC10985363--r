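# Schoener's D, the similarity permutation test, and the E/S/U decomposition.

# hand-buildable niche grids for exact checks
grid_from_z <- function(z, e = NULL) {
  R <- nrow(z)
  structure(list(R = R, x = seq(0, 1, length.out = R),
                 y = seq(0, 1, length.out = R),
                 dx = 1 / (R - 1), dy = 1 / (R - 1),
                 bounds = rbind(lower = c(0, 0), upper = c(1, 1)),
                 o = z, e = if (is.null(e)) matrix(1, R, R) else e,
                 z = z, z_uncor = z, corrected = TRUE,
                 region = "native", n_occ = 1L,
                 bw = list(occurrence = c(1, 1), background = c(1, 1))),
            class = "niche_grid")
}

test_that("D has its identity, disjoint and hand-computed fixed points", {
  set.seed(2)
  z <- matrix(runif(100), 10)
  g <- grid_from_z(z)
  expect_equal(schoener_d(g, g), 1.0)

  za <- matrix(0, 10, 10); za[1:3, 1:3] <- runif(9)
  zb <- matrix(0, 10, 10); zb[7:10, 7:10] <- runif(16)
  expect_equal(schoener_d(grid_from_z(za), grid_from_z(zb)), 0.0)

  # 2x2 hand computation: zhat1 = (.5,.5,0,0), zhat2 = (0,.5,.5,0) -> D = .5
  z1 <- matrix(c(0.5, 0.5, 0, 0), 2)
  z2 <- matrix(c(0, 0.5, 0.5, 0), 2)
  expect_equal(schoener_d(grid_from_z(z1), grid_from_z(z2)), 0.5)
  # normalization is internal: scaling either grid changes nothing
  expect_equal(schoener_d(grid_from_z(10 * z1), grid_from_z(z2)), 0.5)
})

test_that("D is symmetric to 1e-12 on random grids", {
  set.seed(5)
  for (i in 1:20) {
    a <- grid_from_z(matrix(rexp(64), 8))
    b <- grid_from_z(matrix(rexp(64), 8))
    expect_lt(abs(schoener_d(a, b) - schoener_d(b, a)), 1e-12)
    expect_gte(schoener_d(a, b), 0)
    expect_lte(schoener_d(a, b), 1)
  }
})

test_that("mismatched grids are rejected", {
  a <- grid_from_z(matrix(1, 8, 8))
  b <- grid_from_z(matrix(1, 10, 10))
  expect_error(schoener_d(a, b), "not comparable")
})

test_that("similarity p-value hits the analytic floor when D_obs beats every null", {
  st <- fixture_stack(1, shape = c(120, 120), n_layers = 2, autocorr_range = 8)
  sc <- make_scenario("conservatism", st, seed = 11, n_native = 150,
                      n_invaded = 150)
  nc <- niche_compare(sc$native, sc$invaded, st, n_iter = 100, seed = 21)
  sim <- nc$similarity
  expect_true(all(sim$null < sim$D_obs))
  expect_equal(sim$p_value, 1 / 101)
  expect_equal(round(sim$p_value, 3), 0.010)
})

test_that("p-values respect their bounds and the n_iter = 1 tie rule", {
  z <- matrix(0, 12, 12); z[5:7, 5:7] <- 1
  g <- grid_from_z(z)
  # identical grids with a sprawling uniform background: a displaced copy can
  # tie only by landing exactly home, so p is 1/(n+1) or 2/(n+1)
  res <- similarity_test(g, g, n_iter = 50, seed = 1)
  expect_gte(res$p_value, 1 / 51)
  expect_lte(res$p_value, 1)
  one <- similarity_test(g, g, n_iter = 1, seed = 2)
  expect_true(one$p_value %in% c(1 / 2, 1))
  # degenerate background rejected
  e1 <- matrix(0, 12, 12); e1[1, 1] <- 1
  expect_error(similarity_test(g, grid_from_z(z, e = e1), seed = 1),
               "degenerate")
})

test_that("null displacement degrades overlap for a concentrated niche", {
  # conservatism with a broad background: the observed overlap should beat
  # the median null in (nearly) every seeded run
  st <- fixture_stack(1, shape = c(120, 120), n_layers = 2, autocorr_range = 8)
  sc <- make_scenario("conservatism", st, seed = 31, n_native = 120,
                      n_invaded = 120)
  es <- fit_pca_env(st, build_background(sc$native, st),
                    build_background(sc$invaded, st), sc$native, sc$invaded)
  gn <- occupancy_grid(es, "native")
  gi <- occupancy_grid(es, "invaded")
  D_obs <- schoener_d(gn, gi)
  wins <- vapply(1:50, function(s) {
    stats::median(similarity_test(gn, gi, n_iter = 3, seed = s)$null) < D_obs
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("E/S/U matches exhaustive hand computation on 4x4 grids", {
  z1 <- matrix(0, 4, 4); z1[1, 1] <- 0.4; z1[2, 2] <- 0.6; z1[3, 3] <- 0.5
  z2 <- matrix(0, 4, 4); z2[2, 2] <- 0.3; z2[4, 4] <- 0.7; z2[3, 1] <- 0.2
  g1 <- grid_from_z(z1); g2 <- grid_from_z(z2)
  # uniform availability: analog region is the whole grid
  esu <- esu_decomposition(g1, g2, analog_quantile = 0.1)
  # by hand: invaded mass = 1.2, of which on native-empty cells 0.7 + 0.2
  expect_equal(esu$expansion, 0.9 / 1.2)
  expect_equal(esu$stability, 1 - 0.9 / 1.2)
  # native mass = 1.5, unfilled (invaded-empty) cells: (1,1) and (3,3)
  expect_equal(esu$unfilling, 0.9 / 1.5)
  expect_equal(esu$stability + esu$expansion, 1.0)

  # identical grids: no expansion, no unfilling
  same <- esu_decomposition(g1, g1)
  expect_equal(same$expansion, 0)
  expect_equal(same$unfilling, 0)

  # disjoint supports inside a shared analog region: total shift pattern
  tot <- esu_decomposition(g1, grid_from_z({
    zz <- matrix(0, 4, 4); zz[4, 1] <- 1; zz
  }))
  expect_equal(tot$expansion, 1)
  expect_equal(tot$stability, 0)
  expect_equal(tot$unfilling, 1)
})

test_that("binary and density-weighted variants disagree only in weighting", {
  z1 <- matrix(0, 4, 4); z1[1, 1] <- 0.9; z1[2, 2] <- 0.1
  z2 <- matrix(0, 4, 4); z2[2, 2] <- 0.5; z2[3, 3] <- 0.5
  g1 <- grid_from_z(z1); g2 <- grid_from_z(z2)
  dens <- esu_decomposition(g1, g2)
  bin <- esu_decomposition(g1, g2, binary = TRUE)
  expect_equal(dens$expansion, 0.5)
  expect_equal(bin$expansion, 0.5)
  expect_equal(dens$unfilling, 0.9)  # weighted by z
  expect_equal(bin$unfilling, 0.5)   # cells counted equally
})

test_that("an empty analog region yields NA with a reason, not zeros", {
  z <- matrix(1, 6, 6)
  e1 <- matrix(0, 6, 6); e1[1:3, ] <- 1
  e2 <- matrix(0, 6, 6); e2[4:6, ] <- 1
  g1 <- grid_from_z(z, e = e1); g2 <- grid_from_z(z, e = e2)
  expect_warning(out <- esu_decomposition(g1, g2, analog_quantile = 0),
                 "undefined")
  expect_true(is.na(out$expansion) && is.na(out$unfilling))
  expect_match(attr(out, "reason"), "analog")
  expect_error(esu_decomposition(g1, g2, analog_quantile = 0.7),
               "analog_quantile")
})

test_that("expansion recovery tracks the integrated scenario truth", {
  errs <- vapply(1:20, function(s) {
    st <- generate_climate_stack(400 + s, shape = c(120, 120), n_layers = 2,
                                 autocorr_range = 8)
    sc <- make_scenario("expansion", st, magnitude = 1.5, seed = s)
    nc <- niche_compare(sc$native, sc$invaded, st, n_iter = 1, seed = s)
    nc$expansion - sc$expected_expansion
  }, numeric(1))
  expect_lte(abs(stats::median(errs)), 0.10)
})

test_that("conservatism recovers near-zero shift and full_shift near-total shift", {
  st <- fixture_stack(1, shape = c(120, 120), n_layers = 2, autocorr_range = 8)
  cons <- vapply(1:10, function(s) {
    sc <- make_scenario("conservatism", st, seed = 40 + s)
    nc <- niche_compare(sc$native, sc$invaded, st, n_iter = 1, seed = s)
    c(nc$D, nc$expansion, nc$unfilling)
  }, numeric(3))
  expect_gt(stats::median(cons[1, ]), 0.5)
  expect_lt(stats::median(cons[2, ]), 0.1)
  expect_lt(stats::median(cons[3, ]), 0.2)

  fs <- make_scenario("full_shift", st, seed = 55)
  nfs <- niche_compare(fs$native, fs$invaded, st, n_iter = 1, seed = 2)
  expect_lt(nfs$D, 0.05)
})

test_that("median D weakly decreases with scenario shift magnitude", {
  med_d <- vapply(c(0, 1, 2, 4), function(m) {
    stats::median(vapply(1:5, function(s) {
      st <- generate_climate_stack(500 + s, shape = c(100, 100), n_layers = 2,
                                   autocorr_range = 6)
      sc <- make_scenario(if (m == 0) "conservatism" else "expansion", st,
                          magnitude = m, seed = s, n_native = 150,
                          n_invaded = 150)
      niche_compare(sc$native, sc$invaded, st, n_iter = 1, seed = s)$D
    }, numeric(1)))
  }, numeric(1))
  expect_lt(stats::cor(med_d, c(0, 1, 2, 4), method = "spearman"), 0)
  expect_true(all(diff(med_d) < 0))
})

test_that("stability + expansion is exactly 1 on every non-degenerate run", {
  st <- fixture_stack(1, shape = c(100, 100), n_layers = 2)
  for (kind in c("conservatism", "expansion", "unfilling", "mixed")) {
    sc <- make_scenario(kind, st, seed = 13, n_native = 80, n_invaded = 80)
    nc <- niche_compare(sc$native, sc$invaded, st, n_iter = 1, seed = 1)
    expect_equal(nc$stability + nc$expansion, 1.0, info = kind)
    expect_gte(nc$p_similarity, 1 / 2)  # n_iter = 1 floor
  }
})

test_that("undersized regions produce a skip record instead of crashing", {
  st <- fixture_stack(1, shape = c(100, 100), n_layers = 2)
  sc <- make_scenario("conservatism", st, seed = 3, n_native = 60,
                      n_invaded = 60)
  empty <- sc$invaded[0, ]
  out <- niche_compare(sc$native, empty, st)
  expect_true(out$skipped)
  expect_match(out$skip_reason, "invaded")
  expect_output(print(out), "SKIPPED")
  row <- as.data.frame(out)
  expect_true(is.na(row$D) && row$skipped)
})
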