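# Shared fixtures, built in code. Small stacks keep the default run fast;
# the stack cache avoids regenerating identical fields across test files.

.fixture_env <- new.env(parent = emptyenv())

fixture_stack <- function(seed = 1, shape = c(100, 100), n_layers = 2,
                          autocorr_range = 6, ...) {
  key <- paste(seed, paste(shape, collapse = "x"), n_layers, autocorr_range,
               sep = "_")
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_climate_stack(
      seed, shape = shape, n_layers = n_layers,
      autocorr_range = autocorr_range, ...)
  }
  .fixture_env[[key]]
}

# a small fully-valid stack with hand-set layers (no sea), for exact checks
toy_stack <- function(nrow = 20, ncol = 20, values = NULL) {
  b1 <- matrix(seq(0, 10, length.out = nrow * ncol), nrow, ncol)
  b2 <- matrix(rep(seq(0, 5, length.out = ncol), each = nrow), nrow, ncol)
  if (!is.null(values)) { b1[] <- values[[1]]; b2[] <- values[[2]] }
  climate_stack(list(Bio1 = b1, Bio2 = b2), xmin = 0, ymin = 0,
                cellsize = 0.1)
}

# canonical strong-signal species for SDM checks: narrow niche (breadth a
# quarter of the environmental sd) responding to both layers of a 2-layer
# stack, optimum offset 0.3 sd from the pooled centroid
strong_signal_species <- function(stack, breadth_frac = 0.25, shift = 0.3) {
  nms <- names(stack$layers)
  mu <- vapply(nms, function(a) mean(stack$layers[[a]], na.rm = TRUE), 0)
  sdv <- vapply(nms, function(a) stats::sd(stack$layers[[a]], na.rm = TRUE), 0)
  virtual_species(stats::setNames(mu + shift * sdv, nms), breadth_frac * sdv)
}

make_occ <- function(lon, lat, species = "sp", range = "native") {
  occurrence_set(data.frame(species = rep_len(species, length(lon)),
                            longitude = lon, latitude = lat,
                            range = rep_len(range, length(lon))))
}

# lag-1 spatial autocorrelation of a grid (NA-tolerant)
lag1_autocor <- function(m) {
  a <- as.vector(m[, -ncol(m)]); b <- as.vector(m[, -1])
  ok <- !is.na(a) & !is.na(b)
  stats::cor(a[ok], b[ok])
}

# brute-force maximum independent set size of a conflict graph (n <= 20)
mis_size <- function(conflict) {
  n <- nrow(conflict)
  best <- 0L
  for (code in 0:(2^n - 1)) {
    members <- which(bitwAnd(code, 2^(0:(n - 1))) > 0)
    if (length(members) <= best) next
    if (!any(conflict[members, members, drop = FALSE])) {
      best <- length(members)
    }
  }
  best
}
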