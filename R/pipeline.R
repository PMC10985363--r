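# Run configuration, command-style entry points, and report writing. These
# functions are the programmatic equivalents of the `simulate | niche | sdm`
# verbs exposed by the inst/scripts wrapper; each reads/writes plain-text
# artifacts (ASCII grids, CSV, JSON) so runs are fully reproducible from a
# saved config.

#' Build and validate a run configuration
#'
#' Fills in every pipeline default, so a saved config is a complete record
#' of the run. Unknown fields are rejected, typos don't silently fall back
#' to defaults.
#'
#' @param ... named overrides, or a single list of them (e.g. parsed from a
#'   JSON config file).
#' @return A validated config list of class `run_config`.
#' @export
run_config <- function(...) {
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1L]])) {
    over <- over[[1L]]
  }
  cfg <- list(
    seed = 1L, out_dir = "nicheshift_run",
    stack_dir = NULL, occurrences = NULL,
    # synthetic data
    shape = c(150L, 150L), n_layers = 2L, autocorr_range = 8,
    scenario = "conservatism", magnitude = 1.5,
    n_native = 300L, n_invaded = 300L,
    # niche analysis
    buffer_deg = 1, R = 100L, n_iter = 100L, analog_quantile = 0.10,
    correction = TRUE, min_occurrences = 20L,
    # sdm
    algorithms = c("BRT", "MXS", "RDF", "SVM"), variance_target = 0.95,
    pa_ratio = 1, n_folds = 4L, low_quantile = 0.5, min_distance_cells = 10
  )
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop_ns("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path JSON file written by [save_config()].
#' @export
load_config <- function(path) {
  run_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

outfile <- function(cfg, ...) file.path(cfg$out_dir, ...)

check_force <- function(paths, force) {
  hit <- paths[file.exists(paths)]
  if (length(hit) && !force) {
    stop_ns("output exists (use force = TRUE to overwrite): ",
            paste(hit, collapse = ", "))
  }
}

#' Simulate a climate stack and scenario occurrence sets to disk
#'
#' Generates a synthetic climate stack and a paired native/invaded
#' occurrence scenario, writing the stack (ASCII grids + sidecar), one
#' occurrence CSV, and the scenario truth JSON under `cfg$out_dir`.
#'
#' @param cfg a [run_config()].
#' @param force overwrite existing outputs.
#' @return Invisibly, the list of files written.
#' @export
cmd_simulate <- function(cfg = run_config(), force = FALSE) {
  cfg <- run_config(unclass(cfg))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(outfile(cfg, "stack"), outfile(cfg, "occurrences.csv"),
             outfile(cfg, "truth.json"))
  check_force(files[-1L], force)
  seeds <- split_seeds(cfg$seed, 2L)
  stack <- generate_climate_stack(seeds[1L], shape = cfg$shape,
                                  n_layers = cfg$n_layers,
                                  autocorr_range = cfg$autocorr_range)
  sc <- make_scenario(cfg$scenario, stack, magnitude = cfg$magnitude,
                      seed = seeds[2L], n_native = cfg$n_native,
                      n_invaded = cfg$n_invaded)
  write_stack(stack, files[1L])
  write_occurrences(occurrence_set(rbind(as.data.frame(sc$native),
                                         as.data.frame(sc$invaded))),
                    files[2L])
  write_scenario_truth(sc, files[3L])
  save_config(cfg, outfile(cfg, "config.json"))
  message("simulate: wrote ", paste(basename(files), collapse = ", "),
          " to ", cfg$out_dir)
  invisible(files)
}

load_inputs <- function(cfg) {
  stack_dir <- cfg$stack_dir %||% outfile(cfg, "stack")
  occ_path <- cfg$occurrences %||% outfile(cfg, "occurrences.csv")
  if (!file.exists(file.path(stack_dir, "stack.json"))) {
    stop_ns("climate stack not found at ", stack_dir)
  }
  if (!file.exists(occ_path)) stop_ns("occurrence file not found: ", occ_path)
  list(stack = read_stack(stack_dir), occ = read_occurrences(occ_path))
}

# report rounding: 3 decimals in the headline CSV, full precision sidecar
write_report <- function(df, path) {
  full <- sub("\\.csv$", "_full.csv", path)
  utils::write.csv(df, full, row.names = FALSE)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.3f", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the niche comparison stage
#'
#' Compares the native range against every invaded range found in the
#' occurrence table, writing a comparison CSV (one row per invaded region,
#' 3-decimal report plus full-precision sidecar), the PCA loadings, the
#' similarity-test null distributions, and the occupancy grids.
#'
#' @param cfg a [run_config()].
#' @param force overwrite existing outputs.
#' @return Invisibly, the list of `niche_comparison` objects.
#' @export
cmd_niche <- function(cfg = run_config(), force = FALSE) {
  cfg <- run_config(unclass(cfg))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  check_force(outfile(cfg, "niche_comparison.csv"), force)
  inp <- load_inputs(cfg)
  occ <- inp$occ
  regions <- setdiff(unique(occ$range), "native")
  if (!any(occ$range == "native")) stop_ns("no native records in input")
  if (!length(regions)) stop_ns("no invaded regions in input")

  comps <- lapply(regions, function(rg) {
    niche_compare(occ[occ$range == "native", ], occ[occ$range == rg, ],
                  inp$stack, buffer_deg = cfg$buffer_deg, R = cfg$R,
                  n_iter = cfg$n_iter, analog_quantile = cfg$analog_quantile,
                  correction = cfg$correction,
                  min_occurrences = cfg$min_occurrences, seed = cfg$seed)
  })
  names(comps) <- regions

  tab <- do.call(rbind, lapply(comps, as.data.frame))
  write_report(tab, outfile(cfg, "niche_comparison.csv"))
  done <- comps[!vapply(comps, `[[`, TRUE, "skipped")]
  if (length(done)) {
    ld <- done[[1L]]$scores$loadings
    utils::write.csv(data.frame(variable = rownames(ld), ld),
                     outfile(cfg, "pca_loadings.csv"), row.names = FALSE)
    nulls <- do.call(rbind, lapply(names(done), function(rg) {
      data.frame(region = rg, iteration = seq_along(done[[rg]]$similarity$null),
                 D_null = done[[rg]]$similarity$null)
    }))
    utils::write.csv(nulls, outfile(cfg, "similarity_null.csv"),
                     row.names = FALSE)
    for (rg in names(done)) {
      write_niche_grid(done[[rg]]$grids$invaded,
                       outfile(cfg, paste0("grid_", rg, ".json")))
    }
    write_niche_grid(done[[1L]]$grids$native, outfile(cfg, "grid_native.json"))
  }
  message("niche: ", nrow(tab), " comparison row(s) written")
  invisible(comps)
}

#' Run the ensemble SDM stage
#'
#' Fits the ensemble distribution model on all presence records (every range
#' pooled), writing per-algorithm suitability maps, the ensemble, binary and
#' occurrence-constrained maps as ASCII grids, plus the evaluation table.
#'
#' @param cfg a [run_config()].
#' @param force overwrite existing outputs.
#' @return Invisibly, the `sdm_result`.
#' @export
cmd_sdm <- function(cfg = run_config(), force = FALSE) {
  cfg <- run_config(unclass(cfg))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  check_force(outfile(cfg, "sdm_evaluation.csv"), force)
  inp <- load_inputs(cfg)
  res <- sdm_ensemble(inp$occ, inp$stack, algorithms = cfg$algorithms,
                      variance_target = cfg$variance_target,
                      pa_ratio = cfg$pa_ratio, n_folds = cfg$n_folds,
                      low_quantile = cfg$low_quantile,
                      min_distance_cells = cfg$min_distance_cells,
                      seed = cfg$seed)
  sp <- inp$occ$species[1L]
  write_report(sdm_evaluation_table(res, species = sp),
               outfile(cfg, "sdm_evaluation.csv"))
  grids <- c(res$maps, list(ensemble = res$ensemble,
                            binary = res$binary * 1,
                            constrained = res$constrained * 1))
  map_stack <- climate_stack(lapply(grids, function(g) {
    storage.mode(g) <- "double"; g
  }), xmin = inp$stack$xmin, ymin = inp$stack$ymin,
  cellsize = inp$stack$cellsize)
  write_stack(map_stack, outfile(cfg, "sdm_maps"))
  message("sdm: evaluation table and ", length(grids), " maps written")
  invisible(res)
}
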