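# Pipeline orchestration: one JSON-configurable entry point that runs
# synthetic-input generation, the four ES models, landscape metrics,
# constraint-line extraction, characteristic-value dynamics and driver
# attribution, writing CSV tables (and optionally ASCII-grid rasters) plus
# a JSON manifest into an output directory. Fully deterministic under the
# global seed.

PIPELINE_STAGES <- c("simulate", "es", "metrics", "constraint", "trends",
                     "attribute")

#' Default pipeline configuration
#'
#' A desk-scale stand-in for the study region: a 150 x 150 grid of 250 m
#' cells over 21 years (2000-2020), cropland-dominated composition with a
#' slow conversion of cropland to urban land, precipitation around 700 mm
#' with a weak positive trend, and the documented default constraint and
#' attribution settings.
#'
#' @param n_rows,n_cols,years,seed Convenience overrides.
#' @return Nested configuration list (serializable to JSON).
#' @export
default_config <- function(n_rows = 150, n_cols = 150, years = 2000:2020,
                           seed = 42L) {
  list(
    grid = list(n_rows = n_rows, n_cols = n_cols, cell_size = 250),
    years = years,
    landscape = list(
      proportions = list(cropland = 0.62, forest = 0.08, grassland = 0.08,
                         water = 0.05, urban = 0.12, unused = 0.05),
      clumping = 0.6,
      urban_trend = 0.003        # share moved cropland -> urban per year
    ),
    forcing = list(
      ppt = list(mean = 700, sd = 60, spatial_gradient = 0.3, trend = 2),
      tem = list(mean = 12, sd = 0.8, spatial_gradient = 0.25, trend = 0.02),
      sol = list(mean = 5200, sd = 150, spatial_gradient = 0.1, trend = 0),
      ndvi_coupling = 0.6
    ),
    zones = list(n_zones = 9, fp0 = 3.5, trend = 0.025),
    constraint = list(n_bins = 50, quantile = 0.99, min_points = 10,
                      sample_n = 10000),
    attribution = list(max_terms = 6, aicc_margin = NA, vif_cap = 10),
    write_rasters = FALSE,
    seed = as.integer(seed)
  )
}

validate_config <- function(config) {
  required <- c("grid", "years", "landscape", "forcing", "zones",
                "constraint", "attribution", "seed")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0)
    stop_invalid(paste("config missing keys:", paste(missing, collapse = ", ")))
  known <- c(required, "write_rasters")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0)
    stop_invalid(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  invisible(config)
}

#' Run the full pipeline
#'
#' Executes the stages in order (`simulate`, `es`, `metrics`,
#' `constraint`, `trends`, `attribute`), writing each stage's tables into
#' `outdir` as CSV and a `manifest.json` describing the run. A stage
#' failure aborts with the stage named; tables already written are kept.
#'
#' @param config Configuration list (see [default_config()]); validated
#'   before any stage runs.
#' @param outdir Output directory (created if needed).
#' @param until Last stage to run (default: all).
#' @return Invisibly, a list with all in-memory stage results and the
#'   manifest.
#' @export
run_all <- function(config = default_config(), outdir = tempfile("eslines_"),
                    until = "attribute") {
  validate_config(config)
  until <- match.arg(until, PIPELINE_STAGES)
  last <- match(until, PIPELINE_STAGES)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  spec <- grid_spec(config$grid$n_rows, config$grid$n_cols,
                    config$grid$cell_size)
  years <- as.integer(unlist(config$years))
  seed <- as.integer(config$seed)
  res <- list(config = config, outdir = outdir)
  t_start <- Sys.time()

  run_stage <- function(name, f) {
    t0 <- Sys.time()
    out <- tryCatch(f(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }

  ## simulate -------------------------------------------------------------
  sim <- run_stage("simulate", function() {
    forcings <- generate_forcing(
      spec, years,
      ppt_params = config$forcing$ppt, tem_params = config$forcing$tem,
      sol_params = config$forcing$sol,
      ndvi_coupling = config$forcing$ndvi_coupling,
      seed = seed)
    props0 <- unlist(config$landscape$proportions)
    landuse <- lapply(seq_along(years), function(i) {
      dt <- years[i] - years[1]
      p <- props0
      shift <- min(config$landscape$urban_trend * dt, p[["cropland"]] - 0.05)
      p[["cropland"]] <- p[["cropland"]] - shift
      p[["urban"]] <- p[["urban"]] + shift
      generate_landscape(spec, p / sum(p),
                         clumping = config$landscape$clumping,
                         seed = seed + 101L + i)
    })
    zones <- generate_zones(spec, n_zones = config$zones$n_zones,
                            years = years,
                            yield_params = list(fp0 = config$zones$fp0,
                                                trend = config$zones$trend),
                            seed = seed + 7L)
    if (isTRUE(config$write_rasters)) {
      rdir <- file.path(outdir, "rasters")
      dir.create(rdir, showWarnings = FALSE)
      for (i in seq_along(years)) {
        write_ascii_grid(forcings[[i]]$ppt, spec,
                         file.path(rdir, sprintf("ppt_%d.asc", years[i])))
        write_ascii_grid(forcings[[i]]$ndvi, spec,
                         file.path(rdir, sprintf("ndvi_%d.asc", years[i])))
        write_ascii_grid(landuse[[i]]$classes, spec,
                         file.path(rdir, sprintf("landuse_%d.asc", years[i])))
      }
      write_ascii_grid(forcings[[1]]$dem, spec, file.path(rdir, "dem.asc"))
    }
    utils::write.csv(zones$yield_table, file.path(outdir, "zone_yields.csv"),
                     row.names = FALSE)
    list(forcings = forcings, landuse = landuse, zones = zones)
  })
  res$sim <- sim
  if (last < 2) return(finish_run(res, t_start))

  ## es --------------------------------------------------------------------
  res$es <- run_stage("es", function() {
    lapply(seq_along(years), function(i) {
      f <- sim$forcings[[i]]; lu <- sim$landuse[[i]]
      zy <- sim$zones
      zy$yield_table <- zy$yield_table[zy$yield_table$year == years[i], ]
      fl <- compute_rusle_factors(f, lu)
      list(NPP = compute_npp(f, lu),
           FP = suppressWarnings(compute_fp(f$ndvi, lu, zy, year = years[i],
                                            per_ha = TRUE)),
           SC = compute_sc(fl),
           WY = suppressMessages(compute_wy(f, lu)))
    })
  })
  means <- es_means(res$es)
  utils::write.csv(means, file.path(outdir, "es_means.csv"), row.names = FALSE)
  if (isTRUE(config$write_rasters)) {
    rdir <- file.path(outdir, "rasters")
    dir.create(rdir, showWarnings = FALSE)
    for (i in seq_along(years))
      for (sv in names(res$es[[i]]))
        write_ascii_grid(res$es[[i]][[sv]]$values, spec,
                         file.path(rdir, sprintf("%s_%d.asc", tolower(sv),
                                                 years[i])))
  }
  if (last < 3) return(finish_run(res, t_start))

  ## metrics ----------------------------------------------------------------
  res$metrics <- run_stage("metrics", function() {
    do.call(rbind, lapply(seq_along(years), function(i)
      landscape_metrics(sim$landuse[[i]], year = years[i])))
  })
  utils::write.csv(res$metrics, file.path(outdir, "landscape_metrics.csv"),
                   row.names = FALSE)
  if (last < 4) return(finish_run(res, t_start))

  ## constraint ---------------------------------------------------------------
  res$curves <- run_stage("constraint", function() {
    run_pairs(res$es, sample_n = config$constraint$sample_n,
              landuse_by_year = sim$landuse,
              n_bins = config$constraint$n_bins,
              quantile = config$constraint$quantile,
              min_points = config$constraint$min_points,
              seed = seed + 23L)
  })
  utils::write.csv(res$curves, file.path(outdir, "constraint_curves.csv"),
                   row.names = FALSE)
  if (last < 5) return(finish_run(res, t_start))

  ## trends --------------------------------------------------------------------
  res$dynamics <- run_stage("trends", function() {
    if (length(years) < 3)
      stop_with("dynamics needs at least 3 years of curves",
                "eslines_insufficient_data")
    feature_dynamics(res$curves)
  })
  utils::write.csv(res$dynamics$trends, file.path(outdir, "feature_trends.csv"),
                   row.names = FALSE)
  utils::write.csv(res$dynamics$boxstats,
                   file.path(outdir, "feature_boxstats.csv"),
                   row.names = FALSE)
  utils::write.csv(es_annual_report(means),
                   file.path(outdir, "es_annual_report.csv"),
                   row.names = FALSE)
  if (last < 6) return(finish_run(res, t_start))

  ## attribute -------------------------------------------------------------------
  res$attribution <- run_stage("attribute", function() {
    dm <- build_driver_matrix(sim$forcings, res$metrics)
    cfg <- alm_config(max_terms = config$attribution$max_terms,
                      aicc_margin = config$attribution$aicc_margin,
                      vif_cap = config$attribution$vif_cap)
    list(matrix = dm, table = attribute_all(res$dynamics$series, dm, cfg))
  })
  utils::write.csv(res$attribution$table, file.path(outdir, "attribution.csv"),
                   row.names = FALSE)
  finish_run(res, t_start)
}

finish_run <- function(res, t_start) {
  outdir <- res$outdir
  files <- list.files(outdir, pattern = "\\.(csv|asc)$", recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("eslines")),
    seed = res$config$seed,
    config = res$config,
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(outdir, files))), files))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}

#' Write packaged fixture files
#'
#' `table4`: the transcribed characteristic-value table (21 years, six
#' pairs). `toy_clouds`: reference hump and exponential scatter clouds
#' with their true boundary parameters embedded in a side-car JSON.
#'
#' @param name `"table4"` or `"toy_clouds"`.
#' @param dir Output directory.
#' @return Paths of the files written.
#' @export
fixtures <- function(name = c("table4", "toy_clouds"), dir = ".") {
  name <- match.arg(name)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (name == "table4") {
    out <- file.path(dir, "table4_features.csv")
    utils::write.csv(load_table4(), out, row.names = FALSE)
    return(out)
  }
  hump <- generate_constrained_cloud(
    5000, "hump", list(x_star = 5, y_star = 10, width = 1),
    x_range = c(2, 8), seed = 11L, pair_label = "toy_hump")
  expo <- generate_constrained_cloud(
    5000, "exponential", list(k = 0.9995, b = 8),
    x_range = c(0, 3000), seed = 12L, pair_label = "toy_exponential")
  paths <- character(0)
  for (cl in list(hump, expo)) {
    p <- file.path(dir, paste0(cl$pair_label, ".csv"))
    utils::write.csv(data.frame(x = cl$x, y = cl$y), p, row.names = FALSE)
    jsonlite::write_json(
      list(form = cl$truth$form, params = cl$truth$params,
           x_range = cl$truth$x_range),
      file.path(dir, paste0(cl$pair_label, "_truth.json")),
      auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  paths
}

#' Command-line entry point
#'
#' Subcommands: `run-all`, `simulate`, `compute-es`, `metrics`,
#' `constraint-lines`, `trends`, `attribute` (pipeline up to the named
#' stage) and `fixtures`. Options: `--config PATH` (JSON), `--seed INT`,
#' `--outdir PATH`, `--name` (for `fixtures`).
#'
#' @param args Character vector of CLI arguments (default: the process
#'   command line).
#' @return Exit status 0 invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: eslines <run-all|simulate|compute-es|metrics|constraint-lines|",
        "trends|attribute|fixtures> [--config PATH] [--seed INT]",
        "[--outdir PATH] [--name NAME]\n")
    return(invisible(1L))
  }
  sub <- args[1]
  opts <- optparse::parse_args(
    optparse::OptionParser(option_list = list(
      optparse::make_option("--config", type = "character", default = NULL),
      optparse::make_option("--seed", type = "integer", default = NULL),
      optparse::make_option("--outdir", type = "character", default = "eslines_run"),
      optparse::make_option("--name", type = "character", default = "table4")
    )), args = args[-1])
  stage_map <- c("run-all" = "attribute", simulate = "simulate",
                 "compute-es" = "es", metrics = "metrics",
                 "constraint-lines" = "constraint", trends = "trends",
                 attribute = "attribute")
  if (sub == "fixtures") {
    paths <- fixtures(opts$name, opts$outdir)
    cat(paths, sep = "\n")
    return(invisible(0L))
  }
  if (!sub %in% names(stage_map))
    stop_invalid(paste("unknown subcommand:", sub))
  config <- if (is.null(opts$config)) default_config() else
    jsonlite::read_json(opts$config, simplifyVector = TRUE)
  if (!is.null(opts$seed)) config$seed <- opts$seed
  run_all(config, outdir = opts$outdir, until = stage_map[[sub]])
  invisible(0L)
}
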