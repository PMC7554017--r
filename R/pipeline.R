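#' Study configuration
#'
#' Defaults describing a complete synthetic study: a 120 x 120 landscape at
#' 100 m resolution whose class composition matches the published Nanjing
#' 2005 shares, evolved one decade under an urbanisation-dominated
#' transition matrix, then projected one 15-year Markov step under the
#' three scenarios.
#'
#' @param ... Named overrides of the default fields.
#' @return A `study_config` list.
#' @export
study_config <- function(...) {
  tpm <- matrix(c(
    # to: crop  forest grass  wet    built  bare
    0.880, 0.005, 0.002, 0.010, 0.100, 0.003,   # cropland
    0.020, 0.955, 0.005, 0.005, 0.015, 0.000,   # forest
    0.050, 0.020, 0.880, 0.005, 0.040, 0.005,   # grassland
    0.020, 0.005, 0.002, 0.950, 0.020, 0.003,   # wetland
    0.000, 0.000, 0.000, 0.000, 1.000, 0.000,   # built-up
    0.100, 0.020, 0.020, 0.010, 0.100, 0.750),  # bare
    nrow = 6, byrow = TRUE)
  cfg <- list(
    n_rows = 120, n_cols = 120, cell_size = 100,
    class_fractions = c(0.5993, 0.1057, 0.0091, 0.1089, 0.1764, 0.0006),
    patch_size = 5,
    tpm_true = tpm,
    epochs = c("t1", "t2"),
    scenarios = c("BAU", "CP", "ER"),
    n_periods = 1,
    slope_threshold = 6,
    relief_amplitude = 300,
    block_size = 10,
    crop_yield_t_per_km2 = 150,
    seed = 42
  )
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Fields present in the file override the [study_config()] defaults;
#' `tpm_true` may be given as a 36-number row-major list.
#'
#' @param path YAML file path.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$tpm_true))
    y$tpm_true <- matrix(unlist(y$tpm_true), nrow = 6, byrow = TRUE)
  do.call(study_config, y)
}

#' Scale base-year crop production to a scenario map
#'
#' No future NDVI exists for simulated maps, so scenario crop production
#' scales each district's base-year production by the ratio of its cropland
#' area under the scenario to its base-year cropland area. This convention
#' is isolated here.
#'
#' @param district_totals Base data frame with `zone`, `production_t`.
#' @param lc_base,lc_scen Base and scenario [land_cover_grid()]s.
#' @param zones A [zone_grid()].
#' @return `district_totals` with scaled `production_t`.
#' @export
scale_crop_production <- function(district_totals, lc_base, lc_scen, zones) {
  crop_area <- function(lc) {
    m <- continuous_grid(
      (grid_values(lc) == lc_classes()[["cropland"]]) + 0, geometry(lc))
    zonal_stats(m, zones)
  }
  a0 <- crop_area(lc_base); a1 <- crop_area(lc_scen)
  ratio <- a1$sum[match(district_totals$zone, a1$zone)] /
    pmax(a0$sum[match(district_totals$zone, a0$zone)], 1)
  district_totals$production_t <- district_totals$production_t * ratio
  district_totals
}

# Quadrant districts: four zones split at the grid midlines.
quadrant_zones <- function(geom) {
  i <- rep(seq_len(geom$n_rows), times = geom$n_cols)
  j <- rep(seq_len(geom$n_cols), each = geom$n_rows)
  z <- 1L + (i > geom$n_rows / 2) + 2L * (j > geom$n_cols / 2)
  zone_grid(matrix(z, geom$n_rows, geom$n_cols), geom)
}

# All six services for one map; returns long records and the per-pixel grids.
value_services <- function(lc, fields, dem, bio, threats, zones,
                           district_totals, epoch, scenario = NA_character_) {
  g <- geometry(lc)
  erosivity <- grid_like(fields$precipitation,
                         0.1 * grid_values(fields$precipitation))
  attr(erosivity, "quantity") <- "rainfall erosivity"
  erodibility <- constant_grid(0.03, g, "soil erodibility")
  wy <- water_yield(fields$precipitation, lc, bio, epoch, scenario)
  cs <- carbon_storage(lc, bio, epoch, scenario)
  sc <- soil_conservation(dem, erosivity, erodibility, lc, bio,
                          epoch = epoch, scenario = scenario)
  cp <- crop_production(fields$ndvi, lc, zones, district_totals,
                        epoch, scenario)
  ap <- air_purification(lc, bio, epoch, scenario)
  hq <- habitat_quality(lc, threats, bio, epoch, scenario)
  list(records = rbind(wy$record, cs$record, sc$record, cp$record,
                       ap$record, hq$record),
       grids = list(WY = wy$grid, SC = sc$grid, CP = cp$grid, HQ = hq$grid))
}

#' Run the full scenario study
#'
#' End-to-end pipeline on a synthetic landscape: generate the base map,
#' terrain and driver fields; evolve the map one interval under the
#' ground-truth transition model; estimate the transition matrix and fit
#' logistic transition potentials from the two maps; validate a
#' hindcast allocation against the evolved map (overall accuracy, kappa);
#' project demand one Markov step and allocate it under each scenario's
#' rules; value the six ecosystem services for every map; and compute
#' relative changes, pairwise TSD matrices and a spatial TSD map per
#' scenario. Fully deterministic under the config seed.
#'
#' @param config A [study_config()] (or path to a YAML file for
#'   [read_study_config()]).
#' @param outdir Optional directory; when given, class-area tables, service
#'   records, TSD matrices, validation metrics, rasters and a provenance
#'   log are written there.
#' @return List with `maps`, `class_areas`, `tpm`, `validation`,
#'   `es_records`, `delta`, `tsd`, `spatial_tsd`, `potentials`,
#'   `provenance`.
#' @export
run_study <- function(config = study_config(), outdir = NULL) {
  if (is.character(config)) config <- read_study_config(config)
  geom <- grid_geometry(config$n_rows, config$n_cols, config$cell_size)
  bio <- default_biophysical()
  threats <- threat_spec()
  seed <- config$seed

  lc1 <- generate_landcover(landscape_spec(geom, config$class_fractions,
                                           config$patch_size, seed))
  attr(lc1, "epoch") <- config$epochs[1]
  dem <- generate_terrain(geom, config$relief_amplitude, 10, seed + 1)
  slope <- slope_from_dem(dem)
  fields <- generate_fields(geom, lc1, seed + 2)
  zones <- quadrant_zones(geom)

  dmod <- list(from = 1L, to = 5L, coefficients = c(-1.5, -4e-4),
               drivers = list(fields$d2center))
  lc2 <- evolve_landcover(lc1, evolution_spec(config$tpm_true, 1, seed + 3,
                                              driver_mod = dmod))[[1]]
  attr(lc2, "epoch") <- config$epochs[2]
  fields2 <- fields
  fields2$ndvi <- with_seed(seed + 4, {
    nv <- c(0.65, 0.80, 0.55, 0.30, 0.10, 0.15)[grid_values(lc2)]
    continuous_grid(pmin(pmax(nv + stats::rnorm(length(nv), sd = 0.05), -1),
                         1), geom, "NDVI")
  })

  tpm <- estimate_transition_matrix(lc1, lc2)
  drivers <- list(slope = slope, d2majroad = fields$d2majroad,
                  d2minroad = fields$d2minroad, d2center = fields$d2center,
                  popden = fields$popden)
  potentials <- list()
  for (tr in list(c(1L, 5L), c(1L, 4L), c(3L, 5L), c(4L, 5L))) {
    p <- tryCatch(fit_transition_potential(lc1, lc2, drivers, tr,
                                           seed = seed + 5),
                  error = function(e) NULL)
    if (!is.null(p)) potentials[[paste(tr, collapse = "->")]] <- p
  }

  # hindcast validation: allocate the observed t2 composition from t1
  hind <- ca_allocate(lc1, stats::setNames(class_areas(lc2)$area_km2,
                                           names(lc_classes())),
                      potentials, neighborhood_spec(), seed = seed + 6)
  validation <- validate_map(hind$lc, lc2)

  # base-year district crop production from cropland area and a flat yield
  crop0 <- zonal_stats(continuous_grid(
    (grid_values(lc1) == 1L) + 0, geom), zones)
  totals1 <- data.frame(zone = crop0$zone,
                        production_t = crop0$sum * cell_area_km2(geom) *
                          config$crop_yield_t_per_km2)
  totals2 <- scale_crop_production(totals1, lc1, lc2, zones)

  es1 <- value_services(lc1, fields, dem, bio, threats, zones, totals1,
                        config$epochs[1])
  es2 <- value_services(lc2, fields2, dem, bio, threats, zones, totals2,
                        config$epochs[2])

  demand <- project_demand(class_areas(lc2)$area_km2, tpm, config$n_periods)
  core <- as.matrix(grid_values(fields$d2center) <
                      0.15 * config$n_cols * config$cell_size)
  sensitive <- (!is.na(lc2) & grid_values(lc2) %in% c(2L, 4L)) |
    grid_values(slope) > 15

  maps <- list(lc1, lc2)
  names(maps) <- config$epochs
  es_records <- rbind(es1$records, es2$records)
  tsd_list <- list(historical = tsd_matrix(es1$records, es2$records,
                                           config$epochs))
  delta <- list()
  spatial <- list()
  scen_maps <- list()
  for (nm in config$scenarios) {
    scen <- scenario_spec(nm, core_mask = core, sensitive_mask = sensitive,
                          slope_threshold = config$slope_threshold)
    rules <- apply_scenario_rules(lc2, scen, slope, demand)
    alloc <- ca_allocate(rules$lc, rules$demand, potentials,
                         neighborhood_spec(), rules$protected,
                         seed = seed + 7)
    lcs <- alloc$lc
    attr(lcs, "epoch") <- paste0(config$epochs[2], "+", config$n_periods)
    scen_maps[[nm]] <- lcs
    fieldsS <- fields2
    fieldsS$ndvi <- with_seed(seed + 8, {
      nv <- c(0.65, 0.80, 0.55, 0.30, 0.10, 0.15)[grid_values(lcs)]
      continuous_grid(pmin(pmax(nv + stats::rnorm(length(nv), sd = 0.05),
                                -1), 1), geom, "NDVI")
    })
    totalsS <- scale_crop_production(totals2, lc2, lcs, zones)
    esS <- value_services(lcs, fieldsS, dem, bio, threats, zones, totalsS,
                          attr(lcs, "epoch"), scenario = nm)
    es_records <- rbind(es_records, esS$records)
    delta[[nm]] <- vapply(service_order(), function(s)
      relative_change(es2$records$value[es2$records$service == s],
                      esS$records$value[esS$records$service == s])$fraction,
      numeric(1))
    tsd_list[[nm]] <- tsd_matrix(es2$records, esS$records,
                                 c(config$epochs[2], nm))
    spatial[[nm]] <- spatial_tsd(es2$grids$HQ, esS$grids$HQ,
                                 es2$grids$WY, esS$grids$WY,
                                 config$block_size)
  }
  maps <- c(maps, scen_maps)

  provenance <- list(
    package_version = as.character(utils::packageVersion("luces")),
    seed = seed,
    config = unclass(config),
    timestamp_free = TRUE)

  result <- list(maps = maps,
                 class_areas = lapply(maps, class_areas),
                 tpm = tpm, validation = validation,
                 es_records = es_records, delta = delta,
                 tsd = tsd_list, spatial_tsd = spatial,
                 potentials = potentials, provenance = provenance)
  if (!is.null(outdir)) write_study(result, outdir, config)
  result
}

# Write the report bundle: CSV tables, ASCII rasters, YAML provenance.
write_study <- function(result, outdir, config) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(result$maps)) {
    write_ascii_grid(result$maps[[nm]],
                     file.path(outdir, paste0("landcover_", nm, ".asc")))
    utils::write.csv(result$class_areas[[nm]],
                     file.path(outdir, paste0("class_areas_", nm, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(as.data.frame(result$tpm$p),
                   file.path(outdir, "transition_matrix.csv"))
  utils::write.csv(result$es_records,
                   file.path(outdir, "es_records.csv"), row.names = FALSE)
  for (nm in names(result$tsd))
    utils::write.csv(result$tsd[[nm]]$values,
                     file.path(outdir, paste0("tsd_", nm, ".csv")))
  utils::write.csv(
    data.frame(metric = c("overall_accuracy", "kappa"),
               value = c(result$validation$overall_accuracy,
                         result$validation$kappa)),
    file.path(outdir, "validation.csv"), row.names = FALSE)
  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(result$provenance$config, cfg_path)
  prov <- c(result$provenance[c("package_version", "seed")],
            list(config_md5 = unname(tools::md5sum(cfg_path))))
  yaml::write_yaml(prov, file.path(outdir, "provenance.yaml"))
  invisible(outdir)
}
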