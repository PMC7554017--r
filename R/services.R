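# One long-format ecosystem-service record row.
es_record <- function(service, value, units, scope = "global",
                      epoch = NA_character_, scenario = NA_character_) {
  data.frame(service = service, scope = as.character(scope), epoch = epoch,
             scenario = scenario, value = value, units = units)
}

#' Constant-valued convenience raster
#'
#' @param value Single value filling the grid.
#' @param geom A [grid_geometry()].
#' @param quantity Label with units.
#' @return A `continuous_grid`.
#' @export
constant_grid <- function(value, geom, quantity = "value") {
  continuous_grid(matrix(value, geom$n_rows, geom$n_cols), geom, quantity)
}

#' Annual water yield
#'
#' Per pixel, the precipitation that does not evapotranspire:
#' `WY_x = (1 - AET_x/p_x) * p_x`, with the ratio `AET/p` supplied per class
#' as `aet_fraction` in the biophysical table. The global record converts the
#' mm depth to tonnes of water over the cell area.
#'
#' @param precip Precipitation `continuous_grid`, mm/yr.
#' @param lc A [land_cover_grid()].
#' @param bio A [biophysical_table()].
#' @param epoch,scenario Labels copied into the record.
#' @return List with `grid` (mm/yr per pixel) and `record` (total, t/yr).
#' @export
water_yield <- function(precip, lc, bio, epoch = attr(lc, "epoch"),
                        scenario = NA_character_) {
  stop_if_geometry_mismatch(precip, lc)
  if (any(grid_values(precip) < 0, na.rm = TRUE))
    stop("negative precipitation", call. = FALSE)
  aet <- bio_param(bio, "aet_fraction")[grid_values(lc)]
  wy <- (1 - aet) * grid_values(precip)
  g <- geometry(lc)
  total_t <- sum(wy, na.rm = TRUE) * g$cell_size^2 / 1000   # mm * m2 -> t
  list(grid = continuous_grid(wy, g, "water yield mm/yr"),
       record = es_record("WY", total_t, "t", epoch = epoch,
                          scenario = scenario))
}

#' Carbon storage
#'
#' Sums the four carbon pools (above- and below-ground biomass, soil, dead
#' organic matter, t/ha) over class areas.
#'
#' @inheritParams water_yield
#' @return List with `record` (total, t) and `by_class` breakdown.
#' @export
carbon_storage <- function(lc, bio, epoch = attr(lc, "epoch"),
                           scenario = NA_character_) {
  ca <- class_areas(lc)
  dens <- bio$carbon_above + bio$carbon_below + bio$carbon_soil +
    bio$carbon_dead                              # t/ha
  stored <- ca$area_km2 * 100 * dens[match(ca$code, bio$code)]  # km2 -> ha
  list(record = es_record("CS", sum(stored), "t", epoch = epoch,
                          scenario = scenario),
       by_class = data.frame(class = ca$class, code = ca$code,
                             carbon_t = stored))
}

# RUSLE topographic factors from slope (degrees): McCool S with a floor for
# flat terrain, and L for a single-cell slope length.
rusle_ls <- function(slope_deg, cell_size, s_floor = 0.03) {
  theta <- slope_deg * pi / 180
  sl <- sin(theta)
  s_fac <- ifelse(tan(theta) < 0.09, 10.8 * sl + 0.03, 16.8 * sl - 0.5)
  s_fac <- pmax(s_fac, s_floor)
  beta <- (sl / 0.0896) / (3 * sl^0.8 + 0.56)
  m <- beta / (1 + beta)
  l_fac <- (cell_size / 22.13)^m
  l_fac * s_fac
}

#' Soil conservation (RUSLE sediment retention)
#'
#' Potential erosion `Ap = R K L S` minus actual erosion
#' `Ar = R K L S C P`, i.e. `SC = R K L S (1 - C P)`, per pixel in t/ha/yr.
#' L and S derive from the DEM: Horn slope, McCool S factor (floored at
#' `s_floor` on flat terrain) and a single-cell slope length for L.
#'
#' @param dem Elevation `continuous_grid`, metres.
#' @param erosivity Rainfall erosivity R raster (MJ mm / (ha h yr)).
#' @param erodibility Soil erodibility K raster (t ha h / (ha MJ mm)).
#' @param s_floor Minimum S factor on flat terrain.
#' @inheritParams water_yield
#' @return List with `grid` (t/ha/yr) and `record` (total, t/yr).
#' @export
soil_conservation <- function(dem, erosivity, erodibility, lc, bio,
                              s_floor = 0.03, epoch = attr(lc, "epoch"),
                              scenario = NA_character_) {
  if (missing(dem) || is.null(dem)) stop("missing DEM", call. = FALSE)
  stop_if_geometry_mismatch(dem, lc)
  stop_if_geometry_mismatch(erosivity, lc)
  stop_if_geometry_mismatch(erodibility, lc)
  if (any(grid_values(erosivity) < 0, na.rm = TRUE) ||
      any(grid_values(erodibility) < 0, na.rm = TRUE))
    stop("R and K must be non-negative", call. = FALSE)
  g <- geometry(lc)
  ls <- rusle_ls(grid_values(slope_from_dem(dem)), g$cell_size, s_floor)
  cc <- bio_param(bio, "rusle_C")[grid_values(lc)]
  pp <- bio_param(bio, "rusle_P")[grid_values(lc)]
  sc <- grid_values(erosivity) * grid_values(erodibility) * ls * (1 - cc * pp)
  total <- sum(sc, na.rm = TRUE) * g$cell_size^2 / 1e4   # per-ha -> per cell
  list(grid = continuous_grid(sc, g, "soil conservation t/ha/yr"),
       record = es_record("SC", total, "t", epoch = epoch,
                          scenario = scenario))
}

#' Crop production apportioned by NDVI
#'
#' Distributes each district's statistical crop production over its cropland
#' pixels in proportion to NDVI (negative NDVI floored at zero), so district
#' totals are conserved exactly.
#'
#' @param ndvi NDVI `continuous_grid`.
#' @param zones A [zone_grid()] of districts.
#' @param district_totals Data frame with `zone` and `production_t`.
#' @inheritParams water_yield
#' @return List with `grid` (t per pixel, `NA` off cropland), `record`
#'   (global total) and `by_zone`.
#' @export
crop_production <- function(ndvi, lc, zones, district_totals,
                            epoch = attr(lc, "epoch"),
                            scenario = NA_character_) {
  stop_if_geometry_mismatch(ndvi, lc)
  stop_if_geometry_mismatch(zones, lc)
  if (any(district_totals$production_t < 0))
    stop("negative district production", call. = FALSE)
  out <- matrix(NA_real_, geometry(lc)$n_rows, geometry(lc)$n_cols)
  crop <- !is.na(lc) & grid_values(lc) == lc_classes()[["cropland"]]
  nv <- pmax(grid_values(ndvi), 0)
  for (i in seq_len(nrow(district_totals))) {
    z <- district_totals$zone[i]
    sel <- crop & !is.na(zones) & grid_values(zones) == z
    if (!any(sel)) next
    s <- sum(nv[sel], na.rm = TRUE)
    if (s == 0)
      stop("district ", z, " has cropland but zero total NDVI", call. = FALSE)
    out[sel] <- nv[sel] / s * district_totals$production_t[i]
  }
  by_zone <- zonal_stats(continuous_grid(out, geometry(lc)), zones)
  list(grid = continuous_grid(out, geometry(lc), "crop production t"),
       record = es_record("CP", sum(out, na.rm = TRUE), "t", epoch = epoch,
                          scenario = scenario),
       by_zone = data.frame(zone = by_zone$zone, production_t = by_zone$sum))
}

#' Air purification (PM10 removal)
#'
#' Class areas times per-class PM10 removal rates (t/km2/yr).
#'
#' @inheritParams water_yield
#' @return List with `record` (t PM10/yr) and `by_class` breakdown.
#' @export
air_purification <- function(lc, bio, epoch = attr(lc, "epoch"),
                             scenario = NA_character_) {
  ca <- class_areas(lc)
  removed <- ca$area_km2 * bio$pm10_removal[match(ca$code, bio$code)]
  list(record = es_record("AP", sum(removed), "t", epoch = epoch,
                          scenario = scenario),
       by_class = data.frame(class = ca$class, code = ca$code,
                             pm10_t = removed))
}

#' Habitat quality
#'
#' Habitat suitability `H_k` degraded by a saturating function of the
#' accumulated threat level: threats (by default built-up and bare cells)
#' exert an influence that decays with Euclidean distance up to `d_max`, is
#' weighted, summed and scaled by the focal class's sensitivity to give
#' `D_x`; then `HQ_x = H_k (1 - D^z / (D^z + S^z))`.
#'
#' @param threats A [threat_spec()].
#' @inheritParams water_yield
#' @return List with `grid` (dimensionless) and `record` (pixel sum).
#' @export
habitat_quality <- function(lc, threats, bio, epoch = attr(lc, "epoch"),
                            scenario = NA_character_) {
  g <- geometry(lc)
  v <- grid_values(lc)
  influence <- matrix(0, g$n_rows, g$n_cols)
  for (r in seq_along(threats$threat_codes)) {
    src <- !is.na(v) & v == threats$threat_codes[r]
    if (!any(src)) next
    d <- grid_values(nearest_distance(src, g))
    dec <- if (threats$decay[r] == "linear") pmax(1 - d / threats$d_max[r], 0)
           else exp(-2.99 * d / threats$d_max[r]) * (d <= threats$d_max[r])
    influence <- influence + threats$weight[r] * dec
  }
  D <- influence * threats$sensitivity[v]
  S <- threats$half_saturation; z <- threats$z
  hq <- bio_param(bio, "habitat_suitability")[v] *
    (1 - D^z / (D^z + S^z))
  list(grid = continuous_grid(hq, g, "habitat quality"),
       record = es_record("HQ", sum(hq, na.rm = TRUE), "", epoch = epoch,
                          scenario = scenario))
}

#' Relative change of a service total
#'
#' `(value_t2 - value_t1) / value_t1`, the dimensionless change statistic the
#' trade-off/synergy index consumes.
#'
#' @param value_t1,value_t2 Service totals (numbers, or results carrying a
#'   `$record$value`).
#' @return List with `fraction` and `percent`.
#' @export
relative_change <- function(value_t1, value_t2) {
  take <- function(x) if (is.list(x) && !is.null(x$record)) x$record$value
                      else as.numeric(x)
  v1 <- take(value_t1); v2 <- take(value_t2)
  if (v1 == 0)
    stop("undefined relative change: zero baseline", call. = FALSE)
  f <- (v2 - v1) / v1
  list(fraction = f, percent = 100 * f)
}
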