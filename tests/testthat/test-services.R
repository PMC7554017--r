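test_that("water yield is the non-evapotranspired precipitation", {
  g <- toy_geometry()
  lc <- toy_landcover()
  p <- constant_grid(1000, g, "precipitation mm/yr")
  wy0 <- water_yield(p, lc, flat_biophysical(aet = 0))
  expect_equal(grid_values(wy0$grid), grid_values(p))
  wy1 <- water_yield(p, lc, flat_biophysical(aet = 1))
  expect_equal(max(abs(grid_values(wy1$grid))), 0)
  expect_equal(wy1$record$value, 0)
  wy <- water_yield(p, lc, flat_biophysical(aet = 0.6))
  expect_equal(unique(as.vector(grid_values(wy$grid))), 400)
  # 25 cells x 100 m x 400 mm -> tonnes
  expect_equal(wy$record$value, 25 * 100^2 * 400 / 1000)
})

test_that("carbon storage is linear in class areas", {
  lc <- toy_landcover(10, 10, 1000)  # 100 km2 cropland... minus set cells
  zero <- carbon_storage(lc, flat_biophysical(carbon = 0))
  expect_equal(zero$record$value, 0)
  # single class, 10 km2 at pools summing 100 t/ha -> 1e5 t
  lc10 <- toy_landcover(10, 1, 1000)
  cs <- carbon_storage(lc10, flat_biophysical(carbon = 100))
  expect_equal(cs$record$value, 1e5)
  # additivity over a partition of the map
  v <- grid_values(lc); v[1:50] <- 2L
  lc_mix <- land_cover_grid(v, geometry(lc))
  half1 <- land_cover_grid(matrix(v[1:50], 5, 10), grid_geometry(5, 10, 1000))
  half2 <- land_cover_grid(matrix(v[51:100], 5, 10), grid_geometry(5, 10, 1000))
  bio <- default_biophysical()
  expect_equal(carbon_storage(lc_mix, bio)$record$value,
               carbon_storage(half1, bio)$record$value +
                 carbon_storage(half2, bio)$record$value)
  expect_error(flat_biophysical(carbon = -1), "negative carbon")
})

test_that("soil conservation follows RUSLE retention identities", {
  g <- grid_geometry(6, 6, 100)
  dem <- generate_terrain(g, 200, 5, seed = 4)
  lc <- land_cover_grid(matrix(1L, 6, 6), g)
  R <- constant_grid(500, g); K <- constant_grid(0.04, g)
  # C = P = 1: actual equals potential erosion, nothing retained
  sc1 <- soil_conservation(dem, R, K, lc, flat_biophysical(C = 1, P = 1))
  expect_equal(max(abs(grid_values(sc1$grid))), 0)
  # C = 0: everything retained, SC = Ap = R K L S
  sc0 <- soil_conservation(dem, R, K, lc, flat_biophysical(C = 0, P = 1))
  expect_true(all(grid_values(sc0$grid) > 0))
  # flat DEM: L S collapses to the S floor, SC proportional to R K
  flat <- constant_grid(10, g)
  R2 <- continuous_grid(matrix(runif(36, 100, 900), 6, 6), g)
  scf <- soil_conservation(flat, R2, K, lc, flat_biophysical(C = 0, P = 1),
                           s_floor = 0.03)
  expect_equal(grid_values(scf$grid), grid_values(R2) * 0.04 * 0.03,
               tolerance = 1e-12)
  expect_error(soil_conservation(NULL, R, K, lc, flat_biophysical()),
               "missing DEM")
})

test_that("crop production conserves district totals", {
  g <- grid_geometry(2, 2, 100)
  lc <- land_cover_grid(matrix(c(1, 1, 5, 5), 2, byrow = TRUE), g)
  zones <- zone_grid(matrix(1L, 2, 2), g)
  ndvi <- continuous_grid(matrix(c(0.6, 0.3, 0.9, 0.9), 2, byrow = TRUE), g)
  cp <- crop_production(ndvi, lc, zones,
                        data.frame(zone = 1L, production_t = 90))
  expect_equal(sort(grid_values(cp$grid)[1, ]), c(30, 60))
  expect_equal(cp$by_zone$production_t, 90, tolerance = 1e-9)

  # one cropland cell receives the full district total
  lc1 <- land_cover_grid(matrix(c(1, 5, 5, 5), 2, byrow = TRUE), g)
  cp1 <- crop_production(ndvi, lc1, zones,
                         data.frame(zone = 1L, production_t = 42))
  expect_equal(cp1$record$value, 42)

  # multi-district conservation under random inputs
  set.seed(8)
  gg <- grid_geometry(20, 20, 100)
  lcr <- random_landscape(20, 20, seed = 5)
  zz <- zone_grid(matrix(rep(1:4, each = 100), 20, 20), gg)
  nv <- continuous_grid(matrix(runif(400, -0.1, 0.9), 20, 20), gg)
  tot <- data.frame(zone = 1:4, production_t = c(10, 20, 30, 40))
  cpr <- crop_production(nv, lcr, zz, tot)
  expect_equal(cpr$by_zone$production_t[match(tot$zone, cpr$by_zone$zone)],
               tot$production_t, tolerance = 1e-9)
  # zero NDVI with cropland present is an error
  expect_error(crop_production(constant_grid(0, g), lc, zones,
                               data.frame(zone = 1L, production_t = 1)),
               "zero total NDVI")
})

test_that("air purification is the removal-weighted class area", {
  # 2 km2 forest at 3 t/km2/yr + 1 km2 built-up at 0 -> 6 t/yr
  g <- grid_geometry(3, 1, 1000)
  lc <- land_cover_grid(matrix(c(2L, 2L, 5L), 3, 1), g)
  bio <- flat_biophysical(pm10 = 0)
  bio$pm10_removal[bio$code == 2] <- 3
  ap <- air_purification(lc, bio)
  expect_equal(ap$record$value, 6)
  expect_equal(air_purification(lc, flat_biophysical(pm10 = 0))$record$value,
               0)
})

test_that("habitat quality obeys the saturation identities", {
  g <- toy_geometry()
  bio <- flat_biophysical(habitat = 0.4)
  # no threat anywhere: HQ equals the suitability score
  lc_clean <- toy_landcover()
  hq0 <- habitat_quality(lc_clean, threat_spec(), bio)
  expect_equal(unique(as.vector(grid_values(hq0$grid))), 0.4)
  # zero suitability gives zero quality regardless of threat
  lc_mix <- toy_landcover(set = list(c(3, 3, 5)))
  hqz <- habitat_quality(lc_mix, threat_spec(), flat_biophysical(habitat = 0))
  expect_equal(max(abs(grid_values(hqz$grid))), 0)
  # D = S: quality halves (cell (3,4) is 100 m from the threat)
  thr <- threat_spec(threat_codes = 5L, d_max = 300, weight = 1,
                     sensitivity = rep(0.6, 6), half_saturation = 0.4,
                     z = 2.5)
  hq <- habitat_quality(lc_mix, thr, bio)
  # decay at 100 m = 2/3, D = 1 * 2/3 * 0.6 = 0.4 = S
  expect_equal(grid_values(hq$grid)[3, 4], 0.4 / 2, tolerance = 1e-12)
})

test_that("habitat quality is monotone in threat level and saturation", {
  g <- grid_geometry(15, 15, 100)
  lc <- random_landscape(15, 15, seed = 12)
  bio <- default_biophysical()
  set.seed(21)
  for (i in 1:10) {
    s1 <- runif(1, 0.2, 1); s2 <- s1 + runif(1, 0.1, 1)
    z <- runif(1, 0.5, 4)
    h_lo_s <- habitat_quality(lc, threat_spec(half_saturation = s1, z = z),
                              bio)
    h_hi_s <- habitat_quality(lc, threat_spec(half_saturation = s2, z = z),
                              bio)
    # larger half-saturation -> less degradation everywhere
    expect_true(all(grid_values(h_hi_s$grid) - grid_values(h_lo_s$grid) >=
                      -1e-12))
    # stronger weights -> more degradation
    h_w <- habitat_quality(lc, threat_spec(weight = c(0.4, 0.2),
                                           half_saturation = s1, z = z), bio)
    h_W <- habitat_quality(lc, threat_spec(weight = c(1, 0.5),
                                           half_saturation = s1, z = z), bio)
    expect_true(all(grid_values(h_W$grid) - grid_values(h_w$grid) <= 1e-12))
  }
})

test_that("relative change matches the published arithmetic", {
  expect_equal(relative_change(1161.26, 1640.29)$percent, 41.25,
               tolerance = 0.005)
  expect_equal(relative_change(1.59, 2.94)$percent, 84.91, tolerance = 0.005)
  expect_equal(relative_change(5, 5)$fraction, 0)
  expect_error(relative_change(0, 3), "zero baseline")
})
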