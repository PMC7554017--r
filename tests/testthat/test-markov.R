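test_that("transition-matrix estimation matches cell counts", {
  g <- grid_geometry(2, 2, 1000)
  lc1 <- land_cover_grid(matrix(c(1, 1, 1, 5), 2, byrow = TRUE), g)
  lc2 <- land_cover_grid(matrix(c(1, 5, 5, 5), 2, byrow = TRUE), g)
  tpm <- estimate_transition_matrix(lc1, lc2)
  expect_equal(tpm$p["cropland", "builtup"], 2 / 3)
  expect_equal(rowSums(tpm$p), setNames(rep(1, 6), names(lc_classes())))
  # identical maps give the identity matrix (absent classes included)
  expect_equal(estimate_transition_matrix(lc1, lc1)$p,
               diag(6), ignore_attr = TRUE)
})

test_that("Markov demand projection is a matrix power and conserves area", {
  p <- diag(6); p[1, 1] <- 0.9; p[1, 5] <- 0.1
  tpm <- transition_matrix(p)
  s <- c(100, 0, 0, 0, 0, 0)
  out <- project_demand(s, tpm, 2)
  expect_equal(unname(out[c(1, 5)]), c(81, 19))
  expect_equal(sum(out), sum(s), tolerance = 1e-9)
  # projecting 2 periods equals projecting 1 period twice
  expect_equal(project_demand(project_demand(s, tpm, 1), tpm, 1), out)
  # identity TPM changes nothing for any n
  expect_equal(unname(project_demand(s, transition_matrix(diag(6)), 5)), s)
  expect_error(transition_matrix(matrix(0.5, 6, 6)), "row-stochastic")
})

test_that("logistic transition potential recovers known coefficients", {
  g <- grid_geometry(160, 160, 100)   # 25600 cropland cells
  lc1 <- generate_landcover(landscape_spec(g, c(1, 0, 0, 0, 0, 0), 5, 5))
  d1 <- continuous_grid(scale(as.vector(grid_values(
    generate_terrain(g, 10, 6, seed = 6))))[, 1], g, "d1")
  d2 <- continuous_grid(scale(as.vector(grid_values(
    generate_terrain(g, 8, 4, seed = 7))))[, 1], g, "d2")
  truth <- c(-1.2, 0.8, -0.6)
  dm <- list(from = 1L, to = 5L, coefficients = truth,
             drivers = list(d1, d2))
  lc2 <- evolve_landcover(lc1, evolution_spec(urbanising_tpm(0.3), 1,
                                              seed = 8, driver_mod = dm))[[1]]
  fit <- fit_transition_potential(lc1, lc2, list(d1 = d1, d2 = d2),
                                  c(1L, 5L), seed = 9)
  expect_equal(sign(fit$coefficients), sign(truth), ignore_attr = TRUE)
  expect_true(all(abs(fit$coefficients - truth) / abs(truth) <= 0.20))
  expect_gt(fit$auc, 0.6)
  # the potential surface is the logistic link of the raw coefficients
  z <- fit$coefficients[1] + fit$coefficients[2] * grid_values(d1) +
    fit$coefficients[3] * grid_values(d2)
  expect_equal(grid_values(fit$tp), plogis(z), ignore_attr = TRUE,
               tolerance = 1e-12)
  # monotone in a driver with positive coefficient
  ord <- order(grid_values(d1)[1, ])
  same_d2 <- grid_values(d2)[1, ]
  expect_true(all(diff(plogis(fit$coefficients[1] +
    fit$coefficients[2] * sort(grid_values(d1)[1, ]))) >= 0))
  expect_error(fit_transition_potential(lc1, lc1, list(d1 = d1), c(1L, 5L)),
               "at least 30")
})

test_that("CA allocation meets demand and respects neighbourhood pull", {
  g <- grid_geometry(5, 5, 100)
  v <- matrix(1L, 5, 5); v[3, 3] <- 5L
  lc <- land_cover_grid(v, g)
  ca <- cell_area_km2(g)
  demand <- setNames(c(21, 0, 0, 0, 4, 0) * ca, names(lc_classes()))
  out <- ca_allocate(lc, demand, nb = neighborhood_spec(3), seed = 2)
  newb <- which(grid_values(out$lc) == 5L & grid_values(lc) != 5L,
                arr.ind = TRUE)
  expect_equal(nrow(newb), 3)
  # enrichment dominates under uniform TP: growth adjacent to the seed
  expect_true(all(pmax(abs(newb[, 1] - 3), abs(newb[, 2] - 3)) == 1))
  expect_equal(unname(out$achieved), unname(demand))
  expect_true(all(out$shortfall == 0))

  # demand equal to current areas leaves the map unchanged
  cur <- setNames(class_areas(lc)$area_km2, names(lc_classes()))
  expect_identical(grid_values(ca_allocate(lc, cur, seed = 1)$lc),
                   grid_values(lc))

  # a protected cell with top potential never converts
  prot <- matrix(FALSE, 5, 5); prot[2, 3] <- TRUE
  out2 <- ca_allocate(lc, demand, nb = neighborhood_spec(3),
                      protected = prot, seed = 2)
  expect_equal(grid_values(out2$lc)[2, 3], 1L)
  expect_error(ca_allocate(lc, demand * 10, seed = 1), "exceeds total")
})

test_that("allocation is deterministic under seed and reports shortfall", {
  lc <- random_landscape(40, 40, seed = 14)
  ca <- cell_area_km2(geometry(lc))
  cur <- setNames(class_areas(lc)$area_km2, names(lc_classes()))
  demand <- cur
  demand["builtup"] <- demand["builtup"] + 40 * ca
  demand["cropland"] <- demand["cropland"] - 40 * ca
  a1 <- ca_allocate(lc, demand, seed = 5)
  a2 <- ca_allocate(lc, demand, seed = 5)
  expect_identical(grid_values(a1$lc), grid_values(a2$lc))
  expect_equal(unname(a1$achieved), unname(demand))

  # fully protected map: nothing can convert, shortfall reported
  prot <- matrix(TRUE, 40, 40)
  a3 <- ca_allocate(lc, demand, protected = prot, seed = 5)
  expect_identical(grid_values(a3$lc), grid_values(lc))
  expect_equal(unname(a3$shortfall["builtup"]), 40 * ca)
})

test_that("scenario rules perform the prescribed forced conversions", {
  g <- grid_geometry(2, 2, 100)
  # forest at slopes 4 and 8 degrees; CP converts only the gentle cell
  lc <- land_cover_grid(matrix(c(2L, 2L, 1L, 1L), 2, byrow = TRUE), g)
  slope <- continuous_grid(matrix(c(4, 8, 3, 10), 2, byrow = TRUE), g)
  cp <- apply_scenario_rules(lc, scenario_spec("CP"), slope)
  expect_equal(grid_values(cp$lc)[1, ], c(1L, 2L))
  # all cropland is protected under CP
  expect_true(all(cp$protected[grid_values(cp$lc) == 1L]))

  # BAU is the identity
  cur <- setNames(class_areas(lc)$area_km2, names(lc_classes()))
  bau <- apply_scenario_rules(lc, scenario_spec("BAU"), demand = cur)
  expect_identical(grid_values(bau$lc), grid_values(lc))
  expect_equal(bau$demand, cur)

  # ER: steep cropland reverts; sensitive cells protected; infeasible
  # built-up demand is capped with a shortfall
  sens <- matrix(TRUE, 2, 2)
  demand <- setNames(class_areas(lc)$area_km2, names(lc_classes()))
  demand["builtup"] <- demand["cropland"]; demand["cropland"] <- 0
  er <- suppressWarnings(
    apply_scenario_rules(lc, scenario_spec("ER", sensitive_mask = sens),
                         slope, demand))
  expect_identical(grid_values(er$lc), grid_values(lc))  # all protected
  expect_equal(unname(er$demand["builtup"]), 0)          # current area is 0
  expect_gt(er$shortfall["builtup"], 0)

  # ER without full protection reverts steep cropland to the vegetated class
  er2 <- apply_scenario_rules(lc, scenario_spec("ER",
    sensitive_mask = matrix(FALSE, 2, 2)), slope)
  expect_equal(grid_values(er2$lc)[2, ], c(1L, 2L))
  expect_error(apply_scenario_rules(lc, scenario_spec("CP")), "missing slope")
})

test_that("map validation reproduces agreement statistics", {
  lc <- random_landscape(40, 40, seed = 16)
  self <- validate_map(lc, lc)
  expect_equal(self$overall_accuracy, 1)
  expect_equal(self$kappa, 1)
  # hand-computed oracle: OA 0.8, p_e 0.5, kappa 0.6
  cm <- matrix(c(40, 10, 10, 40), 2)
  ag <- agreement_from_confusion(cm)
  po <- sum(diag(cm)) / sum(cm)
  pe <- sum(rowSums(cm) * colSums(cm)) / sum(cm)^2
  expect_equal(ag$overall_accuracy, po)
  expect_equal(ag$kappa, (po - pe) / (1 - pe))
  expect_equal(ag$kappa, 0.6)

  # independent maps with equal marginals: kappa near zero
  set.seed(31)
  g <- grid_geometry(100, 100, 100)
  a <- land_cover_grid(matrix(sample(1:4, 1e4, TRUE), 100), g)
  b <- land_cover_grid(matrix(sample(1:4, 1e4, TRUE), 100), g)
  expect_lt(abs(validate_map(a, b)$kappa), 0.05)
})
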