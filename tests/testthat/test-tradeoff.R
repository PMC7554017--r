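test_that("TSD reproduces the published worked examples", {
  syn <- tsd(-0.0270, -0.1395)
  expect_equal(syn$value, 1.64, tolerance = 0.01)
  expect_equal(syn$relationship, "synergy")
  tra <- tsd(0.0140, -0.1174)
  expect_equal(tra$value, -2.12, tolerance = 0.02)
  expect_equal(tra$relationship, "trade-off")
})

test_that("TSD boundary and invariance properties hold", {
  # either change zero -> no relationship
  expect_equal(tsd(0, 0.3), list(value = 0, relationship = "none"))
  expect_equal(tsd(0, 0), list(value = 0, relationship = "none"))
  # equal changes -> synergy of magnitude zero
  expect_equal(tsd(0.2, 0.2), list(value = 0, relationship = "synergy"))
  set.seed(17)
  for (i in 1:25) {
    di <- runif(1, -1, 1); dj <- runif(1, -1, 1); c0 <- runif(1, 0.1, 10)
    if (di == 0 || dj == 0) next
    a <- tsd(di, dj)
    # scale invariance
    expect_equal(tsd(c0 * di, c0 * dj)$value, a$value, tolerance = 1e-12)
    # symmetry in the pair
    expect_equal(tsd(dj, di)$value, a$value, tolerance = 1e-12)
    # flipping one sign flips class and sign, preserves magnitude
    b <- tsd(-di, dj)
    expect_equal(b$value, -a$value, tolerance = 1e-12)
    expect_true(a$relationship != b$relationship)
  }
})

test_that("pairwise TSD matrix is symmetric and consistent with tsd()", {
  v1 <- c(CS = 10, WY = 5, SC = 8, HQ = 4, CP = 6, AP = 2)
  v2 <- v1 * c(1.1, 1.2, 0.6, 1.1, 1.2, 0.6)
  m <- tsd_matrix(v1, v2)
  expect_equal(m$values, t(m$values))
  expect_true(all(is.na(diag(m$values))))
  # hand-computed toy: deltas +0.1, +0.2, -0.4
  expect_equal(m$values["CS", "WY"], abs(log(0.5)), tolerance = 1e-12)
  expect_equal(m$values["CS", "SC"], -abs(log(0.25)), tolerance = 1e-12)
  expect_equal(m$values["WY", "SC"], -abs(log(0.5)), tolerance = 1e-12)
  expect_equal(m$classification["CS", "HQ"], "synergy")
  expect_equal(m$classification["CS", "SC"], "trade-off")
  # identical relative changes everywhere -> all off-diagonals zero
  m0 <- tsd_matrix(v1, v1 * 1.3)
  expect_true(all(abs(m0$values[upper.tri(m0$values)]) < 1e-12))
})

test_that("TSD matrix from the published service table shows the
           water-yield trade-offs", {
  s05 <- c(CS = 1.37, HQ = 2.24, WY = 1.59, SC = 1.18, CP = 9.65, AP = 8.09)
  s15 <- c(CS = 1.33, HQ = 2.11, WY = 2.94, SC = 1.19, CP = 11.41, AP = 7.45)
  m <- tsd_matrix(s05, s15)
  # WY rose while CS, HQ, AP fell: trade-offs
  expect_equal(m$classification["WY", "CS"], "trade-off")
  expect_equal(m$classification["WY", "HQ"], "trade-off")
  expect_equal(m$classification["WY", "AP"], "trade-off")
  # the declining regulating services move together: synergies
  expect_equal(m$classification["CS", "HQ"], "synergy")
  expect_equal(m$classification["CS", "AP"], "synergy")
})

test_that("spatial TSD blocks agree with the global statistic", {
  g <- grid_geometry(20, 20, 100)
  base_i <- constant_grid(2, g); base_j <- constant_grid(5, g)
  # spatially uniform change: every block equals the global TSD
  si2 <- grid_like(base_i, grid_values(base_i) * 1.10)
  sj2 <- grid_like(base_j, grid_values(base_j) * 0.80)
  sp <- spatial_tsd(base_i, si2, base_j, sj2, block_size = 5)
  g_tsd <- tsd(0.10, -0.20)$value
  expect_equal(as.vector(grid_values(sp$tsd)), rep(g_tsd, 16),
               tolerance = 1e-9)
  expect_true(all(grid_values(sp$relationship) == -1))

  # block covering the whole map equals the pairwise matrix entry
  whole <- spatial_tsd(base_i, si2, base_j, sj2, block_size = 20)
  m <- suppressWarnings(tsd_matrix(c(CS = 4 * 2 * 100, WY = 4 * 5 * 100),
                  c(CS = 4 * 2 * 110, WY = 4 * 5 * 80)))
  expect_equal(as.vector(grid_values(whole$tsd)), m$values["CS", "WY"],
               tolerance = 1e-9)

  # two-region construction: synergy in the top half, trade-off below
  vi2 <- grid_values(base_i); vj2 <- grid_values(base_j)
  vi2[1:10, ] <- vi2[1:10, ] * 1.2; vj2[1:10, ] <- vj2[1:10, ] * 1.3
  vi2[11:20, ] <- vi2[11:20, ] * 1.2; vj2[11:20, ] <- vj2[11:20, ] * 0.7
  sp2 <- spatial_tsd(base_i, grid_like(base_i, vi2),
                     base_j, grid_like(base_j, vj2), block_size = 10)
  expect_true(all(grid_values(sp2$relationship)[1, ] == 1))
  expect_true(all(grid_values(sp2$relationship)[2, ] == -1))

  # zero baseline blocks are flagged nodata
  zi <- grid_values(base_i); zi[1:5, 1:5] <- 0
  spz <- spatial_tsd(grid_like(base_i, zi), si2, base_j, sj2, block_size = 5)
  expect_true(is.na(grid_values(spz$tsd)[1, 1]))
})
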