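# Shared toy fixtures, built in code.

toy_geometry <- function(nr = 5, nc = 5, cell = 100) {
  grid_geometry(nr, nc, cell_size = cell)
}

# all-cropland map with optional cells set to other classes
toy_landcover <- function(nr = 5, nc = 5, cell = 100, set = list()) {
  v <- matrix(1L, nr, nc)
  for (s in set) v[s[1], s[2]] <- as.integer(s[3])
  land_cover_grid(v, toy_geometry(nr, nc, cell))
}

# biophysical table with every parameter constant
flat_biophysical <- function(aet = 0.5, carbon = 25, C = 0.5, P = 0.5,
                             pm10 = 1, habitat = 0.8) {
  biophysical_table(data.frame(
    code = 1:6, aet_fraction = aet,
    carbon_above = carbon, carbon_below = 0, carbon_soil = 0,
    carbon_dead = 0, rusle_C = C, rusle_P = P, pm10_removal = pm10,
    habitat_suitability = habitat))
}

# 6-class TPM concentrating change on cropland -> built-up
urbanising_tpm <- function(p_cb = 0.2) {
  m <- diag(6)
  m[1, 1] <- 1 - p_cb
  m[1, 5] <- p_cb
  m
}

random_landscape <- function(nr = 100, nc = 100, seed = 1,
                             fractions = c(0.6, 0.1, 0.01, 0.11, 0.17, 0.01)) {
  generate_landcover(landscape_spec(grid_geometry(nr, nc, 100), fractions,
                                    patch_size = 5, seed = seed))
}
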