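#' Specification of a synthetic landscape
#'
#' Describes a categorical landscape to generate: the target class
#' composition, the typical patch size controlling spatial autocorrelation,
#' and a seed. Stands in for classified satellite imagery so the rest of the
#' pipeline can be exercised against known ground truth.
#'
#' @param geom A [grid_geometry()].
#' @param class_fractions Length-6 vector of target class shares, summing
#'   to 1 (order of [lc_classes()]).
#' @param patch_size Typical patch diameter in cells (>= 1); larger values
#'   give larger contiguous patches.
#' @param seed Integer seed.
#' @return A `landscape_spec`.
#' @export
landscape_spec <- function(geom, class_fractions, patch_size = 5, seed = 1) {
  stopifnot(length(class_fractions) == 6, patch_size >= 1)
  if (any(class_fractions < 0) || abs(sum(class_fractions) - 1) > 1e-9)
    stop("class_fractions must be non-negative and sum to 1", call. = FALSE)
  structure(list(geom = geom, class_fractions = class_fractions,
                 patch_size = patch_size, seed = as.integer(seed)),
            class = "landscape_spec")
}

#' Generate a spatially clustered categorical landscape
#'
#' Seeds `n_cells / patch_size^2` patch nuclei, assigns them classes by
#' largest-remainder quota on the target fractions, then grows patches by
#' repeated 4-neighbour dilation in randomised direction order until the grid
#' is filled. Patches are contiguous and realised class shares track the
#' quota closely (deviation shrinks with grid size). Fully deterministic
#' under the spec seed.
#'
#' @param spec A [landscape_spec()].
#' @return A [land_cover_grid()].
#' @export
generate_landcover <- function(spec) {
  g <- spec$geom
  nr <- g$n_rows; nc <- g$n_cols; ncell <- nr * nc
  with_seed(spec$seed, {
    n_seeds <- max(sum(spec$class_fractions > 0),
                   round(ncell / spec$patch_size^2))
    n_seeds <- min(n_seeds, ncell)
    lab <- matrix(0L, nr, nc)
    cells <- sample.int(ncell, n_seeds)
    classes <- rep.int(seq_len(6L), quota_counts(spec$class_fractions, n_seeds))
    lab[cells] <- sample(classes)
    while (any(lab == 0L)) {
      for (d in sample(1:4)) {
        shifted <- switch(d,
          rbind(lab[1, , drop = FALSE], lab[-nr, , drop = FALSE]),   # from N
          rbind(lab[-1, , drop = FALSE], lab[nr, , drop = FALSE]),   # from S
          cbind(lab[, 1, drop = FALSE], lab[, -nc, drop = FALSE]),   # from W
          cbind(lab[, -1, drop = FALSE], lab[, nc, drop = FALSE]))   # from E
        take <- lab == 0L & shifted != 0L
        lab[take] <- shifted[take]
      }
    }
    land_cover_grid(lab, g, epoch = "t0")
  })
}

#' Specification of a land-cover evolution process
#'
#' Ground truth for the Markov transition model: each cell changes class with
#' the probabilities in its current class's row of `tpm_true`. Optionally one
#' transition's probability is driven by a logistic model of covariate grids,
#' so logistic-regression recovery is testable against known coefficients.
#'
#' @param tpm_true 6 x 6 row-stochastic matrix of per-step transition
#'   probabilities.
#' @param n_steps Number of steps (>= 1).
#' @param seed Integer seed.
#' @param driver_mod Optional list with elements `from`, `to` (class codes),
#'   `coefficients` (numeric, intercept first) and `drivers` (list of
#'   `continuous_grid`s, one per non-intercept coefficient): for cells of
#'   class `from`, P(change to `to`) becomes `plogis(b0 + sum(b_i x_i))` and
#'   the remaining mass is spread over the other classes in proportion to the
#'   `tpm_true` row.
#' @return An `evolution_spec`.
#' @export
evolution_spec <- function(tpm_true, n_steps = 1, seed = 1, driver_mod = NULL) {
  tpm_true <- as.matrix(tpm_true)
  stopifnot(nrow(tpm_true) == 6, ncol(tpm_true) == 6, n_steps >= 1)
  check_row_stochastic(tpm_true)
  structure(list(tpm_true = tpm_true, n_steps = as.integer(n_steps),
                 seed = as.integer(seed), driver_mod = driver_mod),
            class = "evolution_spec")
}

# One multinomial step of the evolution process.
evolve_step <- function(v, tpm, driver_mod) {
  ok <- which(!is.na(v))
  cum <- t(apply(tpm, 1, cumsum))
  r <- stats::runif(length(ok))
  nxt <- rowSums(r > cum[v[ok], , drop = FALSE]) + 1L
  if (!is.null(driver_mod)) {
    dm <- driver_mod
    sel <- which(v[ok] == dm$from)
    if (length(sel)) {
      z <- rep(dm$coefficients[1], length(sel))
      for (i in seq_along(dm$drivers))
        z <- z + dm$coefficients[i + 1] * grid_values(dm$drivers[[i]])[ok][sel]
      p <- stats::plogis(z)
      u <- stats::runif(length(sel))
      other <- tpm[dm$from, ]
      other[dm$to] <- 0
      s <- sum(other)
      alt <- if (s > 0) {
        cum_o <- cumsum(other / s)
        rowSums(stats::runif(length(sel)) > matrix(cum_o, length(sel), 6,
                                                   byrow = TRUE)) + 1L
      } else rep.int(dm$from, length(sel))
      nxt[sel] <- ifelse(u < p, dm$to, alt)
    }
  }
  v[ok] <- nxt
  v
}

#' Evolve a landscape under a prescribed transition model
#'
#' @param lc Starting [land_cover_grid()].
#' @param evo An [evolution_spec()].
#' @return List of `n_steps` land-cover grids (epochs `"t1"`, `"t2"`, ...).
#' @export
evolve_landcover <- function(lc, evo) {
  stopifnot(inherits(evo, "evolution_spec"))
  with_seed(evo$seed, {
    out <- vector("list", evo$n_steps)
    v <- grid_values(lc)
    for (s in seq_len(evo$n_steps)) {
      v <- evolve_step(v, evo$tpm_true, evo$driver_mod)
      out[[s]] <- land_cover_grid(v, geometry(lc), epoch = paste0("t", s))
    }
    out
  })
}

# Smooth Gaussian random field via FFT low-pass filtered white noise
# (periodic boundary). Returned unscaled.
smooth_noise <- function(nr, nc, correlation_length) {
  noise <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (correlation_length <= 0) return(noise)
  fi <- c(0:floor(nr / 2), -(ceiling(nr / 2) - 1):-1) / nr
  fj <- c(0:floor(nc / 2), -(ceiling(nc / 2) - 1):-1) / nc
  k2 <- outer(fi^2, fj^2, `+`)
  filt <- exp(-2 * (pi * correlation_length)^2 * k2)
  Re(stats::fft(stats::fft(noise) * filt, inverse = TRUE)) / (nr * nc)
}

#' Generate smooth synthetic terrain
#'
#' Gaussian-filtered white noise rescaled to span `relief_amplitude` metres;
#' amplitude 0 gives a flat DEM.
#'
#' @param geom A [grid_geometry()].
#' @param relief_amplitude Total relief (max minus min elevation), metres.
#' @param correlation_length Smoothing length in cells.
#' @param seed Integer seed.
#' @return A `continuous_grid` of elevation in metres.
#' @export
generate_terrain <- function(geom, relief_amplitude = 100,
                             correlation_length = 10, seed = 1) {
  stopifnot(relief_amplitude >= 0)
  with_seed(seed, {
    z <- smooth_noise(geom$n_rows, geom$n_cols, correlation_length)
    rng <- diff(range(z))
    z <- if (relief_amplitude == 0 || rng == 0) z * 0
         else (z - min(z)) / rng * relief_amplitude
    continuous_grid(z, geom, quantity = "elevation m")
  })
}

# Rasterise a random-walk polyline across the grid; returns a logical matrix.
walk_line <- function(nr, nc, horizontal = TRUE) {
  mask <- matrix(FALSE, nr, nc)
  if (horizontal) {
    r <- sample.int(nr, 1)
    for (j in seq_len(nc)) {
      mask[r, j] <- TRUE
      r <- min(max(r + sample(-1:1, 1), 1L), nr)
    }
  } else {
    cidx <- sample.int(nc, 1)
    for (i in seq_len(nr)) {
      mask[i, cidx] <- TRUE
      cidx <- min(max(cidx + sample(-1:1, 1), 1L), nc)
    }
  }
  mask
}

#' Generate synthetic driver and climate fields
#'
#' Produces the covariate rasters the land-cover change model and the
#' valuation models consume: annual precipitation (positive, mild west-east
#' gradient plus smooth noise), NDVI with class-conditional means (vegetated
#' classes high, built-up low), population density decaying from the city
#' centre, and exact Euclidean distances to seeded major/minor road
#' polylines and to the centre cell.
#'
#' @param geom A [grid_geometry()].
#' @param lc A [land_cover_grid()] used for class-conditional NDVI.
#' @param seed Integer seed.
#' @param precip_base Mean annual precipitation, mm.
#' @return Named list of `continuous_grid`s: `precipitation`, `ndvi`,
#'   `popden`, `d2majroad`, `d2minroad`, `d2center`.
#' @export
generate_fields <- function(geom, lc, seed = 1, precip_base = 1000) {
  nr <- geom$n_rows; nc <- geom$n_cols
  with_seed(seed, {
    grad <- matrix(seq(-0.1, 0.1, length.out = nc), nr, nc, byrow = TRUE)
    pn <- smooth_noise(nr, nc, 8)
    precip <- pmax(precip_base * (1 + grad) +
                     30 * pn / max(stats::sd(pn), 1e-12), 1)

    ndvi_mean <- c(0.65, 0.80, 0.55, 0.30, 0.10, 0.15)[grid_values(lc)]
    ndvi <- pmin(pmax(ndvi_mean + stats::rnorm(nr * nc, sd = 0.05), -1), 1)

    major <- walk_line(nr, nc, horizontal = TRUE) |
             walk_line(nr, nc, horizontal = FALSE)
    minor <- walk_line(nr, nc, horizontal = TRUE) |
             walk_line(nr, nc, horizontal = FALSE) |
             walk_line(nr, nc, sample(c(TRUE, FALSE), 1))
    ci <- ceiling(nr / 2); cj <- ceiling(nc / 2)
    dcen <- sqrt(outer((seq_len(nr) - ci)^2, (seq_len(nc) - cj)^2, `+`)) *
      geom$cell_size
    extent <- max(nr, nc) * geom$cell_size
    pop <- 5000 * exp(-3 * dcen / extent) *
      exp(stats::rnorm(nr * nc, sd = 0.2))

    list(
      precipitation = continuous_grid(precip, geom, "precipitation mm/yr"),
      ndvi = continuous_grid(ndvi, geom, "NDVI"),
      popden = continuous_grid(pop, geom, "population density persons/km2"),
      d2majroad = nearest_distance(major, geom),
      d2minroad = nearest_distance(minor, geom),
      d2center = continuous_grid(dcen, geom, "distance m")
    )
  })
}
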