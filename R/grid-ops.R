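#' Class composition of a land-cover map
#'
#' Areas come from cell counts times cell area; percentages are taken over the
#' classified (non-nodata) total, not any nominal administrative area, so they
#' sum to 100.
#'
#' @param lc A [land_cover_grid()].
#' @return Data frame with `class`, `code`, `area_km2`, `percent`.
#' @export
class_areas <- function(lc) {
  stopifnot(inherits(lc, "land_cover_grid"))
  counts <- tabulate(grid_values(lc), nbins = 6L)
  if (sum(counts) == 0L) stop("all-nodata grid", call. = FALSE)
  area <- counts * cell_area_km2(geometry(lc))
  data.frame(class = names(lc_classes()), code = unname(lc_classes()),
             area_km2 = area, percent = 100 * area / sum(area))
}

#' Cross-tabulate two land-cover maps
#'
#' From-to transition areas between two epochs. Cells that are nodata in
#' either map are excluded, so the matrix total is the jointly classified
#' area and the diagonal is persistence.
#'
#' @param lc_t1,lc_t2 Aligned [land_cover_grid()]s.
#' @return 6 x 6 matrix of areas in km^2, rows = classes at t1.
#' @export
cross_tabulate <- function(lc_t1, lc_t2) {
  stop_if_geometry_mismatch(lc_t1, lc_t2)
  ok <- !is.na(lc_t1) & !is.na(lc_t2)
  f <- factor(grid_values(lc_t1)[ok], levels = lc_classes())
  t <- factor(grid_values(lc_t2)[ok], levels = lc_classes())
  m <- table(f, t) * cell_area_km2(geometry(lc_t1))
  m <- matrix(as.numeric(m), 6, 6,
              dimnames = list(from = names(lc_classes()),
                              to = names(lc_classes())))
  m
}

#' Zonal statistics of a continuous field
#'
#' @param values A [continuous_grid()].
#' @param zones An aligned [zone_grid()].
#' @return Data frame with `zone`, `sum`, `mean`, `mean_per_km2` (sum divided
#'   by zone area) and `area_km2`.
#' @export
zonal_stats <- function(values, zones) {
  stop_if_geometry_mismatch(values, zones)
  ok <- !is.na(values) & !is.na(zones)
  z <- grid_values(zones)[ok]
  v <- grid_values(values)[ok]
  s <- tapply(v, z, sum)
  n <- tapply(v, z, length)
  a <- n * cell_area_km2(geometry(values))
  data.frame(zone = as.integer(names(s)), sum = as.numeric(s),
             mean = as.numeric(s / n), mean_per_km2 = as.numeric(s / a),
             area_km2 = as.numeric(a), row.names = NULL)
}

# Edge-replicated padding by one cell on each side.
pad_replicate <- function(m) {
  m <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
  cbind(m[, 1, drop = FALSE], m, m[, ncol(m), drop = FALSE])
}

#' Slope from a digital elevation model
#'
#' Horn's 3x3 finite-difference method, the common GIS default. Border cells
#' use an edge-replicated neighbourhood, so a plane yields its exact slope on
#' interior cells and a slight underestimate on the border.
#'
#' @param dem A [continuous_grid()] of elevations in metres.
#' @return A `continuous_grid` of slope in degrees, in `[0, 90)`.
#' @export
slope_from_dem <- function(dem) {
  g <- geometry(dem)
  if (g$n_rows < 3 || g$n_cols < 3) stop("grid smaller than 3x3", call. = FALSE)
  z <- pad_replicate(grid_values(dem))
  nr <- g$n_rows; nc <- g$n_cols
  sub <- function(dr, dc) z[(1 + dr):(nr + dr), (1 + dc):(nc + dc)]
  # Compass neighbours of each cell in the padded matrix
  nw <- sub(0, 0); n_ <- sub(0, 1); ne <- sub(0, 2)
  w_ <- sub(1, 0);                  e_ <- sub(1, 2)
  sw <- sub(2, 0); s_ <- sub(2, 1); se <- sub(2, 2)
  dzdx <- ((ne + 2 * e_ + se) - (nw + 2 * w_ + sw)) / (8 * g$cell_size)
  dzdy <- ((sw + 2 * s_ + se) - (nw + 2 * n_ + ne)) / (8 * g$cell_size)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  continuous_grid(slope, g, quantity = "slope degrees")
}

#' Euclidean distance to the nearest source cell
#'
#' Exact Euclidean distance transform (via \pkg{EBImage}) from every cell to
#' the nearest `TRUE` cell of `source`, in metres (cell-centre to
#' cell-centre).
#'
#' @param source Logical matrix or grid marking source cells.
#' @param geom The [grid_geometry()] (taken from `source` if it is a grid).
#' @return A `continuous_grid` of distances in metres.
#' @export
nearest_distance <- function(source, geom = geometry(source)) {
  m <- matrix(1, geom$n_rows, geom$n_cols)
  src <- if (inherits(source, "luces_grid")) !is.na(source) & source != 0
         else source
  if (!any(src)) stop("no source cells", call. = FALSE)
  m[src] <- 0
  d <- EBImage::distmap(m, metric = "euclidean")
  continuous_grid(as.numeric(d) * geom$cell_size, geom,
                  quantity = "distance m")
}

# Count of TRUE cells of `mask` within the (2r+1)^2 window centred on each
# cell, window shrunk at borders; returned with the per-cell window size.
window_counts <- function(mask, r) {
  nr <- nrow(mask); nc <- ncol(mask)
  x <- matrix(as.numeric(mask), nr, nc)
  # summed-area table with a zero first row/col
  sat <- matrix(0, nr + 1, nc + 1)
  sat[-1, -1] <- apply(apply(x, 2, cumsum), 1, cumsum) |> t()
  i1 <- pmax(seq_len(nr) - r, 1L); i2 <- pmin(seq_len(nr) + r, nr)
  j1 <- pmax(seq_len(nc) - r, 1L); j2 <- pmin(seq_len(nc) + r, nc)
  I1 <- matrix(i1, nr, nc); I2 <- matrix(i2, nr, nc)
  J1 <- matrix(j1, nr, nc, byrow = TRUE); J2 <- matrix(j2, nr, nc, byrow = TRUE)
  cnt <- sat[cbind(as.vector(I2 + 1), as.vector(J2 + 1))] -
         sat[cbind(as.vector(I1),     as.vector(J2 + 1))] -
         sat[cbind(as.vector(I2 + 1), as.vector(J1))] +
         sat[cbind(as.vector(I1),     as.vector(J1))]
  size <- (I2 - I1 + 1) * (J2 - J1 + 1)
  list(count = matrix(cnt, nr, nc), size = size)
}

# Non-overlapping block sums of a matrix (blocks truncated at the far edges).
block_sums <- function(m, block) {
  nr <- nrow(m); nc <- ncol(m)
  bi <- (seq_len(nr) - 1L) %/% block
  bj <- (seq_len(nc) - 1L) %/% block
  m0 <- m; m0[is.na(m0)] <- 0
  rs <- rowsum(m0, bi)                 # collapse rows
  t(rowsum(t(rs), bj))                 # collapse cols
}
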