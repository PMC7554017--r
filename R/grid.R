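#' Land-cover class codes
#'
#' The six land-cover classes used throughout the package, coded 1 to 6:
#' cropland, forest, grassland, wetland, built-up and bare land.
#'
#' @return Named integer vector of the class codes.
#' @export
#' @examples
#' lc_classes()
lc_classes <- function() {
  c(cropland = 1L, forest = 2L, grassland = 3L, wetland = 4L,
    builtup = 5L, bare = 6L)
}

#' Grid geometry
#'
#' Describes the lattice all rasters in one analysis share: dimensions, cell
#' size in metres and the map coordinates of the lower-left corner (ESRI ASCII
#' grid convention). Cell `[1, 1]` of the value matrix is the top-left map
#' cell; indexing is row-major.
#'
#' @param n_rows,n_cols Positive integers.
#' @param cell_size Cell side length in metres.
#' @param origin_x,origin_y Map coordinates of the lower-left grid corner.
#' @param nodata_code Sentinel written to file for missing cells.
#' @return An object of class `grid_geometry`.
#' @export
grid_geometry <- function(n_rows, n_cols, cell_size = 30,
                          origin_x = 0, origin_y = 0, nodata_code = -9999) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0)
  structure(list(n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
                 origin_x = origin_x, origin_y = origin_y,
                 nodata_code = nodata_code),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("grid_geometry: %d x %d cells, %g m cells, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y))
  invisible(x)
}

same_geometry <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 0))
}

stop_if_geometry_mismatch <- function(a, b, what = "grids") {
  if (!same_geometry(geometry(a), geometry(b)))
    stop("geometry mismatch between ", what, call. = FALSE)
}

#' Grid geometry of a raster
#'
#' @param x A grid object.
#' @return The `grid_geometry` of `x`.
#' @export
geometry <- function(x) attr(x, "geometry")

#' Cell values of a raster
#'
#' @param x A grid object.
#' @return The value matrix (`NA` = nodata), rows top to bottom.
#' @export
grid_values <- function(x) {
  v <- unclass(x)
  attributes(v) <- list(dim = dim(x))
  v
}

new_grid <- function(values, geom, class, extra = list()) {
  stopifnot(inherits(geom, "grid_geometry"))
  values <- matrix(values, nrow = geom$n_rows, ncol = geom$n_cols)
  a <- c(list(geometry = geom), extra)
  for (n in names(a)) attr(values, n) <- a[[n]]
  class(values) <- c(class, "luces_grid")
  values
}

#' Categorical land-cover raster
#'
#' @param values Integer matrix (or vector recycled by column) of class codes
#'   in `lc_classes()`; `NA` marks nodata.
#' @param geom A [grid_geometry()].
#' @param epoch Label for the time point or scenario, e.g. `"2005"`.
#' @return A `land_cover_grid`.
#' @export
land_cover_grid <- function(values, geom, epoch = "t0") {
  v <- suppressWarnings(as.integer(values))
  if (any(!is.na(values) & (is.na(v) | values != v)))
    stop("illegal class code: land-cover values must be integers", call. = FALSE)
  bad <- !is.na(v) & !(v %in% lc_classes())
  if (any(bad))
    stop("illegal class code: ", paste(unique(v[bad]), collapse = ", "),
         call. = FALSE)
  new_grid(v, geom, "land_cover_grid", list(epoch = epoch))
}

#' Continuous-valued raster
#'
#' @param values Numeric matrix; `NA` marks nodata.
#' @param geom A [grid_geometry()].
#' @param quantity Label with units, e.g. `"precipitation mm/yr"`.
#' @return A `continuous_grid`.
#' @export
continuous_grid <- function(values, geom, quantity = "value") {
  new_grid(as.numeric(values), geom, "continuous_grid",
           list(quantity = quantity))
}

#' Zone (district) raster
#'
#' @param values Positive integer zone identifiers; `NA` marks nodata.
#' @param geom A [grid_geometry()].
#' @return A `zone_grid`.
#' @export
zone_grid <- function(values, geom) {
  v <- as.integer(values)
  if (any(!is.na(v) & v <= 0L)) stop("zone ids must be positive", call. = FALSE)
  new_grid(v, geom, "zone_grid")
}

#' @export
print.luces_grid <- function(x, ...) {
  g <- geometry(x)
  kind <- class(x)[1]
  cat(sprintf("%s: %d x %d cells (%g m), %d nodata cells\n",
              kind, g$n_rows, g$n_cols, g$cell_size, sum(is.na(x))))
  if (kind == "land_cover_grid") {
    tab <- table(factor(grid_values(x), levels = lc_classes(),
                        labels = names(lc_classes())))
    cat("  epoch ", attr(x, "epoch"), "; cells per class:\n", sep = "")
    print(tab)
  } else if (kind == "continuous_grid") {
    cat(sprintf("  %s, range [%g, %g]\n", attr(x, "quantity"),
                suppressWarnings(min(x, na.rm = TRUE)),
                suppressWarnings(max(x, na.rm = TRUE))))
  }
  invisible(x)
}

#' Area of one grid cell in square kilometres
#' @param geom A [grid_geometry()].
#' @return Cell area in km^2.
#' @export
cell_area_km2 <- function(geom) (geom$cell_size / 1000)^2

#' Grid with the same geometry and kind as a template
#'
#' @param template An existing grid.
#' @param values Replacement values.
#' @return A grid of the template's class carrying `values`.
#' @export
grid_like <- function(template, values) {
  out <- template
  out[] <- values
  out
}
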