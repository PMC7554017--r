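#' Read an ESRI ASCII grid
#'
#' Parses the standard six-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of cell values,
#' top row first. Categorical reads reject non-integer values and codes
#' outside [lc_classes()].
#'
#' @param path Path to an `.asc` file.
#' @param kind One of `"landcover"`, `"continuous"`, `"zone"`.
#' @param reference Optional `grid_geometry` the file must match exactly.
#' @param ... Passed to the grid constructor (`epoch`, `quantity`).
#' @return A grid of the requested kind.
#' @export
read_ascii_grid <- function(path, kind = c("continuous", "landcover", "zone"),
                            reference = NULL, ...) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("unreadable file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 7) stop("unreadable file: truncated header in ", path,
                              call. = FALSE)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("unreadable file: missing header fields in ", path, call. = FALSE)
  geom <- grid_geometry(hdr$nrows, hdr$ncols, hdr$cellsize,
                        hdr$xllcorner, hdr$yllcorner, hdr$nodata_value)
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != geom$n_rows * geom$n_cols)
    stop("unreadable file: expected ", geom$n_rows * geom$n_cols,
         " values, got ", length(vals), call. = FALSE)
  m <- matrix(vals, nrow = geom$n_rows, ncol = geom$n_cols, byrow = TRUE)
  m[m == geom$nodata_code] <- NA
  if (!is.null(reference) && !same_geometry(geom, reference))
    stop("geometry mismatch against reference geometry", call. = FALSE)
  switch(kind,
         landcover  = land_cover_grid(m, geom, ...),
         continuous = continuous_grid(m, geom, ...),
         zone       = zone_grid(m, geom))
}

#' Write a grid as an ESRI ASCII grid
#'
#' Round-trips losslessly with [read_ascii_grid()]: values are written with
#' full double precision (integers unchanged).
#'
#' @param grid Any `luces_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  g <- geometry(grid)
  v <- grid_values(grid)
  v[is.na(v)] <- g$nodata_code
  hdr <- c(sprintf("ncols %d", g$n_cols),
           sprintf("nrows %d", g$n_rows),
           sprintf("xllcorner %.10g", g$origin_x),
           sprintf("yllcorner %.10g", g$origin_y),
           sprintf("cellsize %.10g", g$cell_size),
           sprintf("NODATA_value %.10g", g$nodata_code))
  rows <- apply(v, 1, function(r) paste(format(r, digits = 17, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
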