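#' Trade-off/synergy degree (TSD) between two service changes
#'
#' The signed log-ratio statistic of two services' relative changes over the
#' same interval:
#' zero when either change is zero (no relationship);
#' `+|ln|d_i/d_j||` when the changes share a sign (synergy);
#' `-|ln|d_i/d_j||` when they oppose (trade-off).
#' Equal-magnitude changes give a relationship of magnitude zero, with the
#' sign-based class retained.
#'
#' @param delta_i,delta_j Relative changes (fractions) of the two services.
#' @return List with `value` and `relationship` (`"synergy"`, `"trade-off"`
#'   or `"none"`).
#' @export
#' @examples
#' tsd(-0.0270, -0.1395)  # strong synergy, value about 1.64
tsd <- function(delta_i, delta_j) {
  stopifnot(is.finite(delta_i), is.finite(delta_j))
  prod <- delta_i * delta_j
  if (prod == 0) return(list(value = 0, relationship = "none"))
  mag <- abs(log(abs(delta_i / delta_j)))
  if (prod > 0) list(value = mag, relationship = "synergy")
  else list(value = -mag, relationship = "trade-off")
}

#' Canonical service order used in reports
#' @return Character vector of the six service labels.
#' @export
service_order <- function() c("CS", "WY", "SC", "HQ", "CP", "AP")

#' Pairwise TSD matrix for a set of services
#'
#' Applies [relative_change()] and [tsd()] to every unordered pair of
#' services observed at two epochs (or scenarios). The result is symmetric
#' because `|ln|a/b|| = |ln|b/a||`.
#'
#' @param values_t1,values_t2 Named numeric vectors of service totals at the
#'   two epochs (names from [service_order()]), or ESRecord-style data
#'   frames with `service` and `value` columns.
#' @param interval Label pair for printing.
#' @return A `tsd_matrix`: list with `services`, `delta` (named fractions),
#'   `values` (symmetric matrix, `NA` diagonal), `classification` (character
#'   matrix) and `interval`.
#' @export
tsd_matrix <- function(values_t1, values_t2, interval = c("t1", "t2")) {
  take <- function(x) {
    if (is.data.frame(x)) stats::setNames(x$value, x$service) else x
  }
  v1 <- take(values_t1); v2 <- take(values_t2)
  services <- intersect(service_order(), names(v1))
  miss <- setdiff(union(names(v1), service_order()), names(v1))
  if (length(setdiff(services, names(v2))))
    stop("both epochs must cover the same services", call. = FALSE)
  if (length(miss))
    warning("services missing and left blank: ",
            paste(miss, collapse = ", "), call. = FALSE)
  delta <- vapply(services, function(s)
    relative_change(v1[[s]], v2[[s]])$fraction, numeric(1))
  k <- length(services)
  vals <- matrix(NA_real_, k, k, dimnames = list(services, services))
  cls <- matrix(NA_character_, k, k, dimnames = list(services, services))
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    r <- tsd(delta[a], delta[b])
    vals[a, b] <- vals[b, a] <- r$value
    cls[a, b] <- cls[b, a] <- r$relationship
  }
  structure(list(services = services, delta = delta, values = vals,
                 classification = cls, interval = interval),
            class = "tsd_matrix")
}

#' @export
print.tsd_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("TSD matrix (%s -> %s); positive = synergy, negative = trade-off\n",
              x$interval[1], x$interval[2]))
  print(round(x$values, digits))
  invisible(x)
}

#' Spatial pattern of trade-offs and synergies
#'
#' Aggregates two services' per-pixel maps at two epochs into non-overlapping
#' square blocks (block sums), computes each block's relative changes and
#' their TSD. Blocks with a zero baseline in either service are flagged
#' nodata. Block aggregation is used because per-pixel baselines are
#' frequently zero.
#'
#' @param si_t1,si_t2 Service i maps (`continuous_grid`) at the two epochs.
#' @param sj_t1,sj_t2 Service j maps at the two epochs.
#' @param block_size Block side length in cells.
#' @return List with `tsd` (`continuous_grid` at block resolution) and
#'   `relationship` (`continuous_grid`; -1 trade-off, 0 none, +1 synergy).
#' @export
spatial_tsd <- function(si_t1, si_t2, sj_t1, sj_t2, block_size = 10) {
  stop_if_geometry_mismatch(si_t1, si_t2)
  stop_if_geometry_mismatch(si_t1, sj_t1)
  stop_if_geometry_mismatch(si_t1, sj_t2)
  stopifnot(block_size >= 1)
  g <- geometry(si_t1)
  b1 <- block_sums(grid_values(si_t1), block_size)
  b2 <- block_sums(grid_values(si_t2), block_size)
  c1 <- block_sums(grid_values(sj_t1), block_size)
  c2 <- block_sums(grid_values(sj_t2), block_size)
  ok <- b1 != 0 & c1 != 0
  di <- ifelse(ok, (b2 - b1) / b1, NA_real_)
  dj <- ifelse(ok, (c2 - c1) / c1, NA_real_)
  prod <- di * dj
  val <- ifelse(prod == 0, 0, sign(prod) * abs(log(abs(di / dj))))
  rel <- ifelse(prod == 0, 0, sign(prod))
  bg <- grid_geometry(nrow(b1), ncol(b1), g$cell_size * block_size,
                      g$origin_x, g$origin_y, g$nodata_code)
  list(tsd = continuous_grid(val, bg, "TSD"),
       relationship = continuous_grid(rel, bg, "TSD class"))
}
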