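#' Per-class biophysical parameter table
#'
#' One row per land-cover class, supplying the parameters of the valuation
#' models: the evapotranspiration fraction AET/p for water yield, the four
#' carbon pool densities (t/ha), the RUSLE cover-management (C) and support
#' practice (P) factors, the PM10 removal rate (t/km2/yr) and the habitat
#' suitability score.
#'
#' @param df Data frame with columns `code`, `aet_fraction`, `carbon_above`,
#'   `carbon_below`, `carbon_soil`, `carbon_dead`, `rusle_C`, `rusle_P`,
#'   `pm10_removal`, `habitat_suitability`, covering all six classes.
#' @return A validated `biophysical_table` (data frame).
#' @export
biophysical_table <- function(df) {
  need <- c("code", "aet_fraction", "carbon_above", "carbon_below",
            "carbon_soil", "carbon_dead", "rusle_C", "rusle_P",
            "pm10_removal", "habitat_suitability")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (!setequal(df$code, lc_classes()))
    stop("table must cover exactly the class codes 1..6", call. = FALSE)
  df <- df[order(df$code), need]
  frac <- c("aet_fraction", "rusle_C", "rusle_P", "habitat_suitability")
  for (col in frac)
    if (any(df[[col]] < 0 | df[[col]] > 1))
      stop(col, " must lie in [0, 1]", call. = FALSE)
  carbon <- c("carbon_above", "carbon_below", "carbon_soil", "carbon_dead")
  if (any(as.matrix(df[carbon]) < 0))
    stop("negative carbon density", call. = FALSE)
  if (any(df$pm10_removal < 0)) stop("negative PM10 removal", call. = FALSE)
  structure(df, class = c("biophysical_table", "data.frame"))
}

#' Default (synthetic) biophysical parameters
#'
#' Plausible placeholder values in the documented ranges, intended for
#' synthetic-landscape experiments and examples. They are not calibrated to
#' any real region; supply your own [biophysical_table()] for applied work.
#'
#' @return A `biophysical_table`.
#' @export
default_biophysical <- function() {
  biophysical_table(data.frame(
    code = 1:6,
    #          crop  forest grass  wet   built bare
    aet_fraction   = c(0.55, 0.70, 0.60, 0.30, 0.10, 0.20),
    carbon_above   = c(5.7,  35.0, 3.0,  4.0,  0.0,  0.0),
    carbon_below   = c(1.1,  8.0,  6.0,  1.0,  0.0,  0.0),
    carbon_soil    = c(80.0, 115.0, 90.0, 70.0, 20.0, 30.0),
    carbon_dead    = c(0.5,  3.5,  0.5,  0.5,  0.0,  0.0),
    rusle_C        = c(0.22, 0.006, 0.04, 0.00, 0.00, 1.00),
    rusle_P        = c(0.35, 1.00, 1.00, 1.00, 1.00, 1.00),
    pm10_removal   = c(1.2,  3.0,  1.5,  0.4,  0.0,  0.0),
    habitat_suitability = c(0.4, 1.0, 0.8, 0.9, 0.0, 0.1)
  ))
}

# Per-class parameter lookup as a vector indexed by class code.
bio_param <- function(bio, col) {
  v <- numeric(6)
  v[bio$code] <- bio[[col]]
  v
}

#' Read / write a biophysical table as CSV
#'
#' @param path CSV path.
#' @return `read_biophysical` returns a `biophysical_table`;
#'   `write_biophysical` returns `path` invisibly.
#' @export
read_biophysical <- function(path) {
  biophysical_table(utils::read.csv(path))
}

#' @param bio A [biophysical_table()].
#' @rdname read_biophysical
#' @export
write_biophysical <- function(bio, path) {
  utils::write.csv(as.data.frame(bio), path, row.names = FALSE)
  invisible(path)
}

#' Habitat threat specification
#'
#' Parameters of the habitat-quality degradation model: which classes act as
#' threats, how far and how fast their influence decays, per-class
#' sensitivity to threats, and the saturation curve shape.
#'
#' @param threat_codes Class codes acting as threat sources (default
#'   built-up and bare land).
#' @param d_max Maximum influence distance of each threat, metres (recycled).
#' @param weight Threat weights in `[0, 1]` (recycled).
#' @param decay `"linear"` or `"exponential"` (recycled).
#' @param sensitivity Length-6 per-class sensitivity in `[0, 1]`.
#' @param half_saturation Half-saturation constant S (> 0) of the
#'   degradation response.
#' @param z Exponent of the saturation curve.
#' @return A `threat_spec`.
#' @export
threat_spec <- function(threat_codes = c(5L, 6L), d_max = 3000,
                        weight = c(1, 0.5), decay = "linear",
                        sensitivity = c(0.6, 0.8, 0.7, 0.9, 0.0, 0.2),
                        half_saturation = 0.5, z = 2.5) {
  n <- length(threat_codes)
  d_max <- rep_len(d_max, n); weight <- rep_len(weight, n)
  decay <- rep_len(decay, n)
  stopifnot(all(threat_codes %in% lc_classes()), all(d_max > 0),
            all(weight >= 0 & weight <= 1), length(sensitivity) == 6,
            all(sensitivity >= 0 & sensitivity <= 1),
            half_saturation > 0, z > 0,
            all(decay %in% c("linear", "exponential")))
  structure(list(threat_codes = as.integer(threat_codes), d_max = d_max,
                 weight = weight, decay = decay, sensitivity = sensitivity,
                 half_saturation = half_saturation, z = z),
            class = "threat_spec")
}
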