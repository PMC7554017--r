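#' Published Nanjing case-study reference values
#'
#' The printed land-cover and ecosystem-service numbers of the published
#' Nanjing (2005--2015, scenarios to 2030) assessment this package's methods
#' follow, embedded as a code-built table so the package's arithmetic can be
#' verified against them without any external data. Each row is one
#' derivable check: a relative change recomputed from printed absolutes, a
#' net area change, a composition share, or a TSD value recomputed from
#' printed relative changes. Tolerances are half of the last printed digit
#' (wider only for the two TSD values, whose inputs are themselves rounded).
#'
#' `type` determines how the row is checked:
#' `relative_change` (percent from `input1` to `input2`),
#' `net_change` (`input2 - input1`),
#' `share` (100 * `input1` / `input2`),
#' `tsd` ([tsd()] of the two fractions).
#'
#' @return Data frame with `id`, `type`, `input1`, `input2`, `expected`,
#'   `tolerance`, `source`.
#' @export
nanjing_reference_values <- function() {
  rc <- function(id, v1, v2, exp, src, tol = 0.005)
    data.frame(id = id, type = "relative_change", input1 = v1, input2 = v2,
               expected = exp, tolerance = tol, source = src)
  nc <- function(id, v1, v2, exp, src, tol = 0.005)
    data.frame(id = id, type = "net_change", input1 = v1, input2 = v2,
               expected = exp, tolerance = tol, source = src)
  sh <- function(id, num, den, exp, src, tol = 0.005)
    data.frame(id = id, type = "share", input1 = num, input2 = den,
               expected = exp, tolerance = tol, source = src)
  ts <- function(id, d1, d2, exp, tol, src)
    data.frame(id = id, type = "tsd", input1 = d1, input2 = d2,
               expected = exp, tolerance = tol, source = src)

  # class areas (km2): 2005, 2010, 2015; classified total 6582.08 km2
  a05 <- c(cropland = 3944.37, forest = 696.04, grassland = 59.64,
           wetland = 716.82, builtup = 1161.26, bare = 3.95)
  a10 <- c(cropland = 3509.21, forest = 673.56, grassland = 54.20,
           wetland = 765.88, builtup = 1552.16, bare = 27.07)
  a15 <- c(cropland = 3433.98, forest = 668.57, grassland = 57.84,
           wetland = 754.57, builtup = 1640.29, bare = 26.83)
  total <- sum(a05)
  # service totals: CS 1e8 t, HQ 1e5, WY 1e15 t, SC 1e7 t, CP 1e5 t, AP 1e3 t
  s05 <- c(CS = 1.37, HQ = 2.24, WY = 1.59, SC = 1.18, CP = 9.65, AP = 8.09)
  s10 <- c(CS = 1.34, HQ = 2.15, WY = 2.21, SC = 1.29, CP = 11.06, AP = 7.54)
  s15 <- c(CS = 1.33, HQ = 2.11, WY = 2.94, SC = 1.19, CP = 11.41, AP = 7.45)

  net0510 <- c(-435.1, -22.48, -5.44, 49.06, 390.90, 23.12)
  net1015 <- c(-75.23, -4.99, 3.64, -11.31, 88.13, -0.24)
  net0515 <- c(-510.39, -27.47, -1.80, 37.75, 479.03, 22.88)
  pct0510 <- c(-2.19, -4.02, 38.99, 9.32, 14.61, -6.80)
  pct1015 <- c(-0.75, -1.86, 33.03, -7.75, 3.16, -1.19)
  pct0515 <- c(-2.92, -5.80, 84.91, 0.85, 18.24, -7.91)
  # printed class shares; the 2005 built-up share is printed inconsistently
  # with its area (16.04 vs 1161.26/6582.08) and is omitted
  shr05 <- c(59.93, 10.57, 0.91, 10.89, NA, 0.06)
  shr10 <- c(53.31, 10.23, 0.82, 11.64, 23.58, 0.41)
  shr15 <- c(52.17, 10.16, 0.88, 11.46, 24.92, 0.41)

  out <- list()
  cl <- names(a05)
  sv <- names(s05)
  for (k in 1:6) {
    out[[length(out) + 1]] <- nc(paste0("net_", cl[k], "_0510"), a05[k],
      a10[k], net0510[k], paste("land-cover areas,", cl[k], "2005-2010"),
      tol = if (k == 1) 0.1 else 0.005)
    out[[length(out) + 1]] <- nc(paste0("net_", cl[k], "_1015"), a10[k],
      a15[k], net1015[k], paste("land-cover areas,", cl[k], "2010-2015"))
    out[[length(out) + 1]] <- nc(paste0("net_", cl[k], "_0515"), a05[k],
      a15[k], net0515[k], paste("land-cover areas,", cl[k], "2005-2015"))
    out[[length(out) + 1]] <- rc(paste0("pct_", sv[k], "_0510"), s05[k],
      s10[k], pct0510[k], paste("service totals,", sv[k], "2005-2010"))
    out[[length(out) + 1]] <- rc(paste0("pct_", sv[k], "_1015"), s10[k],
      s15[k], pct1015[k], paste("service totals,", sv[k], "2010-2015"))
    out[[length(out) + 1]] <- rc(paste0("pct_", sv[k], "_0515"), s05[k],
      s15[k], pct0515[k], paste("service totals,", sv[k], "2005-2015"))
    for (yr in c("05", "10", "15")) {
      shr <- switch(yr, "05" = shr05, "10" = shr10, "15" = shr15)
      ar <- switch(yr, "05" = a05, "10" = a10, "15" = a15)
      if (!is.na(shr[k]))
        out[[length(out) + 1]] <- sh(paste0("share_", cl[k], "_", yr),
          ar[k], total, shr[k],
          paste0("class share, ", cl[k], " 20", yr))
    }
  }
  extra <- list(
    rc("pct_builtup_0515", a05["builtup"], a15["builtup"], 41.25,
       "built-up expansion 2005-2015"),
    sh("share_converted_builtup", 479.03, total, 7.28,
       "land converted to built-up as share of classified area"),
    sh("share_builtup_from_cropland", 436.23, 479.03, 91.07,
       "share of new built-up taken from cropland"),
    sh("share_cropland_loss_0510", 435.1, 510.39, 85.25,
       "share of 2005-2015 cropland loss occurring before 2010"),
    sh("pct_cropland_decrease", 510.39, 3944.37, 12.94,
       "cropland decrease 2005-2015"),
    rc("pct_builtup_bau", 1640.29, 2194.80, 33.81,
       "BAU scenario built-up 2015-2030"),
    rc("pct_builtup_cp", 1640.29, 1640.29 + 204.86, 12.49,
       "CP scenario built-up 2015-2030"),
    rc("pct_builtup_er", 1640.29, 1640.29 * 1.2651, 26.51,
       "ER scenario built-up 2015-2030 (absolute implied by printed percent)"),
    rc("pct_crop_cp", 11.41, 11.63, 1.93, "CP scenario crop production"),
    rc("pct_crop_er", 11.41, 10.07, -11.74, "ER scenario crop production"),
    rc("pct_crop_cp_vs_bau", 11.41 * (1 - 0.1201), 11.63, 15.84,
       "CP crop production relative to BAU 2030"),
    rc("pct_crop_cp_vs_er", 10.07, 11.63, 15.49,
       "CP crop production relative to ER 2030"),
    ts("tsd_cs_ap_cp", -0.0270, -0.1395, 1.64, 0.01,
       "TSD of carbon storage vs air purification, CP scenario"),
    ts("tsd_cs_cp_er", 0.0140, -0.1174, -2.12, 0.02,
       "TSD of carbon storage vs crop production, ER scenario"))
  out <- do.call(rbind, c(out, extra))
  rownames(out) <- NULL
  out
}

#' Recompute every derivable published value
#'
#' Runs the package's own arithmetic ([relative_change()], [tsd()], simple
#' area sums) over [nanjing_reference_values()] and reports each check.
#'
#' @return Data frame of the reference table plus `computed` and `pass`.
#' @export
check_reference_arithmetic <- function() {
  ref <- nanjing_reference_values()
  ref$computed <- mapply(function(type, v1, v2) {
    switch(type,
           relative_change = relative_change(v1, v2)$percent,
           net_change = v2 - v1,
           share = 100 * v1 / v2,
           tsd = tsd(v1, v2)$value)
  }, ref$type, ref$input1, ref$input2)
  ref$pass <- abs(ref$computed - ref$expected) <= ref$tolerance + 1e-12
  ref
}
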