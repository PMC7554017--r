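#' Fit a logistic transition-potential model
#'
#' Among the cells of the source class at t1, models the probability of
#' changing to the target class by t2 as a logistic function of driver
#' rasters (slope, road/centre distances, population density, ...):
#' `TP = exp(z) / (1 + exp(z))`, `z = b0 + b1 x1 + ... + bn xn`.
#'
#' Drivers are standardised before fitting; coefficients are reported on both
#' the standardised and the raw scale. The fit population is split 70/30
#' (seeded) and ROC-AUC on the held-out 30% is recorded as the goodness
#' metric. On (quasi-)perfect separation the fit falls back to
#' ridge-regularised logistic regression (reported in `$method`).
#'
#' @param lc_t1,lc_t2 Aligned [land_cover_grid()]s.
#' @param drivers Named list of aligned `continuous_grid`s.
#' @param transition Length-2 integer vector `c(from, to)` of class codes.
#' @param holdout Held-out fraction for the AUC estimate.
#' @param seed Seed for the train/test split.
#' @return A `transition_potential`: list with `transition`, `coefficients`
#'   (raw scale, intercept first), `coefficients_std`, `auc`, `method`,
#'   `tp` (a `continuous_grid` of per-cell potential over the whole map).
#' @export
fit_transition_potential <- function(lc_t1, lc_t2, drivers, transition,
                                     holdout = 0.3, seed = 1) {
  stop_if_geometry_mismatch(lc_t1, lc_t2)
  from <- transition[1]; to <- transition[2]
  pop <- which(!is.na(lc_t1) & !is.na(lc_t2) & grid_values(lc_t1) == from)
  y <- as.integer(grid_values(lc_t2)[pop] == to)
  if (sum(y == 1) < 30 || sum(y == 0) < 30)
    stop("need at least 30 changed and 30 persisted cells for transition ",
         from, "->", to, call. = FALSE)
  X <- sapply(drivers, function(d) grid_values(d)[pop])
  mu <- colMeans(X); sd_ <- apply(X, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  Xs <- scale(X, center = mu, scale = sd_)

  fit_df <- data.frame(y = y, Xs)
  test <- with_seed(seed, sample.int(nrow(fit_df),
                                     size = round(holdout * nrow(fit_df))))
  train <- setdiff(seq_len(nrow(fit_df)), test)

  method <- "glm"
  fit <- suppressWarnings(stats::glm(y ~ ., data = fit_df[train, ],
                                     family = stats::binomial()))
  separated <- !fit$converged || any(abs(stats::coef(fit)[-1]) > 15)
  if (separated) {
    method <- "ridge"
    warning("perfect separation detected; refitting with ridge penalty",
            call. = FALSE)
    gfit <- glmnet::glmnet(as.matrix(Xs[train, , drop = FALSE]), y[train],
                           family = "binomial", alpha = 0, lambda = 1e-3)
    b_std <- c(as.numeric(gfit$a0), as.numeric(gfit$beta))
  } else {
    b_std <- unname(stats::coef(fit))
  }
  names(b_std) <- c("(Intercept)", names(drivers))

  # back-transform to the raw driver scale
  b_raw <- b_std
  b_raw[-1] <- b_std[-1] / sd_
  b_raw[1] <- b_std[1] - sum(b_std[-1] * mu / sd_)

  lin_test <- as.matrix(Xs[test, , drop = FALSE]) %*% b_std[-1] + b_std[1]
  auc <- if (length(unique(y[test])) == 2)
    as.numeric(pROC::auc(pROC::roc(y[test], as.numeric(lin_test),
                                   quiet = TRUE)))
  else NA_real_

  g <- geometry(lc_t1)
  z <- matrix(b_raw[1], g$n_rows, g$n_cols)
  for (i in seq_along(drivers))
    z <- z + b_raw[i + 1] * grid_values(drivers[[i]])
  structure(list(transition = c(from = from, to = to),
                 coefficients = b_raw, coefficients_std = b_std,
                 auc = auc, method = method, n = length(pop),
                 tp = continuous_grid(stats::plogis(z), g,
                                      "transition potential")),
            class = "transition_potential")
}

#' @export
print.transition_potential <- function(x, ...) {
  cls <- names(lc_classes())
  cat(sprintf("transition_potential %s -> %s (%s fit, n = %d, AUC = %.3f)\n",
              cls[x$transition[1]], cls[x$transition[2]], x$method, x$n,
              x$auc))
  print(round(x$coefficients, 4))
  invisible(x)
}
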