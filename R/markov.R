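#' Transition probability matrix
#'
#' Row-stochastic 6 x 6 matrix of inter-class transition probabilities over a
#' named interval, optionally carrying the area cross-tabulation it was
#' estimated from.
#'
#' @param p 6 x 6 matrix, rows summing to 1.
#' @param interval Character vector `c(t_from, t_to)`.
#' @param basis Optional area matrix the probabilities derive from.
#' @return A `transition_matrix`.
#' @export
transition_matrix <- function(p, interval = c("t1", "t2"), basis = NULL) {
  p <- as.matrix(p)
  stopifnot(nrow(p) == 6, ncol(p) == 6)
  check_row_stochastic(p)
  dimnames(p) <- list(from = names(lc_classes()), to = names(lc_classes()))
  structure(list(p = p, interval = interval, basis = basis),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("transition_matrix (%s -> %s)\n", x$interval[1], x$interval[2]))
  print(round(x$p, digits))
  invisible(x)
}

#' Estimate a transition matrix from two land-cover maps
#'
#' `P_ij = area(i at t1 changing to j) / area(i at t1)`. Classes absent at t1
#' get identity rows (they cannot be observed to change).
#'
#' @param lc_t1,lc_t2 Aligned [land_cover_grid()]s.
#' @return A [transition_matrix()].
#' @export
estimate_transition_matrix <- function(lc_t1, lc_t2) {
  x <- cross_tabulate(lc_t1, lc_t2)
  rs <- rowSums(x)
  p <- diag(6)
  nz <- rs > 0
  p[nz, ] <- x[nz, , drop = FALSE] / rs[nz]
  transition_matrix(p, interval = c(attr(lc_t1, "epoch"),
                                    attr(lc_t2, "epoch")), basis = x)
}

#' Project class-area demand with the Markov model
#'
#' `S_{t+n} = S_t P^n`: the class-area row vector times the n-th power of the
#' transition matrix. Total area is conserved.
#'
#' @param areas Length-6 vector of class areas (any unit) at time t.
#' @param tpm A [transition_matrix()].
#' @param n_periods Number of projection steps.
#' @return Named length-6 vector of projected areas.
#' @export
project_demand <- function(areas, tpm, n_periods = 1) {
  stopifnot(length(areas) == 6, all(areas >= 0), n_periods >= 1)
  p <- tpm$p
  pn <- diag(6)
  for (i in seq_len(n_periods)) pn <- pn %*% p
  out <- as.numeric(matrix(areas, 1) %*% pn)
  names(out) <- names(lc_classes())
  out
}

#' Compare a simulated map against a reference map
#'
#' Overall accuracy (fraction of agreeing cells) and Cohen's kappa
#' (chance-corrected agreement from the confusion-matrix marginals), plus
#' the confusion matrix in cells.
#'
#' @param simulated,reference Aligned [land_cover_grid()]s.
#' @return List with `overall_accuracy`, `kappa`, `confusion`.
#' @export
validate_map <- function(simulated, reference) {
  stop_if_geometry_mismatch(simulated, reference)
  ok <- !is.na(simulated) & !is.na(reference)
  cm <- table(factor(grid_values(simulated)[ok], levels = lc_classes()),
              factor(grid_values(reference)[ok], levels = lc_classes()))
  ag <- e1071::classAgreement(cm)
  list(overall_accuracy = ag$diag, kappa = ag$kappa,
       confusion = matrix(as.numeric(cm), 6, 6,
                          dimnames = list(simulated = names(lc_classes()),
                                          reference = names(lc_classes()))))
}

#' Agreement statistics from a confusion matrix
#'
#' @param cm Square confusion matrix of counts.
#' @return List with `overall_accuracy` and `kappa`.
#' @export
agreement_from_confusion <- function(cm) {
  ag <- e1071::classAgreement(as.table(cm))
  list(overall_accuracy = ag$diag, kappa = ag$kappa)
}
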