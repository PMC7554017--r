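#' Neighbourhood specification for the CA model
#'
#' @param window Odd window side length (cells), default the common 5 x 5
#'   contiguity filter.
#' @param epsilon Floor added to the neighbourhood enrichment so isolated
#'   growth remains possible.
#' @return A `neighborhood_spec`.
#' @export
neighborhood_spec <- function(window = 5, epsilon = 0.05) {
  window <- as.integer(window)
  stopifnot(window >= 3, window %% 2 == 1, epsilon >= 0)
  structure(list(window = window, epsilon = epsilon),
            class = "neighborhood_spec")
}

#' Scenario specification
#'
#' Bundles the constraints of a simulation scenario: cells immune to
#' conversion, the mask of core (central urban) districts exempt from forced
#' conversions, the ecologically sensitive mask, the slope threshold of the
#' forced-conversion rules, and an optional demand override.
#'
#' * `BAU` (business as usual): no constraints, the historical trend runs on.
#' * `CP` (cropland protection): grassland/forest on slopes below the
#'   threshold and outside the core districts are converted to cropland, and
#'   all cropland becomes protected.
#' * `ER` (ecological restoration): sensitive cells are protected from
#'   conversion, and cropland steeper than the threshold reverts to a
#'   vegetated class.
#'
#' @param name One of `"BAU"`, `"CP"`, `"ER"`.
#' @param protected Optional logical matrix/grid of cells immune to
#'   conversion.
#' @param core_mask Optional logical matrix/grid of core districts.
#' @param sensitive_mask Logical matrix/grid of ecologically sensitive cells
#'   (required for ER).
#' @param slope_threshold Slope threshold in degrees for the forced rules.
#' @param revert_to Class code steep cropland reverts to under ER.
#' @param demand_override Optional named length-6 vector of target areas
#'   (km^2) replacing the Markov demand.
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(name = c("BAU", "CP", "ER"), protected = NULL,
                          core_mask = NULL, sensitive_mask = NULL,
                          slope_threshold = 6, revert_to = 2L,
                          demand_override = NULL) {
  name <- match.arg(name)
  stopifnot(is.finite(slope_threshold), revert_to %in% lc_classes())
  structure(list(name = name, protected = protected, core_mask = core_mask,
                 sensitive_mask = sensitive_mask,
                 slope_threshold = slope_threshold,
                 revert_to = as.integer(revert_to),
                 demand_override = demand_override),
            class = "scenario_spec")
}

as_mask <- function(m, geom) {
  if (is.null(m)) return(matrix(FALSE, geom$n_rows, geom$n_cols))
  mm <- if (inherits(m, "luces_grid")) !is.na(m) & grid_values(m) != 0 else m
  stopifnot(identical(dim(mm), c(geom$n_rows, geom$n_cols)))
  mm & !is.na(mm)
}

#' Apply scenario rules to a map and its demand
#'
#' Performs the forced conversions of the scenario, assembles the protection
#' mask, and caps each class's demand at the area achievable under that mask
#' (reporting any shortfall). BAU is the identity.
#'
#' @param lc A [land_cover_grid()].
#' @param scen A [scenario_spec()].
#' @param slope Slope `continuous_grid` in degrees (required when the
#'   scenario has a slope rule).
#' @param demand Named length-6 vector of target class areas (km^2), e.g.
#'   from [project_demand()]; optional.
#' @return List with `lc` (modified grid), `demand` (capped, or `NULL`),
#'   `protected` (logical matrix) and `shortfall` (named vector, km^2).
#' @export
apply_scenario_rules <- function(lc, scen, slope = NULL, demand = NULL) {
  g <- geometry(lc)
  v <- grid_values(lc)
  protected <- as_mask(scen$protected, g)
  if (!is.null(scen$demand_override)) demand <- scen$demand_override

  if (scen$name == "CP") {
    if (is.null(slope)) stop("missing slope grid for the CP slope rule",
                             call. = FALSE)
    stop_if_geometry_mismatch(slope, lc)
    core <- as_mask(scen$core_mask, g)
    flip <- !is.na(v) & v %in% c(2L, 3L) &
      grid_values(slope) < scen$slope_threshold & !core
    v[flip] <- lc_classes()[["cropland"]]
    protected <- protected | (!is.na(v) & v == lc_classes()[["cropland"]])
  } else if (scen$name == "ER") {
    protected <- protected | as_mask(scen$sensitive_mask, g)
    if (is.null(slope)) stop("missing slope grid for the ER slope rule",
                             call. = FALSE)
    stop_if_geometry_mismatch(slope, lc)
    flip <- !is.na(v) & v == lc_classes()[["cropland"]] &
      grid_values(slope) > scen$slope_threshold & !protected
    v[flip] <- scen$revert_to
  }

  out <- land_cover_grid(v, g, epoch = attr(lc, "epoch"))
  shortfall <- stats::setNames(numeric(6), names(lc_classes()))
  if (!is.null(demand)) {
    ca <- cell_area_km2(g)
    cur <- tabulate(v, 6L) * ca
    give <- tabulate(v[!protected & !is.na(v)], 6L) * ca
    for (j in 1:6) {
      achievable <- cur[j] + sum(give[-j])
      if (demand[j] > achievable + ca / 2) {
        shortfall[j] <- demand[j] - achievable
        demand[j] <- achievable
      }
    }
    if (any(shortfall > 0))
      warning("infeasible demand capped for: ",
              paste(names(lc_classes())[shortfall > 0], collapse = ", "),
              call. = FALSE)
  }
  list(lc = out, demand = demand, protected = protected,
       shortfall = shortfall)
}

# Per-cell transition-potential lookup for target class `to`: a matrix whose
# entry for a cell of class i is TP(i -> to), defaulting to 0.5.
tp_for_target <- function(v, to, potentials, geom) {
  tp <- matrix(0.5, geom$n_rows, geom$n_cols)
  for (p in potentials) {
    if (p$transition[2] != to) next
    sel <- !is.na(v) & v == p$transition[1]
    tp[sel] <- grid_values(p$tp)[sel]
  }
  tp
}

#' Allocate projected class demand on the map (CA step)
#'
#' Converts cells so class areas meet the demanded targets. Candidate cells
#' are scored as `TP * (epsilon + omega)`, where `TP` is the transition
#' potential into the target class and `omega` the fraction of the
#' neighbourhood window already holding it; a seeded jitter of magnitude
#' 1e-9 breaks ties reproducibly. Growing classes are processed in
#' descending order of net demand; each takes its highest-scoring candidates
#' from classes with surplus area, and a converted cell leaves later
#' candidate pools. Protected cells never convert. Infeasible demand yields
#' a partial allocation with the shortfall reported.
#'
#' @param lc A [land_cover_grid()] at time t.
#' @param demand Named length-6 vector of target class areas, km^2.
#' @param potentials List of [fit_transition_potential()] results (missing
#'   transitions default to potential 0.5).
#' @param nb A [neighborhood_spec()].
#' @param protected Optional logical matrix of cells immune to conversion
#'   (e.g. from [apply_scenario_rules()]).
#' @param seed Integer seed for the tie-breaking jitter.
#' @return List with `lc` (allocated grid), `achieved` (areas, km^2) and
#'   `shortfall` (km^2 of unmet demand per class).
#' @export
ca_allocate <- function(lc, demand, potentials = list(),
                        nb = neighborhood_spec(), protected = NULL,
                        seed = 1) {
  g <- geometry(lc)
  ca <- cell_area_km2(g)
  v <- grid_values(lc)
  prot <- as_mask(protected, g)
  n_ok <- sum(!is.na(v))
  if (sum(demand) > (n_ok + 0.5) * ca)
    stop("demand exceeds total map area", call. = FALSE)

  target <- round(demand / ca)
  cur <- tabulate(v, 6L)
  net <- target - cur
  give_left <- pmax(cur - target, 0L)       # donor capacity per class
  r <- (nb$window - 1L) %/% 2L
  jitter <- with_seed(seed, matrix(stats::runif(length(v), 0, 1e-9),
                                   nrow(v), ncol(v)))
  shortfall <- stats::setNames(numeric(6), names(lc_classes()))
  converted <- matrix(FALSE, g$n_rows, g$n_cols)

  for (j in order(net, decreasing = TRUE)) {
    need <- net[j]
    if (need <= 0) next
    wc <- window_counts(!is.na(v) & v == j, r)
    omega <- wc$count / wc$size
    score <- tp_for_target(v, j, potentials, g) * (nb$epsilon + omega) +
      jitter
    cand <- which(!is.na(v) & v != j & !prot & !converted &
                    give_left[v] > 0)
    cand <- cand[order(score[cand], decreasing = TRUE)]
    for (cell in cand) {
      i <- v[cell]
      if (give_left[i] <= 0L) next
      give_left[i] <- give_left[i] - 1L
      v[cell] <- j
      converted[cell] <- TRUE
      need <- need - 1L
      if (need == 0L) break
    }
    if (need > 0L) shortfall[j] <- need * ca
  }

  achieved <- stats::setNames(tabulate(v, 6L) * ca, names(lc_classes()))
  list(lc = land_cover_grid(v, g, epoch = paste0(attr(lc, "epoch"), "+1")),
       achieved = achieved, shortfall = shortfall)
}
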