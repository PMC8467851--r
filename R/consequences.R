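# Monetized accident consequences: weighted sums of exposure-ring areas and
# pollution volumes against cost tables.

#' Default population exposure cost table
#'
#' Per-person costs (opaque currency units; CNY in typical use) for the four
#' cost types: 1 evacuation, 2 inspection, 3 medical, 4 casualties.
#' Illustrative magnitudes, not calibrated price standards.
#'
#' @return Named numeric vector of length 4.
#' @export
default_population_costs <- function() {
  c(evacuation = 50, inspection = 300, medical = 2000, casualty = 1.5e6)
}

#' Default cost-incidence probabilities
#'
#' alpha\[u, v\]: probability that a person in exposure ring u incurs cost
#' type v. Severity increases toward the innermost ring (u = 3, inside the
#' highest AEGL threshold), so medical and casualty incidence rise with u.
#' Illustrative values; the model accepts any \[0,1\] entries, constant or
#' per-period (3 x 4 x 24 array).
#'
#' @return 3 x 4 numeric matrix (rings x cost types).
#' @export
default_cost_incidence <- function() {
  m <- rbind(c(0.80, 0.50, 0.10, 0.000),
             c(0.90, 0.80, 0.50, 0.020),
             c(1.00, 0.90, 0.80, 0.200))
  dimnames(m) <- list(paste0("zone", 1:3),
                      names(default_population_costs()))
  m
}

#' Default environmental pollution cost table
#'
#' Per-m^3 treatment costs by medium (rows: air, groundwater, lake, river)
#' and cost type (columns: emergency disposal, monitoring, remediation).
#' Illustrative magnitudes.
#'
#' @return 4 x 3 numeric matrix.
#' @export
default_env_costs <- function() {
  m <- rbind(air    = c(0.5, 0.2, 0.1),
             gwater = c(20, 5, 50),
             lake   = c(10, 3, 30),
             river  = c(8, 3, 25))
  colnames(m) <- c("disposal", "monitoring", "remediation")
  m
}

alpha_at_period <- function(alpha, t) {
  if (is.matrix(alpha)) {
    stopifnot(nrow(alpha) == 3L, ncol(alpha) == 4L)
    return(alpha)
  }
  if (is.array(alpha) && length(dim(alpha)) == 3L) {
    stopifnot(dim(alpha)[1] == 3L, dim(alpha)[2] == 4L, dim(alpha)[3] == 24L)
    return(alpha[, , t + 1L])
  }
  stop("alpha must be a 3x4 matrix or 3x4x24 array", call. = FALSE)
}

#' Population exposure consequence
#'
#' Total monetized consequence of exposing the population along the segment
#' to the three AEGL rings:
#' \deqn{C^{Pop}(t) = \sum_{u=1}^{3}\sum_{v=1}^{4}
#'       S_u \, T(t) \, \alpha_{uv}(t) \, F_v}
#' Linear in the population density, the ring areas and the cost table.
#'
#' @param zones An [exposure_zones()] result.
#' @param population_density Persons/m^2 at the period, >= 0.
#' @param alpha 3 x 4 incidence matrix or 3 x 4 x 24 array.
#' @param costs Length-4 cost vector, currency/person.
#' @param t Period 0..23 (only consulted when alpha is per-period).
#' @return Consequence in currency units, >= 0.
#' @export
population_consequence <- function(zones, population_density,
                                   alpha = default_cost_incidence(),
                                   costs = default_population_costs(),
                                   t = 0L) {
  t <- check_period(t)
  if (population_density < 0) {
    stop("population density must be >= 0", call. = FALSE)
  }
  a <- alpha_at_period(alpha, t)
  if (any(a < 0 | a > 1)) stop("alpha entries must lie in [0, 1]", call. = FALSE)
  if (any(costs < 0)) stop("costs must be >= 0", call. = FALSE)
  sum(zones$areas * population_density * (a %*% as.numeric(costs)))
}

#' Environmental pollution consequence
#'
#' \deqn{C^{Env}(t) = \sum_{r=1}^{4}\sum_{w=1}^{3} V_r \, F_{rw}}
#' Absent media have zero volume and contribute nothing.
#'
#' @param volumes A [pollution_volumes()] result.
#' @param costs 4 x 3 cost matrix (media x cost types), currency/m^3.
#' @return Consequence in currency units, >= 0.
#' @export
environmental_consequence <- function(volumes, costs = default_env_costs()) {
  stopifnot(is.matrix(costs), nrow(costs) == 4L, ncol(costs) == 3L)
  if (any(costs < 0)) stop("costs must be >= 0", call. = FALSE)
  sum(as.numeric(volumes$volumes) * rowSums(costs))
}
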