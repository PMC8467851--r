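# Leakage accident probability: tabulated truck accident rates, conditional
# leakage probabilities, and the per-segment-period probability.

#' Default truck accident rate table
#'
#' Weighted average truck accident rates (accidents per million vehicle-km)
#' by region and road type, as tabulated from US state crash statistics.
#'
#' @return data.frame with columns `region`, `road_type`, `rate`.
#' @export
truck_accident_rates <- function() {
  data.frame(
    region = "city",
    road_type = c("two-lane", "undivided multilane", "divided multilane",
                  "cycle lane", "expressway"),
    rate = c(5.38, 8.65, 7.75, 6.03, 1.35),
    stringsAsFactors = FALSE)
}

#' Default conditional leakage probability table
#'
#' Probability that a given accident type results in a hazmat leak, grouped
#' into single-vehicle noncollision and single-vehicle collision scenarios.
#'
#' @return data.frame with columns `group`, `scenario`, `probability`.
#' @export
leakage_conditionals <- function() {
  data.frame(
    group = c(rep("single-vehicle noncollision", 3),
              rep("single-vehicle collision", 5)),
    scenario = c("leaves the road", "overturned on the road",
                 "other noncollision accident",
                 "collision with stopped vehicle", "collision with a train",
                 "collision with a nonmotorized vehicle",
                 "collision with fixed objects", "other collision accident"),
    probability = c(0.331, 0.375, 0.169, 0.031, 0.455, 0.015, 0.129, 0.059),
    stringsAsFactors = FALSE)
}

#' Look up the truck accident rate
#'
#' @param region Region label (default table covers `"city"`).
#' @param road_type Road type label.
#' @param table Rate table; defaults to [truck_accident_rates()]. Override
#'   with a CSV-loaded data.frame of the same columns.
#' @return Rate in accidents per million vehicle-km.
#' @export
lookup_truck_accident_rate <- function(region, road_type,
                                       table = truck_accident_rates()) {
  hit <- table$region == region & table$road_type == road_type
  if (!any(hit)) {
    keys <- paste0("(", table$region, ", ", table$road_type, ")")
    stop(sprintf("no accident rate for (%s, %s); valid keys: %s",
                 region, road_type, paste(keys, collapse = "; ")),
         call. = FALSE)
  }
  table$rate[which(hit)[1]]
}

#' Look up the conditional leakage probability
#'
#' @param scenario Accident scenario label.
#' @param table Conditional table; defaults to [leakage_conditionals()].
#' @return Probability in \[0, 1\].
#' @export
lookup_leakage_conditional <- function(scenario,
                                       table = leakage_conditionals()) {
  hit <- table$scenario == scenario
  if (!any(hit)) {
    stop(sprintf("no leakage probability for scenario '%s'; valid: %s",
                 scenario, paste(table$scenario, collapse = "; ")),
         call. = FALSE)
  }
  table$probability[which(hit)[1]]
}

#' Leakage accident rate
#'
#' Product of the base accident rate and the conditional leakage
#' probability: the rate of accidents that actually leak.
#'
#' @param p_a Accident rate, accidents per million vehicle-km, > 0.
#' @param p_b Conditional leakage probability in \[0, 1\].
#' @return Leakage rate, accidents per million vehicle-km.
#' @export
leakage_rate <- function(p_a, p_b) {
  if (any(p_a <= 0)) stop("p_a must be > 0", call. = FALSE)
  if (any(p_b < 0 | p_b > 1)) stop("p_b must lie in [0, 1]", call. = FALSE)
  p_a * p_b
}

#' Leakage accident probability for a segment at one period
#'
#' Converts the per-vehicle-km leakage rate into a dimensionless probability
#' for segment (i, j) at period t:
#' \deqn{P_{ij}(t) = 10^{-6} \times P^A \times P^B \times M_{ij}(t) \times L_{ij}/2}
#' with the accident rate \eqn{P^A} looked up from the segment's
#' (region, road type). The final length factor defaults to `L/2`
#' (per-direction traffic); `length_mode = "squared"` switches to `L^2` for
#' sensitivity checks against the alternative reading.
#'
#' Values are typically 1e-6..1e-4; a warning (not an error) is emitted if
#' the formula ever exceeds 1.
#'
#' @param segment A [road_segment()].
#' @param t Period 0..23.
#' @param scenario_type Accident scenario(s) whose conditional probabilities
#'   are summed; default `"overturned on the road"` matching the model
#'   assumption that hazmat leaks immediately after an overturn.
#' @param rate_table,leak_table Optional table overrides.
#' @param length_mode `"half"` (default) or `"squared"`.
#' @return Probability P_ij(t) >= 0.
#' @export
segment_leakage_probability <- function(segment, t,
                                        scenario_type = "overturned on the road",
                                        rate_table = truck_accident_rates(),
                                        leak_table = leakage_conditionals(),
                                        length_mode = c("half", "squared")) {
  length_mode <- match.arg(length_mode)
  t <- check_period(t)
  p_a <- lookup_truck_accident_rate(segment$region, segment$road_type,
                                    rate_table)
  p_b <- sum(vapply(scenario_type, lookup_leakage_conditional, numeric(1),
                    table = leak_table))
  m <- segment$vehicle_density[t + 1L]
  lfac <- if (length_mode == "half") segment$length_km / 2
          else segment$length_km^2
  p <- 1e-6 * p_a * p_b * m * lfac
  if (p > 1) {
    warning(sprintf("segment %s period %d: leakage probability %.3g exceeds 1",
                    segment_id(segment$from, segment$to), t, p))
  }
  p
}

check_period <- function(t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t != as.integer(t) ||
      t < 0 || t > 23) {
    stop("period t must be an integer in 0..23", call. = FALSE)
  }
  as.integer(t)
}
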