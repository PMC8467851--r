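# Bearing-capacity ratios, piecewise risk-preference exponents, and the
# final per-segment-period risk scores.

#' Width of the population bearing area
#'
#' Standard emergency-response isolation corridor half-extent used as the
#' bearing-area width: 600 m.
#' @export
D_POP_DEFAULT <- 600

#' Population bearing-capacity ratio
#'
#' Ratio of the population actually inside the exposure rings to the
#' acceptable upper limit along the segment (the 600 m emergency-response
#' corridor at the same density):
#' \deqn{p^{Pop} = \frac{\sum_u S_u \, T}{10^3 L \, d^{Pop} \, T}
#'             = \frac{\sum_u S_u}{10^3 L \, d^{Pop}}}
#' The density cancels algebraically but must be positive for the ratio to
#' be defined as written.
#'
#' @param zones An [exposure_zones()] result.
#' @param population_density Persons/m^2, > 0.
#' @param length_km Segment length, km, > 0.
#' @param d_pop Bearing-area width, m, > 0; default [D_POP_DEFAULT].
#' @return Dimensionless ratio >= 0.
#' @export
population_ratio <- function(zones, population_density, length_km,
                             d_pop = D_POP_DEFAULT) {
  if (population_density <= 0) {
    stop("population density must be > 0 (ratio undefined at 0)",
         call. = FALSE)
  }
  if (length_km <= 0 || d_pop <= 0) {
    stop("length_km and d_pop must be > 0", call. = FALSE)
  }
  sum(zones$areas) / (1e3 * length_km * d_pop)
}

#' Environmental bearing-capacity ratio
#'
#' Ratio of the amount released to the environment's self-purification
#' capacity, the summed product of each medium's influence volume and limit
#' concentration:
#' \deqn{p^{Env} = \frac{Q}{\sum_{r} V_r \, C_r^{Env}}}
#'
#' @param total_amount_mg Released amount Q, mg, > 0.
#' @param volumes A [pollution_volumes()] result.
#' @param env_thresholds Named per-medium limits (air, gwater, lake, river),
#'   mg/m^3; defaults to the scenario values stored alongside the volumes
#'   when called from [assess_segment()].
#' @return Dimensionless ratio > 0.
#' @export
environment_ratio <- function(total_amount_mg, volumes, env_thresholds) {
  capacity <- sum(as.numeric(volumes$volumes) *
                    as.numeric(env_thresholds[names(volumes$volumes)]))
  if (!is.finite(capacity) || capacity <= 0) {
    stop("environmental bearing capacity is zero: no medium has positive volume",
         call. = FALSE)
  }
  total_amount_mg / capacity
}

#' Piecewise risk-preference parameter
#'
#' Maps a bearing-capacity ratio p to the exponent q applied to the
#' consequence: consequences within capacity are damped (q < 1), those
#' beyond it amplified (q > 1), crossing 1 exactly at p = 1:
#' \deqn{q = 0.9 \;(0 < p \le 0.5);\; 0.95 \;(0.5 < p < 1);\;
#'       1.0 \;(p = 1);\; 1.05 \;(1 < p \le 1.5);\; 1.1 \;(p > 1.5)}
#' p = 0 maps to 0.9 (the consequence is 0 there so the risk is unaffected).
#'
#' @param p Bearing-capacity ratio(s), >= 0 (vectorized).
#' @return Preference exponent(s) in \{0.9, 0.95, 1.0, 1.05, 1.1\}.
#' @export
preference_parameter <- function(p) {
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("ratio p must be finite and >= 0", call. = FALSE)
  }
  vapply(p, function(pi) {
    if (pi <= 0.5) 0.9
    else if (pi < 1) 0.95
    else if (pi == 1) 1.0
    else if (pi <= 1.5) 1.05
    else 1.1
  }, numeric(1))
}

risk_score <- function(p_leak, consequence, q) {
  if (p_leak < 0 || consequence < 0) {
    stop("probability and consequence must be >= 0", call. = FALSE)
  }
  if (consequence == 0 || p_leak == 0) return(0)
  # log-domain evaluation: C^q can overflow for large consequences, q > 1,
  # even when the product with the small probability is representable
  exp(log(p_leak) + q * log(consequence))
}

#' Population exposure risk
#'
#' \deqn{ER^{Pop}(t) = P(t) \times C^{Pop}(t)^{\,q^{Pop}}}
#' With q = 1 this is the traditional probability-times-consequence risk.
#' Note the exponent makes the score unit-sensitive: comparisons are only
#' valid within one currency unit system.
#'
#' @param p_leak Leakage probability P(t), >= 0.
#' @param consequence Consequence C, currency units, >= 0.
#' @param q Preference exponent from [preference_parameter()].
#' @return Risk score >= 0.
#' @export
population_risk <- function(p_leak, consequence, q) {
  risk_score(p_leak, consequence, q)
}

#' Environmental pollution risk
#'
#' \deqn{ER^{Env}(t) = P(t) \times C^{Env}(t)^{\,q^{Env}}}
#'
#' @inheritParams population_risk
#' @return Risk score >= 0.
#' @export
environmental_risk <- function(p_leak, consequence, q) {
  risk_score(p_leak, consequence, q)
}

#' Assessment configuration
#'
#' Bundles the tunable tables and switches used by [assess_segment()].
#'
#' @param d_pop Bearing-area width, m.
#' @param scenario_type Accident scenario(s) for the conditional leakage
#'   probability.
#' @param alpha Cost-incidence matrix/array.
#' @param population_costs Length-4 per-person cost vector.
#' @param env_costs 4 x 3 per-m^3 cost matrix.
#' @param length_mode `"half"` or `"squared"` length factor in the
#'   probability conversion.
#' @param rate_table,leak_table Probability table overrides.
#' @return A list of class `assessment_config`.
#' @export
assessment_config <- function(d_pop = D_POP_DEFAULT,
                              scenario_type = "overturned on the road",
                              alpha = default_cost_incidence(),
                              population_costs = default_population_costs(),
                              env_costs = default_env_costs(),
                              length_mode = "half",
                              rate_table = truck_accident_rates(),
                              leak_table = leakage_conditionals()) {
  structure(list(d_pop = d_pop, scenario_type = scenario_type, alpha = alpha,
                 population_costs = population_costs, env_costs = env_costs,
                 length_mode = length_mode, rate_table = rate_table,
                 leak_table = leak_table),
            class = "assessment_config")
}

#' Assess one segment at one period
#'
#' Runs the full chain: leakage probability, AEGL exposure rings, pollution
#' volumes, monetized consequences, bearing-capacity ratios, preference
#' exponents, and the two risk scores. Deterministic given its inputs.
#'
#' A zero population density at the period short-circuits the population
#' branch to C = 0, q = 0.9, ER = 0 (the bearing ratio is undefined as
#' written but the risk is zero regardless).
#'
#' @param segment A [road_segment()].
#' @param scenario A [release_scenario()].
#' @param stability A [stability_parameters()].
#' @param t Period 0..23.
#' @param config An [assessment_config()].
#' @return One-row data.frame: segment_id, period, p_leak, c_pop, c_env,
#'   p_pop, q_pop, p_env, q_env, er_pop, er_env, and the four medium
#'   volumes v_air, v_gwater, v_lake, v_river.
#' @export
assess_segment <- function(segment, scenario, stability, t,
                           config = assessment_config()) {
  t <- check_period(t)
  p_leak <- segment_leakage_probability(
    segment, t, scenario_type = config$scenario_type,
    rate_table = config$rate_table, leak_table = config$leak_table,
    length_mode = config$length_mode)
  v_wind <- segment$wind_speed[t + 1L]
  zones <- exposure_zones(scenario, stability, v_wind)
  Tt <- segment$population_density[t + 1L]
  if (Tt > 0) {
    c_pop <- population_consequence(zones, Tt, config$alpha,
                                    config$population_costs, t)
    p_pop <- population_ratio(zones, Tt, segment$length_km, config$d_pop)
  } else {
    c_pop <- 0
    p_pop <- 0
  }
  q_pop <- preference_parameter(p_pop)
  vols <- pollution_volumes(segment, scenario, stability, t)
  c_env <- environmental_consequence(vols, config$env_costs)
  p_env <- environment_ratio(scenario$total_amount_mg, vols,
                             scenario$env_thresholds)
  q_env <- preference_parameter(p_env)
  data.frame(
    segment_id = segment_id(segment$from, segment$to),
    period = t,
    p_leak = p_leak,
    c_pop = c_pop, c_env = c_env,
    p_pop = p_pop, q_pop = q_pop,
    p_env = p_env, q_env = q_env,
    er_pop = population_risk(p_leak, c_pop, q_pop),
    er_env = environmental_risk(p_leak, c_env, q_env),
    v_air = vols$volumes[["air"]], v_gwater = vols$volumes[["gwater"]],
    v_lake = vols$volumes[["lake"]], v_river = vols$volumes[["river"]],
    stringsAsFactors = FALSE)
}

#' Assess every segment of a network over all 24 periods
#'
#' Segments are assessed independently (an accident on one segment does not
#' affect the population or environment along another).
#'
#' @param network A [road_network()].
#' @param scenario A [release_scenario()].
#' @param stability A [stability_parameters()].
#' @param config An [assessment_config()].
#' @return data.frame of |segments| x 24 rows in [assess_segment()] layout.
#' @export
assess_network <- function(network, scenario, stability,
                           config = assessment_config()) {
  rows <- lapply(network$segments, function(seg) {
    recs <- lapply(0:23, function(t) {
      tryCatch(assess_segment(seg, scenario, stability, t, config),
               error = function(e) {
                 stop(sprintf("segment %s, period %d: %s",
                              segment_id(seg$from, seg$to), t,
                              conditionMessage(e)), call. = FALSE)
               })
    })
    do.call(rbind, recs)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank segments by their worst-period risk
#'
#' Utility for spotting segments with a high risk of catastrophic
#' consequences: per-segment maxima and means of both risk scores, the
#' period attaining the maximum, and whether any period runs beyond
#' bearing capacity (q > 1).
#'
#' @param records Output of [assess_network()].
#' @return data.frame sorted by decreasing max er_pop.
#' @export
rank_segments <- function(records) {
  ids <- unique(records$segment_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    r <- records[records$segment_id == id, ]
    data.frame(
      segment_id = id,
      max_er_pop = max(r$er_pop), mean_er_pop = mean(r$er_pop),
      max_er_env = max(r$er_env), mean_er_env = mean(r$er_env),
      argmax_period_pop = r$period[which.max(r$er_pop)],
      argmax_period_env = r$period[which.max(r$er_env)],
      over_capacity_pop = any(r$q_pop > 1),
      over_capacity_env = any(r$q_env > 1),
      stringsAsFactors = FALSE)
  }))
  out[order(-out$max_er_pop), , drop = FALSE]
}

#' Route risk at one period
#'
#' Sums both risk scores over an ordered list of segments (the traditional
#' route aggregation: risk is additive over segments, so concatenating two
#' routes adds their risks).
#'
#' @param records Output of [assess_network()].
#' @param route Character vector of segment ids (or list of `c(from, to)`
#'   pairs).
#' @param t Period 0..23.
#' @return Named numeric: `er_pop`, `er_env`.
#' @export
route_risk <- function(records, route, t) {
  t <- check_period(t)
  if (is.list(route)) {
    route <- vapply(route, function(p) segment_id(p[1], p[2]), character(1))
  }
  if (!length(route)) return(c(er_pop = 0, er_env = 0))
  miss <- setdiff(route, unique(records$segment_id))
  if (length(miss)) {
    stop(sprintf("route segments not in assessment: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  rows <- records[records$segment_id %in% route & records$period == t, ]
  # count repeated traversals of the same segment
  mult <- table(route)
  er_pop <- sum(rows$er_pop * as.numeric(mult[rows$segment_id]))
  er_env <- sum(rows$er_env * as.numeric(mult[rows$segment_id]))
  c(er_pop = er_pop, er_env = er_env)
}
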