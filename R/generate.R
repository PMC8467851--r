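# Seeded synthetic-network generator: emulates a compact urban district
# network (38 nodes / 52 arcs by default) with rush-hour traffic peaks,
# land-use-dependent population profiles, diurnal wind, and a subset of
# segments carrying groundwater / lake / river attributes.

#' Generator configuration
#'
#' Defaults emulate the study conditions of a compact, highly urbanized
#' district: 38 nodes and 52 arcs; vehicle densities peaking in the morning
#' (07-09) and afternoon (17-19) rush hours; population profiles following
#' residential / commercial / boarding-school archetypes; strictly positive
#' diurnal wind around 3 m/s; river and groundwater flows around 0.3 and
#' 0.003 m/s so the diurnal variation of the pollution volumes is ordered
#' air > river > groundwater > lake.
#'
#' @param n_nodes Number of nodes (default 38).
#' @param n_segments Number of arcs (default 52); must be >= n_nodes - 1.
#' @param seed Integer seed; the generator owns all its randomness and a
#'   fixed seed reproduces the network exactly.
#' @param land_use_mix Named proportions over residential / commercial /
#'   school / mixed.
#' @param wind_mean Mean wind speed, m/s.
#' @param wind_amplitude Fractional diurnal wind swing (0.5 = +/-50%).
#' @param river_speed,gwater_speed Mean flow speeds, m/s.
#' @param water_prob Named probabilities a segment carries each medium.
#' @param vehicle_base_range Range of per-segment base vehicle densities,
#'   veh/km.
#' @param pop_density_range Range of per-segment peak population densities,
#'   persons/km^2 (converted to persons/m^2 in the output).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_nodes = 38L, n_segments = 52L, seed = 1L,
                             land_use_mix = c(residential = 0.4,
                                              commercial = 0.3,
                                              school = 0.1, mixed = 0.2),
                             wind_mean = 3, wind_amplitude = 0.5,
                             river_speed = 0.3, gwater_speed = 0.003,
                             water_prob = c(gwater = 0.30, lake = 0.15,
                                            river = 0.20),
                             vehicle_base_range = c(20, 60),
                             pop_density_range = c(2000, 15000)) {
  if (n_segments < n_nodes - 1L) {
    stop("n_segments must be at least n_nodes - 1 for connectivity",
         call. = FALSE)
  }
  if (n_nodes < 2L) stop("need at least 2 nodes", call. = FALSE)
  structure(list(n_nodes = as.integer(n_nodes),
                 n_segments = as.integer(n_segments), seed = as.integer(seed),
                 land_use_mix = land_use_mix / sum(land_use_mix),
                 wind_mean = wind_mean, wind_amplitude = wind_amplitude,
                 river_speed = river_speed, gwater_speed = gwater_speed,
                 water_prob = water_prob,
                 vehicle_base_range = vehicle_base_range,
                 pop_density_range = pop_density_range),
            class = "generator_config")
}

# run expr with a private RNG stream, leaving global random state untouched
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# diurnal shape helpers; t = 0..23
rush_hour_shape <- function(t) {
  0.40 + 1.00 * exp(-((t - 8) / 1.5)^2) + 0.90 * exp(-((t - 18) / 1.5)^2)
}

population_shape <- function(land_use, t) {
  day <- exp(-((t - 13) / 5)^2)  # ~0 at night, ~1 mid-afternoon
  switch(land_use,
         residential = 1.0 - 0.4 * day,
         commercial  = 0.3 + 0.7 * day,
         school      = 0.85 + 0.10 * day,  # boarding school: nearly flat
         mixed       = 0.65 + 0.15 * day)
}

wind_shape <- function(t, amplitude) {
  # calmest pre-dawn (~04h), breeziest mid-afternoon (~16h)
  1 + amplitude * sin(2 * pi * (t - 10) / 24)
}

#' Generate a synthetic road network
#'
#' Topology is a jittered planar grid: nodes are laid on a near-square grid
#' with positional noise, joined into a random spanning tree plus extra
#' short chords up to the requested arc count. All attribute profiles are
#' drawn per segment; the same seed reproduces the network exactly, and the
#' result always passes [road_network()] validation.
#'
#' Both the `alongside` and `crossing` water relations are always
#' represented when any lake or river is assigned, and one segment is
#' forced to carry all three water media so every medium is exercised.
#'
#' @param config A [generator_config()].
#' @return A validated [road_network()].
#' @export
generate_network <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_local_seed(config$seed, {
    n <- config$n_nodes
    side <- ceiling(sqrt(n))
    grid <- expand.grid(gx = seq_len(side), gy = seq_len(side))
    grid <- grid[seq_len(n), ]
    nodes <- data.frame(
      id = as.character(seq_len(n)),
      x = grid$gx + stats::runif(n, -0.3, 0.3),
      y = grid$gy + stats::runif(n, -0.3, 0.3),
      stringsAsFactors = FALSE)

    # spanning tree: connect each node (in random order) to the nearest
    # already-connected node, then add shortest unused chords
    ord <- sample.int(n)
    in_tree <- ord[1]
    edges <- matrix(integer(0), ncol = 2)
    for (k in ord[-1]) {
      d <- sqrt((nodes$x[in_tree] - nodes$x[k])^2 +
                  (nodes$y[in_tree] - nodes$y[k])^2)
      edges <- rbind(edges, c(k, in_tree[which.min(d)]))
      in_tree <- c(in_tree, k)
    }
    key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    used <- key(edges)
    all_pairs <- t(utils::combn(n, 2))
    dist_all <- sqrt((nodes$x[all_pairs[, 1]] - nodes$x[all_pairs[, 2]])^2 +
                       (nodes$y[all_pairs[, 1]] - nodes$y[all_pairs[, 2]])^2)
    cand <- all_pairs[order(dist_all), , drop = FALSE]
    cand_key <- key(cand)
    extra_needed <- config$n_segments - nrow(edges)
    free <- which(!cand_key %in% used)
    if (extra_needed > length(free)) {
      stop("n_segments exceeds the number of distinct node pairs",
           call. = FALSE)
    }
    if (extra_needed > 0) {
      edges <- rbind(edges, cand[free[seq_len(extra_needed)], , drop = FALSE])
    }

    road_types <- c("two-lane", "undivided multilane", "divided multilane",
                    "cycle lane", "expressway")
    type_prob <- c(0.35, 0.2, 0.2, 0.1, 0.15)
    land_uses <- names(config$land_use_mix)
    tt <- 0:23

    segs <- lapply(seq_len(nrow(edges)), function(i) {
      a <- edges[i, 1]; b <- edges[i, 2]
      eucl <- sqrt((nodes$x[a] - nodes$x[b])^2 + (nodes$y[a] - nodes$y[b])^2)
      length_km <- max(0.3, eucl * stats::runif(1, 0.8, 1.2))  # grid unit ~1 km
      land_use <- sample(land_uses, 1, prob = config$land_use_mix)

      base_m <- stats::runif(1, config$vehicle_base_range[1],
                             config$vehicle_base_range[2])
      m_prof <- base_m * rush_hour_shape(tt) * stats::runif(24, 0.97, 1.03)

      peak_t <- stats::runif(1, config$pop_density_range[1],
                             config$pop_density_range[2])
      t_prof <- normalize_population_density(
        peak_t * vapply(tt, function(h) population_shape(land_use, h),
                        numeric(1)) * stats::runif(24, 0.97, 1.03))

      w_scale <- stats::runif(1, 0.85, 1.15)
      w_prof <- pmax(0.2, config$wind_mean * w_scale *
                       wind_shape(tt, config$wind_amplitude) *
                       stats::runif(24, 0.97, 1.03))

      water <- water_attributes()
      if (stats::runif(1) < config$water_prob[["gwater"]]) {
        g_scale <- stats::runif(1, 0.85, 1.15)
        water$groundwater <- list(
          flow = pmax(0, config$gwater_speed * g_scale *
                        wind_shape(tt, 0.5) * stats::runif(24, 0.97, 1.03)),
          depth = stats::runif(1, 2, 8),
          wet_area = stats::runif(1, 5, 30))
      }
      if (stats::runif(1) < config$water_prob[["lake"]]) {
        water$lake <- list(depth = stats::runif(1, 1.5, 5),
                           relation = sample(c("alongside", "crossing"), 1))
      }
      if (stats::runif(1) < config$water_prob[["river"]]) {
        r_scale <- stats::runif(1, 0.85, 1.15)
        water$river <- list(
          flow = pmax(0.01, config$river_speed * r_scale *
                        wind_shape(tt, 0.5) * stats::runif(24, 0.97, 1.03)),
          depth = stats::runif(1, 1.5, 5),
          width = stats::runif(1, 15, 60),
          relation = sample(c("alongside", "crossing"), 1))
      }

      road_segment(from = as.character(edges[i, 1]),
                   to = as.character(edges[i, 2]),
                   length_km = length_km,
                   road_type = sample(road_types, 1, prob = type_prob),
                   region = "city", land_use = land_use,
                   vehicle_density = m_prof,
                   population_density = t_prof,
                   wind_speed = w_prof,
                   water = water)
    })

    # guarantee: one segment with all three media; both relations present
    force_water <- function(seg, relation_lake, relation_river) {
      if (is.null(seg$water$groundwater)) {
        seg$water$groundwater <- list(
          flow = rep(config$gwater_speed, 24) * wind_shape(tt, 0.5),
          depth = 4, wet_area = 12)
      }
      if (is.null(seg$water$lake)) {
        seg$water$lake <- list(depth = 3, relation = relation_lake)
      }
      if (is.null(seg$water$river)) {
        seg$water$river <- list(
          flow = rep(config$river_speed, 24) * wind_shape(tt, 0.5),
          depth = 2.5, width = 30, relation = relation_river)
      }
      seg
    }
    segs[[1]] <- force_water(segs[[1]], "alongside", "crossing")
    if (length(segs) > 1) {
      segs[[2]] <- force_water(segs[[2]], "crossing", "alongside")
    }
    road_network(nodes, segs)
  })
}

#' Generate a release scenario from a shipment size
#'
#' Converts a load in metric tons to the released amount Q (mg) and derives
#' the source release rate from a release-duration parameter (default: the
#' full load escapes over 600 s).
#'
#' @param chemical Chemical label; `"ammonia"` picks up
#'   [ammonia_thresholds()] automatically when `thresholds` is omitted.
#' @param total_tons Load in metric tons, > 0.
#' @param release_duration_s Seconds over which the load escapes, > 0.
#' @param thresholds Optional list with `aegl` (length 3) and `env`
#'   (gwater/lake/river) limits, mg/m^3; required for chemicals without
#'   built-in defaults.
#' @param ... Passed on to [release_scenario()] (e.g. `elapsed_s`,
#'   `friction_velocity`).
#' @return A [release_scenario()].
#' @export
generate_scenario <- function(chemical = "ammonia", total_tons = 6,
                              release_duration_s = 600, thresholds = NULL,
                              ...) {
  if (total_tons <= 0) stop("total_tons must be > 0", call. = FALSE)
  if (release_duration_s <= 0) {
    stop("release_duration_s must be > 0", call. = FALSE)
  }
  if (is.null(thresholds)) {
    if (identical(tolower(chemical), "ammonia")) {
      thresholds <- ammonia_thresholds()
    } else {
      stop(sprintf("no built-in thresholds for '%s'; supply `thresholds`",
                   chemical), call. = FALSE)
    }
  }
  q_mg <- total_tons * 1e9  # t -> mg
  release_scenario(chemical_name = chemical,
                   total_amount_mg = q_mg,
                   release_rate_mg_s = q_mg / release_duration_s,
                   aegl_thresholds = thresholds$aegl,
                   env_thresholds = thresholds$env,
                   ...)
}
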