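# Road-network data model: segments with 24-period attribute profiles,
# validation, and JSON / GeoJSON / CSV-bundle readers and writers.

N_PERIODS <- 24L

#' Validate a 24-period time profile
#'
#' A time profile is a numeric vector of exactly 24 non-negative, finite
#' values indexed by the hour of day `t = 0..23`. Units are carried by
#' context (vehicles/km, persons/m^2, m/s).
#'
#' @param values Numeric vector.
#' @param what Label used in error messages (e.g. `"wind_speed"`).
#' @param positive If `TRUE`, require every value to be strictly positive
#'   (wind speed divides in the plume model and must never be zero).
#' @return The validated numeric vector, invisibly usable as-is.
#' @export
time_profile <- function(values, what = "profile", positive = FALSE) {
  values <- as.numeric(values)
  if (length(values) != N_PERIODS) {
    stop(sprintf("%s must have exactly %d entries, got %d",
                 what, N_PERIODS, length(values)), call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop(sprintf("%s contains non-finite values", what), call. = FALSE)
  }
  if (positive && any(values <= 0)) {
    stop(sprintf("%s must be strictly positive everywhere", what),
         call. = FALSE)
  }
  if (!positive && any(values < 0)) {
    stop(sprintf("%s must be non-negative", what), call. = FALSE)
  }
  values
}

#' Construct a road segment
#'
#' One undirected arc (i, j) of the network: the unit of assessment. All
#' time-varying attributes are 24-period profiles; lengths are km, wind
#' speeds m/s, population densities persons/m^2 (use
#' [normalize_population_density()] to convert persons/km^2 on input).
#'
#' @param from,to Node identifiers (coerced to character).
#' @param length_km Segment driving length in km, > 0.
#' @param road_type One of `"two-lane"`, `"undivided multilane"`,
#'   `"divided multilane"`, `"cycle lane"`, `"expressway"`.
#' @param vehicle_density 24-period profile, vehicles/km.
#' @param population_density 24-period profile, persons/m^2.
#' @param wind_speed 24-period profile, m/s, strictly positive.
#' @param region Accident-rate region label; default `"city"`.
#' @param land_use One of `"residential"`, `"commercial"`, `"school"`,
#'   `"mixed"`.
#' @param water Optional water-body attributes from [water_attributes()].
#' @return An object of class `road_segment`.
#' @export
road_segment <- function(from, to, length_km, road_type,
                         vehicle_density, population_density, wind_speed,
                         region = "city", land_use = "mixed",
                         water = water_attributes()) {
  id <- segment_id(from, to)
  if (!is.numeric(length_km) || length(length_km) != 1L || !is.finite(length_km) ||
      length_km <= 0) {
    stop(sprintf("segment %s: length_km must be a positive number", id),
         call. = FALSE)
  }
  road_types <- c("two-lane", "undivided multilane", "divided multilane",
                  "cycle lane", "expressway")
  road_type <- match.arg(road_type, road_types)
  land_use <- match.arg(land_use,
                        c("mixed", "residential", "commercial", "school"))
  seg <- structure(list(
    from = as.character(from),
    to = as.character(to),
    length_km = as.numeric(length_km),
    road_type = road_type,
    region = as.character(region),
    land_use = land_use,
    vehicle_density = time_profile(vehicle_density,
                                   sprintf("segment %s: vehicle_density", id)),
    population_density = time_profile(population_density,
                                      sprintf("segment %s: population_density", id)),
    wind_speed = time_profile(wind_speed,
                              sprintf("segment %s: wind_speed", id),
                              positive = TRUE),
    water = validate_water(water, id)
  ), class = "road_segment")
  seg
}

#' Canonical undirected segment id
#'
#' Segments are undirected for risk purposes: `(i, j)` and `(j, i)` name the
#' same record, so the id orders the endpoints.
#'
#' @param from,to Node identifiers.
#' @return Character id `"i-j"` with `i <= j` in string order.
#' @export
segment_id <- function(from, to) {
  a <- as.character(from); b <- as.character(to)
  paste(pmin(a, b), pmax(a, b), sep = "-")
}

#' Water-body attributes for a segment
#'
#' Any medium may be absent (`NULL`). Present media must satisfy the
#' positivity constraints; `relation` selects the pollution-volume geometry:
#' `"alongside"` (quarter sphere, coefficient 1/3) vs `"crossing"`
#' (hemisphere, 2/3).
#'
#' @param groundwater `NULL` or `list(flow = <24-profile m/s>, depth = m,
#'   wet_area = m^2)`.
#' @param lake `NULL` or `list(depth = m, relation = "alongside"|"crossing")`.
#' @param river `NULL` or `list(flow = <24-profile m/s>, depth = m,
#'   width = m, relation = "alongside"|"crossing")`.
#' @return A `water_attributes` list.
#' @export
water_attributes <- function(groundwater = NULL, lake = NULL, river = NULL) {
  structure(list(groundwater = groundwater, lake = lake, river = river),
            class = "water_attributes")
}

validate_water <- function(water, id) {
  if (is.null(water)) water <- water_attributes()
  if (!inherits(water, "water_attributes")) {
    water <- do.call(water_attributes,
                     water[intersect(names(water),
                                     c("groundwater", "lake", "river"))])
  }
  pos <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop(sprintf("segment %s: water field %s must be > 0", id, field),
           call. = FALSE)
    as.numeric(x)
  }
  rel <- function(x, medium) {
    if (!is.character(x) || !x %in% c("alongside", "crossing"))
      stop(sprintf("segment %s: %s relation must be 'alongside' or 'crossing'",
                   id, medium), call. = FALSE)
    x
  }
  if (!is.null(water$groundwater)) {
    g <- water$groundwater
    water$groundwater <- list(
      flow = time_profile(g$flow, sprintf("segment %s: groundwater flow", id)),
      depth = pos(g$depth, "groundwater depth"),
      wet_area = pos(g$wet_area, "groundwater wet_area"))
  }
  if (!is.null(water$lake)) {
    l <- water$lake
    water$lake <- list(depth = pos(l$depth, "lake depth"),
                       relation = rel(l$relation, "lake"))
  }
  if (!is.null(water$river)) {
    r <- water$river
    water$river <- list(
      flow = time_profile(r$flow, sprintf("segment %s: river flow", id)),
      depth = pos(r$depth, "river depth"),
      width = pos(r$width, "river width"),
      relation = rel(r$relation, "river"))
  }
  water
}

#' Construct a road network
#'
#' @param nodes Character vector of node ids, or a data.frame with columns
#'   `id`, and optionally `x`, `y` (synthetic planar coordinates used only
#'   for GeoJSON decoration, never numerically).
#' @param segments List of [road_segment()] objects.
#' @return An object of class `road_network`.
#' @export
road_network <- function(nodes, segments) {
  if (!is.data.frame(nodes)) {
    nodes <- data.frame(id = as.character(nodes), x = NA_real_, y = NA_real_,
                        stringsAsFactors = FALSE)
  } else {
    nodes$id <- as.character(nodes$id)
    if (is.null(nodes$x)) nodes$x <- NA_real_
    if (is.null(nodes$y)) nodes$y <- NA_real_
  }
  if (anyDuplicated(nodes$id)) stop("duplicate node ids", call. = FALSE)
  if (!all(vapply(segments, inherits, logical(1), "road_segment"))) {
    stop("segments must be a list of road_segment objects", call. = FALSE)
  }
  ids <- vapply(segments, function(s) segment_id(s$from, s$to), character(1))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate segment ids: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  ends <- unique(unlist(lapply(segments, function(s) c(s$from, s$to))))
  missing <- setdiff(ends, nodes$id)
  if (length(missing)) {
    stop(sprintf("segment endpoints not in node set: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  names(segments) <- ids
  structure(list(nodes = nodes, segments = segments), class = "road_network")
}

#' @export
print.road_network <- function(x, ...) {
  n_water <- sum(vapply(x$segments, function(s) {
    !is.null(s$water$groundwater) || !is.null(s$water$lake) ||
      !is.null(s$water$river)
  }, logical(1)))
  cat(sprintf("road_network: %d nodes, %d segments (%d with water bodies)\n",
              nrow(x$nodes), length(x$segments), n_water))
  invisible(x)
}

#' @export
print.road_segment <- function(x, ...) {
  cat(sprintf("road_segment %s: %.3g km %s (%s, %s)\n",
              segment_id(x$from, x$to), x$length_km, x$road_type,
              x$region, x$land_use))
  invisible(x)
}

#' Convert persons per km^2 to persons per m^2
#'
#' The bearing-capacity ratio and the exposure consequence are dimensionally
#' consistent only with population density in persons/m^2; census-style
#' inputs in persons/km^2 are bridged here (factor 1e-6).
#'
#' @param value Density in persons/km^2, >= 0 (vectorized).
#' @return Density in persons/m^2.
#' @examples
#' normalize_population_density(1e6)  # 1 person per m^2
#' @export
normalize_population_density <- function(value) {
  if (any(value < 0, na.rm = TRUE)) {
    stop("population density must be non-negative", call. = FALSE)
  }
  value * 1e-6
}

# ---- serialization ---------------------------------------------------------

segment_to_list <- function(s) {
  w <- s$water
  list(
    from = s$from, to = s$to, length_km = s$length_km,
    road_type = s$road_type, region = s$region, land_use = s$land_use,
    vehicle_density = s$vehicle_density,
    population_density = s$population_density,
    wind_speed = s$wind_speed,
    water = list(groundwater = w$groundwater, lake = w$lake, river = w$river)
  )
}

segment_from_list <- function(x) {
  w <- x$water
  if (is.null(w)) w <- list()
  road_segment(
    from = x$from, to = x$to, length_km = x$length_km,
    road_type = x$road_type,
    region = if (is.null(x$region)) "city" else x$region,
    land_use = if (is.null(x$land_use)) "mixed" else x$land_use,
    vehicle_density = unlist(x$vehicle_density),
    population_density = unlist(x$population_density),
    wind_speed = unlist(x$wind_speed),
    water = water_attributes(
      groundwater = if (!is.null(w$groundwater))
        list(flow = unlist(w$groundwater$flow),
             depth = w$groundwater$depth,
             wet_area = w$groundwater$wet_area),
      lake = if (!is.null(w$lake))
        list(depth = w$lake$depth, relation = w$lake$relation),
      river = if (!is.null(w$river))
        list(flow = unlist(w$river$flow), depth = w$river$depth,
             width = w$river$width, relation = w$river$relation))
  )
}

#' Save a road network
#'
#' Writers for the three interchange formats. `"json"` mirrors the object
#' structure in one document; `"geojson"` emits a FeatureCollection with one
#' LineString Feature per segment and all attributes as properties (geometry
#' is decorative); `"csv"` writes a bundle `segments.csv`, `profiles.csv`
#' (long format: segment_id, quantity, period, value) and `water.csv` into
#' the directory `path`.
#'
#' @param network A `road_network`.
#' @param path File path (json/geojson) or directory (csv bundle).
#' @param format One of `"json"`, `"geojson"`, `"csv"`.
#' @return `path`, invisibly.
#' @export
save_network <- function(network, path, format = c("json", "geojson", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "road_network"))
  switch(format,
    json = {
      doc <- list(nodes = network$nodes,
                  segments = lapply(unname(network$segments), segment_to_list))
      jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                           null = "null", na = "null")
    },
    geojson = {
      feats <- lapply(unname(network$segments), function(s) {
        nd <- network$nodes
        xy <- function(id) {
          r <- nd[nd$id == id, , drop = FALSE]
          c(if (is.na(r$x)) 0 else r$x, if (is.na(r$y)) 0 else r$y)
        }
        list(type = "Feature",
             geometry = list(type = "LineString",
                             coordinates = list(xy(s$from), xy(s$to))),
             properties = segment_to_list(s))
      })
      doc <- list(type = "FeatureCollection",
                  properties = list(nodes = network$nodes),
                  features = feats)
      jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                           null = "null", na = "null")
    },
    csv = {
      if (!dir.exists(path)) dir.create(path, recursive = TRUE)
      segs <- network$segments
      seg_df <- data.frame(
        segment_id = names(segs),
        from = vapply(segs, `[[`, character(1), "from"),
        to = vapply(segs, `[[`, character(1), "to"),
        length_km = fmt_num(vapply(segs, `[[`, numeric(1), "length_km")),
        road_type = vapply(segs, `[[`, character(1), "road_type"),
        region = vapply(segs, `[[`, character(1), "region"),
        land_use = vapply(segs, `[[`, character(1), "land_use"),
        row.names = NULL, stringsAsFactors = FALSE)
      utils::write.csv(seg_df, file.path(path, "segments.csv"),
                       row.names = FALSE, quote = TRUE)
      prof <- do.call(rbind, lapply(names(segs), function(id) {
        s <- segs[[id]]
        qs <- list(vehicle_density = s$vehicle_density,
                   population_density = s$population_density,
                   wind_speed = s$wind_speed)
        if (!is.null(s$water$groundwater))
          qs$groundwater_flow <- s$water$groundwater$flow
        if (!is.null(s$water$river))
          qs$river_flow <- s$water$river$flow
        do.call(rbind, lapply(names(qs), function(q) {
          data.frame(segment_id = id, quantity = q, period = 0:23,
                     value = fmt_num(qs[[q]]), stringsAsFactors = FALSE)
        }))
      }))
      utils::write.csv(prof, file.path(path, "profiles.csv"),
                       row.names = FALSE, quote = TRUE)
      wat <- do.call(rbind, lapply(names(segs), function(id) {
        w <- segs[[id]]$water
        rows <- list()
        if (!is.null(w$groundwater))
          rows[[length(rows) + 1L]] <- data.frame(
            segment_id = id, medium = "groundwater",
            depth = fmt_num(w$groundwater$depth),
            wet_area = fmt_num(w$groundwater$wet_area),
            width = "", relation = "", stringsAsFactors = FALSE)
        if (!is.null(w$lake))
          rows[[length(rows) + 1L]] <- data.frame(
            segment_id = id, medium = "lake",
            depth = fmt_num(w$lake$depth), wet_area = "", width = "",
            relation = w$lake$relation, stringsAsFactors = FALSE)
        if (!is.null(w$river))
          rows[[length(rows) + 1L]] <- data.frame(
            segment_id = id, medium = "river",
            depth = fmt_num(w$river$depth), wet_area = "",
            width = fmt_num(w$river$width),
            relation = w$river$relation, stringsAsFactors = FALSE)
        if (length(rows)) do.call(rbind, rows) else NULL
      }))
      if (is.null(wat)) {
        wat <- data.frame(segment_id = character(), medium = character(),
                          depth = character(), wet_area = character(),
                          width = character(), relation = character())
      }
      utils::write.csv(wat, file.path(path, "water.csv"),
                       row.names = FALSE, quote = TRUE)
      nodes <- network$nodes
      nodes$x <- fmt_num(nodes$x); nodes$y <- fmt_num(nodes$y)
      utils::write.csv(nodes, file.path(path, "nodes.csv"),
                       row.names = FALSE, quote = TRUE)
    })
  invisible(path)
}

# full-precision decimal text so CSV round-trips are exact
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else format(v, digits = 17, scientific = TRUE, trim = TRUE)
  }, character(1))
  out
}

#' Load a road network
#'
#' Inverse of [save_network()] for each format. Every invariant is enforced
#' on load; violations raise an error naming the segment and field.
#'
#' @param path File path (json/geojson) or directory (csv bundle).
#' @param format One of `"json"`, `"geojson"`, `"csv"`. Guessed from the
#'   file extension / path type when omitted.
#' @return A validated `road_network`.
#' @export
load_network <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (dir.exists(path)) "csv"
      else if (grepl("\\.geojson$", path, ignore.case = TRUE)) "geojson"
      else "json"
  }
  format <- match.arg(format, c("json", "geojson", "csv"))
  if (format != "csv" && !file.exists(path)) {
    stop(sprintf("network file not found: %s", path), call. = FALSE)
  }
  switch(format,
    json = {
      doc <- jsonlite::read_json(path)
      nodes <- do.call(rbind, lapply(doc$nodes, function(n) {
        data.frame(id = as.character(n$id),
                   x = if (is.null(n$x)) NA_real_ else as.numeric(n$x),
                   y = if (is.null(n$y)) NA_real_ else as.numeric(n$y),
                   stringsAsFactors = FALSE)
      }))
      segs <- lapply(doc$segments, segment_from_list)
      road_network(nodes, segs)
    },
    geojson = {
      doc <- jsonlite::read_json(path)
      nodes <- do.call(rbind, lapply(doc$properties$nodes, function(n) {
        data.frame(id = as.character(n$id),
                   x = if (is.null(n$x)) NA_real_ else as.numeric(n$x),
                   y = if (is.null(n$y)) NA_real_ else as.numeric(n$y),
                   stringsAsFactors = FALSE)
      }))
      segs <- lapply(doc$features, function(f) segment_from_list(f$properties))
      road_network(nodes, segs)
    },
    csv = {
      need <- file.path(path, c("segments.csv", "profiles.csv"))
      miss <- need[!file.exists(need)]
      if (length(miss)) {
        stop(sprintf("csv bundle incomplete, missing: %s",
                     paste(basename(miss), collapse = ", ")), call. = FALSE)
      }
      seg_df <- utils::read.csv(file.path(path, "segments.csv"),
                                stringsAsFactors = FALSE,
                                colClasses = c(segment_id = "character",
                                               from = "character",
                                               to = "character"))
      prof <- utils::read.csv(file.path(path, "profiles.csv"),
                              stringsAsFactors = FALSE,
                              colClasses = c(segment_id = "character"))
      wat_path <- file.path(path, "water.csv")
      wat <- if (file.exists(wat_path))
        utils::read.csv(wat_path, stringsAsFactors = FALSE,
                        colClasses = c(segment_id = "character"))
        else NULL
      nodes_path <- file.path(path, "nodes.csv")
      nodes <- if (file.exists(nodes_path))
        utils::read.csv(nodes_path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character"))
        else data.frame(id = unique(c(seg_df$from, seg_df$to)),
                        stringsAsFactors = FALSE)
      get_prof <- function(id, q, required = TRUE) {
        rows <- prof[prof$segment_id == id & prof$quantity == q, ]
        if (!nrow(rows)) {
          if (required)
            stop(sprintf("segment %s: missing %s profile", id, q),
                 call. = FALSE)
          return(NULL)
        }
        rows$value[order(rows$period)]
      }
      segs <- lapply(seq_len(nrow(seg_df)), function(i) {
        r <- seg_df[i, ]
        id <- r$segment_id
        water <- water_attributes()
        if (!is.null(wat) && nrow(wat)) {
          wrows <- wat[wat$segment_id == id, ]
          for (k in seq_len(nrow(wrows))) {
            wr <- wrows[k, ]
            if (wr$medium == "groundwater") {
              water$groundwater <- list(flow = get_prof(id, "groundwater_flow"),
                                        depth = as.numeric(wr$depth),
                                        wet_area = as.numeric(wr$wet_area))
            } else if (wr$medium == "lake") {
              water$lake <- list(depth = as.numeric(wr$depth),
                                 relation = wr$relation)
            } else if (wr$medium == "river") {
              water$river <- list(flow = get_prof(id, "river_flow"),
                                  depth = as.numeric(wr$depth),
                                  width = as.numeric(wr$width),
                                  relation = wr$relation)
            }
          }
        }
        road_segment(from = r$from, to = r$to, length_km = r$length_km,
                     road_type = r$road_type, region = r$region,
                     land_use = r$land_use,
                     vehicle_density = get_prof(id, "vehicle_density"),
                     population_density = get_prof(id, "population_density"),
                     wind_speed = get_prof(id, "wind_speed"),
                     water = water)
      })
      road_network(nodes, segs)
    })
}
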