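# Water-medium pollution: advection-dispersion influence radii for
# groundwater, lakes and rivers, and the sphere-sector volumes.

#' Groundwater pollution influence radius
#'
#' Advection plus turbulent-dispersion spread of the spill through the
#' aquifer over the assessment horizon:
#' \deqn{r = v^{Gw} t^{Gw} + \sqrt{H u^* t^{Gw}}\,
#'   \ln\!\frac{Q}{C^{Env}_{gw}\, S \sqrt{\pi H u^* t^{Gw}}}}
#' clamped below at 0 (a negative value means the limit concentration is
#' never exceeded beyond the source; the model is outside its validity
#' regime there).
#'
#' @param scenario A [release_scenario()] (total amount, groundwater limit,
#'   horizon, friction velocity).
#' @param groundwater Segment groundwater attributes: `flow` (24-profile,
#'   m/s), `depth` (m), `wet_area` (m^2).
#' @param t Period 0..23 (selects the flow profile value only).
#' @return Radius in m, >= 0.
#' @export
groundwater_radius <- function(scenario, groundwater, t) {
  if (is.null(groundwater)) stop("groundwater attributes absent", call. = FALSE)
  t <- check_period(t)
  H <- groundwater$depth; S <- groundwater$wet_area
  if (H <= 0 || S <= 0) stop("groundwater depth and wet_area must be > 0",
                             call. = FALSE)
  tg <- scenario$elapsed_s[["gwater"]]
  if (tg <= 0) stop("groundwater elapsed time must be > 0", call. = FALSE)
  u <- scenario$friction_velocity
  v <- groundwater$flow[t + 1L]
  disp <- sqrt(H * u * tg)
  lnarg <- scenario$total_amount_mg /
    (scenario$env_thresholds[["gwater"]] * S * sqrt(pi * H * u * tg))
  max(0, v * tg + disp * log(lnarg))
}

#' Groundwater pollution hemisphere volume
#'
#' @param r Influence radius, m, >= 0.
#' @return \eqn{(2/3)\pi r^3} in m^3.
#' @export
groundwater_volume <- function(r) {
  if (any(r < 0)) stop("radius must be >= 0", call. = FALSE)
  2 / 3 * pi * r^3
}

#' Lake pollution influence radius
#'
#' Still-water dispersion only (no advection), so the radius is the same at
#' every time of day:
#' \deqn{r = \sqrt{0.58 H u^* t^{Lake}}\,
#'   \ln\!\frac{Q}{0.58 \pi H^2 u^* t^{Lake} C^{Env}_{lake}}}
#' clamped below at 0.
#'
#' @param scenario A [release_scenario()].
#' @param lake Segment lake attributes: `depth` (m), `relation`.
#' @return Radius in m, >= 0.
#' @export
lake_radius <- function(scenario, lake) {
  if (is.null(lake)) stop("lake attributes absent", call. = FALSE)
  H <- lake$depth
  if (H <= 0) stop("lake depth must be > 0", call. = FALSE)
  tl <- scenario$elapsed_s[["lake"]]
  if (tl <= 0) stop("lake elapsed time must be > 0", call. = FALSE)
  u <- scenario$friction_velocity
  disp <- sqrt(0.58 * H * u * tl)
  lnarg <- scenario$total_amount_mg /
    (0.58 * pi * H^2 * u * tl * scenario$env_thresholds[["lake"]])
  max(0, disp * log(lnarg))
}

#' River pollution influence radius
#'
#' Longitudinal advection plus dispersion, with a bank-reflection factor
#' that interpolates between 3 (narrow river, full reflection) and 2 (wide
#' river):
#' \deqn{r = v^{Riv} t^{Riv} + \sqrt{0.58 H u^* t^{Riv}}\,
#'   \ln\!\frac{Q\left(2 + e^{-W^2/(0.145 H u^* t^{Riv})}\right)}
#'             {0.58 \pi H^2 u^* t^{Riv} C^{Env}_{river}}}
#' clamped below at 0.
#'
#' @param scenario A [release_scenario()].
#' @param river Segment river attributes: `flow` (24-profile m/s), `depth`
#'   (m), `width` (m), `relation`.
#' @param t Period 0..23 (selects the flow profile value only).
#' @return Radius in m, >= 0.
#' @export
river_radius <- function(scenario, river, t) {
  if (is.null(river)) stop("river attributes absent", call. = FALSE)
  t <- check_period(t)
  H <- river$depth; W <- river$width
  if (H <= 0 || W <= 0) stop("river depth and width must be > 0", call. = FALSE)
  tr <- scenario$elapsed_s[["river"]]
  if (tr <= 0) stop("river elapsed time must be > 0", call. = FALSE)
  u <- scenario$friction_velocity
  v <- river$flow[t + 1L]
  disp <- sqrt(0.58 * H * u * tr)
  bank <- 2 + exp(-W^2 / (0.145 * H * u * tr))
  lnarg <- scenario$total_amount_mg * bank /
    (0.58 * pi * H^2 * u * tr * scenario$env_thresholds[["river"]])
  max(0, v * tr + disp * log(lnarg))
}

#' Surface-water pollution volume
#'
#' A road alongside the water body pollutes a quarter sphere
#' (\eqn{(1/3)\pi r^3}); a road crossing it pollutes a hemisphere
#' (\eqn{(2/3)\pi r^3}).
#'
#' @param r Influence radius, m, >= 0.
#' @param relation `"alongside"` or `"crossing"`.
#' @return Volume in m^3.
#' @export
surface_water_volume <- function(r, relation) {
  if (any(r < 0)) stop("radius must be >= 0", call. = FALSE)
  coef <- switch(relation,
                 alongside = 1 / 3,
                 crossing = 2 / 3,
                 stop(sprintf("unknown relation '%s' (alongside or crossing)",
                              relation), call. = FALSE))
  coef * pi * r^3
}

#' Pollution influence radii and volumes for all four media
#'
#' Air is always assessed (the wind profile is mandatory); each water medium
#' contributes only when the segment carries it, otherwise its radius and
#' volume are 0.
#'
#' @param segment A [road_segment()].
#' @param scenario A [release_scenario()].
#' @param stability A [stability_parameters()].
#' @param t Period 0..23.
#' @return A `pollution_volumes` list with numeric vectors `radii` and
#'   `volumes` named `air`, `gwater`, `lake`, `river`, and a logical
#'   `present` vector.
#' @export
pollution_volumes <- function(segment, scenario, stability, t) {
  t <- check_period(t)
  air <- air_pollution_volume(scenario, stability,
                              segment$wind_speed[t + 1L])
  w <- segment$water
  r <- c(air = air$radius, gwater = 0, lake = 0, river = 0)
  v <- c(air = air$volume, gwater = 0, lake = 0, river = 0)
  present <- c(air = TRUE, gwater = !is.null(w$groundwater),
               lake = !is.null(w$lake), river = !is.null(w$river))
  if (present[["gwater"]]) {
    r[["gwater"]] <- groundwater_radius(scenario, w$groundwater, t)
    v[["gwater"]] <- groundwater_volume(r[["gwater"]])
  }
  if (present[["lake"]]) {
    r[["lake"]] <- lake_radius(scenario, w$lake)
    v[["lake"]] <- surface_water_volume(r[["lake"]], w$lake$relation)
  }
  if (present[["river"]]) {
    r[["river"]] <- river_radius(scenario, w$river, t)
    v[["river"]] <- surface_water_volume(r[["river"]], w$river$relation)
  }
  structure(list(radii = r, volumes = v, present = present),
            class = "pollution_volumes")
}

#' @export
print.pollution_volumes <- function(x, ...) {
  cat("pollution_volumes\n")
  for (m in names(x$radii)) {
    cat(sprintf("  %-7s r = %10.4g m  V = %10.4g m^3%s\n", m,
                x$radii[[m]], x$volumes[[m]],
                if (x$present[[m]]) "" else "  (absent)"))
  }
  invisible(x)
}
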