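# Gaussian plume dispersion: concentration fields, AEGL exposure rings,
# and the air-pollution hemisphere volume.

#' Gaussian plume concentration at a downwind point
#'
#' Full three-dimensional steady-state plume with ground reflection:
#' \deqn{C(x,y,z) = \frac{Q^{Hazard}}{\pi v \sigma_y \sigma_z}
#'   \exp\!\left(-\frac{y^2}{2\sigma_y^2}\right)
#'   \left[\exp\!\left(-\frac{(z-H)^2}{2\sigma_z^2}\right) +
#'         \exp\!\left(-\frac{(z+H)^2}{2\sigma_z^2}\right)\right]}
#' with \eqn{\sigma_y = a x^c}, \eqn{\sigma_z = b x^d}. Provided for
#' completeness; the risk chain uses the simplified centerline form.
#'
#' @param x Downwind distance, m, > 0 (sigmas are undefined at the source).
#' @param y Crosswind offset, m.
#' @param z Height of the receptor, m.
#' @param scenario A [release_scenario()] (source rate and height).
#' @param stability A [stability_parameters()].
#' @param v_wind Wind speed, m/s, > 0.
#' @return Concentration in mg/m^3.
#' @export
plume_concentration <- function(x, y, z, scenario, stability, v_wind) {
  if (any(x <= 0)) stop("downwind distance x must be > 0", call. = FALSE)
  if (any(v_wind <= 0)) stop("wind speed must be > 0", call. = FALSE)
  s <- stability
  sy <- s$a * x^s$c
  sz <- s$b * x^s$d
  H <- scenario$source_height_m
  scenario$release_rate_mg_s / (pi * v_wind * sy * sz) *
    exp(-y^2 / (2 * sy^2)) *
    (exp(-(z - H)^2 / (2 * sz^2)) + exp(-(z + H)^2 / (2 * sz^2)))
}

#' Simplified centerline concentration
#'
#' Ground-level point-source form with crosswind offset, receptor height and
#' source height dropped:
#' \deqn{C(x) = \frac{Q^{Hazard}}{\pi a b \, v \, x^{c+d}}}
#' Strictly decreasing in both x and wind speed.
#'
#' @inheritParams plume_concentration
#' @return Concentration in mg/m^3.
#' @export
centerline_concentration <- function(x, scenario, stability, v_wind) {
  if (any(x <= 0)) stop("downwind distance x must be > 0", call. = FALSE)
  if (any(v_wind <= 0)) stop("wind speed must be > 0", call. = FALSE)
  s <- stability
  scenario$release_rate_mg_s / (pi * s$a * s$b * v_wind * x^(s$c + s$d))
}

#' Distance at which the plume decays to a threshold concentration
#'
#' Closed-form inverse of [centerline_concentration()]:
#' \deqn{r = \left(\frac{Q^{Hazard}}{\pi a b \, v \, C}\right)^{1/(c+d)}}
#' Monotone decreasing in both the threshold and the wind speed.
#'
#' @param c_threshold Threshold concentration, mg/m^3, > 0.
#' @inheritParams plume_concentration
#' @return Radius in m.
#' @export
exposure_radius <- function(c_threshold, scenario, stability, v_wind) {
  if (any(c_threshold <= 0)) {
    stop("threshold concentration must be > 0", call. = FALSE)
  }
  if (any(v_wind <= 0)) stop("wind speed must be > 0", call. = FALSE)
  s <- stability
  (scenario$release_rate_mg_s /
     (pi * s$a * s$b * v_wind * c_threshold))^(1 / (s$c + s$d))
}

#' AEGL exposure zones around the release point
#'
#' The three AEGL thresholds carve the plume footprint into concentric
#' rings: ring u lies between the radius where concentration falls to the
#' AEGL-u threshold and the next (higher-threshold, smaller) radius, with
#' the innermost ring a full disc (r_4 = 0). Because AEGL-1 is the lowest
#' concentration it is exceeded farthest out, so r_1 >= r_2 >= r_3.
#'
#' @inheritParams plume_concentration
#' @return An `exposure_zones` list with `radii` (m, zones 1..3 outer to
#'   inner threshold) and `areas` (m^2 ring areas summing to pi * r_1^2).
#' @export
exposure_zones <- function(scenario, stability, v_wind) {
  r <- vapply(scenario$aegl_thresholds, exposure_radius, numeric(1),
              scenario = scenario, stability = stability, v_wind = v_wind)
  r_next <- c(r[2:3], 0)
  areas <- pi * (r^2 - r_next^2)
  structure(list(radii = r, areas = areas), class = "exposure_zones")
}

#' @export
print.exposure_zones <- function(x, ...) {
  cat("exposure_zones (AEGL rings)\n")
  cat(sprintf("  radii (m): %s\n", paste(signif(x$radii, 5), collapse = ", ")))
  cat(sprintf("  areas (m^2): %s\n", paste(signif(x$areas, 5), collapse = ", ")))
  invisible(x)
}

#' Air-pollution influence radius and hemisphere volume
#'
#' The air environmental limit (the AEGL-2 value) fixes the pollution
#' radius via [exposure_radius()]; the influence volume is the hemisphere
#' \eqn{V = (2/3)\pi r^3} over the ground.
#'
#' @inheritParams plume_concentration
#' @return list with `radius` (m) and `volume` (m^3).
#' @export
air_pollution_volume <- function(scenario, stability, v_wind) {
  r <- exposure_radius(scenario$env_thresholds[["air"]], scenario, stability,
                       v_wind)
  list(radius = r, volume = 2 / 3 * pi * r^3)
}
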