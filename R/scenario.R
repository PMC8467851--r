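# Release scenario and atmospheric stability configuration.

#' Construct a release scenario
#'
#' Describes one hazmat release: the total amount spilled (used by every
#' water medium and by the environmental bearing-capacity ratio), the source
#' release rate feeding the plume, AEGL concentration thresholds for the
#' three population exposure rings, per-medium environmental limits, and the
#' water-dispersion constants.
#'
#' The air environmental limit is always the AEGL-2 value, so it is derived
#' from `aegl_thresholds[2]` rather than supplied.
#'
#' @param chemical_name Label, e.g. `"ammonia"`.
#' @param total_amount_mg Total amount released Q, mg, > 0.
#' @param release_rate_mg_s Source release rate, mg/s, > 0.
#' @param aegl_thresholds Numeric length 3, mg/m^3, strictly increasing
#'   (AEGL-1 < AEGL-2 < AEGL-3): lower thresholds are exceeded farther out.
#' @param env_thresholds Numeric length 3 named or ordered
#'   (groundwater, lake, river), mg/m^3, all > 0.
#' @param source_height_m Source height H, m, >= 0 (full-plume model only).
#' @param elapsed_s Named numeric: assessment horizons `gwater`, `lake`,
#'   `river` in seconds, all > 0. These are scenario-level constants, not
#'   the time-of-day index.
#' @param friction_velocity Water-flow friction velocity u*, m/s, within
#'   \[0.02, 0.553\].
#' @return An object of class `release_scenario`.
#' @export
release_scenario <- function(chemical_name, total_amount_mg, release_rate_mg_s,
                             aegl_thresholds, env_thresholds,
                             source_height_m = 0,
                             elapsed_s = c(gwater = 1800, lake = 1800,
                                           river = 1800),
                             friction_velocity = 0.1) {
  stopifnot(is.numeric(total_amount_mg), length(total_amount_mg) == 1L)
  if (total_amount_mg <= 0) stop("total_amount_mg must be > 0", call. = FALSE)
  if (release_rate_mg_s <= 0) stop("release_rate_mg_s must be > 0", call. = FALSE)
  aegl <- as.numeric(aegl_thresholds)
  if (length(aegl) != 3L || any(aegl <= 0) || any(diff(aegl) <= 0)) {
    stop("aegl_thresholds must be 3 positive values with AEGL-1 < AEGL-2 < AEGL-3",
         call. = FALSE)
  }
  envt <- env_thresholds
  if (!is.null(names(envt)) && all(c("gwater", "lake", "river") %in% names(envt))) {
    envt <- as.numeric(envt[c("gwater", "lake", "river")])
  } else {
    envt <- as.numeric(envt)
  }
  if (length(envt) != 3L || any(envt <= 0)) {
    stop("env_thresholds must give positive limits for groundwater, lake, river",
         call. = FALSE)
  }
  if (source_height_m < 0) stop("source_height_m must be >= 0", call. = FALSE)
  el <- elapsed_s
  if (!all(c("gwater", "lake", "river") %in% names(el)) ||
      any(as.numeric(el[c("gwater", "lake", "river")]) <= 0)) {
    stop("elapsed_s must name positive gwater, lake, river horizons",
         call. = FALSE)
  }
  if (friction_velocity < 0.02 || friction_velocity > 0.553) {
    stop("friction_velocity must lie in [0.02, 0.553]", call. = FALSE)
  }
  structure(list(
    chemical_name = as.character(chemical_name),
    total_amount_mg = as.numeric(total_amount_mg),
    release_rate_mg_s = as.numeric(release_rate_mg_s),
    source_height_m = as.numeric(source_height_m),
    aegl_thresholds = aegl,
    # per-medium limits: air == AEGL-2 by construction
    env_thresholds = c(air = aegl[2], gwater = envt[1], lake = envt[2],
                       river = envt[3]),
    elapsed_s = c(gwater = as.numeric(el[["gwater"]]),
                  lake = as.numeric(el[["lake"]]),
                  river = as.numeric(el[["river"]])),
    friction_velocity = as.numeric(friction_velocity)
  ), class = "release_scenario")
}

#' @export
print.release_scenario <- function(x, ...) {
  cat(sprintf("release_scenario: %s, Q = %.3g mg, rate = %.3g mg/s\n",
              x$chemical_name, x$total_amount_mg, x$release_rate_mg_s))
  cat(sprintf("  AEGL thresholds (mg/m^3): %s\n",
              paste(signif(x$aegl_thresholds, 4), collapse = ", ")))
  invisible(x)
}

#' Atmospheric stability (dispersion-coefficient) parameters
#'
#' The plume's lateral and vertical spreads are power laws of downwind
#' distance: `sigma_y = a * x^c`, `sigma_z = b * x^d` (x and sigmas in m).
#'
#' @param a,b Positive coefficients (m^(1-c), m^(1-d)).
#' @param c,d Positive exponents; `c + d` controls how fast the centerline
#'   concentration decays.
#' @return An object of class `stability_parameters`.
#' @export
stability_parameters <- function(a, b, c, d) {
  v <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("stability parameters a, b, c, d must all be positive", call. = FALSE)
  }
  structure(as.list(v), class = "stability_parameters")
}

#' Pasquill-Gifford stability classes as power-law coefficients
#'
#' Near-field power-law approximations to the Briggs open-country dispersion
#' curves (linear growth, valid to roughly 1 km downwind), one row per
#' stability class A (very unstable) through F (very stable). These are a
#' documented convenience; any explicit `(a, b, c, d)` can be passed
#' instead.
#'
#' @param class Optional single class letter; if given, returns the
#'   corresponding [stability_parameters()].
#' @return A data.frame of coefficients, or a `stability_parameters` object.
#' @export
pasquill_gifford <- function(class = NULL) {
  tbl <- data.frame(
    class = c("A", "B", "C", "D", "E", "F"),
    a = c(0.22, 0.16, 0.11, 0.08, 0.06, 0.04),
    c = 1,
    b = c(0.20, 0.12, 0.08, 0.06, 0.03, 0.016),
    d = 1,
    stringsAsFactors = FALSE)
  if (is.null(class)) return(tbl)
  row <- tbl[tbl$class == toupper(class), ]
  if (!nrow(row)) {
    stop(sprintf("unknown stability class '%s' (valid: %s)", class,
                 paste(tbl$class, collapse = ", ")), call. = FALSE)
  }
  stability_parameters(a = row$a, b = row$b, c = row$c, d = row$d)
}

#' Load a stability-class table from CSV
#'
#' Expected columns: `class, a, c, b, d` (any order).
#'
#' @param path CSV file path.
#' @return A data.frame usable like [pasquill_gifford()]'s table.
#' @export
load_stability_table <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("class", "a", "b", "c", "d")
  if (!all(need %in% names(tbl))) {
    stop(sprintf("stability table must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  if (any(tbl$a <= 0 | tbl$b <= 0 | tbl$c <= 0 | tbl$d <= 0)) {
    stop("stability coefficients must be positive", call. = FALSE)
  }
  tbl
}

#' Illustrative ammonia concentration thresholds
#'
#' Published 60-minute AEGL values for ammonia (30 / 160 / 1100 ppm)
#' converted to mg/m^3 at 25 degrees C, plus order-of-magnitude water
#' quality limits typical of ammonia-nitrogen surface/groundwater standards.
#' These are configuration defaults for convenience, not calibrated values;
#' real assessments should supply jurisdiction-specific limits.
#'
#' @return A list with elements `aegl` (length 3, mg/m^3) and `env`
#'   (named gwater/lake/river, mg/m^3).
#' @export
ammonia_thresholds <- function() {
  ppm_to_mg_m3 <- 17.03 / 24.45  # molar mass over molar volume at 25 C
  list(aegl = c(30, 160, 1100) * ppm_to_mg_m3,
       env = c(gwater = 500, lake = 1000, river = 1000))
}
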