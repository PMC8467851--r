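# Shared fixtures: tiny synthetic scenarios and segments with simple round
# numbers so every expected value can be recomputed by hand.

# unit-ish stability: sigma_y = sigma_z = sqrt(x), so c + d = 1
unit_stability <- function() stability_parameters(a = 1, b = 1, c = 0.5, d = 0.5)

# plume scenario: release rate pi mg/s makes the radius formula collapse to
# r = 1/C under unit_stability and v = 1
plume_scenario <- function(rate = pi, Q = 1e9,
                           aegl = c(0.25, 0.5, 1.0),
                           env = c(gwater = 1, lake = 1, river = 1),
                           elapsed = c(gwater = 1e4, lake = 1e4, river = 1e4),
                           ustar = 0.1) {
  release_scenario(chemical_name = "testgas", total_amount_mg = Q,
                   release_rate_mg_s = rate, aegl_thresholds = aegl,
                   env_thresholds = env, elapsed_s = elapsed,
                   friction_velocity = ustar)
}

const_profile <- function(value) rep(value, 24)

make_segment <- function(from = "1", to = "2", length_km = 2,
                         road_type = "two-lane",
                         vehicle = 50, population = 0.01, wind = 1,
                         water = water_attributes(), land_use = "mixed") {
  road_segment(from = from, to = to, length_km = length_km,
               road_type = road_type,
               vehicle_density = const_profile(vehicle),
               population_density = const_profile(population),
               wind_speed = const_profile(wind),
               water = water, land_use = land_use)
}

# the composed hand-computation fixture: one segment carrying all media
full_fixture_segment <- function() {
  make_segment(water = water_attributes(
    groundwater = list(flow = const_profile(1e-4), depth = 5, wet_area = 10),
    lake = list(depth = 2, relation = "alongside"),
    river = list(flow = const_profile(0.1), depth = 2, width = 50,
                 relation = "crossing")))
}

# independent bisection inversion of the centerline concentration: the x at
# which the plume decays to c_target, found without the closed form
bisect_radius <- function(c_target, scenario, stability, v_wind,
                          lo = 1e-8, hi = 1e12, iters = 200L) {
  f <- function(x) centerline_concentration(x, scenario, stability, v_wind) -
    c_target
  stopifnot(f(lo) > 0, f(hi) < 0)
  llo <- log(lo); lhi <- log(hi)
  for (i in seq_len(iters)) {
    mid <- (llo + lhi) / 2
    if (f(exp(mid)) > 0) llo <- mid else lhi <- mid
  }
  exp((llo + lhi) / 2)
}
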