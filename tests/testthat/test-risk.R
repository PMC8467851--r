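test_that("population bearing ratio matches the footprint formula", {
  z <- list(areas = c(1.2e6, 0, 0))
  expect_equal(population_ratio(z, 0.01, length_km = 2, d_pop = 600), 1.0)
  z0 <- list(areas = c(0, 0, 0))
  expect_equal(population_ratio(z0, 0.01, 2, 600), 0)
  # density cancels: any positive T gives the same ratio
  expect_equal(population_ratio(z, 5, 2, 600),
               population_ratio(z, 1e-6, 2, 600))
  expect_error(population_ratio(z, 0, 2, 600), "undefined")
  expect_error(population_ratio(z, 0.01, 0, 600), "> 0")
})

test_that("environmental bearing ratio divides Q by capacity", {
  vols <- list(volumes = c(air = 100, gwater = 0, lake = 0, river = 0))
  th <- c(air = 2, gwater = 1, lake = 1, river = 1)
  expect_equal(environment_ratio(500, vols, th), 2.5)
  expect_equal(environment_ratio(200, vols, th), 1)
  expect_equal(environment_ratio(1000, vols, th),
               2 * environment_ratio(500, vols, th))
  empty <- list(volumes = c(air = 0, gwater = 0, lake = 0, river = 0))
  expect_error(environment_ratio(500, empty, th), "capacity")
})

test_that("preference parameter reproduces every piecewise bracket and boundary", {
  # interior probes
  expect_equal(preference_parameter(0.3), 0.9)
  expect_equal(preference_parameter(0.7), 0.95)
  expect_equal(preference_parameter(1.0), 1.0)
  expect_equal(preference_parameter(1.2), 1.05)
  expect_equal(preference_parameter(2.0), 1.1)
  # boundaries follow the printed brackets exactly
  expect_equal(preference_parameter(0), 0.9)
  expect_equal(preference_parameter(0.5), 0.9)
  expect_equal(preference_parameter(0.5 + 1e-12), 0.95)
  expect_equal(preference_parameter(1 - 1e-12), 0.95)
  expect_equal(preference_parameter(1 + 1e-12), 1.05)
  expect_equal(preference_parameter(1.5), 1.05)
  expect_equal(preference_parameter(1.5 + 1e-12), 1.1)
  expect_error(preference_parameter(-0.1), ">= 0")
  # step function: non-decreasing, crosses 1 exactly at p = 1
  ps <- sort(c(runif(200, 0, 3), 1))
  qs <- preference_parameter(ps)
  expect_true(all(diff(qs) >= 0))
  expect_identical(qs[ps == 1], 1.0)
  expect_true(all(qs[ps < 1] < 1) && all(qs[ps > 1] > 1))
})

test_that("risk scores are P * C^q with safe zero and log-domain handling", {
  expect_equal(population_risk(2e-4, 1e6, 1), 2e-4 * 1e6)
  expect_equal(population_risk(0, 1e6, 1.1), 0)
  expect_equal(population_risk(1e-4, 0, 0.9), 0)
  expect_equal(population_risk(1e-4, 1e6, 1.1), 1e-4 * 10^6.6,
               tolerance = 1e-12)
  expect_equal(environmental_risk(2e-5, 5e5, 0.9), 2e-5 * 5e5^0.9,
               tolerance = 1e-12)
  # no overflow when C^q alone exceeds double range but P * C^q does not
  expect_true(is.infinite(1e300^1.05))
  expect_true(is.finite(population_risk(1e-60, 1e300, 1.05)))
  expect_equal(log(population_risk(1e-60, 1e300, 1.05)),
               log(1e-60) + 1.05 * log(1e300))
  # linear in P; increasing in C
  expect_equal(population_risk(2e-4, 123, 1.05),
               2 * population_risk(1e-4, 123, 1.05))
  expect_lt(environmental_risk(1e-4, 100, 1.05),
            environmental_risk(1e-4, 200, 1.05))
})

test_that("assess_segment composes the chain deterministically", {
  sc <- plume_scenario()
  st <- unit_stability()
  seg <- full_fixture_segment()
  rec1 <- assess_segment(seg, sc, st, 5)
  rec2 <- assess_segment(seg, sc, st, 5)
  expect_identical(rec1, rec2)
  expect_equal(rec1$period, 5)
  expect_equal(rec1$segment_id, "1-2")

  # zero vehicle density forces both risks to zero
  still <- make_segment(vehicle = 0)
  rec0 <- assess_segment(still, sc, st, 0)
  expect_equal(rec0$p_leak, 0)
  expect_equal(rec0$er_pop, 0)
  expect_equal(rec0$er_env, 0)
  expect_gt(rec0$c_pop, 0)

  # zero population density zeroes the population branch only
  ghost <- make_segment(population = 0)
  recg <- assess_segment(ghost, sc, st, 0)
  expect_equal(recg$c_pop, 0)
  expect_equal(recg$er_pop, 0)
  expect_equal(recg$q_pop, 0.9)
  expect_gt(recg$er_env, 0)
})

test_that("higher wind never increases either consequence", {
  sc <- plume_scenario(rate = 1e7, aegl = c(2, 10, 50))
  st <- stability_parameters(0.08, 0.06, 1, 1)
  lo <- make_segment(wind = 1)
  hi <- make_segment(wind = 3)
  r_lo <- assess_segment(lo, sc, st, 0)
  r_hi <- assess_segment(hi, sc, st, 0)
  expect_lt(r_hi$c_pop, r_lo$c_pop)
  expect_lt(r_hi$c_env, r_lo$c_env)
})

test_that("assess_network yields one record per segment-period", {
  sc <- plume_scenario()
  st <- unit_stability()
  one <- road_network(c("1", "2"), list(make_segment()))
  rec <- assess_network(one, sc, st)
  expect_equal(nrow(rec), 24)
  expect_equal(sort(rec$period), 0:23)

  net <- generate_network(generator_config(n_nodes = 6, n_segments = 8,
                                           seed = 3))
  recs <- assess_network(net, generate_scenario(), pasquill_gifford("D"))
  expect_equal(nrow(recs), 8 * 24)
  # independence across segments: a segment's rows equal its solo assessment
  seg <- net$segments[[4]]
  solo <- assess_segment(seg, generate_scenario(), pasquill_gifford("D"), 7)
  joint <- recs[recs$segment_id == solo$segment_id & recs$period == 7, ]
  rownames(joint) <- NULL
  expect_equal(joint, solo)
})

test_that("route risk is additive over segments", {
  sc <- plume_scenario()
  st <- unit_stability()
  segA <- make_segment("1", "2")
  segB <- make_segment("2", "3", vehicle = 80, length_km = 1.5)
  net <- road_network(c("1", "2", "3"), list(segA, segB))
  rec <- assess_network(net, sc, st)
  expect_equal(route_risk(rec, character(0), 4), c(er_pop = 0, er_env = 0))
  one <- route_risk(rec, "1-2", 4)
  ab <- route_risk(rec, c("1-2", "2-3"), 4)
  b <- route_risk(rec, "2-3", 4)
  expect_equal(ab, one + b)
  # endpoint-pair form maps to the same ids
  expect_equal(route_risk(rec, list(c("1", "2"), c("2", "3")), 4), ab)
  expect_error(route_risk(rec, "9-9", 4), "not in assessment")
})

test_that("ranking by ER matches ranking by preference-adjusted consequence at fixed P", {
  sc <- generate_scenario()
  st <- pasquill_gifford("D")
  net <- generate_network(generator_config(n_nodes = 10, n_segments = 14,
                                           seed = 5))
  # force identical probability inputs so only consequences differ
  segs <- lapply(net$segments, function(s) {
    s$vehicle_density <- const_profile(40)
    s$length_km <- 2
    s$road_type <- "two-lane"
    s
  })
  net2 <- road_network(net$nodes, segs)
  rec <- assess_network(net2, sc, st)
  r0 <- rec[rec$period == 8, ]
  adj <- r0$c_pop^r0$q_pop
  expect_equal(order(r0$er_pop), order(adj))
})
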