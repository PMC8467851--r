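test_that("groundwater radius matches a step-by-step hand evaluation", {
  sc <- plume_scenario(Q = 1e9, env = c(gwater = 1, lake = 1, river = 1),
                       elapsed = c(gwater = 1e4, lake = 1e4, river = 1e4),
                       ustar = 0.1)
  gw <- list(flow = const_profile(1e-4), depth = 5, wet_area = 10)
  # hand chain: advection + sqrt(H u* t) * ln(Q / (C S sqrt(pi H u* t)))
  adv <- 1e-4 * 1e4
  disp <- sqrt(5 * 0.1 * 1e4)
  lnterm <- log(1e9 / (1 * 10 * sqrt(pi * 5 * 0.1 * 1e4)))
  expect_equal(groundwater_radius(sc, gw, 0), adv + disp * lnterm,
               tolerance = 1e-14)

  # pure advection when the ln argument is exactly 1:
  # choose Q = C * S * sqrt(pi H u* t)
  q1 <- 1 * 10 * sqrt(pi * 5 * 0.1 * 1e4)
  sc1 <- plume_scenario(Q = q1, env = c(gwater = 1, lake = 1, river = 1),
                        elapsed = c(gwater = 1e4, lake = 1e4, river = 1e4),
                        ustar = 0.1)
  expect_equal(groundwater_radius(sc1, gw, 0), adv, tolerance = 1e-12)

  # zero flow with ln argument e gives exactly the dispersion length
  gw0 <- list(flow = const_profile(0), depth = 5, wet_area = 10)
  sce <- plume_scenario(Q = exp(1) * q1,
                        env = c(gwater = 1, lake = 1, river = 1),
                        elapsed = c(gwater = 1e4, lake = 1e4, river = 1e4),
                        ustar = 0.1)
  expect_equal(groundwater_radius(sce, gw0, 0), disp, tolerance = 1e-12)

  expect_equal(groundwater_volume(0), 0)
  expect_equal(groundwater_volume(1), 2 * pi / 3)
  expect_equal(groundwater_volume(3), 18 * pi)
  expect_error(groundwater_volume(-1), ">= 0")
})

test_that("lake radius matches hand evaluation and clamps at zero", {
  sc <- plume_scenario(Q = 1e9, env = c(gwater = 1, lake = 1, river = 1),
                       elapsed = c(gwater = 1e4, lake = 1e4, river = 1e4),
                       ustar = 0.1)
  lake <- list(depth = 2, relation = "alongside")
  expected <- sqrt(0.58 * 2 * 0.1 * 1e4) *
    log(1e9 / (0.58 * pi * 4 * 0.1 * 1e4))
  expect_equal(lake_radius(sc, lake), expected, tolerance = 1e-14)

  # ln argument <= 1 clamps to zero: tiny spill into a huge-capacity lake
  sc0 <- plume_scenario(Q = 1, env = c(gwater = 1, lake = 1, river = 1),
                        elapsed = c(gwater = 1e4, lake = 1e4, river = 1e4),
                        ustar = 0.1)
  expect_equal(lake_radius(sc0, lake), 0)
})

test_that("river radius has the right bank-reflection limits and hand value", {
  sc <- plume_scenario(Q = 1e9, env = c(gwater = 1, lake = 1, river = 1),
                       elapsed = c(gwater = 1e4, lake = 1e4, river = 1e4),
                       ustar = 0.1)
  river <- function(W) list(flow = const_profile(0.1), depth = 2, width = W,
                            relation = "crossing")
  # hand chain at W = 50
  denom <- 0.58 * pi * 4 * 0.1 * 1e4
  bank <- 2 + exp(-50^2 / (0.145 * 2 * 0.1 * 1e4))
  expected <- 0.1 * 1e4 + sqrt(0.58 * 2 * 0.1 * 1e4) * log(1e9 * bank / denom)
  expect_equal(river_radius(sc, river(50), 0), expected, tolerance = 1e-14)

  # wide-river limit: factor -> 2; narrow limit: factor -> 3
  r_wide <- river_radius(sc, river(1e6), 0)
  wide_expected <- 1000 + sqrt(0.58 * 2 * 0.1 * 1e4) * log(2e9 / denom)
  expect_equal(r_wide, wide_expected, tolerance = 1e-12)
  r_narrow <- river_radius(sc, river(1e-6), 0)
  narrow_expected <- 1000 + sqrt(0.58 * 2 * 0.1 * 1e4) * log(3e9 / denom)
  expect_equal(r_narrow, narrow_expected, tolerance = 1e-9)
  expect_gt(r_narrow, r_wide)
})

test_that("surface-water volumes use the quarter-sphere / hemisphere split", {
  expect_equal(surface_water_volume(1, "crossing"), 2 * pi / 3)
  expect_equal(surface_water_volume(1, "alongside"), pi / 3)
  for (r in c(0, 0.5, 7, 120)) {
    expect_equal(surface_water_volume(r, "alongside"),
                 surface_water_volume(r, "crossing") / 2)
  }
  expect_error(surface_water_volume(1, "under"), "relation")
  expect_error(surface_water_volume(-1, "crossing"), ">= 0")
})

test_that("pollution_volumes composes the per-medium models", {
  sc <- plume_scenario(Q = 1e9, env = c(gwater = 1, lake = 1, river = 1),
                       elapsed = c(gwater = 1e4, lake = 1e4, river = 1e4),
                       ustar = 0.1)
  st <- unit_stability()

  dry <- make_segment()
  pv <- pollution_volumes(dry, sc, st, 0)
  expect_true(pv$volumes[["air"]] > 0)
  expect_equal(unname(pv$volumes[c("gwater", "lake", "river")]), c(0, 0, 0))

  seg <- full_fixture_segment()
  pv <- pollution_volumes(seg, sc, st, 0)
  expect_equal(pv$radii[["gwater"]],
               groundwater_radius(sc, seg$water$groundwater, 0))
  expect_equal(pv$volumes[["lake"]],
               surface_water_volume(lake_radius(sc, seg$water$lake),
                                    "alongside"))
  expect_equal(pv$volumes[["river"]],
               surface_water_volume(river_radius(sc, seg$water$river, 0),
                                    "crossing"))
  expect_true(all(pv$present))

  # monotone (non-decreasing) in the released amount Q
  qs <- 10^seq(6, 12, by = 1)
  for (m in c("gwater", "lake", "river")) {
    vols <- vapply(qs, function(q) {
      scq <- plume_scenario(Q = q, env = c(gwater = 1, lake = 1, river = 1),
                            elapsed = c(gwater = 1e4, lake = 1e4, river = 1e4),
                            ustar = 0.1)
      pollution_volumes(seg, scq, st, 0)$volumes[[m]]
    }, numeric(1))
    expect_true(all(diff(vols) >= 0))
  }
})

test_that("lake volume is identical across all 24 periods", {
  sc <- plume_scenario()
  st <- unit_stability()
  seg <- full_fixture_segment()
  lake_v <- vapply(0:23, function(t)
    pollution_volumes(seg, sc, st, t)$volumes[["lake"]], numeric(1))
  expect_identical(lake_v, rep(lake_v[1], 24))
})
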