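test_that("time profiles enforce length, finiteness and sign", {
  expect_silent(time_profile(rep(1, 24)))
  expect_error(time_profile(rep(1, 23)), "exactly 24")
  expect_error(time_profile(rep(1, 25)), "exactly 24")
  expect_error(time_profile(c(rep(1, 23), NA)), "non-finite")
  expect_error(time_profile(c(rep(1, 23), -0.1)), "non-negative")
  expect_error(time_profile(c(rep(1, 23), 0), positive = TRUE),
               "strictly positive")
})

test_that("a minimal 2-node / 1-segment network validates and loads", {
  seg <- make_segment()
  net <- road_network(c("1", "2"), list(seg))
  expect_s3_class(net, "road_network")
  expect_length(net$segments, 1L)
  expect_equal(names(net$segments), "1-2")

  path <- tempfile(fileext = ".json")
  save_network(net, path, "json")
  back <- load_network(path)
  expect_equal(back$segments[["1-2"]]$vehicle_density,
               seg$vehicle_density)
})

test_that("network validation rejects bad structure with named errors", {
  seg <- make_segment()
  expect_error(road_network(c("1"), list(seg)), "endpoints")
  expect_error(road_network(c("1", "2"), list(seg, seg)), "duplicate segment")
  expect_error(
    road_segment("1", "2", length_km = 0, road_type = "two-lane",
                 vehicle_density = rep(1, 24),
                 population_density = rep(1, 24),
                 wind_speed = rep(1, 24)),
    "length_km")
  expect_error(
    road_segment("1", "2", length_km = 1, road_type = "two-lane",
                 vehicle_density = rep(1, 24),
                 population_density = rep(1, 24),
                 wind_speed = rep(0, 24)),
    "wind_speed")
  expect_error(
    road_segment("1", "2", length_km = 1, road_type = "two-lane",
                 vehicle_density = rep(1, 23),
                 population_density = rep(1, 24),
                 wind_speed = rep(1, 24)),
    "vehicle_density")
})

test_that("segments are undirected: (i,j) and (j,i) share one id", {
  expect_equal(segment_id("7", "3"), segment_id("3", "7"))
})

test_that("water attributes enforce positivity and relation labels", {
  expect_error(make_segment(water = water_attributes(
    lake = list(depth = -1, relation = "alongside"))), "depth")
  expect_error(make_segment(water = water_attributes(
    lake = list(depth = 2, relation = "under"))), "relation")
  expect_silent(make_segment(water = water_attributes(
    river = list(flow = const_profile(0.2), depth = 2, width = 10,
                 relation = "crossing"))))
})

test_that("generated networks round-trip through all three formats", {
  net <- generate_network(generator_config(n_nodes = 8, n_segments = 10,
                                           seed = 42))
  for (fmt in c("json", "geojson")) {
    path <- tempfile(fileext = paste0(".", fmt))
    save_network(net, path, fmt)
    back <- load_network(path)
    expect_equal(length(back$segments), length(net$segments))
    for (id in names(net$segments)) {
      a <- net$segments[[id]]; b <- back$segments[[id]]
      expect_identical(a$road_type, b$road_type)
      expect_equal(a$length_km, b$length_km, tolerance = 0)
      expect_equal(a$wind_speed, b$wind_speed, tolerance = 0)
      expect_equal(a$population_density, b$population_density, tolerance = 0)
      expect_identical(is.null(a$water$river), is.null(b$water$river))
      if (!is.null(a$water$river)) {
        expect_equal(a$water$river$flow, b$water$river$flow, tolerance = 0)
        expect_identical(a$water$river$relation, b$water$river$relation)
      }
    }
  }
  dir <- tempfile("csvnet")
  save_network(net, dir, "csv")
  back <- load_network(dir)
  for (id in names(net$segments)) {
    a <- net$segments[[id]]; b <- back$segments[[id]]
    expect_equal(a$vehicle_density, b$vehicle_density, tolerance = 1e-15)
    expect_equal(a$length_km, b$length_km, tolerance = 1e-15)
    if (!is.null(a$water$groundwater)) {
      expect_equal(a$water$groundwater$wet_area, b$water$groundwater$wet_area,
                   tolerance = 1e-15)
    }
  }
})

test_that("population density unit bridge is exact", {
  expect_equal(normalize_population_density(1e6), 1.0)
  expect_equal(normalize_population_density(0), 0)
  expect_equal(normalize_population_density(2500), 2.5e-3)
  expect_error(normalize_population_density(-1), "non-negative")
})
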