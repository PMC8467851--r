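Package: hazmatrisk
Title: Quantitative Risk Assessment of Hazardous-Materials Road
    Transportation under Time-Varying Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Per-road-segment quantitative risk assessment for hazardous
    materials (hazmat) shipments across 24 daily time periods. Combines a
    leakage accident probability model driven by tabulated truck accident
    rates and time-varying vehicle density, a Gaussian plume model yielding
    three AEGL-based population exposure rings, advection-dispersion
    influence radii for air, groundwater, lake and river pollution,
    monetized accident consequences, and bearing-capacity-adjusted risk
    scores with piecewise risk-preference exponents. Includes a seeded
    generator of synthetic urban road networks with diurnal traffic,
    population, wind and water-flow profiles, CSV/JSON/GeoJSON readers and
    writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
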