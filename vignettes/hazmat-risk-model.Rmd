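---
title: "The hazmatrisk model: assumptions, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The hazmatrisk model: assumptions, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hazmatrisk)
```

## The model

`hazmatrisk` scores every road segment of a network, at every hour of the
day, for the risk that a hazmat shipment leaks there and harms people or
the environment. The chain has four stages.

**1. Leakage probability.** A tabulated truck accident rate $P^A$
(accidents per million vehicle-km, keyed by region and road type) is
multiplied by the conditional probability $P^B$ that the accident type
releases cargo, then converted to a per-segment-hour probability using the
time-varying vehicle density $M_{ij}(t)$ (veh/km) and segment length
$L_{ij}$ (km):
$$P_{ij}(t) = 10^{-6}\, P^A P^B M_{ij}(t)\, L_{ij}/2 .$$
The default accident type is an overturn on the road ($P^B = 0.375$),
consistent with treating the stopped, overturned vehicle as a point source;
a subset of accident types can be summed instead. The trailing length
factor is implemented as $L/2$ — per-direction traffic on an undirected
segment — with a `length_mode = "squared"` override for sensitivity
analysis against the alternative $L^2$ reading; dimensional bookkeeping
(rate × veh/km × km is dimensionless) supports $L/2$. $P_{ij}(t)$ is not
clamped at 1 (realistic values are $10^{-6}$–$10^{-4}$); a warning is
emitted if it ever exceeds 1.

**2. Exposure and pollution geometry.** The release disperses through a
Gaussian plume with power-law coefficients $\sigma_y = a x^c$,
$\sigma_z = b x^d$. Dropping crosswind offset, receptor height and source
height gives the centerline concentration
$C(x) = Q^{Hazard} / (\pi a b\, v^{Wind} x^{c+d})$, whose closed-form
inverse yields the distance at which any threshold is reached. Three AEGL
thresholds produce nested rings (AEGL-1 is the lowest concentration, so its
radius is the largest); the air pollution volume is the hemisphere at the
AEGL-2 limit. Water media use advection–dispersion radii: groundwater
(advection + $\sqrt{H u^* t}$ dispersion against the wet cross-section),
lakes (dispersion only — hence constant over the day), rivers (advection +
dispersion with a bank-reflection factor between 2 and 3). A road
*alongside* surface water pollutes a quarter sphere ($\tfrac13\pi r^3$),
one *crossing* it a hemisphere ($\tfrac23\pi r^3$).

**3. Monetized consequences.** Ring areas times population density times a
3×4 incidence matrix $\alpha_{uv}(t)$ times per-person costs (evacuation,
inspection, medical, casualties) give $C^{Pop}(t)$; medium volumes times
per-m³ costs (emergency disposal, monitoring, remediation) give
$C^{Env}(t)$. Both are homogeneous of degree 1 in their cost tables.

**4. Bearing capacity and risk preference.** The population ratio
$p^{Pop} = \sum_u S_u / (10^3 L\, d^{Pop})$ compares the exposed footprint
with a $d^{Pop} = 600$ m emergency-response corridor along the segment; the
environmental ratio $p^{Env} = Q / \sum_r V_r C_r^{Env}$ compares the
released amount with the media's self-purification capacity. A piecewise
step maps each ratio to an exponent
$q \in \{0.9, 0.95, 1.0, 1.05, 1.1\}$, crossing 1 exactly at $p = 1$, and
the final scores are $ER = P(t)\, C(t)^{q}$. With $q = 1$ this collapses to
the traditional probability × consequence risk; $q > 1$ amplifies
consequences beyond the area's capacity so that rare-but-catastrophic
segments are not masked by their low probability.

### Model assumptions

- The overturned vehicle is a point source; pollution spreads in all
  directions at once, so exposure zones are circles/rings and pollution
  volumes are sphere sectors.
- The spilled material does not degrade during diffusion, and the same
  total amount $Q$ is used for every water medium (the spill reaches air
  and water in equal amounts; it is not split between them).
- Segments are independent: an accident on one segment does not affect
  populations or media along another. Route risk is therefore additive.
- Time is a discrete 24-period hour-of-day index. Profiles select values;
  no sub-hour interpolation is performed.

## Parameters that matter

| Parameter | Unit | Default | Rationale |
|---|---|---|---|
| $P^B$ accident type | – | overturn, 0.375 | matches the point-source assumption |
| $a,b,c,d$ | – | class D power law (0.08, 0.06, 1, 1) | neutral stability; near-field linear-growth approximation to the Briggs open-country curves, adequate below ~1 km |
| AEGL thresholds | mg/m³ | ammonia 60-min AEGLs (≈ 20.9 / 111.4 / 766.2) | published values, shipped as config defaults only — thresholds are always scenario configuration, never hardcoded |
| water limits $C^{Env}_{2..4}$ | mg/m³ | 500 / 1000 / 1000 | order-of-magnitude ammonia-nitrogen water standards; illustrative |
| $d^{Pop}$ | m | 600 | standard emergency-response isolation corridor width |
| $u^*$ | m/s | 0.1 | friction velocity; validated to [0.02, 0.553] |
| $t^{Gwater}, t^{Lake}, t^{River}$ | s | 1800 | 30-minute response horizon: the time emergency crews need to reach and contain an urban spill; scenario-level constants, distinct from the hour-of-day index |
| release duration | s | 600 | converts the load (6 t → $Q = 6\times10^9$ mg) to $Q^{Hazard} = 10^7$ mg/s; a 10-minute catastrophic tank failure |
| $\alpha_{uv}$ | – | severity increasing toward the innermost ring | illustrative; medical/casualty incidence rises with the AEGL level |
| cost tables | currency | illustrative magnitudes | currency is opaque; because $C^q$ is unit-sensitive, scores are comparable only within one currency system |

The exponent $q$ makes risk scores *unit-dependent*: for $C > 1$ risk
increases with $q$, for $C < 1$ it decreases. Rankings at fixed $P$ are
unaffected (the adjusted consequence $C^q$ is monotone in $C$ within a
bracket), but absolute scores must never be compared across currency
conventions.

## The synthetic-data generator

`generate_network()` emulates the study conditions of a compact, highly
urbanized district: 38 nodes and 52 arcs on a jittered planar grid joined
by a random spanning tree plus short chords; vehicle densities with
morning (07–09) and afternoon (17–19) rush-hour peaks over a 0.4× base;
population profiles by land use (residential: higher at night; commercial:
higher in daytime; boarding school: nearly flat; mixed: in between) at
2 000–15 000 persons/km² peak; strictly positive diurnal wind around
3 m/s ± 50 %; and water bodies on a subset of segments with river flows
around 0.3 m/s and groundwater flows around 0.003 m/s (±50 % diurnal).
These speed scales are what make the diurnal variation of the influence
volumes come out ordered air > river > groundwater > lake (= 0), the
qualitative signature the assessment is expected to show. One segment is
forced to carry all three water media and both `alongside`/`crossing`
relations are always represented, so every code path is exercised.

All randomness flows through one seeded private stream (the global RNG
state is saved and restored), so a fixed seed reproduces a network
byte-for-byte.

What the generator does *not* emulate: real street topology and arc
lengths, measured traffic/population/wind statistics, correlations between
neighbouring segments, weekday/weekend or seasonal structure, and
calibrated cost standards. Passing tests on synthetic networks therefore
demonstrate the *structural* behaviour of the model (peak placement,
monotonicities, orderings, determinism), not predictive accuracy on any
real road network.

## Numerical choices

- **Radius clamping.** Water radii are $\max(0, \cdot)$: when the log
  argument drops below 1 the dispersion term goes negative, meaning the
  limit concentration is never exceeded beyond the source; a negative
  radius has no physical meaning and the model is outside its validity
  regime, so the radius (and volume) is 0.
- **Log-domain risk.** $ER = \exp(\log P + q \log C)$, so $C^q$ may
  overflow a double while the product remains representable. Zero $P$ or
  $C$ short-circuits to 0.
- **Piecewise boundaries.** The printed brackets are followed exactly:
  $p = 0.5 \to 0.9$, $p = 1 \to 1.0$, $p = 1.5 \to 1.05$. The first
  bracket excludes 0; $p = 0$ is mapped to 0.9, which never matters
  because the consequence is 0 there. The environmental capacity sum runs
  over the four defined media (air, groundwater, lake, river).
- **Zero population density** inside the full assessment short-circuits
  the population branch to $C^{Pop} = 0$, $q = 0.9$, $ER^{Pop} = 0$; the
  standalone ratio function instead errors, because the ratio as written
  divides population by population. (The density cancels algebraically —
  the "acceptable limit" is the corridor footprint at the same density —
  so any positive density yields the same ratio.)
- **Ambiguous renderings resolved by dimensional analysis.** The
  probability conversion's trailing factor is $L/2$, not $L^2$; each
  additive term in the water radii is in meters and every log argument is
  dimensionless, which fixes the square-root placements; the surface-water
  volume is $k \pi r^3$ (mirroring the groundwater hemisphere), with
  $k = \tfrac13$ for the quarter sphere.
- **Hour-of-day convention.** Periods are `0..23`; R's 1-based indexing is
  confined to profile lookups.
- **Serialization.** JSON numbers are written with 17 significant digits so
  save→load round-trips are bit-exact; CSV bundles use full-precision
  scientific notation.

## Problem sizes

The shipped tests run the full 38×52 network where determinism or peak
placement is the property under test, smaller 5–10-node networks for I/O
and orchestration checks, 1 000 random draws for the closed-form-inverse
and ring-conservation properties, and 20 seeded fixtures for the
volume-variation ordering — sizes chosen to exercise every branch while
keeping the default suite fast.

## Known limitations

- The plume is steady-state; no puff (instantaneous release) model, plume
  rise, deposition, terrain or chemical reaction.
- Water models are radial one-dimensional approximations; no hydrodynamic
  transport, adsorption or tides.
- AEGL exposure-duration choice (10 min / 30 min / 1 h / …) is left to
  scenario configuration; defaults use the 60-min values.
- $ER^{Pop}$ and $ER^{Env}$ are reported separately and never summed into
  one score; their units differ by the exponent and a sum would be
  meaningless across currency conventions.
- No routing or location optimization: the package scores networks; what
  to do with the scores is the planner's problem.
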