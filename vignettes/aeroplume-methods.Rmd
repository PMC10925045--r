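---
title: "Modelling airport-level aviation PM2.5: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling airport-level aviation PM2.5: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aeroplume)
```

`aeroplume` estimates the monthly, airport-level PM2.5 concentration
attributable to aircraft landing–take-off (LTO) activity. It is aimed at
exposure assessment: given national aviation activity statistics and a small
set of dispersion constants, it produces a year × airport table of monthly
emission flows (g/s) and 24-hour average concentrations (reported as
μg/m³), plus a station-based accuracy check. This vignette explains the
model chain, the tunable parameters, the synthetic data generator used for
testing, and the design decisions taken where the procedure is genuinely
ambiguous.

## The emission stage

Airport-level activity data are usually published as national monthly
totals of transport turnover (ton-km: tonnes carried × kilometres flown)
together with per-airport shares. The emission stage is a chain of
definitional products:

1. **Apportionment.** Each airport's share of a month's national turnover is
   its turnover divided by the national total
   (`compute_turnover_shares()`). Shares are non-negative and sum to one; a
   month with no activity anywhere is an error rather than a silent 0/0.
   The share basis is turnover by default; a count of LTO movements can be
   used instead (`basis = "lto_count"`), but turnover is the quantity the
   fuel factor multiplies, so it is the default.
2. **Fuel.** Airport fuel burn (kg) is turnover × unit ton-kilometre
   consumption (kg fuel per ton-km), a published efficiency statistic
   (`compute_fuel()`).
3. **PM2.5 mass.** Emitted mass (g) is fuel × an emission intensity in g
   PM2.5 per kg fuel (`compute_emission_mass()`). The intensity stands in
   for a full per-engine, per-mode emission-index calculation
   (Boeing Fuel Flow Method 2 with first-order approximations for
   particulates); those internals are deliberately out of scope, and the
   intensity is a pluggable scalar or per-year table. The packaged default,
   0.2772 g/kg, is a fleet-average value for a narrow-body-dominated
   fleet year.
4. **Flow.** The monthly mass is averaged over the month's seconds
   (Gregorian day count × 86,400, leap-year aware) to an emission flow
   `E` in g/s (`mass_to_flow()`). This is the source strength the plume
   model consumes. `flow × seconds` recovers the mass exactly, and airports
   with zero turnover keep zero-valued rows so output tables stay
   rectangular.

## The dispersion stage

Concentration at a receptor offset $y$ follows a steady-state Gaussian
plume with image-source reflection terms:

$$C = \frac{E}{2\pi\mu\delta_y\delta_z}
      \exp\!\left(\frac{-y^2}{2\delta_y^2}\right) P, \qquad
  P = 2e^{-h^2/2\delta_z^2}
    + \sum_{n=1}^{N} e^{-(nl-h)^2/2\delta_z^2}
    + \sum_{n=1}^{N} e^{-(nl+h)^2/2\delta_z^2}.$$

$P$ collects the direct near-ground term and the reflections of the plume
at the ground and at the mixing-layer lid at height $l$; the reported
concentration is the mean of $C$ over the configured receptor offsets.

The constants, all carried by `plume_params()`:

| parameter | meaning | default |
|---|---|---|
| `mu` | wind speed (m/s), one fixed scalar for all airports and months | 3.7 |
| `delta_y`, `delta_z` | horizontal / vertical diffusion coefficients | 1.33 / 1 |
| `h` | effective source height (m) | 2 |
| `n_reflections` | upper bound $N$ of the reflection sums | 2 |
| `l` | mixing-layer height (m): 900 coastal, 1100 inland | per airport |
| `receptor_offsets` | offsets $y$ (m) averaged into the report | 1, 2, 3 |
| `unit_scale` | multiplicative output scale | 1 |

The diffusion coefficients are fixed constants: there is no
downwind-distance dependence and no stability-class scheme. That makes the
model a deliberately coarse, fast screening model — adequate for long-term
relative comparisons across airports, not for episode analysis. At the
default geometry the reflection exponents are of order
$-(900-2)^2/2$ and underflow to zero, so $P$ reduces to the direct term
$2e^{-2} \approx 0.27067$ and the mean concentration per unit flow is
$\bar C / E \approx 3.3708\times10^{-3}$ — both of which the test suite
pins against an independently coded term-by-term evaluation.

Design decisions where the procedure was open:

- **Sum of exponentials.** The reflection factor is evaluated as a sum of
  exponentials, the standard image-source form; an exponential-of-summed-
  exponents variant (`literal_exp_of_sum = TRUE`) is kept for comparison
  because the formula can be typeset ambiguously. The two coincide whenever
  the reflection terms underflow, which includes the default geometry.
- **Reflection count.** The stated reflection count of three conflicts with
  summation bounds of two in the written sums; the default is $N = 2$, the
  written bound, and `n_reflections` is configurable. Numerically identical
  at the defaults.
- **Role of `y`.** The offsets {1, 2, 3} m are described in the source
  procedure as near-ground receptor heights but sit in the horizontal-offset
  slot of the formula. The formula is applied literally at those values and
  averaged; their effect is a fixed multiplicative factor, so no ordering or
  ratio across airports depends on the reading.
- **Units.** Evaluating the formula literally with `E` in g/s yields
  g/m³-scaled values, yet the convention in this literature is to label the
  result μg/m³ without an explicit conversion. The package reports the
  literal value under that label by default (`unit_scale = 1`), surfacing
  the ambiguity as a parameter (`unit_scale = 1e6` for a strict SI
  reading) instead of hiding a silent factor. Relative comparisons,
  seasonality, shares and the validation relative error are invariant to
  this choice.

## The validation stage

Modeled concentrations are checked against monitoring stations by inverse
distance weighting: station $i$ at distance $d_i$ gets weight
$d_i^{-p}/\sum_j d_j^{-p}$, stations beyond a 50 km radius are dropped, and
the relative error is $|{\rm obs} - {\rm mod}|/{\rm obs}$. The IDW power is
not fixed by the procedure; the default is $p = 1$, the plainest reading of
"inverse distance", exposed as an argument. The packaged fixture
`can_station_distances()` carries the 16 published station identifiers and
distances around Guangzhou Baiyun airport (CAN); the source text counts
"12 monitoring stations" but lists 16 IDs and distances, and the fixture
ships all 16. With the published June 2020 pair — observed station average
2.767 μg/m³, modeled 2.603 μg/m³ — the relative error is 5.9%.

## The synthetic scenario generator

Real activity inputs are national statistics that are not archived in
machine-readable form, so the package generates inputs with the structure
the analysis assumes (`scenario_config()`, `generate_airports()`,
`generate_activity()`, `generate_station_observations()`):

- **Trend**: national monthly turnover grows multiplicatively at
  `annual_growth` (default 11 %/yr, a long-run growth rate typical of the
  2006–2023 Chinese market).
- **Seasonality**: a mean-one 12-vector peaking in August (multiplier 1.10)
  and troughing in February (0.86), the summer-travel peak and
  post-holiday trough. The profile is chosen so the ordering survives
  division by month length: August beats 30-day September and February
  stays below 31-day months *per second*, not just per month, so emission
  flows and concentrations inherit the ordering. A smooth cosine through
  realistic August/February annual shares (~8.9 %/7.5 %) cannot satisfy
  this — the day-count effect (28 vs 31 days, ~10 %) would dominate its
  amplitude — hence the slightly sharpened hand-set profile
  (`seasonal_multipliers()`).
- **Shock**: one year's activity drops by `shock_depth` (default 0.3165)
  relative to its no-shock counterfactual, then grows at `recovery_rate`
  (default 0.0477/yr) from the shock level until it rejoins the trend,
  never overshooting it. The depth is parameterised against the
  counterfactual (the clean reading for a trend model); against the
  previous year's actual level the same default produces a smaller
  year-over-year drop, because one year of trend growth intervenes.
- **Heterogeneity**: airport shares come from a Dirichlet-type allocation
  (independent Gamma draws with shape `share_concentration = 0.5`,
  normalised), so a few hub airports dominate as in real networks.
- **Noise**: turnover noise is multiplicative log-normal with mean one
  (relative sd `noise_sd`, default 0.05), keeping turnover positive;
  station noise is additive Gaussian truncated at zero on top of a constant
  background. Neither distribution is prescribed by the procedure; both are
  config-exposed.

Everything is reproducible from the config seed, and generation does not
disturb the caller's RNG state.

What the generator does **not** emulate: aircraft-type fleet mix (the
intensity is a single national scalar), within-month and within-airport
wind or weather variation, spatial correlation between neighbouring
airports' activity, and station-to-station background differences. Passing
tests on synthetic data therefore demonstrate that the pipeline's
arithmetic, orderings and inversions are correct under the assumed
structure — not that the model reproduces observed concentrations at any
real airport.

## Numerical choices and degenerate inputs

- Month lengths are Gregorian and leap-year aware throughout.
- Empty cells in the wide tables are missing values, never zero: zero is a
  meaningful emission level (a dormant airport).
- Wide-table CSV cells are written with 17 significant digits and parsed
  with base R's exact decimal reader, so write → read is bit-exact; the
  test suite checks this on a 175-airport × 18-year table (2,100 rows).
- Degenerate inputs error loudly: all-zero months in apportionment,
  non-positive intensities and distances, unknown airport codes (named in
  the error), duplicate keys, malformed wide-table cells (reported with
  row numbers).
- Test problem sizes were chosen as the smallest that exercise every code
  path: 20 airports × 3 years for scenario properties, 1,000 random
  parameter draws for plume-oracle agreement, full scale (175 × 18) only
  for the round-trip check.

## Known limitations

The dispersion model is single-source, wind-direction-free and
chemistry-free; it ignores secondary PM2.5 formation, deposition, terrain
and airport layout, and it uses one national wind speed. The emission stage
inherits whatever bias the single intensity scalar carries across years of
changing fleet mix. The validation compares against stations that see many
other sources, so its relative error conflates model error with background
attribution. These are properties of the published procedure that the
package reproduces, not implementation shortcuts.
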