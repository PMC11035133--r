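---
title: "Characterizing sorghum drought-stress environments in Mali"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing sorghum drought-stress environments in Mali}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sorghumTPE)
```

## The problem

Malian sorghum is grown under rain-fed conditions across a steep North–South
rainfall gradient (isohyets of 400–600 mm up to more than 1000 mm annual
rainfall). The farmer-preferred Guinea-type landraces are photoperiod
sensitive: because the onset of the rains varies widely while their cessation
is comparatively fixed, a photoperiod-driven delay of panicle initiation lets
crops sown at any point in a six-week window all flower in a narrow September
window, filling grain on stored soil water as the rains end. Whether a season
stresses the crop therefore depends on the interplay of sowing date,
cultivar photoperiod sensitivity, canopy size, soil water storage, and the
tail of the monsoon.

`sorghumTPE` characterizes these production environments the way
envirotyping studies do: simulate many site–season–soil–cultivar
combinations with a daily crop model, express each run as the trajectory of
the crop water supply/demand (S/D) ratio around flowering, cluster the
trajectories into a small set of drought-stress scenarios, and summarize the
weighted frequency and yield consequences of each scenario per isohyet zone,
soil and cultivar.

## Phenology

Development is clocked in thermal time (degree-days above a base
temperature) with a broken-linear temperature response using cardinal
temperatures 11/30/42&nbsp;°C (conventional sorghum values; never reported
with the cultivar coefficients, so they are package defaults and
configurable). The stage sequence is sowing → emergence → end of juvenile
phase → panicle initiation → flag leaf → flowering → start of grain fill →
maturity → ripe.

Stage boundaries live on the continuous cumulative degree-day axis: when a
day's thermal time overshoots a stage target, the excess is credited to the
next phase. Phase durations in degree-days therefore equal their targets
exactly — the simulated flowering-to-maturity duration is 484 °Cd for CSM63E
and 518 °Cd for CSM335 by construction of the stage machine, not by
rounding luck of the daily time step.

The photoperiod response is the triple broken-linear function: the duration
of the end-of-juvenile → panicle-initiation phase equals a 50 °Cd base below
the minimum photoperiod Ppcrit1 (11.5 h), rises at Ppslope (126 °Cd h⁻¹ for
CSM63E, 226 for CSM335) between Ppcrit1 and Ppcrit2 (13.5 h), and plateaus
above. Day length includes civil twilight to 2.2° below the horizon. The
photoperiod driving the extension is the running mean over the days spent in
the sensitive phase, re-evaluated daily, rather than the sowing-day value —
this matches the definition of the slope as a regression of phase duration
on the phase-mean photoperiod, and is what `fit_ppslope()` inverts when
calibrating the slope from trial data.

Two deliberate simplifications: emergence and the juvenile phase are lumped
into a single 200 °Cd sowing → end-of-juvenile duration (no coefficient is
published for it), and years are 365 days with no leap handling, which keeps
thermal-time bookkeeping trivial.

## Canopy: the individual-leaf-area loop

The mechanistic heart of the model is the loop that ties photoperiod to
water demand:

longer days → later panicle initiation → more initiated leaves → a larger
largest leaf and more total leaf area → higher transpiration demand before
flowering.

Leaves are initiated at one per plastochron from emergence to panicle
initiation on top of four embryonic leaves, so the total main-stem leaf
number is `embryo + tt_emergence_to_init / plastochron`, rounded to the
nearest integer (ties up). The plastochron default is 21 °Cd per leaf — the
APSIM sorghum leaf initiation rate — because it reproduces observed leaf
numbers (about 21 for CSM63E and 28–30 for CSM335 at early Sudanian
sowings); with substantially slower initiation the photoperiod-sensitive
cultivar cannot build the large canopies that drive its pre-flowering water
demand. Leaves appear at one per phyllochron (40 °Cd), and the panicle
initiation → flag leaf phase lasts exactly as long as the remaining leaves
take to appear.

Individual leaf size follows the bell-shaped rank profile
`Y = Y0 exp(a (X − X0)² + b (X − X0)³)`, with the largest-leaf area linear
in total leaf number (`Y0 = MaxLNo · aMaxSlope + aMaxIntercept`, cultivar
coefficients) scaled by the cultivar's largest-leaf multiplier, which we
interpret as converting the main-culm regression to an effective per-plant
area. The profile-shape constants are not published for these cultivars, so
the package ships configurable defaults: the largest leaf at rank
`0.66 · MaxLNo`, breadth `a = −0.009 − 0.2/MaxLNo`, skewness `b = 0.0006`.
These give realistic unimodal profiles but are the least-constrained part of
the canopy model; anyone with leaf-size data for their own material should
refit them.

Leaf area index is the emerged-leaf profile area times plant density
(5.7 plants m⁻², 86 cm rows — the standard farmer practice held constant
throughout). After flowering, 0.05% of leaf area senesces per degree-day,
tripled while the stress index is below 0.3.

## Growth, water, and the S/D index

Potential biomass gain is radiation-limited: intercepted radiation by Beer's
law (extinction 0.4) times a radiation use efficiency of 1.25 g MJ⁻¹.
Transpiration demand converts that gain to water through the
transpiration-efficiency coefficient (9 Pa) at the daytime vapour pressure
deficit, estimated as 0.75 of the saturation-vapour-pressure span between
Tmax and Tmin. The daily stress index is `S/D = min(1, supply/demand)`,
defined as 1 when demand is zero and floored at 10⁻⁶ so the index stays in
(0, 1] even on a fully dried root zone. Actual growth is potential growth
times the (uncapped-below-one) supply/demand ratio; actual transpiration is
`min(supply, demand)`.

The soil is a layered bucket. Two presets bracket the Malian sorghum soils:
62 mm of plant-available water over 1010 mm (six layers) and 156 mm over
1200 mm (seven layers), built with uniform per-layer (DUL − LL) so the
stated capacities are exact, and a root extraction coefficient kl = 0.07 d⁻¹
in every layer. Each day, root uptake is extracted first against the morning
state (distributed over layers proportional to kl-weighted available water —
this makes the uptake the soil grants identical to the supply the crop saw),
then rain infiltrates and cascades (water above the drained upper limit
drains at 0.5 d⁻¹ per layer, saturation overflow immediately; drainage below
the profile is lost), then bare-soil evaporation leaves the top layer under
a two-stage (energy-limited, then falling-rate) regime. There is no runoff —
sites are flat cultivated fields — and mass balance closes to better than
10⁻⁹ mm by construction, which the test suite asserts on random forcing.
Roots descend at 25 mm d⁻¹ from a 100 mm sowing depth until flowering.

Seasons start with the soil reset to 20% of fractional available water,
filled top-down (the published protocol does not say how the reset is
distributed over depth; top-down mimics a profile wetted by first rains, and
the alternative uniform-fraction filling would slightly change early-season
supply). Sowing follows the farmer rule: the first day in the June 1 –
July 15 window with 20 mm of rain in the trailing 7 days and at least 10 mm
of stored plant-available water, else forced on the window's last day.

## Grain

Grain number is set from the mean daily biomass gain per plant over the
±100 °Cd window around flowering divided by the cultivar's dry matter per
seed — the growth-rate reading of the seed-set relationship, which yields
realistic grain numbers (roughly 10–20 × 10³ grains m⁻²); dividing the whole
window's biomass by dm_per_seed instead would give order 10⁵. Daily grain
growth is the minimum of sink demand (maxGFRate, interpreted in mg grain⁻¹
°Cd⁻¹, times grain number and the day's thermal time) and available
assimilate plus retranslocation; the retranslocatable pool is 20% of stem
biomass at the start of grain fill (stem taken as 55% of shoot biomass,
since organs are not simulated separately), released uniformly over the
fill. Filling runs from 80 °Cd after flowering to maturity. Grain yield can
never exceed biomass because every gram of grain comes from current
assimilate or the retranslocated pool.

With these coefficients CSM63E is source-limited (large maxGFRate, many
grains) while CSM335 is sink-limited (small maxGFRate). A consequence worth
knowing: CSM335's grain yield is nearly insensitive to mild terminal
stress — assimilate plus reserves cover the modest sink — so the
flowering-stress and no-stress scenario means for CSM335 sit close together
(a few percent), while early pre-flowering stress, which cuts grain number
itself, depresses yield clearly. Biomass separates the three scenarios much
more strongly than grain does.

## Synthetic weather

No historical records ship with the package; the generator emulates the
monsoonal climate per isohyet zone so every stage of the pipeline is
testable offline. Rainfall occurrence is a first-order two-state Markov
chain (persistence 0.25) whose marginal wet-day probability traces a
half-sine between a stochastic onset (mean mid-to-late June, earlier
southward, sd 12 d) and cessation (mid-October, sd 5 d — the end of the
rains is far less variable than the start). Wet-day amounts are gamma
distributed (shape 1) with the scale set so the expected annual total equals
the site target; over 500 seasons the realized mean is within a few percent
of target, and the four zone defaults (500/700/900/1100 mm) are strictly
ordered. Temperatures and radiation are sinusoidal annual cycles with
Gaussian noise inside the observed Malian ranges; wet days are 2 °C cooler
and receive 20% less radiation. All rain falls between the drawn onset and
cessation, so the configured wet window always holds at least 95% of the
annual total.

What the generator does not emulate: multi-day synoptic dry spells beyond
what the Markov chain produces, year-to-year autocorrelation, extreme
single-storm events, and within-zone spatial correlation. The practical
consequence is a somewhat milder Sahelian drought signal than the historical
records carry — in our ensembles the short-cycle CSM63E almost never
experiences classified drought stress (the field-data-driven study found
about 5% overall and up to ~40% of seasons on the shallow soil in the
400–600 mm zone), while CSM335's stress frequencies (roughly 75–85%
no-stress overall, rising steeply in the 400–600 mm zone and on the shallow
soil) reproduce the published structure well. Passing ensemble tests
therefore demonstrate the pipeline's ordering properties (soil, cultivar and
isohyet effects), not calibrated absolute frequencies for real Mali.

## Envirotyping

Each completed run is reduced to eight interval means of the daily S/D index
over 100 °Cd bins from 400 °Cd before to 400 °Cd after flowering (no zero
bin; the flowering day falls in the first post-flowering interval, and the
anchor is the exact continuous thermal-time position of the flowering
transition). Runs lacking 400 °Cd on either side of flowering — crop
failures or truncated seasons — are excluded and reported with reasons, as
the clustering input must be rectangular.

Trajectories from all cultivars, soils, sites and seasons are clustered
jointly in raw S/D space (Euclidean distance; the values already share the
(0, 1] scale) with k = 3, by k-means (25 restarts, fixed seed, best
within-cluster sum of squares) or PAM (BUILD + SWAP on Euclidean
dissimilarities). Labeling is rule-based: the centroid with mean S/D ≥ 0.95
is *no stress* (two such centroids raise an ambiguity error — lower k); of
the remaining two, the one whose index first drops below 0.9 earlier on the
thermal-time axis is *early pre-flowering stress*, the other *flowering
stress*; ties on the drop position break by the lower mean. On archetype
mixtures with noise sd ≤ 0.05 both methods recover the generating labels
with adjusted Rand index 1.

Because the number of recorded seasons differs per isohyet zone, each season
is weighted by `max_seasons / (total_seasons × seasons_in_isohyet)`, where
`max_seasons` is the largest per-zone count — under this reading every
zone's total weight is identical (the typeset formula is ambiguous about the
denominator grouping; we adopt the reading that equalizes zone totals and
assert it as a property). The weights apply to scenario *frequencies* and to
the cumulative yield-probability curves, which compare occurrence and risk
across the region; scenario yield *means* are unweighted, since they
describe the effect of a scenario on the runs that experienced it.

## Problem sizes and reproducibility

The bundled site network mirrors the 18 reference stations with their
latitudes, isohyet classes and mean annual rainfall as calibration targets.
`mali_site_specs(seasons_scale)` scales the per-site season counts
proportionally to the historical record lengths; the test suite and examples
use `seasons_scale = 0.12` (96 site-years, 384 runs, well under a minute),
while `seasons_scale = 1` emulates the full 459-site-year design (1836
runs). Weather seeds derive from one base seed and are shared across soils
and cultivars within a site-season, so all soil and cultivar contrasts are
paired on weather. Every stochastic component is seeded; identical
configurations yield byte-identical outputs.

## Known limitations

* No nitrogen or phosphorus dynamics (fertilizer doses are treated as
  non-limiting), no tillering, no pests, diseases or waterlogging, no
  lodging or plant height.
* No runoff; all rain infiltrates.
* The leaf-profile shape constants (a, b, X0 fraction) and the meaning of
  the largest-leaf multiplier are under-determined by published material;
  they are exposed as arguments and documented above.
* Organ partitioning is not simulated; the stem share used for the
  retranslocation pool is a fixed fraction.
* The synthetic climate underestimates Sahelian rainfall variability (see
  above); absolute scenario frequencies are qualitative.
* Highly photoperiod-sensitive, very tall material (the Guinean-zone type)
  is outside the calibrated domain.
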