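---
title: "Methods: a composite index of coastal drinking-water vulnerability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a composite index of coastal drinking-water vulnerability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coastvuln)
```

## The model

Storm-surge inundation salinises the drinking-water sources of low-lying
coasts — ponds, shallow tubewells, stored rainwater. The risk an individual
coastal segment faces is a joint property of its exposure (how often
cyclones strike, how low and how flat the land is), its sensitivity (how
many people depend on local sources) and its resilience (whether rainfall
or fresh groundwater can replace a salinised source). `coastvuln`
operationalises this as six ordinal scores per half-degree grid element,
each 1 (low), 2 (moderate) or 3 (high vulnerability), combined with equal
weight into a Coastal Vulnerability Index in the Gornitz tradition:

$$\mathrm{CVI} = \sqrt{\frac{a \cdot b \cdot c \cdot d \cdot e \cdot f}{6}}$$

with a = elevation, b = geomorphology, c = cyclone landfall frequency,
d = September rainfall, e = groundwater availability, f = population
density. The product form rewards co-occurrence: a cell that is
simultaneously low, deltaic and densely populated scores far above one
that is extreme on a single axis. Because each factor takes only the
values 1–3, every attainable CVI is $\sqrt{p/6}$ for an integer product
$p \in [1, 729]$, so the index lives on a discrete grid between
$\sqrt{1/6} \approx 0.41$ and $\sqrt{729/6} \approx 11.02$:

```{r enumeration}
tab <- enumerate_score_space()
c(n = nrow(tab), min = round(min(tab$cvi), 2), max = round(max(tab$cvi), 2))
attr(tab, "class_counts")
```

Equal weighting is an assumption, not a finding: differential weights are
defensible but subjective, and `compare_aggregators()` shows the index is
rank-correlated with the plain mean over the full score space while
disagreeing on a small fraction of pairs — the product form is what
separates compound hotspots from the rest.

## Classification thresholds

The interval classifiers follow fixed break points, with the edge
conventions pinned exactly (and exercised by dedicated boundary tests):

* elevation (m amsl): ≤ 2 high, > 2 and < 5 moderate, ≥ 5 low — 5.0 m
  exactly is **low**; negative (subsided) elevations are legal input;
* cyclone landfalls over the record: < 5 low, 5–10 moderate (closed band),
  > 10 high;
* population density (people/km²): < 100 low, 100–500 moderate (closed),
  > 500 high;
* September rainfall (mm): > 300 low, 150–300 moderate (closed), < 150
  high. The September total matters because roughly 300 mm at the end of
  the wet season fills household rainwater storage — `harvest_volume()`
  gives 300 mm × 20 m² × 1.0 = 6000 l, several months of drinking water
  for a household of five. The default runoff coefficient is 1.0 so that
  this round figure is reproduced exactly; a realistic collection
  efficiency of ~0.89 reproduces the 4000 l figure often quoted for a
  15 m² roof, and the coefficient is an explicit argument;
* geomorphology and groundwater are categorical maps: beach-with-cliff /
  beach-with-river-mouth / delta-plain and fresh-shallow /
  saline-shallow-fresh-deep / saline-both.

All thresholds live in `default_thresholds()` and are echoed into the run
manifest by `run_pipeline()` for provenance.

CVI classes use the limits 1.73 (the three-lows + one-moderate + two-highs
combination) and 3.27 (all-moderate). Those limits are themselves CVI
values of attainable score vectors, so class membership is decided on the
exact integer product — LOW for $p \le 18$, MODERATE for $18 < p \le 64$,
HIGH above — which avoids any floating-point edge ambiguity and, as a
suite property, agrees with floating comparison against $\sqrt{18/6}$ and
$\sqrt{64/6}$ on all 729 combinations. Both limits were deliberately
placed on the lower class, reading each quoted limit combination as the
maximum of its class.

## Grid and geometry

The coastal grid is the half-degree lattice anchored at (0°, 0°) with
half-open cells $[\min, \min + 0.5)$; anchoring and half-openness are
choices made here for reproducible cell ids and no double counting on
edges. A cell is coastal iff the great-circle length of coastline inside
it is positive (tangent contact does not count), lengths use a spherical
Earth of radius 6371 km, and clipped lengths are additive: summed over
cells they recover the total coastline length to well within 0.1 %.
Segment clipping assigns each sub-segment to the cell containing its
midpoint, which implements the half-open convention without special
casing.

## Cyclone incidence

Track records (storm id, timestamp, lon, lat, Saffir–Simpson category per
6-hourly fix) are grouped per storm and time-sorted. Storms whose peak
category never reaches 1 — tropical storms, depressions — and storms with
no category on any fix (uncategorised) are excluded. A landfall is the
first intersection of each sea→land transition of the track polyline with
the land-polygon boundary, located by linear interpolation between the
bracketing fixes; at 6-hourly archive resolution anything fancier than
linear would be spurious. The category at landfall is that of the last
at-sea fix, falling back to the storm maximum. Successive landfalls of one
storm closer than 1° of arc are merged, so a track skimming the coast is
one event, not several.

Because a mature cyclone is far wider than half a degree, each landfall
increments every coastal cell whose centre lies within 1.0° of arc of the
landfall point — a disc footprint that touches about four half-degree
elements along a straight coast. Whether incidence should count per storm
or per fix, and the exact footprint shape, are genuinely open choices; the
package counts **once per storm per cell** (the quantity of interest is
landfall frequency, not fix frequency) through an isotropic disc, and both
the footprint radius and the minimum category are arguments. The counting
kernel is verified against a brute-force (event × cell) double loop on
fixtures.

## Scenario projection

The built-in 2050 and 2100 scenarios adjust three variables relative to
the 2010 baseline: population density ×1.40 (2050) and ×1.35 (2100 — the
end-of-century multiplier is relative to 2010, *not* compounded on 2050),
effective elevation −0.2 m and −0.6 m for sea-level rise, rainfall ×1.05
and ×1.10. Cyclone incidence, geomorphology and groundwater are held
fixed, the assumption being that these will not change materially at this
scale over the horizon. Sea-level rise enters as an offset on the
representative elevation statistic; no inundation remodelling is
attempted. Scenario application is attribute-local and invertible, and a
suite property confirms the only possible component movements are the
dictated ones: elevation and population scores never fall, rainfall scores
never rise.

## Exposure summaries

`coast_length_by_class()` sums per-cell coastline length by CVI class;
totals are conserved by construction. `exposed_population()` estimates
people per class as density × cell area × land fraction × buffer fraction,
where the land and buffer fractions come from sampling each cell on a
0.05° sub-grid against land membership and distance to the coastline
(buffer default 30 km). The sub-grid method is a package choice — simple,
resolution-configurable and oracle-testable; distances use a local
equirectangular projection per coastline segment, whose error at regional
scale is far below the sampling resolution. The absolute magnitudes such
summaries take on real continental data (hundreds of km of highly
vulnerable coast, tens of millions of people) require the real global
elevation, population, rainfall and track datasets and are out of scope
here; the package reproduces the structure of those summaries on synthetic
data with exact conservation properties.

## The synthetic world

`generate_world()` emulates the statistical structure of the real inputs:
a tropical coastline alternating low, flat, densely populated deltaic
segments with steeper, sparser beach/cliff segments; a west-wetter
longitudinal rainfall gradient; categorical groundwater zones skewed
saline under deltas; and cyclone landfalls as a per-segment Poisson
process with deltaic coasts struck more often (defaults: mean 9 storms per
deltaic and 2 per beach segment over the record, 6 segments of 1.5°, half
deltaic — magnitudes chosen to span all three cyclone classes on a
century-and-a-half-scale record). Default problem sizes (a ~19-cell coast,
tens of storms) keep any seeded world well under a second to generate and
assess.

Two design rules make it a ground-truth generator rather than a mere
fixture. First, every attribute draw is kept strictly inside its class
band with a margin of one output-precision unit (elevation for the high
class is drawn from [−0.5, 1.9] m, never 2.0), so the intended class of
every variable in every cell is recovered exactly by the classifiers —
boundary behaviour is tested by dedicated unit tests, not left to chance
draws. Second, each synthetic storm's final approach is steered
perpendicularly through its target point on the coast, so the landfall the
track analysis interpolates coincides with the landfall the generator
intended, and the per-cell incidence the pipeline counts equals the
generator's own direct count. Worlds are bit-identical under a fixed seed.

What the generator does **not** emulate: real storm climatology (tracks
are four-fix walks, not basin-scale trajectories), tides and surge
physics, raster noise in elevation or population, spatial autocorrelation
beyond the segment structure, and hand-digitised geomorphology error.
Passing the recovery tests therefore demonstrates that the pipeline's
plumbing is exact — classification, counting, aggregation introduce zero
error — not that the index is robust to the measurement error real
datasets carry.

## Numerical and degenerate-input choices

* All great-circle arithmetic: haversine on a 6371 km sphere; footprint
  radii expressed in degrees of arc.
* CVI is reported to 2 dp in file outputs; full precision is kept
  internally and class decisions never pass through the rounded value.
* A coastline that never enters the grid, or a zero-length polyline, is an
  error (`"no coastal cells"`); a track that never reaches land yields an
  empty event set, not an error; an empty track file is a warning plus an
  empty collection.
* Cells missing any of the six attributes fail assessment with the
  offending `cell_id`s listed; unknown categorical levels name the level.
* Track rows with unparseable coordinates are dropped with a message
  giving the count.

## Limitations

The index is relative and ordinal: CVI 6 is not "twice as vulnerable" as
CVI 3. Tsunami, tide and subsidence processes are intentionally outside
the variable set, as are health-outcome attribution and
adaptation-engineering questions. The half-degree lattice registration is
a convention; real analyses that hand-delineate elements along the coast
will not match cell-for-cell. Scenario projection is a static
re-classification — it propagates no uncertainty and models no dynamic
response such as polder raising or migration.
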