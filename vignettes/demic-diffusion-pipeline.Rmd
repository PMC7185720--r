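---
title: "Modelling archaeological expansions as demic diffusion: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling archaeological expansions as demic diffusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

When an archaeological culture spreads across a continent, two broad
mechanisms can drive it: *demic diffusion* — the migration and growth of
people — and *cultural diffusion* — the spread of practices without major
population movement. A demic wave of advance leaves a characteristic
signature in the radiocarbon record: the earliest dates per region fall off
linearly with distance from the source, at a slope whose inverse is the
front speed (km/yr). `demicsim` implements the full chain of analysis for
testing this hypothesis on a compilation of ¹⁴C determinations:

1. **Calibration** of each determination against an IntCal/ShCal-format
   curve into a probability mass function over calendar years.
2. **Space–time regression** of calibrated dates against great-circle
   distances from candidate origins, estimating origin, start date and
   front speed.
3. **Agent-based simulation** of village-level demographic expansion on an
   equal-area suitability landscape.
4. **Fitness scoring** of a simulated arrival raster against the calibrated
   record, and **genetic-algorithm** search of the demographic parameter
   space.
5. **Synthetic data generation** with known ground truth, so that every
   stage can be validated by parameter recovery.

# Calibration

A determination (age $a$, lab error $\sigma$) is calibrated against a curve
$(\mu(t), \sigma_c(t))$ by evaluating, at every integer calendar year $t$ on
the curve's range,

$$w(t) \propto \phi\!\left(\frac{a - \mu(t)}{\sqrt{\sigma^2 + \sigma_c(t)^2}}\right),$$

normalising to sum to one. This is the standard intercept-free
probabilistic calibration. Numerical choices: a 1-year grid with linear
interpolation of the curve between knots; support truncated where the
cumulative mass in either tail falls below $10^{-6}$ (then renormalised);
ages more than $5\sigma$ outside the curve's ¹⁴C range are rejected as a
coverage error. One curve is used for all records — mixing hemispheric
curves shifts dates by an order of ~15 yr, well below lab errors.

The *median* of a calibrated density is defined by cumulating mass from the
older (larger cal BP) end and taking the first year where it reaches 0.5;
for the tied two-point density $\{3000\!: 0.5,\ 2000\!: 0.5\}$ this yields
3000, the conservative (older) choice. "Earliest" is everywhere judged on
this median: per site, and per spatial bin, the record with the largest
median calibrated age is kept (ties broken by smaller lab error, then input
order).

Records are pre-filtered by lab error (dropping $\sigma > 200$ yr; stricter
cuts would discard legacy dates that anchor first-arrival times in poorly
dated regions) and by a reliability flag carried in the input table. The
package deliberately does not re-adjudicate chronological controversies:
alternative chronologies are expressed as different input files or flags.

# Space–time regression

Distances are haversine great-circle distances on a 6371-km sphere.
Because travelled distances are themselves error-prone proxies, the line is
fitted by **reduced major axis (RMA)** regression rather than ordinary
least squares: $r$ is the Pearson correlation, the slope is
$\mathrm{sign}(r)\,s_y/s_x$ and the intercept $\bar y - b\bar x$. Front
speed is reported as $-1/b$ (dates in cal BP decrease outward, so an
expansion has $b < 0$); bootstrap iterations with $b \ge 0$ carry no
outward-expansion signal and are excluded from the speed summary, with
their count reported.

Sites are first thinned to one per distance bin (half-open intervals
$[kw, (k+1)w)$; widths 100–500 km are scanned) to correct for uneven
research intensity; combinations retaining fewer than 5 sites are rejected.
Rather than fitting point estimates, the regression is repeated 999 times,
each iteration drawing one calendar year per site from its calibrated
density; means and 2.5/97.5 percentile intervals of $r$, intercept, slope
and speed are reported. The per-iteration correlation p-value (two-sided
t-test) is averaged; fits with mean $p < 0.05$ count as significant, and
the origin scan flags as best the candidate site with maximal mean $|r|$
among significant fits. Percentile rather than normal-theory intervals are
used because slope and speed distributions are skewed for small $n$.

Under the synthetic study conditions used throughout the tests (40 sites,
60-yr lab errors, 2000 years of expansion depth), these intervals cover the
true speed in ≈93–95% of replicates at speeds 0.5–2 km/yr, and the best
origin falls within one bin width of the true source.

# The expansion simulator

Agents are villages on a grid of 10 × 10 km cells (100 km² — the scale of
ethnographic village territories) in an equal-area projection, so that cell
distances are Euclidean in km. One step is one year; the clock runs in
"sim BP" and stops at 500 sim BP, the approximate horizon of European
contact. Each village has a real-valued population, a home cell, an
exclusive set of claimed cells within its catchment radius, and a residence
clock. The landscape carries a suitability value in [0, 1]; cells below a
settleability threshold (in practice the niche model's optimal cut-point)
cannot be settled.

Per year, in seeded-random order (to avoid systematic agent-ordering bias),
each active village:

* **Grows** exponentially, $N_{t} = N_0(1 + a)$ with $a = 0.025$ yr⁻¹
  fixed — between the growth rates inferred for Eurasian farming
  expansions and those observed in modern tropical-forest populations.
  Its ceiling is $K^* \times$ (claimed cells). When over the ceiling it
  claims one more free settleable cell within its catchment per year
  (highest suitability, seeded random tie-break); when none exists the
  population is clamped back to the ceiling.
* **Fissions** when at or above the fission threshold, provided at most 6
  other villages have homes within twice the catchment radius (6
  neighbours approximates hexagonal close packing; $2R$ is the
  nearest-neighbour distance of a hexagonal lattice of non-overlapping
  catchments). The daughter settles the best free cell in the ring just
  beyond the parent's catchment, $(R, R + 10]$ km; if blocked and
  leapfrogging is enabled, a search is made in the annulus
  `leap_km` ± one cell, with the additional requirement that the target's
  suitability strictly exceed the home cell's (migration effort must be
  compensated). Parent and daughter split the population evenly — the
  symmetric default, which also makes the initial condition well defined.
  If no target exists the village simply keeps growing past the threshold.
* **Relocates** when it has stayed home strictly longer than the
  permanence time, searching the same adjacency ring and leap annulus; on
  moving it releases all claimed cells and resets its clock. Short-range
  (1–2 km) garden moves are below the grid resolution and are not
  modelled.

A village at its ceiling with nothing to claim, nowhere to settle a
daughter and nowhere to move becomes inactive; the simulation tracks the
expanding front, not post-saturation social dynamics (warfare, hierarchy,
trade are out of scope).

The run starts with a single village at the origin holding exactly the
fission threshold, so it fissions immediately. **First arrival** is
recorded the first time a cell is occupied — settled as a home *or* claimed
into a catchment — and never overwritten. Claimed cells count as occupied
because claiming is the model's act of taking territory into use;
recording homes only would leave permanent holes between village sites
(about half of a uniform landscape), which would zero out evaluation sites
the front in fact swept over. With this definition, a uniform-landscape
run reproduces the expected wave-of-advance phenomenology: the aggregate
population is sigmoid (early exponential phase at ≈ the intrinsic rate, a
plateau at ≈97% of $K^* \times$ settleable cells), the front distance is
linear in time ($R^2 > 0.99$), and wider catchments accelerate the front
(≈0.72 km/yr at 10 km vs ≈1.2 km/yr at 30 km catchment, at default
parameters).

Daughter villages start their residence clock at zero (the natural reading;
inheritance of the parent's clock would make daughters relocate
immediately).

# Model evaluation

Simulated arrival times are compared with the earliest dates per spatial
bin, selected exactly as in the regression stage at the bin width that gave
the strongest correlation. Each site's score is the calibrated density at
the arrival year of the site's cell, **normalised so the density peak
equals 1**; the model fitness is the mean over sites. Max-normalisation is
the single most consequential interpretation in this module: a score of 1
must mean "every simulated arrival coincides with the peak of its
calibrated distribution", which a sum-normalised density could never
attain. Unreached cells and arrival years outside the support score 0 ("no
match"). Densities are evaluated at the exact (rounded) year with no
smoothing window.

# Parameter search

The five free parameters are searched by a generational genetic algorithm:
100 genomes initialised uniformly within the ranges below, the best 40
selected as parents each generation, single-point crossover with
probability 0.8 in the fixed gene order, per-gene mutation with probability
0.2 (redrawing uniformly from the range), the 5 best genomes copied
verbatim, for 20 generations.

| parameter | range | unit |
|---|---|---|
| growth rate $a$ | 0.025 (fixed, not a gene) | yr⁻¹ |
| max population density $K^*$ | 20–100 | individuals / 100 km² cell |
| catchment radius | 10–30 | km |
| leap distance | 0 or 150–250 | km |
| fission threshold | 50–300 | individuals |
| permanence | 10–30 | yr |

The leap gene is drawn as 0 ("no leapfrogging") with probability ½ and
otherwise uniformly in its range, at initialisation and on mutation, so
both movement regimes stay represented. Parents are paired uniformly at
random with replacement; offspring count is `pop_size − n_elite`, keeping
the population at 100. Fitness values are single simulation draws —
genomes are re-evaluated rather than cached because the simulator is
stochastic, which makes the fitness signal noisy; elitism guarantees the
best-ever fitness is monotone anyway. Because $K^*$ and catchment radius
trade off against each other (the same population can be held by a larger
territory at lower density), a fixed-catchment mode pins the catchment
gene at 10, 20 or 30 km to control for equifinality.

# Synthetic data and what passing tests show

The generator produces: an identity ("toy") calibration curve
($\mu(t) = t$, constant curve error) under which calibrated densities are
analytic Gaussians; uniform, gradient and smooth-random landscapes (coarse
seeded noise, bilinearly interpolated, rescaled to [0, 1]); date tables
from constant-speed radial expansions — sites at seeded-random bearings,
uniform in distance by default so every bin stays populated (area-uniform
is available), true arrival $t(d) = \mathrm{start} - d/\mathrm{speed}$,
recorded age = curve at the true year plus Gaussian lab noise, rounded
(reported errors are floored at 1 yr so the noise-free case still yields
valid records); and closed-form arrival rasters for testing the fitness
stage independently of the simulator. A companion sampler turns any
arrival raster back into a date table (stratified by distance), closing
the simulator–regression loop.

Synthetic expansions are perfectly radial, their speed is constant, lab
errors are homoskedastic, and site discovery is unbiased. Real
compilations violate all four (rivers and coasts channel movement, speeds
change, legacy dates have large errors, research effort is uneven), so
recovery on synthetic data demonstrates correctness of the machinery, not
archaeological validity of any particular reconstruction.

Problem sizes used by the test suite and the acceptance script: coverage
checks use 40 sites, σ = 60 yr, 100 replicates per speed (0.5, 1, 2 km/yr)
with 999 bootstrap draws each; the simulator checks use a 200 × 200
uniform grid run for 2000 years; the pipeline-closure check uses a
150 × 150 grid with dates generated at 0.75 km/yr — the simulator's own
realized wave speed at a 10-km catchment — then scored against matched
(10 km) and speed-distorting (30 km) catchments. The genetic algorithm is
validated on the deterministic toy fitness $1 - |K^* - 60|/80$ rather than
on full simulations, which isolates the search machinery from simulator
noise.

# Known limitations

* Rasters are accepted only as ESRI ASCII grids already in an equal-area
  projection with square 10-km cells; the package validates but does not
  reproject, and GeoTIFF input is not parsed.
* The lon/lat ↔ plane mapping is a spherical Albers equal-area conic
  (closed form, with inverse); with standard parallels spanning a
  continent, distances on the plane can deviate from great-circle
  distances by a few percent between the parallels.
* The neighbour-counting radius ($2\times$ catchment) and the even fission
  split are modelling choices the underlying behavioural rules do not pin
  down; both are documented above and isolated in single functions.
* Fitness weights all evaluation sites equally; there is no spatial
  weighting and no likelihood-based (or ABC-style) inference.
* Reproduction of published continental-scale estimates requires the
  original date compilation and the Southern Hemisphere calibration curve
  file, which are inputs the user must supply (see
  `tests/testthat/test-acceptance.R` for where they are looked up).
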