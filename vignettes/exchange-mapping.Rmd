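---
title: "Mapping river–aquifer exchanges: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping river–aquifer exchanges: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwex)
```

`gwex` maps water exchanges between an alluvial aquifer and a river
corridor with three independent indicators — a Darcy-law hydraulic
diagnosis on TIN surfaces, stygobite community indices, and
macrophyte-based trophic/groundwater indices — and overlays the three maps
on a common zonation. This vignette is the package's account of the
underlying models, the parameters that matter, the numerical conventions,
and the choices made where the method leaves room.

## 1. The hydraulic model

### Surfaces

Piezometric heads and river water-surface levels come as scattered
`(x, y, z)` points in projected metres (geographic coordinates are
rejected: gradients need metric units). Each cloud is triangulated —
Delaunay on the `(x, y)` projection, computed with a sweep-hull algorithm
that tolerates regular lattices and collinear survey rows — and every
triangle carries the unique plane through its vertices:

* **elevation** — mean of the three vertex heads (m);
* **slope** — the gradient magnitude $i = \sqrt{a^2+b^2}$ of the plane
  $z = ax + by + c$ (dimensionless rise/run);
* **aspect** — the azimuth of $(-a, -b)$, i.e. the *downslope* direction,
  in degrees clockwise from grid north.

The aspect convention is a declared choice: the flow-angle weighting below
needs the direction water actually moves, so aspect points downslope. GIS
products differ on this; any upslope-azimuth input data must be converted.
A triangle with all three heads equal has slope 0, an undefined aspect
(`defined_aspect = FALSE`), and contributes zero flux downstream rather
than raising an error — flat reaches are physically meaningful.

### Sampling along the bank

Bank polylines are split into segments (100 m in the synthetic scenes).
The method needs one `(i, aspect, head)` triple per segment from the
piezometric TIN and one river-flow aspect from the river-stage TIN. Where a
segment crosses several triangles, the package clips the segment against
the triangulation exactly (each triangle contributes the sub-interval of
the segment it contains) and uses crossed-length-weighted means: arithmetic
for slope and elevation, circular (resultant-vector) for aspect. A
zero-length segment degenerates to a point lookup; a point on a shared edge
resolves to the lowest adjacent triangle index (a deterministic tie-break);
a segment lying exactly on a shared edge is weighted over both adjacent
triangles, which cancels the centroid bias of the two flanking triangles on
planar surfaces.

### The flux chain

Per segment,

$$Q_e = 86400 \cdot K \cdot i \cdot A \cdot \sin D \quad
  [\mathrm{m^3\,day^{-1}}\ \text{per m of bank}],$$

where `K` (m/s) is the bank permeability, `i` the piezometric TIN slope,
`A` (m) the saturated cross-section thickness, and `D` the angle between
the groundwater and river downslope azimuths, normalised to
$(-180°, 180°]$. Three conventions are deliberate:

* **All directionality lives in $\sin D$.** The gradient is used as a
  magnitude; groundwater flowing toward the river gives $\sin D > 0$
  (gaining, aquifer → river, positive flux), away gives $\sin D < 0$
  (losing). Parallel flows ($D = 0$) exchange nothing.
* **`A` is a thickness in metres**, computed as groundwater head minus
  riverbed elevation and floored at zero (no saturated connection). Fluxes
  are per metre of bank, so the zone flux $Q_f = \sum Q_e L$ comes out in
  m³/day — the only dimensionally consistent reading of the chain.
* **The 86400 s/day factor** lives inside `segment_qe()`: in m³/s the
  exchange intensities are impractically small numbers.

Zone aggregation (`zone_qf()`) never mixes signs: gaining and losing
segments are summed separately with their bank lengths, mirroring
synthesis tables that print one gaining and one losing row per zone. Unit
flows `Qu = Qf/(L/1000)` are rounded half-away-from-zero to integers for
reporting, which is how published synthesis tables print them.

## 2. Stygobite indices

Stygobites are obligate groundwater dwellers; their presence in channel
sediments requires upwelling. From interstitial samples
(`site, KP, habitat, date, taxon, status, count`) the package computes,
per pooled unit: richness `S` (distinct stygobite taxa with positive
pooled count), relative richness `S% = 100·S/S_total`, and abundance.
Pooling decisions, both documented and deliberate: repeated visits to one
site are **summed**, not averaged (integer counts survive multi-campaign
pooling); the `S%` denominator is the total richness **of the same pool**.
An empty pool leaves `S%` undefined (flagged) rather than zero.

Sections are classified `upwelling` when at least one member site reaches
both cut-offs (`s_min = 2` taxa and `n_min = 10` individuals by default),
`none` when no member site holds any stygobite, `mixed` otherwise. The
literature describing such contrasts is qualitative; the defaults are
chosen so that clearly contrasting field patterns (15 individuals of
several taxa at one station versus entirely stygobite-free sections)
separate cleanly, and both cut-offs are echoed in every output row so
verdicts remain auditable. A reference list of the nine stygobite species
recorded in the study corridor ships in `inst/extdata`.

## 3. Macrophyte profiling and site indices

### Site classes

Wetland sites are classified on three environmental axes:

* **thermal stability** — the relative standard deviation (percent CV) of
  at least a year of monthly temperatures; groundwater-fed wetlands are
  thermally stable. Five classes.
* **phosphorus** — monthly PO₄ log₁₀-means plus the across-site z-score of
  log₁₀ mean substrate total P, summed per site. Five classes. Substrate
  replicates are averaged *before* the log; zero concentrations are
  shifted by half the smallest positive value before taking logs.
* **ammonia** — log₁₀ monthly means. Four classes (nitrate is deliberately
  not profiled: it correlates poorly with eutrophication for aquatic
  plants).

Classes are *equilibrated*: balanced-quantile bins whose site counts
differ by at most one when values are distinct. Tied values always share a
class — a tie spanning a provisional boundary falls entirely into the
lower class, a deterministic rule that a brute-force oracle reproduces in
the tests.

### Species profiles

For every species occurring in at least five sites, the abundance
distribution across classes is tested: a mean-centred Levene test at
α = 0.05 gates between one-way ANOVA (homogeneous variances) and
Kruskal–Wallis. α is a package default (config-exposed), as is the
Braun-Blanquet numeric conversion (r → 0.1, + → 0.5, 1–5 at face value).
The affinity profile is the per-class mean abundance normalised to sum 1;
degenerate species (constant everywhere) get flat profiles and are never
significant.

Phosphorus (5-class) and ammonia (4-class) profiles are combined into one
4-class trophic profile by **ordered-quantile correspondence**: class *j*
of *k* is identified with the quantile interval $[(j{-}1)/k,\ j/k]$ and
weight moves proportionally to interval overlap (`class_mapping_matrix()`,
columns summing to 1), then the two mapped profiles are averaged and
renormalised. The combination step in the field literature is qualitative;
the explicit matrix makes it reproducible and overridable.

### Site scores

The trophic level of a relevé is the argmax over classes of
$\sum_\text{species} \text{abundance} \times \text{weight}$ — linear in the
abundance codes, with exact ties resolved toward the more eutrophic class
and flagged. The groundwater-influence index counts species preferentially
occurring in groundwater-fed systems minus species intolerant of
stenothermic (thermally stable) water, floored at zero, with classes
0 → null, 1–4 → low, 5–9 → intermediate, >9 → high. Two conventions close
gaps in the verbal class definition: the value 4 (left unassigned verbally)
goes to "low", and the subtraction is oriented so that a *larger index
means more groundwater influence* — the verbal statement of the difference
reads the other way around, but contradicts its own class labels, and the
class semantics win. Both conventions are flagged in the output
(`floored`, echoed thresholds). Thermal preference categories themselves
come from the stability profiles: significant profiles centred in the two
most stable classes (weight-averaged class ≤ 2.25) are
groundwater-preferring; centred in the two most variable (≥ 3.75),
stenothermy-intolerant.

## 4. Overlay, verdicts, correlations

The three maps align on a user-supplied KP partition per bank (overlaps
rejected); each metric maps to the interval containing its KP midpoint,
absences stay explicit (`NA`), and inputs falling outside every interval
are reported in an `unassigned` attribute rather than dropped. Verdicts
reduce each present metric to a sign — hydraulic by the sign of `Qf`;
macrophyte influence and invertebrate categories through an explicit,
overridable reduction table (`verdict_reduction()`), since groundwater
influence classes express gains but published comparisons sometimes read
"no influence" as a losing signal. A zone is `convergent` when all present
signs agree, `divergent` when a gain and a loss co-occur, `partial` when
directional signs agree but some metric says "none", `incomparable` with
fewer than two metrics. Correlations are ordinary least squares on pairs
of zone metrics (qualitative classes encoded 0–3 by default), reporting
the squared Pearson correlation and the two-sided slope t-test p-value;
published R² values for this kind of comparison are not reproduced
numerically because the underlying zone table is not available — the
engine is instead validated against closed-form regression statistics.

## 5. The synthetic scenes: what they emulate, and what not

`generate_valley()` builds an analytic scene, not a flow model: a straight
river along `y = 0`, stage plane with a 5×10⁻⁴ downstream slope, and a
piezometric plane that matches the stage at the bank with a transverse
gradient `g` per reach (`+2×10⁻³` gaining, `−2×10⁻³` losing by default;
`K` of 1.3×10⁻³ and 3.9×10⁻⁴ m/s; saturated thickness `A₀ = 4.2` m).
Adjacent reaches blend linearly over a ±60 m band whose segments are
tagged `transition` and excluded from closed-form expectations. Because
each reach is exactly planar, every zone flux has the closed form
$86400\,K\,i\,A_0 \sin D \sum L$, the oracle the pipeline is tested
against (agreement within 1 % at ≥ 500 TIN points; observed ≈ 0.2 %). The
point layout mimics a piezometric survey: symmetric rows straddling the
bank (which cancels the triangle-centroid bias in sampled heads), columns
along reach boundaries, a border frame, and uniform scatter, with a
deterministic 10⁻⁵ m coordinate jitter to keep the triangulation away from
exact-lattice degeneracies. Optional Gaussian head noise is off by
default so oracle comparisons stay tight. What the scene does *not*
contain: curved channels, heterogeneous K within a reach, riverbed
clogging, transient stages — the generator validates the estimation
chain, not groundwater physics.

`generate_community()` emulates 36 wetlands on two gradients: temperature
series built from a sinusoidal annual cycle scaled to an exact target CV
(2–40 %), and chemistry (PO₄, substrate P, NH₃) increasing log-linearly
with a latent 4-level trophic status under small lognormal noise. Fifteen
thermal-indicator species sit on the realised stability classes and
fifteen trophic indicators respond to the latent trophic status itself —
species track the environment, not the analysis's bins — with expected
abundance decaying geometrically (`breadth = 0.3` per class step,
`mu_max = 30`) and negative-binomial counts (`size = 5`), coded to
Braun-Blanquet classes. The generator emits ground truth at two levels:
site class labels recomputed from the emitted tables with the package's
own class functions (hence exactly reproducible downstream), and each
species' *analytic* expected per-class argmax computed before any noise is
drawn. Under the default noise the full vegetation chain recovers planted
site classes at ≈ 90–100 % and species argmaxes at ≈ 90–100 % (the tests
assert ≥ 80 % and ≥ 90 % respectively, seed-fixed); recovery degrades
monotonically as niche breadth grows, which the tests also check. Real
relevé data are messier in ways the simulator does not attempt: species
interactions, spatial autocorrelation, uneven sampling effort — passing
recovery tests validates the estimation chain, not field performance.

`generate_stygofauna()` draws per-sample stygobite totals as Poisson with
mean equal to the zone's upwelling intensity, split multinomially over the
packaged species list, over an epigean background; zero-intensity zones
are exactly stygobite-free.

## 6. Numerical conventions and degenerate inputs

* Duplicate survey points with identical heads collapse silently;
  conflicting heads at one location are an error ("ambiguous elevation").
* Fewer than three points, or an all-collinear cloud, cannot form a
  surface ("degenerate point set").
* Angle normalisation maps differences to $(-180°, 180°]$; −180 is mapped
  to +180.
* `Qu` rounding is half-away-from-zero (4262.6 → 4263, −430.7 → −431).
* Zero-variance abundance vectors short-circuit the test gate with p = 1.
* All log transforms are base 10; zero concentrations are shifted by half
  the smallest positive value of the variable.
* Segments with `A = 0` (head below the riverbed) or an undefined flow
  angle contribute zero flux, not errors.
* Identical config and seed give byte-identical generator output and
  pipeline results; the run manifest isolates its timestamp on a single
  line so reproduced runs diff in one line only.

## 7. Problem sizes

The test-suite and acceptance scenes use a 4 km valley with ~900
triangulated points and 40 bank segments, 36 wetlands × 30 species, and
500 Monte-Carlo fauna samples for the intensity check — sizes at which the
closed-form agreement is already at the 0.2 % level and the whole suite
runs in well under a minute per property group.

## 8. Known limitations

The hydraulic chain assumes quasi-steady low-water conditions and a
spatially uniform `K` per segment; there is no riverbed-conductance or
clogging term, so fluxes through heavily silted reaches will be
overestimated. Aspect differences degrade gracefully but the method cannot
sign exchanges where either surface is locally flat. The biological
indices are ordinal and threshold-based; their verdict reductions are
config, not inference. Correlations across zones ignore spatial
autocorrelation and are reported raw, without multiple-testing correction,
matching the three-pair reporting practice they emulate.
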