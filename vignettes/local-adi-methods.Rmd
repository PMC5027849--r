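---
title: "Locally calibrated area deprivation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locally calibrated area deprivation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(localADI)
```

## The problem

An area deprivation index (ADI) summarizes the socioeconomic disadvantage
of a small geographic unit (a ZCTA, a census tract) as a single composite
over census variables, and is widely used to screen patients for social
determinants of health by the area they live in. The usual ADI is
percentile-ranked against a national or regional reference, so "deprived"
means deprived relative to the whole country or study region. In a
heterogeneous region, that global ranking hides locally deprived places: a
unit that is the poorest in an affluent county may sit well below the
regional cut even though, relative to its immediate surroundings — where
its residents actually seek care and services — it is strongly
disadvantaged.

This package implements the locally calibrated alternative: each unit's
ADI percentile is recomputed *within a moving window* of the units whose
centroids lie within a fixed radius (10, 20, 30 km by default), and the
top-percent dichotomization is applied window by window. It also
implements the validation machinery used to compare calibration scales —
indirect age standardization and age-stratified (Mantel–Haenszel) odds
ratios relating each scale's deprivation flags to hospitalization
outcomes — and a synthetic-geography simulator that reproduces the
statistical structure the comparison turns on.

## The composite score

The raw ADI of unit $u$ is

$$s_u = \sum_{v=1}^{17} w_v \, d_v \, z_{uv},$$

where $z_{uv}$ is the z-score of census variable $v$ across the reference
units, $d_v \in \{+1, -1\}$ orients every variable so larger means more
deprived (income, education attainment, white-collar share, home value,
rent, mortgage and owner occupancy are reversed), and $w_v$ are weights.
Choices made here:

* **Weights.** Operational ADIs use factor-analytic loadings that are not
  reproducible from public summaries. The default is equal weights
  $1/17$ on direction-adjusted z-scores — a transparent, reproducible
  baseline — and `adi_weights()` accepts any published loading vector.
* **Standardization** uses the population (divide-by-$n$) standard
  deviation, so the score is an exact deterministic function of the
  reference set. Variables are standardized within the study region; a
  zero-variance variable contributes 0 to every score and is warned
  about, rather than producing division by zero.
* **Percentiles** use the weak-inequality count definition
  $p_u = 100 \cdot \#\{v : s_v \le s_u\}/n$: ties share the highest
  applicable percentile and the maximum is always at 100. A region of
  all-equal scores therefore puts everyone at percentile 100.
* **Dichotomization** flags a unit when it is *strictly inside* the top
  `threshold_pct` percent: $p_u > 100 - t$. Under the count-based
  percentile this makes "top 15%" exact — with $n$ unique scores,
  $\lfloor 0.15\,n \rfloor$ units are flagged (15 of 100) — and keeps the
  all-ties region fully flagged. An inclusive cut ($\ge$) would flag 16
  of 100, which is not what a top-15% screen means.

## The moving-window calibration

Distances are centroid-to-centroid: great-circle (haversine, authalic
sphere radius 6371.0088 km) for lon/lat input, Euclidean for projected
input. The window of unit $u$ at radius $r$ contains every unit within
$r$ km, *including $u$ itself* — a percentile of a value within a set is
only well defined when the value belongs to the set, and self-inclusion
makes the $r \to \infty$ limit coincide exactly with the regional
calibration (a property the test suite checks). `include_self = FALSE` is
available for sensitivity analysis.

Two guards matter in practice:

* **Minimum window size** (`min_window`, default 10 units): a top-15% cut
  among a handful of neighbors is noise, so smaller windows keep their
  percentile but return an indeterminate flag (`NA`), and downstream
  association analyses exclude those units (reporting how many).
* **Radii** are arbitrary positive reals; 10/20/30 km are defaults chosen
  to bracket the scale of a local service environment.

## Validation statistics

Hospitalization outcomes are grouped into major ICD-9 diagnostic
categories by the 3-digit code root: respiratory 460–519, circulatory
390–459, mental disorders 290–319, and total. V- and E-codes fall outside
all categories by default (configurable), and multi-year tables are
averaged to a single period by the arithmetic mean with absent years
counted as zero (and warned about).

**Indirect age standardization.** With standard-population stratum rates
$\lambda_s$ and unit stratum populations $n_{us}$, the expected count is
$E_u = \sum_s \lambda_s n_{us}$, the standardized morbidity ratio is
$\mathrm{SMR}_u = O_u / E_u$, and the adjusted rate is $\mathrm{SMR}_u$
times the standard crude rate. Indirect (not direct) standardization is
used because unit-level stratum-specific rates in small areas are too
unstable to weight directly.

**Age-adjusted odds ratios.** The exposure is the unit-level deprivation
flag; the outcome is person-level hospitalization within the period. Per
age stratum the 2×2 cells aggregate events and remaining population over
flagged and unflagged units; averaged fractional counts are rounded half
up (banker's rounding would make cells depend on parity). The summary OR
is Mantel–Haenszel,

$$\widehat{OR}_{MH} = \frac{\sum_i a_i d_i / n_i}{\sum_i b_i c_i / n_i},$$

with the Robins–Breslow–Greenland variance of $\log \widehat{OR}_{MH}$
for the CI; strata contributing to neither sum are skipped and counted.
MH needs no iterative fitting, tolerates zero cells, and reduces exactly
to the crude OR for a single stratum. A grouped-binomial logistic fit
with stratum indicators (`logistic_or()`) is provided as an independent
cross-check, and crude ORs use the Haldane–Anscombe 0.5 correction only
when a zero cell is present. Confidence level defaults to 95%. Note that
with ecological exposure and very large denominators, CIs this narrow
overstate certainty about any individual-level effect; the package
surfaces this as a caveat, not a correction.

## The synthetic geography

The simulator exists so the whole pipeline — and specifically the
*scale sensitivity* of the association — can be studied without
restricted census extracts or hospital discharge records. It emulates the
statistical structure the comparison turns on, not any real geography.

Latent deprivation is $L(u) = \text{trend}(u) + A_p \cdot
\mathbf{1}[u \in \text{pocket}]$: a linear west–east gradient of total
range `trend_amplitude` plus disc-shaped pockets of excess deprivation.
The 17 census variables are monotone transforms of $L$ plus per-variable
Gaussian noise (`noise_sd`), each oriented by its deprivation direction
and mapped into its legal range (logistic link for percentages, log link
for dollar amounts and the income-disparity ratio, baselines at plausible
census magnitudes). Populations are log-normal around `mean_unit_pop`
(≈4000, ZCTA-like) and split into 18 five-year age bands by a
pyramid-shaped default profile.

Events per (unit, stratum) are $\mathrm{Binomial}(n_{us}, p_{us})$ with

$$\operatorname{logit} p_{us} = \operatorname{logit}(\text{baseline}_s)
  + \beta \, D(u),$$

where $D$ is the deprivation signal matched to the scenario's
`effect_scale` — the unit's latent deprivation centered on its 10-km
window mean (`local`), on the region mean (`regional`), or 0 (`none`) —
standardized across units so $\beta$ (`effect_log_or`) is a log-OR per SD
of the scale-matched signal. Binomial (not Poisson) events keep the
person-level outcome well defined for odds-ratio assembly. Baseline
hospitalization probabilities rise from ~3% in youth to 35% at 85+, with
an infancy bump; named categories are scaled fractions of the total
curve. The generator emits a single event period; the multi-year
averaging path is exercised with explicitly constructed tables.

Three presets share one geography family (grid layout at ~4 km spacing —
a ZCTA-like centroid density — `trend_amplitude` 3, `pocket_amplitude`
1.5, `noise_sd` 0.3): **`null`** (no effect; 200 units in a 60-km square,
6 pockets), **`regional-effect`** ($\beta = 0.7$ on the regional signal),
and **`local-pockets`** ($\beta = 0.7$ on the 10-km local signal; 400
units in an 80-km square, 10 pockets) — the headline demonstration.

Two geometric constraints, found during design, are worth recording:

* **Window population.** With the default `min_window = 10`, grid spacing
  must keep the 10-km windows above the floor; ~4 km spacing gives ≈21
  units per interior window (corner windows fall below the floor and are
  reported as indeterminate, exercising that path).
* **Pocket size versus flag capacity.** The top-15% cut gives each window
  a fixed flagging capacity. If a pocket covers more than ~15% of the
  matched (10-km) window — i.e. pocket radius above ≈4 km — part of every
  pocket interior is necessarily pushed into the *unflagged* arm at the
  matched scale, which attenuates the 10-km odds ratio below the
  coarser scales and destroys the phenomenon the scenario exists to
  display. Pocket radius 3 km (9% of the matched window) respects the
  capacity constraint; pocket density (~1 per 640 km²) makes larger
  windows span several pockets with different trend baselines, which is
  what degrades the 20- and 30-km calibrations relative to 10 km.

What the simulator does *not* emulate: real census marginal
distributions, irregular unit geometry and population-density gradients,
spatial autocorrelation of the noise, multi-factor deprivation structure,
migration between unit of residence and site of care. Passing tests on
this geography show the *method* behaves as designed (oracle-exact window
percentiles, calibrated null, recovery of a locally generated effect);
they do not show that any particular real region has a locally acting
deprivation effect.

## Problem sizes and numerical conventions

The simulation studies in the test suite and the acceptance script use
200-unit regions (500 null replicates for CI calibration) and 400-unit
regions (100 replicates for the scale-sensitivity study) — sizes at which
the Monte-Carlo error of a coverage estimate is below one percentage
point while a full study runs in well under a minute. Other conventions:
distances in km; CSV in UTF-8 with a header row, `.` decimal and a
leading `#` provenance comment line; GeoJSON per RFC 7946 (synthetic
planar coordinates are exported as-is with an explanatory note, since the
simulator's geometry is not georeferenced); all randomness flows through
the scenario seed, with the event stream decoupled from the geography
stream by a fixed offset so the same region can be re-dosed with
different effects.

## A compact example

```{r example, eval = FALSE}
sim <- simulate_scenario("local-pockets", seed = 1)
raw <- compute_raw_adi(sim$region$profile)
compare_scales(sim$region, raw, sim$events)
```

The returned table has one Mantel–Haenszel OR per calibration scale
(local 10/20/30 km and regional) for the same events; under this scenario
the 10-km local flags show the strongest association and the regional
flags the weakest.

## Known limitations

* The equal-weight composite is a stand-in for factor-analytic loadings;
  rankings are broadly, not exactly, comparable to operational ADIs.
* The ecological design carries its usual caveat: unit-level
  associations license no individual-level inference.
* Windows are radius-based only (no adjacency or k-nearest-neighbor
  option) and distances are centroid-to-centroid, which understates
  proximity for large irregular units.
* Whether a real analysis should include the central unit in its own
  comparison window is a genuine modeling choice; both are supported,
  and the default (inclusion) is the one with a well-defined percentile
  and an exact regional limit.
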