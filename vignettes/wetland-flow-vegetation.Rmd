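---
title: "Coupled flow–vegetation modelling of dryland wetlands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled flow–vegetation modelling of dryland wetlands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wetsim)
```

# The problem

Dryland floodplain wetlands persist through an extreme hydrological regime:
years of negligible flow punctuated by large flood pulses. Their vegetation
mosaics — reed beds fringing the channels, marsh further out, river red gum
woodland on the least frequently flooded ground, and dryland (chenopod)
vegetation beyond — expand and contract with this regime. Prolonged drought
lets terrestrial species invade wetland ground and defoliates the woodland;
floods re-wet the system and the wetland species re-establish from seed and
rhizome banks. Quantifying that cycle, and how it changes when inflows shrink
under a drying climate, requires inundation information at the patch scale
and at daily resolution over decades — beyond what either remote sensing or
lumped hydrology alone can supply.

`wetsim` couples three components at the water-year (June–May) scale:

1. a **quasi-2D storage-cell hydrodynamic model** that routes daily inflows
   over a raster domain and returns daily depth grids;
2. the **Minimum Inundation Index (MII)**: the percentage of each vegetation
   patch whose annual depth–duration regime meets the minimum water
   requirement of the patch's association;
3. a **rule-based vegetation transition model** driven by MII thresholds and
   consecutive-year counters, which feeds back on the flow by updating the
   Manning roughness of transitioned patches.

Climate scenarios rescale the inflow series by a proportionality factor
(1.0, 0.8, 1.2, 0.4 for the Current, Median, Upper-limit and Lower-limit
runs, i.e. runoff changes of 0, −20 %, +20 %, −60 %), and degradation is
tracked as the percentage of wetland area that is terrestrially invaded
non-woody vegetation plus woody vegetation in poor condition.

# The hydrodynamic model

Each raster cell is a storage element. Mass conservation is solved fully in
two dimensions,

$$A_{S,i}\,\frac{dz_i}{dt} \;=\; \sum_k Q_{k,i},$$

where $z_i$ is the water-surface elevation, $A_{S,i}$ the plan wetted area
(the full cell area when wet; channel width × cell length for a channel cell
below bank-full), and $Q_{k,i}$ the discharges exchanged with the orthogonal
neighbours. Momentum on each link is simplified to a one-dimensional Manning
friction law: at steady state every link satisfies

$$Q_{k,i} \;=\; \frac{A_{k,i}\,R_{k,i}^{2/3}}{n_{k,i}}
  \left(\frac{|z_k - z_i|}{\Delta x}\right)^{1/2}
  \operatorname{sign}(z_k - z_i),$$

with conveyance area $A$ and hydraulic radius $R$ evaluated at the *upwind*
depth above the link sill (the higher of the two bed elevations), wide-
rectangular geometry ($R \approx h$) on floodplain and bank links, the stored
rectangular section on channel–channel links, and the arithmetic mean of the
two cells' roughness. The square root of a signed head difference is handled
with the standard diffusive-wave convention shown above.

## Numerical scheme

The time stepper is the *local-inertial* relaxation of the Manning law: each
link carries a discharge state $Q$ updated as

$$Q^{+} = \frac{Q + g\,A\,\Delta t\,S}
  {1 + g\,\Delta t\, n^2 |Q| \,/\, (A R^{4/3})},
  \qquad S = \frac{z_a - z_b}{\Delta x},$$

whose fixed point is exactly the Manning discharge. This keeps the scheme
stable at the gravity-wave CFL step
$\Delta t \le \alpha\,\Delta x/\sqrt{g h_{\max}}$ (default $\alpha = 0.7$)
instead of the far smaller diffusive step a purely explicit Manning update
would need, while leaving the steady-state physics untouched: the
steady-flow verification below reproduces the Manning normal depth to
machine precision. Fluxes are evaluated simultaneously on all links, so they
are antisymmetric by construction, and a donor-cell limiter scales each
cell's gross outflow so volumes never go negative (the scaling applies the
same factor to both sides of a link, preserving antisymmetry). Volume is
therefore conserved to floating-point round-off; the daily mass-balance
report (inflow − outflow − loss − Δstorage) closes to ~1e-13 relative.

Further numerical choices, all exposed in `solver_config()`:

* `dt_min = 1`, `dt_max = 5` s by default — the sub-step range appropriate
  for fine channel networks. On the 90 m synthetic grids used throughout the
  package the CFL bound itself is 17–40 s, so long runs raise `dt_max` to
  60 s and let the CFL condition govern.
* wetting/drying: cells (and link sills) shallower than `dry_depth`
  (default 1 mm) carry no flux; dormant links lose their discharge memory.
* an **active-set** optimisation evaluates links only where at least one
  endpoint is wet, rebuilding the set every ten sub-steps with a one-cell
  halo so wetting fronts can advance; this makes drought periods nearly
  free. Sweep order is fixed row-major, so runs are bit-reproducible.
* `loss_mm_day`: a daily open-water loss (evapotranspiration plus
  infiltration) removed from wetted cells at the end of each day, bounded by
  the stored volume and reported in the mass balance. It defaults to 0 in
  the bare router — the conservation and equilibrium verifications use the
  pure scheme — and to 4 mm/day in the coupled vegetation loop, a typical
  dryland open-water loss. Without it, microtopographic depressions would
  stay ponded through multi-year droughts and the simulated hydroperiods
  would not respond to dry years at all.

Boundary conditions: upstream forcing is a daily discharge injected at the
designated inflow cells (or a stage held at them); the downstream boundary —
the whole last row, representing diffuse floodplain outflow — is held at a
daily stage, drained freely to bed level, or closed; all other boundaries
are no-flow.

# MII: from depth grids to patch-scale inundation

For every cell and water year the daily depths give an exceedance
(depth–duration) curve; a cell *complies* with a requirement
(`min_depth`, `min_duration`) when its depth is at or above `min_depth` for
at least `min_duration` of the year. Defaults: Common Reed needs about four
months (33 % of the year) at or above 0.02 m; Mixed Marsh/Water Couch and
River Red Gum need three months (25 %). The MII of a patch is the percentage
of its cells that comply — e.g. three compliant cells of five give
MII = 60 %. Two deliberate conventions (both configurable): duration counts
*total* days, not consecutive days, because an exceedance curve aggregates
non-contiguous wet spells; and both comparisons are `>=`, which makes
boundary cases deterministic. A patch is always judged against the
requirement of its current class; an invaded (terrestrial) patch is judged
against its remembered wetland class, which is what makes recovery
detectable.

# The vegetation transition rules

Six classes: Common Reed, Mixed Marsh/Water Couch, Terrestrial, and River
Red Gum in good, intermediate and poor condition (condition bands correspond
to <40 %, 40–80 % and >80 % apparent canopy mortality). Annual updates per
patch, with MII thresholds of 55 (Common Reed), 20 (Mixed Marsh) and 55
(RRG) percent:

* counters: a below-threshold year (`MII < threshold`, strictly) increments
  `consecutive_below` and zeroes `consecutive_above`; an above-threshold
  year does the reverse. Transitions never reset the counters — only an
  opposite-sign year does ("consecutive means consecutive").
* degradation: a non-woody patch becomes Terrestrial on its 3rd consecutive
  below year (remembering its class); good RRG degrades to intermediate on
  the 3rd ("more than two") and any RRG reaches poor on the 7th ("more than
  six") consecutive below year. Transitions are single-step per year.
* recovery: the reference behaviour — reed recovering the year after a
  flood, marsh two years after, woodland rapidly after re-wetting —
  constrains but does not dictate a rule, so the package adopts the simplest
  consistent one: an invaded patch reverts to its remembered class after
  `years_to_recover` (default 1) consecutive above-threshold years, and RRG
  condition improves one level per above-threshold year. A one-shot
  poor→good option exists (`rrg_one_shot_recovery`) because a direct jump
  after a single very wet year cannot be excluded; the default is stepwise.
* non-woody patches never transition into RRG classes, and originally
  terrestrial patches (no remembered wetland class) never transition at all.

After the annual update, every transitioned patch's cells take the Manning
roughness of the new class (`roughness_feedback()`), so vegetation change
feeds back on next year's flow. The class→roughness table is a set of
plausible literature values (reed 0.12, marsh 0.08, terrestrial 0.04, RRG
0.12/0.09/0.06 by condition, channel 0.035 s m^-1/3) and is fully
configurable — calibrated site-specific values should replace it when
available.

# Threshold calibration

`calibrate_thresholds()` re-casts the trial-and-error threshold selection as
an exhaustive search: every candidate (reed, marsh, RRG) triple is run
through the transition engine and scored by the mean area-weighted overall
accuracy of its predicted patch classes against reference maps at the check
years; ties break toward lower thresholds. The search runs on a *fixed*
per-class MII array computed once under the initial-condition roughness
(feedback frozen): re-running the hydrodynamics inside the search loop would
multiply its cost by the candidate count while changing the scores only
through the (second-order) roughness feedback. The package validates the
operation by parameter recovery: reference maps generated by the known rule
set 55/20/55 on a 10-year synthetic flow ladder are fed back to the search,
which must return 55/20/55 uniquely. Designing that ladder is instructive:
years must *straddle* the candidate thresholds (flow levels that leave some
patches with MII between neighbouring candidates), because uniformly wet or
uniformly dry years cannot distinguish one threshold from another.

# What the synthetic generators emulate — and what they do not

`make_dem()` builds a valley plane (slope 2e-4) with an incised channel
(1 m, 20 m wide) and uncorrelated Gaussian microtopography (default 5 cm);
`make_initial_vegetation()` lays the classes in lateral distance-to-channel
bands and partitions them into rectangular patches of 20–840 cells,
mirroring the observed patch-size range; `make_hydrograph()` produces
365-day water years (leap days dropped, so water-year arithmetic is exact)
with a perennial base flow (2 m³/s), an annual winter–spring half-sine pulse
(peak 20 m³/s over 180 days), flood pulses (peak 80 m³/s) in designated
years and a multiplicative reduction (default 0.25) in drought years. The
default 22-year series places floods in water years 10 and 20 with a
nine-year drought between them, echoing a record with two major floods
bracketing the Millennium Drought. All generators are pure functions of
their spec and seed.

These synthetics capture the *structure* the model responds to — an
elevation gradient, a channel that confines low flows, hydroperiod contrast
between band positions and year types — but not real-data features:
correlated LiDAR noise, meandering channels, anabranches, rainfall-driven
local runoff, seasonality changes, or ENSO-like interannual spectra. Tests
passing on them demonstrate internal correctness and qualitative behaviour
(degradation under drought, recovery after floods, ordering across
scenarios), not site-specific predictive skill, which requires real DEMs,
gauge records and vegetation surveys.

# Verification and problem sizes

The test suite verifies, among others: exact closed-basin volume
conservation; level-pool equilibrium of a two-cell basin from z = (1, 0) m
to (0.5, 0.5) m; steady uniform flow on a sloped plane against the Manning
normal depth $h = (n q / \sqrt{S})^{3/5}$ (within 5 %; in practice exact);
link-discharge antisymmetry; MII equivalence with brute-force day counting
and monotonicity under pointwise-deeper stacks; the five-cell MII = 60 %
worked example; the 3rd/7th-year transition timing; threshold parameter
recovery; and non-increasing peak degradation across flow factors
0.4/0.8/1.0/1.2. Simulation sizes are chosen for fast, deterministic tests:
hydraulic oracles on grids up to 15×5, the coupled behaviour suite on a
10×9 valley over 2–7 years, parameter recovery on a 20×20 grid over 10
years, and the scenario ordering on a 12×9 grid over 10 years. The analysis
scripts run the full 22-year Current scenario on a 20×17 valley (3.1 km²
at 90 m cells).

# Known limitations

* No groundwater, soil moisture, seed-bank depletion, or local facilitation
  mechanisms: the water regime is the sole driver, applied at patch scale.
* The open-water loss is a single constant rate, not a seasonal
  evapotranspiration signal.
* Channel–floodplain exchange is a Manning link over the bank crest; no
  weir-type bank overflow formula.
* Non-woody↔non-woody transitions (reed↔marsh) are narrated in observations
  but have no established rule; an optional mechanism exists but is disabled
  by default, so simulated reed/marsh interchange is absent unless enabled.
* Scenario monotonicity (less water ⇒ no less degradation) is guaranteed
  only with roughness feedback frozen; with feedback enabled it is expected
  but not provable, since roughness changes alter routing.
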