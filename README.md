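# wetsim — coupled flow–vegetation simulation for dryland wetlands

Dryland floodplain wetlands cycle between drought contraction and flood-pulse
recovery. Whether their vegetation persists depends on the *inundation
regime* each patch experiences — how deep, how long, how often — which
neither satellite snapshots nor lumped hydrology resolve. `wetsim` is for
ecohydrologists who need that link made explicit: it couples a quasi-2D
storage-cell flood-routing model to an annual, rule-based vegetation
transition model through the **Minimum Inundation Index (MII)**, and runs
climate scenarios by rescaling the inflow record.

The core pieces, in the field's standard notation:

* **Hydrodynamics** — raster storage cells exchange discharge over links
  while conserving mass exactly:
  `A_Si dz_i/dt = Σ_k Q_ki`, with each link at steady state obeying Manning's
  law `Q = (A R^(2/3) / n) (|Δz|/Δx)^(1/2) sign(Δz)` (upwind conveyance
  depth; CFL-adaptive sub-stepping; daily inflow in, daily depth grids out).
* **MII** — for each patch and June–May water year, the percentage of cells
  whose depth–duration exceedance curve meets the class's minimum water
  requirement (Common Reed: ≥ 0.02 m for ≥ 33 % of the year; Mixed
  Marsh/Water Couch and River Red Gum: ≥ 0.02 m for ≥ 25 %).
* **Vegetation rules** — MII thresholds 55/20/55 % (reed/marsh/RRG) with
  consecutive-year counters: non-woody patches turn terrestrial on the 3rd
  consecutive below-threshold year; good RRG degrades to intermediate on the
  3rd and to poor on the 7th; recovery reverses these after re-wetting.
  Transitioned patches update their Manning roughness, feeding back on the
  flow.
* **Scenarios & evaluation** — inflow factors 1.0/0.8/1.2/0.4
  (Current/Median/Upper/Lower runoff projections), degraded-area fraction and
  duration, overall accuracy and Cohen's κ for maps, PBIAS/NSE/RSR for gauge
  series.

Everything runs on self-contained synthetic inputs (sloped valley with an
incised channel, banded vegetation mosaic in 20–840-cell patches, multi-year
daily hydrographs with drought and flood blocks), so the whole pipeline is
testable without downloads.

## Worked example

A 22-water-year run (1991–2012 labels) on a 20 × 17-cell synthetic valley
(90 m cells, 2.75 km²), with floods in water years 10 and 20 bracketing a
nine-year drought:

```r
library(wetsim)
dom <- make_dem(domain_spec(n_rows = 20, n_cols = 17, seed = 11))
veg <- make_initial_vegetation(dom)
hg  <- make_hydrograph(hydrograph_spec())      # 22 years, drought WY11-19
run <- run_coupled(dom, hg, veg)
colSums(run$extent[c("CommonReed", "MixedMarsh"), ])  # non-woody extent
max(run$degraded_pct)
```

Output from this exact run (`analysis/03_coupled_current.R`):

```
Non-woody wetland extent (cells) by water year:
1991 1992 1993 1994 1995 1996 1997 1998 1999 2000 2001 2002 2003 2004 2005 2006
 180  180  160  160  160  160  160  160  160  180  180  180   20   20   20   20
2007 2008 2009 2010 2011 2012
  20   20   20  180  180  180
RRG condition (good/intermediate/poor) at the drought peak (WY2007):
   RRG_good RRG_intermediate  RRG_poor
          0                0       120
Peak degraded fraction: 93.3% (WY2007); final: 0.0%
```

Read: the mosaic stays healthy through the wet 1990s (one marginal reed
patch dips in 1993 and recovers with the 2000 flood); on the 3rd drought
year terrestrial vegetation invades the reed and marsh bands (180 → 20
cells, the surviving 20 being the channel-fringing patch); River Red Gum
reaches poor condition on the 7th dry year; the WY2010 flood drives full
recovery within two years. `run$log` lists every transition
(year, patch, from, to) and replays exactly to the final state.

The numbered scripts under `analysis/` run the full study line: input
generation, hydrodynamic verification (mass-balance residual ~1e-15 of
inflow; gauge skill vs noisy pseudo-observations PBIAS 0.11 %, NSE 0.996),
the coupled Current run above, threshold calibration by parameter recovery
(the search returns the generating 55/20/55 uniquely out of 27 candidates),
and the four climate scenarios (peak degraded fraction 57.1 % for the
Lower/Median/Current factors vs 28.6 % for Upper on the scenario testbed).
Tables land under `results/`.

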