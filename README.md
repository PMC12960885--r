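# coastbc

Mapping coastal blue carbon habitats and scoring their exposure to
land-based human pressure, on a regular planar grid.

Blue carbon (BC) habitats — seagrass meadows, other rooted submerged
macrophytes, open wetlands (salt marshes, reed/bullrush beds) and coastal
forested wetlands — are efficient organic-carbon sinks, and knowing where
they are and how exposed they are to human activity is the starting point
of any coastal carbon management plan. `coastbc` implements that workflow
as composable, tested R functions:

- **Coastal domain delimitation** — land with elevation ≤ 2 m reachable
  from the sea through connected low-lying cells (roads and other barriers
  block the path; lakes are excluded and are not a marine connection),
  plus the submerged area where satellite mapping was feasible.
- **Habitat compilation** — merge wetland classes from a land-cover raster
  and a protected-area habitat inventory (inventory wins on conflict),
  filter submerged aquatic vegetation (SAV) to cells detected in ≥ 4 of 5
  years, split SAV into seagrass vs. other rooted macrophytes by regional
  rule and modelled-seagrass overlap, and patchify into contiguous units.
- **Pressure index** — per habitat patch, three components each on a 0–4
  scale: distance class to the nearest agricultural land (≤100 m → 4,
  ≤400 → 3, ≤1000 → 2, ≤5000 → 1, else 0), the innermost urban buffer zone
  intersected (same classes), and the modified-land proportion of the
  linked coastal drainage basin (≥80% → 4 … <20% → 0; patches spanning
  basins take the unweighted mean, patches within 500 m link to the
  nearest basin, farther ones are excluded from this component). The
  cumulative impact value `v_agri + v_urban + v_basin` ranges 0–12;
  values **≥ 6** flag higher-level pressure.
- **Protection overlap** — per-patch protected/unprotected area split,
  area accounting per habitat class and subbasin (integer percentages,
  half away from zero), and a pooled-variance Student's *t* test of
  cumulative pressure inside vs. outside protection (protected group
  first, so lower pressure inside gives *t* < 0).
- **Quality control** — field points are correctly mapped when a patch of
  their observed class lies within 30 m (boundary distance, inclusive);
  plus balanced-accuracy selection of the SAV persistence threshold.
- **Synthetic landscapes** — `generate_landscape()` builds complete scenes
  (coastline, elevation, basins, habitat blobs, stressors placed at
  requested distance classes, protected areas, noisy field points) with a
  construction-time ground-truth record, so the whole pipeline is testable
  without restricted national data layers.

Spatial primitives (exact Euclidean distance transform, flood fill,
connected-component labelling) are implemented in C++ via Rcpp; every one
is checked against a brute-force R oracle in the test suite.

## Worked example

```r
library(coastbc)

sim <- simulation_config(seed = 42, grid_width = 300, grid_height = 300,
                         basin_modified_props = c(0, 20, 45),
                         stressor_layout = data.frame(
                           type  = c("urban", "agriculture", "urban", "agriculture"),
                           class = c(4L, 4L, 2L, 3L),
                           realm = c("land", "land", "submerged", "submerged")))
res <- run_pipeline(pipeline_config(simulation = sim))
res
#> Blue carbon mapping pipeline result
#> <coastal_domain> land 0.8996 km2 (<= 2 m), submerged 1.2000 km2, combined 2.0996 km2
#>   21 habitat patches
#>   total habitat 0.0440 km2 (2% of coastal area); 77% under higher-level pressure; 33% protected
#>   field-point accuracy 100.0% (60 of 60)
#>   pressure inside vs outside protection: t = -1.148, df = 10, p = 0.2779
```

The 3 km × 3 km scene has a 2.1 km² coastal domain (0.9 km² of low-lying
land, 1.2 km² of mappable seabed). Of the 0.044 km² of compiled habitat,
77% sits at cumulative pressure ≥ 6 — the land patches were deliberately
given nearby urban/agricultural stressors (distance class 4), the
submerged ones more distant ones — and 33% lies inside protected areas.
With zero GPS noise every field point validates (100%). The per-class
summary follows the published table conventions:

```r
s <- res$summary
s[s$subbasin == "all", c("habitat_class", "total_area_km2", "area_pct",
                         "high_pressure_pct", "protected_pct")]
#>             habitat_class total_area_km2 area_pct high_pressure_pct protected_pct
#>          forested_wetland         0.0104        0               100            30
#>              open_wetland         0.0108        1               100            47
#>  other_rooted_macrophytes         0.0125        1                34            34
#>                  seagrass         0.0103        0                81            19
#>                       all         0.0440        2                77            33
```

Lower-level pieces are directly usable:

```r
classify_distance(c(80, 350, 900, 4000, 9000))
#> [1] 4 3 2 1 0
cumulative_pressure(2, 2, 2)
#>   v_agri v_urban v_basin cumulative high_pressure
#> 1      2       2       2          6          TRUE
```

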