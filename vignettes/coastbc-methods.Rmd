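---
title: "Mapping coastal blue carbon habitats and their exposure to land-based pressure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping coastal blue carbon habitats and their exposure to land-based pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coastbc)
```

## The problem

Vegetated coastal habitats — seagrass meadows, other rooted submerged
macrophytes, open wetlands (salt marshes, reed and bullrush beds) and
coastal forested wetlands — sequester and store large amounts of organic
carbon ("blue carbon"). Managing them requires three things this package
provides in one tested pipeline:

1. a **coastal analysis domain**: which land and which submerged area count
   as "coastal" for the accounting;
2. a **habitat map** compiled from heterogeneous sources (a national
   land-cover raster, a quality-controlled habitat inventory inside
   protected areas, a multi-year satellite layer of submerged aquatic
   vegetation, and a modelled seagrass distribution);
3. a **pressure index** translating the proximity and extent of
   agricultural and urban land into a relative exposure score per habitat,
   plus protected-area overlap accounting and field-point validation.

Because the national input layers are not redistributable, the package
ships a synthetic landscape generator that emulates all of them with known
ground truth, so every stage is testable end to end.

## Data model

All layers live on one planar grid in metres (`bc_raster`: a matrix plus a
cell size, 10 m by default, matching the national products the design
follows). Vector-type inputs (basins, urban areas, protected areas, the
habitat inventory) are represented as label or boolean rasters on the same
grid; at 10 m resolution this loses nothing the analysis uses, and it keeps
the package free of a GDAL dependency. Habitat patches are connected
components of the class raster (4-connectivity by default, 8 available),
carried as a data frame with a list-column of cell indices.

## Coastal domain

Coastal land is every cell with elevation at or below 2 m (ties included:
"2 m or less") that is reachable from a sea cell through a connected path
of such cells. Reachability, not distance, operationalises "directly
adjacent to the sea": it excludes low-lying enclaves severed from the sea
by roads or other barriers with the same mechanism. Lake cells neither
count as coastal land nor carry the flood fill — a lake is not a marine
connection — so habitat reachable only through a lake stays excluded. The
submerged domain is the satellite mapping-feasibility mask, taken as given.
No hard inland distance cap is imposed; the limited extent of the ≤ 2 m
fringe is emergent.

## Habitat compilation

Wetland classes come from the union of the land-cover raster and the
inventory layer; where the two disagree on the class at a cell the
inventory wins, because it is the quality-controlled source within
protected areas (the reconciliation rule is ours — the sources' precedence
is not documented). Submerged vegetation is filtered by persistence: a cell
must be detected in at least 4 of the 5 observation years (the default; the
threshold-selection routine in `select_persistence_threshold()` scores all
five candidates by balanced accuracy against reference points, ties going
to the stricter threshold). Retained cells split into *seagrass* vs *other
rooted macrophytes* by a per-region rule: where a modelled seagrass surface
exists, overlap decides; northern regions map everything to other
macrophytes, southern and west-coast regions to seagrass. Every retained
cell gets exactly one label — mixed meadows exist in reality but the map
carries a single class per cell.

## The pressure index

Three components, each on a relative 0–4 scale:

| component | basis | classing |
|---|---|---|
| `v_agri` | nearest distance to agricultural land | ≤ 100 m → 4; ≤ 400 → 3; ≤ 1000 → 2; ≤ 5000 → 1; else 0 |
| `v_urban` | innermost urban buffer zone intersected | identical distance classes |
| `v_basin` | % agricultural + urban area of the linked coastal drainage basin | ≥ 80% → 4; ≥ 60 → 3; ≥ 40 → 2; ≥ 20 → 1; else 0 |

The cumulative impact value is their sum (0–12); values of 6 and above —
half the maximum or more — flag *higher-level pressure*, and the band is
inclusive at 6. Numerical conventions we fixed where the source tables are
ambiguous: the four buffer figures are read as radial distance thresholds
in metres; distance classes are closed on the upper end (exactly 400 m is
class 3) and proportion classes closed on the lower end (exactly 40% is
class 2); patch distance is the minimum from any part of the patch (the
most-exposed reading). The buffer-ring and nearest-distance constructions
of `v_urban` are provably equivalent and both are implemented
(`urban_pressure()` via an exact Euclidean distance transform,
`urban_pressure_rings()` by direct pairwise distances); their agreement is
a standing test.

Basin linking: a patch inside one basin takes that basin's value; a patch
spanning several takes the unweighted mean of the basins touched, kept
fractional — no rounding is applied anywhere in the index, and the ≥ 6
comparison is unchanged. A patch outside all basins (submerged habitats,
typically) takes the nearest basin's value if within 500 m, and is
otherwise excluded from this component (`v_basin = 0`, flagged). Land and
submerged habitats run through identical scoring rules; the realm is
recorded on output.

## Protection overlap and the t test

Patches straddling a protected-area boundary contribute their split areas
to the accounting, not a whole-patch label. For the inside/outside pressure
comparison a patch counts as protected when more than half its area is; the
test is the classical pooled-variance two-sample Student's t (two-sided),
with the protected group first so that lower pressure inside protection
gives a negative t. The default sampling unit is the stratum (mean
cumulative value per habitat class × subbasin × protection cell), which
keeps the degrees of freedom small and the observations closer to
exchangeable than raw patches; patch-level testing is available. Identical
constant groups return t = 0, p = 1 by convention.

## Quality control

A field point is correctly mapped when a patch of its observed class lies
within 30 m — boundary distance, inclusive at exactly 30 m, measured to the
cell square rather than the cell centre — covering GPS and map uncertainty.
Matching is class-aware by default (distance to the nearest patch of the
observed class); a class-blind mode exists for sensitivity checks.

## The synthetic generator

`generate_landscape()` builds: a vertical coastline with a low (≤ 2 m)
coastal fringe (default 300 m) and land rising inland; a submerged
feasibility strip (default 400 m); habitat patches as seeded region-grown
blobs (so patchification is exercised on irregular shapes), mutually
separated by a one-cell halo; per-cell SAV year counts drawn as
Binomial(5, p) inside true submerged patches (default p = 0.9, giving ≈ 92%
retention at the 4-of-5 filter — satellite detection of shallow vegetation
is good but not perfect); three horizontal region bands emulating the
latitudinal classification rule; drainage basins as contiguous row bands
whose modified-land proportion is achieved by painting agriculture from the
inland edge; urban/agricultural stressor blocks placed to hit requested
distance classes exactly (verified at construction by direct pairwise
distance; an unachievable request is a configuration error); protected
areas as whole patches plus a one-cell halo; and field points sampled
uniformly from habitat cells with isotropic Gaussian positional noise.

The truth record is filled from construction bookkeeping — never by running
the mapping pipeline. Because stressors interact across patches (a block
placed for one patch is also near its neighbours, and basin fill is itself
agricultural land), the per-patch truth distances are established by a
direct all-pairs check against every stressor cell, which the test suite
re-derives independently.

What the generator does *not* emulate: realistic bathymetry or salinity
gradients, satellite reflectance, false-positive SAV detections, curved
coastlines, or spatially autocorrelated land-cover noise. Passing tests
therefore demonstrate the correctness of the algorithms under controlled
geometry, not map accuracy on real national data.

## Problem sizes and numerical choices

The test suite runs scenes up to 200 × 200 cells (2 km × 2 km at 10 m) and
verifies the compiled primitives — exact Euclidean distance transform,
flood fill, component labelling — against brute-force R oracles on 100
randomised scenes; recovery scenes (150 × 270) are constructed so the
expected high-pressure fraction per class is exact by design (equal-sized
patches in a heavily modified vs a lightly modified basin, separated by a
≥ 1 km unmodified buffer basin). These sizes exercise every code path while
keeping the default check fast; nothing in the algorithms is
size-dependent. Distances are centre-to-centre between cells and exact (no
raster approximation beyond the grid itself); the distance transform is the
two-pass parabolic-envelope algorithm. All areas are reported in km², all
distances in metres; printed percentages round half away from zero to match
the conventions of published accounting tables.

## Known limitations

- Raster-native geometry: sub-cell polygon boundaries are not represented;
  area splits are exact at cell resolution only.
- The basin component inherits whatever subjectivity the basin polygons
  carry; only the 500 m link radius and the class table are principled
  here.
- The index deliberately ignores water quality, eutrophication,
  hydrological connectivity and erosion; it is a proximity proxy, not an
  impact model.
- The t test's sampling unit in the original analysis is not documented;
  stratum-level testing is our default and the df will generally differ
  from published values.
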