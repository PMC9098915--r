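# hpindex — Habitat Protection Indexes for coastal and marine conservation

`hpindex` implements a standardized, reproducible workflow that measures how
much of each coastal or marine habitat (warm- and cold-water corals, knolls
and seamounts, mangroves, saltmarshes, seagrasses, or any mapped habitat)
lies within protected or conserved areas (PCAs — protected areas plus other
effective area-based conservation measures, OECMs). It is aimed at
conservation scientists and national statistical offices tracking
area-based targets such as the 30%-by-2030 goal, and at anyone who needs
per-jurisdiction habitat-protection statistics from WDPA/WD-OECM-style
records and habitat extent layers.

## The indexes

All quantities are pixel counts on an equal-area 1 km² grid (Behrmann
cylindrical equal-area projection; a cell is occupied iff a polygon covers
its center — the centroid rule). For jurisdiction *j* and habitat *h*, let
*E*<sub>j,h</sub> be the habitat pixels in the jurisdiction,
*P*<sub>j,h</sub> the habitat pixels that also fall in PCAs, and
*E*<sub>glob,h</sub> = Σ<sub>j</sub> *E*<sub>j,h</sub> the global extent
over all retained jurisdictions (areas beyond national jurisdiction, ABNJ,
count as one extra jurisdiction). Then, per habitat:

* **LPHPI** (Local Proportion of Habitats Protected Index):
  *P*<sub>j,h</sub> / *E*<sub>j,h</sub> — how much of its own habitat a
  jurisdiction protects;
* **GPHPI** (Global Proportion of Habitats Protected Index):
  *P*<sub>j,h</sub> / *E*<sub>glob,h</sub> — how much a jurisdiction
  contributes to the habitat's global protection;
* **targeted score**: GPHPI<sub>j,h</sub> − τ·*E*<sub>j,h</sub>/*E*<sub>glob,h</sub>
  with τ = 0.3 by default — positive exactly when the jurisdiction protects
  more than the fraction τ of its habitat, scaled by its global share.

A jurisdiction's reported LPHPI/GPHPI/targeted values are the unweighted
means over the habitats *present* there (*E*<sub>j,h</sub> > 0); absent
habitats never enter an average. Both indexes range from 0 to 1.

The pipeline covers the full path from raw vector layers to index tables:
WDPA-style record cleaning (drop UNESCO Man and the Biosphere reserves,
records with status "Proposed"/"Not Reported", and point records without a
reported area; buffer remaining points to circles of their reported area),
equal-area projection, centroid-rule rasterization, jurisdiction zones with
an ABNJ remainder, zonal pixel counting, and index aggregation — plus a
synthetic-world generator with exact vector-geometry ground truth for
validation.

## Worked example

Index arithmetic from a count table (the first zone mirrors a real pattern:
a remote island whose 50 pixels of knolls-and-seamounts all fall inside a
protected area and which hosts no other mapped habitat — its averaged
LPHPI is exactly 1):

```r
library(hpindex)
counts <- data.frame(
  zone_id = rep(c("BVT", "NOR"), each = 2),
  habitat = rep(c("knolls-and-seamounts", "saltmarshes"), 2),
  E = c(50L, 0L, 1200L, 800L),
  P = c(50L, 0L, 300L, 120L))
aggregate_indexes(per_habitat_ratios(counts), tau = 0.3)
#> Habitat protection indexes (tau = 0.3, 2 zones)
#>  zone_id n_habitats LPHPI GPHPI targeted
#>      BVT          1   1.0 0.040    0.028
#>      NOR          2   0.2 0.195   -0.099
```

`BVT` protects 100% of its (single, tiny) habitat but contributes only 4%
of the global protected extent; `NOR` protects 20% on average, short of the
30% target (negative targeted score) despite a large global contribution —
precisely the local-vs-global distinction the two indexes are designed to
separate.

The same numbers fall out of the full raster pipeline on a synthetic world
whose true protection fractions are known exactly:

```r
w <- generate_world(synth_world_spec(seed = 1, world_km = c(300, 300),
  n_jurisdictions = 3, n_habitats = 2, n_patches = 5,
  patch_area_km2 = c(40, 250)))
grid <- build_grid(w$extent, cell_size = 1000, crs = "planar")
pca  <- prepare_pca_raster(w$pca, filter_rules(), grid)
attr(pca, "log")$dropped_by_reason
#>                mab             status point_without_area
#>                  4                  8                  4
hr <- lapply(w$habitats, prepare_habitat_raster, grid = grid)
pr <- lapply(hr, protected_habitat_raster, pca = pca)
zs <- build_zoneset(w$jurisdictions, w$ocean, grid, crs = "planar")
aggregate_indexes(per_habitat_ratios(zonal_counts(hr, pr, zs)), tau = 0.3)
#> Habitat protection indexes (tau = 0.3, 4 zones)
#>  zone_id n_habitats  LPHPI   GPHPI  targeted
#>     ABNJ          2 0.6227 0.15436  0.082534
#>      Z01          2 0.5000 0.12279  0.048419
#>      Z02          2 0.1256 0.03696 -0.029101
#>      Z03          2 0.3782 0.09515  0.007413
```

The 16 decoy records (proposed areas, MAB reserves, points without area)
were dropped by the cleaning rules before rasterization; `Z01`'s LPHPI of
0.5000 is the mean of its two habitats' true protection fractions (0 and 1
by construction).

The same run is available from a shell via the thin CLI wrapper
(`inst/cli/hpindex.R`) driven by a YAML config with subcommands
`validate`, `synth`, `prepare-pca`, `prepare-habitats`, `zones`, `counts`,
`indexes` and `run`.

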