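---
title: "Measuring habitat protection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring habitat protection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model behind `hpindex`, the parameters that
matter, the numerical conventions the package fixes where standard practice
is silent, and what the synthetic validation worlds do and do not show
about real data.

## The measurement model

The object being measured is a proportion of *mapped habitat extent* lying
inside *protected or conserved areas* (PCAs: formal protected areas plus
OECMs), per jurisdiction and per habitat. Everything is reduced to counts
on a common equal-area lattice:

1. **Cleaning.** PCA records are filtered with the conventions of
   protected-area coverage statistics: UNESCO Man and the Biosphere
   reserves are dropped (their wide zonation over-states protection), as
   are records with status `Proposed` or `Not Reported` and point records
   without a reported area. Each dropped record carries exactly one primary
   reason, tested in the fixed order MAB → status → point-without-area, so
   audit counts are well defined. Missing status is read conservatively as
   `Not Reported`. Surviving point records are buffered to circles whose
   polygon area equals the reported area.
2. **Projection.** All geometries are projected to an equal-area plane.
   Real-world input declared as `longlat` goes through the Behrmann
   cylindrical equal-area projection, implemented on the WGS84 ellipsoid
   via the authalic `q` function, so areas are preserved exactly up to
   floating point; synthetic worlds declare an already-planar CRS and skip
   the transform. Polygon edges are densified (default 0.05°) before
   projection so long graticule-straight edges stay area-faithful.
3. **Rasterization.** Polygons become binary presence rasters under the
   *centroid rule*: a cell is occupied iff its center lies in the polygon
   union. Layers are merged with logical OR (overlap never double-counts)
   and habitat × PCA intersection is logical AND. On an equal-area grid,
   `pixel_count × cell_area` is then an unbiased area estimate whose error
   comes only from boundary cells.
4. **Zones.** Jurisdiction zones are the union of a territory's land and
   its EEZ; landlocked, disputed and joint-regime entries are removed
   before analysis. Ocean cells assigned to no jurisdiction form the ABNJ
   zone, which participates in all tables as an ordinary zone.
5. **Indexes.** With `E`, `P` the habitat and protected-habitat pixel
   counts and `E_glob` the per-habitat sum over all retained zones:
   `lphpi = P/E`, `gphpi = P/E_glob`,
   `targeted = gphpi − τ·E/E_glob`. Zone-level values are unweighted means
   over habitats present in the zone (`E > 0`); absent habitats are *not*
   zeros, they are excluded. Zones with no habitat present are omitted.

Useful identities (all enforced by tests): `gphpi = lphpi · E/E_glob`; the
zone-sum of `gphpi` equals the habitat's global protected proportion;
`targeted > 0 ⟺ lphpi > τ`; all averaged indexes lie in [0, 1].

## Parameters

| parameter | default | units | why |
|---|---|---|---|
| `cell_size` | 1000 | m | 1 km² pixels: fine enough that rasterized areas track vector areas to well under 0.5%, coarse enough for global runs |
| `tau` | 0.3 | fraction | the 30% area-based coverage target; configurable so the same workflow serves any target |
| `default_point_area_km2` | 1 | km² | a habitat point with no reported area is taken to occupy one cell; a reported area of 0 is read as "not assigned" and falls back to this default |
| `excluded_statuses` | `Proposed`, `Not Reported` | — | exact, case-sensitive matching against a configurable list |
| `mab_pattern` | `"Man and( the)? Biosphere"` | regex | catches both phrasings that appear in designation text, case-insensitively |
| `densify_deg` | 0.05 | degrees | max lon/lat edge length before projection |

## Numerical conventions

These are points where the standard workflow description is silent; the
package fixes one deterministic convention for each.

* **Grid alignment.** The origin is the upper-left corner of the analysis
  extent; rows grow southward. Cell (i, j) has center
  `(origin_x + (j−0.5)·cell_size, origin_y − (i−0.5)·cell_size)`. Grid
  dimensions are ceilings of extent/cell_size, so the grid always covers
  the extent.
* **Centroid tie-break.** A cell center lying exactly on a polygon
  boundary counts as *inside* (detected with a relative tolerance of 1e-9
  of the ring's coordinate scale). Random real-world geometry almost never
  triggers this; constructed grid-aligned geometry does, and the inclusive
  rule makes those cases reproducible.
* **Even-odd containment.** All containment uses the even-odd rule, which
  is well defined for multi-ring and even self-intersecting polygons.
  Holes are just additional rings; MultiPolygons flatten to multi-ring
  polygons. Because of this, geometry "repair" is unnecessary for
  rasterization: validation is structural only (≥3 finite vertices,
  nonzero area) and structurally broken features are rejected and logged
  by id rather than silently fixed.
* **Circle buffering.** Points are buffered *after* projection, as planar
  circles: regular 128-gons whose vertex radius is inflated so the polygon
  area equals the requested area exactly (an inscribed n-gon would
  undershoot by (2π/n)²/6 ≈ 0.04%). Geodesic buffering is a non-goal.
* **Zone overlap.** If jurisdiction polygons overlap, a cell goes to the
  zone earliest in the stable sort of `zone_id`; conflicts are counted in
  the run log. Habitat pixels outside every zone are excluded from all
  denominators and logged — the global extent is by definition the sum
  over retained jurisdictions plus ABNJ.
* **Degenerate inputs.** Empty polygon collections rasterize to all-zero
  rasters (not errors); a run in which every PCA record is filtered away
  produces an empty PCA raster with a warning; an empty ocean drops the
  ABNJ zone with a warning; habitats whose global extent is zero cannot be
  normalized and are dropped from the index stage with a warning.
* **Antimeridian and poles.** Out of scope: real-world inputs are assumed
  pre-split at the antimeridian (the usual convention in distributed
  marine layers).

## The synthetic validation worlds

`generate_world()` emulates the three real inputs — PCA records with a
WDPA-style schema, per-habitat feature layers (polygons and
points-with-reported-area), jurisdictions plus an ocean outline — with
ground truth known *exactly* from vector geometry, no rasters involved:

* the ocean is a rectangle; jurisdictions are vertical strips tiling its
  bottom half; the top half is the ABNJ remainder;
* habitat patches are randomly rotated rectangles (or points buffered to
  exact-area circles), placed pairwise disjoint across *all* habitats so
  vector areas are additive and zone membership is unambiguous;
* per (zone, habitat) the target protection fraction `p` is realized
  exactly by clipping each feature with a straight cut line whose offset
  is solved by `uniroot` until the clipped area is `p` times the feature
  area;
* decoy records matching every filter rule (Proposed, Not Reported, MAB
  designation, point-without-area) are appended, each covering a whole
  zone — if cleaning ever failed, every index would move visibly toward 1.

Two construction details matter for the recovery tolerance. First, patch
rectangles are randomly *rotated* and protection cut lines have random
orientation: if both were axis-aligned, the centroid rule's quantization
error along a cut would be identical in every raster row and would not
average out (per-patch error ~0.3/columns with no √rows gain); oblique
edges restore independent per-row errors. Second, the defaults (10 patches
of 50–500 km² per zone-habitat pair, a 900 × 900 km world) follow from
that error model: per (zone, habitat) extents of ~2,000 pixels give a
predicted lphpi standard error of ~0.002, so the ±0.02 recovery tolerance
at 1 km cells holds with a wide margin at any seed, tightening to ±0.005
at 500 m cells (both checked by tests).

What the synthetic worlds do **not** emulate: the size heterogeneity and
spatial clustering of real habitats (real GPHPI distributions are strongly
right-skewed), real Marine Regions topology, coastlines, the antimeridian,
datum subtleties, or attribute noise beyond the decoy records. Passing the
synthetic suites therefore demonstrates the correctness of the *pipeline
machinery* — cleaning, buffering, projection, rasterization, zonal
counting, index algebra — not the ecological accuracy of any real habitat
map.

## Design decisions that were genuinely open

* **Averaging.** Zone indexes are unweighted means over present habitats,
  which treats each habitat as one unit of ecological representation; an
  extent-weighted mean is available (`weighted = TRUE`) but off by
  default, since weighting by extent would let one large habitat dominate
  the representation signal.
* **Averaged targeted score.** The zone's targeted score is the mean of
  the per-habitat targeted values. The algebraically equivalent
  alternative (average GPHPI minus τ × average global share) coincides
  whenever the same habitat set is averaged, which is the case here by
  construction.
* **OECMs.** OECM records travel exactly the same cleaning path as
  protected areas; in practice the MAB rule only ever matches
  protected-area designations.
* **Reported area for buffering** is a single per-record field; a separate
  marine/terrestrial split of reported area is not modelled.
* **Point habitat records with area 0** are treated as "no area assigned"
  and get the 1 km² default, since a zero-area habitat observation is
  meaningless.
* **Problem sizes.** The validation suites run desk-scale worlds (hundreds
  of km, hundreds of features, grids up to ~4M cells) chosen so the full
  suite completes in about a minute while every tolerance is exercised at
  its stated value.

## Storage formats

Vector layers are read and written as GeoJSON (WDPA-style attribute names
mapped via a configurable `attr_map`); GeoPackage/Shapefile inputs are
recognized but rejected with a clear message, as no OGR driver is
available to the package. Rasters persist as single-band ESRI ASCII grids
(values 0/1, or zone indexes with a CSV lookup sidecar) with the CRS name
in a JSON sidecar — a plain-text, GIS-readable representation. Index
tables are UTF-8 CSV with a fixed column order and a `#`-prefixed
run-metadata header, so identical inputs yield byte-identical outputs.

## Limitations

* Spatial overlap with a PCA does not imply effective protection of the
  habitat (a marine PCA may not regulate mangrove clearing); the indexes
  measure mapped co-location, not management effectiveness or equity.
* Point buffering can count habitat as protected when it merely lies near
  a PCA, and vice versa.
* Results are sensitive to the habitat layers chosen and to their mapping
  gaps; sub-pixel habitat patches that miss every cell center vanish at
  1 km resolution (by design of the centroid rule).
* No-take status is not modelled separately.
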