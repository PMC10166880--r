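---
title: "Polygon gating on single-cell data: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygon gating on single-cell data: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellgate)
```

`cellgate` classifies cells by point-in-polygon tests on two-dimensional
views of a UMI count matrix and summarizes the resulting regions with
count-based statistics. This vignette is the package's account of the
method: what is computed, which conventions were chosen where more than one
was defensible, and what the synthetic-data tests do and do not demonstrate.

## The data model

A `CellDataset` holds raw UMI counts (cells × genes, sparse), an optional
normalized layer, per-cell annotation columns, named 2-D embeddings, and a
store of polygon sessions. Cell order is the canonical index: counts,
embeddings and annotations align positionally, and `cell_id` is used only
when joining files. Embeddings are strictly two-dimensional — gates are
planar polygons, so a third dimension would make membership ill-defined —
and are inputs: the package never computes UMAP or t-SNE coordinates, and
deliberately refuses to re-apply a stored session to a dataset lacking the
embedding it was drawn on, because coordinates recomputed after subsetting
are a different space in which the old vertices are meaningless.

Antibody-capture features (CITE-seq style protein counts) are ordinary count
columns; they differ from mRNA genes only in their dynamic range, which is
why scatter axes support `log10` scale.

## Membership: the even-odd rule with an inclusive boundary

A cell is inside a polygon iff a ray from its coordinate crosses the closed
boundary an odd number of times (crossing-number test). Two conventions were
open:

- **Boundary cells.** Plotting libraries leave edge behaviour undefined.
  Points within an absolute tolerance of `1e-9` of an edge or vertex count
  as *inside*, making gates closed sets — the flow-cytometry convention, and
  the only choice under which shrinking a gate can never *add* cells.
- **Self-intersection.** Hand-drawn polygons can self-intersect. The
  even-odd rule (rather than nonzero winding) resolves them, matching the
  default fill rule of the plotting paths such tools draw. A polygon whose
  vertices are collinear encloses no area; it is accepted with a warning and
  matches only boundary points.

Cells inside several polygons receive the comma-joined names in drawing
order (`"CCR7,SELL"`); polygons default to decimal-integer names `"0",
"1", ...` in drawing order; cells in no polygon get the `outside_label`,
`"rest"` by default (the label for unselected cells is this package's
convention — nothing in the underlying method prescribes one). Composite
labels are atomic strings for statistics; `label_has_polygon()` splits them
when polygon-level pooling is wanted instead.

## Scatter gating and the placement of zeros

For gates drawn on a feature-vs-feature scatter, each cell is mapped to its
displayed coordinate: the requested layer's value, log10-transformed when
that axis uses `log10` scale. Polygon vertices live in the displayed
coordinate system, so a gate drawn on a log axis is applied to log values —
which makes gating raw counts on log axes exactly equivalent to gating
log-counts on linear axes for positive counts (a property the test suite
asserts).

Zero counts have no log10 image. They are placed at `log10(0.5)` — half a
count, i.e. half the smallest observable signal — so that zero cells remain
visible and gateable below every positive cell; the offset is a documented
argument (`zero_offset`) of `scatter_coords()` and `select_on_scatter()`.
Negative values under a log axis are a domain error rather than silently
dropped.

## Region statistics

All abundance statistics are computed on **raw** UMI counts, never the
normalized layer, because their interpretation rests on one UMI
representing one detected transcript:

- `pct_cells`: `100 · n_label / n_total`; sums to 100 over labels.
- `pct_expressing`: share of region cells with raw count ≥ threshold. The
  threshold defaults to 1 — "expressing" means at least one detected
  transcript; any stricter cutoff is a user decision.
- `tpm`: the gene's share of all UMIs in the region, × 10^6. Per region,
  TPM summed over all genes is identically 10^6, and TPM is invariant under
  uniform scaling of all counts — both enforced by tests.
- `enrichment`: region TPM over complement TPM. A gene detected only inside
  the region yields `+Inf` with a warning; a gene detected nowhere yields
  `NaN`. For positive TPMs, the enrichment of a region and of its
  complement multiply to 1.

`combined_enrichment` pools several labels (e.g. three subclusters) into one
region before the inside/outside split — the pooled value is *not* any
average of the per-label enrichments. Percentages are kept at full precision
internally; rounding happens only at print/CSV level.

## The normalized layer

When a normalized layer is requested (scatter gating, mixture modelling) but
absent, counts are scaled per cell to the median total count and
log1p-transformed. This is the dominant single-cell convention and is
deliberately replaceable: any externally computed matrix of the same shape
can be supplied as the `normalized` field and takes precedence.

## Gaussian mixture grouping

`fit_gmm` places cells on the plane of two marker genes (normalized layer by
default) and fits a K-component full-covariance Gaussian mixture by EM,
initialized from a hand-rolled k-means (k-means++ seeding, Lloyd iterations
to an assignment fixpoint or 300 rounds). Numerical choices:

- responsibilities via log-sum-exp; covariance regularization `reg = 1e-6`
  added to the diagonal (an eigenvalue floor against degenerate components);
- convergence when the relative log-likelihood change drops below
  `tol = 1e-6`, cap `max_iter = 200` — the common defaults of mainstream
  mixture implementations;
- components reported in descending-weight order so runs are comparable;
  ties in hard assignment break to the first component.

EM guarantees a non-decreasing log-likelihood; the suite checks the trace on
50 random datasets and compares the converged log-likelihood against an
independent reference EM (mclust) from a shared initialization.

Two behavioural regimes matter scientifically. With well-separated
components the groups coincide with rectangle gates on the same axes — the
regime in which mixture grouping and manual gating agree. With fully
overlapping components the method cannot and should not find spatial
regions; the package's tests encode this as two components with identical
means and different covariance scales, for which the fitted means must
remain essentially coincident (separation < 1 within-component SD). The
identical-components case (truth a single Gaussian) is *not* used for that
assertion: converged EM — any correct EM, not just this one — splits a
finite Gaussian sample into two half-components whose means sit ~1.2–1.6 SD
apart, so "no separation" is only observable when the overlapping truth has
distinguishable non-spatial structure.

## The synthetic-data generator

`simulate_dataset` emulates the structure gating assumes: a categorical
ground-truth cluster per cell; isotropic Gaussian embedding coordinates at
cluster-specific centres (default centres on a circle giving ~10 SD
nearest-neighbour separation, i.e. visually distinct islands); UMI counts
drawn negative-binomial (dispersion 0.5 by default — overdispersion typical
of droplet data, which Poisson would understate) with cluster-specific
mean elevation for marker genes (default: one marker per cluster, 10-fold);
independent dropout zeroing (default 10%); and optional antibody-capture
features drawn as rounded log-normals whose location differs by orders of
magnitude between positive and negative clusters, reproducing the wide
dynamic range that motivates log-axis gating. Defaults (2 000 cells, 100
genes, baseline mean 2) keep simulated totals small enough for fast exact
recomputation in tests while preserving every structural feature the
methods rely on; `reference_polygon` returns a regular 16-gon at the
quantile radius of a cluster's embedding Gaussian, giving gates with
analytically known expected coverage.

What the generator does **not** emulate: batch effects, doublets, ambient
RNA, gene–gene correlation beyond cluster structure, and library-size
variation beyond NB noise. Passing tests therefore demonstrate the
correctness of the geometry, bookkeeping and statistics on data with the
assumed structure — not robustness of gating decisions on real tissue.

## Gate versus cluster: what the comparison shows

A recurring use case is a marker whose high-expression zone straddles two
clusters. The suite simulates this directly: four embedding clusters in a
row, the marker elevated in the two central ones, and a coarse "block"
partition that cuts the zone in half. A tight rectangle around the zone then
out-enriches the best block in ≥95 of 100 seeded replicates — the
qualitative phenomenon that motivates manual selection. The magnitude of
the advantage is dataset-dependent and is not asserted.

## Command-line interface

The CLI (`inst/exec/cellgate`) is a thin dispatcher over exported functions:
`simulate`, `select`, `select-scatter`, `rename`, `stats`, `gmm`, `filter`,
`plot`. Datasets travel between steps as Matrix Market directories, so a
workflow is an ordered sequence of subcommands, each a pure function of its
file inputs; there is no separate workflow-config engine, as flags fully
determine every step. Exit codes are 0 (success), 2 (configuration error,
detected before any computation), 1 (runtime error). `filter` removes
labelled cells and re-emits the reduced raw dataset for external
re-embedding — recomputing embeddings is out of scope. Figure export
(`plot` / `render_overlay`) writes a static scatter with closed polygon
overlays plus a sidecar JSON of the session; tests assert file existence
and sidecar fidelity, never pixels, which vary by renderer.

## Known limitations

- Gates on embeddings select populations *enriched* for a phenotype, not
  binary expression truth: dropout and neighbourhood structure put
  false-negative cells inside the gate by design.
- No spatial indexing: membership is O(cells × vertices) per polygon, ample
  for the intended scale (10^4–10^6 cells, few gates).
- Sessions bind to the coordinate system they were drawn in; re-embedding
  invalidates them by construction.
- `NaN`/`Inf` enrichment values are contractual outcomes (empty-signal
  cases), and downstream code must handle them.
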