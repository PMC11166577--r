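---
title: "Graph-based spatial statistics for molecular pixelation data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based spatial statistics for molecular pixelation data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pixelgraph)
```

## The data model

Molecular pixelation measures the relative spatial arrangement of cell-surface
proteins without optics. Antibody–oligonucleotide conjugates (AOCs) bound to a
fixed cell are associated into local neighbourhoods by two successive sets of
DNA "pixels" — rolling-circle-amplified DNA balls, each carrying a unique
pixel identifier (UPI). Every sequenced amplicon carries four motifs: a 10-nt
UMI naming the individual AOC molecule, a protein-identity barcode, and the
25-nt UPI-A and UPI-B of the two pixels the molecule hybridised to.

Each unique molecule is an edge of a bipartite graph whose nodes are UPI-A and
UPI-B pixels. A cell appears as one dense connected component; the UPI-A
one-mode projection (A-pixels joined when they share a B-pixel, with
per-A-pixel marker counts as node attributes) is the substrate for all spatial
statistics. `pixelgraph` implements the full path from FASTQ to these
statistics, plus a generative simulator so that every stage can be tested
against ground truth.

## The simulator

A cell is a unit sphere. Molecules of each marker are placed uniformly or from
a von Mises–Fisher (vMF) distribution with concentration `kappa` around a
pole; `pattern_colocalized()` reuses a partner marker's pole so a pair
co-occupies one cap. Pixel zones are spherical caps with centres uniform on
the sphere; a molecule hybridises to one uniformly chosen A zone and one B
zone among those whose cap covers it, and is dropped (unhybridised) if either
set has no zone in reach. We deliberately model hybridisation to *any*
proximal pixel rather than the nearest one: nearest-centre assignment
partitions the sphere into two overlaid Voronoi diagrams and produces
near-tree bipartite graphs (average deduplicated degree ≈ 2.3 at calibration
scale, with dozens of disconnected satellite fragments per cell), whereas
pixel reach in the assay overlaps and yields the dense single-component cell
graphs observed in practice.

Calibration defaults follow the assay's published per-cell averages: 1,737
A zones, 1,737 B zones and an expected 9,580 molecules per cell, spread over
an 80-marker panel with a log-normal abundance profile. The default zone
radius is `4 / sqrt(n_pixels_a)` radians — twice the close-packing radius at
which `n_pixels_a` caps tile the sphere — which captures about 96% of
molecules and reproduces the ~5.6 molecules per A-pixel of the calibration.
Zones that end up sharing no bridging molecule with the main body of the cell
form tiny satellite components; these mirror the small debris components of
real libraries and are removed by the size filter.

PCR is modelled as `1 + Geometric` duplicate reads per molecule (heavy right
tail), sequencing error as independent per-base substitutions, and dropout as
a per-molecule Bernoulli. Doublets merge two cells' molecules into one
entity; a small interface fraction (0.1%) of the smaller cell's molecules
re-hybridise to partner B zones, which is what makes a fused particle a
single weakly-bridged component. UMIs are globally unique and, within one
A zone, kept at pairwise Hamming distance ≥ 3, so the deduplication key
(UMI + UPI-A) is collision-robust by design — the same property a
well-designed barcode chemistry targets.

What the simulator does *not* model: binding kinetics, steric hindrance,
membrane deformation (a polarized cap stands in for a uropod), cell-type
mixtures of real PBMC composition, or amplification bias that varies by
sequence content. Passing tests therefore demonstrate the pipeline's
correctness on idealised pixelated geometry, not robustness to every
real-library artefact.

## Read processing

Reads are parsed positionally against the configurable amplicon layout
(UMI · barcode · BS1 · UPI-A · BS2 · UPI-B). A read is rejected when mean
Phred quality falls below 20, when either binding-site motif mismatches by
more than 10% of its length, or when the protein barcode matches no panel
entry within one substitution (panel barcodes are pairwise Hamming ≥ 3, so
one substitution resolves uniquely). Duplicates collapse on the (UMI, UPI-A)
key; the representative UPI-B and marker are read-weighted majorities.

Error correction clusters the concatenated UMI·UPI-A keys by **directional
adjacency**: key *b* merges into representative *a* when their Hamming
distance is ≤ 2 and `reads(a) ≥ 2·reads(b) − 1`. Candidate neighbours are
found exactly via the pigeonhole partition of each key into three slices.
Two implementation choices matter:

* assignment is *one-hop* — only direct neighbours of a representative merge.
  Transitive chaining lets a low-count error key bridge two genuine molecules
  three substitutions apart and destroys one of them;
* the pass repeats until no merge occurs, which makes the operation
  idempotent by construction.

At 0.5% substitution and 12× duplication (the ≈120,000 reads / 9,580
molecules per cell depth the assay recommends), 99.9% of truth molecules are
recovered with the correct marker within the correction radius. Exact-key
recovery saturates near 97% for an identifiability reason no algorithm can
beat: a molecule seen in exactly two reads, one clean and one erroneous,
yields two 1-read keys whose representative is an arbitrary tie-break.

## Graph assembly and component calling

The bipartite multigraph keeps one edge per unique molecule. Spurious-edge
removal runs Leiden modularity communities per connected component on the
deduplicated graph and cuts the edges between a community pair only when
**all** of the following hold: the pair is joined by at most `crossing_max`
(10) distinct pixel pairs; both communities have at least `min_community`
(20) nodes; and the crossing edges number at most `crossing_rel` (1%) of the
smaller community's internal edges. The default resolution is deliberately
low (0.01) so a dense cell resolves as one community. The last two guards are
this package's own additions: at any resolution, modularity partitions of a
sparse random cell graph contain community pairs joined by ≤ 10 edges, and an
unguarded crossing-count rule fragments intact cells (measured directly on
simulated cells). The conductance-style guard encodes the actual target —
*densely connected blobs joined by a weak bridge* — and, across seeds, leaves
single simulated cells untouched while splitting doublets and the classic
two-blocks-plus-one-edge construction.

Components are labelled in decreasing molecule order (ties by smallest member
UPI, so labels are insertion-order invariant). The size threshold fits a
cubic smoothing spline (GCV) to log10(size) versus rank; its first and second
derivatives locate the sharp decline of the edge-rank curve, and the cutoff
is the *fitted* size at the steepest point of that decline. Reading the
fitted mid-cliff value matters: the second-derivative minimum sits at the top
shoulder of the cliff and, when the cell mode is tight, returns a size inside
the mode that filters out genuine cells (observed directly on 50-cell
simulations); the mid-cliff value lies strictly between the cell and debris
modes. With fewer than 20 components, or
a curvature-free curve, a typed condition (`mpx_size_fallback`) instructs the
caller to use the manual cutoff instead; published analyses used manual
minimums of 4,000–20,000 molecules per cell depending on the experiment.
Filtering drops the ten largest components (aggregates) before applying the
size cutoff; for simulated samples, where no aggregates exist, the
recommended setting is `drop_top_k = 0` — with the default 10, any simulation
of ≤ 10 cells would discard every cell by construction.

The Tau skewness score of a component's marker counts is
`sum(1 − x/max(x)) / (n − 1)`: 0 for even counts, 1 for a single-marker
component. Components are flagged `HighTau` above 0.995 or beyond 2 IQRs from
the population median, `LowTau` beyond 5 IQRs, with `HighTau` taking
precedence when both fire.

## Spatial statistics

**CLR.** Counts are transformed as `ln(1 + x) − mean(ln(1 + x))`. The log1p
variant (rather than the geometric-mean CLR) is defined for the zero counts
that dominate a sparse 80-marker panel at per-node resolution.

**Polarity.** For each marker, node counts are CLR-transformed per node
across markers, and Moran's I is computed over the row-normalised adjacency
of the projection:

$$I = \frac{N}{\sum_{ij} w_{ij}} \cdot
      \frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2},
      \qquad z_i = x_i - \bar{x}.$$

The z-score and two-sided p-value use the closed-form randomization moments
(`E[I] = −1/(N−1)` and the kurtosis-corrected variance), verified in the test
suite against a brute-force double sum, a Monte-Carlo permutation null, and
`ape::Moran.I`. Zero-variance markers are flagged, never silently zeroed.
Polarity is reported as raw Moran's I, with the z exposed alongside.

**Colocalization.** Per unordered marker pair: markers under 10 total
molecules are dropped; counts are aggregated over each node and its immediate
neighbours, and nodes whose aggregated total (across surviving markers) is
below 5 are dropped; `n_perm` permuted cells shuffle each marker's node
counts independently (preserving totals and topology) and are re-aggregated
and re-filtered identically; Pearson's r on log1p aggregated counts is
compared to a Gaussian fit of the permuted r values, giving
`z = (r − mean)/sd` and a two-sided p. The reported score is `z`; negative
values indicate segregation. One calibration property is worth knowing: on
realistic cells the null mean of z is slightly positive (≈ +0.5 on simulated
cells) because every marker shares each pixel's capture-size factor — larger
or better-connected pixels collect more of *all* markers, and permutation
destroys that shared factor. The statistic is centred when counts are placed
independently of the topology (measured |mean z| ≈ 0.15), and
between-condition comparisons are unaffected because the offset is
condition-invariant. The number of permutations trades precision of the null
for time; the default 50 gives a z resolution of about ±0.2.

**Differential comparisons.** Conditions are compared per feature by
two-sided Wilcoxon rank-sum tests after downsampling cells without
replacement (convention: 50 cells per group for abundance and polarity, 100
for colocalization), with BH or Bonferroni adjustment across features within
each condition. Effects are group-mean differences; abundance effects are
expressed as log2 fold changes of CLR counts. Gating on CLR counts implements
conjunction/disjunction rule sets; `t_cell_gate()` reproduces the published
T-cell rules (CD3 > 0.9 and CD4 > 1.8 or CD8 > 1.5; CD19 < 0.5, CD20 < 1.1,
CD14 < 0.5).

## Layouts and density grids

3D Kamada–Kawai coordinates (seeded initial placement) are centred on their
centroid and normalised onto the unit sphere; centring is a deliberate
deviation from dividing raw coordinates by their norm, which collapses
asymmetric layouts onto a hemisphere. Density heatmaps evaluate, at each
point of a 2,000-point Fibonacci lattice, the natural log of
`sum(count · (1 − d/cutoff))` over nodes within the chord-distance cutoff
(default 0.3); empty grid points are masked. The kernel weights nodes by
their marker count, treating a count of *k* as *k* coincident coordinates.

## Numerical and design choices

* Ties in zone assignment, majority votes and representative selection break
  lexicographically; component labels sort by size then smallest UPI — every
  pipeline output is reproducible from the manifest's seeds.
* Stage seeds derive from `hash(top seed, stage name)`, so re-running one
  stage is independent of execution order.
* Leiden community detection ran on the bipartite graph directly (not a
  projection), and `HighTau` outranks `LowTau` where both IQR rules fire.
* The amplicon layout (UMI 10 · barcode 8 · BS1 20 · UPI-A 25 · BS2 20 ·
  UPI-B 25, 5'→3') is a configurable stand-in; the real read structure is
  split across two sequencing reads and is not part of this package's
  contract.
* Whether the original pipeline corrects UPI-B errors is unspecified; we
  correct them within each merged key cluster by the same directional rule.

## Problem sizes used in the shipped checks

The test-suite simulations are sized for a single CPU: statistic calibration
suites use 8-marker panels, 120-pixel lattices and 800–1,200 molecules per
cell (50–100 cells per condition); the polarity-versus-concentration suite
uses a 500-pixel lattice (2,500 molecules per cell) because the lattice must
spatially resolve the tightest cap tested; cell-count recovery runs at
the full calibration scale (80 markers, 1,737 + 1,737 zones, ~9,580 molecules
per cell) over 20 seeded replicates split across 5-, 10- and 50-cell samples.
These sizes are the package's choices for routine verification; all scale
parameters are arguments.

## Known limitations

* Polarity and colocalization are pairwise/single-marker; spatial
  constellations of three or more proteins are out of scope.
* The simulator's cells are spheres with isotropic pixel placement; real
  membranes wrinkle, and pixel density varies with surface chemistry.
* The colocalization null inherits the capture-heterogeneity offset described
  above; compare scores between conditions rather than against zero.
* The spline elbow needs a clearly bimodal edge-rank curve; sparse samples
  should rely on the manual cutoff (the typed fallback enforces this).
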