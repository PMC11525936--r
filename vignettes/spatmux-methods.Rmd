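---
title: "Methods: spatial single-cell analysis of multiplexed tissue imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial single-cell analysis of multiplexed tissue imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spatmux)
```

spatmux analyzes multiplexed fluorescence imaging of tissue sections
(CODEX/PhenoCycler-style panels of 20–30 protein markers) at single-cell
resolution. This vignette documents the models and procedures, the tunable
parameters and their defaults, the synthetic-tissue generator that every
stage is validated against, and the numerical conventions. All coordinates
are physical micrometres with the origin at the top-left image corner, x
along columns, y along rows; pixels are converted through the acquisition
pixel size (0.51 µm/px by default, the resolution of a ×20 PhenoCycler
scan).

## Instance segmentation by nuclei/membrane fusion

Cell boundaries in dense embryonic tissue cannot be recovered from a
nuclear stain alone (cytoplasm is invisible) nor from a membrane stain
alone (only epithelial cells carry EPCAM). The segmentation therefore fuses
two complementary sources:

1. **Channel preprocessing** (`preprocess_channel()`). The lower
   0.01-percentile (the 1e-4 quantile) of the raw channel is subtracted,
   the result min–max normalized into [0, 1], and two cut points computed
   by exhaustive 3-class Otsu on a 256-bin histogram. Thresholds are
   reported as upper bin edges so that a value binned at the cut satisfies
   `x <= threshold` exactly; with discrete synthetic intensities the
   bin-centre convention misclassifies whole intensity levels.
2. **Nuclei** (`detect_nuclei()`). Foreground is the smoothed DAPI channel
   (Gaussian sigma 2 px) above the lower Otsu cut. Touching nuclei are
   split by a seeded watershed on the smoothed distance transform, seeded
   at its regional maxima (plateaus merged; minimum peak separation 7 px
   ≈ 3.5 µm, about one nucleus radius). The watershed is a deterministic
   priority flood written in C++: pixels are flooded in ascending intensity
   with ties broken by insertion order in row-major scan, so results are
   bit-reproducible. Each nucleus is then expanded by a cytoplasm rim
   (default 3 µm, a typical rim for dense tissue) with contested pixels
   assigned to the nearest nucleus, so expansions never overlap.
3. **Membrane compartments** (`membrane_watershed()`). The EPCAM channel is
   smoothed lightly (sigma 1 px — membranes are thin, ~1.5 µm, and heavier
   smoothing erases the ridge), thresholded into a filled figure (lower
   cut) and a ridge mask (upper cut). Sub-ridge chambers that contain no
   nucleus and are fully enclosed by ridge become their own seeds; chambers
   adjacent to the outside are blur halos, not cells, and are not seeded.
   The same priority flood over EPCAM intensity, seeded by nuclei, orphan
   chambers and the background, partitions the figure with boundaries on
   membrane ridges.
4. **Fusion** (`fuse_masks()`). Each expanded nucleus is cut to the
   compartment holding the majority of its pure nucleus (ties to the lower
   compartment label); compartments with no nucleus become cells verbatim
   (membrane-only cells); nuclei outside all compartments keep their
   expansion. A sanity filter removes cells outside the 20–5000 px area
   window or below the intensity floor — `floor_frac` (default 0.5) times
   the lower Otsu cut of DAPI and EPCAM, on the mean normalized intensity
   over the cell. The factor accounts for the roughly threefold dilution
   of nuclear signal when averaged over the whole footprint. Where the
   criteria for rejecting an *incorrectly* detected nucleus are concerned,
   only the unambiguous "no nucleus" branch is implemented; flagging
   wrong nuclei would need a reference the pipeline does not have.
5. **Quantification** (`quantify_cells()`). Per cell: centroid (µm), area
   (px and µm²), mean of the *original* unnormalized intensity per channel,
   and a binary positivity call (mean normalized intensity above the upper
   Otsu cut of that channel — the upper cut is the natural "clearly
   positive" boundary of the 3-class model; the source toolkits store such
   calls without defining the rule).

## Table preprocessing

The canonical order is subtract → exclude → normalize. Background is a
constant per (marker, week) measured in signal-free regions and subtracted
with clipping at 0. Region files are GeoJSON-like polygons in µm
(replacing interactive viewer selections); point-in-polygon uses the
even-odd rule with boundary counted inside, which is deterministic on the
grid-aligned polygons of the synthetic fixtures. Arcsinh normalization
`x' = asinh(x / cofactor)` uses cofactor 5, the flow/mass-cytometry
convention; the transform is monotone so downstream rank statistics are
unchanged by the choice.

## Phenotyping

`cluster_cells()` is PCA (up to 20 components, capped at the marker count)
→ exact brute-force kNN graph (k = 10, Euclidean) → Leiden community
detection under the modularity objective at resolution 1, seeded and with
cluster ids re-indexed by decreasing size so labels are deterministic. The
PC cap is the marker count, not markers − 1: with a 2-marker panel a single
PC collapses the data onto a line whose kNN graph is a path, which
community detection shatters.

Cluster annotation mirrors how a dot plot is read
(`annotation_rulebook()`): markers are z-scored **across cluster means**,
and an ordered rule list maps profiles to cell-type labels. A marker counts
as *high* when its z-score reaches `z_high` (default 0.5) **and** its plain
cluster mean exceeds `min_mean` (default 1.5 on the arcsinh scale, i.e. raw
intensity around twice the cofactor).
The absolute floor matters: a marker expressed nowhere has cluster-mean
z-scores that are pure noise, and without the floor silent markers fire
rules. *Low* means below the floor. Clusters sharing a label merge;
unmatched clusters are labelled `unassigned` and reported with their top-3
markers as evidence. Subclustering (`subcluster()`) reruns the machinery on
one annotation at a stated resolution (airway smooth muscle at 0.5; immune
at 0.2, or 0.3 for weeks 8.5 and 12) with labels namespaced under the
parent. Manual gates (`gate_cells()`) are conjunctions of percentile or
absolute thresholds (B: CD19 ∧ CD45; NK: CD56 ∧ CD45; 90th-percentile
defaults, configurable) and take precedence over subcluster labels.

## Neighborhood enrichment

`build_neighbor_graph()` connects cells whose centroids lie within a fixed
radius, 50 µm by default. The radius is physical µm throughout; if the
acquisition convention were pixels at 0.51 µm/px the same code applies with
the radius rescaled — the unit choice is exposed, not hard-wired.
`nhood_enrichment()` counts unordered label pairs over edges (the homotypic
diagonal counts pairs, not cells, so counts over all pairs sum to |E|) and
compares with a null obtained by permuting labels over nodes with the graph
fixed (default 1000 permutations, seeded):
`Z = (obs − mean_perm) / sd_perm`. Pairs whose permutation counts never
vary (e.g. a single label) get Z = 0 with a degenerate flag rather than an
infinity. Cross-week comparison scales each week's Z matrix column-wise to
mean 0 / unit sample variance, then subsets to the common labels — scaling
first, subsetting after, so a label absent elsewhere still influences the
scale of its own week.

## Spatial domains

`neighbor_augmented_features()` concatenates each cell's expression block,
weighted √(1 − λ), with its spatial neighbours' mean expression, weighted
√λ, so ‖feature‖² decomposes as (1 − λ)‖x‖² + λ‖x̄_neighbours‖². λ = 0.8
is the domain-segmentation operating point; neighbours default to the 18
nearest cells. Only the mean block is implemented — the azimuthal-gradient
block of the full published domain algorithm is omitted as the mean block
carries the domain signal at λ = 0.8; this is a documented simplification.
`cluster_domains()` feeds the augmented matrix through the same
PCA/kNN/Leiden machinery (default resolution 0.1; lower than phenotyping
because domains are few and large). At λ = 0 the neighbour block is zero
and the procedure reduces exactly to expression clustering — a property the
tests assert. Domain compositions are compared across weeks over the union
type vocabulary (absent types zero-filled) with Pearson correlation and
Ward (`ward.D2`) linkage.

A caveat the synthetic experiments make explicit: with fully separated
lineage islands (disjoint marker supports, low dispersion) the kNN graph
contains *no* cross-type edges, and no resolution can merge different cell
types into one spatial domain. Domain inference presumes expression
continua between neighbouring cells. The domain preset
(`synthetic_domain_config()`) therefore raises the log-normal coefficient
of variation to 2, which is also the realistic regime for embryonic tissue
where lineages are still converging.

## Proliferation

`classify_proliferating()` thresholds background-subtracted Ki67 at a
per-week percentile of that week's population: 70 for weeks 6 and 8.5, 85
for weeks 11 and 12, 86 for week 13. Percentiles use linear interpolation
between order statistics; positivity is strict (`>`), so an all-equal
population yields no proliferating cells. The percentile is taken over the
analyzed (post-artifact-exclusion) population; the alternative — the
pre-exclusion population — would shift the threshold by the artifact mass
and is not reproducible from the processed tables.

Comparisons: per-type homotypic adjacency of proliferating vs
non-proliferating cells uses the scaled enrichment diagonals across weeks
with a two-sided equal-variance Student t-test (zero pooled variance:
t = 0/p = 1 when means agree, ±Inf/0 when not); the week-wise ratio
non-proliferating / proliferating is guarded against near-zero
denominators. Airway-region contrasts use a two-sided Fisher's exact test
by full hypergeometric enumeration with the point-probability rule (tables
as improbable as observed, within a 1e-7 relative tie tolerance, are
summed), validated against an independent enumeration oracle over every
table with margins ≤ 30.

## Immune subanalysis

Immune cells are subclustered on the ten-marker immune panel (CD3, CD4,
CD44, CD45, CD56, CD68, CD163, HLA-DR, Ki67, MRC1). B and NK cells enter by
manual gates which override subcluster labels. The proximity network uses
the *observed* neighbour-pair counts restricted to immune cells, normalized
by the total immune pair count, so edge weights (self-loops included) sum
to 1 and are comparable across weeks.

## Artery proximity, two routes

**Instance route.** Artery-close immune cells (focal set) are compared
with an equal number of artery-distant immune controls sampled uniformly
without replacement (seeded; focal cells excluded from the pool). Per
marker: two-sided Wilcoxon rank-sum with the normal approximation and tie
correction (no continuity correction — matching the large-sample reference
implementations), Benjamini–Hochberg adjustment across markers, and
`log2FC = log2((mean_A + ε)/(mean_B + ε))` with ε = 1e-9; significant means
adjusted p < 0.05 and |log2FC| > 1. Fold changes are computed on
linear-scale (background-subtracted) intensities; on the compressed arcsinh
scale a genuine four-fold shift can fall below the log2FC = 1 line.
Neighborhood composition profiles pool neighbours of all focal cells into
5-µm distance bins to 50 µm, excluding each focal cell from its own
neighbourhood.

**Semantic route** (`semantic_artery_masks()`), a faithful batch
reimplementation of an interactive macro workflow: CD45 rolling-ball
background subtraction (grayscale opening with a radius-50 px disk,
subtracted — the morphological equivalent of the named filter); Gaussian
blur (sigma 4 px for ACTA2 and CD144, 2 px for CD45); per-channel triangle
threshold (256-bin histogram, peak-to-tail chord, maximum perpendicular
distance); artery core = ACTA2 ∧ CD144 with components under 2000 px
removed; an optional correction mask (add/remove) replaces the interactive
validation step; expansion = ACTA2 components overlapping the core by ≥ 1
px; proximity zone = maximum filter with an 80 px (≈40 µm) Euclidean disk,
computed exactly via the distance transform — on binary input the maximum
filter *is* dilation, and the tests verify the identity against a
brute-force structuring element. The zone splits the CD45 mask into
artery-close and artery-distant immune regions, whose per-channel mean and
median intensities are contrasted and ordered. The two routes deliberately
keep their different "close" constants (50 µm graph radius vs 40 µm
semantic zone), as configured.

## The synthetic-tissue generator

`synthetic_config()` defines the study conditions the pipeline is tested
under; its defaults are fixed, not tuned per test:

* **Field**: 1000 × 1000 µm at 0.51 µm/px with 3000 cells
  (3000 cells/mm², dense embryonic tissue).
* **Types and composition**: nine free-field types led by mesenchymal
  (34%), endothelial (20%), SOX9-high (14%) and SOX2-high (10%) epithelium,
  airway smooth muscle (10%) and an immune compartment (12%) dominated by
  macrophages. Marker profiles are log-normal per (type, marker), baseline
  mean 2, lineage markers 40–60, shared coefficient of variation 0.35.
* **Proliferation**: per-type Bernoulli rates (SOX9-high epithelium 0.6,
  airway smooth muscle 0.15, macrophages 0.10, B cells 0.5, others near
  0.3); proliferating cells carry an eight-fold Ki67 mean shift, giving the
  continuous bimodal distribution percentile thresholding requires.
* **Placement**: sequential rejection sampling under a minimum
  centre-to-centre spacing of 2.8 × the nucleus radius (grid-accelerated;
  spacing checks use the panel-wide maximum radius so acceptance is
  independent of the sampled type, keeping realized composition unbiased).
  A zero spacing factor gives uniform placement for large-n statistical
  fixtures.
* **Structures**: airways (SOX2-high epithelial ring on the lumen, ASM
  ring 8 µm outside), SOX9-high distal tips (disks), and vessels — an
  endothelial ring, a vascular-smooth-muscle ring 6 µm outside, solid
  ACTA2 (media, ring + 10 µm) and CD144 (lining, ±2 µm) annuli painted for
  the semantic masks, and an immune collar 22 µm outside the endothelial
  ring tagged `artery-close`. Collar cells (70% macrophage / 30% ILC & T)
  carry the configured marker shifts: CD90 and HLA-DR means ×4, CD163 and
  MRC1 ×0.25. Four-fold shifts are used because the significance rule
  requires |log2FC| > 1: a planted effect exactly at a two-fold boundary
  would make the fixture ill-posed.
* **Rendering**: DAPI and Ki67 over nucleus disks; EPCAM as a ~1.5 µm
  membrane ring (plus contested borders) with a dim interior on epithelial
  cells; other markers over the whole footprint; contested pixels to the
  nearest centre, making the returned mask a valid instance ground truth.
  Optional Poisson resampling, then Gaussian noise with sd 5% of the
  nominal high-signal level, clamped and rounded to integer counts.

What the generator does **not** emulate: optics (PSF, chromatic shifts),
autofluorescence spectra, cycle-to-cycle registration error, tissue
deformation, and 3D structure. Passing tests therefore demonstrate the
correctness of the algorithms under the stated statistical structure, not
robustness to acquisition artifacts.

Presets freeze the two non-default regimes used in validation:
`synthetic_domain_config()` (three tissue bands — mesenchymal,
distal-epithelial, vascular — sharing a 10% macrophage infiltrate, cv = 2,
n = 10⁴) and `synthetic_vessel_config()` (vessel collars with the immune
shifts over a 7:3 macrophage:ILC & T free field so the planted shifts are
the only systematic close-vs-distant difference).

## Numerical conventions and degenerate inputs

* All randomness flows from explicit seeds; community detection, the
  watershed and sampling are deterministic given them.
* Watershed ties: ascending intensity, then insertion order in row-major
  scan; compartment assignment ties go to the lower label.
* Constant rasters are rejected by thresholding functions; constant
  channels in quantification yield no positivity calls rather than errors.
* Zero-variance columns scale to 0 with a flag; degenerate permutation
  nulls give Z = 0 with a flag; zero pooled variance in the t-test follows
  the t = 0 / p = 1 convention; empty region sets pass tables through with
  a notice.
* The fixed-radius graph is grid-bucketed but exactly equals the O(n²)
  brute force, asserted in tests.

## Problem sizes used in validation

The test-suite fixtures are sized for thorough yet quick runs: phenotyping
and adjacency properties at 1500 cells, segmentation geometry at a few
hundred cells with the full 3000-cell default exercised end-to-end,
domains at 3000 (units) and 10⁴ (end-to-end), the Fisher oracle over all
~2.5 × 10⁵ tables with margins ≤ 30, and the permutation null at 2000
cells × 20 seeds × 1000 permutations.

## Known limitations

* The classical nuclei detector replaces a trained deep model; it is
  accurate on disk-like embryonic nuclei but will undersegment strongly
  lobed or overlapping nuclei.
* Only the "no nucleus" branch of compartment rescue exists; wrongly
  split or merged nuclei inside a compartment are not detected.
* Leiden modularity at resolution 1 subdivides large homogeneous
  populations; annotation merging absorbs this, but cluster counts should
  not be read as type counts.
* Domain inference requires expression continua (see above); on perfectly
  separated synthetic types it cannot cross type boundaries.
* The proximity network uses raw pair frequencies; it is not corrected
  for subtype abundance (by design, matching the frequency semantics of
  the original analysis).
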