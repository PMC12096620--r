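---
title: "Quantifying intra-tumoral heterogeneity from multiplexed immunofluorescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intra-tumoral heterogeneity from multiplexed immunofluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Breast cancers are spatially heterogeneous: different regions of one surgical
specimen can differ in hormone-receptor expression, proliferation, molecular
subtype, and immune contexture. mxifhet implements an analysis chain for
quantifying that heterogeneity from single-cell tables exported by
multiplexed immunofluorescence (MxIF) platforms, where multiple tissue
microarray (TMA) cores are sampled per lumpectomy case. Two staining panels
are handled:

* **IHC4 panel** — ER, PR, HER2, Ki67 plus CK8/18 as the epithelial mask.
  Used for clinical-style histoscoring, co-expression clustering, and
  diversity analysis of cluster compositions.
* **Immune panel** — CK8/18, CD3, CD8, CD68, CD163, FoxP3, PD1, PDL1, Ki67.
  Used for binary gating into lineage phenotypes and spatial image-patch
  analysis of immune niches.

Everything operates on plain tabular data (one row per segmented cell with
coordinates and raw intensities), so the package sits downstream of
segmentation and upstream of interpretation.

## Preprocessing model

Cells with raw DAPI below 1000 are excluded (`qc_filter()`); the boundary
value 1000 is retained, reading the exclusion rule as a strict inequality.
Raw intensities are transformed as `log2(x + 1)`; the unit offset is a
convention for handling raw zeros, which segmentation exports do produce.
Per-marker scaling is then:

* min–max to the 0–15 range for the IHC4 panel (`range_0_15`), and
* standardization to mean 0, SD 1 for the immune panel (`zscore`).

Scaling is **global per marker across the run**, not per core: histoscores
are compared across cores of one cohort on a single scale, which requires a
shared normalization. Per-core scaling can be obtained by grouping before
the call. Min–max (rather than percentile) scaling is the plainest reading
of "range normalized"; optional percentile winsorization (`clip_quantiles`)
is exposed for robustness against single extreme cells but is off by
default.

## Scoring model

ER/PR categories on the 0–15 scale are `negative` (exactly 0), `1+` on
(0, 7), `2+` on [7, 12], `3+` on (12, 15]. HER2 categories are `0` on
[0, 5], `1+` on (5, 10], `2+` on (10, 13), `3+` on [13, 15]; the published
edge conventions overlap at 13, resolved here in favour of `3+` as a
documented convention. The per-core histoscore is

$$H = 3\cdot(\%\,3{+}) + 2\cdot(\%\,2{+}) + (\%\,1{+}) \in [0, 300],$$

computed over cancer cells, i.e. cells whose normalized CK8/18 exceeds a
threshold. The CK rule is not fixed by convention anywhere we know of, so
the threshold is estimated from the bimodality of the CK distribution
(valley method) with a configurable fallback at 7.5 on the 0–15 scale.
Ki67 positivity is the percentage of cancer cells with normalized Ki67
strictly above 0 — any measurable normalized signal counts, mirroring
clinical Ki67 reading where any nuclear stain is positive. Whether the
denominator should be all cells or CK+ cells is ambiguous in clinical
practice; we use CK+ cells ("cancer cells") and document it.

Immune gating thresholds come from an on-slide tonsil control: tonsil
carries abundant positive and negative cells per marker, so each marker's
control distribution is bimodal and the threshold is placed at the density
valley between the two dominant modes. Unimodal distributions trigger a
warning and a configured fallback. Gates are evaluated
most-specific-first (number of constrained markers, descending; ties by
listed order), so `CD3+/CD8+/PD1+` wins over `CD3+/CD8+`; ungated cells are
`other`. FoxP3 is measured but deliberately unused by the default gates,
matching the ten patch features below.

## Clustering model

Cell and patch clustering is PhenoGraph-style: a K-nearest-neighbour graph
(Euclidean metric, ties broken by item index, directed edges symmetrized by
union), edges weighted by the Jaccard index of the endpoints' closed
neighbour sets, and Louvain community detection. Modularity

$$Q = \sum_c \left( \frac{w_c^{in}}{w} - \left(\frac{w_c^{tot}}{w}\right)^2 \right) \in [-1, 1]$$

is reported for every partition. Conventional neighbour counts are K = 300
for single-cell IHC4 clustering and K = 30 for patch-composition
clustering; `select_k()` scans a K grid and keeps the K with maximal Q
(ties to the smallest K, favouring finer graphs). A caution we verified
empirically: at very small K (say 2–10 on a few hundred points) Louvain
finds many micro-communities whose modularity *exceeds* that of the true
coarse structure, so modularity maximization over a grid that includes very
small K can select a fragmented partition. Scans should start at K large
enough for the intended granularity; the package's defaults do.

Louvain's greedy sweep visits vertices in a randomized order, so results
are seed-controlled (`seed` arguments feed R's RNG). Under row
permutation the recovered partition is identical up to label names when K
is large enough for the partition to be stable; at small K the sweep order
genuinely matters, which is a property of the published algorithm, not of
this implementation. Cluster ids are relabelled by decreasing size purely
for stable reporting.

Fine clusters are aggregated by average-linkage hierarchical clustering of
their centroid vectors cut at a configured group count
(`merge_clusters()`), the dendrogram-based step used to reduce ~12 fine
spatial clusters to 8 interpretable immune phenotypes. Whether that merge
should be a formal linkage cut or a visual grouping is not fixed by
convention; we use the formal cut so it is reproducible.

## Patch model

Each core is divided into square patches of 150 px (48.75 µm at the immune
panel's 0.325 µm/px), on a half-open grid anchored at the per-core
bounding-box minimum, since TMA core images carry arbitrary offsets. For
each patch we compute the fractions of ten cell-type features: CK+ cancer
cells and nine immune phenotypes. The denominator is **all** cells in the
patch including `other` (so the ten fractions sum to at most 1); a
classified-only denominator is available via `denominator = "classified"`.
Patches with fewer than 5 cells are dropped, then cores with fewer than 10
surviving patches. Patch composition vectors are clustered (K = 30),
merged to 8 phenotype groups, auto-named from their dominant features, and
summarized as per-core phenotype fractions.

## Diversity model

Heterogeneity of cluster compositions is quantified with Rao's quadratic
entropy under the identity dissimilarity (no dissimilarity tree), which
reduces to Simpson's index: $\alpha_k = 1 - \sum_i p_{ki}^2$ per core.
Within one case,

* **alpha** (intra-core heterogeneity) is the weighted mean of
  $\alpha_k$ over the case's cores,
* **total** is the Simpson index of the pooled composition, and
* **beta** (intra-tumoral heterogeneity) is `total - alpha`, which is
  non-negative for cell-count weights by Jensen's inequality.

Cores are weighted by cell count by default since cellularity varies;
equal weights are available. The pairwise among-core matrix
$D_{kl} = 1 - \sum_i p_{ki} p_{li}$ is also reported because
"among-community diversity" is sometimes read as a pairwise average; the
additive decomposition is the headline value. Cases with one analysed core
report `beta = NA`, not 0 — a single core carries no among-core
information. The species space is the global cluster label set of the run;
clusters absent from a core contribute $p_i = 0$.

## Group comparisons

`compare_groups()` wraps one-way fixed-effects ANOVA and the two-sample
Wilcoxon rank-sum test on per-core values, treating cores as independent
observations (case-level nesting is deliberately ignored, matching the
per-core comparisons this pipeline is built for; nested models are out of
scope). No multiple-testing correction is applied by default — single
feature-wise p-values are reported; `stats::p.adjust()` can be applied
downstream. The Wilcoxon test is exact for combined n ≤ 20 without ties and
a tie-corrected normal approximation otherwise.

## The synthetic cohort generator

Because cohort-scale MxIF data with ground truth are rarely shareable, the
generator (`simulate_cohort()`) produces cohorts with the statistical and
spatial structure the analysis assumes, plus complete ground truth:

* **Design**: each case receives 2–9 circular TMA cores; case subtypes are
  drawn from a mix proportional to 10 LumA : 7 LumB : 2 HER2E : 6 Basal and
  a case is polytypic with probability 13/38, in which case at least one
  core switches to a second subtype.
* **Intensities** are log-normal per marker per archetype
  (`2^rnorm(mean, sd)`, clipped to the 16-bit range [0, 65535]); positive
  and negative populations sit 5 log2 units apart with SD 0.7, a
  well-separated regime (≥ 5 pooled SDs between archetype centroids) chosen
  so that recovery failures indicate pipeline defects rather than
  insufficient signal.
* **DAPI** is a mixture with a configurable sub-1000 fraction (default
  10%) to exercise the QC filter.
* **Space**: cores are discs of radius 1500 px (≈ 1 mm diameter at
  0.325 µm/px). Niche blobs are isotropic Gaussians (SD 50 µm, truncated at
  2 SD so niches stay locally coherent) with centres kept apart by
  rejection sampling; a cell's niche is that of its *nearest* blob centre,
  making the niche map a spatial partition with Gaussian density — mixing
  occurs only along territory boundaries, as in tissue. Eight niche
  archetypes span immune-cold to immune-hot compositions plus a
  PDL1-macrophage pattern; subtype-dependent niche weights give Luminal A
  cores more CD3-rich and immune-rich territory than Luminal B, so the
  expected direction of that contrast is testable end to end.
* Default cellularity (2000–3500 cells/core) yields roughly 9–20 cells per
  surviving patch, the regime the patch filters are designed for.

What the generator does **not** emulate: staining batch effects and
illumination gradients, segmentation errors (doublets, split nuclei),
spill-over between markers, cell-shape/area biology, tertiary lymphoid
structures, and any correlation between the two panels' sections beyond
shared metadata. Tests passing on synthetic cohorts therefore demonstrate
the pipeline's correctness and recoverability under its stated assumptions,
not robustness to those real-data artifacts.

## Numerical choices and degenerate inputs

* Min–max outputs are clamped to [0, 15] (an ulp of rounding can otherwise
  overshoot); constant markers error under z-score and map to 0 with a
  warning under range scaling.
* Neighbour ties in the KNN graph are broken by item index; zero-Jaccard
  edges are dropped.
* Modularity of the all-in-one partition is exactly 0; empty graphs and
  K ≥ n are errors.
* Compositions must sum to 1 within 1e-9; Rao additivity
  (`alpha + beta = total`) holds to machine precision by construction and
  is asserted against a brute-force double sum in the tests.
* The H-score is a linear functional of category percentages; pooling
  cores and recomputing equals the cell-count-weighted recount (tested by
  brute force).
* Patch grids use half-open intervals, so a cell at an exact patch border
  belongs to the higher-index patch.

## Problem sizes used by the shipped checks

The test-suite and the acceptance script run, by design, on scaled-down
cohorts: archetype recovery on 3000 cells at K = 300; niche recovery on 8
cases × 2–3 cores at 2500–3500 cells/core; determinism on 3 cases × 2 cores
at 350–450 cells/core with K = 60/15. These sizes were chosen as the
smallest at which the respective structure (five archetypes, eight niches,
stable partitions) is comfortably identifiable; the methods themselves have
no size-specific logic.

## Known limitations

* HER2 histoscores quantify fluorescence intensity, not the
  membrane-morphology criteria of clinical HER2 IHC scoring; discordance
  with clinical scores is expected and not a defect.
* Modularity-maximizing K selection is unreliable when the scan includes
  very small K (see above).
* ANOVA on per-core values ignores case-level clustering; p-values are
  anti-conservative when cores within a case are correlated.
* Phenotype auto-naming is heuristic (dominant composition features);
  duplicate names are disambiguated with numeric suffixes and should be
  reviewed before publication-grade labelling.
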