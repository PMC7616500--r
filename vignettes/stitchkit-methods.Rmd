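---
title: "Methods: section stitching, doublet consolidation and spatial statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: section stitching, doublet consolidation and spatial statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stitchkit)
```

# Scope and model

stitchkit implements six cooperating pieces: synthetic fixtures, Space
Ranger-style I/O, affine section stitching, cluster-level doublet
flagging, pixel co-occurrence statistics, and a set of atlas-level rules
(QC filters, crown-rump-length ageing, odds-ratio gene selection,
NMF-microenvironment membership). This vignette records the assumptions,
parameter choices and numerical decisions behind each, and what the test
suite does and does not establish.

# Coordinate conventions

All spot and image coordinates are 0-based full-resolution pixels in
(column = x, row = y) order, the Space Ranger convention. Affine
transforms use the SVG/TrakEM2 six-coefficient form
$(x, y) \mapsto (ax + cy + e,\; bx + dy + f)$ and must be invertible
($ad - bc \neq 0$). Registration exports do not record which image
resolution a matrix acts on, so affine files must declare
`"resolution": "fullres"` explicitly; the reader refuses to guess.

# Section stitching

Spots are mapped through their section's transform, suffixed
`-<section_id>` (spatial barcodes repeat across capture areas of one
chip), and concatenated — **never** deduplicated or masked in overlaps:
overlap handling is purely an image-rendering decision, and the data
matrix keeps every spot. Counts are merged by outer join on gene
identifiers with zero fill: sections from one chip normally share a gene
list, but the contract must be total.

The composite canvas is the bounding box of all transformed image
corners, translated so its minimum corner is (0, 0); the translation is
kept as `frame_offset` so raw transform outputs remain recoverable. Where
sections overlap, each pixel keeps the value of the highest-priority
section covering it, with the centre section first — a generalisation of
"keep the centre portion" to an arbitrary priority list so more than
three sections work. Resampling is inverse-mapping with bilinear
interpolation and background fill 0: standard, deterministic, and exact
for the integer translations used in the fixtures.

Sections with spot-diameter scale factors differing by more than 1% are
assumed to come from different chips and are rejected; cross-chip
stitching would need rescaling that the six-coefficient contract cannot
express safely.

A landmark least-squares estimator (`estimate_affine_from_landmarks`) is
provided as plumbing for when no registration export exists; it solves
two independent 3-parameter linear systems and errors on collinear
landmarks. On noiseless consistent input it recovers the generating
transform to < 1e-9, which the suite asserts over random transforms.

# Doublet consolidation

The tested unit is the fine cluster, not the cell: per-cell scores are
replaced by their fine-cluster median, and the null is fitted to the
per-cluster medians (fitting to cells would mix within- and
between-cluster variation and overstate sigma). The null is
$\mathcal N(\mathrm{center}, \sigma)$ with center the median of cluster
medians and $\sigma = 1.4826 \cdot \mathrm{median}\{m_c - \mathrm{center}
: m_c > \mathrm{center}\}$. Using only above-median values avoids the
truncation artefact when many clusters pile at score ≈ 0; 1.4826 is the
usual normal-consistency constant for a MAD. The fit is global across
lanes (per-lane nulls with few clusters per lane would be unstable); the
per-lane Scrublet scoring itself is upstream and out of scope.

P-values are right-tailed and BH-adjusted. Flagging requires both
`q < 0.05` and a consolidated median ≥ 0.1. The low-score cut could also
be read as *removing* low-score clusters during manual curation; since
that reading contradicts flagging doublets, the floor is implemented as a
conjunct of significance, both thresholds are exposed as parameters, and
significant-but-low clusters are reported as `borderline` for manual
curation rather than decided automatically.

# RNA-ISH co-occurrence

For binary masks on a common grid (default 0.14 µm pixels), the statistic
is $P(T\,|\,R) = |T \wedge R| / |R|$: strictly same-pixel, no spatial
tolerance, asymmetric in its arguments. Masks come from an external pixel
classifier; the bundled Otsu converter is a convenience, not a
replacement for it. The implementation is verified against a literal
double loop over pixels, and monotonicity/cropping invariances are tested
as properties. One published gene pair prints a probability inconsistent
with its own pixel tallies; it is excluded from the acceptance targets
and the package makes no attempt to reproduce it.

# Atlas rules

**QC.** Boundary semantics are strict per the usual wording: < 200
expressed genes removes a cell (200 kept), < 5 expressing cells removes a
gene (5 kept), mito fraction > 0.10 removes a cell (exactly 0.10 kept).
The filter order — cells, then genes, then mito — is not dictated by the
data; it is fixed and written into the report for reproducibility. Mito
fractions are computed on each cell's unfiltered profile, so the gene
filter cannot change a cell's mito call. The cell and mito filters are
idempotent; the gene filter can in principle cascade (removing cells
changes expressing-cell counts), which the report makes visible.

**Ageing.** `days = 0.9022 × CRL(mm) + 27.372`; days are rounded to the
nearest integer before the divmod by 7, so `PCW5.6` means 5 weeks 6 days.

**Odds ratios.** `OR = odds(p_a) / odds(p_b)` on non-zero cell fractions.
Zeros get the Haldane–Anscombe +0.5 on all four counts of the 2×2 table,
and the result is flagged as corrected. Cut-offs (30-fold
proximal/distal, 3-fold forelimb/hindlimb) are inclusive (≥) and applied
symmetrically in both directions; neither strictness nor symmetry is
dictated elsewhere, so both are parameters.

**Microenvironments.** NMF is a plain Lee–Seung multiplicative-update
factorisation under Frobenius loss, 500 iterations, seeded uniform
initialisation — deterministic given a seed, adequate for the small
spots × cell-types matrices this rule consumes. Membership normalises the
loadings *per cell type across environments* (so "fraction of that cell
type" reads literally; per-environment normalisation would answer a
different question) and uses a strict `> 0.2`, so a cell type can belong
to at most four environments at the default threshold, and a fraction of
exactly 0.2 is excluded.

# Synthetic data: what it emulates, and what a green test proves

The fixtures reproduce the *structure* each consumer needs, not limb
biology:

- a reduced Visium lattice (8×16 by default instead of 78×128, ~100 µm
  pitch at ~8 µm/px giving a 6 px column and 10 px row step) with the
  array parity rule, so readers and the stitcher face realistic geometry;
- negative binomial counts (dispersion 2, log-normal gene means around 2)
  — a generic droplet-like count model chosen once as scaffolding; no
  simulator is prescribed anywhere, and nothing downstream depends on it;
- section images sampled analytically from one smooth global scene
  through each section's ground-truth transform, so stitching with the
  true transforms reassembles the scene and round-trips are exact;
- doublet tables with normal noise (sd 0.02) around a base score of 0.05
  and planted clusters at 0.6 — an effect far beyond the 4-sigma regime
  the power criterion stipulates, mimicking how real doublet clusters
  separate;
- mask pairs constructed to exact dual/total counts, so the expected
  probability is known by construction.

Every generator is a pure function of (spec, seed): RNG state is saved
and restored around each call, and repeated calls are bit-identical.

A green suite therefore establishes the algebra and the contracts —
conservation, round-trips, boundary semantics, error control on the
stated noise model — but not performance on real tissue, where
segmentation quality, image distortion beyond affine, and non-normal
score distributions all intrude.

# Numerical notes

- Stitched containers are plain text (MTX + CSV + JSON + a text image
  matrix); doubles are serialised with `%.17g` so write∘read is
  bit-exact. PGM (ASCII P2) images round to integer gray levels, which
  the fixture images use natively.
- Bilinear samples within a half-pixel guard band (1e-9) of the image
  edge are clamped; outside, the background fill applies.
- `bh_adjust` underflow: extreme z-scores give p = 0 exactly; BH maps
  them to q = 0, which is the correct limit.
- NMF reconstruction error is reported (Frobenius) and is non-increasing
  in the number of environments on fixtures; multiplicative updates can
  stall at zero entries, which the 0.1 lower bound on the initialisation
  avoids.

# Known limitations

- No automatic image registration: transforms come from files or
  landmarks, by design.
- Cross-chip stitching (unequal scale factors) is rejected rather than
  attempted.
- The doublet module consumes any per-cell score in [0, 1]; it neither
  computes Scrublet scores nor produces the over-clustering.
- The NMF solver is basic by intent; swap in a specialised factorisation
  if environments-on-large-slides becomes the bottleneck.
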