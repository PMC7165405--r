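---
title: "Quantifying sarcolemmal proteins and regeneration in muscle sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sarcolemmal proteins and regeneration in muscle sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrequant)
```

## The measurement problem

Quantifying dystrophin in muscle biopsies from Duchenne and Becker muscular
dystrophy (DMD/BMD) patients is a central molecular endpoint for genetic
therapies: trials need to detect subtle increases in sarcolemmal dystrophin,
down to the trace levels many DMD fibres express at baseline. Manual scoring
is subjective and slow; global intensity thresholds fail because background
fluorescence and non-specific signal vary strongly across a section.

fibrequant implements an automated per-fibre analysis of multiplexed
immunofluorescent images of transverse muscle sections. Three channels are
expected: a membrane **mask** stain (laminin alpha-2) outlining every fibre,
a **primary** sarcolemmal stain (dystrophin), and a **tertiary** stain that
is either a second sarcolemmal marker (alpha-sarcoglycan or
beta-dystroglycan, for colocalisation with dystrophin) or a sarcoplasmic
marker (fetal/developmental myosin, for regeneration).

Processing has three stages: (1) tissue detection and artefact exclusion,
(2) fibre segmentation from the laminin mask with partition of each fibre
into sarcolemma ring and sarcoplasm, and (3) per-fibre characterisation —
morphometrics, staining profile, coverage classification, colocalisation
and regeneration calls — aggregated into section-level endpoints.

## Per-fibre background-referenced positivity

The core idea is that each fibre supplies its own background reference: no
functionally relevant sarcolemmal protein is expected in the cytoplasm, and
the cytoplasmic and sarcolemmal background levels are assumed equal. For
fibre $i$ with sarcoplasm pixel intensities $x_{i\cdot}$, the positivity
threshold for a sarcolemmal channel is

$$ t_i = \bar{x}_i + k \, s_i, \qquad k = 3 \text{ by default}, $$

computed independently per fibre; no global threshold exists anywhere in
the pipeline. Sarcolemmal intensities are always *reported raw* (no
background subtraction) — the threshold only decides which ring pixels count
as positive. This makes positivity calls invariant under affine intensity
transforms of a channel, while reported means transform equivariantly.

Ring pixels above $t_i$ are grouped into 8-connected **positive objects**
(components smaller than 3 px are discarded as noise). Fibres with fewer
than 25 sarcoplasm pixels cannot support a stable background estimate and
are flagged unquantifiable: they keep their morphometrics and raw means but
contribute no positivity call.

## Circumference Positivity and coverage classes

Coverage of the sarcolemma is summarised by the **Circumference
Positivity**: the percentage of the fibre's ring circumference covered by
positive objects. The ring mid-line — the closed pixel path equidistant
between the ring's outer and inner edges — provides the reference
circumference; path lengths use chain-code step weights (0.948 per
axis-parallel step, 1.340 per diagonal step), which measure digitised
smooth contours to about 1%.

Two estimators are implemented:

* **projection** (default): each object pixel is projected to its nearest
  mid-line vertex; the covered arc length (full steps where both endpoints
  are covered, half steps where coverage starts or ends) over the
  circumference gives the percentage.
* **literal**: per object, $(\text{border length} - 2w)/2$ summed over
  objects and divided by the circumference, where $w$ is the object's mean
  radial width. A band-shaped object of arc length $s$ and thickness $w$
  has border $\approx 2s + 2w$, so the formula recovers $s$; the
  subtraction removes the two radial end segments. For annular (full-ring)
  objects the border includes the inner boundary. The historical form of
  this formula leaves the units of the subtracted term ambiguous; we read
  the "2" as twice the radial width, which is the only reading that is
  dimensionally consistent and validates against geometric ground truth.

Both estimators are cross-validated on noise-free synthetic arcs against a
brute-force angular sweep from the fibre centroid; they agree with each
other and the sweep to within 2 percentage points over the full coverage
range (the package's acceptance suite runs exactly this check).

Each quantifiable fibre falls into one of four coverage classes —
`0-25` (protein negative), `25-50`, `50-75`, `75-100` — with the negative
bin closed on the right: exactly 25.0% coverage is negative, and a fibre is
protein positive if and only if coverage strictly exceeds 25%. The
conservative 25% cutoff suppresses false-positive classification of trace
or non-specific membrane signal.

## Colocalisation and the myosin module

For a sarcolemmal tertiary stain, ring pixels are split into the
primary-positive set (union of primary objects) and the primary-negative
remainder, and the raw tertiary mean is reported over each. This measures
directly whether the dystrophin-associated protein is enriched where
dystrophin is present. When a fibre has no positive (or no negative) ring
pixels the corresponding mean is *missing*, never zero — zeros would bias
section aggregates.

For a sarcoplasmic tertiary stain (f/d myosin), positivity uses a single
threshold derived from negative-control sections in which the protein is
absent: by default the 99.5th percentile of per-fibre sarcoplasm means
across at least 50 control fibres (a `mean + 5 sd` variant is also
provided). The percentile is robust to occasional outlier control fibres.
A fibre is myosin positive iff its sarcoplasm mean strictly exceeds the
threshold. The threshold is persisted to JSON so every classification is
made against an explicit, auditable value.

## Segmentation design

The membrane-guided segmentation is deliberately simple and deterministic:

1. *Tissue*: Gaussian-smooth the mask channel (sigma 0.5 um), Otsu
   threshold, morphological closing and hole filling, drop components below
   50 um^2. A contrast guard (mean intensity above/below threshold must
   exceed 1.5x) rejects images with no membrane signal, such as pure
   background noise.
2. *Artefacts*: regions saturated in at least two channels (at >= 95% of
   full scale, >= 20 um^2) — section folds, bright debris — are excluded
   before segmentation.
3. *Fibres*: the membrane band is thresholded on the *raw* mask channel
   within tissue (thresholding the smoothed channel would fatten the band
   by its blurred skirts); enclosed interiors seed an intensity-guided
   propagation across the band (a seeded watershed on the laminin ridge),
   which splits membrane shared by touching fibres along the ridge line.
4. *Filters*: accepted fibres must lie within 150-12000 um^2, have
   solidity >= 0.80 (rejects non-convex profiles such as longitudinal
   fibres), mean ring thickness <= 5 um, and must not touch the image
   border (circumference statistics require complete rings). Every
   rejection is recorded with a reason (`area`, `shape`, `ring-thickness`,
   `border`, `ring-dominant`).

The filter values are declared defaults, all configurable; their purposes
(excluding debris-scale and regenerating/atrophic profiles, longitudinal
fibres, and mis-recognised membrane) are fixed, but no published values
exist for them.

Per fibre, the ring is the detected membrane band (mode `laminin-band`) or
a fixed-width inward band (mode `fixed-band`); the sarcoplasm is the fibre
minus the ring, and the two exactly tile the fibre. Tissue-halo fragments
beyond the band's outer edge are trimmed so that the fibre boundary is the
outer edge of the membrane band. "Fibre width" is the minimum caliper
(Feret) diameter — standard muscle-morphometry practice, robust to oblique
sectioning — with one pixel of extent added so an axis-aligned square of
side $n$ pixels measures $n$. Ring thickness is twice the ring's distance
transform sampled along the mid-line.

## The synthetic-section generator

Because no annotated reference images are deposited for this assay, every
stage is validated against synthetic sections with exact ground truth.
`section_spec()` / `generate_section()` render packed convex-polygonal
fibres (8-16 vertices perturbed from random ellipses — transverse fibres
are polygonal, not circular), each with:

* a closed laminin ring of 1.5-2.5 um thickness at 30000 AU;
* one contiguous primary arc subtending a controlled fraction of the ring
  mid-line *arc length* (the quantity Circumference Positivity estimates),
  at 30000 AU — from absent (0) through trace to full revertant-like rings
  (1);
* a tertiary channel either coupled to the primary arc (24000 AU on
  primary-positive arcs vs 12000 AU elsewhere on the ring, a 2:1 effect)
  or sarcoplasmic in a controlled fraction of fibres (4x background,
  emulating regenerating fibres);
* cytoplasmic/background fluorescence of 8000 AU — the weak-fluorescence
  floor of the assay — additive Gaussian noise (sd 500 AU) and clipping to
  the 16-bit range;
* optional injected artefacts: all-channel saturating fold streaks and
  debris blobs, recorded in the ground truth.

Defaults (0.5 um/px, fibre diameters 25-60 um) describe a 20x-scan-like
acquisition of a paediatric biopsy. Identical seeds give bit-identical
sections; control panels derive per-replicate sub-seeds from one master
seed.

The generator emulates the *layout and intensity logic* of the assay, not
its optics: there is no point-spread function, no uneven illumination, no
Poisson photon statistics, and no longitudinal fibres. Passing tests
therefore demonstrate that the measurement logic is correct on images whose
ground truth is known exactly — not that segmentation is robust to every
real-world staining pathology. Heavily damaged tissue remains out of scope,
as for any membrane-mask method.

## Numerical and design choices

* Coordinates are 1-based `[row, col]` matrix indices; area = pixel count
  x pixel_size^2. Default pixel size 0.325 um/px is assumed (with a
  warning) only when reading files that carry no configured value.
* Regions use 4-connectivity; positive objects and mid-line tracing use
  8-connectivity (closed-loop stability).
* Labels are consecutive integers in raster order of first pixel, making
  re-runs byte-identical; there is no randomness anywhere in the analysis
  path.
* Section endpoints average per-fibre values (not pooled pixels), so large
  fibres do not dominate; cumulative-frequency tables are emitted at
  1-percentile resolution.
* Percentages are over quantifiable analysed fibres; rejected and
  unquantifiable counts are reported alongside so any alternative
  denominator can be reconstructed.
* Degenerate inputs fail loudly and specifically: blank or contrast-free
  images ("no tissue detected"), fibres without sarcoplasm
  (`ring-dominant`), sub-8-px masks (error), out-of-range coverage
  percentages (error).

## Validation problem sizes

The test and acceptance suites run on synthetic sections of 12-200 fibres:
coverage recovery uses 200 noisy fibres over the coverage grid
$\{0, 0.1, \ldots, 1\}$; estimator cross-validation uses 22 noise-free
fibres (two per grid step, diameters 40-60 um so the thin-ring
approximation of the literal estimator holds); segmentation fidelity uses
100 fibres plus a 64-fibre section with an injected fold; the myosin
module uses 5 x 64 control fibres, a 200-fibre test section at 30%
positivity and 2 x 100 fresh control fibres; the replicate harness uses
five 64-fibre sections differing only by seed. These sizes give stable
statistics at desk scale; all parameters scale to larger sections
unchanged.

## Limitations

Whole-slide inputs must be tiled upstream (a size guard rejects
whole-slide-scale arrays); longitudinal fibres are rejected, not analysed;
the literal coverage estimator loses accuracy when the ring thickness is
not small against the circumference (thick rings on small fibres); and the
colocalisation ratio is only meaningful when both primary-positive and
primary-negative membrane exist on a fibre — the flagged-missing values
must be respected downstream.
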