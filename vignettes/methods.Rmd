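---
title: "Methods: screening woody plants for drought-heat dual-stress tolerance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening woody plants for drought-heat dual-stress tolerance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woodscreen)
```

## The screening problem

Climate change exposes trees to *sequential* drought and heat stress:
weeks of water withholding followed by acute high temperature.  Screening
woody species for tolerance to that sequence combines four measurements,
and this package implements the quantitative layer of that workflow:

1. **Relative water content (RWC)** after a dehydration shock,
   `100 * (fresh - dry) / (turgid - dry)`, indexes drought tolerance —
   water-retaining species hold high RWC in detached leaves.
2. **Electrolyte leakage index (ELI)** after heat exposure,
   `(EL_H - EL_C) / EL_C` with `EL = conductivity(sample) /
   conductivity(autoclaved control)`, indexes membrane damage — low
   values mean heat-stable membranes.
3. **Evans-blue inhibition index**, `100 * (A_H - A_NC) / (A_PC - A_NC)`
   at 500 nm, scales cell death between an intact negative control and a
   boiled positive control.
4. **DAB staining** visualizes hydrogen peroxide as a brown precipitate;
   its quantification over a 14-phase stress/recovery schedule measures
   how fast a species clears oxidative stress.

Species with high standardized RWC and low standardized ELI — quadrant II
of the standardized scatter — are pre-selected as tolerance candidates;
recovery kinetics and group statistics refine the call.

## Index conventions

The indices are deliberately left unclamped.  RWC outside [0, 100] and
negative ELI are arithmetically possible and always indicate measurement
issues (or genuinely lower leakage under heat); both are returned as
computed with a warning.  Clamping would silently distort the cohort
standardization that the classifier depends on.  Replicates (n = 3
throughout the assays) are aggregated as mean and *sample* SD after the
per-replicate index is computed, not before.

## DAB image quantification

The quantifier reimplements an ROI-based protocol for 8-bit RGB images of
DAB-stained leaf tissue:

* **Stain score** = `255 - red channel`.  The DAB reaction darkens the
  red channel most; inverting makes high score = heavy stain.  The
  inversion is applied unconditionally so that no operator-dependent
  branch exists.
* **ROI placement**: all `size x size` windows (default 100 px) with
  top-left corners on a `stride` grid (default 25 px) are scored by mean
  stain score; a greedy pass picks the best window, then repeatedly the
  best window not overlapping previous picks, until `k = 3` ROIs are
  placed.  Ties break by (row, col) lexicographically, making placement
  fully deterministic.  `stride = 1` is an exhaustive search and serves
  as the oracle for the default grid in the tests.
* **Values**: the reported quantity is the mean HSV **saturation**
  (scaled to 0-255; the published intensities exceed 150, which is
  impossible on a unit scale) inside each ROI.  Stain location and stain
  value thus come from different channels by design: the inverted red
  channel decides *where*, the saturation component decides *how much*.
* **Background correction**: the candidate window with the *lowest* mean
  stain score acts as the non-stained background; its mean saturation is
  subtracted from each ROI mean and the result floored at 0, since
  negative corrected saturation is physically meaningless.

Windows use 1-based, row-major coordinates with origin top-left, covering
rows `row .. row+size-1` — the native R array convention, stated here
once because the exhaustive-oracle tests compare positions bit-exactly.

## Screening classifier

Standardization uses the sample SD, matching the replicate convention.
The scatter orientation is x = z(ELI), y = z(RWC); under this orientation
quadrant II is the high-RWC / low-ELI corner and quadrant IV its
sensitive opposite, which is the only orientation consistent with how
those quadrants are described for the validated species.  Exact zeros on
either standardized axis are labelled `boundary` and never classified.

"Close proximity" to the validated tolerant references is operationalized
as Euclidean distance to the reference *centroid* in z-space with a
configurable radius (default 1.0); a k-nearest alternative is exposed
because no published criterion exists.  The full rule set: references are
`tolerant`; quadrant IV is `sensitive`; quadrant II within the radius is
`candidate`; everything else `unclassified`.

## Recovery kinetics

The 14 phases are A (control), B (H2O2 staining positive control), C
(drought), D-G (45 °C for 30/60/90/120 min) and H-N (recovery for
15/30/60/90/120/240/480 min).  Phase B is a staining control and is
excluded from kinetics summaries.  "Undetectable" hydrogen peroxide is
operationalized as a *sustained* threshold: the first recovery phase
whose mean falls to the control mean plus `margin` (default 2) control
SDs *and stays there through every later phase*.  The sustained rule is a
documented choice — these series show transient mid-recovery rises, and a
plain first-crossing rule would call clearance during a dip.  Ranking
uses the endpoint value at N (primary key) because late-recovery levels
are what separates resilient from persistent-damage species; ties break
by larger net recovery (H minus N), then species code.  Profile
clustering z-normalizes each series so shape, not absolute level, drives
the grouping, then applies average-linkage agglomerative clustering on
Euclidean distances.

## Group statistics

One-way ANOVA is fitted via `stats::lm`/`anova`.  Duncan's multiple range
test computes least-significant ranges `r_p * sqrt(MSE/n)` from the
studentized range quantile at protection level `1 - (1-alpha)^(p-1)`
(`stats::qtukey`), applies the standard step-down non-contradiction rule,
and uses the harmonic mean of group sizes when unbalanced.  Compact
letters follow the insert-and-absorb algorithm, ordered by descending
mean.  `dmrt_from_summary()` reconstructs the test from published
mean ± SD tables with `MSE = mean(SD^2)` and `(n-1)k` error degrees of
freedom; that reconstruction is exact for balanced designs, but letter
displays from published tables are still labelled approximate because the
original software's tie handling is unknowable.

## Synthetic data: what it emulates, and what it does not

Every generator is a right inverse of its analysis at zero noise, so the
pipeline can be validated on inputs with known truth:

* `gen_leaf_image()` plants brown blobs (hue 30°, value 200, saturation
  = the controlled target) on an achromatic background; at zero noise the
  only recovery error is 8-bit rounding (≤ ~0.7 saturation units with
  these defaults).  Blob centers snap to the 25-px ROI grid so the greedy
  search and the exhaustive oracle coincide on these images.  Default
  images are 512 × 512: large enough for three non-overlapping ROIs and
  a clean background window, small enough that a twenty-image recovery
  sweep runs in seconds.
* `gen_weight_series()` and `gen_conductivity()` invert the RWC and
  ELI formulas exactly.
* `gen_dab_series()` produces the two published kinetic regimes:
  *tolerant* (rise over D-G, exponential decay pinned to cross the
  control baseline exactly at the programmed clearance phase) and
  *sensitive* (rise to a persistent high plateau).
* `gen_cohort()` plants tolerant/sensitive classes separated by a chosen
  number of within-class SDs on both axes.  For separations of 2 SD or
  more the generator truncates class draws to ±0.75 class SDs and redraws
  the cohort until each class falls strictly on its own side of the
  cohort mean on both axes: "separated by s SD" is a statement about the
  cohort actually returned, not about latent means, and that realized
  separation is what makes planted labels recoverable by construction.
  At separation 0 the classes coincide and recovery is at chance.  In
  recovery tests the selection radius is set to 2.5 standardized units —
  an upper bound on the planted tolerant cluster's diameter in z-space —
  so that "within radius of the references" covers exactly the planted
  class.

The noise model everywhere is additive Gaussian truncated to valid
ranges.  This is a stand-in sufficient for recovery and power checks, not
a claim about real assay noise: real stained leaves have venation,
uneven illumination, chlorophyll-bleaching artifacts and spatially
correlated stain texture that these images do not emulate.  Passing
recovery tests therefore demonstrates the correctness of the algorithms,
not field performance on real imagery.

## Packaged reference values

The package ships three small fixtures: the 27-species screening panel
with abbreviation codes; the published DAB intensity table (6 species ×
14 phases, mean ± SD and Duncan letters — one cell, *C. sinensis* at
phase L, carries no letter in the source and is stored empty); and the
per-species RWC/ELI values printed in the running text of the source
study (8 species).  The full 27-species RWC/ELI values were published
only graphically, so cohort-level examples beyond those 8 species use
`gen_cohort()`.  Heat-treatment metadata (temperature, duration) are
deliberately not inputs to any formula: the indices are ratios of
measured quantities, and treatment conditions are recorded alongside, not
inside, the computation.

## Numerical choices and degenerate inputs

* Degenerate cohorts (zero SD on an axis) are refused, not propagated as
  NaN z-scores.
* `survival_rate()` takes explicit counts; no denominator is assumed.
* DMRT with zero MSE declares any nonzero difference significant and
  ties non-significant, the limit of the range test.
* Clearance uses `<=` against the threshold, so a series equal to its
  baseline clears at the first recovery phase.
* Images must be 8-bit 3-channel; grayscale or 16-bit input raises an
  explicit unsupported-format error instead of being converted, because
  silent conversion would change saturation values downstream.

## Known limitations

* Letter displays recomputed from published mean ± SD tables can differ
  from the original raw-data letters; only the all-`a` control column is
  asserted against the source.
* The published narrative clearance times for some species cannot be
  cross-validated against the published table (different species sets);
  no reconciliation is attempted.
* Species where visual stain intensity and saturation-based values
  disagree (dense but weakly chromatic staining) are reproduced as
  measured; no algorithmic correction is attempted.
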