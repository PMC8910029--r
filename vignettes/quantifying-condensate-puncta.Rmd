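---
title: "Quantifying condensate puncta in fluorescence micrographs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying condensate puncta: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Biomolecular condensates such as yeast P-bodies appear in wide-field
fluorescence micrographs as bright puncta on a dimmer cytoplasmic
background.  Their accumulation is continuous — miniscule foci in
exponentially growing cells intensify gradually under stress or in
post-exponential growth — so "fraction of cells with visible puncta" is a
poor readout.  `punctaquant` implements an intensity-based quantification
chain instead:

1. **Shading correction.** Raw images follow
   `I(x) = flatfield(x) * S(x) + darkfield(x)`, where the flat-field is the
   multiplicative spatial gain of the optics/camera (mean 1 by convention)
   and the dark-field an additive offset.  `correct_image()` inverts this
   model; `estimate_shading()` recovers both fields retrospectively from a
   stack of fields (below).
2. **Segmentation.** Each corrected image is rescaled to 8 bit and the top
   0.05% brightest pixels (`top_fraction = 0.0005`, with
   `k = floor(top_fraction * N)` and a strict-greater threshold at the
   `(N-k)`-th order statistic) form the punctum mask.  Ties at the
   threshold are excluded, so a constant image selects nothing and the
   selected-pixel budget `k` is never exceeded.
3. **Particle analysis.** 8-connected components of the mask become
   puncta; each carries its maximal intensity and integrated density
   (sum of member intensities), with no minimum-area filter.
4. **Per-field metrics.** The distribution of per-punctum maximal
   intensities measures punctum density/brightness; the summed integrated
   density divided by the cell count gives the *integrated density per
   cell*, the per-cell accumulation metric.
5. **Statistics.** Mean ± SEM summaries, pooled Student's t tests, and —
   when many puncta from few independent experiments are compared — a
   nested t test that uses the between-experiment mean square as the error
   term, guarding against pseudoreplication.  Significance stars use
   strict thresholds (`*` p<0.05 … `****` p<0.0001, `n.s.` otherwise).
6. **RRR.** The Relative Response Ratio re-anchors a test construct's
   mutant/wild-type response ratio so the negative control (empty vector)
   maps to 0 and the positive control (reference scaffold) to 1:

   RRR = (R_test − R_neg) / (R_pos − R_neg), with R = I_mut / I_wt and
   I the integrated density per cell.

   It is affine in R_test and invariant to jointly rescaling all mutant
   (or all wild-type) measurements, so exposure-level differences between
   backgrounds cancel.

## The synthetic micrograph generator

No raw micrographs are publicly available for this class of experiment,
so the package ships a generator whose ground truth makes every stage
testable.  A field is rendered as:

* **Cells:** filled ellipses, radii 15–25 px (a 4–5 µm yeast cell at the
  ~150 nm/px sampling the radii imply), placed on a jittered grid that
  guarantees separation — automated counting is then well-posed.  A
  `placement = "uniform"` mode instead draws centers uniformly over a
  margin-expanded frame, giving spatially flat expected coverage; that is
  the geometry shading estimation relies on, at the price of cells that
  may touch or clip the border.
* **Puncta:** isotropic 2D Gaussians truncated at 4σ, σ = 0.8 px by
  default.  The value follows from the cell geometry: radii of 15–25 px
  for a yeast cell imply ~150 nm pixels, where a diffraction-limited PSF
  has σ ≈ 0.7–0.8 px.  Punctum counts per cell are negative-binomial
  (Poisson when the dispersion is infinite); amplitudes are log-normal
  with a stated mean and CV (0.25 by default).  Each punctum center lies
  inside its parent cell.
* **Shading:** a smooth radial-polynomial flat-field scaled into
  [0.7, 1.3] and normalized to mean 1, plus a constant-with-gradient
  dark-field (8 counts by default).  One shading model is shared by all
  fields of a simulated imaging session, as on a real microscope.
* **Noise:** Poisson shot noise on the shaded signal (photon gain 1.0)
  plus Gaussian read noise (SD 2 counts), then rounding and clipping to
  the 16-bit range — a typical CCD regime.  Setting both to zero yields
  exact noise-free fields used by the analytic oracle tests.
* **Phase images:** synthetic contrast only (dark interiors and rims on a
  light background), sufficient for counting; no physical phase-contrast
  optics are modelled.

Condition presets map the experimental designs this pipeline targets onto
generator parameters: log-phase (dim, sparse puncta), diauxic shift and
glucose deprivation (intensified puncta), empty-vector control vs.
scaffold overexpression (4-fold punctum amplitude), persistence under
cycloheximide, and dispersal presets (hexanediol treatment, glucose
replenishment) that move the expected punctum intensity into the
cytoplasmic baseline so total cell fluorescence is conserved — dispersal
changes localization, not protein level.

What the generator does *not* emulate: budding morphology, crowded or
overlapping cells, vacuole-dark regions, per-cell expression variability
of the baseline, photobleaching, focus drift, or 3D structure.  Passing
tests therefore demonstrate correctness of the measurement chain under a
controlled image model, not robustness to every real-world artefact.

## Retrospective shading estimation: design rationale

`estimate_shading()` must separate a multiplicative and an additive field
from the images alone.  Two observations drive the design:

* Across a stack of fields whose cells land at different positions, every
  pixel sees both cell-free background (level `darkfield(x)`) and
  cell-covered signal (level `flatfield(x) * s0 + darkfield(x)`, `s0` the
  typical cytoplasmic signal) somewhere in the stack.
* Both fields are physically smooth, so low-order surfaces are the right
  regularizer.

The estimator alternates (a) a robust per-pixel two-level summary —
samples are split by a threshold surface; the background mean estimates
the dark-field and the foreground *median* the covered level, the median
rejecting the rare bright punctum samples — with (b) weighted
polynomial-surface fits (degree = `smoothness`, default 4) of the two
raw summaries, the foreground surface rescaled to mean 1 as the
flat-field and the background surface clamped non-negative as the
dark-field.  The threshold surface is then updated to the midpoint of the
two fitted levels and the loop repeats until the relative change drops
below `tol`.

A per-pixel linear regression of intensity against a per-image brightness
scalar (the textbook rank-one formulation) was evaluated first and
rejected: its per-pixel noise is dominated by *cell-coverage* fluctuations,
which are correlated over cell-sized patches, so the smoothness fit
cannot average them away — flat-field errors of tens of percent remained
on 32-image stacks.  The two-level summary's residual noise is per-pixel
photon noise, which is spatially independent, and the surface fit reduces
it to well under 1%.

Properties: the estimate is deterministic for a fixed stack and settings,
invariant to image order (all summaries are order statistics), needs at
least 8 images (`min_images`), warns and returns the identity model for
structureless stacks (flat-field 1, dark-field 0 — the zero-dark-field
convention), and warns on non-convergence while still returning the
current estimate (partial correction beats none).  Limitations: a real
cytoplasm is not a single level; per-cell expression variability inflates
the foreground spread, and the polynomial surface cannot follow
high-frequency shading (dust specks).  Profiles estimated once can be
saved (`save_shading_profile()`) and reused (`load_shading_profile()`),
covering the predefined-profile workflow.

## The 8-bit question

An ImageJ-style workflow converts to 8 bit before segmenting and
measuring.  With a *per-image* min–max display range the conversion
destroys absolute comparability: every image's brightest pixel becomes
255, so intensities from different images live on different scales.
`measure_field()` follows the literal transform-then-measure order and
defaults to per-image scaling with the mapping recorded for audit, but
accepts a fixed `bit8_range`; `run_pipeline()` defaults to one *global*
range shared by every image of a run (`bit8_range: "global"`), which
keeps intensities comparable across conditions while staying within the
8-bit workflow, and records the range used in the run manifest.
`measure_on = "corrected"` bypasses 8-bit quantization entirely and reads
intensities from the full-depth corrected image.  The whole-pixel budget
`k`, threshold, and 8-bit mapping are logged per field so the percentile
segmentation is auditable.

## Statistical conventions

* "Student's t test" is the pooled-variance two-sided test
  (`df = n_a + n_b − 2`); Welch's form is available behind a flag.  Zero
  pooled variance with equal means returns `t = 0, p = 1` by convention;
  with unequal means the statistic is undefined and raises an error.
* The nested t test is the one-way nested-ANOVA ratio
  `t² = MS(group) / MS(experiment-within-group)` with
  `df = m_a + m_b − 2` experiments.  In the balanced case this is exactly
  the mixed-model "nested t"; unbalanced designs reuse the same sums of
  squares and df convention (a documented simplification — no
  Satterthwaite adjustment).  With one value per experiment it reduces
  exactly to the pooled t test.
* Tests are unpaired, and no multiple-testing correction is applied:
  comparisons are reported per contrast with stars, matching the
  reporting style this pipeline reproduces.
* RRR is computed from the grand mean of integrated density per cell per
  strain × construct; a per-experiment RRR distribution is a possible
  extension but the grand-mean form is the default.

## Numerical choices and degenerate inputs

* Percentile tie-breaking is strict (`> t`), making the constant image
  well-defined (empty mask) and the budget `Σ area ≤ k` an invariant.
  `k` uses `floor`, a conservative budget.
* 8-bit conversion of a constant image yields all zeros.
* Cell count 0 with puncta present is an error (the per-cell metric is
  undefined); 0 cells with 0 puncta yields 0.
* Coordinates are 1-based `(row, col)` matrix indices, the R convention.
* Shading profile TIFFs store grids scaled into [0, 1] by a recorded
  power-of-two factor at 32 bits per sample (~1e-9 relative
  quantization).

## Problem sizes used by the shipped checks

The package's own verification uses desk-scale versions of the target
designs, chosen to keep the full suite to a few minutes while preserving
the statistical structure: shading recovery uses 5 × 32 fields of
128 × 128 px with 10–60 cells each; the end-to-end effect-size check uses
20 simulated experiments of 2 groups × 3 replicate experiments × 2 fields
× 50 cells at 512 × 512 (100 cells per group per experiment, >300 per
group overall); the RRR demonstrations use 6 strain × construct groups ×
3 experiments × 3 fields × 24 cells at 256 × 256 (~220 cells per group).
Ground-truth cell counts are used in the end-to-end checks; automated
phase-image counting is validated separately (exact on ≥95% of default
fields across 20 seeds).

## Known limitations

* The nested test's unbalanced-design df convention is approximate (see
  above).
* Automated counting assumes separated cells of roughly elliptical shape;
  crowded real fields need precomputed counts (supported everywhere a
  count is consumed).
* The RRR propagates no uncertainty; report it alongside the per-group
  mean ± SEM.
* Segmentation at a fixed top-percentile budget is intrinsically
  relative: with many equally bright puncta the budget is shared, and
  absolute integrated densities saturate as puncta multiply.
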