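# punctaquant

Quantification of biomolecular-condensate accumulation in wide-field
fluorescence micrographs.

Condensates such as yeast P-bodies show up as bright puncta over a dimmer
cytoplasm, and their accumulation is continuous — from miniscule foci in
exponentially growing cells to intense granules under stress or in
post-exponential growth.  `punctaquant` is for microscopists and image
analysts who need that accumulation measured reproducibly rather than
scored by eye.  It implements, as tested R functions:

* **retrospective shading correction** under the acquisition model
  `I(x) = flatfield(x)·S(x) + darkfield(x)`, with the flat-field
  (mean-1 multiplicative gain) and dark-field (additive offset) either
  estimated from the image stack itself or loaded as predefined profiles;
* **top-percentile punctum segmentation**: the top 0.05% brightest pixels
  of each (8-bit rescaled) corrected image, `k = floor(0.0005·N)`, with a
  strict-greater threshold at the `(N−k)`-th order statistic;
* **particle analysis**: 8-connected components with per-punctum maximal
  intensity and integrated density, and the per-field summary
  *integrated density per cell* = Σ punctum integrated density ÷ cell
  count (cells counted automatically from phase images, or supplied);
* **Relative Response Ratio (RRR)**: with `R = I_mut/I_wt` for a
  construct's integrated density per cell in two genetic backgrounds,

  `RRR = (R_test − R_neg) / (R_pos − R_neg)`

  anchors the empty-vector negative control at 0 and the reference
  scaffold positive control at 1;
* **replicate-aware statistics**: mean ± SEM, pooled Student's *t*, and a
  nested *t* test (`t² = MS(group)/MS(experiment-within-group)`,
  `df = m_a + m_b − 2`) for many-puncta/few-experiments comparisons, with
  strict star coding (`*` p<0.05 … `****` p<0.0001, `n.s.` otherwise);
* **a synthetic micrograph generator** with complete ground truth (cells,
  puncta, shading, noise) and condition presets (log phase, diauxic
  shift, glucose deprivation, vector control vs. scaffold
  overexpression, cycloheximide persistence, hexanediol/glucose
  dispersal), so the whole chain is testable without any data download;
* **a declarative pipeline** (`run_pipeline()`) driving
  simulate/ingest → correct → measure → test/RRR from one config, with a
  run manifest that makes every number re-derivable.

See `vignettes/quantifying-condensate-puncta.Rmd` for the methods and the
design rationale.

## Worked example

Simulate a field of 50 cells under scaffold overexpression, correct it,
and measure it:

```r
library(punctaquant)

presets <- pb_presets()
field <- generate_field(presets$scaffold_overexpression, n_cells = 50, seed = 42)
corrected <- correct_image(field$fluor, identity_shading(c(512, 512)))
m <- measure_field(corrected, field$phase,
                   condition = "overexpression", experiment_id = "e1",
                   field_id = "f1")
m
#> <field_measurement overexpression/e1/f1: 50 cells, 53 puncta, intden/cell 412.260>
mean_sem(m$max_intensities)
#>       mean        sem
#> 177.415094   4.685418
```

All 50 simulated cells were found in the phase image; the top-0.05%
segmentation yielded 53 puncta (the generator placed about one per cell)
whose summed integrated density, divided by the 50 cells, gives an
integrated density per cell of 412 (8-bit units under the per-image
display mapping recorded in `m$mapping`).

A two-condition experiment — empty vector vs. scaffold overexpression
(4× punctum amplitude), three replicate experiments of two fields × 50
cells each — through the full pipeline:

```r
cfg <- list(
  mode = "simulate", seed = 1, shading = "identity", cell_counts = "truth",
  design = list(
    groups = list(list(label = "vector", preset = "vector_control"),
                  list(label = "overexpression", preset = "scaffold_overexpression")),
    n_experiments = 3, n_fields_per_experiment = 2, cells_per_field = 50,
    simulate_shading = FALSE),
  comparisons = list(
    list(a = "overexpression", b = "vector", metric = "max_intensity", test = "nested"),
    list(a = "overexpression", b = "vector", metric = "intden_per_cell", test = "student")))
bundle <- run_pipeline(validate_config(cfg))
bundle$tests
#>                a      b          metric    test statistic df            p stars
#> 1 overexpression vector   max_intensity  nested  72.27008  4 2.196660e-07  ****
#> 2 overexpression vector intden_per_cell student  26.39379 10 1.405112e-10  ****
tapply(bundle$fields$integrated_density_per_cell, bundle$fields$condition, mean)
#> overexpression         vector
#>         312.01         124.46
```

The overexpression group's integrated density per cell is about 2.5-fold
the vector control's (the 4× amplitude effect compressed by the shared
cytoplasmic baseline), the nested *t* on punctum maximal intensities uses
the 6 replicate experiments as its error units (`df = 4`), and both
metrics are starred `****`.

A thin command-line front end over the same functions lives at
`inst/cli/punctaquant.R` (`simulate | correct | measure | stats | run`).

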