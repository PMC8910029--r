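# Shared fixtures for the suite: small presets and fields so individual
# tests stay fast; intensity parameters mirror the package defaults.

tiny_preset <- function(amp = 120, n_mean = 1, cv = 0.25, name = "tiny") {
  condition_preset(name, c(mean = n_mean, dispersion = Inf),
                   c(mean = amp, cv = cv), 0.8, 40, TRUE)
}

# A corrected micrograph built directly from a pixel matrix.
as_corrected <- function(px) micrograph(px, corrected = TRUE)

# Measure a generated field against its ground-truth cell count on the
# full-depth corrected image (identity shading).
measure_truth <- function(field, dim, ...) {
  corr <- correct_image(field$fluor, identity_shading(dim))
  measure_field(corr, field$truth$cell_count, ...)
}

# Independent nested-ANOVA oracle: explicit sums of squares, F on the
# experiment-within-group mean square, df = m_total - 2.
nested_oracle <- function(va, ea, vb, eb) {
  gmean <- mean(c(va, vb))
  ss_group <- length(va) * (mean(va) - gmean)^2 +
    length(vb) * (mean(vb) - gmean)^2
  ss_expt <- 0
  for (x in split(va, ea)) ss_expt <- ss_expt + length(x) * (mean(x) - mean(va))^2
  for (x in split(vb, eb)) ss_expt <- ss_expt + length(x) * (mean(x) - mean(vb))^2
  df <- length(unique(ea)) + length(unique(eb)) - 2L
  t2 <- ss_group / (ss_expt / df)
  t <- sign(mean(va) - mean(vb)) * sqrt(t2)
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
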