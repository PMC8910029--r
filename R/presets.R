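#' Define a biological condition preset for the simulator
#'
#' A preset parameterizes the fluorescence phenotype of one strain x
#' construct x treatment combination: how many puncta a cell carries, how
#' bright and how wide they are, and the dispersed cytoplasmic baseline.
#' All intensities are expressed in raw camera counts *before* shading and
#' noise are applied.
#'
#' @param name Preset label.
#' @param puncta_per_cell Length-2 numeric `c(mean, dispersion)`: the mean
#'   punctum count per cell and the negative-binomial size parameter
#'   (`Inf` gives a Poisson count).
#' @param punctum_amplitude Length-2 numeric `c(mean, cv)`: mean peak
#'   amplitude above the cytoplasmic baseline, in camera counts, and its
#'   coefficient of variation (log-normal across puncta).
#' @param punctum_sigma_px Isotropic Gaussian spot width (SD) in pixels.
#' @param cytoplasm_baseline Mean dispersed cytoplasmic intensity inside
#'   cells, camera counts.
#' @param condensed Logical: `TRUE` for a punctate state, `FALSE` for a
#'   dispersed state.  A zero mean punctum count is only valid when
#'   `condensed` is `FALSE`.
#' @return An object of class `condition_preset`.
#' @export
condition_preset <- function(name,
                             puncta_per_cell = c(mean = 1, dispersion = Inf),
                             punctum_amplitude = c(mean = 100, cv = 0.25),
                             punctum_sigma_px = 0.8,
                             cytoplasm_baseline = 40,
                             condensed = TRUE) {
  stopifnot(length(puncta_per_cell) == 2L, length(punctum_amplitude) == 2L)
  mu <- puncta_per_cell[[1]]; amp <- punctum_amplitude[[1]]
  cv <- punctum_amplitude[[2]]
  if (mu < 0 || puncta_per_cell[[2]] <= 0)
    stop("punctum count mean must be >= 0 and dispersion > 0")
  if (condensed && amp <= 0)
    stop("a condensed preset requires a positive punctum amplitude")
  if (!condensed && mu > 0)
    stop("a dispersed preset must have zero mean puncta per cell")
  if (condensed && mu == 0)
    stop("zero mean puncta per cell is only valid for a dispersed preset")
  if (cv < 0 || punctum_sigma_px <= 0 || cytoplasm_baseline < 0)
    stop("invalid intensity parameters")
  structure(
    list(name = name,
         puncta_per_cell = c(mean = mu, dispersion = puncta_per_cell[[2]]),
         punctum_amplitude = c(mean = amp, cv = cv),
         punctum_sigma_px = punctum_sigma_px,
         cytoplasm_baseline = cytoplasm_baseline,
         condensed = condensed),
    class = "condition_preset"
  )
}

#' @export
print.condition_preset <- function(x, ...) {
  cat(sprintf(
    "<preset '%s': %s, %.2g puncta/cell, amplitude %g (cv %.2g), sigma %.2g px, baseline %g>\n",
    x$name, if (x$condensed) "condensed" else "dispersed",
    x$puncta_per_cell[["mean"]], x$punctum_amplitude[["mean"]],
    x$punctum_amplitude[["cv"]], x$punctum_sigma_px, x$cytoplasm_baseline))
  invisible(x)
}

#' Derive a dispersed preset that conserves total cell fluorescence
#'
#' Models condensate dispersal (1,6-hexanediol treatment, glucose
#' replenishment): puncta vanish and their expected integrated intensity is
#' redistributed into the cytoplasmic baseline, so the expected total
#' fluorescence per cell is unchanged.  This mirrors the observation that
#' protein levels are unaffected when condensates disperse; only the
#' spatial distribution changes.
#'
#' @param preset A condensed [condition_preset].
#' @param name Label for the derived preset.
#' @param mean_cell_area_px Mean cell area in pixels used to spread the
#'   punctum intensity; the default matches the generator's default cell
#'   geometry (mean radius 20 px).
#' @return A dispersed [condition_preset].
#' @export
disperse_preset <- function(preset, name = paste0(preset$name, "_dispersed"),
                            mean_cell_area_px = pi * 20^2) {
  stopifnot(inherits(preset, "condition_preset"), preset$condensed)
  # expected integrated punctum intensity per cell: E[count] * E[amp] * 2*pi*sigma^2
  vol <- preset$puncta_per_cell[["mean"]] *
    preset$punctum_amplitude[["mean"]] * 2 * pi * preset$punctum_sigma_px^2
  condition_preset(
    name = name,
    puncta_per_cell = c(mean = 0, dispersion = Inf),
    punctum_amplitude = c(mean = 0, cv = 0),
    punctum_sigma_px = preset$punctum_sigma_px,
    cytoplasm_baseline = preset$cytoplasm_baseline + vol / mean_cell_area_px,
    condensed = FALSE
  )
}

#' Built-in condition presets
#'
#' Named presets emulating the experimental designs the pipeline targets:
#' exponential (log-phase) growth with miniscule P-body puncta, the diauxic
#' shift and glucose deprivation with intensified condensates, an
#' empty-vector control versus scaffold overexpression (4-fold punctum
#' amplitude), condensates persisting under cycloheximide, and
#' fluorescence-conserving dispersal presets for hexanediol treatment and
#' glucose replenishment.
#'
#' @return A named list of [condition_preset] objects.
#' @export
pb_presets <- function() {
  vector_amp <- 60
  presets <- list(
    log_phase = condition_preset(
      "log_phase", c(mean = 1.5, dispersion = 5),
      c(mean = 60, cv = 0.25), 0.8, 40, TRUE),
    diauxic_shift = condition_preset(
      "diauxic_shift", c(mean = 3, dispersion = 5),
      c(mean = 180, cv = 0.25), 0.8, 40, TRUE),
    glucose_deprivation = condition_preset(
      "glucose_deprivation", c(mean = 4, dispersion = 5),
      c(mean = 220, cv = 0.25), 0.8, 40, TRUE),
    vector_control = condition_preset(
      "vector_control", c(mean = 1, dispersion = Inf),
      c(mean = vector_amp, cv = 0.25), 0.8, 40, TRUE),
    scaffold_overexpression = condition_preset(
      "scaffold_overexpression", c(mean = 1, dispersion = Inf),
      c(mean = 4 * vector_amp, cv = 0.25), 0.8, 40, TRUE),
    chx_persistence = condition_preset(
      "chx_persistence", c(mean = 1, dispersion = Inf),
      c(mean = 4 * vector_amp, cv = 0.25), 0.8, 40, TRUE),
    mutant_vector = condition_preset(
      "mutant_vector", c(mean = 0.3, dispersion = Inf),
      c(mean = 40, cv = 0.25), 0.8, 40, TRUE)
  )
  presets$hexanediol_dispersal <- disperse_preset(
    presets$scaffold_overexpression, "hexanediol_dispersal")
  presets$glucose_replenishment <- disperse_preset(
    presets$glucose_deprivation, "glucose_replenishment")
  presets
}

#' Rescale the punctum amplitude of a preset
#'
#' Convenience for building effect-size series (e.g. amplitude ratios
#' 1, 2, 4 between otherwise identical groups).
#'
#' @param preset A [condition_preset].
#' @param factor Positive multiplier applied to the mean punctum amplitude.
#' @param name Label for the derived preset.
#' @return A [condition_preset].
#' @export
scale_amplitude <- function(preset, factor,
                            name = sprintf("%s_x%g", preset$name, factor)) {
  stopifnot(inherits(preset, "condition_preset"), factor > 0)
  condition_preset(
    name = name,
    puncta_per_cell = preset$puncta_per_cell,
    punctum_amplitude = c(mean = preset$punctum_amplitude[["mean"]] * factor,
                          cv = preset$punctum_amplitude[["cv"]]),
    punctum_sigma_px = preset$punctum_sigma_px,
    cytoplasm_baseline = preset$cytoplasm_baseline,
    condensed = preset$condensed
  )
}
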