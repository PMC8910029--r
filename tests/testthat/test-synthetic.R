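test_that("identical seeds give bit-identical image pairs and ground truth", {
  p <- pb_presets()$glucose_deprivation
  a <- generate_field(p, 15, seed = 9L, dim = c(128L, 128L))
  b <- generate_field(p, 15, seed = 9L, dim = c(128L, 128L))
  expect_identical(a$fluor$pixels, b$fluor$pixels)
  expect_identical(a$phase$pixels, b$phase$pixels)
  expect_identical(a$truth, b$truth)
  # a different seed changes the field
  c <- generate_field(p, 15, seed = 10L, dim = c(128L, 128L))
  expect_false(identical(a$fluor$pixels, c$fluor$pixels))
})

test_that("generator leaves the caller's RNG stream untouched", {
  set.seed(123); r1 <- runif(1)
  set.seed(123); invisible(generate_field(tiny_preset(), 5, seed = 1L,
                                          dim = c(96L, 96L), phase = FALSE))
  r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("noise-free dispersed field is constant at the baseline inside cells", {
  d <- pb_presets()$hexanediol_dispersal
  fl <- generate_field(d, 10, seed = 3L, dim = c(200L, 200L),
                       gain = 0, read_noise_sd = 0, phase = FALSE)
  vals <- sort(unique(as.vector(fl$fluor$pixels)))
  expect_equal(vals, c(0, d$cytoplasm_baseline))
  expect_identical(sum(fl$fluor$pixels > 0), fl$truth$n_cell_pixels)
})

test_that("noise-free field intensity matches the analytic bookkeeping within 0.1%", {
  p <- pb_presets()$glucose_deprivation
  for (s in 1:5) {
    fl <- generate_field(p, 20, seed = s, dim = c(256L, 256L),
                         gain = 0, read_noise_sd = 0, phase = FALSE)
    tr <- fl$truth
    # baseline-weighted coverage + truncated Gaussian spot volumes
    expected <- p$cytoplasm_baseline * tr$n_cell_pixels +
      sum(tr$puncta_records$amplitude) *
        2 * pi * p$punctum_sigma_px^2 * (1 - exp(-8))
    expect_lt(abs(sum(fl$fluor$pixels) - expected) / expected, 0.001)
  }
})

test_that("every punctum center lies inside its parent cell", {
  p <- pb_presets()$diauxic_shift
  for (s in 1:5) {
    fl <- generate_field(p, 15, seed = 100 + s, dim = c(256L, 256L),
                         phase = FALSE)
    tr <- fl$truth
    expect_identical(tr$cell_count, nrow(tr$cell_records))
    for (j in seq_len(nrow(tr$puncta_records))) {
      pu <- tr$puncta_records[j, ]
      ce <- tr$cell_records[pu$cell, ]
      dx <- pu$row - ce$row; dy <- pu$col - ce$col
      u <- dx * cos(ce$theta) + dy * sin(ce$theta)
      v <- -dx * sin(ce$theta) + dy * cos(ce$theta)
      expect_lte((u / ce$r1)^2 + (v / ce$r2)^2, 1)
    }
  }
})

test_that("simulated flat-fields have mean 1 and dark-fields are non-negative", {
  for (s in 1:5) {
    sm <- simulate_shading(c(96L, 96L), seed = s)
    expect_lt(abs(mean(sm$flatfield) - 1), 1e-6)
    expect_true(all(sm$flatfield > 0))
    expect_true(all(sm$darkfield >= 0))
  }
  expect_identical(simulate_shading(c(64L, 64L), 5)$flatfield,
                   simulate_shading(c(64L, 64L), 5)$flatfield)
})

test_that("invalid generator inputs are rejected", {
  p <- tiny_preset()
  expect_error(generate_field(p, 5, dim = c(0L, 64L)), "positive")
  huge <- condition_preset("huge", c(1, Inf), c(100, 0.2),
                           punctum_sigma_px = 200, cytoplasm_baseline = 40)
  expect_error(generate_field(huge, 5, dim = c(64L, 64L)), "sigma")
  expect_error(condition_preset("bad", c(0, Inf), c(100, 0.2),
                                condensed = TRUE), "dispersed")
  expect_error(condition_preset("bad", c(2, Inf), c(100, 0.2),
                                condensed = FALSE), "dispersed")
})

test_that("an experiment yields one record per group x experiment x field with distinct seeds", {
  pr <- pb_presets()
  des <- experiment_design(
    list(a = pr$vector_control, b = pr$vector_control),
    n_experiments = 3L, n_fields_per_experiment = 2L, cells_per_field = 6L,
    base_seed = 11L, dim = c(96L, 96L), cell_radius_px = c(6, 9),
    shading = FALSE, phase = FALSE)
  ex <- generate_experiment(des)
  expect_length(ex$records, 12L)
  seeds <- vapply(ex$records, `[[`, 0L, "seed")
  expect_identical(anyDuplicated(seeds), 0L)
  # two groups sharing a preset: ground-truth amplitude ratio is 1
  expect_equal(unname(ex$amplitude_ratio["wildtype:b", "wildtype:a"]), 1)
  # reproducible end to end
  ex2 <- generate_experiment(des)
  expect_identical(ex$records[[5]]$fluor$pixels, ex2$records[[5]]$fluor$pixels)
  expect_error(experiment_design(list()), "empty")
})

test_that("a 4x punctum amplitude ratio is recovered as a measured intden ratio in [2.5, 6]", {
  pr <- pb_presets()
  ratios <- vapply(1:10, function(s) {
    des <- experiment_design(
      list(vec = pr$vector_control, oe = pr$scaffold_overexpression),
      n_experiments = 2L, n_fields_per_experiment = 2L, cells_per_field = 20L,
      base_seed = 500L + s, dim = c(256L, 256L), shading = FALSE,
      phase = FALSE)
    ex <- generate_experiment(des)
    idpc <- vapply(ex$records, function(r)
      measure_truth(r, c(256L, 256L),
                    measure_on = "corrected")$integrated_density_per_cell, 0)
    grp <- vapply(ex$records, `[[`, "", "group")
    mean(idpc[grp == "wildtype:oe"]) / mean(idpc[grp == "wildtype:vec"])
  }, 0)
  expect_true(all(ratios >= 2.5 & ratios <= 6))
})

test_that("raising punctum amplitude never lowers integrated density per cell (paired seeds)", {
  pr <- pb_presets()
  for (s in 1:10) {
    f1 <- generate_field(pr$vector_control, 12, seed = s,
                         dim = c(160L, 160L), phase = FALSE)
    f2 <- generate_field(scale_amplitude(pr$vector_control, 2), 12, seed = s,
                         dim = c(160L, 160L), phase = FALSE)
    m1 <- measure_truth(f1, c(160L, 160L), measure_on = "corrected")
    m2 <- measure_truth(f2, c(160L, 160L), measure_on = "corrected")
    expect_gte(m2$integrated_density_per_cell, m1$integrated_density_per_cell)
  }
})

test_that("segmentation recovers >= 90% of bright ground-truth puncta within 2 px", {
  p <- pb_presets()$scaffold_overexpression
  hits <- 0L; total <- 0L
  for (s in 1:10) {
    fl <- generate_field(p, 50, seed = s, phase = FALSE)
    corr <- correct_image(fl$fluor, identity_shading(c(512L, 512L)))
    msk <- segment_puncta(to_8bit(corr), 0.0005)
    sel <- which(msk, arr.ind = TRUE)
    tr <- fl$truth$puncta_records
    # background SD from within-cell non-punctum intensities
    bg <- corr$pixels[corr$pixels > 10 & corr$pixels < 100]
    qual <- tr[tr$amplitude > 5 * sd(bg), ]
    for (i in seq_len(nrow(qual))) {
      total <- total + 1L
      if (any((sel[, 1] - qual$row[i])^2 + (sel[, 2] - qual$col[i])^2 <= 4))
        hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.90)
})

test_that("dispersal presets conserve expected total cell fluorescence", {
  pr <- pb_presets()
  cond <- pr$scaffold_overexpression
  disp <- pr$hexanediol_dispersal
  area <- pi * 20^2
  per_cell_cond <- cond$cytoplasm_baseline * area +
    cond$puncta_per_cell[["mean"]] * cond$punctum_amplitude[["mean"]] *
      2 * pi * cond$punctum_sigma_px^2
  per_cell_disp <- disp$cytoplasm_baseline * area
  expect_equal(per_cell_cond, per_cell_disp, tolerance = 1e-12)
  expect_false(disp$condensed)
  expect_identical(unname(disp$puncta_per_cell[["mean"]]), 0)
})
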