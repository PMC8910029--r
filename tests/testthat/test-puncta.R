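test_that("to_8bit maps the image extrema to 0 and 255 and preserves ordering", {
  px <- matrix(100, 10, 10)
  px[1, 1] <- 355; px[5, 5] <- 228
  m <- to_8bit(micrograph(px))
  expect_identical(m$bit_depth, 8L)
  expect_equal(m$pixels[2, 2], 0)            # vmin -> 0
  expect_equal(m$pixels[1, 1], 255)          # vmax -> 255
  expect_equal(unname(attr(m, "mapping")), c(100, 355))

  expect_true(all(to_8bit(micrograph(matrix(77, 6, 6)))$pixels == 0))

  for (s in 1:5) {
    set.seed(s)
    v <- matrix(runif(400, 0, 65535), 20, 20)
    mp <- to_8bit(micrograph(v))$pixels
    # order statistics agree with a brute-force pairwise comparison
    expect_true(all(diff(mp[order(v)]) >= 0))
  }
})

test_that("to_8bit honours a fixed shared display range", {
  a <- micrograph(matrix(c(0, 100, 200, 400), 2, 2))
  m <- to_8bit(a, range = c(0, 400))
  expect_equal(as.vector(m$pixels), round(255 * c(0, 100, 200, 400) / 400))
})

test_that("top-fraction segmentation matches the sort-based oracle exactly", {
  set.seed(7)
  v <- matrix(sample(seq_len(1e6), 200 * 200), 200, 200)  # distinct values
  msk <- segment_puncta(micrograph(v, corrected = TRUE), 0.0005)
  expect_identical(sum(msk), 20L)                          # k = floor(.0005*40000)
  oracle <- order(v, decreasing = TRUE)[1:20]
  expect_identical(sort(which(msk)), sort(oracle))
  expect_identical(attr(msk, "k"), 20L)
  expect_true(all(v[msk] > attr(msk, "threshold_used")))
})

test_that("ties at the threshold are excluded, never over-selecting", {
  const <- micrograph(matrix(5, 50, 50))
  msk <- segment_puncta(const, 0.01)
  expect_identical(sum(msk), 0L)             # every pixel ties at t

  px <- matrix(0, 60, 60); px[10, 10] <- 255
  msk2 <- segment_puncta(micrograph(px), 0.001)
  expect_identical(which(msk2), which(px == 255))

  expect_warning(segment_puncta(micrograph(matrix(1:4, 2, 2)), 0.01),
                 "zero pixels")
})

test_that("particle analysis uses 8-connectivity and ImageJ-style measurements", {
  px <- matrix(0, 12, 12)
  px[2, 2] <- 10; px[2, 3] <- 20; px[3, 2] <- 30   # blob 1 (3 px)
  px[9, 9] <- 40                                    # blob 2 (1 px)
  mask <- px > 0
  ps <- analyze_particles(mask, micrograph(px))
  expect_identical(nrow(ps$puncta), 2L)
  b1 <- ps$puncta[ps$puncta$area_px == 3, ]
  expect_equal(b1$max_intensity, 30)
  expect_equal(b1$integrated_density, 60)
  expect_equal(ps$puncta$integrated_density[ps$puncta$area_px == 1], 40)
  # pixel sets are pairwise disjoint
  allpx <- do.call(rbind, ps$pixel_coords)
  expect_identical(anyDuplicated(allpx), 0L)

  # diagonal-only contact merges into one punctum
  dg <- matrix(0, 6, 6); dg[2, 2] <- 1; dg[3, 3] <- 1
  ps2 <- analyze_particles(dg > 0, micrograph(dg))
  expect_identical(nrow(ps2$puncta), 1L)
  expect_identical(ps2$puncta$area_px, 2L)

  expect_error(analyze_particles(matrix(TRUE, 3, 3),
                                 micrograph(matrix(0, 4, 4))), "shape")
})

test_that("max intensity never exceeds integrated density over random masks", {
  for (s in 1:10) {
    set.seed(s)
    px <- matrix(sample(0:255, 900, TRUE), 30, 30)
    mask <- matrix(runif(900) < 0.05, 30, 30)
    ps <- analyze_particles(mask, micrograph(px))
    expect_true(all(ps$puncta$integrated_density >= ps$puncta$max_intensity))
    expect_identical(sum(ps$puncta$area_px), sum(mask))
  }
})

test_that("cell counting is exact on clean synthetic fields", {
  bg <- micrograph(matrix(180, 128, 128), bit_depth = 8L, channel = "phase")
  expect_identical(count_cells(bg), 0L)

  fl <- generate_field(pb_presets()$log_phase, 12, seed = 77L,
                       dim = c(256L, 256L))
  expect_identical(count_cells(fl$phase), 12L)
})

test_that("cell counting is exact on >= 95% of default fields (error <= 1 otherwise)", {
  errs <- vapply(1:20, function(s) {
    fl <- generate_field(pb_presets()$log_phase, 12, seed = 400L + s,
                         dim = c(256L, 256L))
    abs(count_cells(fl$phase) - fl$truth$cell_count)
  }, 0)
  expect_gte(mean(errs == 0), 0.95)
  expect_true(all(errs <= 1))
})

test_that("measure_field aggregates puncta into the per-cell metric", {
  px <- matrix(0, 100, 100)
  px[30, 30] <- 30; px[30, 31] <- 20; px[31, 30] <- 10  # intden 60
  px[70, 70] <- 25; px[70, 71] <- 15                    # intden 40
  m <- measure_field(as_corrected(px), 10L, top_fraction = 6e-4,
                     measure_on = "corrected")
  expect_equal(m$integrated_density_per_cell, 10)
  expect_identical(m$n_puncta, 2L)
  expect_setequal(m$max_intensities, c(30, 25))

  empty <- measure_field(as_corrected(matrix(3, 64, 64)), 5L)
  expect_equal(empty$integrated_density_per_cell, 0)
  expect_length(empty$max_intensities, 0L)

  expect_error(measure_field(as_corrected(px), 0L, top_fraction = 6e-4),
               "undefined")
  zero <- measure_field(as_corrected(matrix(3, 64, 64)), 0L)
  expect_equal(zero$integrated_density_per_cell, 0)
  expect_error(measure_field(micrograph(px), 10L), "corrected")
})

test_that("field labels do not affect measured values; padding shifts the pixel budget", {
  px <- matrix(sample(0:500, 200 * 200, TRUE), 200, 200)
  m1 <- measure_field(as_corrected(px), 7L, condition = "a",
                      field_id = "f1")
  m2 <- measure_field(as_corrected(px), 7L, condition = "relabeled",
                      field_id = "zz")
  expect_identical(m1$integrated_density_per_cell,
                   m2$integrated_density_per_cell)
  expect_identical(m1$max_intensities, m2$max_intensities)

  # the percentile budget k depends on N: padding with background changes it
  expect_identical(attr(segment_puncta(as_corrected(px)), "k"), 20L)
  pad <- rbind(px, matrix(0, 10, 200))
  expect_identical(attr(segment_puncta(as_corrected(pad)), "k"), 21L)
})

test_that("a 4x amplitude change raises integrated density per cell in >= 95% of paired fields", {
  pr <- pb_presets()
  wins <- vapply(1:40, function(s) {
    f1 <- generate_field(pr$vector_control, 8, seed = s, dim = c(128L, 128L),
                         cell_radius_px = c(8, 12), phase = FALSE)
    f4 <- generate_field(pr$scaffold_overexpression, 8, seed = s,
                         dim = c(128L, 128L), cell_radius_px = c(8, 12),
                         phase = FALSE)
    m1 <- measure_truth(f1, c(128L, 128L), measure_on = "corrected")
    m4 <- measure_truth(f4, c(128L, 128L), measure_on = "corrected")
    m4$integrated_density_per_cell > m1$integrated_density_per_cell
  }, TRUE)
  expect_gte(mean(wins), 0.95)
})

test_that("dispersal lowers punctum max intensity and integrated density per cell", {
  pr <- pb_presets()
  shared <- NULL
  msr <- function(preset, s) {
    fl <- generate_field(preset, 30, seed = s, dim = c(256L, 256L),
                         phase = FALSE)
    corr <- correct_image(fl$fluor, identity_shading(c(256L, 256L)))
    measure_field(corr, 30L, measure_on = "8bit", bit8_range = c(0, 600))
  }
  cond <- lapply(1:5, function(s) msr(pr$scaffold_overexpression, s))
  disp <- lapply(1:5, function(s) msr(pr$hexanediol_dispersal, 100L + s))
  mx_cond <- mean(unlist(lapply(cond, `[[`, "max_intensities")))
  mx_disp <- mean(unlist(lapply(disp, `[[`, "max_intensities")))
  id_cond <- mean(vapply(cond, `[[`, 0, "integrated_density_per_cell"))
  id_disp <- mean(vapply(disp, `[[`, 0, "integrated_density_per_cell"))
  expect_lt(mx_disp, mx_cond)
  expect_lt(id_disp, id_cond)
})
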