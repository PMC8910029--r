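# Puncta segmentation and measurement.
#
# The segmentation rule is a per-image intensity percentile: the top
# 0.05% brightest pixels form the punctum mask.  Connected components
# (8-connectivity, as in ImageJ's Analyze Particles) become puncta, each
# carrying its maximal intensity and integrated density; the field-level
# summary divides the summed integrated density by the cell count.

#' Segment the top-fraction brightest pixels of an image
#'
#' With `N` pixels and `k = floor(top_fraction * N)`, the threshold `t` is
#' the `(N - k)`-th order statistic of the pixel values and the mask
#' selects pixels **strictly greater** than `t`.  Ties at `t` are
#' excluded, so at most `k` pixels are selected and a constant image gives
#' an empty mask.
#'
#' @param image A [micrograph].
#' @param top_fraction Fraction of pixels to target (default 0.0005,
#'   i.e. the top 0.05%).
#' @return A logical mask matrix with attributes `threshold_used` and `k`.
#'   If `k == 0` (image too small for the fraction) an empty mask is
#'   returned with a warning.
#' @export
segment_puncta <- function(image, top_fraction = 0.0005) {
  stopifnot(is_micrograph(image), top_fraction > 0, top_fraction < 1)
  v <- image$pixels
  N <- length(v)
  k <- floor(top_fraction * N)
  if (k == 0L) {
    warning("top_fraction selects zero pixels for this image size")
    mask <- array(FALSE, dim(v))
    attr(mask, "threshold_used") <- NA_real_
    attr(mask, "k") <- 0L
    return(mask)
  }
  t <- sort(v, partial = N - k)[N - k]
  mask <- v > t
  attr(mask, "threshold_used") <- t
  attr(mask, "k") <- as.integer(k)
  mask
}

# 8-connected two-pass labeling restricted to the (sparse) mask pixels.
# Returns an integer label matrix; 0 = background.
label_components_8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  coords <- which(mask, arr.ind = TRUE)
  if (nrow(coords) == 0L) return(lab)
  coords <- coords[order(coords[, 1], coords[, 2]), , drop = FALSE]
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  nxt <- 0L
  nr <- nrow(mask); nc <- ncol(mask)
  for (p in seq_len(nrow(coords))) {
    r <- coords[p, 1]; c <- coords[p, 2]
    nb <- integer(0)
    if (r > 1L) {
      if (c > 1L && lab[r - 1L, c - 1L] > 0L) nb <- c(nb, lab[r - 1L, c - 1L])
      if (lab[r - 1L, c] > 0L) nb <- c(nb, lab[r - 1L, c])
      if (c < nc && lab[r - 1L, c + 1L] > 0L) nb <- c(nb, lab[r - 1L, c + 1L])
    }
    if (c > 1L && lab[r, c - 1L] > 0L) nb <- c(nb, lab[r, c - 1L])
    if (length(nb) == 0L) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      lab[r, c] <- nxt
    } else {
      roots <- unique(vapply(nb, find, 0L))
      keep <- min(roots)
      for (rt in roots) parent[rt] <- keep
      lab[r, c] <- keep
    }
  }
  # resolve and renumber consecutively
  roots <- vapply(seq_len(nxt), find, 0L)
  relab <- match(roots, sort(unique(roots)))
  pos <- lab > 0L
  lab[pos] <- relab[lab[pos]]
  lab
}

#' Particle analysis of a segmentation mask
#'
#' Connected components of the mask under 8-connectivity become puncta
#' (matching ImageJ Analyze Particles' default connectivity); no size or
#' shape filter is applied, so single-pixel puncta are kept.  Intensities
#' are read from `intensity_image`, which may be the 8-bit segmentation
#' image or the corrected full-depth image (see [measure_field]).
#'
#' @param mask Logical mask, e.g. from [segment_puncta].
#' @param intensity_image [micrograph] the intensities are read from; must
#'   share the mask's shape.
#' @param source Optional field identifier carried into the result.
#' @param measured_on Label recording which image intensities came from.
#' @return An object of class `puncta_set`: a list with `puncta` (data
#'   frame: `label`, `area_px`, `max_intensity`, `integrated_density`),
#'   `pixel_coords` (list of per-punctum coordinate matrices, 1-based
#'   `(row, col)`), `threshold_used`, `top_fraction`, `k`, `source`,
#'   `measured_on`.
#' @export
analyze_particles <- function(mask, intensity_image, source = NA_character_,
                              measured_on = "8bit") {
  stopifnot(is_micrograph(intensity_image))
  if (!all(dim(mask) == dim(intensity_image$pixels)))
    stop("mask and intensity image shapes differ")
  lab <- label_components_8(mask)
  n <- max(lab)
  if (n == 0L) {
    puncta <- data.frame(label = integer(0), area_px = integer(0),
                         max_intensity = numeric(0),
                         integrated_density = numeric(0))
    coords <- list()
  } else {
    idx <- which(lab > 0L)
    l <- lab[idx]
    v <- intensity_image$pixels[idx]
    area <- tabulate(l, n)
    maxi <- vapply(split(v, l), max, 0)
    intden <- vapply(split(v, l), sum, 0)
    puncta <- data.frame(label = seq_len(n), area_px = area,
                         max_intensity = as.numeric(maxi),
                         integrated_density = as.numeric(intden))
    ai <- arrayInd(idx, dim(mask))
    coords <- lapply(split(seq_along(l), l),
                     function(i) ai[i, , drop = FALSE])
  }
  structure(list(puncta = puncta, pixel_coords = coords,
                 threshold_used = attr(mask, "threshold_used"),
                 top_fraction = attr(mask, "top_fraction"),
                 k = attr(mask, "k"), source = source,
                 measured_on = measured_on),
            class = "puncta_set")
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("<puncta_set: %d puncta, %d selected px (threshold %s)>\n",
              nrow(x$puncta), sum(x$puncta$area_px),
              format(x$threshold_used)))
  invisible(x)
}

#' Count cells in a phase-contrast image
#'
#' Automated counting: Otsu threshold (cells are darker than background in
#' the synthetic phase rendering), hole filling, distance-transform
#' watershed to split touching cells, and a minimum-area filter.
#'
#' @param phase_image A phase-contrast [micrograph].
#' @param min_area_px Minimum component area kept as a cell.
#' @param tolerance Watershed tolerance (in distance-map units); larger
#'   values split less aggressively.
#' @return Integer cell count (0 for an empty image).
#' @export
count_cells <- function(phase_image, min_area_px = 50L, tolerance = 6) {
  stopifnot(is_micrograph(phase_image))
  v <- phase_image$pixels / (2^phase_image$bit_depth - 1)
  th <- EBImage::otsu(EBImage::Image(v), range = c(0, 1))
  mask <- v < th
  if (!any(mask)) return(0L)
  mask <- EBImage::fillHull(EBImage::Image(mask * 1))
  dm <- EBImage::distmap(mask)
  ws <- EBImage::watershed(dm, tolerance = tolerance)
  areas <- tabulate(as.integer(EBImage::imageData(ws)))
  sum(areas >= min_area_px)
}

#' Measure a corrected field: the full segmentation-to-summary pipeline
#'
#' Runs 8-bit conversion, top-fraction segmentation and particle analysis,
#' then aggregates to the two field-level metrics: the list of per-punctum
#' maximal intensities, and the integrated density per cell (sum of
#' punctum integrated densities divided by the cell count).
#'
#' By default intensities are measured on the 8-bit segmentation image
#' (the literal transform-then-measure reading of an ImageJ workflow);
#' `measure_on = "corrected"` reads them from the full-depth corrected
#' image instead.  With per-image min--max 8-bit scaling, absolute 8-bit
#' intensities are not comparable across images; pass a shared
#' `bit8_range` (or measure on the corrected image) when comparing
#' conditions.
#'
#' @param corrected A corrected [micrograph] (set `allow_uncorrected =
#'   TRUE` to override the check).
#' @param phase_or_count A phase [micrograph] (cells are counted
#'   automatically) or a precomputed integer cell count.
#' @param top_fraction Segmentation fraction (default 0.0005).
#' @param condition,experiment_id,field_id Labels carried into the result.
#' @param measure_on `"8bit"` or `"corrected"`.
#' @param bit8_range Optional fixed display range `c(vmin, vmax)` shared
#'   across compared images for the 8-bit transform; `NULL` uses the
#'   per-image extrema.
#' @param allow_uncorrected Skip the corrected-flag check.
#' @param ... Passed to [count_cells].
#' @return An object of class `field_measurement`: `condition`,
#'   `experiment_id`, `field_id`, `cell_count`,
#'   `integrated_density_per_cell`, `max_intensities`, `n_puncta`, plus
#'   the underlying `puncta_set` and the 8-bit `mapping` used.
#' @export
measure_field <- function(corrected, phase_or_count,
                          top_fraction = 0.0005,
                          condition = NA_character_,
                          experiment_id = NA_character_,
                          field_id = NA_character_,
                          measure_on = c("8bit", "corrected"),
                          bit8_range = NULL,
                          allow_uncorrected = FALSE, ...) {
  measure_on <- match.arg(measure_on)
  stopifnot(is_micrograph(corrected))
  if (!corrected$corrected && !allow_uncorrected)
    stop("image is not flagged as shading-corrected; ",
         "pass allow_uncorrected = TRUE to measure it anyway")
  cell_count <- if (is_micrograph(phase_or_count))
    count_cells(phase_or_count, ...) else as.integer(phase_or_count)
  if (cell_count < 0) stop("cell count must be >= 0")

  img8 <- to_8bit(corrected, range = bit8_range)
  mask <- segment_puncta(img8, top_fraction)
  attr(mask, "top_fraction") <- top_fraction
  intensity <- if (measure_on == "8bit") img8 else corrected
  ps <- analyze_particles(mask, intensity, source = field_id,
                          measured_on = measure_on)

  n_puncta <- nrow(ps$puncta)
  if (cell_count == 0L && n_puncta > 0L)
    stop("cell count is 0 but puncta were found: ",
         "integrated density per cell is undefined")
  idpc <- if (n_puncta == 0L) 0
  else sum(ps$puncta$integrated_density) / cell_count

  structure(
    list(condition = condition, experiment_id = experiment_id,
         field_id = field_id, cell_count = cell_count,
         integrated_density_per_cell = idpc,
         max_intensities = ps$puncta$max_intensity,
         n_puncta = n_puncta, puncta = ps,
         threshold_used = ps$threshold_used,
         mapping = attr(img8, "mapping"), measured_on = measure_on,
         top_fraction = top_fraction),
    class = "field_measurement"
  )
}

#' @export
print.field_measurement <- function(x, ...) {
  cat(sprintf("<field_measurement %s/%s/%s: %d cells, %d puncta, intden/cell %.3f>\n",
              x$condition, x$experiment_id, x$field_id, x$cell_count,
              x$n_puncta, x$integrated_density_per_cell))
  invisible(x)
}

#' Flatten field measurements to data frames
#'
#' @param measurements A list of `field_measurement` objects.
#' @return `fields_table()`: one row per field; `puncta_table()`: one row
#'   per punctum.
#' @export
fields_table <- function(measurements) {
  do.call(rbind, lapply(measurements, function(m) data.frame(
    condition = m$condition, experiment_id = m$experiment_id,
    field_id = m$field_id, cell_count = m$cell_count,
    n_puncta = m$n_puncta,
    integrated_density_per_cell = m$integrated_density_per_cell,
    threshold_used = if (is.null(m$threshold_used)) NA_real_
    else m$threshold_used,
    measured_on = m$measured_on, top_fraction = m$top_fraction,
    stringsAsFactors = FALSE)))
}

#' @rdname fields_table
#' @export
puncta_table <- function(measurements) {
  out <- lapply(measurements, function(m) {
    if (m$n_puncta == 0L) return(NULL)
    cbind(data.frame(condition = m$condition,
                     experiment_id = m$experiment_id,
                     field_id = m$field_id, stringsAsFactors = FALSE),
          m$puncta$puncta)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L)
    return(data.frame(condition = character(0), experiment_id = character(0),
                      field_id = character(0), label = integer(0),
                      area_px = integer(0), max_intensity = numeric(0),
                      integrated_density = numeric(0)))
  do.call(rbind, out)
}
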