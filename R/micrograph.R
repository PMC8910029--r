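#' Construct a micrograph
#'
#' A `micrograph` is a 2D grid of non-negative intensities plus the
#' acquisition metadata the pipeline needs downstream: camera bit depth,
#' exposure time, channel label, and whether shading correction has
#' already been applied.
#'
#' Quantized images (fresh off the camera) must fit in `[0, 2^bit_depth - 1]`;
#' corrected images carry continuous intensities and are not re-quantized,
#' so for those the range check is skipped.
#'
#' @param pixels Numeric matrix of intensities (rows = image rows).
#' @param bit_depth Integer, 8 or 16.
#' @param exposure Exposure time in seconds.
#' @param channel Channel label (e.g. `"GFP"`, `"phase"`).
#' @param corrected Logical; `TRUE` once shading correction has been applied.
#' @return An object of class `micrograph`.
#' @export
micrograph <- function(pixels, bit_depth = 16L, exposure = 1,
                       channel = "GFP", corrected = FALSE) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix")
  if (any(dim(pixels) <= 0L))
    stop("image dimensions must be positive")
  if (!bit_depth %in% c(8L, 16L))
    stop("'bit_depth' must be 8 or 16")
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("pixel values must be finite")
  if (any(pixels < 0))
    stop("pixel values must be non-negative")
  if (!corrected && any(pixels > 2^bit_depth - 1))
    stop("pixel values exceed the bit-depth range of an uncorrected image")
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth),
         exposure = exposure, channel = channel, corrected = corrected),
    class = "micrograph"
  )
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph %dx%d, %d-bit, channel '%s', exposure %gs%s>\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$channel,
              x$exposure, if (x$corrected) ", corrected" else ""))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.micrograph <- function(x) dim(x$pixels)

is_micrograph <- function(x) inherits(x, "micrograph")

#' Rescale a micrograph to 8-bit
#'
#' Linear min-max transform mirroring ImageJ's 8-bit conversion with a
#' per-image display range: `v -> round(255 * (v - vmin) / (vmax - vmin))`
#' where `vmin`/`vmax` are the image's own extrema.  A constant image maps
#' to all zeros by convention.  The mapping parameters are recorded in the
#' `mapping` attribute for auditability, since they differ per image and
#' affect the absolute comparability of 8-bit intensities.
#'
#' @param image A [micrograph].
#' @param range Optional fixed display range `c(vmin, vmax)` shared across
#'   a set of compared images; the default `NULL` uses the image's extrema.
#' @return An 8-bit [micrograph]; attribute `mapping` holds `c(vmin, vmax)`.
#' @export
to_8bit <- function(image, range = NULL) {
  stopifnot(is_micrograph(image))
  v <- image$pixels
  if (is.null(range)) {
    vmin <- min(v); vmax <- max(v)
  } else {
    stopifnot(length(range) == 2L, range[2] >= range[1])
    vmin <- range[1]; vmax <- range[2]
  }
  if (vmax > vmin) {
    out <- round(255 * (pmin(pmax(v, vmin), vmax) - vmin) / (vmax - vmin))
  } else {
    out <- array(0, dim(v))  # degenerate constant image
  }
  res <- micrograph(out, bit_depth = 8L, exposure = image$exposure,
                    channel = image$channel, corrected = image$corrected)
  attr(res, "mapping") <- c(vmin = vmin, vmax = vmax)
  res
}

#' Read a grayscale TIFF as a micrograph
#'
#' @param path Path to an 8- or 16-bit single-channel TIFF.
#' @inheritParams micrograph
#' @return A [micrograph].
#' @export
read_micrograph <- function(path, exposure = 1, channel = "GFP",
                            corrected = FALSE) {
  px <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] != 1L) stop("expected a single-channel grayscale TIFF")
    px <- px[, , 1L]
  }
  bits <- attr(px, "bits.per.sample")
  if (is.null(bits)) bits <- if (max(px) > 255) 16L else 8L
  micrograph(px + 0, bit_depth = as.integer(bits), exposure = exposure,
             channel = channel, corrected = corrected)
}

#' Write a micrograph to a grayscale TIFF
#'
#' Values are stored at the image's bit depth; corrected (continuous)
#' images are rounded to the nearest integer count on write.
#'
#' @param image A [micrograph].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(image, path) {
  stopifnot(is_micrograph(image))
  maxval <- 2^image$bit_depth - 1
  v <- pmin(pmax(round(image$pixels), 0), maxval) / maxval
  tiff::writeTIFF(v, path, bits.per.sample = image$bit_depth)
  invisible(path)
}

# Seed-scoped RNG: runs `expr` under `seed` and restores the caller's RNG
# state, so generators are pure functions of their seeds.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
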