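# Retrospective shading correction.
#
# Acquisition model for image i of a stack:
#     I_i(x) = flatfield(x) * S_i(x) + darkfield(x)
# with S_i the true signal.  The estimator exploits that, across a stack of
# fields with varying cell density, the per-pixel expected signal is
# (approximately) rank one: S_i(x) ~ b_i * u(x), with b_i a per-image
# brightness scalar.  Regressing each pixel's trajectory on b_i separates
# the multiplicative gain (slope) from the additive offset (intercept);
# fitting smooth low-order surfaces to both enforces the smoothness a
# shading field physically has.

#' Construct a shading model
#'
#' @param flatfield Strictly positive matrix of multiplicative gains with
#'   mean 1 (within 1e-6).
#' @param darkfield Non-negative matrix of additive offsets, same shape.
#' @param provenance How the model was obtained: `"estimated"`,
#'   `"predefined"` or `"synthetic"`.
#' @return An object of class `shading_model`.
#' @export
shading_model <- function(flatfield, darkfield,
                          provenance = c("predefined", "estimated",
                                         "synthetic")) {
  provenance <- match.arg(provenance)
  stopifnot(is.matrix(flatfield), is.matrix(darkfield))
  if (!all(dim(flatfield) == dim(darkfield)))
    stop("flatfield and darkfield must have identical shape")
  if (any(flatfield <= 0))
    stop("flatfield must be strictly positive everywhere")
  if (abs(mean(flatfield) - 1) > 1e-6)
    stop("flatfield must have mean 1 (within 1e-6)")
  if (any(darkfield < 0))
    stop("darkfield must be non-negative")
  structure(list(flatfield = flatfield, darkfield = darkfield,
                 provenance = provenance),
            class = "shading_model")
}

#' @export
print.shading_model <- function(x, ...) {
  cat(sprintf("<shading_model %dx%d (%s): flatfield range [%.3f, %.3f], darkfield mean %.2f>\n",
              nrow(x$flatfield), ncol(x$flatfield), x$provenance,
              min(x$flatfield), max(x$flatfield), mean(x$darkfield)))
  invisible(x)
}

#' Identity shading model
#'
#' Flat-field 1, dark-field 0 everywhere: the convention used when shading
#' estimation is skipped so the pipeline can run on pre-corrected data.
#'
#' @param dim Image dimensions `c(rows, cols)`.
#' @return A [shading_model].
#' @export
identity_shading <- function(dim) {
  shading_model(matrix(1, dim[1], dim[2]), matrix(0, dim[1], dim[2]),
                provenance = "predefined")
}

#' Bundle same-shape micrographs into a stack
#'
#' All members must share shape, bit depth, channel and exposure — the
#' acquisition contract under which intensities are comparable and a single
#' shading model applies.
#'
#' @param images List of [micrograph] objects (or plain matrices, which are
#'   wrapped with default metadata).
#' @param channel,exposure Expected metadata; defaults taken from the first
#'   image.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(images, channel = NULL, exposure = NULL) {
  stopifnot(length(images) >= 1L)
  images <- lapply(images, function(im) {
    if (is.matrix(im)) micrograph(im) else im
  })
  stopifnot(all(vapply(images, is_micrograph, TRUE)))
  ref <- images[[1]]
  if (is.null(channel)) channel <- ref$channel
  if (is.null(exposure)) exposure <- ref$exposure
  for (im in images) {
    if (!all(dim(im$pixels) == dim(ref$pixels)))
      stop("all images in a stack must share the same shape")
    if (im$bit_depth != ref$bit_depth)
      stop("all images in a stack must share the same bit depth")
    if (!identical(im$channel, channel) || !identical(im$exposure, exposure))
      stop("all images in a stack must share channel and exposure")
  }
  structure(list(images = images, channel = channel, exposure = exposure),
            class = "image_stack")
}

#' @export
length.image_stack <- function(x) length(x$images)

# Polynomial surface basis on coordinates normalized to [-1, 1].
poly_basis <- function(dim, degree) {
  x <- rep(2 * (seq_len(dim[1]) - 0.5) / dim[1] - 1, times = dim[2])
  y <- rep(2 * (seq_len(dim[2]) - 0.5) / dim[2] - 1, each = dim[1])
  cols <- list()
  for (d in 0:degree) for (i in 0:d)
    cols[[length(cols) + 1L]] <- x^(d - i) * y^i
  do.call(cbind, cols)
}

fit_surface <- function(values, basis, weights = NULL) {
  fit <- if (is.null(weights)) stats::lm.fit(basis, values)
  else stats::lm.wfit(basis, values, w = weights)
  as.vector(basis %*% fit$coefficients)
}

#' Estimate flat-field and dark-field from an image stack
#'
#' Retrospective estimation from the images themselves, for stacks of
#' fields whose cells land at different positions image to image, so that
#' every pixel sees both cell-free background and cell-covered signal
#' somewhere in the stack.  Under the acquisition model
#' `I_i(x) = flatfield(x) * S_i(x) + darkfield(x)`, the per-pixel sample
#' set is (to a robust approximation) two-level: a background level equal
#' to the dark-field, and a foreground level `flatfield(x) * s0 +
#' darkfield(x)` with `s0` the typical cytoplasmic signal.  The fit
#' alternates (a) a robust per-pixel two-level summary of the stack —
#' background mean and foreground median (the median rejects the rare,
#' bright punctum outliers) split by the current threshold surface — with
#' (b) smoothness-penalized updates: weighted low-order polynomial
#' surfaces fitted to the foreground excess (rescaled to mean 1 as the
#' flat-field) and to the background level (clamped non-negative as the
#' dark-field).  Iteration stops when the relative parameter change drops
#' below `tol` or after `max_iter` rounds.  The result is deterministic
#' for a fixed stack and settings, and invariant to the order of the
#' images (all per-pixel summaries are order-free).
#'
#' A stack with no intensity structure (e.g. identical constant images)
#' carries no shading information and yields the identity model with a
#' warning; non-convergence also warns but still returns the current
#' estimate.
#'
#' @param stack An [image_stack] (or list of micrographs/matrices).
#' @param smoothness Degree of the fitted polynomial surfaces (the
#'   regularization knob: lower = smoother).  Default 4.
#' @param max_iter Maximum alternation count.
#' @param tol Relative-change convergence threshold.
#' @param min_images Minimum stack size; estimation is ill-posed below it.
#' @return A [shading_model] with provenance `"estimated"` and attributes
#'   `converged` and `iterations`.
#' @export
estimate_shading <- function(stack, smoothness = 4L, max_iter = 10L,
                             tol = 1e-4, min_images = 8L) {
  if (!inherits(stack, "image_stack")) stack <- image_stack(stack)
  n <- length(stack)
  if (n < min_images)
    stop(sprintf("shading estimation needs at least %d images (got %d)",
                 min_images, n))
  dm <- dim(stack$images[[1]]$pixels)
  N <- prod(dm)
  P <- matrix(0, N, n)
  for (i in seq_len(n)) P[, i] <- as.vector(stack$images[[i]]$pixels)

  if (stats::sd(P) < 1e-8) {
    warning("stack has no intensity structure; returning identity shading")
    res <- identity_shading(dm)
    attr(res, "converged") <- TRUE
    attr(res, "iterations") <- 0L
    return(res)
  }

  # deterministic global 1D 2-means for the initial background/foreground
  # threshold (centers initialized at the 10% / 90% quantiles)
  vs <- as.vector(P)
  cen <- stats::quantile(vs, c(0.1, 0.9), names = FALSE)
  for (i in seq_len(25L)) {
    mid <- mean(cen)
    c_new <- c(mean(vs[vs < mid]), mean(vs[vs >= mid]))
    c_new[is.na(c_new)] <- cen[is.na(c_new)]
    if (max(abs(c_new - cen)) < 1e-8) break
    cen <- c_new
  }
  tvec <- rep(mean(cen), N)

  basis <- poly_basis(dm, smoothness)
  f <- rep(1, N); d <- rep(0, N)
  converged <- FALSE; it <- 0L
  for (it in seq_len(max_iter)) {
    B <- P < tvec                       # background membership per pixel
    nb <- rowSums(B); nf <- n - nb
    d_raw <- ifelse(nb > 0, rowSums(P * B) / nb, 0)
    v_raw <- rep(NA_real_, N)
    has_fg <- nf > 0L
    v_raw[has_fg] <- vapply(which(has_fg), function(i)
      stats::median(P[i, !B[i, ]]), 0)
    if (sum(nf) == 0L) {
      warning("no foreground signal found; returning identity shading")
      res <- identity_shading(dm)
      attr(res, "converged") <- TRUE
      attr(res, "iterations") <- it
      return(res)
    }
    d_s <- pmax(fit_surface(d_raw, basis, weights = nb), 0)
    g_raw <- ifelse(has_fg, v_raw - d_s, 0)   # flatfield * typical signal
    g_s <- fit_surface(g_raw, basis, weights = nf)
    g_s <- pmax(g_s, 1e-6 * max(g_s))
    f_new <- g_s / mean(g_s)
    f_new <- pmax(f_new, 1e-3)
    f_new <- f_new / mean(f_new)

    delta <- max(max(abs(f_new - f)),
                 max(abs(d_s - d)) / max(mean(d_s), 1))
    f <- f_new; d <- d_s
    tvec <- d_s + 0.5 * g_s            # midpoint threshold surface
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("shading estimation did not converge in %d iterations",
                    max_iter))
  res <- shading_model(matrix(f, dm[1], dm[2]), matrix(d, dm[1], dm[2]),
                       provenance = "estimated")
  attr(res, "converged") <- converged
  attr(res, "iterations") <- it
  res
}

#' Correct a micrograph with a shading model
#'
#' `corrected(x) = max(0, (I(x) - darkfield(x)) / flatfield(x))`.  The
#' output keeps the image's metadata, gains the `corrected` flag, and
#' carries continuous (not re-quantized) intensities.
#'
#' @param image A [micrograph].
#' @param model A [shading_model] of the same shape.
#' @return A corrected [micrograph].
#' @export
correct_image <- function(image, model) {
  stopifnot(is_micrograph(image), inherits(model, "shading_model"))
  if (!all(dim(image$pixels) == dim(model$flatfield)))
    stop("image and shading model shapes differ")
  out <- pmax((image$pixels - model$darkfield) / model$flatfield, 0)
  micrograph(out, bit_depth = image$bit_depth, exposure = image$exposure,
             channel = image$channel, corrected = TRUE)
}

#' Save a shading model as a pair of 32-bit float TIFFs
#'
#' Grids are stored scaled into \[0, 1\] by a power-of-two factor recorded,
#' together with shape, normalization convention and provenance, in a YAML
#' sidecar (`<basename>.yml`).  Storage is 32 bits per sample, i.e. a
#' relative quantization of about 1e-9 of the scaled grid — far below any
#' shading estimate's uncertainty.
#'
#' @param model A [shading_model].
#' @param basename Output path prefix; writes `<basename>_flat.tif`,
#'   `<basename>_dark.tif` and `<basename>.yml`.
#' @return `basename`, invisibly.
#' @export
save_shading_profile <- function(model, basename) {
  stopifnot(inherits(model, "shading_model"))
  pow2_scale <- function(x) 2^ceiling(log2(max(max(x), 1)))
  fs <- pow2_scale(model$flatfield)
  ds <- pow2_scale(model$darkfield)
  tiff::writeTIFF(model$flatfield / fs, paste0(basename, "_flat.tif"),
                  bits.per.sample = 32L)
  tiff::writeTIFF(model$darkfield / ds, paste0(basename, "_dark.tif"),
                  bits.per.sample = 32L)
  meta <- list(shape = dim(model$flatfield), flatfield_scale = fs,
               darkfield_scale = ds, normalization = "flatfield mean 1",
               provenance = model$provenance)
  yaml::write_yaml(meta, paste0(basename, ".yml"))
  invisible(basename)
}

#' Load a shading model from predefined profiles
#'
#' Accepts either matrices or paths to the TIFF pair written by
#' [save_shading_profile].  The flat-field is normalized to mean 1
#' (rescaling the profile, never the data); invariants are validated.
#'
#' @param flatfield Matrix, or path prefix (as passed to
#'   [save_shading_profile]), or path to the flat-field TIFF.
#' @param darkfield Matrix or path to the dark-field TIFF; ignored when
#'   `flatfield` is a path prefix with a sidecar.
#' @return A [shading_model] with provenance `"predefined"`.
#' @export
load_shading_profile <- function(flatfield, darkfield = NULL) {
  if (is.character(flatfield)) {
    side <- paste0(flatfield, ".yml")
    if (file.exists(side)) {
      meta <- yaml::read_yaml(side)
      ff <- tiff::readTIFF(paste0(flatfield, "_flat.tif")) *
        meta$flatfield_scale
      df <- tiff::readTIFF(paste0(flatfield, "_dark.tif")) *
        meta$darkfield_scale
    } else {
      ff <- tiff::readTIFF(flatfield)
      df <- tiff::readTIFF(darkfield)
    }
  } else {
    ff <- flatfield; df <- darkfield
  }
  ff <- as.matrix(ff); df <- as.matrix(df)
  if (!all(dim(ff) == dim(df))) stop("profile shapes differ")
  if (any(ff <= 0)) stop("flat-field profile contains non-positive pixels")
  ff <- ff / mean(ff)
  shading_model(ff, df, provenance = "predefined")
}
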