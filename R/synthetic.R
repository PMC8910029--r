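# Synthetic wide-field micrograph generator with full ground truth.
#
# The image model mirrors the physical acquisition chain the correction
# stage assumes:  I(x) = flatfield(x) * S(x) + darkfield(x), followed by
# Poisson shot noise (scaled by the photon gain) and additive Gaussian read
# noise, clipped to the 16-bit range.  S(x) is the cytoplasmic baseline on
# the cell mask plus a sum of isotropic Gaussian puncta truncated at 4
# sigma.

#' Simulate a microscope shading model
#'
#' Builds a ground-truth flat-field (smooth radial polynomial rescaled into
#' `flat_range`, then normalized to mean 1) and dark-field (constant plus a
#' mild linear gradient).  One shading model is intended to be shared by
#' all fields of an imaging session, as on a real microscope.
#'
#' @param dim Image dimensions `c(rows, cols)`.
#' @param seed RNG seed.
#' @param flat_range Range the raw flat-field surface is scaled into before
#'   mean-1 normalization.
#' @param dark_base Mean dark-field offset, camera counts.
#' @param dark_gradient Relative amplitude of the linear dark-field gradient
#'   (0 gives a constant dark-field).
#' @return A [shading_model] with provenance `"synthetic"`.
#' @export
simulate_shading <- function(dim = c(512L, 512L), seed = 1L,
                             flat_range = c(0.7, 1.3), dark_base = 8,
                             dark_gradient = 0.02) {
  stopifnot(length(dim) == 2L, all(dim > 0), flat_range[1] > 0,
            flat_range[2] >= flat_range[1], dark_base >= 0)
  with_seed(seed, {
    nr <- dim[1]; nc <- dim[2]
    cx <- nr / 2 + stats::runif(1, -0.15, 0.15) * nr
    cy <- nc / 2 + stats::runif(1, -0.15, 0.15) * nc
    X <- matrix(seq_len(nr), nr, nc)
    Y <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    rho2 <- ((X - cx)^2 + (Y - cy)^2) / (nr^2 + nc^2)  # normalized radius^2
    a2 <- stats::runif(1, -1, 1); a4 <- stats::runif(1, -1, 1)
    raw <- a2 * rho2 + a4 * rho2^2
    rng <- range(raw)
    flat <- if (diff(rng) < 1e-12) {
      matrix(1, nr, nc)
    } else {
      flat_range[1] + diff(flat_range) * (raw - rng[1]) / diff(rng)
    }
    flat <- flat / mean(flat)
    gx <- stats::runif(1, -1, 1) * dark_gradient
    gy <- stats::runif(1, -1, 1) * dark_gradient
    dark <- dark_base * (1 + gx * (2 * X / nr - 1) + gy * (2 * Y / nc - 1))
    dark <- pmax(dark, 0)
    shading_model(flat, dark, provenance = "synthetic")
  })
}

# Cell placement.  "grid": jittered-grid, guaranteeing separation between
# neighbouring cells so that automated counting is well-posed (radii are
# drawn from `rad_range` but shrunk if the grid spacing cannot accommodate
# them).  "uniform": centers uniform over the frame expanded by the cell
# radius, so the expected coverage is spatially flat out to the borders —
# the geometry shading estimation relies on (counting may then be
# ill-posed: cells can clip the frame and touch).
place_cells <- function(n_cells, dim, rad_range, allow_edge_cells = FALSE,
                        placement = c("grid", "uniform")) {
  placement <- match.arg(placement)
  if (n_cells == 0L)
    return(data.frame(row = numeric(0), col = numeric(0), r1 = numeric(0),
                      r2 = numeric(0), theta = numeric(0)))
  if (placement == "uniform") {
    rmax <- min(rad_range[2], min(dim) / 3)
    rmin <- min(rad_range[1], 0.7 * rmax)
    return(data.frame(
      row = stats::runif(n_cells, 1 - rmax, dim[1] + rmax),
      col = stats::runif(n_cells, 1 - rmax, dim[2] + rmax),
      r1 = stats::runif(n_cells, rmin, rmax),
      r2 = stats::runif(n_cells, rmin, rmax),
      theta = stats::runif(n_cells, 0, pi)))
  }
  ng <- ceiling(sqrt(n_cells))
  sx <- dim[1] / ng; sy <- dim[2] / ng
  rmax <- min(rad_range[2], min(sx, sy) / 2 - 1)
  if (rmax < 2)
    stop("too many cells for the image size: cells would overlap heavily")
  rmin <- min(rad_range[1], 0.7 * rmax)
  slots <- sample.int(ng * ng, n_cells)
  gi <- (slots - 1L) %% ng
  gj <- (slots - 1L) %/% ng
  jit <- max(0, min(sx, sy) / 2 - rmax - 1)
  row <- (gi + 0.5) * sx + stats::runif(n_cells, -jit, jit)
  col <- (gj + 0.5) * sy + stats::runif(n_cells, -jit, jit)
  r1 <- stats::runif(n_cells, rmin, rmax)
  r2 <- stats::runif(n_cells, rmin, rmax)
  if (!allow_edge_cells) {
    rcell <- pmax(r1, r2)
    row <- pmin(pmax(row, rcell + 1), dim[1] - rcell)
    col <- pmin(pmax(col, rcell + 1), dim[2] - rcell)
  }
  data.frame(row = row, col = col, r1 = r1, r2 = r2,
             theta = stats::runif(n_cells, 0, pi))
}

# Rasterize filled ellipses onto a logical mask.
render_cell_mask <- function(cells, dim) {
  mask <- matrix(FALSE, dim[1], dim[2])
  for (i in seq_len(nrow(cells))) {
    ce <- cells[i, ]
    r <- max(ce$r1, ce$r2)
    r0 <- max(1L, floor(ce$row - r)); r1 <- min(dim[1], ceiling(ce$row + r))
    c0 <- max(1L, floor(ce$col - r)); c1 <- min(dim[2], ceiling(ce$col + r))
    if (r0 > r1 || c0 > c1) next   # cell entirely outside the frame
    ri <- r0:r1; ci <- c0:c1
    dx <- outer(ri - ce$row, rep(1, length(ci)))
    dy <- outer(rep(1, length(ri)), ci - ce$col)
    u <- dx * cos(ce$theta) + dy * sin(ce$theta)
    v <- -dx * sin(ce$theta) + dy * cos(ce$theta)
    q <- (u / ce$r1)^2 + (v / ce$r2)^2
    mask[ri, ci] <- mask[ri, ci] | (q <= 1)
  }
  mask
}

# Add a truncated (4 sigma) isotropic Gaussian spot to `img` in place.
add_punctum <- function(img, row, col, amplitude, sigma) {
  dim <- dim(img)
  r <- 4 * sigma
  r0 <- max(1L, floor(row - r)); r1 <- min(dim[1], ceiling(row + r))
  c0 <- max(1L, floor(col - r)); c1 <- min(dim[2], ceiling(col + r))
  if (r0 > r1 || c0 > c1) return(img)
  ri <- r0:r1; ci <- c0:c1
  d2 <- outer((ri - row)^2, rep(1, length(ci))) +
    outer(rep(1, length(ri)), (ci - col)^2)
  g <- amplitude * exp(-d2 / (2 * sigma^2))
  g[d2 > r^2] <- 0
  img[ri, ci] <- img[ri, ci] + g
  img
}

#' Generate one synthetic field with ground truth
#'
#' Renders a fluorescence / phase-contrast image pair for `n_cells`
#' yeast-like cells under a [condition_preset], applies the shading model
#' and the Poisson--Gaussian noise chain, and records every sampled
#' quantity.  Identical arguments yield bit-identical output.
#'
#' @param preset A [condition_preset].
#' @param n_cells Number of cells to place (>= 0).
#' @param shading A [shading_model] shared by the imaging session, or
#'   `NULL` for identity shading (flat-field 1, dark-field 0).
#' @param seed RNG seed for this field.
#' @param dim Image dimensions `c(rows, cols)`; default 512 x 512.
#' @param cell_radius_px Range of ellipse radii in pixels.
#' @param gain Photon gain of the Poisson shot-noise stage; 0 disables
#'   shot noise.
#' @param read_noise_sd Gaussian read-noise SD in counts; 0 disables it.
#' @param allow_edge_cells If `TRUE`, cells may clip the image border;
#'   the default keeps every cell fully inside the frame so that counting
#'   is exact.
#' @param placement `"grid"` (default): jittered-grid placement keeping
#'   cells separated, as automated counting needs; `"uniform"`: centers
#'   uniform over the margin-expanded frame, giving spatially flat
#'   expected coverage — the geometry retrospective shading estimation
#'   relies on.
#' @param phase If `TRUE` (default) also render the phase-contrast image.
#' @return A list with elements `fluor` ([micrograph]), `phase`
#'   ([micrograph] or `NULL`) and `truth` (ground-truth record: cell and
#'   punctum tables, true shading grids, noise parameters, cell-mask pixel
#'   count).
#' @export
generate_field <- function(preset, n_cells, shading = NULL, seed = 1L,
                           dim = c(512L, 512L), cell_radius_px = c(15, 25),
                           gain = 1, read_noise_sd = 2,
                           allow_edge_cells = FALSE,
                           placement = c("grid", "uniform"), phase = TRUE) {
  placement <- match.arg(placement)
  stopifnot(inherits(preset, "condition_preset"), n_cells >= 0,
            length(dim) == 2L)
  if (any(dim <= 0)) stop("image dimensions must be positive")
  if (preset$punctum_sigma_px >= min(dim))
    stop("punctum sigma must be smaller than the image")
  if (!is.null(shading)) {
    stopifnot(inherits(shading, "shading_model"))
    if (!all(dim(shading$flatfield) == dim))
      stop("shading model shape does not match the requested image size")
  }
  with_seed(seed, {
    cells <- place_cells(n_cells, dim, cell_radius_px, allow_edge_cells,
                         placement)
    mask <- render_cell_mask(cells, dim)
    signal <- matrix(0, dim[1], dim[2])
    signal[mask] <- preset$cytoplasm_baseline

    # sample puncta: count per cell, then center inside the parent ellipse
    puncta <- data.frame(row = numeric(0), col = numeric(0),
                         amplitude = numeric(0), sigma = numeric(0),
                         cell = integer(0))
    if (n_cells > 0 && preset$condensed &&
        preset$puncta_per_cell[["mean"]] > 0) {
      mu <- preset$puncta_per_cell[["mean"]]
      disp <- preset$puncta_per_cell[["dispersion"]]
      counts <- if (is.infinite(disp)) stats::rpois(n_cells, mu)
      else stats::rnbinom(n_cells, mu = mu, size = disp)
      amp_mean <- preset$punctum_amplitude[["mean"]]
      cv <- preset$punctum_amplitude[["cv"]]
      for (i in seq_len(n_cells)) {
        k <- counts[i]
        if (k == 0L) next
        ce <- cells[i, ]
        a <- sqrt(stats::runif(k)) * 0.8     # radial position inside ellipse
        phi <- stats::runif(k, 0, 2 * pi)
        u <- a * ce$r1 * cos(phi); v <- a * ce$r2 * sin(phi)
        prow <- ce$row + u * cos(ce$theta) - v * sin(ce$theta)
        pcol <- ce$col + u * sin(ce$theta) + v * cos(ce$theta)
        amps <- if (cv > 0) {
          sdlog <- sqrt(log(1 + cv^2))
          stats::rlnorm(k, log(amp_mean) - sdlog^2 / 2, sdlog)
        } else rep(amp_mean, k)
        puncta <- rbind(puncta, data.frame(
          row = prow, col = pcol, amplitude = amps,
          sigma = preset$punctum_sigma_px, cell = i))
      }
      for (j in seq_len(nrow(puncta)))
        signal <- add_punctum(signal, puncta$row[j], puncta$col[j],
                              puncta$amplitude[j], puncta$sigma[j])
    }

    if (is.null(shading)) {
      flat <- matrix(1, dim[1], dim[2]); dark <- matrix(0, dim[1], dim[2])
    } else {
      flat <- shading$flatfield; dark <- shading$darkfield
    }
    img <- flat * signal + dark
    noisy <- gain > 0 || read_noise_sd > 0
    if (gain > 0)
      img[] <- stats::rpois(length(img), img / gain) * gain
    if (read_noise_sd > 0)
      img[] <- img + stats::rnorm(length(img), 0, read_noise_sd)
    if (noisy) img[] <- round(img)
    img[] <- pmin(pmax(img, 0), 65535)
    fluor <- micrograph(img, bit_depth = 16L, channel = "GFP")

    ph <- NULL
    if (phase) {
      pimg <- matrix(180, dim[1], dim[2])
      for (i in seq_len(nrow(cells))) {
        ce <- cells[i, ]
        r <- max(ce$r1, ce$r2)
        ri <- max(1L, floor(ce$row - r)):min(dim[1], ceiling(ce$row + r))
        ci <- max(1L, floor(ce$col - r)):min(dim[2], ceiling(ce$col + r))
        dx <- outer(ri - ce$row, rep(1, length(ci)))
        dy <- outer(rep(1, length(ri)), ci - ce$col)
        u <- dx * cos(ce$theta) + dy * sin(ce$theta)
        v <- -dx * sin(ce$theta) + dy * cos(ce$theta)
        q <- (u / ce$r1)^2 + (v / ce$r2)^2
        blk <- pimg[ri, ci]
        blk[q <= 1] <- 90
        blk[q <= 1 & q > 0.72] <- 55   # dark cell rim
        pimg[ri, ci] <- blk
      }
      pimg[] <- round(pimg + stats::rnorm(length(pimg), 0, 2))
      pimg[] <- pmin(pmax(pimg, 0), 255)
      ph <- micrograph(pimg, bit_depth = 8L, channel = "phase")
    }

    truth <- list(
      seed = seed,
      preset = preset$name,
      cell_records = cells,
      cell_count = nrow(cells),
      puncta_records = puncta,
      n_cell_pixels = sum(mask),
      flatfield_true = flat,
      darkfield_true = dark,
      noise_params = c(gain = gain, read_noise_sd = read_noise_sd)
    )
    list(fluor = fluor, phase = ph, truth = truth)
  })
}

#' Describe a simulated multi-replicate experiment
#'
#' @param groups A named list of [condition_preset] objects (names are the
#'   group labels), or a list of lists with fields `strain`, `construct`
#'   and `preset` when the strain x construct structure matters (RRR
#'   designs).
#' @param n_experiments Number of independent replicate experiments (>= 1).
#' @param n_fields_per_experiment Fields imaged per group per experiment.
#' @param cells_per_field A single count or a range `c(min, max)` sampled
#'   uniformly per field.
#' @param base_seed Integer master seed; all per-field and per-experiment
#'   seeds are derived from it, distinct and reproducible.
#' @param dim,cell_radius_px,gain,read_noise_sd Passed to [generate_field].
#' @param shading `TRUE` to simulate one shading model per experiment
#'   (an imaging session), `FALSE` for identity shading.
#' @param flat_range,dark_base,dark_gradient Passed to [simulate_shading].
#' @param phase Render phase images (default `TRUE`).
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(groups, n_experiments = 3L,
                              n_fields_per_experiment = 3L,
                              cells_per_field = 100L, base_seed = 1L,
                              dim = c(512L, 512L), cell_radius_px = c(15, 25),
                              gain = 1, read_noise_sd = 2, shading = TRUE,
                              flat_range = c(0.7, 1.3), dark_base = 8,
                              dark_gradient = 0.02, phase = TRUE) {
  if (length(groups) == 0L) stop("'groups' must not be empty")
  groups <- lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    if (inherits(g, "condition_preset")) {
      label <- names(groups)[i]
      if (is.null(label) || !nzchar(label)) label <- g$name
      g <- list(strain = "wildtype", construct = label, preset = g)
    }
    stopifnot(inherits(g$preset, "condition_preset"))
    if (is.null(g$label))
      g$label <- paste(g$strain, g$construct, sep = ":")
    g
  })
  if (anyDuplicated(vapply(groups, `[[`, "", "label")))
    stop("group labels must be unique")
  if (n_experiments < 1L) stop("'n_experiments' must be >= 1")
  if (n_fields_per_experiment < 1L) stop("need at least one field")
  structure(
    list(groups = groups, n_experiments = as.integer(n_experiments),
         n_fields_per_experiment = as.integer(n_fields_per_experiment),
         cells_per_field = cells_per_field, base_seed = as.integer(base_seed),
         dim = dim, cell_radius_px = cell_radius_px, gain = gain,
         read_noise_sd = read_noise_sd, shading = shading,
         flat_range = flat_range, dark_base = dark_base,
         dark_gradient = dark_gradient, phase = phase),
    class = "experiment_design"
  )
}

#' Simulate a full multi-group, multi-replicate experiment
#'
#' Produces one record per group x experiment x field.  Per-field seeds are
#' drawn without replacement from the master seed, so they are distinct and
#' the whole collection is reproducible.  One shading model is simulated
#' per experiment (imaging session) and shared by all its fields.
#'
#' @param design An [experiment_design].
#' @return A list of class `pq_experiment` with elements `records` (each a
#'   list with `group`, `strain`, `construct`, `experiment`, `field`,
#'   `fluor`, `phase`, `truth`), `shading` (per-experiment true
#'   [shading_model] or `NULL`), `amplitude_ratio` (matrix of ground-truth
#'   mean punctum-amplitude ratios between groups) and `design`.
#' @export
generate_experiment <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  ng <- length(design$groups)
  ne <- design$n_experiments
  nf <- design$n_fields_per_experiment
  n_fields <- ng * ne * nf
  seeds <- with_seed(design$base_seed,
                     sample.int(2147483646L, n_fields + ne))
  shade_seeds <- seeds[n_fields + seq_len(ne)]
  shading <- if (isTRUE(design$shading)) {
    lapply(shade_seeds, function(s)
      simulate_shading(design$dim, seed = s, flat_range = design$flat_range,
                       dark_base = design$dark_base,
                       dark_gradient = design$dark_gradient))
  } else NULL

  cpf <- design$cells_per_field
  records <- vector("list", n_fields)
  idx <- 0L
  for (g in seq_len(ng)) for (e in seq_len(ne)) for (f in seq_len(nf)) {
    idx <- idx + 1L
    sd_i <- seeds[idx]
    n_cells <- if (length(cpf) == 2L)
      with_seed(sd_i + 1L, sample(cpf[1]:cpf[2], 1L)) else cpf
    fld <- generate_field(
      design$groups[[g]]$preset, n_cells,
      shading = if (is.null(shading)) NULL else shading[[e]],
      seed = sd_i, dim = design$dim,
      cell_radius_px = design$cell_radius_px, gain = design$gain,
      read_noise_sd = design$read_noise_sd, phase = design$phase)
    records[[idx]] <- list(
      group = design$groups[[g]]$label,
      strain = design$groups[[g]]$strain,
      construct = design$groups[[g]]$construct,
      experiment = e, field = f, seed = sd_i,
      fluor = fld$fluor, phase = fld$phase, truth = fld$truth)
  }

  amps <- vapply(design$groups,
                 function(g) g$preset$punctum_amplitude[["mean"]], 0)
  labels <- vapply(design$groups, `[[`, "", "label")
  ratio <- outer(amps, amps, function(a, b) ifelse(b > 0, a / b, NA_real_))
  dimnames(ratio) <- list(labels, labels)

  structure(list(records = records, shading = shading,
                 amplitude_ratio = ratio, design = design),
            class = "pq_experiment")
}

#' @export
print.pq_experiment <- function(x, ...) {
  cat(sprintf("<simulated experiment: %d groups x %d experiments x %d fields = %d records>\n",
              length(x$design$groups), x$design$n_experiments,
              x$design$n_fields_per_experiment, length(x$records)))
  invisible(x)
}
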