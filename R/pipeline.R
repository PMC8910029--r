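# Pipeline orchestration: a single declarative configuration drives
# simulate/ingest -> shading correction -> per-field measurement ->
# tests / RRR, with a run manifest that makes every number re-derivable.

pq_config_keys <- c("mode", "seed", "out_dir", "top_fraction", "measure_on",
                    "bit8_range", "shading", "cell_counts", "design",
                    "input", "comparisons", "rrr")

#' Validate and resolve a pipeline configuration
#'
#' Accepts a YAML path or a list.  Unknown keys are rejected (strict
#' mode), defaults are applied, and cross-references (comparison and RRR
#' group labels) are checked; all failures are reported together.
#'
#' Keys: `mode` (`"simulate"` or `"directory"`); `seed`; `out_dir`
#' (optional); `top_fraction` (default 0.0005); `measure_on` (`"8bit"`,
#' default, or `"corrected"`); `bit8_range` (`"global"`, default: one
#' shared display range across all images of the run — preserving
#' absolute comparability — or `"per_image"`, or a fixed `c(lo, hi)`);
#' `shading` (`"estimate"`, `"identity"`, or a profile basename for
#' [load_shading_profile]); `cell_counts` (`"auto"` = count from phase
#' images, `"truth"` = simulated ground truth, `"manifest"` = precomputed
#' column); `design` (simulate mode: `groups`, each with `label`,
#' `strain`, `construct`, `preset` naming a [pb_presets] entry or given
#' inline, plus `n_experiments`, `n_fields_per_experiment`,
#' `cells_per_field`, optional `dim`, `gain`, `read_noise_sd`,
#' `simulate_shading`, `cell_radius_px`); `input` (directory mode:
#' `manifest` CSV with columns `fluor_path`, `phase_path` or `cell_count`,
#' `condition`, `experiment_id`, `field_id`); `comparisons` (list of
#' `a`, `b`, `metric` in `max_intensity`/`intden_per_cell`, `test` in
#' `student`/`nested`); `rrr` (`test`, `neg`, `pos` construct labels and
#' `mut`, `wt` strain labels).
#'
#' @param config A list or the path of a YAML document.
#' @return A validated `pipeline_config` with all defaults resolved.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  errs <- character(0)
  unknown <- setdiff(names(config), pq_config_keys)
  if (length(unknown) > 0)
    errs <- c(errs, paste0("unknown config keys: ",
                           paste(unknown, collapse = ", ")))

  cfg <- list(
    mode = config$mode %||% "simulate",
    seed = as.integer(config$seed %||% 1L),
    out_dir = config$out_dir,
    top_fraction = config$top_fraction %||% 0.0005,
    measure_on = config$measure_on %||% "8bit",
    bit8_range = config$bit8_range %||% "global",
    shading = config$shading %||% "estimate",
    cell_counts = config$cell_counts %||%
      if ((config$mode %||% "simulate") == "simulate") "auto" else "manifest",
    design = config$design, input = config$input,
    comparisons = config$comparisons, rrr = config$rrr
  )

  if (!cfg$mode %in% c("simulate", "directory"))
    errs <- c(errs, sprintf("mode '%s' is not 'simulate' or 'directory'",
                            cfg$mode))
  if (!is.numeric(cfg$top_fraction) || cfg$top_fraction <= 0 ||
      cfg$top_fraction >= 1)
    errs <- c(errs, sprintf("top_fraction %s is outside (0, 1)",
                            format(cfg$top_fraction)))
  if (!cfg$measure_on %in% c("8bit", "corrected"))
    errs <- c(errs, "measure_on must be '8bit' or 'corrected'")
  if (is.character(cfg$bit8_range) &&
      !cfg$bit8_range %in% c("global", "per_image"))
    errs <- c(errs, "bit8_range must be 'global', 'per_image' or c(lo, hi)")
  if (!cfg$cell_counts %in% c("auto", "truth", "manifest"))
    errs <- c(errs, "cell_counts must be 'auto', 'truth' or 'manifest'")
  if (is.character(cfg$shading) &&
      !cfg$shading %in% c("estimate", "identity") &&
      !file.exists(paste0(cfg$shading, ".yml")))
    errs <- c(errs, sprintf("shading profile '%s' not found", cfg$shading))

  group_labels <- character(0)
  if (cfg$mode == "simulate") {
    if (is.null(cfg$design) || is.null(cfg$design$groups)) {
      errs <- c(errs, "simulate mode needs design$groups")
    } else {
      presets <- pb_presets()
      cfg$design$groups <- lapply(cfg$design$groups, function(g) {
        if (is.character(g$preset)) {
          if (!g$preset %in% names(presets)) {
            errs <<- c(errs, sprintf("unknown preset '%s'", g$preset))
            return(g)
          }
          g$preset <- presets[[g$preset]]
        }
        g$strain <- g$strain %||% "wildtype"
        g$construct <- g$construct %||% g$label %||% g$preset$name
        g$label <- g$label %||% paste(g$strain, g$construct, sep = ":")
        g
      })
      group_labels <- vapply(cfg$design$groups,
                             function(g) g$label %||% "", "")
    }
  } else if (is.null(cfg$input) || is.null(cfg$input$manifest)) {
    errs <- c(errs, "directory mode needs input$manifest")
  } else if (!file.exists(cfg$input$manifest)) {
    errs <- c(errs, sprintf("manifest '%s' not found", cfg$input$manifest))
  } else {
    mf <- utils::read.csv(cfg$input$manifest, stringsAsFactors = FALSE)
    group_labels <- unique(mf$condition)
  }

  for (cmp in cfg$comparisons) {
    for (side in c("a", "b"))
      if (length(group_labels) > 0 && !cmp[[side]] %in% group_labels)
        errs <- c(errs, sprintf("comparison references undefined group '%s'",
                                cmp[[side]]))
    if (!is.null(cmp$metric) &&
        !cmp$metric %in% c("max_intensity", "intden_per_cell"))
      errs <- c(errs, sprintf("unknown metric '%s'", cmp$metric))
    if (!is.null(cmp$test) && !cmp$test %in% c("student", "nested"))
      errs <- c(errs, sprintf("unknown test '%s'", cmp$test))
  }

  if (length(errs) > 0)
    stop("invalid pipeline config:\n  - ", paste(errs, collapse = "\n  - "))
  structure(cfg, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build simulation records from the config's design block.
simulate_from_config <- function(cfg) {
  d <- cfg$design
  groups <- lapply(d$groups, function(g)
    list(strain = g$strain, construct = g$construct, preset = g$preset,
         label = g$label))
  des <- experiment_design(
    groups,
    n_experiments = d$n_experiments %||% 3L,
    n_fields_per_experiment = d$n_fields_per_experiment %||% 2L,
    cells_per_field = unlist(d$cells_per_field %||% 50L),
    base_seed = cfg$seed,
    dim = unlist(d$dim %||% c(512L, 512L)),
    cell_radius_px = unlist(d$cell_radius_px %||% c(15, 25)),
    gain = d$gain %||% 1,
    read_noise_sd = d$read_noise_sd %||% 2,
    shading = d$simulate_shading %||% TRUE,
    phase = !identical(cfg$cell_counts, "truth"))
  generate_experiment(des)
}

ingest_from_manifest <- function(cfg) {
  mf <- utils::read.csv(cfg$input$manifest, stringsAsFactors = FALSE)
  base <- dirname(cfg$input$manifest)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  records <- lapply(seq_len(nrow(mf)), function(i) {
    row <- mf[i, ]
    ph <- if (!is.null(row$phase_path) && nzchar(row$phase_path))
      read_micrograph(resolve(row$phase_path), channel = "phase") else NULL
    list(group = row$condition,
         strain = row$strain %||% "wildtype",
         construct = row$construct %||% row$condition,
         experiment = row$experiment_id, field = row$field_id,
         fluor = read_micrograph(resolve(row$fluor_path)),
         phase = ph,
         cell_count = if ("cell_count" %in% names(row)) row$cell_count
         else NA_integer_,
         truth = NULL)
  })
  list(records = records)
}

#' Run the full analysis pipeline
#'
#' Executes simulate/ingest, shading correction, per-field measurement and
#' the configured statistics.  Identical configuration and seed reproduce
#' every output; when `out_dir` is set, the per-field and per-punctum
#' tables, test results, RRR report and a JSON run manifest are written
#' there.
#'
#' @param config A `pipeline_config` (or anything [validate_config]
#'   accepts).
#' @return A `results_bundle`: `fields` (per-field table), `puncta`
#'   (per-punctum table), `tests` (per-comparison results), `rrr` (report
#'   or `NULL`), `measurements` (raw `field_measurement` list) and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
  else validate_config(config)

  sim <- if (cfg$mode == "simulate") simulate_from_config(cfg)
  else ingest_from_manifest(cfg)
  records <- sim$records

  # --- shading ----------------------------------------------------------
  shading_prov <- cfg$shading
  model_for <- local({
    models <- list()
    function(key, stack_images) {
      if (identical(cfg$shading, "identity"))
        return(identity_shading(dim(stack_images[[1]]$pixels)))
      if (!identical(cfg$shading, "estimate"))
        return(load_shading_profile(cfg$shading))
      if (is.null(models[[key]])) {
        m <- if (length(stack_images) >= 8L)
          estimate_shading(image_stack(stack_images))
        else {
          warning("fewer than 8 images for shading estimation; ",
                  "using identity shading")
          identity_shading(dim(stack_images[[1]]$pixels))
        }
        models[[key]] <<- m
      }
      models[[key]]
    }
  })

  corrected <- vector("list", length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    key <- as.character(rec$experiment)
    stack_imgs <- lapply(records[vapply(records, function(r)
      identical(r$experiment, rec$experiment), TRUE)], `[[`, "fluor")
    corrected[[i]] <- correct_image(rec$fluor, model_for(key, stack_imgs))
  }

  # --- shared 8-bit display range --------------------------------------
  bit8_range <- NULL
  if (cfg$measure_on == "8bit") {
    if (identical(cfg$bit8_range, "global")) {
      gmax <- max(vapply(corrected, function(im) max(im$pixels), 0))
      bit8_range <- c(0, gmax)
    } else if (is.numeric(cfg$bit8_range)) {
      bit8_range <- cfg$bit8_range
    }
  }

  # --- per-field measurement -------------------------------------------
  measurements <- vector("list", length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    counts <- switch(cfg$cell_counts,
                     truth = rec$truth$cell_count,
                     manifest = rec$cell_count,
                     auto = rec$phase)
    if (is.null(counts))
      stop("no cell-count source for field ", i)
    measurements[[i]] <- measure_field(
      corrected[[i]], counts, top_fraction = cfg$top_fraction,
      condition = rec$group, experiment_id = as.character(rec$experiment),
      field_id = sprintf("%s_e%s_f%s", rec$group, rec$experiment, rec$field),
      measure_on = cfg$measure_on, bit8_range = bit8_range)
  }

  fields <- fields_table(measurements)
  puncta <- puncta_table(measurements)

  # --- comparisons ------------------------------------------------------
  tests <- NULL
  for (cmp in cfg$comparisons) {
    metric <- cmp$metric %||% "intden_per_cell"
    testname <- cmp$test %||%
      if (metric == "max_intensity") "nested" else "student"
    pull <- function(label) {
      if (metric == "intden_per_cell") {
        sel <- fields$condition == label
        list(values = fields$integrated_density_per_cell[sel],
             experiment = fields$experiment_id[sel])
      } else {
        sel <- puncta$condition == label
        list(values = puncta$max_intensity[sel],
             experiment = puncta$experiment_id[sel])
      }
    }
    va <- pull(cmp$a); vb <- pull(cmp$b)
    res <- if (testname == "nested")
      nested_t(nested_sample(va$values, va$experiment, cmp$a),
               nested_sample(vb$values, vb$experiment, cmp$b))
    else student_t(va$values, vb$values)
    tests <- rbind(tests, data.frame(
      a = cmp$a, b = cmp$b, metric = metric, test = res$method,
      statistic = res$statistic, df = res$df, p = res$p, stars = res$stars,
      stringsAsFactors = FALSE))
  }

  # --- RRR --------------------------------------------------------------
  rrr <- NULL
  if (!is.null(cfg$rrr)) {
    strains <- vapply(records, function(r) r$strain, "")
    constructs <- vapply(records, function(r) r$construct, "")
    idpc <- vapply(measurements, `[[`, 0, "integrated_density_per_cell")
    gm <- function(strain, construct) {
      sel <- strains == strain & constructs == construct
      if (!any(sel))
        stop(sprintf("RRR: no fields for strain '%s', construct '%s'",
                     strain, construct))
      mean(idpc[sel])   # grand mean of integrated density per cell
    }
    ins <- rrr_inputs(
      I_test_mut = gm(cfg$rrr$mut, cfg$rrr$test),
      I_test_wt = gm(cfg$rrr$wt, cfg$rrr$test),
      I_neg_mut = gm(cfg$rrr$mut, cfg$rrr$neg),
      I_neg_wt = gm(cfg$rrr$wt, cfg$rrr$neg),
      I_pos_mut = gm(cfg$rrr$mut, cfg$rrr$pos),
      I_pos_wt = gm(cfg$rrr$wt, cfg$rrr$pos))
    rrr <- list(inputs = ins, rrr = compute_rrr(ins))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("punctaquant")),
    seed = cfg$seed, mode = cfg$mode,
    top_fraction = cfg$top_fraction, measure_on = cfg$measure_on,
    bit8_range = bit8_range %||% "per_image",
    shading = shading_prov, cell_counts = cfg$cell_counts,
    n_fields = length(records),
    thresholds = stats::setNames(fields$threshold_used, fields$field_id),
    mappings = lapply(measurements, `[[`, "mapping"))

  bundle <- structure(list(fields = fields, puncta = puncta, tests = tests,
                           rrr = rrr, measurements = measurements,
                           manifest = manifest),
                      class = "results_bundle")
  if (!is.null(cfg$out_dir)) write_bundle(bundle, cfg$out_dir)
  bundle
}

#' @export
print.results_bundle <- function(x, ...) {
  cat(sprintf("<results_bundle: %d fields, %d puncta, %d comparisons%s>\n",
              nrow(x$fields), nrow(x$puncta),
              if (is.null(x$tests)) 0L else nrow(x$tests),
              if (is.null(x$rrr)) ""
              else sprintf(", RRR = %.4f", x$rrr$rrr)))
  invisible(x)
}

# Write a results bundle to disk (CSV tables + JSON manifest).
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$fields, file.path(out_dir, "fields.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$puncta, file.path(out_dir, "puncta.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$tests))
    utils::write.csv(bundle$tests, file.path(out_dir, "tests.csv"),
                     row.names = FALSE)
  if (!is.null(bundle$rrr)) {
    rep <- c(unclass(bundle$rrr$inputs), list(rrr = bundle$rrr$rrr))
    jsonlite::write_json(rep, file.path(out_dir, "rrr.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}
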