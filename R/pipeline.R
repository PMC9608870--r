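#' Pipeline configuration
#'
#' Assembles and validates the configuration of the end-to-end analysis.
#' Unknown keys in any section are rejected. The global seed is expanded
#' into per-stage seeds by a fixed scheme (`derive_seed(seed, stage_index)`
#' with stages numbered 1..6 in execution order), and the cross-validation
#' stage further derives per-fold seeds, so one integer reproduces every
#' output byte.
#'
#' @param simulation list of overrides for [simulation_config()] (e.g.
#'   `n_vertices`, `trials_per_subject`, `effect_size`); `n_vertices` and
#'   `region_spec` configure the source space.
#' @param preprocess list: `eog_threshold_uv` (default 100), `window_ms`
#'   (default `c(150, 250)`).
#' @param projection list: `grid_size` (default 60).
#' @param training list: `channels`, `hidden`, `lr` (scalar or grid),
#'   `val_fraction`, `batch_size`, `max_epochs`, `patience`.
#' @param lrp list: `eps`, `gamma`, `scope`.
#' @param stats list: `fraction` (default 0.03).
#' @param seed global integer seed.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = list(), preprocess = list(),
                            projection = list(), training = list(),
                            lrp = list(), stats = list(), seed = 1L) {
  check_keys <- function(x, allowed, section) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      stop_("unknown ", section, " config keys: ", paste(bad, collapse = ", "))
    }
    x
  }
  cfg <- list(
    simulation = check_keys(simulation, c(
      "n_vertices", "region_spec", names(formals(simulation_config))),
      "simulation"),
    preprocess = check_keys(preprocess, c("eog_threshold_uv", "window_ms"),
                            "preprocess"),
    projection = check_keys(projection, "grid_size", "projection"),
    training = check_keys(training, c("channels", "hidden", "lr",
                                      "val_fraction", "batch_size",
                                      "max_epochs", "patience"), "training"),
    lrp = check_keys(lrp, c("eps", "gamma", "scope"), "lrp"),
    stats = check_keys(stats, "fraction", "stats"),
    seed = as.integer(seed)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> preprocess -> project -> crossval -> explain ->
#' correlate, saving each stage's artifact under `out_dir` and writing a
#' manifest (config hash, seeds, stage checksums, package version). With
#' `resume = TRUE`, stages whose artifact file already exists are loaded
#' instead of recomputed, so deleting one artifact re-executes only that
#' stage and those after it.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory (created if missing).
#' @param resume reuse existing stage artifacts (default FALSE).
#' @param verbose print stage progress.
#' @return the run manifest (list), invisibly; artifacts and CSV/JSON
#'   summaries are in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, resume = FALSE, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(...)
  artifact <- function(name) file.path(out_dir, paste0(name, ".rds"))

  dirty <- FALSE   # once any stage recomputes, everything downstream does too
  stage <- function(name, index, depends, compute) {
    path <- artifact(name)
    if (resume && !dirty && file.exists(path) &&
        all(vapply(depends, function(d) file.exists(artifact(d)), logical(1)))) {
      say("[", name, "] reusing ", path)
      return(readRDS(path))
    }
    for (d in depends) {
      if (!file.exists(artifact(d))) {
        stop_("missing upstream artifact '", d, "'; rerun stage ", d)
      }
    }
    say("[", name, "] computing")
    dirty <<- TRUE
    value <- compute(derive_seed(config$seed, index))
    saveRDS(value, path)
    value
  }

  sim_over <- config$simulation
  n_vertices <- sim_over$n_vertices %||% 15002L
  region_spec <- sim_over$region_spec %||% default_region_spec()
  sim_over$n_vertices <- NULL
  sim_over$region_spec <- NULL

  space <- stage("space", 1L, character(0), function(seed) {
    generate_source_space(n_vertices, region_spec, seed = seed)
  })

  sim <- stage("simulate", 2L, "space", function(seed) {
    sim_cfg <- do.call(simulation_config, c(sim_over, list(seed = seed)))
    generate_trials(space, sim_cfg)
  })
  write_clinical_csv(sim$clinical, file.path(out_dir, "clinical.csv"))

  windowed <- stage("preprocess", 3L, "simulate", function(seed) {
    thr <- config$preprocess$eog_threshold_uv %||% 100
    win <- config$preprocess$window_ms %||% c(150, 250)
    trials <- apply_retention(sim$trials, reject_by_eog(sim$trials, thr))
    window_average(trials, win[1], win[2])
  })

  images <- stage("project", 4L, "preprocess", function(seed) {
    project_trials(windowed, space, config$projection$grid_size %||% 60)
  })

  cv <- stage("crossval", 5L, "project", function(seed) {
    tr <- config$training
    crossval_cnn(images,
                 channels = tr$channels %||% c(64, 128),
                 hidden = tr$hidden %||% c(256, 64),
                 lr = tr$lr %||% 1e-3,
                 val_fraction = tr$val_fraction %||% (1 / 11),
                 batch_size = tr$batch_size %||% 64L,
                 max_epochs = tr$max_epochs %||% 300L,
                 patience = tr$patience %||% 20L,
                 seed = seed)
  })
  write.csv(cv$per_subject, file.path(out_dir, "fold_results.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(accuracy_mean = cv$accuracy_mean, accuracy_sd = cv$accuracy_sd,
         auc = cv$roc$auc),
    file.path(out_dir, "crossval_summary.json"),
    auto_unbox = TRUE, digits = NA)

  rmap <- stage("explain", 6L, "crossval", function(seed) {
    comp <- lrp_composite(eps = config$lrp$eps %||% 0.01,
                          gamma = config$lrp$gamma %||% 0.25)
    # held-out LRP: each subject's trials explained by the model that did
    # not see them
    maps <- lapply(cv$folds, function(fr) {
      lrp_explain(fr$model, images$images[fr$test_idx, , drop = FALSE],
                  composite = comp,
                  label = as.numeric(images$group[fr$test_idx] == "patient"),
                  subject = images$subject[fr$test_idx])
    })
    pixel <- do.call(rbind, lapply(maps, `[[`, "pixel"))
    prov <- do.call(rbind, lapply(maps, `[[`, "provenance"))
    prov$trial <- unlist(lapply(cv$folds, `[[`, "test_idx"))
    structure(list(pixel = pixel, image_dim = images$image_dim,
                   provenance = prov, composite = comp),
              class = "relevance_map")
  })

  corr <- stage("correlate", 7L, "explain", function(seed) {
    agg <- aggregate_relevance(rmap, scope = config$lrp$scope %||% "pooled")
    vrel <- pixel_to_vertex(agg, images$map)
    regs <- critical_regions(vrel, space,
                             fraction = config$stats$fraction %||% 0.03)
    pat <- windowed_subset(windowed, windowed$group == "patient")
    list(regions = regs,
         table = build_correlation_table(regs, pat, sim$clinical))
  })
  write_correlation_csv(corr$table, file.path(out_dir, "correlations.csv"))

  cfg_json <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE,
                               digits = NA, null = "null", force = TRUE)
  cfg_path <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_path)
  artifacts <- list.files(out_dir, pattern = "\\.rds$", full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("cortexlrp")),
    seed = config$seed,
    stage_seeds = stats::setNames(
      vapply(1:7, function(i) derive_seed(config$seed, i), integer(1)),
      c("space", "simulate", "preprocess", "project", "crossval",
        "explain", "correlate")),
    config_md5 = unname(tools::md5sum(cfg_path)),
    artifact_md5 = as.list(tools::md5sum(artifacts)),
    accuracy_mean = cv$accuracy_mean,
    auc = cv$roc$auc
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a pipeline configuration from a YAML file
#'
#' The file may contain the sections `simulation`, `preprocess`,
#' `projection`, `training`, `lrp`, `stats` and a `seed`; unknown keys are
#' rejected by [pipeline_config()].
#'
#' @param path YAML file path.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop_("reading YAML configs requires the 'yaml' package")
  }
  raw <- yaml::read_yaml(path)
  known <- c("simulation", "preprocess", "projection", "training",
             "lrp", "stats", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop_("unknown config sections: ", paste(bad, collapse = ", "))
  # scalar lists from YAML (e.g. effect_size) arrive as named lists
  if (!is.null(raw$simulation$effect_size)) {
    raw$simulation$effect_size <- unlist(raw$simulation$effect_size)
  }
  do.call(pipeline_config, raw)
}

# Restrict a windowed_trials object to a subset of trials.
windowed_subset <- function(windowed, keep) {
  windowed$data <- windowed$data[keep, , drop = FALSE]
  windowed$subject <- windowed$subject[keep]
  windowed$group <- windowed$group[keep]
  windowed
}

# Recursively strip classes/functions so a config can be serialized to JSON.
unclass_deep <- function(x) {
  if (is.function(x)) return("<function>")
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}
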