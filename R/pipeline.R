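#' Pipeline configuration
#'
#' One object holding every tunable of the mapping pipeline. Defaults are
#' the published study settings wherever one exists: 500 background points,
#' a 75% positive subsample of the over-sampled region, BRT learning rate
#' 0.005 with interaction depth 4, 100 repetitions of an 80% training
#' split, selection thresholds AUC 0.8 / TSS 0.7, and a 1% prevalence
#' exceedance threshold. Any value changed away from these defaults is
#' reported at startup by [run_pipeline()].
#'
#' @param out_dir output directory for all artifacts.
#' @param seed master seed; per-stage seeds are derived with
#'   [derive_seed()].
#' @param synth a [synth_config()] describing the world to simulate (or
#'   `NULL` when `surveys_csv` plus raster inputs are supplied).
#' @param surveys_csv optional path to a survey CSV (used instead of
#'   simulation).
#' @param n_background background points.
#' @param positive_fraction retained fraction of region positives.
#' @param kde_bandwidth bias-surface bandwidth, km (`NULL` = Silverman).
#' @param lr,max_interactions BRT settings.
#' @param n_reps,train_frac,auc_min,tss_min ensemble settings.
#' @param exceedance_threshold prevalence threshold for exceedance maps.
#' @param n_samples predictive samples in the geostatistical stage.
#' @param adult_fraction scalar adult (15+) population fraction.
#' @param geostat_covariates covariate names entering the prevalence model
#'   (`NULL` = all).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("podomap"), seed = 1,
                            synth = strong_signal_config(
                              seed = seed, grid_shape = c(60, 60),
                              n_communities = 400),
                            surveys_csv = NULL,
                            n_background = 500, positive_fraction = 0.75,
                            kde_bandwidth = NULL,
                            lr = 0.005, max_interactions = 4,
                            n_reps = 100, train_frac = 0.8,
                            auc_min = 0.8, tss_min = 0.7,
                            exceedance_threshold = 0.01, n_samples = 1000,
                            adult_fraction = 0.55,
                            geostat_covariates = NULL) {
  cfg <- as.list(environment())
  defaults <- list(n_background = 500, positive_fraction = 0.75, lr = 0.005,
                   max_interactions = 4, n_reps = 100, train_frac = 0.8,
                   auc_min = 0.8, tss_min = 0.7, exceedance_threshold = 0.01)
  cfg$deviations <- names(Filter(isTRUE, lapply(names(defaults), function(k) {
    !isTRUE(all.equal(cfg[[k]], defaults[[k]]))
  }) |> stats::setNames(names(defaults))))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the [pipeline_config()] argument names; `synth.*` keys fill
#' the synthetic-world config. The seed is mandatory.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config: seed is mandatory", call. = FALSE)
  synth_args <- y$synth %||% list()
  synth_args$seed <- synth_args$seed %||% y$seed
  if (!is.null(synth_args$grid_shape)) {
    synth_args$grid_shape <- as.integer(unlist(synth_args$grid_shape))
  }
  y$synth <- do.call(synth_config, synth_args)
  known <- names(formals(pipeline_config))
  do.call(pipeline_config, y[intersect(names(y), known)])
}

stage_manifest_row <- function(stage, outputs, seed, t0) {
  data.frame(
    stage = stage,
    outputs = paste(basename(outputs), collapse = ";"),
    md5 = paste(unname(tools::md5sum(outputs)), collapse = ";"),
    seed = seed,
    wall_s = round(as.numeric(Sys.time()) - t0, 2),
    status = "ok")
}

#' Run the full mapping pipeline
#'
#' Executes the stages in order — simulate, extract, background, sdm,
#' geostat, burden, report — writing every surface as an ESRI ASCII grid,
#' every table as CSV, and a manifest (stage, outputs, md5 hashes, derived
#' seed, wall time) that makes reruns hash-checkable. Fails fast on the
#' first stage error, recording the failure point in the manifest.
#'
#' @param config a [pipeline_config()].
#' @return list of in-memory stage results plus `manifest` (also written to
#'   `manifest.csv`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (length(config$deviations)) {
    message("pipeline: settings deviating from the study defaults: ",
            paste(config$deviations, collapse = ", "))
  }
  manifest <- list()
  res <- list()
  run_stage <- function(stage, fn) {
    t0 <- as.numeric(Sys.time())
    seed <- derive_seed(config$seed, stage)
    out <- tryCatch(fn(seed), error = function(e) {
      manifest[[length(manifest) + 1]] <<- data.frame(
        stage = stage, outputs = "", md5 = "", seed = seed,
        wall_s = round(as.numeric(Sys.time()) - t0, 2),
        status = paste0("error: ", conditionMessage(e)))
      utils::write.csv(do.call(rbind, manifest),
                       file.path(config$out_dir, "manifest.csv"),
                       row.names = FALSE)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest[[length(manifest) + 1]] <<- stage_manifest_row(
      stage, out$files, seed, t0)
    out$value
  }

  res$world <- run_stage("simulate", function(seed) {
    world <- simulate_world(config$synth)
    if (!is.null(config$surveys_csv)) {
      world$surveys <- read_surveys(config$surveys_csv)
    }
    f_surv <- file.path(config$out_dir, "surveys.csv")
    write_surveys(world$surveys, f_surv)
    f_truth <- file.path(config$out_dir, "truth_prevalence.asc")
    write_asc(world$truth$prevalence, f_truth)
    f_pop <- file.path(config$out_dir, "population.asc")
    write_asc(world$population, f_pop)
    list(value = world, files = c(f_surv, f_truth, f_pop))
  })
  world <- res$world

  res$features <- run_stage("extract", function(seed) {
    stack <- standardize_stack(world$covariates)
    features <- extract_features(stack, world$surveys)
    f <- file.path(config$out_dir, "features.csv")
    utils::write.csv(features, f, row.names = FALSE)
    meta <- file.path(config$out_dir, "features_meta.csv")
    utils::write.csv(stack$standardization, meta, row.names = FALSE)
    list(value = list(stack = stack, features = features), files = c(f, meta))
  })
  stack <- res$features$stack
  features <- res$features$features

  res$training <- run_stage("background", function(seed) {
    message(sprintf("background: %d communities, %d with zero cases",
                    nrow(features), sum(features$label == 0)))
    grid <- stack$layers[[1]]
    thinned <- subsample_positives(
      features, config$synth$oversample_region, grid,
      fraction = config$positive_fraction, seed = seed)
    pres <- thinned[thinned$label == 1, , drop = FALSE]
    abs_ <- thinned[thinned$label == 0, , drop = FALSE]
    occ <- data.frame(x = pres$x_km, y = pres$y_km)
    bias <- if (is.null(config$kde_bandwidth)) build_bias_surface(occ, grid)
            else build_bias_surface(occ, grid, bandwidth = config$kde_bandwidth)
    bg_pts <- sample_background(bias, config$n_background, seed = seed + 1L)
    bg_surv <- data.frame(community_id = sprintf("bg%04d", seq_len(nrow(bg_pts))),
                          x_km = bg_pts$x, y_km = bg_pts$y,
                          n_screened = 0L, n_cases = 0L)
    bg_feat <- suppressMessages(extract_features(stack, bg_surv))
    train <- assign_weights(pres, abs_, bg_feat)
    f_bias <- file.path(config$out_dir, "bias_surface.asc")
    write_asc(bias$grid, f_bias)
    f_train <- file.path(config$out_dir, "training_set.csv")
    utils::write.csv(train, f_train, row.names = FALSE)
    list(value = list(train = train, bias = bias), files = c(f_bias, f_train))
  })
  train <- res$training$train

  res$ensemble <- run_stage("sdm", function(seed) {
    ens <- run_ensemble(train, stack, n_reps = config$n_reps,
                        train_frac = config$train_frac,
                        auc_min = config$auc_min, tss_min = config$tss_min,
                        seed = seed, lr = config$lr,
                        max_interactions = config$max_interactions)
    files <- c(suitability = "suitability_mean.asc",
               ci_low = "suitability_ci_low.asc",
               ci_high = "suitability_ci_high.asc",
               limits = "limits.asc")
    write_asc(ens$mean_suitability, file.path(config$out_dir, files[1]))
    write_asc(ens$ci_low, file.path(config$out_dir, files[2]))
    write_asc(ens$ci_high, file.path(config$out_dir, files[3]))
    write_asc(ens$limits, file.path(config$out_dir, files[4]))
    f_runs <- file.path(config$out_dir, "model_runs.csv")
    utils::write.csv(ens$runs, f_runs, row.names = FALSE)
    list(value = ens, files = c(file.path(config$out_dir, files), f_runs))
  })
  ens <- res$ensemble

  res$geostat <- run_stage("geostat", function(seed) {
    geo_feat <- features
    if (!is.null(config$geostat_covariates)) {
      keep <- c("community_id", "x_km", "y_km", "n_screened", "n_cases",
                config$geostat_covariates, "label", "weight")
      geo_feat <- features[, intersect(keep, names(features)), drop = FALSE]
      class(geo_feat) <- class(features)
    }
    model <- geostat_fit(geo_feat, seed = seed)
    pred <- geostat_predict(model, stack, limits = ens$limits,
                            threshold = config$exceedance_threshold,
                            n_samples = config$n_samples, seed = seed)
    f_par <- file.path(config$out_dir, "geostat_parameters.csv")
    utils::write.csv(model$se, f_par, row.names = FALSE)
    files <- file.path(config$out_dir,
                       c("prevalence_mean.asc", "prevalence_ci_low.asc",
                         "prevalence_ci_high.asc", "exceedance.asc",
                         "prevalence_se.asc"))
    write_asc(pred$mean, files[1]); write_asc(pred$ci_low, files[2])
    write_asc(pred$ci_high, files[3]); write_asc(pred$exceedance, files[4])
    write_asc(pred$se, files[5])
    list(value = list(model = model, prediction = pred),
         files = c(f_par, files))
  })
  pred <- res$geostat$prediction

  res$burden <- run_stage("burden", function(seed) {
    adults <- adult_population(world$population, config$adult_fraction)
    cs <- cases_surface(pred, adults)
    # default admin partition: four synthetic quadrant "regions"
    ext <- c(0, config$synth$grid_shape[2] * config$synth$cell_size,
             0, config$synth$grid_shape[1] * config$synth$cell_size)
    mx <- ext[2] / 2; my <- ext[4] / 2
    rect <- function(x1, x2, y1, y2) {
      list(cbind(c(x1, x2, x2, x1, x1), c(y1, y1, y2, y2, y1)))
    }
    admin <- admin_polygons(list(
      NW = rect(ext[1], mx, my, ext[4]), NE = rect(mx, ext[2], my, ext[4]),
      SW = rect(ext[1], mx, ext[3], my), SE = rect(mx, ext[2], ext[3], my)))
    tab <- aggregate_burden(cs, adults, admin, limits = ens$limits)
    f_tab <- file.path(config$out_dir, "burden_table.csv")
    utils::write.csv(tab, f_tab, row.names = FALSE)
    f_cases <- file.path(config$out_dir, "cases_mean.asc")
    write_asc(cs$mean, f_cases)
    list(value = list(table = tab, cases = cs, adults = adults),
         files = c(f_tab, f_cases))
  })

  res$report <- run_stage("report", function(seed) {
    summ <- survey_summary(world$surveys)
    endem <- summarize_endemicity(res$burden$table)
    rep <- c(
      summ[c("n_rows", "total_screened", "total_cases", "prevalence_pct",
             "zero_case_communities", "zero_case_share_pct")],
      list(selected_runs = sum(ens$runs$selected),
           total_runs = nrow(ens$runs),
           suitability_threshold = ens$threshold$threshold,
           total_cases_estimated = endem$total_cases,
           population_at_risk = endem$total_population_at_risk))
    f <- file.path(config$out_dir, "report.json")
    jsonlite::write_json(rep, f, auto_unbox = TRUE, digits = NA)
    list(value = rep, files = f)
  })

  res$manifest <- do.call(rbind, manifest)
  utils::write.csv(res$manifest, file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(res)
}
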