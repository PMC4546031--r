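# Orchestration of the full study design: per-sample preprocessing, kit
# working-range exclusion, sorted every-third prediction split, Monte Carlo
# CV calibration, final-model evaluation and artifact export.

#' RID kit working ranges
#'
#' Closed working ranges (mg/dL) of the reference radial-immunodiffusion
#' kits: `standard` 196-2748 and `ultra_low` 10-100 (the latter used for
#' pre-colostrum calves).
#'
#' @return Named list of `(low, high)` pairs.
#' @export
kit_working_ranges <- function() {
  list(standard = c(196, 2748), ultra_low = c(10, 100))
}

#' Exclude samples outside their RID kit's working range
#'
#' A sample is retained iff its reference IgG lies inside the *closed*
#' working range of the kit it was assayed with.
#'
#' @param samples Data frame with at least `igg_reference` and `kit`.
#' @param ranges Named list of `(low, high)` pairs per kit tag.
#' @return List with data frames `retained` and `excluded` (each carrying
#'   an added logical `in_range` column).
#' @export
exclude_out_of_range <- function(samples, ranges = kit_working_ranges()) {
  unknown <- setdiff(unique(samples$kit), names(ranges))
  if (length(unknown) > 0L) {
    stop("unknown kit tag(s): ", paste(unknown, collapse = ", "))
  }
  lo <- vapply(samples$kit, function(k) ranges[[k]][1], numeric(1))
  hi <- vapply(samples$kit, function(k) ranges[[k]][2], numeric(1))
  samples$in_range <- samples$igg_reference >= lo & samples$igg_reference <= hi
  list(retained = samples[samples$in_range, , drop = FALSE],
       excluded = samples[!samples$in_range, , drop = FALSE])
}

#' Sorted every-third prediction/calibration split
#'
#' Samples are sorted ascending by reference IgG (ties broken by
#' `sample_id`); ranks 1, 4, 7, ... (1-based) form the prediction set and
#' the remainder the calibration set. The prediction set therefore spans
#' the full concentration range; 200 retained samples split 67/133.
#'
#' @param samples Data frame with `sample_id` and `igg_reference`;
#'   at least 3 rows.
#' @return List of class `split_plan` with character vectors
#'   `prediction_ids` and `calibration_ids`.
#' @export
split_every_third <- function(samples) {
  n <- nrow(samples)
  if (is.null(n) || n < 3L) stop("need at least 3 samples to split")
  ord <- order(samples$igg_reference, samples$sample_id)
  pred_rank <- seq(1L, n, by = 3L)
  structure(list(
    prediction_ids = samples$sample_id[ord[pred_rank]],
    calibration_ids = samples$sample_id[ord[-pred_rank]]
  ), class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("Split plan: %d prediction / %d calibration samples (every-third rule)\n",
              length(x$prediction_ids), length(x$calibration_ids)))
  invisible(x)
}

# Preprocess every sample of a dataset. Returns the averaged spectra matrix
# (one row per sample), the shared selected grid, the stacked outlier
# report, and the per-replicate processed spectra for precision analysis.
preprocess_dataset <- function(dataset, spec) {
  ids <- dataset$samples$sample_id
  grid_sel <- NULL
  averaged <- NULL
  reports <- list()
  rep_proc <- list()
  for (i in seq_along(ids)) {
    rows <- which(dataset$replicates$sample_id == ids[i])
    pp <- apply_pipeline(dataset$spectra[rows, , drop = FALSE],
                         dataset$grid, spec)
    if (is.null(grid_sel)) {
      grid_sel <- pp$grid
      averaged <- matrix(NA_real_, length(ids), length(grid_sel),
                         dimnames = list(ids, NULL))
    }
    averaged[i, ] <- pp$spectrum
    rep_proc[[ids[i]]] <- pp$replicates
    if (!is.null(pp$report)) {
      rp <- pp$report
      rp$sample_id <- ids[i]
      rp$replicate_id <- dataset$replicates$replicate_id[rows]
      reports[[i]] <- as.data.frame(rp)[, c("sample_id", "replicate_id",
                                            "flagged_fraction", "excluded")]
    }
  }
  list(averaged = averaged, grid = grid_sel,
       outlier_report = if (length(reports)) do.call(rbind, reports) else NULL,
       replicates = rep_proc)
}

#' Run configuration for the end-to-end pipeline
#'
#' @param sim A [sim_config()] describing the synthetic dataset (ignored
#'   when `manifest` is given).
#' @param manifest Optional path to a CSV manifest of measured spectra; if
#'   supplied the dataset is loaded with [read_manifest()] instead of
#'   simulated.
#' @param preprocess A [preprocess_spec()] (default the smoothing + SNV
#'   variant, the best-performing combination for this assay).
#' @param kit_ranges Named working-range list, see [kit_working_ranges()].
#' @param cutoff FTPI cut-off, mg/dL.
#' @param mccv List of Monte Carlo CV settings: `k_max`, `n_repeats`,
#'   `train_size` (`NULL` = half the calibration set).
#' @param seed Master seed; the simulation uses it directly and the Monte
#'   Carlo CV a fixed offset of it, so a whole run is reproducible from
#'   this one integer.
#' @param output_dir Optional directory for on-disk artifacts (split plan,
#'   outlier report, model JSON, metric tables).
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), manifest = NULL,
                       preprocess = pp_preset("smooth+snv"),
                       kit_ranges = kit_working_ranges(), cutoff = 1000,
                       mccv = list(k_max = 30, n_repeats = 500,
                                   train_size = NULL),
                       seed = 1, output_dir = NULL) {
  seed <- as.integer(seed)
  if (is.null(manifest)) {
    sim$seed <- seed
  }
  structure(list(sim = sim, manifest = manifest, preprocess = preprocess,
                 kit_ranges = kit_ranges, cutoff = cutoff, mccv = mccv,
                 seed = seed, output_dir = output_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognized top-level keys: `sim` (fields of [sim_config()]),
#' `preprocess` (either a preset name or fields of [preprocess_spec()]),
#' `manifest`, `cutoff`, `mccv`, `seed`, `output_dir`.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$sim)) args$sim <- do.call(sim_config, y$sim)
  if (!is.null(y$preprocess)) {
    args$preprocess <- if (is.character(y$preprocess)) {
      pp_preset(y$preprocess)
    } else {
      do.call(preprocess_spec, y$preprocess)
    }
  }
  for (k in c("manifest", "cutoff", "mccv", "seed", "output_dir")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(run_config, args)
}

#' Run the full calibration and evaluation pipeline
#'
#' Simulate (or load) replicate spectra, preprocess each sample, exclude
#' samples outside their kit's working range, form the sorted every-third
#' prediction split, select the number of PLS factors by Monte Carlo
#' cross-validation on the calibration set, refit on the full calibration
#' set, predict the held-out prediction set, and compute the full
#' agreement, precision and diagnostic evaluation.
#'
#' @param config A [run_config()].
#' @return A list of class `atr_run` with elements `dataset`, `excluded`,
#'   `split`, `mccv`, `model`, `grid`, `calibration` / `prediction`
#'   (each: `ids`, `reference`, `predicted`, `agreement`),
#'   `diagnostics` (`prediction` and `all` 2x2 tables), `precision`
#'   (per-sample ATR CV* over replicate predictions, prediction set),
#'   `outlier_report`, and `config`.
#' @export
run_full <- function(config = run_config()) {
  dataset <- if (!is.null(config$manifest)) {
    read_manifest(config$manifest)
  } else {
    simulate_dataset(config$sim)
  }
  pp <- preprocess_dataset(dataset, config$preprocess)
  excl <- exclude_out_of_range(dataset$samples, config$kit_ranges)
  retained <- excl$retained
  split <- split_every_third(retained)

  ref_of <- stats::setNames(dataset$samples$igg_reference,
                            dataset$samples$sample_id)
  X_cal <- pp$averaged[split$calibration_ids, , drop = FALSE]
  y_cal <- ref_of[split$calibration_ids]
  X_pred <- pp$averaged[split$prediction_ids, , drop = FALSE]
  y_pred <- ref_of[split$prediction_ids]

  mccv <- mccv_select_factors(
    X_cal, y_cal, k_max = config$mccv$k_max,
    n_repeats = config$mccv$n_repeats,
    train_size = config$mccv$train_size,
    seed = config$seed + 1L
  )
  model <- fit_final_model(X_cal, y_cal, mccv$chosen_k)
  yhat_cal <- predict(model, X_cal)
  yhat_pred <- predict(model, X_pred)

  precision <- do.call(rbind, lapply(split$prediction_ids, function(id) {
    reps <- pp$replicates[[id]]
    keep <- rep(TRUE, nrow(reps))
    rep_out <- pp$outlier_report
    if (!is.null(rep_out)) {
      ex <- rep_out$excluded[rep_out$sample_id == id]
      if (length(ex) == nrow(reps)) keep <- !ex
    }
    preds <- predict(model, reps[keep, , drop = FALSE])
    if (length(preds) < 2L || mean(preds) <= 0) {
      return(data.frame(sample_id = id, n_replicates = length(preds),
                        mean = mean(preds), sd = stats::sd(preds),
                        cv = NA_real_, cv_star = NA_real_))
    }
    cs <- cv_star(preds)
    data.frame(sample_id = id, n_replicates = cs$n, mean = cs$mean,
               sd = cs$sd, cv = cs$cv, cv_star = cs$cv_star)
  }))

  run <- structure(list(
    dataset = dataset, excluded = excl$excluded, split = split,
    mccv = mccv, model = model, grid = pp$grid,
    calibration = list(ids = split$calibration_ids, reference = y_cal,
                       predicted = yhat_cal,
                       agreement = evaluate_agreement(y_cal, yhat_cal)),
    prediction = list(ids = split$prediction_ids, reference = y_pred,
                      predicted = yhat_pred,
                      agreement = evaluate_agreement(y_pred, yhat_pred)),
    diagnostics = list(
      prediction = diagnostic_table(y_pred, yhat_pred, config$cutoff),
      all = diagnostic_table(c(y_cal, y_pred), c(yhat_cal, yhat_pred),
                             config$cutoff)
    ),
    precision = precision,
    outlier_report = pp$outlier_report,
    config = config
  ), class = "atr_run")

  if (!is.null(config$output_dir)) write_run_artifacts(run, config$output_dir)
  run
}

# On-disk artifacts: split plan, outlier report, model JSON, RMMCCV curve,
# per-sample predictions and a metrics JSON.
write_run_artifacts <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(
    data.frame(sample_id = c(run$split$prediction_ids,
                             run$split$calibration_ids),
               set = rep(c("prediction", "calibration"),
                         c(length(run$split$prediction_ids),
                           length(run$split$calibration_ids)))),
    file.path(dir, "split_plan.csv"), row.names = FALSE)
  if (!is.null(run$outlier_report)) {
    utils::write.csv(run$outlier_report,
                     file.path(dir, "outlier_report.csv"), row.names = FALSE)
  }
  utils::write.csv(as.data.frame(run$mccv), file.path(dir, "rmmccv.csv"),
                   row.names = FALSE)
  write_model_json(run$model, file.path(dir, "model.json"), grid = run$grid)
  preds <- data.frame(
    sample_id = c(run$calibration$ids, run$prediction$ids),
    set = rep(c("calibration", "prediction"),
              c(length(run$calibration$ids), length(run$prediction$ids))),
    igg_reference = c(run$calibration$reference, run$prediction$reference),
    igg_predicted = c(run$calibration$predicted, run$prediction$predicted))
  utils::write.csv(preds, file.path(dir, "predictions.csv"),
                   row.names = FALSE)
  jsonlite::write_json(run_metrics(run), file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Flat numeric summary of a pipeline run
#'
#' @param run An `atr_run` from [run_full()].
#' @return Named list of the headline metrics (correlations, errors,
#'   Bland-Altman, RPD/RER, diagnostic rates, mean ATR CV*).
#' @export
run_metrics <- function(run) {
  pa <- run$prediction$agreement
  ca <- run$calibration$agreement
  dp <- run$diagnostics$prediction
  da <- run$diagnostics$all
  list(
    n_calibration = ca$n, n_prediction = pa$n,
    chosen_pls_factors = run$mccv$chosen_k,
    rmmccv_min = run$mccv$rmmccv[run$mccv$chosen_k],
    pearson_r_calibration = ca$pearson_r, rmsec = ca$rmse,
    ccc_calibration = ca$ccc,
    pearson_r_prediction = pa$pearson_r, rmsep = pa$rmse,
    ccc_prediction = pa$ccc,
    bland_altman_mean_diff = pa$bland_altman$mean_diff,
    bland_altman_loa_low = pa$bland_altman$loa_low,
    bland_altman_loa_high = pa$bland_altman$loa_high,
    rpd = pa$rpd, rer = pa$rer,
    sensitivity_prediction = dp$sensitivity,
    specificity_prediction = dp$specificity,
    accuracy_prediction = dp$accuracy,
    sensitivity_all = da$sensitivity, specificity_all = da$specificity,
    accuracy_all = da$accuracy,
    true_prevalence_all = da$true_prevalence,
    apparent_prevalence_all = da$apparent_prevalence,
    mean_cv_star_atr = mean(run$precision$cv_star, na.rm = TRUE)
  )
}

#' @export
print.atr_run <- function(x, ...) {
  m <- run_metrics(x)
  cat(sprintf(paste0(
    "ATR IgG calibration run\n",
    "  samples: %d calibration / %d prediction (%d excluded out of range)\n",
    "  PLS factors: %d (RMMCCV %.4g mg/dL, %d MC repeats)\n",
    "  calibration: r %.3f, RMSEC %.4g mg/dL\n",
    "  prediction:  r %.3f, CCC %.3f, RMSEP %.4g mg/dL\n",
    "  Bland-Altman: %.4g [%.4g, %.4g] mg/dL\n",
    "  RPD %.2f, RER %.2f (%s)\n",
    "  FTPI (prediction set): Se %s, Sp %s, accuracy %s\n"),
    m$n_calibration, m$n_prediction, nrow(x$excluded),
    m$chosen_pls_factors, m$rmmccv_min, x$mccv$n_repeats,
    m$pearson_r_calibration, m$rmsec,
    m$pearson_r_prediction, m$ccc_prediction, m$rmsep,
    m$bland_altman_mean_diff, m$bland_altman_loa_low, m$bland_altman_loa_high,
    m$rpd, m$rer, x$prediction$agreement$rpd_interpretation,
    if (is.na(m$sensitivity_prediction)) "NA" else
      sprintf("%.0f%%", 100 * m$sensitivity_prediction),
    if (is.na(m$specificity_prediction)) "NA" else
      sprintf("%.0f%%", 100 * m$specificity_prediction),
    sprintf("%.0f%%", 100 * m$accuracy_prediction)))
  invisible(x)
}

#' Compare pre-processing variants on one dataset
#'
#' Runs the exclusion/split/Monte-Carlo-CV/final-fit chain once per
#' pre-processing variant on a shared dataset and collects one result row
#' per variant: chosen factor count, RMMCCV at that count, calibration r
#' and RMSEC, prediction r, RMSEP, RPD and RER. The lowest-RMMCCV variant
#' is reported via the `winner` attribute, never auto-selected silently.
#'
#' @param dataset An `atr_dataset`.
#' @param variants Character vector of [pp_presets()] names, or a named
#'   list of [preprocess_spec()] objects.
#' @param mccv List of Monte Carlo CV settings (`k_max`, `n_repeats`,
#'   `train_size`).
#' @param kit_ranges Working ranges for the exclusion stage.
#' @param seed Seed for the (shared) Monte Carlo splits.
#' @return Data frame with one row per variant; attribute `winner` holds
#'   the lowest-RMMCCV variant name.
#' @export
compare_preprocessing <- function(dataset, variants = pp_presets(),
                                  mccv = list(k_max = 30, n_repeats = 500,
                                              train_size = NULL),
                                  kit_ranges = kit_working_ranges(),
                                  seed = 1) {
  if (is.character(variants)) {
    variants <- stats::setNames(lapply(variants, pp_preset), variants)
  }
  if (length(variants) < 1L) stop("need at least one pre-processing variant")
  rows <- lapply(names(variants), function(nm) {
    pp <- preprocess_dataset(dataset, variants[[nm]])
    excl <- exclude_out_of_range(dataset$samples, kit_ranges)
    split <- split_every_third(excl$retained)
    ref_of <- stats::setNames(dataset$samples$igg_reference,
                              dataset$samples$sample_id)
    X_cal <- pp$averaged[split$calibration_ids, , drop = FALSE]
    y_cal <- ref_of[split$calibration_ids]
    sel <- mccv_select_factors(X_cal, y_cal, k_max = mccv$k_max,
                               n_repeats = mccv$n_repeats,
                               train_size = mccv$train_size, seed = seed)
    model <- fit_final_model(X_cal, y_cal, sel$chosen_k)
    y_pred <- ref_of[split$prediction_ids]
    yhat_pred <- predict(model, pp$averaged[split$prediction_ids, ,
                                            drop = FALSE])
    pa <- evaluate_agreement(y_pred, yhat_pred)
    data.frame(
      preprocessing = nm, pls_factors = sel$chosen_k,
      rmmccv = sel$rmmccv[sel$chosen_k],
      r_calibration = pearson(y_cal, predict(model, X_cal)),
      rmsec = rmse(y_cal, predict(model, X_cal)),
      r_prediction = pa$pearson_r, rmsep = pa$rmse,
      rpd = pa$rpd, rer = pa$rer,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "winner") <- out$preprocessing[which.min(out$rmmccv)]
  out
}
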