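#' Pipeline run configuration
#'
#' Bundles every stage configuration and seed of the end-to-end pipeline:
#' cohort simulation, preprocessing, ensemble training, overlapping-patch
#' prediction with D95 renormalization, plan evaluation and flagging.
#'
#' @param out_dir Output directory for artifacts.
#' @param n_plans Cohort size (>= 5).
#' @param phantom A [phantom_config()].
#' @param net A [network_config()].
#' @param train A [train_config()].
#' @param loss A [loss_config()].
#' @param patch A [patch_spec()].
#' @param n_models Ensemble size.
#' @param model_seeds Distinct seeds, one per ensemble member.
#' @param flag_thresholds Threshold list for
#'   [flag_and_extract_objectives()].
#' @param equivalence_bound_Gy TOST equivalence bound.
#' @param alpha TOST level.
#' @param seed Master seed (cohort generation and split).
#' @param write_volumes Also write every plan's channels as NIfTI.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       n_plans = 10L,
                       phantom = phantom_config(),
                       net = network_config(),
                       train = train_config(),
                       loss = loss_config(),
                       patch = patch_spec(),
                       n_models = 3L,
                       model_seeds = seq_len(n_models),
                       flag_thresholds = list(),
                       equivalence_bound_Gy = 1.0,
                       alpha = 0.05,
                       seed = 1L,
                       write_volumes = FALSE) {
  stopifnot(inherits(phantom, "phantom_config"), inherits(net, "network_config"),
            inherits(train, "train_config"), inherits(loss, "loss_config"),
            inherits(patch, "patch_spec"))
  if (is.null(phantom$prescription_Gy) || !is.finite(phantom$prescription_Gy))
    stop("config error: prescription is missing", call. = FALSE)
  structure(
    list(out_dir = out_dir, n_plans = as.integer(n_plans), phantom = phantom,
         net = net, train = train, loss = loss, patch = patch,
         n_models = as.integer(n_models), model_seeds = as.integer(model_seeds),
         flag_thresholds = flag_thresholds,
         equivalence_bound_Gy = equivalence_bound_Gy, alpha = alpha,
         seed = as.integer(seed), write_volumes = isTRUE(write_volumes)),
    class = "run_config"
  )
}

sample_structures <- function(sample) {
  st <- list(ptv = sample$ptv_mask)
  for (nm in structure_vocabulary())
    st[[nm]] <- structure_mask(nm, sample$channels[[nm]]$values,
                               sample$channels[[nm]]$spacing,
                               sample$channels[[nm]]$origin)
  st
}

#' Run the full dose-prediction pipeline
#'
#' simulate -> preprocess -> train ensemble -> predict (overlapping
#' patches, ensemble mean, D95 renormalization) -> evaluate -> flag.
#' Writes the configuration, the split membership, per-model training
#' histories, the metrics report, TOST results and extracted objectives
#' under `config$out_dir`.
#'
#' @param config A [run_config()].
#' @param verbose Print stage progress.
#' @return Invisibly, a list with `split`, `models`, `predictions`,
#'   `comparisons`, `report`, `tost`, `flags`, `status` (0 on success).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  note <- function(...) if (verbose) message(sprintf(...))

  note("[simulate] %d phantoms", config$n_plans)
  cohort <- make_cohort(config$phantom, config$n_plans, config$seed)
  ids <- vapply(cohort$samples, function(s) s$plan_id, character(1))
  jsonlite::write_json(cohort$split, file.path(config$out_dir, "split.json"),
                       auto_unbox = FALSE)
  if (config$write_volumes)
    for (s in cohort$samples) write_plan_sample(s, file.path(config$out_dir, "plans"))

  pick <- function(id_set) cohort$samples[match(id_set, ids)]
  train_s <- pick(cohort$split$train_ids)
  val_s <- pick(cohort$split$validation_ids)
  test_s <- pick(cohort$split$test_ids)

  note("[train] %d models on %d plans", config$n_models, length(train_s))
  models <- train_ensemble(train_s, val_s, config$net, config$train, config$loss,
                           n_models = config$n_models, seeds = config$model_seeds,
                           verbose = verbose)
  for (i in seq_along(models))
    utils::write.csv(models[[i]]$history,
                     file.path(config$out_dir, sprintf("history_model%d.csv", i)),
                     row.names = FALSE)

  note("[predict] %d test plans", length(test_s))
  predictions <- list()
  comparisons <- list()
  flags <- list()
  for (s in test_s) {
    pred <- predict_volume(models, s, config$patch)
    pred <- normalize_to_reference_d95(pred, s$reference_dose, s$ptv_mask)
    predictions[[s$plan_id]] <- pred
    st <- sample_structures(s)
    cmp <- plan_dose_deltas(pred, s$reference_dose, st, plan_id = s$plan_id)
    comparisons[[s$plan_id]] <- cmp
    flags[[s$plan_id]] <- flag_and_extract_objectives(cmp, pred, s$body_mask,
                                                      config$flag_thresholds)
    if (config$write_volumes)
      write_volume(pred, file.path(config$out_dir, "plans", s$plan_id,
                                   "predicted_dose.nii.gz"))
  }

  note("[evaluate] report + TOST")
  report <- write_metrics_report(comparisons, file.path(config$out_dir, "report"))
  body_pred <- vapply(test_s, function(s)
    mean(predictions[[s$plan_id]]$values[s$body_mask$values != 0]), numeric(1))
  body_ref <- vapply(test_s, function(s)
    mean(s$reference_dose$values[s$body_mask$values != 0]), numeric(1))
  # the paired equivalence test needs at least 3 test plans
  tost <- if (length(test_s) >= 3)
    tost_equivalence(body_pred, body_ref,
                     bound_Gy = config$equivalence_bound_Gy, alpha = config$alpha)
  else NULL
  flag_json <- lapply(flags, function(f) list(
    flag = f$flag,
    objectives = lapply(f$objectives, function(o)
      list(kind = o$kind, structure = o$structure, dose_Gy = o$dose_Gy,
           volume_fraction = o$volume_fraction))))
  jsonlite::write_json(flag_json, file.path(config$out_dir, "flags.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  tost_json <- if (is.null(tost)) list(note = "fewer than 3 test plans")
  else list(mean_diff_Gy = tost$mean_diff_Gy, p_lower = tost$p_lower,
            p_upper = tost$p_upper, equivalent = tost$equivalent,
            bound_Gy = tost$bound_Gy, alpha = tost$alpha, n = tost$n)
  jsonlite::write_json(tost_json, file.path(config$out_dir, "tost.json"),
                       auto_unbox = TRUE, digits = NA)

  cfg_json <- config
  cfg_json$phantom$organs <- NULL  # data.frame; re-created from defaults
  jsonlite::write_json(cfg_json, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE, na = "null")

  invisible(list(split = cohort$split, models = models, predictions = predictions,
                 comparisons = comparisons, report = report, tost = tost,
                 flags = flags, status = 0L))
}
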