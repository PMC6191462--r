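# End-to-end orchestration: one case (segment -> skeleton -> features) and a
# full study (features -> selection -> stability -> classification ->
# clustering), with a single master seed fanned out to per-stage seeds.

#' Default pipeline configuration
#'
#' Every tunable of the pipeline in one structure: region-growing settings
#' (S, connectivity, cap, random seed count), VOI margin, skeletonization
#' knobs, feature configuration, classifier specification, mRMR k, and the
#' master seed.
#'
#' @param seed master seed; per-stage seeds are derived from it by stable
#'   hashing of stage names.
#' @return A named list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    voi_margin_mm = 10,
    use_lung_mask = TRUE,
    region_grow = region_grow_config(rng_seed = derive_seed(seed, "region-grow")),
    skeleton = list(centeredness_power = 6, endpoint_tolerance_mm = NULL,
                    resample_step_mm = NULL),
    qvt = qvt_config(),
    select_k = 12L,
    classifier = classifier_spec(rng_seed = derive_seed(seed, "classifier")),
    consensus = list(k_list = c(2, 3, 4),
                     metric_list = c("euclidean", "cityblock", "correlation"),
                     n_restarts = 20L)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; omitted keys keep their defaults.
#'
#' @param path YAML file.
#' @param seed master seed used for any seed field the file does not set.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path, seed = 1L) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config(seed = raw$seed %||% seed)
  known <- names(cfg)
  for (key in names(raw)) {
    if (!key %in% known) stopf("read_config: unknown key '%s'", key)
    if (is.list(cfg[[key]]) && is.list(raw[[key]])) {
      sub_known <- names(cfg[[key]])
      for (sk in names(raw[[key]])) {
        if (!sk %in% sub_known) stopf("read_config: unknown key '%s.%s'", key, sk)
        cfg[[key]][[sk]] <- raw[[key]][[sk]]
      }
    } else {
      cfg[[key]] <- raw[[key]]
    }
  }
  cfg
}

#' Segment, skeletonize and featurize one case
#'
#' @param volume an [image_volume()] (or a path readable by [read_volume()]).
#' @param nodule_mask a [binary_mask()] (or a path).
#' @param config a [default_config()] list.
#' @return A list: `features` (named 35-vector), `lung_mask`, `vessel_mask`,
#'   `tree`, `voi`, `log` (parameters, seeds, degeneracy flags).
#' @export
case_features <- function(volume, nodule_mask, config = default_config()) {
  if (is.character(volume)) volume <- read_volume(volume)
  if (is.character(nodule_mask)) nodule_mask <- read_mask(nodule_mask)
  if (!any(nodule_mask$values)) stopf("case_features: empty nodule mask")
  lung <- if (isTRUE(config$use_lung_mask)) segment_lungs(volume) else NULL
  vessel <- region_grow_vasculature(volume, nodule_mask, config$region_grow, lung)
  voi <- define_voi(nodule_mask, config$voi_margin_mm)
  tree <- if (any(vessel$values)) {
    extract_tree(vessel,
                 centeredness_power = config$skeleton$centeredness_power,
                 endpoint_tolerance_mm = config$skeleton$endpoint_tolerance_mm,
                 resample_step_mm = config$skeleton$resample_step_mm)
  } else vessel_tree(list(), degenerate = TRUE)
  feats <- compute_qvt(tree, vessel, voi, config$qvt)
  list(features = feats, lung_mask = lung, vessel_mask = vessel, tree = tree,
       voi = voi,
       log = list(S_hu = config$region_grow$S_hu,
                  rng_seed = config$region_grow$rng_seed,
                  n_voxels = attr(vessel, "n_voxels"),
                  truncated = isTRUE(attr(vessel, "truncated")),
                  degenerate_tree = tree$degenerate,
                  degenerate_features = isTRUE(attr(feats, "degenerate"))))
}

#' Run one case from files, writing artifacts
#'
#' @param volume_path,nodule_path input files (NIfTI, or a DICOM directory
#'   for the volume).
#' @param config a `pipeline_config`.
#' @param out_dir optional directory for artifacts (lung mask, vessel mask,
#'   tree JSON, feature row CSV, log JSON).
#' @param case_id identifier used in the feature row.
#' @return The [case_features()] result, invisibly when `out_dir` is given.
#' @export
run_case <- function(volume_path, nodule_path, config = default_config(),
                     out_dir = NULL, case_id = "case001") {
  if (!file.exists(volume_path) && !dir.exists(volume_path)) {
    stopf("run_case: volume not found: %s", volume_path)
  }
  if (!file.exists(nodule_path)) stopf("run_case: nodule mask not found: %s", nodule_path)
  res <- case_features(volume_path, nodule_path, config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(res$lung_mask)) {
      write_volume(res$lung_mask, file.path(out_dir, "lung_mask.nii.gz"))
    }
    write_volume(res$vessel_mask, file.path(out_dir, "vessel_mask.nii.gz"))
    write_tree(res$tree, file.path(out_dir, "tree.json"))
    row <- data.frame(case_id = case_id, label = NA, t(res$features))
    write_feature_table(row, file.path(out_dir, "features.csv"))
    jsonlite::write_json(res$log, file.path(out_dir, "log.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(res)
}

#' Feature table for a list of in-memory phantom cases
#'
#' @param cases list of `phantom_case` objects (or lists with `volume` and
#'   `nodule_mask`).
#' @param manifest data.frame with `case_id` and `label` rows matching
#'   `cases`.
#' @param config a `pipeline_config`.
#' @return data.frame: `case_id`, `label`, 35 feature columns.
#' @export
cohort_feature_table <- function(cases, manifest, config = default_config()) {
  stopifnot(length(cases) == nrow(manifest))
  rows <- lapply(seq_along(cases), function(i) {
    f <- case_features(cases[[i]]$volume, cases[[i]]$nodule_mask, config)$features
    cbind(data.frame(case_id = manifest$case_id[i], label = manifest$label[i],
                     stringsAsFactors = FALSE),
          as.data.frame(t(f)))
  })
  do.call(rbind, rows)
}

#' Run a full study
#'
#' Features for every case, mRMR selection of the top k features, optional
#' test-retest stability filtering, cross-validated training, optional
#' held-out validation, and consensus clustering with a chi-squared
#' label-association test.
#'
#' @param cohort training cohort: a [make_cohort()] result, or a list with
#'   `cases` and `manifest` (>= 4 cases, both classes present).
#' @param config a `pipeline_config`.
#' @param retest_cohort optional re-test copy of the same cases for ICC
#'   stability; when absent the stability section is marked skipped.
#' @param validation_cohort optional held-out cohort scored with the locked
#'   model.
#' @param stability_min when stability is available, keep only selected
#'   features with ICC above this bound (if at least 2 survive).
#' @param out_dir optional output directory (report JSON + feature CSVs).
#' @return A list of class `study_report`.
#' @export
run_study <- function(cohort, config = default_config(), retest_cohort = NULL,
                      validation_cohort = NULL, stability_min = 0.4,
                      out_dir = NULL) {
  manifest <- cohort$manifest
  if (nrow(manifest) < 4) stopf("run_study: need at least 4 cases")
  if (length(unique(manifest$label)) < 2) stopf("run_study: single-class manifest")

  tab <- cohort_feature_table(cohort$cases, manifest, config)
  pool <- setdiff(names(tab), c("case_id", "label"))
  sel <- mrmr_select(tab, min(config$select_k, length(pool)))

  # the ICC stability filter uses retest agreement only (no class labels), so
  # it may restrict the candidate pool ahead of cross-validation without
  # leaking label information
  stability <- NULL
  if (!is.null(retest_cohort)) {
    retab <- cohort_feature_table(retest_cohort$cases, retest_cohort$manifest,
                                  config)
    stability <- icc(tab[pool], retab[pool])
    stable <- stability$feature[stability$icc > stability_min]
    if (length(stable) >= 2) pool <- stable
  }

  # label-driven mRMR selection is rerun inside every training fold, so the
  # reported CV AUC carries no selection optimism; the locked model uses the
  # selection on all rows
  cv <- train_evaluate(tab[c("case_id", "label", pool)], config$classifier,
                       pool, select_k = min(config$select_k, length(pool)))
  kept <- cv$model$features

  validation_auc <- NULL
  if (!is.null(validation_cohort)) {
    vtab <- cohort_feature_table(validation_cohort$cases,
                                 validation_cohort$manifest, config)
    validation_auc <- roc_auc(vtab$label, predict_scores(cv$model, vtab))
  }

  km <- kmeans_cluster(tab[kept], 2, rng_seed = derive_seed(config$seed, "kmeans"))
  chi2 <- if (length(unique(km)) >= 2) chi2_association(km, tab$label) else NULL
  cons <- consensus_cluster(tab[kept], k_list = config$consensus$k_list,
                            metric_list = config$consensus$metric_list,
                            n_restarts = config$consensus$n_restarts,
                            rng_seed = derive_seed(config$seed, "consensus"),
                            labels = tab$label)

  report <- structure(list(
    features = tab, selection = sel, selected_features = kept,
    stability = stability,
    stability_skipped = is.null(retest_cohort),
    cv_auc_mean = cv$cv_auc_mean, cv_auc_sd = cv$cv_auc_sd,
    fold_aucs = cv$fold_aucs, model = cv$model,
    validation_auc = validation_auc,
    kmeans_assignment = km, chi2 = chi2, consensus = cons,
    seed = config$seed, timestamp = format(Sys.time(), tz = "UTC")
  ), class = "study_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(tab, file.path(out_dir, "features.csv"))
    jsonlite::write_json(list(
      selected_features = kept,
      stability_skipped = report$stability_skipped,
      cv_auc_mean = report$cv_auc_mean, cv_auc_sd = report$cv_auc_sd,
      fold_aucs = report$fold_aucs,
      validation_auc = validation_auc,
      chi2_p = if (!is.null(chi2)) chi2$p_value else NULL,
      consensus_overall_purity = cons$overall_purity,
      seed = config$seed, timestamp = report$timestamp
    ), file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  cases: %d   selected features: %d\n", nrow(x$features),
              length(x$selected_features)))
  cat(sprintf("  CV AUC: %.3f +/- %.3f\n", x$cv_auc_mean, x$cv_auc_sd))
  if (!is.null(x$validation_auc)) {
    cat(sprintf("  validation AUC: %.3f\n", x$validation_auc))
  }
  if (!is.null(x$consensus$overall_purity)) {
    cat(sprintf("  consensus purity: %.3f\n", x$consensus$overall_purity))
  }
  if (!is.null(x$chi2)) {
    cat(sprintf("  cluster/label chi2 p-value: %.3g\n", x$chi2$p_value))
  }
  invisible(x)
}
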