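#' Run the complete study pipeline on a dataset
#'
#' Orchestrates the full analysis on a (synthetic or real) study: QC cascade
#' -> log10 + batchwise z-score normalization -> PC covariates -> optional
#' biomarker-based training-eligibility refinement (AD must be A+T+, CO
#' A-T-; PD/FTD/DLB enter on clinical diagnosis) -> three-stage feature
#' selection -> stratified split, SMOTE+Tomek rebalancing and boosted-tree
#' training via [nd_fit()] -> held-out Shapley attributions -> zero-shot
#' scoring of any non-core diagnostic groups.
#'
#' @param ds A `synthetic_dataset` (or a list with the same fields: `rfu`
#'   [proteomic_matrix()], `metadata`, `buffer`).
#' @param k Number of features for the F-test stage.
#' @param qc_cfg A [qc_config()].
#' @param spec A [model_spec()].
#' @param eligibility Apply biomarker eligibility refinement when the
#'   metadata carries `abeta42`/`ptau` columns (default TRUE).
#' @param split_seed Seed for the train/test split.
#' @param selection `"split_safe"` (default): PCs and the feature-selection
#'   cascade are fitted on the training partition only, with held-out
#'   samples projected onto the fitted PC axes --- no information from the
#'   test partition reaches selection. `"pooled"` fits them on all core
#'   samples.
#' @param shap Compute Shapley attributions on the held-out test partition
#'   (default TRUE).
#' @return List of class `nd_study`: `qc` (matrix + report), `norm`, `pcs`,
#'   `meta` (aligned to QC'd samples, with `eligibility` column when
#'   applied), `at` (AT status, when computed), `selection`, `model`
#'   ([nd_fit()] result), `metrics` (held-out [multiclass_metrics()]),
#'   `shap`, `zero_shot`.
#' @export
nd_pipeline <- function(ds, k, qc_cfg = qc_config("csf"),
                        spec = model_spec("csf"), eligibility = TRUE,
                        split_seed = 42L,
                        selection = c("split_safe", "pooled"), shap = TRUE) {
  selection <- match.arg(selection)
  ann <- analyte_annotations(analyte_ids(ds$rfu), buffer = ds$buffer)
  qc <- qc_pipeline(ds$rfu, ann, qc_cfg)
  norm <- normalize_matrix(qc$matrix)
  meta <- ds$metadata[match(sample_ids(norm), ds$metadata$sample_id), ]

  at <- NULL
  core <- meta$diagnosis %in% ND_CLASSES
  if (eligibility && !is.null(meta$abeta42) && !is.null(meta$ptau)) {
    at <- assign_at_status(meta[, c("abeta42", "ptau")])
    meta$eligibility <- training_eligibility(meta, at, qc_cfg$fluid)
    core <- core & meta$eligibility == "core_train"
  }
  core_idx <- which(core)

  # the split is deterministic given labels + seed, so nd_fit reproduces it
  if (selection == "split_safe") {
    plan <- stratified_split(meta$diagnosis[core_idx], 0.7, split_seed)
    fit_rows <- core_idx[plan$train]
  } else {
    fit_rows <- core_idx
  }
  pcs <- pca_scores(norm, 2, fit_rows = fit_rows)
  sel <- select_features(pm_subset(norm, i = fit_rows),
                         meta[fit_rows, , drop = FALSE],
                         pcs[fit_rows, , drop = FALSE], k = k)
  feats <- sel$selected
  model <- nd_fit(norm$values[core_idx, feats, drop = FALSE],
                  meta$diagnosis[core_idx], spec = spec,
                  split_seed = split_seed)
  metrics <- multiclass_metrics(model$test_labels, model$test_probs)

  shap_t <- NULL
  if (shap) {
    test_rows <- core_idx[model$split$test]
    shap_t <- shap_attributions(model,
                                norm$values[test_rows, feats, drop = FALSE])
  }
  zs_rows <- which(!(meta$diagnosis %in% ND_CLASSES))
  zero_shot <- if (length(zs_rows) > 0)
    zero_shot_apply(model, norm$values[zs_rows, feats, drop = FALSE],
                    meta$diagnosis[zs_rows])
  else NULL

  structure(list(qc = qc, norm = norm, pcs = pcs, meta = meta, at = at,
                 selection = sel, model = model, metrics = metrics,
                 shap = shap_t, zero_shot = zero_shot),
            class = "nd_study")
}

#' @export
print.nd_study <- function(x, ...) {
  cat("nd_study: full pipeline result\n")
  cat(sprintf("  QC'd matrix: %d samples x %d analytes\n",
              nrow(x$norm$values), ncol(x$norm$values)))
  cat(sprintf("  features selected: %d\n", length(x$selection$selected)))
  print(x$model)
  print(x$metrics)
  invisible(x)
}
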