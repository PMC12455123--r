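# End-to-end convenience wrapper: precursor report -> classified map.

#' Build a spatial dataset from a long precursor table
#'
#' Runs, per replicate: pivot to a features-by-fractions matrix, the QC
#' chain (contaminants/ambiguous, intensity high-pass, column and row
#' missingness filters), imputation under the chosen strategy,
#' sum-normalization and protein-level aggregation; then intersects the
#' replicates into the combined profile dataset with marker labels.
#'
#' @param table Long precursor tibble (`run_id`, `protein_group`,
#'   `precursor_id`, `intensity`), e.g. from [read_precursor_report()] or
#'   a [simulate_experiment()] report.
#' @param design Run design tibble.
#' @param markers Optional marker tibble (`accession`, `marker`).
#' @param qc_cfg A [qc_config()].
#' @param impute_cfg An [impute_config()].
#' @param impute_mode Imputation strategy (see [impute_profiles()]).
#' @param aggregate_method `"median"` (DIA default) or `"robust"`.
#' @param renormalize Re-sum-normalize protein-level replicate blocks.
#' @return Spatial-dataset tibble (`accession`, `marker`, profile
#'   columns); per-replicate QC reports in the `"qc_reports"` attribute.
#' @export
build_spatial_dataset <- function(table, design, markers = NULL,
                                  qc_cfg = qc_config(),
                                  impute_cfg = impute_config(),
                                  impute_mode = "mixed",
                                  aggregate_method = "median",
                                  renormalize = TRUE) {
  reps <- sort(unique(design$replicate))
  mats <- vector("list", length(reps))
  reports <- vector("list", length(reps))
  for (i in seq_along(reps)) {
    m <- pivot_replicate(table, design, reps[i]) |>
      qc_replicate(qc_cfg) |>
      impute_profiles(mode = impute_mode, cfg = impute_cfg)
    reports[[i]] <- qc_report(m)
    mats[[i]] <- m |>
      normalize_profiles() |>
      aggregate_proteins(method = aggregate_method)
  }
  out <- combine_replicates(mats, markers = markers,
                            renormalize = renormalize)
  attr(out, "qc_reports") <- reports
  out
}

#' Classify a spatial dataset end to end
#'
#' Cross-validates the marker SVM, trains the final model with the modal
#' hyperparameters, derives per-organelle thresholds from the held-out
#' score distributions, and assigns every protein.
#'
#' @param dataset Spatial-dataset tibble with marker labels.
#' @param cfg An [svm_config()].
#' @return List with `cv` (`svm_cv`), `model` (`organelle_svm`),
#'   `thresholds`, and `assignment` (`organelle_assignment`).
#' @export
classify_spatial_dataset <- function(dataset, cfg = svm_config()) {
  cv <- crossvalidate_f1(dataset, cfg)
  model <- train_final(dataset, cfg, params = cv$chosen)
  thresholds <- compute_thresholds(cv)
  assignment <- assign_with_thresholds(model, dataset, thresholds)
  list(cv = cv, model = model, thresholds = thresholds,
       assignment = assignment)
}
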