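# Missing-value imputation on replicate matrices.
#
# The mixed strategy assigns each precursor row a missingness mechanism
# from its own missing-value count within the replicate: rows missing
# more than `mnar_missing_count_threshold` values are treated as missing
# not at random (left-censored, imputed with the global observed minimum),
# the remaining incomplete rows as missing at random (imputed by
# k-nearest-neighbour row averaging). Each replicate is imputed
# independently. Global k-NN and global MinDet are provided as the
# cautionary single-mechanism baselines.

#' Imputation configuration
#'
#' @param mnar_missing_count_threshold Rows missing strictly more than
#'   this many values are labelled MNAR (default 2, so a 10-fraction row
#'   with 3 missing values is MNAR and one with 2 missing is MAR). The
#'   count is absolute, not rescaled with the number of fractions; set
#'   `proportion_mode = TRUE` to use a proportion instead.
#' @param knn_k Number of neighbour rows averaged per missing cell.
#' @param mindet_quantile Column quantile used by the deterministic
#'   left-censor (MinDet) baseline.
#' @param min_scope `"global"` (default): the min method uses the single
#'   minimum observed value of the whole replicate matrix; `"column"`:
#'   per-column minima.
#' @param proportion_mode Label rows MNAR when their missing proportion
#'   exceeds `mnar_missing_prop_threshold` instead of the absolute count.
#' @param mnar_missing_prop_threshold Proportion threshold used when
#'   `proportion_mode` is on.
#' @return An `impute_config` list. Neighbour ties are broken by row
#'   order; the whole module is deterministic, with no RNG.
#' @export
impute_config <- function(mnar_missing_count_threshold = 2, knn_k = 10,
                          mindet_quantile = 0.01,
                          min_scope = c("global", "column"),
                          proportion_mode = FALSE,
                          mnar_missing_prop_threshold = 0.2) {
  stopifnot(
    mnar_missing_count_threshold >= 0, knn_k >= 1,
    mindet_quantile > 0, mindet_quantile < 1,
    mnar_missing_prop_threshold >= 0, mnar_missing_prop_threshold <= 1
  )
  structure(
    list(
      mnar_missing_count_threshold = as.integer(mnar_missing_count_threshold),
      knn_k = as.integer(knn_k),
      mindet_quantile = mindet_quantile,
      min_scope = match.arg(min_scope),
      proportion_mode = isTRUE(proportion_mode),
      mnar_missing_prop_threshold = mnar_missing_prop_threshold
    ),
    class = "impute_config"
  )
}

#' Label each row's missingness mechanism
#'
#' @param matrix Replicate-matrix tibble (post-QC: every row should have
#'   at least one observed value).
#' @param cfg An [impute_config()].
#' @return Tibble `precursor_id`, `n_missing`, `label` with `label` in
#'   `{"COMPLETE", "MAR", "MNAR"}`.
#' @export
classify_missingness <- function(matrix, cfg = impute_config()) {
  m <- value_matrix(matrix)
  n_missing <- rowSums(is.na(m))
  thr <- if (cfg$proportion_mode) {
    cfg$mnar_missing_prop_threshold * ncol(m)
  } else {
    cfg$mnar_missing_count_threshold
  }
  label <- dplyr::case_when(
    n_missing == 0 ~ "COMPLETE",
    n_missing > thr ~ "MNAR",
    TRUE ~ "MAR"
  )
  tibble::tibble(
    precursor_id = matrix$precursor_id,
    n_missing = as.integer(n_missing),
    label = label
  )
}

# Pairwise row distances on mutually observed columns, rescaled by
# sqrt(total columns / shared columns) to compensate unequal overlap.
# Rows with no shared observed column are at infinite distance.
scaled_row_distances <- function(m) {
  obs <- !is.na(m)
  z <- m
  z[!obs] <- 0
  z2 <- z^2
  omat <- obs * 1
  shared <- omat %*% t(omat)
  d2 <- z2 %*% t(omat) + omat %*% t(z2) - 2 * z %*% t(z)
  d2[d2 < 0] <- 0 # numerical noise
  d <- sqrt(d2 * ncol(m) / shared) # shared = 0 -> Inf via division
  d[shared == 0] <- Inf
  diag(d) <- Inf
  d
}

#' k-nearest-neighbour imputation
#'
#' For each missing cell of a selected row, takes the mean of that column
#' over the `k` nearest rows (Euclidean distance on mutually observed
#' columns, each distance scaled by `sqrt(total/shared)` columns) among
#' the rows observed in that column, excluding the row itself. Ties in
#' distance are broken by row order. Falls back to the column mean of
#' observed values when no donor row is observed in the needed column.
#'
#' @param matrix Replicate-matrix tibble; every row needs at least one
#'   observed value.
#' @param rows Optional subset of rows to impute: logical mask, integer
#'   indices, or precursor ids. Default: all rows with a missing cell.
#' @param cfg An [impute_config()].
#' @return The matrix with the selected rows' missing cells filled;
#'   observed cells are untouched.
#' @export
impute_knn <- function(matrix, rows = NULL, cfg = impute_config()) {
  m <- value_matrix(matrix)
  if (any(rowSums(!is.na(m)) == 0)) {
    stop("impute_knn requires every row to have at least one observed value",
         call. = FALSE)
  }
  if (any(colSums(!is.na(m)) == 0)) {
    stop("a column has no observed value; run QC column filtering first",
         call. = FALSE)
  }
  idx <- resolve_rows(matrix, rows, m)
  if (length(idx) == 0) {
    return(matrix)
  }
  d <- scaled_row_distances(m)
  col_means <- colMeans(m, na.rm = TRUE)
  obs <- !is.na(m)
  for (i in idx) {
    miss_cols <- which(!obs[i, ])
    if (length(miss_cols) == 0) next
    # stable order: increasing distance, ties by row index
    ord <- order(d[i, ], seq_len(nrow(m)))
    for (j in miss_cols) {
      donors <- ord[obs[ord, j] & is.finite(d[i, ord])]
      if (length(donors) == 0) {
        m[i, j] <- col_means[j]
      } else {
        k <- min(cfg$knn_k, length(donors))
        m[i, j] <- mean(m[donors[seq_len(k)], j])
      }
    }
  }
  set_value_matrix(matrix, m)
}

resolve_rows <- function(matrix, rows, m) {
  if (is.null(rows)) {
    which(rowSums(is.na(m)) > 0)
  } else if (is.logical(rows)) {
    which(rows)
  } else if (is.character(rows)) {
    which(matrix$precursor_id %in% rows)
  } else {
    as.integer(rows)
  }
}

#' Minimum-value imputation
#'
#' Sets every missing cell of the selected rows to the minimum observed
#' value of the replicate matrix (computed before any imputation). This
#' is the classic left-censor "min" method for values missing not at
#' random. With `min_scope = "column"` the per-column minimum is used
#' instead.
#'
#' @inheritParams impute_knn
#' @export
impute_min <- function(matrix, rows = NULL, cfg = impute_config()) {
  m <- value_matrix(matrix)
  idx <- resolve_rows(matrix, rows, m)
  if (length(idx) == 0) {
    return(matrix)
  }
  if (cfg$min_scope == "global") {
    fill <- rep(min(m, na.rm = TRUE), ncol(m))
  } else {
    fill <- apply(m, 2, min, na.rm = TRUE)
  }
  for (i in idx) {
    miss <- which(is.na(m[i, ]))
    m[i, miss] <- fill[miss]
  }
  set_value_matrix(matrix, m)
}

#' Deterministic left-censor (MinDet) imputation
#'
#' Every missing cell is set to the `mindet_quantile` quantile of its
#' column's observed values (linear-interpolation quantile, R type 7).
#' Provided as the global left-censor baseline.
#'
#' @inheritParams impute_knn
#' @export
impute_mindet <- function(matrix, cfg = impute_config()) {
  m <- value_matrix(matrix)
  if (any(colSums(!is.na(m)) == 0)) {
    stop("a column has no observed value; run QC column filtering first",
         call. = FALSE)
  }
  fill <- apply(m, 2, stats::quantile, probs = cfg$mindet_quantile,
                na.rm = TRUE, type = 7, names = FALSE)
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    m[miss, j] <- fill[j]
  }
  set_value_matrix(matrix, m)
}

#' Mixed MNAR/MAR imputation of one replicate
#'
#' Classifies each row's mechanism with [classify_missingness()], then
#' min-imputes the MNAR rows (global minimum taken before any imputation)
#' and k-NN-imputes the MAR rows (donor pool = all rows, pre-imputation).
#' Complete rows are untouched; the output has no missing cells. Call
#' once per replicate: replicates are imputed independently.
#'
#' @inheritParams impute_knn
#' @return The imputed matrix; the per-row labels are attached as the
#'   `"missingness"` attribute (see [missingness_labels()]).
#' @export
impute_mixed <- function(matrix, cfg = impute_config()) {
  labels <- classify_missingness(matrix, cfg)
  out <- impute_min(matrix, rows = labels$label == "MNAR", cfg = cfg)
  # donor pool for k-NN is the original (pre-imputation) matrix
  knn_filled <- impute_knn(matrix, rows = labels$label == "MAR", cfg = cfg)
  vc <- value_cols(matrix)
  mar_rows <- which(labels$label == "MAR")
  out[mar_rows, vc] <- knn_filled[mar_rows, vc]
  attr(out, "missingness") <- labels
  attr(out, "qc_report") <- qc_report(matrix)
  out
}

#' @rdname impute_mixed
#' @param x A matrix returned by [impute_mixed()].
#' @export
missingness_labels <- function(x) {
  attr(x, "missingness")
}

#' Impute a replicate matrix under a named strategy
#'
#' Convenience dispatcher over the implemented strategies: `"mixed"`
#' (per-row MNAR/MAR as above), `"knn_global"` (k-NN for every missing
#' cell), `"mindet_global"` (column-quantile left-censoring everywhere),
#' and `"min_global"` (global minimum everywhere).
#'
#' @inheritParams impute_knn
#' @param mode Strategy name.
#' @export
impute_profiles <- function(matrix,
                            mode = c("mixed", "knn_global", "mindet_global",
                                     "min_global"),
                            cfg = impute_config()) {
  mode <- match.arg(mode)
  switch(mode,
    mixed = impute_mixed(matrix, cfg),
    knn_global = impute_knn(matrix, cfg = cfg),
    mindet_global = impute_mindet(matrix, cfg),
    min_global = impute_min(matrix, cfg = cfg)
  )
}
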