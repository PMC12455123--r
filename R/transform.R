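# Normalization, protein-level aggregation, and cross-replicate assembly.

#' Sum-normalize feature profiles
#'
#' Divides each row of the quantitative columns by its row sum, so every
#' profile expresses relative distribution along the gradient and sums to
#' 1 (within 1e-9). Requires complete (post-imputation) data with
#' positive row sums.
#'
#' @param matrix Replicate-matrix or spatial-dataset tibble with no
#'   missing values in its quantitative columns.
#' @return The normalized tibble.
#' @export
normalize_profiles <- function(matrix) {
  m <- value_matrix(matrix)
  if (anyNA(m)) {
    stop("normalize_profiles requires complete data; impute first",
         call. = FALSE)
  }
  s <- rowSums(m)
  if (any(s <= 0)) {
    bad <- rownames(m)[which(s <= 0)[1]]
    stop("feature '", bad, "' has a non-positive row sum", call. = FALSE)
  }
  set_value_matrix(matrix, m / s)
}

#' Aggregate features to the protein level
#'
#' Collapses precursor (or PSM) rows to one row per protein group.
#' `method = "median"` takes per-column medians (the DIA path);
#' `method = "robust"` fits, per protein, the two-way additive model
#' `value = column effect + feature effect` by iteratively reweighted
#' least squares with Huber weights and returns the estimated column
#' effects (the DDA path), falling back to the median with a warning on
#' non-convergence. Proteins with a single feature pass through either
#' way.
#'
#' @param matrix Feature-level tibble with a `protein_group` column and
#'   complete quantitative columns.
#' @param method `"median"` or `"robust"`.
#' @param huber_k Huber tuning constant for the robust fit.
#' @param maxit Maximum IRLS iterations.
#' @return Protein-level tibble: `accession` plus the quantitative
#'   columns, one row per protein group, in first-appearance order.
#' @export
aggregate_proteins <- function(matrix, method = c("median", "robust"),
                               huber_k = 1.345, maxit = 20) {
  method <- match.arg(method)
  vc <- value_cols(matrix)
  m <- value_matrix(matrix, id = "precursor_id")
  groups <- matrix$protein_group
  uniq <- unique(groups)
  res <- matrix(NA_real_, length(uniq), length(vc),
                dimnames = list(uniq, vc))
  for (g in uniq) {
    rows <- m[groups == g, , drop = FALSE]
    if (nrow(rows) == 1) {
      res[g, ] <- rows
    } else if (method == "median") {
      res[g, ] <- apply(rows, 2, stats::median)
    } else {
      res[g, ] <- robust_column_effects(rows, huber_k, maxit)
    }
  }
  out <- tibble::tibble(accession = uniq)
  out[, vc] <- as.data.frame(res)
  out
}

# Huber IRLS fit of value ~ column + feature (sum-to-zero feature
# effects); returns the column effects. MASS::rlm is the fitting engine.
robust_column_effects <- function(rows, huber_k, maxit) {
  nf <- nrow(rows)
  nc <- ncol(rows)
  df <- data.frame(
    y = as.vector(t(rows)),
    col = factor(rep(seq_len(nc), nf)),
    feat = factor(rep(seq_len(nf), each = nc))
  )
  fit <- tryCatch(
    MASS::rlm(y ~ 0 + col + feat, data = df,
              psi = MASS::psi.huber, k = huber_k, maxit = maxit,
              contrasts = list(feat = "contr.sum")),
    error = function(e) NULL
  )
  if (is.null(fit) || !isTRUE(fit$converged)) {
    warning("robust summarization did not converge; falling back to median")
    return(apply(rows, 2, stats::median))
  }
  unname(stats::coef(fit)[seq_len(nc)])
}

#' Restrict a spatial dataset to a subset of fractions
#'
#' Keeps only the chosen fraction indices in every replicate block and
#' (by default) re-sum-normalizes each block, emulating an experiment
#' that collected fewer fractions. Used to study how map resolution
#' degrades with coarser gradients.
#'
#' @param dataset Spatial-dataset tibble.
#' @param fractions Integer fraction indices to keep.
#' @param renormalize Re-sum-normalize each replicate block.
#' @return The reduced dataset.
#' @export
subset_fractions <- function(dataset, fractions, renormalize = TRUE) {
  pc <- profile_cols(dataset)
  f_idx <- as.integer(sub("^R[0-9]+_F", "", pc))
  keep <- pc[f_idx %in% fractions]
  if (length(keep) == 0) stop("no profile column matches", call. = FALSE)
  out <- dataset[, c(setdiff(names(dataset), pc), keep)]
  if (isTRUE(renormalize)) {
    reps <- unique(sub("_F[0-9]+$", "", keep))
    for (r in reps) {
      block <- keep[startsWith(keep, paste0(r, "_"))]
      m <- as.matrix(out[, block])
      out[, block] <- as.data.frame(m / rowSums(m))
    }
  }
  out
}

#' Combine per-replicate protein matrices into a spatial dataset
#'
#' Inner-joins proteins across replicates (only proteins quantified in
#' every replicate are retained), concatenates their profiles
#' replicate-major (`R1_F1 ... R1_F<F>, R2_F1, ...`), optionally
#' re-sum-normalizes each replicate block (medians of normalized rows do
#' not themselves sum to 1), and attaches marker labels where accessions
#' match.
#'
#' @param matrices List of protein-level tibbles (from
#'   [aggregate_proteins()]), in replicate order.
#' @param markers Optional marker tibble (`accession`, `marker`).
#' @param renormalize Re-sum-normalize each replicate block (default
#'   `TRUE`).
#' @return Spatial-dataset tibble: `accession`, `marker` (`NA` where
#'   unannotated), profile columns.
#' @export
combine_replicates <- function(matrices, markers = NULL, renormalize = TRUE) {
  stopifnot(is.list(matrices), length(matrices) >= 1)
  renamed <- purrr::imap(matrices, function(mat, r) {
    vc <- value_cols(mat)
    if (isTRUE(renormalize)) mat <- normalize_profiles(mat)
    names(mat)[match(vc, names(mat))] <- sprintf(
      "R%d_%s", if (is.character(r)) match(r, names(matrices)) else r, vc
    )
    mat[, c("accession", grep("^R[0-9]+_F", names(mat), value = TRUE))]
  })
  out <- purrr::reduce(renamed, dplyr::inner_join, by = "accession")
  if (nrow(out) == 0) {
    warning("no protein is present in all replicates; empty dataset")
  }
  marker <- if (!is.null(markers)) {
    markers$marker[match(out$accession, markers$accession)]
  } else {
    rep(NA_character_, nrow(out))
  }
  out <- dplyr::bind_cols(
    out[, "accession", drop = FALSE],
    tibble::tibble(marker = marker),
    out[, setdiff(names(out), "accession"), drop = FALSE]
  )
  out
}
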