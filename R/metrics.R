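# Map-resolution metrics and ordination.

#' QSep cluster-resolution metric
#'
#' Compares the average Euclidean distance of the full n-dimensional
#' protein profiles within and between subcellular marker clusters.
#' `raw[i, j]` is the mean distance over all cross-pairs between clusters
#' `i` and `j` (distinct pairs when `i = j`); each row of the normalized
#' matrix is divided by its within-cluster diagonal, so `normalized[i, j]`
#' expresses how far cluster `j` sits from cluster `i` in units of `i`'s
#' own spread. The normalized matrix is therefore asymmetric and has a
#' unit diagonal; values well above 1 indicate good separation.
#'
#' @param dataset Spatial-dataset tibble with a `marker` column; at least
#'   two marker classes with at least two members each (a singleton
#'   cluster has no within-distance and is an error).
#' @return A `qsep` object: list with `raw` and `normalized` K x K
#'   matrices and `summary` (per-class median of the off-diagonal
#'   normalized row plus a `"global"` row). [tidy()] returns the
#'   normalized matrix in long form; [glance()] the global median.
#' @export
qsep <- function(dataset) {
  mk <- marker_frame(dataset)
  cls <- sort(unique(mk$marker))
  if (length(cls) < 2) {
    stop("qsep needs at least 2 marker classes", call. = FALSE)
  }
  sizes <- table(mk$marker)
  singletons <- names(sizes)[sizes < 2]
  if (length(singletons) > 0) {
    stop("singleton marker cluster(s): ",
         paste(singletons, collapse = ", "), call. = FALSE)
  }
  x <- value_matrix(mk, id = "accession")
  d <- as.matrix(stats::dist(x))
  k <- length(cls)
  raw <- matrix(0, k, k, dimnames = list(cls, cls))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      ri <- which(mk$marker == cls[i])
      rj <- which(mk$marker == cls[j])
      block <- d[ri, rj, drop = FALSE]
      raw[i, j] <- if (i == j) {
        sum(block) / (length(ri) * (length(ri) - 1)) # distinct pairs
      } else {
        mean(block)
      }
    }
  }
  normalized <- raw / diag(raw)
  off <- normalized
  diag(off) <- NA
  summary <- tibble::tibble(
    class = c(cls, "global"),
    median_qsep = c(
      apply(off, 1, stats::median, na.rm = TRUE),
      stats::median(off, na.rm = TRUE)
    )
  )
  structure(list(raw = raw, normalized = normalized, summary = summary),
            class = "qsep")
}

#' @export
tidy.qsep <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$normalized,
                                        responseName = "normalized",
                                        stringsAsFactors = FALSE)) |>
    stats::setNames(c("reference", "cluster", "normalized"))
}

#' @export
glance.qsep <- function(x, ...) {
  tibble::tibble(
    classes = nrow(x$raw),
    global_median_qsep = x$summary$median_qsep[x$summary$class == "global"]
  )
}

#' Per-class median marker profiles with standard errors
#'
#' For each marker class and each profile column: the median of the
#' member values and the standard error `sd/sqrt(n)` (0 for single-member
#' columns, by convention).
#'
#' @param dataset Spatial-dataset tibble with a `marker` column.
#' @return Long tibble: `marker`, `column`, `replicate`, `fraction`,
#'   `median`, `se`, `n`.
#' @export
marker_profile_summary <- function(dataset) {
  mk <- marker_frame(dataset)
  pc <- value_cols(mk)
  long <- mk |>
    tidyr::pivot_longer(dplyr::all_of(pc), names_to = "column",
                        values_to = "value")
  out <- long |>
    dplyr::summarise(
      median = stats::median(.data$value),
      se = if (dplyr::n() > 1) {
        stats::sd(.data$value) / sqrt(dplyr::n())
      } else {
        0
      },
      n = dplyr::n(),
      .by = c("marker", "column")
    )
  rf <- stringr::str_match(out$column, "^R([0-9]+)_F([0-9]+)$")
  out$replicate <- as.integer(rf[, 2])
  out$fraction <- if (all(is.na(rf[, 1]))) {
    as.integer(sub("^F", "", out$column))
  } else {
    as.integer(rf[, 3])
  }
  out[, c("marker", "column", "replicate", "fraction", "median", "se", "n")]
}

#' PCA map coordinates with display-outlier trimming
#'
#' Column-mean-centred principal component analysis of the profiles. The
#' proteins in the extreme `trim_frac` tails of PC1 and of PC2 are
#' flagged as display outliers (flagged only -- nothing is removed from
#' the dataset, and trimming never feeds back into classification).
#' Component signs follow a fixed convention (the largest-magnitude
#' loading of each component is positive) so repeated runs agree.
#'
#' @param dataset Spatial-dataset tibble.
#' @param trim_frac Tail fraction flagged per component (default 1e-4,
#'   i.e. the top and bottom 0.01\% of points by PC1 and PC2 rank).
#' @param n_components Number of components returned.
#' @param scale Scale columns to unit variance before PCA (default
#'   `FALSE`: centring only).
#' @return A `pca_map` tibble: `accession`, `marker` (when present),
#'   `PC1..PCn`, `outlier`; explained-variance ratios in the
#'   `"var_explained"` attribute and the full `prcomp` fit in `"fit"`.
#' @export
pca_map <- function(dataset, trim_frac = 1e-4, n_components = 2,
                    scale = FALSE) {
  stopifnot(trim_frac >= 0, trim_frac < 0.5)
  x <- value_matrix(dataset, id = "accession")
  n_components <- min(n_components, ncol(x), nrow(x) - 1)
  fit <- stats::prcomp(x, center = TRUE, scale. = scale)
  # deterministic sign: largest-|loading| entry of each rotation column > 0
  for (j in seq_len(ncol(fit$rotation))) {
    piv <- which.max(abs(fit$rotation[, j]))
    if (fit$rotation[piv, j] < 0) {
      fit$rotation[, j] <- -fit$rotation[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  coords <- fit$x[, seq_len(n_components), drop = FALSE]
  n <- nrow(coords)
  n_trim <- floor(trim_frac * n)
  outlier <- rep(FALSE, n)
  if (n_trim > 0) {
    for (j in seq_len(min(2, ncol(coords)))) {
      rk <- rank(coords[, j], ties.method = "first")
      outlier <- outlier | rk <= n_trim | rk > n - n_trim
    }
  }
  out <- tibble::tibble(accession = dataset$accession)
  if ("marker" %in% names(dataset)) out$marker <- dataset$marker
  out <- dplyr::bind_cols(out, tibble::as_tibble(as.data.frame(coords)))
  out$outlier <- outlier
  var_expl <- fit$sdev^2 / sum(fit$sdev^2)
  class(out) <- c("pca_map", class(out))
  attr(out, "var_explained") <- var_expl
  attr(out, "fit") <- fit
  out
}

#' t-SNE pass-through embedding
#'
#' Optional non-linear 2-D embedding of the profiles for visual
#' inspection, with no role in classification or resolution metrics.
#' Delegates to the Rtsne package when it is installed; otherwise falls
#' back to the first two principal components (with a message), so the
#' function always returns coordinates.
#'
#' @param dataset Spatial-dataset tibble.
#' @param perplexity,seed Embedding parameters.
#' @return Tibble `accession`, `Dim1`, `Dim2`.
#' @export
tsne_map <- function(dataset, perplexity = 30, seed = 1) {
  if (requireNamespace("Rtsne", quietly = TRUE)) {
    x <- value_matrix(dataset, id = "accession")
    set.seed(seed)
    emb <- Rtsne::Rtsne(x, perplexity = perplexity, check_duplicates = FALSE)
    tibble::tibble(accession = dataset$accession,
                   Dim1 = emb$Y[, 1], Dim2 = emb$Y[, 2])
  } else {
    message("Rtsne not installed; returning the first two principal components")
    pc <- pca_map(dataset, trim_frac = 0, n_components = 2)
    tibble::tibble(accession = pc$accession,
                   Dim1 = pc$PC1, Dim2 = pc$PC2)
  }
}
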