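# Internal helpers shared across the pipeline.

#' The 13 subcellular marker classes
#'
#' Fixed vocabulary of subcellular compartments used for marker annotation
#' and classification: cytosol, mitochondrion, nucleus, chromatin, plasma
#' membrane, endoplasmic reticulum, Golgi apparatus, endosome, lysosome,
#' peroxisome, proteasome, and the 40S and 60S ribosomal subunits.
#'
#' @return Character vector of length 13.
#' @export
marker_classes <- function() {
  c(
    "cytosol", "mitochondrion", "nucleus", "chromatin", "plasma membrane",
    "endoplasmic reticulum", "Golgi apparatus", "endosome", "lysosome",
    "peroxisome", "proteasome", "ribosome 40S", "ribosome 60S"
  )
}

#' Fraction columns of a replicate matrix
#'
#' Replicate matrices carry one column per fraction, named `F1`, `F2`, ...
#' in fraction order; spatial datasets carry replicate-major profile
#' columns named `R1_F1`, `R1_F2`, ..., `R2_F1`, ... These helpers locate
#' them by name.
#'
#' @param x A replicate-matrix or spatial-dataset tibble.
#' @return Character vector of matching column names, in table order.
#' @export
fraction_cols <- function(x) {
  grep("^F[0-9]+$", names(x), value = TRUE)
}

#' @rdname fraction_cols
#' @export
profile_cols <- function(x) {
  grep("^R[0-9]+_F[0-9]+$", names(x), value = TRUE)
}

# Either fraction (per-replicate) or profile (combined) columns.
value_cols <- function(x) {
  fc <- fraction_cols(x)
  if (length(fc) > 0) fc else profile_cols(x)
}

# Numeric matrix of the quantitative columns, rows named by the id column.
value_matrix <- function(x, id = NULL) {
  vc <- value_cols(x)
  if (length(vc) == 0) {
    stop("no fraction (F*) or profile (R*_F*) columns found", call. = FALSE)
  }
  if (is.null(id)) {
    id <- intersect(c("precursor_id", "accession", "psm_id"), names(x))[1]
  }
  m <- as.matrix(x[, vc, drop = FALSE])
  storage.mode(m) <- "double"
  if (!is.null(id) && !is.na(id)) rownames(m) <- x[[id]]
  m
}

# Replace the quantitative columns of `x` with the rows of matrix `m`
# (same dimensions and order).
set_value_matrix <- function(x, m) {
  vc <- value_cols(x)
  stopifnot(length(vc) == ncol(m), nrow(x) == nrow(m))
  x[, vc] <- as.data.frame(m)
  x
}

# One accounting row used by the QC and imputation stages.
stage_report <- function(stage, n_in, n_removed, detail = NA_character_) {
  tibble::tibble(
    stage = stage, n_in = as.integer(n_in),
    n_removed = as.integer(n_removed),
    n_out = as.integer(n_in - n_removed),
    detail = detail
  )
}

#' Per-stage QC accounting attached to a filtered table
#'
#' Each QC filter records how many rows (or cells/columns) it saw and
#' removed; the reports accumulate as the table moves through the filter
#' chain and are conserved stage-wise (`n_in = n_out + n_removed`).
#'
#' @param x A table returned by one of the QC filters.
#' @return A tibble with columns `stage`, `n_in`, `n_removed`, `n_out`,
#'   `detail`, one row per stage applied so far (or `NULL` if none).
#' @export
qc_report <- function(x) {
  attr(x, "qc_report")
}

# Deterministic seed derivation for per-replicate sub-streams; kept below
# 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 7919) %% 2147483587)
}
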