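# Quality-control filtration.
#
# DIA branch (replicate matrices): contaminant/ambiguous removal, optional
# intensity high-pass, then column (fraction) missingness filtering, then
# row (precursor) minimum-value filtering -- in that order, because rows
# are counted "across the remaining fractions". DDA branch (PSM tables):
# reporter signal-to-noise, co-isolation and SPS-match thresholds.
# Every filter appends an accounting row retrievable with [qc_report()].

#' Quality-control configuration
#'
#' @param max_column_missing_frac Drop a fraction column when its missing
#'   proportion is strictly greater than this (default 0.70, the "over
#'   70\%" rule; a column at exactly the boundary survives).
#' @param min_row_values Drop a precursor row with strictly fewer observed
#'   values than this across the remaining fractions (default 2; a row
#'   with exactly 2 survives).
#' @param min_intensity High-pass threshold: cells strictly below it
#'   become missing. Default 0 = off; no published value exists for this
#'   filter, so it must be set deliberately.
#' @param contaminant_accessions Character vector of exact contaminant
#'   accessions.
#' @param contaminant_prefix Accession prefix marking contaminant entries
#'   (e.g. from a universal contaminants FASTA); `NULL` disables.
#' @param dda_min_sn Keep PSMs with average reporter signal-to-noise at or
#'   above this (default 10; a PSM at 9.9 is removed).
#' @param dda_max_coisolation_pct Remove PSMs whose co-isolation
#'   interference is at or above this percentage (default 75).
#' @param dda_min_sps_pct Keep PSMs with synchronous-precursor-selection
#'   match percentage at or above this. The default 65 is a common
#'   community setting, not a published value; review it for your data.
#' @return A `qc_config` list.
#' @export
qc_config <- function(max_column_missing_frac = 0.70, min_row_values = 2,
                      min_intensity = 0, contaminant_accessions = character(),
                      contaminant_prefix = "Cont_", dda_min_sn = 10,
                      dda_max_coisolation_pct = 75, dda_min_sps_pct = 65) {
  stopifnot(
    is.finite(max_column_missing_frac),
    max_column_missing_frac >= 0, max_column_missing_frac <= 1,
    min_row_values >= 1, is.finite(min_intensity), min_intensity >= 0,
    is.finite(dda_min_sn), is.finite(dda_max_coisolation_pct),
    is.finite(dda_min_sps_pct)
  )
  structure(
    list(
      max_column_missing_frac = max_column_missing_frac,
      min_row_values = as.integer(min_row_values),
      min_intensity = min_intensity,
      contaminant_accessions = contaminant_accessions,
      contaminant_prefix = contaminant_prefix,
      dda_min_sn = dda_min_sn,
      dda_max_coisolation_pct = dda_max_coisolation_pct,
      dda_min_sps_pct = dda_min_sps_pct
    ),
    class = "qc_config"
  )
}

is_contaminant_group <- function(group, cfg) {
  hit <- group %in% cfg$contaminant_accessions
  if (!is.null(cfg$contaminant_prefix) && nzchar(cfg$contaminant_prefix)) {
    hit <- hit | startsWith(group, cfg$contaminant_prefix)
  }
  hit
}

#' Remove contaminant and ambiguous protein groups
#'
#' Drops rows whose protein group matches the contaminant list or prefix,
#' and rows whose group contains more than one accession (";"-separated),
#' which cannot be assigned to a single protein.
#'
#' @param matrix Replicate-matrix tibble (see [pivot_replicate()]).
#' @param cfg A [qc_config()].
#' @return Filtered tibble; accounting via [qc_report()].
#' @export
remove_contaminants_and_ambiguous <- function(matrix, cfg = qc_config()) {
  ambiguous <- grepl(";", matrix$protein_group, fixed = TRUE)
  contaminant <- is_contaminant_group(matrix$protein_group, cfg)
  drop <- ambiguous | contaminant
  out <- matrix[!drop, , drop = FALSE]
  if (nrow(out) == 0) warning("all rows removed as contaminant/ambiguous")
  attr(out, "qc_report") <- dplyr::bind_rows(qc_report(matrix), stage_report(
    "contaminants_ambiguous", nrow(matrix), sum(drop),
    sprintf("%d ambiguous, %d contaminant", sum(ambiguous), sum(contaminant))
  ))
  out
}

#' Blank cells below a minimum intensity
#'
#' Cells with intensity strictly below `min_intensity` become missing;
#' rows left with no observed cell are removed. A threshold of 0 (the
#' default) is the identity.
#'
#' @inheritParams remove_contaminants_and_ambiguous
#' @export
filter_intensity_highpass <- function(matrix, cfg = qc_config()) {
  m <- value_matrix(matrix)
  blank <- !is.na(m) & m < cfg$min_intensity
  m[blank] <- NA_real_
  out <- set_value_matrix(matrix, m)
  keep <- rowSums(!is.na(m)) > 0
  out <- out[keep, , drop = FALSE]
  attr(out, "qc_report") <- dplyr::bind_rows(qc_report(matrix), stage_report(
    "intensity_highpass", nrow(matrix), sum(!keep),
    sprintf("%d cell(s) blanked below %g", sum(blank), cfg$min_intensity)
  ))
  out
}

#' Drop fractions with excessive missingness
#'
#' A fraction column is removed when its proportion of missing cells is
#' strictly greater than `max_column_missing_frac`; the dropped fraction
#' indices are recorded in the report.
#'
#' @inheritParams remove_contaminants_and_ambiguous
#' @export
filter_columns_by_missingness <- function(matrix, cfg = qc_config()) {
  vc <- value_cols(matrix)
  m <- value_matrix(matrix)
  miss_frac <- colMeans(is.na(m))
  drop <- miss_frac > cfg$max_column_missing_frac
  out <- matrix[, c(setdiff(names(matrix), vc[drop])), drop = FALSE]
  attr(out, "qc_report") <- dplyr::bind_rows(qc_report(matrix), stage_report(
    "column_missingness", length(vc), sum(drop),
    if (any(drop)) {
      paste("dropped fractions:", paste(vc[drop], collapse = ", "))
    } else {
      "no fraction dropped"
    }
  ))
  attr(out, "dropped_fractions") <- vc[drop]
  out
}

#' Drop rows with too few observed values
#'
#' Removes precursor rows with strictly fewer than `min_row_values`
#' observed cells across the remaining fractions. Run this after
#' [filter_columns_by_missingness()], since the count refers to the
#' columns that survive.
#'
#' @inheritParams remove_contaminants_and_ambiguous
#' @export
filter_rows_min_values <- function(matrix, cfg = qc_config()) {
  m <- value_matrix(matrix)
  keep <- rowSums(!is.na(m)) >= cfg$min_row_values
  out <- matrix[keep, , drop = FALSE]
  attr(out, "qc_report") <- dplyr::bind_rows(qc_report(matrix), stage_report(
    "row_min_values", nrow(matrix), sum(!keep),
    sprintf("rows with < %d observed value(s)", cfg$min_row_values)
  ))
  out
}

#' Apply the full DIA QC chain to a replicate matrix
#'
#' Contaminant/ambiguous removal, intensity high-pass, column-missingness
#' filter, then row minimum-value filter, in that order.
#'
#' @inheritParams remove_contaminants_and_ambiguous
#' @export
qc_replicate <- function(matrix, cfg = qc_config()) {
  matrix |>
    remove_contaminants_and_ambiguous(cfg) |>
    filter_intensity_highpass(cfg) |>
    filter_columns_by_missingness(cfg) |>
    filter_rows_min_values(cfg)
}

#' Filter PSMs on reporter quality metrics
#'
#' Keeps PSMs with `avg_sn >= dda_min_sn`, co-isolation interference
#' strictly below `dda_max_coisolation_pct`, and SPS match percentage at
#' least `dda_min_sps_pct`.
#'
#' @param psms PSM tibble from [read_psm_table()].
#' @param cfg A [qc_config()].
#' @return Filtered PSM tibble; accounting via [qc_report()].
#' @export
filter_psms <- function(psms, cfg = qc_config()) {
  keep <- psms$avg_sn >= cfg$dda_min_sn &
    psms$coisolation_pct < cfg$dda_max_coisolation_pct &
    psms$sps_match_pct >= cfg$dda_min_sps_pct
  out <- psms[keep, , drop = FALSE]
  attr(out, "qc_report") <- dplyr::bind_rows(qc_report(psms), stage_report(
    "psm_quality", nrow(psms), sum(!keep),
    sprintf("S/N >= %g, co-isolation < %g%%, SPS >= %g%%",
            cfg$dda_min_sn, cfg$dda_max_coisolation_pct, cfg$dda_min_sps_pct)
  ))
  out
}
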