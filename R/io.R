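# Reading and writing the tabular formats the pipeline touches:
# DIA-NN-style precursor reports, PSM-level TMT exports, marker and
# contaminant lists, run designs, and the processed spatial map.

#' Build a run design
#'
#' Maps each MS run to its (replicate, fraction) position on the gradient.
#' The mapping is explicit and user-supplied (or generated here), never
#' inferred from file names.
#'
#' @param replicates Number of replicates `R`.
#' @param fractions Number of fractions per replicate `F`.
#' @param run_ids Optional character vector of run ids in replicate-major
#'   order (`R * F` entries); default `"R<r>_F<f>"`.
#' @return Tibble with columns `run_id`, `replicate`, `fraction`; one row
#'   per run, injective on (replicate, fraction).
#' @export
run_design <- function(replicates, fractions, run_ids = NULL) {
  stopifnot(replicates >= 1, fractions >= 1)
  d <- tidyr::expand_grid(
    replicate = seq_len(replicates),
    fraction = seq_len(fractions)
  )
  if (is.null(run_ids)) {
    run_ids <- sprintf("R%d_F%02d", d$replicate, d$fraction)
  }
  stopifnot(length(run_ids) == nrow(d), !anyDuplicated(run_ids))
  tibble::tibble(run_id = run_ids, replicate = d$replicate,
                 fraction = d$fraction)
}

#' @rdname run_design
#' @param path TSV file with columns `run_id`, `replicate`, `fraction`.
#' @export
read_run_design <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("run_id", "replicate", "fraction")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    stop("run design is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(d[, c("replicate", "fraction")])) {
    stop("run design maps two runs to the same (replicate, fraction)",
         call. = FALSE)
  }
  tibble::tibble(run_id = as.character(d$run_id),
                 replicate = as.integer(d$replicate),
                 fraction = as.integer(d$fraction))
}

#' Column dialect of a precursor report
#'
#' Report dialects drift between DIA-NN versions; the defaults follow the
#' common `Run` / `Protein.Group` / `Precursor.Id` naming with intensity
#' taken from `Precursor.Normalised`, falling back to `Precursor.Quantity`
#' when absent. All names are overridable.
#'
#' @param run,protein_group,precursor Column names for the run, protein
#'   group and precursor identifiers.
#' @param intensity Candidate intensity columns, tried in order.
#' @param keep_zero Keep zero intensities as values instead of coercing
#'   them to missing (an MS zero usually means non-detection).
#' @return A `diann_dialect` list.
#' @export
diann_dialect <- function(run = "Run", protein_group = "Protein.Group",
                          precursor = "Precursor.Id",
                          intensity = c("Precursor.Normalised",
                                        "Precursor.Quantity"),
                          keep_zero = FALSE) {
  structure(list(run = run, protein_group = protein_group,
                 precursor = precursor, intensity = intensity,
                 keep_zero = keep_zero),
            class = "diann_dialect")
}

#' Read a long-format precursor quantification report
#'
#' Parses a tab-separated DIA-NN-style report into the long precursor
#' table the pipeline consumes. Zero and empty intensities become missing
#' (unless the dialect keeps zeros); every run must appear in the design.
#'
#' @param path TSV report file.
#' @param design Run design tibble (see [run_design()]).
#' @param dialect A [diann_dialect()] naming the columns to use.
#' @return Tibble with columns `run_id`, `protein_group`, `precursor_id`,
#'   `intensity` (`NA` = missing).
#' @export
read_precursor_report <- function(path, design, dialect = diann_dialect()) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  need <- c(dialect$run, dialect$protein_group, dialect$precursor)
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("precursor report is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  int_col <- intersect(dialect$intensity, names(raw))[1]
  if (is.na(int_col)) {
    stop("precursor report has none of the intensity column(s): ",
         paste(dialect$intensity, collapse = ", "), call. = FALSE)
  }
  int_chr <- raw[[int_col]]
  intensity <- suppressWarnings(as.numeric(int_chr))
  bad <- which(!is.na(int_chr) & int_chr != "" & is.na(intensity))
  if (length(bad) > 0) {
    stop(sprintf(
      "non-numeric intensity '%s' in column '%s' at data line %d",
      int_chr[bad[1]], int_col, bad[1]
    ), call. = FALSE)
  }
  if (!isTRUE(dialect$keep_zero)) {
    intensity[!is.na(intensity) & intensity == 0] <- NA_real_
  }
  tab <- tibble::tibble(
    run_id = raw[[dialect$run]],
    protein_group = raw[[dialect$protein_group]],
    precursor_id = raw[[dialect$precursor]],
    intensity = intensity
  )
  unknown <- setdiff(unique(tab$run_id), design$run_id)
  if (length(unknown) > 0) {
    stop("report contains run(s) absent from the design: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  tab
}

#' Pivot one replicate of a precursor table to a features-by-fractions matrix
#'
#' @param table Long precursor tibble (`run_id`, `protein_group`,
#'   `precursor_id`, `intensity`).
#' @param design Run design tibble.
#' @param replicate Replicate index to extract.
#' @return Replicate-matrix tibble: `precursor_id`, `protein_group`, then
#'   one `F<f>` column per fraction of the design (missing = `NA`). Rows
#'   are precursors observed in at least one fraction of the replicate.
#' @export
pivot_replicate <- function(table, design, replicate) {
  des <- dplyr::filter(design, .data$replicate == !!replicate)
  if (nrow(des) == 0) {
    stop("replicate ", replicate, " not present in the design", call. = FALSE)
  }
  unknown <- setdiff(unique(table$run_id), design$run_id)
  if (length(unknown) > 0) {
    stop("table contains run(s) absent from the design: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  sub <- dplyr::inner_join(table, des, by = "run_id")
  dup <- sub |>
    dplyr::count(.data$precursor_id, .data$fraction) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop(sprintf(
      "ambiguous quantification: precursor '%s' has %d records in fraction %d",
      dup$precursor_id[1], dup$n[1], dup$fraction[1]
    ), call. = FALSE)
  }
  fractions <- sort(unique(des$fraction))
  wide <- sub |>
    dplyr::mutate(fraction = factor(.data$fraction, levels = fractions)) |>
    tidyr::pivot_wider(
      id_cols = c("precursor_id", "protein_group"),
      names_from = "fraction", values_from = "intensity",
      names_prefix = "F", names_expand = TRUE
    )
  vc <- paste0("F", fractions)
  keep <- rowSums(!is.na(wide[, vc, drop = FALSE])) > 0
  wide[keep, c("precursor_id", "protein_group", vc)]
}

#' Read a marker annotation table
#'
#' @param path TSV with columns `accession`, `marker`.
#' @param classes Allowed class vocabulary; labels outside it are an error.
#' @return Tibble `accession`, `marker`; one class per accession.
#' @export
read_markers <- function(path, classes = marker_classes()) {
  m <- readr::read_tsv(path, show_col_types = FALSE)
  miss <- setdiff(c("accession", "marker"), names(m))
  if (length(miss) > 0) {
    stop("marker table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(m$accession)) {
    stop("marker table maps an accession to more than one class",
         call. = FALSE)
  }
  bad <- setdiff(unique(m$marker), classes)
  if (length(bad) > 0) {
    stop("unknown marker class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(accession = as.character(m$accession),
                 marker = as.character(m$marker))
}

#' Read a PSM-level TMT export
#'
#' Expects a tab-separated export with one row per PSM: an id, a protein
#' group, one reporter intensity column per TMT channel, and the QC
#' columns (average reporter signal-to-noise, co-isolation interference,
#' synchronous-precursor-selection match percentage).
#'
#' @param path TSV file.
#' @param plex Declared plex size; the number of reporter columns must
#'   match exactly.
#' @param dialect Named list of column patterns: `psm_id`, `protein_group`,
#'   `reporter_prefix` (columns `<prefix><channel>`), `avg_sn`,
#'   `coisolation_pct`, `sps_match_pct`.
#' @return Tibble `psm_id`, `protein_group`, `avg_sn`, `coisolation_pct`,
#'   `sps_match_pct`, then reporter columns renamed `F1..F<plex>` in
#'   channel order (TMT channel order = fraction order on the gradient),
#'   so PSM tables flow through the same normalization, imputation and
#'   aggregation machinery as replicate matrices.
#' @export
read_psm_table <- function(path, plex,
                           dialect = list(
                             psm_id = "PSM.Id",
                             protein_group = "Protein.Group",
                             reporter_prefix = "Reporter.",
                             avg_sn = "Avg.SN",
                             coisolation_pct = "Coisolation.Pct",
                             sps_match_pct = "SPS.Match.Pct"
                           )) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  need <- unlist(dialect[c("psm_id", "protein_group", "avg_sn",
                           "coisolation_pct", "sps_match_pct")])
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("PSM table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  rep_cols <- grep(paste0("^", gsub("\\.", "\\\\.", dialect$reporter_prefix),
                          "[0-9]+$"),
                   names(raw), value = TRUE)
  ord <- order(as.integer(sub(".*?([0-9]+)$", "\\1", rep_cols)))
  rep_cols <- rep_cols[ord]
  if (length(rep_cols) != plex) {
    stop(sprintf(
      "PSM table has %d reporter channel(s) but plex = %d",
      length(rep_cols), plex
    ), call. = FALSE)
  }
  out <- tibble::tibble(
    psm_id = as.character(raw[[dialect$psm_id]]),
    protein_group = as.character(raw[[dialect$protein_group]]),
    avg_sn = as.numeric(raw[[dialect$avg_sn]]),
    coisolation_pct = as.numeric(raw[[dialect$coisolation_pct]]),
    sps_match_pct = as.numeric(raw[[dialect$sps_match_pct]])
  )
  rep_mat <- as.data.frame(raw[, rep_cols, drop = FALSE])
  names(rep_mat) <- paste0("F", seq_len(plex))
  dplyr::bind_cols(out, tibble::as_tibble(rep_mat))
}

#' Write (and read back) a classified spatial map
#'
#' One row per protein: accession, the full concatenated profile, the
#' curated marker label (blank when absent), the predicted class, the
#' winning score, per-class score columns (`score.<class>`), and the final
#' assignment. Profile values are formatted with 17 significant digits so
#' re-reading reproduces them bit-exactly.
#'
#' @param dataset Spatial-dataset tibble (`accession`, profile columns,
#'   optional `marker`).
#' @param result Optional `organelle_assignment` from
#'   [assign_with_thresholds()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_spatial_map <- function(dataset, result = NULL, path) {
  pc <- profile_cols(dataset)
  out <- dataset[, c("accession", pc), drop = FALSE]
  for (col in pc) out[[col]] <- sprintf("%.17g", out[[col]])
  out$marker <- if ("marker" %in% names(dataset)) {
    ifelse(is.na(dataset$marker), "", dataset$marker)
  } else {
    ""
  }
  if (!is.null(result)) {
    res <- tibble::as_tibble(result)
    scores <- attr(result, "scores")
    res <- dplyr::left_join(
      res[, c("accession", "predicted", "score", "assignment")],
      scores, by = "accession"
    )
    cls <- setdiff(names(scores), "accession")
    names(res)[match(cls, names(res))] <- paste0("score.", cls)
    out <- dplyr::left_join(out, res, by = "accession")
  }
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' @rdname write_spatial_map
#' @return `read_spatial_map()`: the spatial-dataset tibble (`accession`,
#'   `marker`, profile columns); classification columns, when present, are
#'   kept after the profile.
#' @export
read_spatial_map <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  pc <- profile_cols(raw)
  out <- tibble::tibble(accession = raw$accession)
  out$marker <- if ("marker" %in% names(raw)) raw$marker else NA_character_
  out$marker[!is.na(out$marker) & out$marker == ""] <- NA_character_
  for (col in pc) out[[col]] <- as.numeric(raw[[col]])
  extra <- setdiff(names(raw), c("accession", "marker", pc))
  for (col in extra) out[[col]] <- raw[[col]]
  out[, c("accession", "marker", pc, extra)]
}
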