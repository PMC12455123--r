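# Synthetic fractionation-experiment generator.
#
# Emulates the correlation-profiling premise: proteins of one compartment
# co-distribute across biochemical fractions, so each class gets a smooth
# enrichment profile along the gradient and every precursor of a protein
# samples that profile multiplicatively. Missingness is generated
# mechanistically -- left-censoring at a detection limit (MNAR) plus
# uniform random dropout (MAR) -- so imputation strategies can be judged
# against the true mechanism of every missing cell.

#' Configuration for a synthetic fractionation experiment
#'
#' The generative model for protein `i` of class `k`, precursor `j`,
#' fraction `f` is
#' `intensity = A_i * e_ij * w_k[f] * eps`, where `A_i` is a lognormal
#' protein abundance, `e_ij` a lognormal precursor response, `w_k` the
#' class enrichment profile (a Gaussian bump over fraction index,
#' normalized to sum 1) and `eps` multiplicative lognormal noise. A cell
#' is censored (missing not at random) with probability
#' `plogis((log(lod) - log(intensity)) * lod_slope)`, and surviving cells
#' drop out at random with probability `mar_rate`.
#'
#' @param n_classes Number of subcellular classes (<= 13 uses the standard
#'   vocabulary of [marker_classes()]).
#' @param fractions Fractions per replicate (columns of the gradient).
#' @param replicates Number of biological replicates.
#' @param proteins_per_class Proteins simulated per class.
#' @param precursor_lambda Precursors per protein are `1 + Poisson(lambda)`.
#' @param profile_centers Optional numeric vector of bump centres on the
#'   fraction axis, one per class; default evenly spaced over `1..fractions`.
#' @param profile_sigma Bump width (fractions).
#' @param profile_baseline Additive baseline before normalization.
#' @param center_jitter Standard deviation (fractions) of the per-protein
#'   offset added to the class bump centre: proteins of one compartment
#'   do not co-sediment perfectly, so each protein's profile peaks near,
#'   not exactly at, its class centre. Drawn once per protein and shared
#'   across replicates (a biological property, not measurement noise).
#' @param abundance_meanlog,abundance_sdlog Lognormal protein abundance.
#' @param response_sdlog Lognormal spread of per-precursor response.
#' @param noise_sdlog Multiplicative measurement noise (log scale sd).
#' @param lod Detection limit on the intensity scale; `0` disables
#'   censoring entirely.
#' @param lod_slope Steepness of the logistic censoring curve (per log
#'   intensity unit).
#' @param mar_rate Random dropout probability for cells that survive
#'   censoring, in `[0, 1]`.
#' @param marker_frac Fraction of each class's proteins annotated as
#'   curated markers (training labels); the rest are held-out "unknowns"
#'   whose true class is recorded in the truth tables.
#' @param seed Integer seed; the whole simulation is a deterministic
#'   function of the configuration.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_classes = 13, fractions = 10, replicates = 3,
                       proteins_per_class = 40, precursor_lambda = 4,
                       profile_centers = NULL, profile_sigma = 0.6,
                       profile_baseline = 0.02, center_jitter = 0.15,
                       abundance_meanlog = log(1e6), abundance_sdlog = 1,
                       response_sdlog = 0.5, noise_sdlog = 0.2,
                       lod = exp(8.6), lod_slope = 1.5, mar_rate = 0.05,
                       marker_frac = 0.4, seed = 1) {
  stopifnot(
    n_classes >= 2, fractions >= 2, replicates >= 1,
    proteins_per_class >= 1, mar_rate >= 0, mar_rate <= 1,
    marker_frac >= 0, marker_frac <= 1, lod >= 0
  )
  if (is.null(profile_centers)) {
    profile_centers <- seq(1, fractions, length.out = n_classes)
  }
  stopifnot(length(profile_centers) == n_classes)
  structure(
    list(
      n_classes = n_classes, fractions = fractions, replicates = replicates,
      proteins_per_class = proteins_per_class,
      precursor_lambda = precursor_lambda,
      profile_centers = profile_centers, profile_sigma = profile_sigma,
      profile_baseline = profile_baseline, center_jitter = center_jitter,
      abundance_meanlog = abundance_meanlog,
      abundance_sdlog = abundance_sdlog,
      response_sdlog = response_sdlog, noise_sdlog = noise_sdlog,
      lod = lod, lod_slope = lod_slope, mar_rate = mar_rate,
      marker_frac = marker_frac, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Enrichment profiles: Gaussian bump + baseline, normalized to sum 1.
# One column per centre.
bump_profiles <- function(cfg, centers) {
  f <- seq_len(cfg$fractions)
  vapply(centers, function(mu) {
    v <- cfg$profile_baseline + exp(-(f - mu)^2 / (2 * cfg$profile_sigma^2))
    v / sum(v)
  }, numeric(cfg$fractions))
}

# Nominal class profiles (at the exact class centres).
class_profiles <- function(cfg) {
  w <- bump_profiles(cfg, cfg$profile_centers)
  colnames(w) <- class_names(cfg)
  w
}

class_names <- function(cfg) {
  if (cfg$n_classes <= 13) {
    marker_classes()[seq_len(cfg$n_classes)]
  } else {
    sprintf("class_%02d", seq_len(cfg$n_classes))
  }
}

#' Simulate a full fractionation experiment with ground truth
#'
#' Draws the protein/precursor hierarchy once from the configured seed,
#' then generates each replicate's noise and missingness from a
#' deterministically derived per-replicate sub-stream, so a replicate's
#' content does not depend on processing order.
#'
#' @param cfg A [sim_config()].
#' @return A `frac_sim` list with elements:
#'   * `report`: long precursor tibble (`run_id`, `protein_group`,
#'     `precursor_id`, `intensity`) holding observed cells only, all
#'     replicates together -- the shape a DIA-NN-style report ingests to;
#'   * `design`: the run design tibble (`run_id`, `replicate`, `fraction`);
#'   * `markers`: marker annotation tibble (`accession`, `marker`) for the
#'     marker subset;
#'   * `truth`: list with `proteins` (accession, class, abundance,
#'     is_marker) and `cells` (replicate, fraction, precursor_id,
#'     accession, true_intensity, mechanism in
#'     {observed, MNAR, MAR}).
#' @export
simulate_experiment <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)

  classes <- class_names(cfg)
  w <- class_profiles(cfg)

  n_prot <- cfg$n_classes * cfg$proteins_per_class
  proteins <- tibble::tibble(
    accession = sprintf("SP%05d", seq_len(n_prot)),
    class = rep(classes, each = cfg$proteins_per_class),
    abundance = stats::rlnorm(n_prot, cfg$abundance_meanlog,
                              cfg$abundance_sdlog),
    center = rep(cfg$profile_centers, each = cfg$proteins_per_class) +
      stats::rnorm(n_prot, 0, cfg$center_jitter)
  )
  w_prot <- bump_profiles(cfg, proteins$center) # F x n_prot
  colnames(w_prot) <- proteins$accession
  # markers: first marker_frac share of each class (draw order is random in
  # abundance already; membership itself is deterministic)
  n_mark <- max(1L, round(cfg$marker_frac * cfg$proteins_per_class))
  proteins$is_marker <- rep(
    seq_len(cfg$proteins_per_class) <= n_mark,
    times = cfg$n_classes
  )

  n_prec <- 1L + stats::rpois(n_prot, cfg$precursor_lambda)
  precursors <- tibble::tibble(
    accession = rep(proteins$accession, n_prec),
    class = rep(proteins$class, n_prec),
    abundance = rep(proteins$abundance, n_prec),
    prot_idx = rep(seq_len(n_prot), n_prec),
    precursor_id = sprintf(
      "%s_PEP%02d.2", rep(proteins$accession, n_prec),
      unlist(lapply(n_prec, seq_len))
    ),
    response = stats::rlnorm(sum(n_prec), 0, cfg$response_sdlog)
  )

  design <- run_design(cfg$replicates, cfg$fractions)

  per_rep <- lapply(seq_len(cfg$replicates), function(r) {
    set.seed(derive_seed(cfg$seed, r))
    np <- nrow(precursors)
    F <- cfg$fractions
    base <- precursors$abundance * precursors$response
    wmat <- w_prot[, precursors$prot_idx, drop = FALSE] # F x np
    true_int <- t(wmat) * base # np x F; base recycles down each column
    noise <- matrix(stats::rlnorm(np * F, 0, cfg$noise_sdlog), np, F)
    true_int <- true_int * noise
    # censoring (MNAR): logistic in log intensity around the LOD
    p_cens <- if (cfg$lod > 0) {
      stats::plogis((log(cfg$lod) - log(true_int)) * cfg$lod_slope)
    } else {
      matrix(0, np, F)
    }
    # random detection failure is independent of abundance, so dropout is
    # drawn over all cells; the remainder face intensity censoring
    mar <- matrix(stats::runif(np * F), np, F) < cfg$mar_rate
    mnar <- !mar & matrix(stats::runif(np * F), np, F) < p_cens
    mech <- matrix("observed", np, F)
    mech[mnar] <- "MNAR"
    mech[mar] <- "MAR"
    cells <- tibble::tibble(
      replicate = r,
      fraction = rep(seq_len(F), each = np),
      precursor_id = rep(precursors$precursor_id, F),
      accession = rep(precursors$accession, F),
      true_intensity = as.vector(true_int),
      mechanism = as.vector(mech)
    )
    cells
  })
  cells <- dplyr::bind_rows(per_rep)

  observed <- dplyr::filter(cells, .data$mechanism == "observed")
  report <- dplyr::inner_join(observed, design,
                              by = c("replicate", "fraction")) |>
    dplyr::transmute(
      run_id = .data$run_id,
      protein_group = .data$accession,
      precursor_id = .data$precursor_id,
      intensity = .data$true_intensity
    )

  markers <- proteins |>
    dplyr::filter(.data$is_marker) |>
    dplyr::transmute(accession = .data$accession, marker = .data$class)

  structure(
    list(
      report = report, design = design, markers = markers,
      truth = list(proteins = proteins, cells = cells),
      profiles = w, config = cfg
    ),
    class = "frac_sim"
  )
}

#' Named scenario presets
#'
#' Fully specified configurations for the comparison scenarios the package
#' is validated on:
#' * `"dialop-like"`: 13 classes x 10 fractions x 3 replicates with evenly
#'   spread, well-resolved class profiles (a differential-centrifugation
#'   style gradient).
#' * `"detergent-like"`: 6 fractions with the secretory classes
#'   (endoplasmic reticulum, Golgi apparatus, endosome, lysosome) centred
#'   within one fraction of each other, emulating the limited secretory
#'   resolution of sequential detergent solubilization.
#' * `"fraction-dropout"`: identical to `"dialop-like"`; downstream code
#'   subsets its fractions to study resolution loss.
#' * `"mechanism-mix"`: `"dialop-like"` conditions with heavier censoring
#'   and random dropout, for comparing imputation strategies.
#'
#' @return Named list of [sim_config()] objects.
#' @export
scenario_presets <- function() {
  detergent_centers <- c(
    cytosol = 1.0, mitochondrion = 2.2, nucleus = 5.2, chromatin = 5.6,
    `plasma membrane` = 3.0, `endoplasmic reticulum` = 4.0,
    `Golgi apparatus` = 4.4, endosome = 4.2, lysosome = 4.6,
    peroxisome = 3.4, proteasome = 1.6, `ribosome 40S` = 1.3,
    `ribosome 60S` = 1.45
  )
  list(
    "dialop-like" = sim_config(seed = 101L),
    "detergent-like" = sim_config(
      fractions = 6, profile_centers = unname(detergent_centers),
      seed = 101L
    ),
    "fraction-dropout" = sim_config(seed = 101L),
    "mechanism-mix" = sim_config(
      lod = exp(9.0), mar_rate = 0.08, seed = 101L
    )
  )
}

#' Write a simulated experiment to disk as plain TSV
#'
#' Emits the precursor report in the default DIA-NN dialect
#' (`Run`, `Protein.Group`, `Precursor.Id`, `Precursor.Normalised`),
#' alongside the run design, markers, and both truth tables. Intensities
#' are formatted with 17 significant digits so a read-back reproduces
#' them bit-exactly.
#'
#' @param sim A `frac_sim` from [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly; files `report.tsv`, `design.tsv`,
#'   `markers.tsv`, `truth_proteins.tsv`, `truth_cells.tsv`.
#' @export
write_report <- function(sim, dir) {
  stopifnot(inherits(sim, "frac_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rep_out <- tibble::tibble(
    Run = sim$report$run_id,
    `Protein.Group` = sim$report$protein_group,
    `Precursor.Id` = sim$report$precursor_id,
    `Precursor.Normalised` = sprintf("%.17g", sim$report$intensity)
  )
  readr::write_tsv(rep_out, file.path(dir, "report.tsv"))
  readr::write_tsv(sim$design, file.path(dir, "design.tsv"))
  readr::write_tsv(sim$markers, file.path(dir, "markers.tsv"))
  readr::write_tsv(sim$truth$proteins, file.path(dir, "truth_proteins.tsv"))
  truth_cells <- sim$truth$cells
  truth_cells$true_intensity <- sprintf("%.17g", truth_cells$true_intensity)
  readr::write_tsv(truth_cells, file.path(dir, "truth_cells.tsv"))
  invisible(dir)
}
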