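# Small in-code fixtures used across the suite.

# Replicate-matrix tibble from a numeric matrix (NA = missing).
rm_tbl <- function(m, groups = NULL, ids = NULL) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (is.null(ids)) ids <- sprintf("pep%02d", seq_len(n))
  if (is.null(groups)) groups <- sprintf("P%05d", seq_len(n))
  out <- tibble::tibble(precursor_id = ids, protein_group = groups)
  cols <- paste0("F", seq_len(ncol(m)))
  out[, cols] <- as.data.frame(unname(m))
  out
}

# Spatial-dataset tibble from a numeric matrix with marker labels.
sd_tbl <- function(m, marker, replicates = 1) {
  m <- as.matrix(m)
  stopifnot(ncol(m) %% replicates == 0)
  f <- ncol(m) / replicates
  out <- tibble::tibble(
    accession = sprintf("ACC%04d", seq_len(nrow(m))),
    marker = marker
  )
  cols <- as.vector(vapply(seq_len(replicates), function(r) {
    sprintf("R%d_F%d", r, seq_len(f))
  }, character(f)))
  out[, cols] <- as.data.frame(unname(m))
  out
}

# Random replicate matrix with given missingness rate.
random_rm <- function(n, f, miss = 0.2, seed = 1) {
  set.seed(seed)
  m <- matrix(rlnorm(n * f, 10, 1), n, f)
  m[matrix(runif(n * f) < miss, n, f)] <- NA
  # guarantee at least one observed value per row and column
  for (i in seq_len(n)) if (all(is.na(m[i, ]))) m[i, 1] <- rlnorm(1, 10, 1)
  for (j in seq_len(f)) if (all(is.na(m[, j]))) m[1, j] <- rlnorm(1, 10, 1)
  rm_tbl(m)
}

# Two well-separated classes in 4 dimensions, n members each.
separable_dataset <- function(n = 8, seed = 1) {
  set.seed(seed)
  a <- matrix(rnorm(n * 4, sd = 0.05), n, 4)
  a[, 1] <- a[, 1] + 1
  b <- matrix(rnorm(n * 4, sd = 0.05), n, 4)
  b[, 3] <- b[, 3] + 1
  sd_tbl(abs(rbind(a, b)) + 0.01,
         marker = rep(c("cytosol", "nucleus"), each = n))
}

# Session-level cache so the heavier end-to-end objects (simulated
# experiments, cross-validation runs) are built once and shared between
# test blocks.
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, expr, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# Marker macro-F1 (median across rounds) for one imputation strategy on a
# simulated experiment.
pipeline_macro_f1 <- function(sim, mode, rounds = 5, seed = 7) {
  ds <- build_spatial_dataset(sim$report, sim$design, sim$markers,
                              impute_mode = mode)
  cv <- crossvalidate_f1(ds, svm_config(outer_rounds = rounds, seed = seed))
  glance(cv)$median_macro_f1
}

# Brute-force QSep oracle: double loop over all profile pairs.
bf_qsep <- function(x, labels) {
  cls <- sort(unique(labels))
  k <- length(cls)
  raw <- matrix(0, k, k, dimnames = list(cls, cls))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      ri <- which(labels == cls[i]); rj <- which(labels == cls[j])
      tot <- 0; n <- 0
      for (a in ri) {
        for (b in rj) {
          if (i == j && a == b) next
          tot <- tot + sqrt(sum((x[a, ] - x[b, ])^2)); n <- n + 1
        }
      }
      raw[i, j] <- tot / n
    }
  }
  list(raw = raw, normalized = raw / diag(raw))
}
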