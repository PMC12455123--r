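test_that("missingness labels follow the absolute-count rule", {
  vals <- rbind(
    c(NA, NA, NA, 4:10),   # 3 missing of 10 -> MNAR
    c(NA, NA, 3:10),       # 2 missing -> MAR
    1:10                   # complete
  )
  lab <- classify_missingness(rm_tbl(vals))
  expect_equal(lab$label, c("MNAR", "MAR", "COMPLETE"))
  expect_equal(lab$n_missing, c(3L, 2L, 0L))

  # proportion mode rescales with the fraction count
  lab20 <- classify_missingness(
    rm_tbl(cbind(vals, vals)),
    impute_config(proportion_mode = TRUE, mnar_missing_prop_threshold = 0.2)
  )
  expect_equal(lab20$label, c("MNAR", "MAR", "COMPLETE"))
})

test_that("k-NN imputation matches hand-computed neighbour means", {
  # A is the unique nearest neighbour of B on the shared columns
  m <- rm_tbl(rbind(c(1, 2, 3), c(1, 2, NA), c(10, 10, 10)))
  out <- impute_knn(m, cfg = impute_config(knn_k = 1))
  expect_equal(out$F3[2], 3)

  # two equidistant donors with k = 2 -> mean of their column values
  m2 <- rm_tbl(rbind(c(1, 2, NA), c(1.1, 2, 3), c(0.9, 2, 5)))
  out2 <- impute_knn(m2, cfg = impute_config(knn_k = 2))
  expect_equal(out2$F3[1], 4)

  # no missing cells -> identity
  full <- rm_tbl(matrix(1:12, 3, 4))
  expect_equal(as.data.frame(impute_knn(full)), as.data.frame(full))
})

test_that("min imputation uses the global observed minimum", {
  set.seed(3)
  m <- random_rm(30, 6, miss = 0.3, seed = 3)
  vals <- as.matrix(m[, fraction_cols(m)])
  out <- impute_min(m)
  om <- as.matrix(out[, fraction_cols(out)])
  expect_equal(unique(om[is.na(vals)]), min(vals, na.rm = TRUE))

  # column scope uses per-column minima
  outc <- impute_min(m, cfg = impute_config(min_scope = "column"))
  oc <- as.matrix(outc[, fraction_cols(outc)])
  for (j in seq_len(ncol(vals))) {
    miss <- is.na(vals[, j])
    if (any(miss)) {
      expect_equal(unique(oc[miss, j]), min(vals[, j], na.rm = TRUE))
    }
  }
})

test_that("MinDet imputes the column quantile, with the minimum as limit", {
  # column with observed values 1..100: linear-interpolation quantile at
  # 0.01 is 1.99
  v100 <- cbind(c(1:100, NA), rep(5, 101))
  o100 <- impute_mindet(rm_tbl(v100), impute_config(mindet_quantile = 0.01))
  expect_equal(o100$F1[101], 1.99)

  vals <- cbind(c(1:100), c(rep(NA, 50), 1:50))
  m <- rm_tbl(vals)
  out <- impute_mindet(m, impute_config(mindet_quantile = 0.01))
  oc <- as.matrix(out[, fraction_cols(out)])
  # column 2 observed values 1..50; type-7 quantile at 0.01 = 1.49
  expect_equal(unique(oc[1:50, 2]), 1 + 0.01 * 49)

  tiny <- impute_mindet(m, impute_config(mindet_quantile = 1e-9))
  tc <- as.matrix(tiny[, fraction_cols(tiny)])
  expect_equal(unique(tc[1:50, 2]), 1, tolerance = 1e-6)

  full <- rm_tbl(matrix(1:10, 5, 2))
  expect_equal(as.data.frame(impute_mindet(full)), as.data.frame(full))
})

test_that("mixed imputation composes min for MNAR and k-NN for MAR", {
  vals <- rbind(
    c(0.5, 2, 3, 4, 5),      # complete; global min 0.5 lives here
    c(NA, NA, NA, 4.5, 5),   # 3 missing -> MNAR
    c(0.6, 2, 3, 4, NA),     # 1 missing -> MAR
    c(0.62, 2, 3, 4, 5.2)    # complete, the MAR row's nearest neighbour
  )
  out <- impute_mixed(rm_tbl(vals), impute_config(knn_k = 1))
  om <- as.matrix(out[, fraction_cols(out)])
  expect_equal(unname(om[2, 1:3]), rep(0.5, 3))
  expect_equal(unname(om[3, 5]), 5.2)
  lab <- missingness_labels(out)
  expect_equal(lab$label, c("COMPLETE", "MNAR", "MAR", "COMPLETE"))
  expect_false(anyNA(om))

  # all-complete matrix passes through untouched
  full <- rm_tbl(matrix(runif(20) + 1, 4, 5))
  expect_equal(as.data.frame(impute_mixed(full)), as.data.frame(full),
               ignore_attr = TRUE)

  # threshold = F makes every incomplete row MAR -> equals plain k-NN
  m <- random_rm(25, 6, miss = 0.25, seed = 8)
  all_mar <- impute_mixed(m, impute_config(mnar_missing_count_threshold = 6))
  knn <- impute_knn(m, cfg = impute_config())
  expect_equal(as.data.frame(all_mar), as.data.frame(knn),
               ignore_attr = TRUE)
})

test_that("no imputation mode ever alters an observed value", {
  for (seed in 1:3) {
    m <- random_rm(30, 8, miss = 0.3, seed = seed)
    vals <- as.matrix(m[, fraction_cols(m)])
    obs <- !is.na(vals)
    for (mode in c("mixed", "knn_global", "mindet_global", "min_global")) {
      out <- impute_profiles(m, mode = mode)
      om <- as.matrix(out[, fraction_cols(out)])
      expect_identical(om[obs], vals[obs])
      expect_false(anyNA(om))
    }
  }
})

test_that("replicates impute independently of processing order", {
  sim <- simulate_experiment(sim_config(
    n_classes = 4, proteins_per_class = 6, seed = 13
  ))
  mats <- lapply(1:3, function(r) {
    qc_replicate(pivot_replicate(sim$report, sim$design, r))
  })
  fwd <- lapply(mats, impute_mixed)
  rev <- lapply(rev(mats), impute_mixed)
  expect_equal(as.data.frame(fwd[[1]]), as.data.frame(rev[[3]]))
  expect_equal(as.data.frame(fwd[[3]]), as.data.frame(rev[[1]]))
})

test_that("left-censored rows are imputed lower than random-dropout rows", {
  sim <- simulate_experiment(sim_config(
    n_classes = 6, proteins_per_class = 20, seed = 17
  ))
  m <- qc_replicate(pivot_replicate(sim$report, sim$design, 1))
  out <- impute_mixed(m)
  lab <- missingness_labels(out)
  vals_before <- as.matrix(m[, fraction_cols(m)])
  vals_after <- as.matrix(out[, fraction_cols(out)])
  imputed <- is.na(vals_before)
  mean_imp <- function(rows) mean(vals_after[imputed & rows])
  mnar_rows <- matrix(lab$label == "MNAR", nrow(m), ncol(vals_before))
  mar_rows <- matrix(lab$label == "MAR", nrow(m), ncol(vals_before))
  expect_lte(mean_imp(mnar_rows), mean_imp(mar_rows))
})
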