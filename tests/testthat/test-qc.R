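test_that("contaminant and ambiguous protein groups are removed", {
  m <- rm_tbl(matrix(1, 4, 3),
              groups = c("P12345;Q67890", "Cont_ALBU_BOVIN", "P11111",
                         "Q22222"))
  out <- remove_contaminants_and_ambiguous(m, qc_config())
  expect_equal(out$protein_group, c("P11111", "Q22222"))
  rep <- qc_report(out)
  expect_equal(rep$n_removed, 2)
  expect_match(rep$detail, "1 ambiguous, 1 contaminant")

  clean <- rm_tbl(matrix(1, 3, 3))
  out2 <- remove_contaminants_and_ambiguous(clean, qc_config())
  expect_equal(dplyr::select(out2, -dplyr::any_of("nothing")),
               clean, ignore_attr = TRUE)
})

test_that("intensity high-pass blanks sub-threshold cells and drops empty rows", {
  m <- rm_tbl(rbind(c(5, 20, NA), c(1, 2, 3)))
  out <- filter_intensity_highpass(m, qc_config(min_intensity = 10))
  expect_equal(nrow(out), 1)
  expect_equal(unlist(out[1, fraction_cols(out)], use.names = FALSE),
               c(NA, 20, NA))

  # threshold 0 is the identity
  out0 <- filter_intensity_highpass(m, qc_config(min_intensity = 0))
  expect_equal(as.data.frame(out0), as.data.frame(m), ignore_attr = TRUE)

  # observed-cell count equals brute-force count of cells >= threshold
  rnd <- random_rm(40, 8, miss = 0.3, seed = 9)
  thr <- exp(10)
  vals <- as.matrix(rnd[, fraction_cols(rnd)])
  out_r <- filter_intensity_highpass(rnd, qc_config(min_intensity = thr))
  expect_equal(sum(!is.na(out_r[, fraction_cols(out_r)])),
               sum(vals >= thr, na.rm = TRUE))
})

test_that("column filter drops fractions with missingness strictly over the limit", {
  vals <- matrix(1, 10, 3)
  vals[1:8, 1] <- NA    # 0.8 missing -> dropped
  vals[1:7, 2] <- NA    # 0.7 missing -> exactly at the boundary, retained
  m <- rm_tbl(vals)
  out <- filter_columns_by_missingness(m, qc_config())
  expect_equal(fraction_cols(out), c("F2", "F3"))
  expect_equal(attr(out, "dropped_fractions"), "F1")

  full <- rm_tbl(matrix(1, 4, 3))
  expect_equal(fraction_cols(filter_columns_by_missingness(full, qc_config())),
               c("F1", "F2", "F3"))
})

test_that("row filter keeps rows with at least the minimum observed values", {
  vals <- rbind(c(10, NA, NA), c(1, 2, NA), c(1, 2, 3))
  m <- rm_tbl(vals)
  out <- filter_rows_min_values(m, qc_config())
  expect_equal(out$precursor_id, c("pep02", "pep03"))

  all_obs <- rm_tbl(matrix(1, 5, 3))
  expect_equal(nrow(filter_rows_min_values(all_obs, qc_config())), 5)
})

test_that("PSM quality thresholds honour the stated boundaries", {
  psm <- function(sn, coiso, sps) {
    tibble::tibble(psm_id = "x", protein_group = "P", avg_sn = sn,
                   coisolation_pct = coiso, sps_match_pct = sps,
                   F1 = 1, F2 = 2)
  }
  expect_equal(nrow(filter_psms(psm(9.9, 0, 100), qc_config())), 0)
  expect_equal(nrow(filter_psms(psm(10, 75, 100), qc_config())), 0)
  expect_equal(nrow(filter_psms(psm(10, 0, 100), qc_config())), 1)
  expect_equal(nrow(filter_psms(psm(10, 74.9, 65), qc_config())), 1)
  expect_equal(nrow(filter_psms(psm(10, 0, 64.9), qc_config())), 0)
})

test_that("filters are idempotent, conserve counts, and never alter surviving values", {
  cfg <- qc_config(min_intensity = exp(9.5))
  m <- random_rm(60, 10, miss = 0.35, seed = 21)
  m$protein_group[1:3] <- c("A;B", "Cont_X", "P1;P2;P3")

  once <- qc_replicate(m, cfg)
  twice <- qc_replicate(once, cfg)
  expect_equal(as.data.frame(twice), as.data.frame(once),
               ignore_attr = TRUE)

  rep <- qc_report(once)
  expect_true(all(rep$n_in == rep$n_out + rep$n_removed))
  expect_true(all(rep$n_removed >= 0))

  # surviving cells carry their original values
  orig <- as.matrix(m[, fraction_cols(m)])
  rownames(orig) <- m$precursor_id
  out_m <- as.matrix(once[, fraction_cols(once)])
  rownames(out_m) <- once$precursor_id
  for (id in rownames(out_m)) {
    ov <- orig[id, fraction_cols(once)]
    kept <- !is.na(out_m[id, ])
    expect_identical(out_m[id, kept], ov[kept])
  }
})

test_that("column-then-row order matches the column-first brute force", {
  # crafted so dropping the over-missing column changes which rows survive:
  # F1 is observed in only 2 of 10 rows (80% missing -> dropped); pep02 has
  # two observed values overall but only one outside F1, so it survives a
  # row-first reading and dies under the correct column-first order
  vals <- matrix(NA_real_, 10, 4)
  vals[1, 1] <- 5                        # pep01: F1 only
  vals[2, c(1, 2)] <- c(6, 7)            # pep02: F1 + F2
  for (i in 3:10) vals[i, 2:4] <- i      # the rest observed in F2..F4
  m <- rm_tbl(vals)
  out <- qc_replicate(m, qc_config())

  # brute force: drop columns with > 70% missing, then rows with < 2 values
  bf <- vals[, colMeans(is.na(vals)) <= 0.7, drop = FALSE]
  bf <- bf[rowSums(!is.na(bf)) >= 2, , drop = FALSE]
  expect_equal(unname(as.matrix(out[, fraction_cols(out)])), unname(bf))
  expect_equal(fraction_cols(out), c("F2", "F3", "F4"))
  expect_equal(out$precursor_id, sprintf("pep%02d", 3:10))
  # a row-first reading would instead have kept pep02
  expect_true(sum(!is.na(vals[2, ])) >= 2)
})
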