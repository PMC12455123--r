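test_that("the F1 score agrees with the harmonic-mean form on all confusion tables", {
  # direct examples
  expect_equal(unname(f1_scores(c("a", "b"), c("a", "b"))), c(1, 1))
  # P = 0.5, R = 1 -> F1 = 2/3: one true "a", predicted "a" twice
  expect_equal(unname(f1_scores(c("a", "b"), c("a", "a"))["a"]), 2 / 3)

  # TP = 8, FP = 2, FN = 4 -> P = 0.8, R = 2/3, F1 = 0.7272...
  truth <- c(rep("a", 12), rep("b", 10))
  pred <- c(rep("a", 8), rep("b", 4), rep("a", 2), rep("b", 8))
  expect_equal(unname(f1_scores(truth, pred)["a"]), 8 / 11)
  expect_equal(unname(f1_scores(truth, pred)["a"]),
               2 * 0.8 * (2 / 3) / (0.8 + 2 / 3))

  # property: 2TP/(2TP+FP+FN) == 2PR/(P+R) over integer confusion tables
  set.seed(1)
  for (i in 1:50) {
    tp <- sample(0:20, 1); fp <- sample(0:20, 1); fn <- sample(0:20, 1)
    den <- 2 * tp + fp + fn
    direct <- if (den == 0) 0 else 2 * tp / den
    p <- if (tp + fp == 0) NA else tp / (tp + fp)
    r <- if (tp + fn == 0) NA else tp / (tp + fn)
    hm <- if (is.na(p) || is.na(r) || p + r == 0) 0 else 2 * p * r / (p + r)
    if (den > 0) expect_equal(direct, hm)
  }
})

test_that("marker checks reject small classes and missing labels", {
  ds <- separable_dataset(n = 8)
  ds$marker[ds$marker == "nucleus"][1:5] <- NA # leaves nucleus with 3
  expect_error(crossvalidate_f1(ds, svm_config(outer_rounds = 1)),
               "nucleus")
  no_mk <- dplyr::select(ds, -marker)
  expect_error(crossvalidate_f1(no_mk, svm_config(outer_rounds = 1)),
               "marker")
})

test_that("well-separated classes train to perfect F1 and score deterministically", {
  ds <- separable_dataset(n = 10)
  cfg <- svm_config(cost_grid = c(1, 4), gamma_grid = c(0.1, 1),
                    outer_rounds = 3, seed = 5)
  cv <- crossvalidate_f1(ds, cfg)
  expect_true(all(cv$f1$f1 == 1))

  model <- train_final(ds, cfg, cv$chosen)
  scores <- predict_scores(model, ds)
  # training set re-scored: macro F1 on markers is perfect
  pred <- c("cytosol", "nucleus")[max.col(as.matrix(scores[, model$classes]))]
  expect_equal(mean(f1_scores(ds$marker, pred)), 1)

  # score vectors are simplex points
  sm <- as.matrix(scores[, model$classes])
  expect_true(all(sm >= 0))
  expect_true(all(abs(rowSums(sm) - 1) < 1e-6))

  # a duplicated profile scores identically to the original
  dup <- dplyr::bind_rows(ds, ds[1, ] |>
                            dplyr::mutate(accession = "DUP"))
  s2 <- predict_scores(model, dup)
  expect_equal(unlist(s2[nrow(dup), model$classes]),
               unlist(s2[1, model$classes]))

  # same seed, same everything
  cv2 <- crossvalidate_f1(ds, cfg)
  expect_identical(cv$f1, cv2$f1)
  expect_identical(cv$heldout, cv2$heldout)
  model2 <- train_final(ds, cfg, cv$chosen)
  expect_identical(predict_scores(model2, ds), scores)
})

test_that("thresholding is monotone and honours degenerate settings", {
  ds <- separable_dataset(n = 10)
  extra <- separable_dataset(n = 5, seed = 99) |>
    dplyr::mutate(accession = paste0("U", dplyr::row_number()),
                  marker = NA_character_)
  all_ds <- dplyr::bind_rows(ds, extra)
  cfg <- svm_config(cost_grid = 1, gamma_grid = 0.5, outer_rounds = 2,
                    seed = 2)
  model <- train_final(all_ds, cfg)

  asg0 <- assign_with_thresholds(model, all_ds, 0)
  expect_true(all(asg0$assignment != "unknown"))

  asg1 <- assign_with_thresholds(model, all_ds, 1 + 1e-9)
  non_marker <- is.na(asg1$marker)
  expect_true(all(asg1$assignment[non_marker] == "unknown"))
  # markers keep their curated labels regardless
  expect_equal(asg1$assignment[!non_marker], asg1$marker[!non_marker])

  # raising one class's threshold never increases its assignment count
  counts <- vapply(c(0, 0.3, 0.6, 0.9, 1.01), function(t) {
    a <- assign_with_thresholds(model, all_ds,
                                c(cytosol = t, nucleus = 0))
    sum(a$assignment[is.na(a$marker)] == "cytosol")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("quantile thresholds equal brute-force medians of correct held-out scores", {
  ds <- separable_dataset(n = 10)
  cfg <- svm_config(cost_grid = 1, gamma_grid = 0.5, outer_rounds = 4,
                    threshold_quantile = 0.5, seed = 3)
  cv <- crossvalidate_f1(ds, cfg)
  thr <- compute_thresholds(cv)
  for (cl in cv$classes) {
    s <- cv$heldout$score[cv$heldout$correct & cv$heldout$class == cl]
    expect_equal(unname(thr[cl]), median(s))
  }
})
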