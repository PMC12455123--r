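test_that("sum normalization rescales rows to unit sum", {
  m <- rm_tbl(rbind(c(1, 1, 2)))
  out <- normalize_profiles(m)
  expect_equal(unlist(out[1, fraction_cols(out)], use.names = FALSE),
               c(0.25, 0.25, 0.5))

  # idempotence
  again <- normalize_profiles(out)
  expect_equal(as.data.frame(again), as.data.frame(out))

  # property: random positive matrices always land within 1e-9 of 1
  for (seed in 1:3) {
    set.seed(seed)
    r <- rm_tbl(matrix(rlnorm(80, 8, 2), 10, 8))
    s <- rowSums(as.matrix(normalize_profiles(r)[, fraction_cols(r)]))
    expect_true(all(abs(s - 1) < 1e-9))
  }

  bad <- rm_tbl(rbind(c(0, 0, 0)), ids = "pep_zero")
  expect_error(normalize_profiles(bad), "pep_zero")
  expect_error(normalize_profiles(rm_tbl(rbind(c(1, NA, 2)))), "impute")
})

test_that("median aggregation equals brute-force per-column medians", {
  m <- rm_tbl(rbind(c(0.2, 0.8), c(0.4, 0.6)), groups = c("P1", "P1"))
  out <- aggregate_proteins(m)
  expect_equal(unlist(out[1, c("F1", "F2")], use.names = FALSE), c(0.3, 0.7))

  single <- rm_tbl(rbind(c(0.1, 0.9)), groups = "P9")
  outs <- aggregate_proteins(single)
  expect_equal(unlist(outs[1, c("F1", "F2")], use.names = FALSE), c(0.1, 0.9))

  set.seed(12)
  vals <- matrix(runif(25), 5, 5)
  rnd <- rm_tbl(vals, groups = rep("PX", 5))
  outr <- aggregate_proteins(rnd)
  expect_equal(unlist(outr[1, fraction_cols(rnd)], use.names = FALSE),
               apply(vals, 2, median))

  # permutation invariance in feature order
  perm <- rnd[sample(5), ]
  expect_equal(as.data.frame(aggregate_proteins(perm)), as.data.frame(outr))
})

test_that("robust aggregation recovers shape and resists outliers", {
  profile <- c(1, 3, 7, 2, 5)
  offsets <- c(-1, 0, 0.5, 2)
  set.seed(7)
  vals <- t(vapply(offsets, function(o) profile + o, numeric(5))) +
    matrix(rnorm(20, sd = 1e-3), 4, 5)
  m <- rm_tbl(vals, groups = rep("P1", 4))
  out <- aggregate_proteins(m, method = "robust")
  est <- unlist(out[1, fraction_cols(m)], use.names = FALSE)
  # column effects equal the shared profile up to an additive constant
  expect_equal(est - mean(est), profile - mean(profile), tolerance = 1e-2)

  # a single gross outlier cell: robust beats the plain mean in L2
  dirty <- vals
  dirty[2, 3] <- dirty[2, 3] + 50
  md <- rm_tbl(dirty, groups = rep("P1", 4))
  rob <- unlist(aggregate_proteins(md, method = "robust")[1, fraction_cols(md)],
                use.names = FALSE)
  mn <- colMeans(dirty)
  truth <- profile + mean(offsets)
  l2 <- function(a, b) sqrt(sum((a - b)^2))
  expect_lt(l2(rob, truth), l2(mn, truth))

  # single feature passes through
  one <- rm_tbl(rbind(profile), groups = "P2")
  expect_equal(
    unlist(aggregate_proteins(one, method = "robust")[1, fraction_cols(one)],
           use.names = FALSE),
    profile
  )
})

test_that("combine_replicates keeps exactly the proteins present everywhere", {
  mk_mat <- function(acc) {
    out <- tibble::tibble(accession = acc)
    out[, c("F1", "F2")] <- as.data.frame(matrix(runif(2 * length(acc)) + 0.1,
                                                 length(acc)))
    out
  }
  set.seed(2)
  mats <- list(mk_mat(c("A", "B", "C")), mk_mat(c("A", "C")),
               mk_mat(c("A", "C", "D")))
  ds <- combine_replicates(mats)
  expect_equal(sort(ds$accession), c("A", "C"))
  expect_equal(profile_cols(ds),
               c("R1_F1", "R1_F2", "R2_F1", "R2_F2", "R3_F1", "R3_F2"))

  expect_warning(
    empty <- combine_replicates(list(mk_mat("A"), mk_mat("B"))),
    "all replicates"
  )
  expect_equal(nrow(empty), 0)

  # random sets vs brute-force intersection
  for (seed in 1:4) {
    set.seed(seed)
    sets <- lapply(1:3, function(i) sample(LETTERS, sample(5:20, 1)))
    got <- suppressWarnings(combine_replicates(lapply(sets, mk_mat)))
    expect_equal(sort(got$accession), sort(Reduce(intersect, sets)))
  }

  # marker labels attach by accession
  with_mk <- combine_replicates(
    mats, markers = tibble::tibble(accession = "C", marker = "cytosol")
  )
  expect_equal(with_mk$marker[with_mk$accession == "C"], "cytosol")
  expect_true(is.na(with_mk$marker[with_mk$accession == "A"]))
})

test_that("replicate blocks renormalize to unit sums after median aggregation", {
  sim <- simulate_experiment(sim_config(
    n_classes = 4, proteins_per_class = 8, seed = 19
  ))
  raw <- build_spatial_dataset(sim$report, sim$design, sim$markers,
                               renormalize = FALSE)
  renorm <- build_spatial_dataset(sim$report, sim$design, sim$markers,
                                  renormalize = TRUE)
  f <- 10
  for (r in 1:3) {
    block <- paste0("R", r, "_F", 1:f)
    s_raw <- rowSums(as.matrix(raw[, block]))
    expect_true(all(s_raw > 0 & s_raw <= f))
    s_re <- rowSums(as.matrix(renorm[, block]))
    expect_true(all(abs(s_re - 1) < 1e-9))
  }
})
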