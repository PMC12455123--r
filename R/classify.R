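# Marker-based SVM localization.
#
# A radial-kernel support vector machine is trained on curated marker
# profiles. Hyperparameters (cost, kernel width) are chosen by stratified
# five-fold cross-validation on macro-F1 inside repeated stratified 80/20
# train/test rounds, which also yield the per-class F1 distributions used
# as a resolution readout. Scores are probability-calibrated (pairwise
# coupling) so per-organelle thresholds live on a common [0, 1] scale.

#' SVM training configuration
#'
#' @param cost_grid Candidate soft-margin costs (default powers of two,
#'   `2^-4 .. 2^4`).
#' @param gamma_grid Candidate radial-kernel widths (default powers of
#'   ten, `10^-3 .. 10^2`).
#' @param outer_rounds Number of stratified 80/20 train/test rounds over
#'   which per-class F1 distributions are collected (default 100;
#'   reducible for desk-scale work).
#' @param inner_folds Folds of the inner cross-validation used for
#'   hyperparameter selection (default 5).
#' @param train_frac Training share of each outer split.
#' @param threshold_quantile Per-class quantile of correct held-out marker
#'   scores used as the default assignment threshold (see
#'   [compute_thresholds()]).
#' @param seed Integer seed; identical seeds give identical results.
#' @return An `svm_config` list. Class weights are always inverse class
#'   frequency, to counter marker-set imbalance.
#' @export
svm_config <- function(cost_grid = 2^(-4:4), gamma_grid = 10^(-3:2),
                       outer_rounds = 100, inner_folds = 5,
                       train_frac = 0.8, threshold_quantile = 0.5,
                       seed = 1) {
  stopifnot(
    length(cost_grid) >= 1, length(gamma_grid) >= 1,
    outer_rounds >= 1, inner_folds >= 2,
    train_frac > 0, train_frac < 1,
    threshold_quantile >= 0, threshold_quantile <= 1
  )
  structure(
    list(
      cost_grid = cost_grid, gamma_grid = gamma_grid,
      outer_rounds = as.integer(outer_rounds),
      inner_folds = as.integer(inner_folds),
      train_frac = train_frac,
      threshold_quantile = threshold_quantile,
      seed = as.integer(seed)
    ),
    class = "svm_config"
  )
}

#' Per-class F1 from predictions
#'
#' `F1 = 2 TP / (2 TP + FP + FN)`, algebraically identical to the
#' harmonic mean of precision and recall, and defined as 0 when the
#' denominator vanishes.
#'
#' @param truth,predicted Factors or character vectors of equal length.
#' @param classes Class vocabulary to report on (default: levels seen in
#'   `truth`).
#' @return Named numeric vector of per-class F1 scores in `[0, 1]`.
#' @export
f1_scores <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (is.null(classes)) classes <- sort(unique(truth))
  vapply(classes, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    den <- 2 * tp + fp + fn
    if (den == 0) 0 else 2 * tp / den
  }, numeric(1))
}

marker_frame <- function(dataset) {
  if (!"marker" %in% names(dataset)) {
    stop("dataset has no 'marker' column", call. = FALSE)
  }
  dplyr::filter(dataset, !is.na(.data$marker))
}

check_marker_counts <- function(labels, min_members) {
  tab <- table(labels)
  small <- names(tab)[tab < min_members]
  if (length(small) > 0) {
    stop("marker class(es) with fewer than ", min_members, " members: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  invisible(tab)
}

# Stratified indices: for each class, a train/test split or fold labels.
stratified_split <- function(labels, frac) {
  idx <- seq_along(labels)
  train <- unlist(lapply(split(idx, labels), function(ix) {
    n <- max(1L, round(frac * length(ix)))
    sample(ix, n)
  }), use.names = FALSE)
  sort(train)
}

stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (ix in split(seq_along(labels), labels)) {
    folds[ix] <- sample(rep_len(seq_len(k), length(ix)))
  }
  folds
}

inverse_class_weights <- function(labels) {
  tab <- table(labels)
  w <- sum(tab) / (length(tab) * tab)
  stats::setNames(as.numeric(w), names(tab))
}

fit_svm <- function(x, y, cost, gamma, probability = FALSE) {
  e1071::svm(
    x = x, y = y, kernel = "radial", cost = cost, gamma = gamma,
    class.weights = inverse_class_weights(y), scale = FALSE,
    probability = probability
  )
}

# Argmax class from a pairwise-coupled probability matrix; the deployed
# scorer assigns by calibrated score, so model selection must judge the
# calibrated predictor, not the raw decision values (which can disagree
# at degenerate hyperparameters).
prob_predict <- function(fit, x) {
  pred <- stats::predict(fit, x, probability = TRUE)
  prob <- attr(pred, "probabilities")
  list(
    predicted = colnames(prob)[max.col(prob, ties.method = "first")],
    prob = prob
  )
}

# Mean inner-CV macro-F1 for one (cost, gamma) pair, evaluated with the
# probability-calibrated predictor.
inner_cv_macro_f1 <- function(x, y, folds, cost, gamma) {
  k <- max(folds)
  f1 <- vapply(seq_len(k), function(fold) {
    tr <- folds != fold
    fit <- fit_svm(x[tr, , drop = FALSE], droplevels(y[tr]), cost, gamma,
                   probability = TRUE)
    pred <- prob_predict(fit, x[!tr, , drop = FALSE])$predicted
    mean(f1_scores(y[!tr], pred, classes = levels(y)))
  }, numeric(1))
  mean(f1)
}

#' Cross-validated per-class F1 distributions and hyperparameter choice
#'
#' Runs `outer_rounds` stratified 80/20 train/test rounds on the marker
#' proteins. In each round the (cost, gamma) pair with the best inner
#' stratified 5-fold macro-F1 on the training share is selected, a
#' probability-calibrated SVM is refit on the whole training share, and
#' per-class F1 plus held-out scores are recorded on the test share. The
#' modal (cost, gamma) pair across rounds is reported as the chosen
#' hyperparameters.
#'
#' @param dataset Spatial-dataset tibble with a `marker` column labelling
#'   at least two classes, each with at least 6 members.
#' @param cfg An [svm_config()].
#' @return An object of class `svm_cv`: list with `f1` (tibble `round`,
#'   `class`, `f1`), `heldout` (tibble of held-out predictions with
#'   calibrated scores and correctness), `params` (per-round choices),
#'   `chosen` (modal cost/gamma), `classes`, and `config`. [tidy()]
#'   returns the F1 tibble; [glance()] a one-row summary.
#' @export
crossvalidate_f1 <- function(dataset, cfg = svm_config()) {
  mk <- marker_frame(dataset)
  y_all <- factor(mk$marker)
  if (nlevels(y_all) < 2) {
    stop("need markers for at least 2 classes", call. = FALSE)
  }
  check_marker_counts(y_all, max(cfg$inner_folds, 6))
  x_all <- value_matrix(mk, id = "accession")
  set.seed(cfg$seed)

  grid <- expand.grid(cost = cfg$cost_grid, gamma = cfg$gamma_grid)
  rounds <- vector("list", cfg$outer_rounds)
  for (r in seq_len(cfg$outer_rounds)) {
    tr_idx <- stratified_split(y_all, cfg$train_frac)
    te_idx <- setdiff(seq_along(y_all), tr_idx)
    x_tr <- x_all[tr_idx, , drop = FALSE]
    y_tr <- droplevels(y_all[tr_idx])
    folds <- stratified_folds(y_tr, cfg$inner_folds)
    cv_f1 <- vapply(seq_len(nrow(grid)), function(i) {
      inner_cv_macro_f1(x_tr, y_tr, folds, grid$cost[i], grid$gamma[i])
    }, numeric(1))
    best <- which.max(cv_f1)
    fit <- fit_svm(x_tr, y_tr, grid$cost[best], grid$gamma[best],
                   probability = TRUE)
    pp <- prob_predict(fit, x_all[te_idx, , drop = FALSE])
    win <- apply(pp$prob, 1, max)
    rounds[[r]] <- list(
      f1 = tibble::tibble(
        round = r, class = levels(y_all),
        f1 = unname(f1_scores(y_all[te_idx], pp$predicted, levels(y_all)))
      ),
      heldout = tibble::tibble(
        round = r,
        accession = mk$accession[te_idx],
        class = as.character(y_all[te_idx]),
        predicted = pp$predicted,
        score = unname(win),
        correct = pp$predicted == as.character(y_all[te_idx])
      ),
      params = tibble::tibble(
        round = r, cost = grid$cost[best], gamma = grid$gamma[best],
        inner_macro_f1 = cv_f1[best]
      )
    )
  }
  params <- dplyr::bind_rows(purrr::map(rounds, "params"))
  key <- paste(params$cost, params$gamma)
  modal <- names(sort(table(key), decreasing = TRUE))[1]
  chosen <- params[match(modal, key), c("cost", "gamma")]
  structure(
    list(
      f1 = dplyr::bind_rows(purrr::map(rounds, "f1")),
      heldout = dplyr::bind_rows(purrr::map(rounds, "heldout")),
      params = params,
      chosen = list(cost = chosen$cost[[1]], gamma = chosen$gamma[[1]]),
      classes = levels(y_all),
      config = cfg
    ),
    class = "svm_cv"
  )
}

#' @export
tidy.svm_cv <- function(x, ...) {
  x$f1
}

#' @export
glance.svm_cv <- function(x, ...) {
  per_round <- x$f1 |>
    dplyr::summarise(macro_f1 = mean(.data$f1), .by = "round")
  tibble::tibble(
    rounds = max(x$f1$round),
    classes = length(x$classes),
    median_macro_f1 = stats::median(per_round$macro_f1),
    median_class_f1 = stats::median(x$f1$f1),
    cost = x$chosen$cost,
    gamma = x$chosen$gamma
  )
}

#' Train the final marker classifier
#'
#' Fits a probability-calibrated radial SVM on all marker proteins with
#' the supplied (or cross-validated) hyperparameters. Deterministic given
#' the configuration seed.
#'
#' @param dataset Spatial-dataset tibble with marker labels.
#' @param cfg An [svm_config()].
#' @param params List with `cost` and `gamma`; default the `chosen` pair
#'   of a [crossvalidate_f1()] result, or the grid midpoints.
#' @return An `organelle_svm` object usable with [predict_scores()] and
#'   [assign_with_thresholds()].
#' @export
train_final <- function(dataset, cfg = svm_config(), params = NULL) {
  mk <- marker_frame(dataset)
  y <- factor(mk$marker)
  check_marker_counts(y, max(cfg$inner_folds, 6))
  x <- value_matrix(mk, id = "accession")
  if (is.null(params)) {
    params <- list(cost = stats::median(cfg$cost_grid),
                   gamma = stats::median(cfg$gamma_grid))
  }
  set.seed(cfg$seed)
  fit <- fit_svm(x, y, params$cost, params$gamma, probability = TRUE)
  structure(
    list(fit = fit, classes = levels(y), params = params,
         feature_cols = colnames(x), config = cfg),
    class = "organelle_svm"
  )
}

#' Calibrated per-class scores for every protein
#'
#' @param model An `organelle_svm` from [train_final()].
#' @param dataset Spatial-dataset tibble with the same profile columns the
#'   model was trained on.
#' @return Tibble `accession` plus one score column per class; each row is
#'   non-negative and sums to 1.
#' @export
predict_scores <- function(model, dataset) {
  stopifnot(inherits(model, "organelle_svm"))
  x <- as.matrix(dataset[, model$feature_cols, drop = FALSE])
  rownames(x) <- dataset$accession
  prob <- prob_predict(model$fit, x)$prob[, model$classes, drop = FALSE]
  dplyr::bind_cols(
    tibble::tibble(accession = dataset$accession),
    tibble::as_tibble(as.data.frame(prob))
  )
}

#' Per-class score thresholds from cross-validation
#'
#' The default thresholding rule: for each class, the
#' `threshold_quantile` quantile (default the median) of the calibrated
#' scores that *correct* marker predictions achieved in the held-out
#' shares of the cross-validation rounds. A class whose markers were
#' never correctly predicted gets threshold 1 (nothing assigned to it),
#' with a warning.
#'
#' @param cv An `svm_cv` from [crossvalidate_f1()].
#' @param quantile Quantile level; default taken from the CV config.
#' @return Named numeric vector of thresholds in `[0, 1]`.
#' @export
compute_thresholds <- function(cv, quantile = NULL) {
  stopifnot(inherits(cv, "svm_cv"))
  if (is.null(quantile)) quantile <- cv$config$threshold_quantile
  correct <- dplyr::filter(cv$heldout, .data$correct)
  thr <- vapply(cv$classes, function(cl) {
    s <- correct$score[correct$class == cl]
    if (length(s) == 0) NA_real_ else
      stats::quantile(s, quantile, names = FALSE, type = 7)
  }, numeric(1))
  if (anyNA(thr)) {
    warning("class(es) never correctly predicted; threshold set to 1: ",
            paste(names(thr)[is.na(thr)], collapse = ", "))
    thr[is.na(thr)] <- 1
  }
  thr
}

#' Assign localizations with per-organelle thresholds
#'
#' Every protein receives its argmax class and winning score; the
#' assignment is kept iff the score reaches that class's threshold,
#' otherwise the protein is left `"unknown"`. Marker proteins retain
#' their curated labels.
#'
#' @param model An `organelle_svm`.
#' @param dataset Spatial-dataset tibble.
#' @param thresholds Named per-class thresholds in `[0, 1]` (e.g. from
#'   [compute_thresholds()]), or one number recycled to all classes.
#' @return An `organelle_assignment` tibble: `accession`, `marker`,
#'   `predicted`, `score`, `assignment`; full score vectors in the
#'   `"scores"` attribute, thresholds in `"thresholds"`.
#' @export
assign_with_thresholds <- function(model, dataset, thresholds) {
  scores <- predict_scores(model, dataset)
  if (length(thresholds) == 1 && is.null(names(thresholds))) {
    thresholds <- stats::setNames(rep(thresholds, length(model$classes)),
                                  model$classes)
  }
  miss <- setdiff(model$classes, names(thresholds))
  if (length(miss) > 0) {
    stop("missing threshold(s) for class(es): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  smat <- as.matrix(scores[, model$classes, drop = FALSE])
  best <- max.col(smat, ties.method = "first")
  predicted <- model$classes[best]
  win <- smat[cbind(seq_len(nrow(smat)), best)]
  marker <- if ("marker" %in% names(dataset)) {
    dataset$marker
  } else {
    rep(NA_character_, nrow(dataset))
  }
  assignment <- ifelse(win >= unname(thresholds[predicted]),
                       predicted, "unknown")
  assignment[!is.na(marker)] <- marker[!is.na(marker)]
  out <- tibble::tibble(
    accession = dataset$accession,
    marker = marker,
    predicted = predicted,
    score = win,
    assignment = assignment
  )
  class(out) <- c("organelle_assignment", class(out))
  attr(out, "scores") <- scores
  attr(out, "thresholds") <- thresholds
  out
}

#' @export
tidy.organelle_assignment <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.organelle_assignment <- function(x, ...) {
  non_marker <- is.na(x$marker)
  tibble::tibble(
    n_proteins = nrow(x),
    n_markers = sum(!non_marker),
    n_assigned = sum(non_marker & x$assignment != "unknown"),
    n_unknown = sum(non_marker & x$assignment == "unknown"),
    frac_localized = (sum(!non_marker) +
                        sum(non_marker & x$assignment != "unknown")) / nrow(x)
  )
}
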