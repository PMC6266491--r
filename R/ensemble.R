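# Five-fold random-forest ensembles with fractile-score rank aggregation
# and empirical FPR calibration. Each fold's forest is a bagged ensemble of
# unpruned trees (per-tree bootstrap with replacement, so ~2/3 of rows
# train each tree and ~1/3 are out-of-bag); scores are the positive-class
# probabilities.

# Stratified K-fold assignment, deterministic given seed.
stratified_folds <- function(y, k = 5L, seed = 1L) {
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

as_label <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.numeric(y) || is.logical(y)) y <- ifelse(as.numeric(y) > 0, "pos", "neg")
  factor(y, levels = c("neg", "pos"))
}

forest_scores <- function(fit, x) {
  p <- predict(fit, data = as.data.frame(x), num.threads = 1)$predictions
  unname(p[, "pos"])
}

#' Train a five-fold cross-validation forest ensemble
#'
#' Splits the rows into five stratified folds; for each fold, fits a
#' probability random forest on the other four and stores the held-out
#' fold's positive-class scores (sorted) as that model's validation score
#' distribution, used later for fractile conversion.
#'
#' @param x feature matrix or feature tibble (normalized)
#' @param y binary labels (1/0, logical, or `"pos"`/`"neg"`)
#' @param n_trees number of trees per forest
#' @param seed integer seed; training is reproducible bit-for-bit
#' @param k number of folds
#' @return a `circ_ensemble`: `models` (list of k forests),
#'   `fold` (row assignment), `val_scores` (per-fold sorted held-out
#'   scores), `oof_scores` (per-row out-of-fold score), `oof_auc`,
#'   `n_trees`, `seed`
#' @export
train_cv_ensemble <- function(x, y, n_trees = 100L, seed = 1L, k = 5L) {
  x <- feature_matrix(x)
  y <- as_label(y)
  if (nrow(x) < 2 * k) abort("too few rows to train a cross-validation ensemble")
  if (dplyr::n_distinct(y) < 2) abort("training labels contain a single class")
  fold <- stratified_folds(y, k, seed)
  models <- vector("list", k)
  val_scores <- vector("list", k)
  oof <- numeric(nrow(x))
  for (f in seq_len(k)) {
    tr <- fold != f
    models[[f]] <- ranger::ranger(
      x = as.data.frame(x[tr, , drop = FALSE]), y = y[tr],
      num.trees = n_trees, probability = TRUE, keep.inbag = TRUE,
      seed = derive_seed(seed, f), num.threads = 1
    )
    s <- forest_scores(models[[f]], x[!tr, , drop = FALSE])
    oof[!tr] <- s
    val_scores[[f]] <- sort(s)
  }
  structure(list(models = models, fold = fold, val_scores = val_scores,
                 oof_scores = oof, y = y,
                 oof_auc = auc_mw(oof[y == "pos"], oof[y == "neg"]),
                 n_trees = as.integer(n_trees), seed = as.integer(seed),
                 feature_names = colnames(x)),
            class = "circ_ensemble")
}

#' @export
print.circ_ensemble <- function(x, ...) {
  cat(sprintf("<circ_ensemble: %d folds x %d trees, %d features, out-of-fold AUC %.3f>\n",
              length(x$models), x$n_trees, length(x$feature_names), x$oof_auc))
  invisible(x)
}

# Mean over folds of the held-out AUC, deterministic given seed; folds are
# shared across calls with the same seed so tree counts compare cleanly.
cv_auc <- function(x, y, n_trees, seed = 1L, k = 5L) {
  x <- feature_matrix(x)
  y <- as_label(y)
  fold <- stratified_folds(y, k, seed)
  mean(vapply(seq_len(k), function(f) {
    tr <- fold != f
    fit <- ranger::ranger(x = as.data.frame(x[tr, , drop = FALSE]), y = y[tr],
                          num.trees = n_trees, probability = TRUE,
                          seed = derive_seed(seed, f), num.threads = 1)
    s <- forest_scores(fit, x[!tr, , drop = FALSE])
    auc_mw(s[y[!tr] == "pos"], s[y[!tr] == "neg"])
  }, numeric(1)))
}

#' Tune the number of trees by cross-validated AUC
#'
#' Evaluates each candidate tree count by five-fold cross-validated AUC
#' (same folds for every candidate) and returns the best; ties go to the
#' smallest count. The default grid is 10 to 100 in steps of 10.
#'
#' @param x feature matrix or tibble
#' @param y binary labels
#' @param grid candidate tree counts
#' @param seed integer seed
#' @return the selected tree count (one of `grid`)
#' @export
tune_num_trees <- function(x, y, grid = seq(10L, 100L, by = 10L), seed = 1L) {
  stopifnot(length(grid) >= 1)
  aucs <- vapply(grid, function(g) cv_auc(x, y, g, seed), numeric(1))
  grid[which.max(aucs)]          # which.max takes the first (smallest) on ties
}

#' Convert a raw score to a fractile within a validation distribution
#'
#' The fractile of `score` in `val_scores` is
#' `(#\{v < score\} + 0.5 * #\{v = score\}) / n`, i.e. the mid-rank
#' quantile position, in `[0, 1]`.
#'
#' @param score numeric vector of raw scores
#' @param val_scores sorted numeric vector, a model's validation scores
#' @return numeric vector of fractiles in `[0, 1]`
#' @examples
#' score_to_fractile(2, c(1, 2, 3, 4))  # (1 + 0.5) / 4 = 0.375
#' @export
score_to_fractile <- function(score, val_scores) {
  if (length(val_scores) == 0) abort("empty validation score distribution")
  v <- sort(val_scores)
  n_lt <- findInterval(score, v, left.open = TRUE)
  n_le <- findInterval(score, v)
  (n_lt + 0.5 * (n_le - n_lt)) / length(v)
}

#' Estimate a false-positive-rate calibration table
#'
#' For each cutoff `t` of an ascending grid, tabulates the fraction of
#' negative mean-fractile scores at or above `t` — the empirical FPR of
#' calling everything with mean fractile `>= t` positive.
#'
#' @param neg_mean_fractiles mean fractile scores of negative examples
#' @param cutoffs ascending cutoff grid in `[0, 1]`
#' @return a `circ_calibration` tibble with columns `cutoff` and `fpr`
#'   (non-increasing in cutoff)
#' @export
calibrate_fpr <- function(neg_mean_fractiles, cutoffs = seq(0, 1, by = 0.01)) {
  if (length(neg_mean_fractiles) == 0) abort("no negative scores to calibrate on")
  stopifnot(!is.unsorted(cutoffs))
  out <- tibble(cutoff = cutoffs,
                fpr = vapply(cutoffs,
                             function(t) mean(neg_mean_fractiles >= t), numeric(1)))
  class(out) <- c("circ_calibration", class(out))
  out
}

#' Look up the estimated FPR for mean-fractile scores
#'
#' Step-function lookup: each query takes the FPR of the largest tabulated
#' cutoff at or below it (queries above the grid return 0, below it 1).
#'
#' @param calibration a `circ_calibration` from [calibrate_fpr()]
#' @param mean_fractile numeric vector of query scores
#' @return numeric vector of estimated FPRs
#' @export
fpr_lookup <- function(calibration, mean_fractile) {
  stopifnot(inherits(calibration, "circ_calibration"))
  i <- findInterval(mean_fractile, calibration$cutoff)
  out <- ifelse(i == 0, 1, calibration$fpr[pmax(i, 1)])
  ifelse(mean_fractile > max(calibration$cutoff), 0, out)
}

#' Score new feature vectors with a cross-validation ensemble
#'
#' Each of the fold models scores the input; each raw score is converted to
#' a fractile within that model's own validation score distribution; the
#' mean fractile is the aggregated score, and an FPR is attached when a
#' calibration table is supplied.
#'
#' @param object a `circ_ensemble`
#' @param newdata feature matrix or tibble conforming to the ensemble's
#'   schema
#' @param calibration optional `circ_calibration`
#' @param ... unused
#' @return tibble with `id` (when present in `newdata`), per-fold
#'   `raw_1..raw_k` and `fractile_1..fractile_k`, `mean_fractile`, and
#'   `fpr` when calibrated
#' @export
predict.circ_ensemble <- function(object, newdata, calibration = NULL, ...) {
  ids <- if (is.data.frame(newdata) && "id" %in% names(newdata)) newdata$id else NULL
  x <- feature_matrix(newdata)
  if (!identical(colnames(x), object$feature_names)) {
    abort("feature columns do not match the ensemble's schema")
  }
  k <- length(object$models)
  raw <- vapply(object$models, forest_scores, numeric(nrow(x)), x = x)
  raw <- matrix(raw, nrow = nrow(x))
  frac <- vapply(seq_len(k), function(f) {
    score_to_fractile(raw[, f], object$val_scores[[f]])
  }, numeric(nrow(x)))
  frac <- matrix(frac, nrow = nrow(x))
  out <- dplyr::bind_cols(
    as_tibble(setNames(as.data.frame(raw), paste0("raw_", seq_len(k)))),
    as_tibble(setNames(as.data.frame(frac), paste0("fractile_", seq_len(k)))),
    tibble(mean_fractile = rowMeans(frac))
  )
  if (!is.null(calibration)) out$fpr <- fpr_lookup(calibration, out$mean_fractile)
  if (!is.null(ids)) out <- dplyr::bind_cols(tibble(id = ids), out)
  out
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a random positive outscores a random negative, with
#' ties counted half.
#'
#' @param scores_pos,scores_neg numeric score vectors for the two classes
#' @return AUC in `[0, 1]`
#' @export
auc_mw <- function(scores_pos, scores_neg) {
  np <- length(scores_pos); nn <- length(scores_neg)
  if (np == 0 || nn == 0) abort("AUC needs scores from both classes")
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Out-of-bag permutation importance of one forest
#'
#' For each tree, the rows left out of its bootstrap sample (out-of-bag)
#' are scored before and after randomly shuffling one feature's values over
#' those rows; the importance of the feature is the increase in
#' misclassification error, averaged over trees. Trees without out-of-bag
#' rows are skipped with a warning.
#'
#' @param fit a `ranger` probability forest trained with `keep.inbag = TRUE`
#' @param x the feature matrix the forest was trained on
#' @param y the matching binary labels
#' @param seed integer seed for the shuffles
#' @return named numeric vector of importance scores, one per feature
#' @export
permutation_importance <- function(fit, x, y, seed = 1L) {
  x <- feature_matrix(x)
  y <- as_label(y)
  if (is.null(fit$inbag.counts)) abort("forest must be trained with keep.inbag = TRUE")
  n_trees <- fit$num.trees
  oob <- purrr::map(fit$inbag.counts, ~ which(.x == 0))
  empty <- lengths(oob) == 0
  if (any(empty)) {
    warn(sprintf("%d trees have no out-of-bag rows and were skipped", sum(empty)))
  }
  trees <- which(!empty)
  # per-tree error on a stacked block matrix: one predict call per variant
  per_tree_err <- function(xblock, block_tree, block_truth) {
    p <- predict(fit, data = as.data.frame(xblock), predict.all = TRUE,
                 num.threads = 1)$predictions
    pos_col <- which(colnames(fit$predictions) == "pos")
    err <- numeric(n_trees)
    for (t in trees) {
      rows <- which(block_tree == t)
      pred <- ifelse(p[rows, pos_col, t] > 0.5, "pos", "neg")
      err[t] <- mean(pred != block_truth[rows])
    }
    err
  }
  block_rows <- unlist(oob[trees])
  block_tree <- rep(trees, lengths(oob[trees]))
  xb <- x[block_rows, , drop = FALSE]
  yb <- as.character(y)[block_rows]
  base_err <- per_tree_err(xb, block_tree, yb)
  p_feat <- ncol(x)
  imp <- withr::with_seed(seed, {
    vapply(seq_len(p_feat), function(j) {
      xs <- xb
      for (t in trees) {
        rows <- which(block_tree == t)
        xs[rows, j] <- xs[rows[sample.int(length(rows))], j]
      }
      mean(per_tree_err(xs, block_tree, yb)[trees] - base_err[trees])
    }, numeric(1))
  })
  setNames(imp, colnames(x))
}
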