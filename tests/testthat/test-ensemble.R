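test_that("cross-validation folds are disjoint, covering and stratified", {
  d <- separable_features(30, seed = 1)
  ens <- train_cv_ensemble(d$x, d$y, n_trees = 30, seed = 2)
  expect_setequal(unique(ens$fold), 1:5)
  expect_length(ens$fold, nrow(d$x))
  for (f in 1:5) {
    expect_true(all(table(d$y[ens$fold == f]) >= 1))  # both classes held out
  }
  expect_equal(lengths(ens$val_scores), unname(table(ens$fold)), ignore_attr = TRUE)
  expect_true(all(vapply(ens$val_scores, function(v) !is.unsorted(v), logical(1))))
  expect_error(train_cv_ensemble(d$x, rep(1, nrow(d$x)), 10, 1), "single class")
})

test_that("separable features give high out-of-fold AUC; shuffled labels do not", {
  d <- separable_features(50, gap = 3, seed = 3)
  ens <- train_cv_ensemble(d$x, d$y, n_trees = 50, seed = 4)
  expect_gte(ens$oof_auc, 0.95)

  y_shuf <- withr::with_seed(5, sample(d$y))
  ens0 <- train_cv_ensemble(d$x, y_shuf, n_trees = 50, seed = 4)
  expect_gte(ens0$oof_auc, 0.4)
  expect_lte(ens0$oof_auc, 0.6)
})

test_that("training is reproducible bit-for-bit under a fixed seed", {
  d <- separable_features(25, seed = 6)
  e1 <- train_cv_ensemble(d$x, d$y, n_trees = 20, seed = 7)
  e2 <- train_cv_ensemble(d$x, d$y, n_trees = 20, seed = 7)
  expect_identical(e1$fold, e2$fold)
  expect_identical(e1$val_scores, e2$val_scores)
  expect_identical(predict(e1, d$x), predict(e2, d$x))
})

test_that("fractile conversion follows the mid-rank tie rule", {
  v <- c(1, 2, 3, 4)
  expect_equal(score_to_fractile(5, v), 1)
  expect_equal(score_to_fractile(2.5, v), 0.5)
  expect_equal(score_to_fractile(2, v), 0.375)   # (1 + 0.5) / 4
  expect_equal(score_to_fractile(0, v), 0)
  expect_equal(score_to_fractile(c(5, 2), v), c(1, 0.375))
  expect_error(score_to_fractile(1, numeric(0)), "empty")
  # monotone: larger scores never get smaller fractiles
  withr::local_seed(8)
  vs <- sort(runif(50))
  q <- sort(runif(30, -0.2, 1.2))
  expect_true(all(diff(score_to_fractile(q, vs)) >= 0))
})

test_that("hand-set validation distributions aggregate to the expected mean fractile", {
  vals <- list(c(1, 2), c(1, 3), c(2, 4), c(0, 1), c(1, 1))
  fr <- vapply(vals, function(v) score_to_fractile(5, v), numeric(1))
  expect_equal(fr, rep(1, 5))
  expect_equal(mean(fr), 1)
  fr2 <- vapply(vals, function(v) score_to_fractile(1, v), numeric(1))
  expect_equal(fr2, c(0.25, 0.25, 0, 0.75, 0.5))
})

test_that("ensemble predictions carry fractiles, bounds and schema checks", {
  d <- separable_features(40, gap = 3, seed = 9)
  ens <- train_cv_ensemble(d$x, d$y, n_trees = 40, seed = 10)
  pred <- predict(ens, d$x)
  expect_true(all(pred$mean_fractile >= 0 & pred$mean_fractile <= 1))
  expect_equal(pred$mean_fractile,
               rowMeans(as.matrix(pred[paste0("fractile_", 1:5)])))
  # a strongly positive point sits at the top of every fold's distribution
  # (forest scores saturate at 1, so ties keep the fractile just below 1)
  x_extreme <- matrix(c(10, rep(0, ncol(d$x) - 1)), 1,
                      dimnames = list(NULL, colnames(d$x)))
  mf <- predict(ens, x_extreme)$mean_fractile
  expect_gte(mf, max(pred$mean_fractile[d$y == 0]))
  expect_gte(mf, 0.9)
  # and a score strictly above every validation score fractiles to exactly 1
  expect_equal(mean(vapply(ens$val_scores, function(v) score_to_fractile(2, v),
                           numeric(1))), 1)
  bad <- d$x; colnames(bad) <- rev(colnames(bad))
  expect_error(predict(ens, bad), "schema")
})

test_that("FPR calibration tabulates tail fractions with a step lookup", {
  cal <- calibrate_fpr(c(0.1, 0.4, 0.6, 0.9), cutoffs = c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(fpr_lookup(cal, 0.5), 0.5)
  expect_equal(fpr_lookup(cal, 0), 1)
  expect_equal(fpr_lookup(cal, 1.5), 0)
  expect_true(all(diff(cal$fpr) <= 0))
  expect_error(calibrate_fpr(numeric(0)), "negative")

  # lookup at tabulated cutoffs reproduces empirical tail fractions exactly
  withr::local_seed(11)
  neg <- runif(400)
  grid <- seq(0, 1, by = 0.05)
  cal2 <- calibrate_fpr(neg, grid)
  expect_equal(fpr_lookup(cal2, grid),
               vapply(grid, function(t) mean(neg >= t), numeric(1)))
})

test_that("AUC follows the Mann-Whitney pair-counting definition", {
  expect_equal(auc_mw(c(0.9, 0.8), c(0.7, 0.1)), 1)
  expect_equal(auc_mw(c(0.8, 0.2), c(0.6, 0.1)), 0.75)
  expect_equal(auc_mw(c(1, 2), c(1, 2)), 0.5)    # ties count half
  expect_error(auc_mw(numeric(0), 1), "both classes")
  withr::local_seed(12)
  sp <- rnorm(80, 1); sn <- rnorm(120)
  expect_equal(auc_mw(sp, sn),
               as.numeric(pROC::auc(pROC::roc(
                 rep(c(1, 0), c(80, 120)), c(sp, sn), quiet = TRUE,
                 direction = "<"))))
})

test_that("tree-count tuning returns a grid member and degenerates correctly", {
  d <- separable_features(25, gap = 1, seed = 13)
  expect_equal(tune_num_trees(d$x, d$y, grid = 30, seed = 1), 30)
  best <- tune_num_trees(d$x, d$y, grid = c(10, 40), seed = 2)
  expect_true(best %in% c(10, 40))
})

test_that("permutation importance recovers planted signal and zeroes constants", {
  withr::local_seed(14)
  n <- 150
  x <- matrix(runif(n * 12), n, 12, dimnames = list(NULL, paste0("f", 1:12)))
  x[, 12] <- 0.5                                  # constant feature
  y <- as.integer(x[, 4] > 0.5)
  fit <- ranger::ranger(x = as.data.frame(x),
                        y = factor(ifelse(y == 1, "pos", "neg"),
                                   levels = c("neg", "pos")),
                        num.trees = 40, probability = TRUE, keep.inbag = TRUE,
                        seed = 1, num.threads = 1)
  imp <- permutation_importance(fit, x, y, seed = 2)
  expect_length(imp, 12)
  expect_equal(names(which.max(imp)), "f4")
  expect_equal(unname(imp["f12"]), 0)
  expect_identical(imp, permutation_importance(fit, x, y, seed = 2))
})
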