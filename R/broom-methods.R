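# broom-style accessors and ggplot2 autoplot methods for fitted objects.

#' Tidy a trained circRNA-potential model
#'
#' One row per schema feature with the normalization bounds learned from
#' training data; graph features additionally carry the impurity importance
#' from the graph-feature ranking forest.
#'
#' @param x a `circ_model`
#' @param ... unused
#' @return a tibble with `feature`, `group`, `norm_min`, `norm_max`,
#'   `rank_importance`
#' @export
tidy.circ_model <- function(x, ...) {
  out <- tibble(feature = x$schema$name, group = x$schema$group,
                norm_min = unname(x$normalizer$min),
                norm_max = unname(x$normalizer$max),
                rank_importance = NA_real_)
  if (!is.null(x$graph_index)) {
    gnames <- paste0("graph_", x$graph_index$selected_ids)
    out$rank_importance[match(gnames, out$feature)] <- x$graph_index$importance
  }
  out
}

#' Glance at a trained circRNA-potential model
#'
#' @param x a `circ_model`
#' @param ... unused
#' @return a one-row tibble with the model role, profile, feature count,
#'   tree count, cross-validated out-of-fold AUC, training size and seed
#' @export
glance.circ_model <- function(x, ...) {
  tibble(model = x$model_name, profile = x$profile,
         n_features = nrow(x$schema), n_trees = x$n_trees,
         cv_auc = x$cv_auc, n_train = x$n_train, seed = x$seed)
}

#' Tidy a calibration table
#'
#' @param x a `circ_calibration`
#' @param ... unused
#' @return a tibble with `cutoff` and `fpr`
#' @export
tidy.circ_calibration <- function(x, ...) {
  tibble(cutoff = x$cutoff, fpr = x$fpr)
}

#' Plot an FPR calibration table
#'
#' Step plot of the estimated false positive rate as a function of the
#' mean-fractile cutoff.
#'
#' @param object a `circ_calibration`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.circ_calibration <- function(object, ...) {
  ggplot2::ggplot(tidy.circ_calibration(object),
                  ggplot2::aes(x = .data$cutoff, y = .data$fpr)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "mean-fractile cutoff", y = "estimated FPR") +
    ggplot2::theme_minimal()
}

#' Plot the out-of-fold ROC curve of a trained model
#'
#' @param object a `circ_model`
#' @param ... unused
#' @return a ggplot of the ROC curve built from out-of-fold scores, with
#'   the AUC in the subtitle
#' @export
autoplot.circ_model <- function(object, ...) {
  ens <- object$ensemble
  s <- ens$oof_scores
  y <- ens$y
  thr <- sort(unique(s), decreasing = TRUE)
  roc <- tibble(
    tpr = vapply(thr, function(t) mean(s[y == "pos"] >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(s[y == "neg"] >= t), numeric(1))
  )
  roc <- dplyr::bind_rows(tibble(tpr = 0, fpr = 0), roc, tibble(tpr = 1, fpr = 1))
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(linetype = "dashed", color = "grey60") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("%s, out-of-fold AUC = %.3f",
                                     object$model_name, object$cv_auc)) +
    ggplot2::theme_minimal()
}

#' Plot the top-ranked features of an importance table
#'
#' @param importance tibble from [circ_feature_importance()]
#' @param top_n number of features to show
#' @return a ggplot bar chart, highest importance on top
#' @export
plot_importance <- function(importance, top_n = 10L) {
  d <- utils::head(dplyr::arrange(importance, dplyr::desc(.data$importance)), top_n)
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$importance, y = .data$feature,
                                  fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "OOB permutation importance", y = NULL, fill = "group") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
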