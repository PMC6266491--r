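# End-to-end train/predict workflow: feature assembly -> graph-feature
# selection -> tree-count tuning -> CV ensemble -> FPR calibration, and the
# matching prediction surface. The three shipped model roles mirror the
# classifiers CP-PCG (circRNA potential of protein-coding genes),
# CP-lncRNA (of lncRNAs) and SP-circRNA (stem-cell expression of circRNAs).

.model_roles <- c("cp-pcg" = "pcg_circRNA",
                  "cp-lncrna" = "lncRNA_circRNA",
                  "sp-circrna" = "stem_cell_circRNA")

#' Train a circRNA-potential classifier
#'
#' Runs the full training pipeline on a labeled transcript tibble: graph
#' features are ranked on a (seeded) class-balanced subset and the Top-K
#' kept; the profile's features are assembled and min-max normalized; the
#' tree count is tuned by five-fold cross-validated AUC (or fixed); a
#' five-fold forest ensemble is trained; and an FPR calibration table is
#' estimated from negative mean-fractile scores.
#'
#' @param records transcript tibble with `sequence` and a binary `label`
#'   column (1 = positive); intervals required for `profile = "all"`
#' @param model_name one of `"cp-pcg"`, `"cp-lncrna"`, `"sp-circrna"`
#' @param profile feature profile, see [schema_features()]
#' @param annotations [annotation_bundle()] for `profile = "all"`
#' @param top_k graph features to keep (default 101)
#' @param n_trees `"auto"` (tune over `tree_grid`) or a fixed tree count
#' @param tree_grid candidate tree counts for tuning
#' @param graph [graph_params()] for the encoder
#' @param rank_subset per-class cap on the sequences used for graph-feature
#'   ranking (default 1747)
#' @param cal_records optional held-out negative transcripts for FPR
#'   calibration; when `NULL` the training negatives are scored through the
#'   predict path instead (slightly optimistic)
#' @param cal_annotations annotation bundle for `cal_records` (defaults to
#'   `annotations`)
#' @param seed integer seed controlling every random choice
#' @return a `circ_model` bundling the graph index, normalizer, ensemble,
#'   calibration table and training report
#' @export
circ_train <- function(records,
                       model_name = c("cp-pcg", "cp-lncrna", "sp-circrna"),
                       profile = c("sequence_only", "all", "gc_len"),
                       annotations = NULL, top_k = 101L, n_trees = "auto",
                       tree_grid = seq(10L, 100L, by = 10L),
                       graph = graph_params(), rank_subset = 1747L,
                       cal_records = NULL, cal_annotations = annotations,
                       seed = 1L) {
  model_name <- match.arg(model_name)
  profile <- match.arg(profile)
  validate_records(records)
  if (!"label" %in% names(records)) abort("training records need a `label` column")
  y <- as_label(records$label)
  if (dplyr::n_distinct(y) < 2) abort("training labels contain a single class")

  graph_index <- NULL
  if (profile != "gc_len") {
    pos <- records$sequence[y == "pos"]
    neg <- records$sequence[y == "neg"]
    withr::with_seed(derive_seed(seed, 101L), {
      if (length(pos) > rank_subset) pos <- sample(pos, rank_subset)
      if (length(neg) > rank_subset) neg <- sample(neg, rank_subset)
    })
    graph_index <- rank_graph_features(pos, neg, params = graph, top_k = top_k,
                                       seed = derive_seed(seed, 102L))
  }
  feats <- assemble_features(records, profile, graph_index, annotations)
  normalizer <- fit_normalizer(feats)
  xn <- apply_normalizer(feats, normalizer)
  if (identical(n_trees, "auto")) {
    n_trees <- tune_num_trees(xn, y, grid = tree_grid, seed = derive_seed(seed, 103L))
  }
  ensemble <- train_cv_ensemble(xn, y, n_trees = n_trees,
                                seed = derive_seed(seed, 104L))
  model <- structure(list(
    model_name = model_name, role = unname(.model_roles[model_name]),
    profile = profile, graph_index = graph_index, normalizer = normalizer,
    schema = schema_features(profile, graph_index),
    ensemble = ensemble, calibration = NULL,
    n_trees = as.integer(n_trees), cv_auc = ensemble$oof_auc,
    n_train = nrow(records), seed = as.integer(seed), version = "1"
  ), class = "circ_model")
  neg_mf <- if (!is.null(cal_records)) {
    circ_predict(cal_records, model, annotations = cal_annotations)$mean_fractile
  } else {
    predict(ensemble, xn)$mean_fractile[y == "neg"]
  }
  model$calibration <- calibrate_fpr(neg_mf)
  model
}

#' @export
print.circ_model <- function(x, ...) {
  cat(sprintf("<circ_model %s (%s profile): %d features, %d trees, CV AUC %.3f>\n",
              x$model_name, x$profile, nrow(x$schema), x$n_trees, x$cv_auc))
  invisible(x)
}

#' Score transcripts with one or more trained models
#'
#' Assembles each model's feature profile for the input records, scores
#' them with the model's CV ensemble, and reports the mean fractile (also
#' as an integer percentage, the display convention) and the calibrated
#' FPR. With several models the score/FPR column pairs appear in the fixed
#' role order `pcg_circRNA`, `lncRNA_circRNA`, `stem_cell_circRNA`.
#'
#' @param records transcript tibble (or interval tibble plus `genome`)
#' @param models a `circ_model` or list of them
#' @param annotations [annotation_bundle()] if any model uses profile
#'   `"all"`
#' @param genome optional genome (path or named vector) to fill sequences
#'   for interval-only records
#' @return a tibble with `id`, `position` (when intervals are present) and
#'   per model `<role>_score` (percent) and `<role>_fpr`; the underlying
#'   `mean_fractile` is kept for single-model calls
#' @export
circ_predict <- function(records, models, annotations = NULL, genome = NULL) {
  if (inherits(models, "circ_model")) models <- list(models)
  if (!"sequence" %in% names(records)) {
    if (is.null(genome)) abort("interval records need a genome to extract sequences")
    records <- bed_to_sequences(records, genome)
  }
  validate_records(records)
  out <- tibble(id = records$id)
  if (all(c("chrom", "start", "end") %in% names(records))) {
    out$position <- sprintf("%s:%d-%d", records$chrom, records$start, records$end)
  }
  roles <- vapply(models, function(m) m$role, character(1))
  ord <- order(match(roles, unname(.model_roles)))
  models <- models[ord]
  single <- length(models) == 1
  for (m in models) {
    feats <- assemble_features(records, m$profile, m$graph_index, annotations)
    xn <- apply_normalizer(feats, m$normalizer)
    pred <- predict(m$ensemble, xn, calibration = m$calibration)
    if (single) out$mean_fractile <- pred$mean_fractile
    out[[paste0(m$role, "_score")]] <- as.integer(round(100 * pred$mean_fractile))
    out[[paste0(m$role, "_fpr")]] <-
      if ("fpr" %in% names(pred)) pred$fpr else NA_real_
  }
  out
}

#' Write predictions as a TSV table
#'
#' Scores are written as percentages (e.g. `72%`) next to their estimated
#' FPR, one row per input transcript.
#'
#' @param predictions tibble from [circ_predict()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_predictions <- function(predictions, path) {
  out <- predictions
  out$mean_fractile <- NULL
  for (cn in grep("_score$", names(out), value = TRUE)) {
    out[[cn]] <- sprintf("%d%%", out[[cn]])
  }
  for (cn in grep("_fpr$", names(out), value = TRUE)) {
    out[[cn]] <- sprintf("%.3f", out[[cn]])
  }
  lines <- c(paste(names(out), collapse = "\t"),
             do.call(paste, c(out, sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Evaluate a model on labeled transcripts
#'
#' @param model a `circ_model`
#' @param records labeled transcript tibble
#' @param annotations [annotation_bundle()] if the model needs one
#' @return one-row tibble with `auc`, `n_pos`, `n_neg`
#' @export
circ_evaluate <- function(model, records, annotations = NULL) {
  if (!"label" %in% names(records)) abort("evaluation records need a `label` column")
  pred <- circ_predict(records, model, annotations = annotations)
  y <- as_label(records$label)
  tibble(model = model$model_name,
         auc = auc_mw(pred$mean_fractile[y == "pos"],
                      pred$mean_fractile[y == "neg"]),
         n_pos = sum(y == "pos"), n_neg = sum(y == "neg"))
}

#' Save / load a trained model archive
#'
#' The archive bundles the schema, normalizer bounds, graph-feature index,
#' the five fold forests with their validation score distributions, and the
#' calibration table, with a format version tag.
#'
#' @param model a `circ_model`
#' @param path archive path (`.rds`)
#' @return `path` invisibly; `circ_load_model()` returns the model
#' @export
circ_save_model <- function(model, path) {
  stopifnot(inherits(model, "circ_model"))
  saveRDS(model, path, version = 2)
  invisible(path)
}

#' @rdname circ_save_model
#' @export
circ_load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "circ_model")) abort("not a circ_model archive")
  model
}

#' Out-of-bag permutation importance of a trained model's features
#'
#' Averages [permutation_importance()] over the five fold forests, each
#' evaluated on its own training rows' out-of-bag samples.
#'
#' @param model a `circ_model`
#' @param records the training transcripts (with labels)
#' @param annotations [annotation_bundle()] if the model needs one
#' @param seed integer seed for the shuffles
#' @return tibble with `feature`, `group`, `importance`, sorted by
#'   decreasing importance
#' @export
circ_feature_importance <- function(model, records, annotations = NULL, seed = 1L) {
  feats <- assemble_features(records, model$profile, model$graph_index, annotations)
  xn <- feature_matrix(apply_normalizer(feats, model$normalizer))
  y <- as_label(records$label)
  ens <- model$ensemble
  imps <- purrr::imap(ens$models, function(fit, f) {
    tr <- ens$fold != f
    permutation_importance(fit, xn[tr, , drop = FALSE], y[tr],
                           seed = derive_seed(seed, f))
  })
  imp <- Reduce(`+`, imps) / length(imps)
  dplyr::arrange(
    tibble(feature = names(imp),
           group = model$schema$group[match(names(imp), model$schema$name)],
           importance = unname(imp)),
    dplyr::desc(.data$importance)
  )
}
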