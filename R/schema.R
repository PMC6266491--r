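# Feature schema, min-max normalization and feature assembly. The full
# profile has 178 features: 70 basic + 101 graph + 2 conservation + 5 other.

#' Bundle annotation tracks for feature extraction
#'
#' @param conservation a bedgraph `circ_track` of per-base conservation
#'   scores
#' @param repeats a bed `circ_track` (or tibble with `chrom`, `start`,
#'   `end`, `name`) of repeat annotations; ALU elements are recognized by a
#'   case-insensitive `ALU` prefix of the name
#' @param variants a vcf `circ_track` (or tibble with `chrom`, `pos`) of
#'   variant positions
#' @return an `annotation_bundle`
#' @export
annotation_bundle <- function(conservation = NULL, repeats = NULL, variants = NULL) {
  get_data <- function(x) if (inherits(x, "circ_track")) x$data else x
  structure(list(conservation = conservation,
                 repeats = get_data(repeats),
                 variants = get_data(variants)),
            class = "annotation_bundle")
}

other_feature_names <- function() {
  c("alu_fraction", "tandem_fraction", "orf_length", "orf_prop", "snp_density")
}

conservation_feature_names <- function() c("cons_mean", "cons_sd")

#' Feature names of a profile, in canonical schema order
#'
#' Profiles mirror the feature-set comparisons used to probe what drives
#' performance: `"gc_len"` is the minimal GC-content + length baseline,
#' `"sequence_only"` adds everything derivable from the primary sequence
#' (70 basic + selected graph features), and `"all"` appends the external
#' conservation (2) and annotation (5) features for 178 in total when
#' `top_k = 101`.
#'
#' @param profile one of `"gc_len"`, `"sequence_only"`, `"all"`
#' @param graph_index a `graph_index` (required unless `profile = "gc_len"`)
#' @return tibble with columns `name` and `group`
#' @export
schema_features <- function(profile = c("all", "sequence_only", "gc_len"),
                            graph_index = NULL) {
  profile <- match.arg(profile)
  if (profile == "gc_len") {
    return(tibble(name = c("gc_content", "length"), group = "basic"))
  }
  if (is.null(graph_index)) {
    abort("graph features: a graph_index is required for this profile")
  }
  out <- dplyr::bind_rows(
    tibble(name = basic_feature_names(), group = "basic"),
    tibble(name = paste0("graph_", graph_index$selected_ids), group = "graph")
  )
  if (profile == "all") {
    out <- dplyr::bind_rows(
      out,
      tibble(name = conservation_feature_names(), group = "conservation"),
      tibble(name = other_feature_names(), group = "other")
    )
  }
  out
}

#' Fit per-feature min-max normalization bounds
#'
#' Records the per-column minimum and maximum of a training feature matrix.
#' Constant columns get `max = min` and are mapped to 0 when applied.
#'
#' @param x numeric matrix or feature tibble (an `id` column is ignored)
#' @return a `circ_normalizer` with `min` and `max` vectors
#' @export
fit_normalizer <- function(x) {
  x <- feature_matrix(x)
  if (nrow(x) < 2) abort("normalization needs at least 2 training rows")
  if (!all(is.finite(x))) abort("feature matrix contains non-finite values")
  structure(list(min = apply(x, 2, min), max = apply(x, 2, max)),
            class = "circ_normalizer")
}

#' Apply fitted min-max normalization
#'
#' Maps each feature to `(v - min) / (max - min)` using the training
#' bounds, clipping out-of-range test values into `[0, 1]`; constant
#' training features map to 0.
#'
#' @param x numeric matrix or feature tibble conforming to the normalizer
#' @param normalizer a `circ_normalizer` from [fit_normalizer()]
#' @return object of the same shape with all values in `[0, 1]`
#' @export
apply_normalizer <- function(x, normalizer) {
  stopifnot(inherits(normalizer, "circ_normalizer"))
  ids <- if (is.data.frame(x) && "id" %in% names(x)) x$id else NULL
  m <- feature_matrix(x)
  if (ncol(m) != length(normalizer$min)) {
    abort(sprintf("feature/normalizer length mismatch: %d vs %d",
                  ncol(m), length(normalizer$min)))
  }
  rng <- normalizer$max - normalizer$min
  out <- sweep(m, 2, normalizer$min)
  out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/")
  out[, rng == 0] <- 0
  out <- pmin(pmax(out, 0), 1)
  if (is.null(ids)) out else dplyr::bind_cols(tibble(id = ids), as_tibble(out))
}

# Strip an id column and coerce a feature tibble to a numeric matrix.
feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    x <- as.data.frame(x)
    x <- as.matrix(x[, setdiff(names(x), "id"), drop = FALSE])
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  storage.mode(x) <- "double"
  x
}

#' Assemble the feature tibble for a set of transcripts
#'
#' Computes, per record and in canonical schema order, the features of the
#' requested profile. Conservation, ALU and SNP features require genomic
#' intervals plus the matching annotation tracks; sequence-only inputs
#' (plain FASTA) therefore support the `"gc_len"` and `"sequence_only"`
#' profiles.
#'
#' @param records transcript tibble with `sequence` (and interval columns
#'   for `profile = "all"`)
#' @param profile one of `"all"`, `"sequence_only"`, `"gc_len"`
#' @param graph_index `graph_index` from [rank_graph_features()] (required
#'   unless `profile = "gc_len"`)
#' @param annotations an [annotation_bundle()] (required for
#'   `profile = "all"`)
#' @return tibble with `id` plus one column per schema feature (raw,
#'   unnormalized values)
#' @export
assemble_features <- function(records, profile = c("all", "sequence_only", "gc_len"),
                              graph_index = NULL, annotations = NULL) {
  profile <- match.arg(profile)
  validate_records(records)
  if (profile == "gc_len") {
    return(tibble(id = records$id,
                  gc_content = vapply(records$sequence, gc_content, numeric(1),
                                      USE.NAMES = FALSE),
                  length = nchar(records$sequence)))
  }
  basic <- t(vapply(records$sequence, basic_features,
                    numeric(70), USE.NAMES = FALSE))
  colnames(basic) <- basic_feature_names()
  if (is.null(graph_index)) {
    abort("graph features: a graph_index is required for this profile")
  }
  graph <- graph_feature_matrix(records$sequence, graph_index)
  out <- cbind(basic, graph)
  if (profile == "all") {
    if (is.null(annotations) || !inherits(annotations, "annotation_bundle")) {
      abort("annotation features: an annotation_bundle is required for profile 'all'")
    }
    if (is.null(annotations$conservation)) {
      abort("conservation features: the bundle has no conservation track")
    }
    validate_records(records, need_interval = TRUE)
    alu <- annotations$repeats
    if (!is.null(alu)) {
      alu <- alu[stringr::str_detect(alu$name, stringr::regex("^ALU",
                                                              ignore_case = TRUE)), ,
                 drop = FALSE]
    }
    ann <- t(vapply(seq_len(nrow(records)), function(i) {
      r <- records[i, ]
      scores <- track_query(annotations$conservation, r$chrom, r$start, r$end)
      c(conservation_stats(scores),
        alu_fraction = interval_overlap_fraction(r$chrom, r$start, r$end, alu),
        tandem_fraction = tandem_repeat_fraction(r$sequence),
        longest_orf(r$sequence),
        snp_density = snp_density(r$chrom, r$start, r$end, annotations$variants))
    }, numeric(7)))
    colnames(ann) <- c(conservation_feature_names(), other_feature_names())
    # reorder "other" block to schema order (alu, tandem, orf_length, orf_prop, snp)
    out <- cbind(out, ann)
  }
  expected <- schema_features(profile, graph_index)$name
  out <- out[, expected, drop = FALSE]
  dplyr::bind_cols(tibble(id = records$id), as_tibble(out))
}
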