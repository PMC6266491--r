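# Hashed neighborhood-pair (NSPDK-style) graph features on the sequence
# path graph. Each transcript is viewed as a labeled path graph (one node
# per nucleotide, backbone edges between neighbors, no secondary-structure
# edges). For every radius r <= R and every unordered pair of roots at
# backbone distance d <= D, the pair of rooted radius-r neighborhoods is
# canonicalized and hashed into a fixed-dimension count vector.
#
# A radius-r neighborhood is emitted only when the full ball fits inside
# the sequence (no boundary truncation). This keeps the encoding
# shift-covariant: the feature multiset of any subsequence is contained in
# that of every supersequence.

#' Default graph-feature encoding parameters
#'
#' @param radius maximum neighborhood radius R (nt)
#' @param distance maximum backbone distance D between roots (nt)
#' @param hash_dim dimension of the hashed feature space
#' @param hash_seed seed of the string hash (part of the feature definition:
#'   changing it relabels features)
#' @return a `graph_params` list
#' @export
graph_params <- function(radius = 2L, distance = 4L, hash_dim = 32768L,
                         hash_seed = 42L) {
  stopifnot(radius >= 0, distance >= 1, hash_dim >= 64)
  structure(list(radius = as.integer(radius), distance = as.integer(distance),
                 hash_dim = as.integer(hash_dim), hash_seed = as.integer(hash_seed)),
            class = "graph_params")
}

.hash_m <- 2147483647   # 2^31 - 1
.hash_m2 <- 1048573     # neighborhood hashes are folded below this prior to pairing

#' Deterministic polynomial string hash
#'
#' Non-cryptographic, seedable rolling hash used to map canonical
#' neighborhood keys into the feature space; collisions are accepted as in
#' standard hashed-kernel encodings.
#'
#' @param x character vector of keys
#' @param seed integer hash seed
#' @return numeric vector of hash values in `[0, 2^31 - 1)`
#' @export
hash_string <- function(x, seed = 42L) {
  vapply(x, function(s) {
    h <- seed %% .hash_m
    for (c in utf8ToInt(s)) h <- (h * 131 + c) %% .hash_m
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# Combine radius, distance and the two (sorted) neighborhood hashes into a
# feature id in [0, hash_dim). All arithmetic stays below 2^53.
hash_pair <- function(r, d, h1, h2, hash_dim) {
  lo <- pmin(h1, h2) %% .hash_m2
  hi <- pmax(h1, h2) %% .hash_m2
  k <- ((r * 131 + d) * .hash_m2 + lo) %% .hash_m
  k <- (k * 8191 + hi) %% .hash_m
  k %% hash_dim
}

# Canonical key of the radius-r neighborhood rooted at each position.
# The neighborhood of a path graph is a path with the root marked; its only
# non-trivial automorphism is the reflection about the root, so the
# canonical form is (root label, sorted pair of outward-read arms). Roots
# whose ball does not fit return NA.
neighborhood_hashes <- function(sequence, r, seed) {
  n <- nchar(sequence)
  out <- rep(NA_real_, n)
  if (n < 2 * r + 1) return(out)
  pos <- (r + 1):(n - r)
  root <- substring(sequence, pos, pos)
  if (r == 0) {
    keys <- paste0("0|", root, "||")
  } else {
    rev_seq <- intToUtf8(rev(utf8ToInt(sequence)))
    right <- substring(sequence, pos + 1, pos + r)
    left <- substring(rev_seq, n - pos + 2, n - pos + r + 1)  # outward-read left arm
    keys <- paste0(r, "|", root, "|", pmin(left, right), "|", pmax(left, right))
  }
  uk <- unique(keys)
  out[pos] <- hash_string(uk, seed)[match(keys, uk)]
  out
}

#' Encode a sequence as hashed neighborhood-pair graph features
#'
#' @param sequence nucleotide string
#' @param params a [graph_params()] list
#' @return a tibble with columns `id` (feature id in `[0, hash_dim)`) and
#'   `count`, sorted by id; only nonzero features are listed
#' @examples
#' encode_graph_features("ACGT", graph_params(radius = 1, distance = 2,
#'                                            hash_dim = 1024))
#' @export
encode_graph_features <- function(sequence, params = graph_params()) {
  stopifnot(inherits(params, "graph_params"), nzchar(sequence))
  n <- nchar(sequence)
  ids <- numeric(0)
  for (r in 0:params$radius) {
    h <- neighborhood_hashes(sequence, r, params$hash_seed)
    ok <- which(!is.na(h))
    if (length(ok) == 0) next
    for (d in 0:min(params$distance, n - 1)) {
      i <- ok[ok + d <= n]
      i <- i[!is.na(h[i + d])]
      if (length(i) == 0) next
      ids <- c(ids, hash_pair(r, d, h[i], h[i + d], params$hash_dim))
    }
  }
  uid <- sort(unique(ids))
  tibble(id = uid, count = as.numeric(tabulate(match(ids, uid), nbins = length(uid))))
}

# Sparse n x hash_dim count matrix for a set of sequences.
encode_graph_matrix <- function(sequences, params) {
  enc <- purrr::map(sequences, encode_graph_features, params = params)
  Matrix::sparseMatrix(
    i = rep(seq_along(enc), vapply(enc, nrow, integer(1))),
    j = unlist(purrr::map(enc, "id")) + 1,
    x = unlist(purrr::map(enc, "count")),
    dims = c(length(sequences), params$hash_dim)
  )
}

#' Rank hashed graph features and select the Top-K
#'
#' Encodes positive and negative sequence sets, fits a random forest on the
#' hashed count features, ranks features by the forest's impurity importance
#' and returns the `top_k` highest-ranked feature ids (ties broken toward
#' the lower id). The default of 101 selected features follows the
#' observation that Top-50/101/200 perform near-identically downstream.
#'
#' @param pos,neg character vectors of sequences for the two classes
#' @param params a [graph_params()] list
#' @param top_k number of features to keep (default 101)
#' @param seed integer seed; the result is reproducible bit-for-bit
#' @param num_trees trees in the ranking forest
#' @return a `graph_index` object: `selected_ids` (0-based, ordered by
#'   non-increasing importance), `importance`, and the encoding `params`
#' @export
rank_graph_features <- function(pos, neg, params = graph_params(),
                                top_k = 101L, seed = 1L, num_trees = 100L) {
  if (length(pos) == 0 || length(neg) == 0) abort("both classes must be non-empty")
  X <- encode_graph_matrix(c(pos, neg), params)
  nonzero <- which(Matrix::colSums(X) > 0)
  if (top_k > length(nonzero)) {
    abort(sprintf("top_k = %d exceeds the %d nonzero graph features present",
                  top_k, length(nonzero)))
  }
  y <- factor(rep(c("pos", "neg"), c(length(pos), length(neg))),
              levels = c("neg", "pos"))
  Xnz <- as.matrix(X[, nonzero, drop = FALSE])
  colnames(Xnz) <- paste0("g", nonzero)
  fit <- ranger::ranger(x = Xnz, y = y, num.trees = num_trees,
                        importance = "impurity", seed = seed, num.threads = 1)
  imp <- fit$variable.importance
  ord <- order(-imp, nonzero)               # ties -> lower feature id
  sel <- ord[seq_len(top_k)]
  structure(list(selected_ids = nonzero[sel] - 1,
                 importance = unname(imp[sel]),
                 params = params),
            class = "graph_index")
}

#' @export
print.graph_index <- function(x, ...) {
  cat(sprintf("<graph_index: %d features, R=%d D=%d dim=%d>\n",
              length(x$selected_ids), x$params$radius, x$params$distance,
              x$params$hash_dim))
  invisible(x)
}

#' Serialize / restore a graph-feature index as JSON
#'
#' The JSON carries the encoding parameters (radius, distance, hash
#' dimension, hash seed), the selected feature ids and their importances,
#' so an index can be shared between runs and tools.
#'
#' @param index a `graph_index`
#' @param path JSON file path
#' @return `path` invisibly; `read_graph_index()` returns the index
#' @export
write_graph_index <- function(index, path) {
  stopifnot(inherits(index, "graph_index"))
  jsonlite::write_json(
    list(params = unclass(index$params), selected_ids = index$selected_ids,
         importance = index$importance),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_graph_index
#' @export
read_graph_index <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(selected_ids = as.numeric(x$selected_ids),
                 importance = as.numeric(x$importance),
                 params = do.call(graph_params, as.list(x$params))),
            class = "graph_index")
}

# Dense K-column matrix of selected graph-feature counts for sequences.
graph_feature_matrix <- function(sequences, index) {
  stopifnot(inherits(index, "graph_index"))
  X <- encode_graph_matrix(sequences, index$params)
  out <- as.matrix(X[, index$selected_ids + 1, drop = FALSE])
  colnames(out) <- paste0("graph_", index$selected_ids)
  out
}
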