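# Brute-force reference implementations used to verify the package's
# feature computations. These deliberately use the simplest possible
# character-level loops, independent of the vectorized production code.

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

oracle_gc <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  sum(ch %in% c("G", "C")) / sum(ch %in% c("A", "C", "G", "T"))
}

oracle_trinuc <- function(seq) {
  kmers <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                             c("A","C","G","T"))[, 3:1], 1, paste, collapse = "")
  ch <- strsplit(seq, "")[[1]]
  counts <- setNames(numeric(64), kmers)
  denom <- 0
  for (i in seq_len(length(ch) - 2)) {
    w <- paste(ch[i:(i + 2)], collapse = "")
    if (!grepl("N", w)) {
      denom <- denom + 1
      counts[w] <- counts[w] + 1
    }
  }
  out <- if (denom > 0) counts / denom else counts
  setNames(out, paste0("freq_", kmers))
}

oracle_motifs <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  out <- numeric(4)
  motifs <- c("AG", "GT", "GTAG", "AGGT")
  for (m in seq_along(motifs)) {
    w <- nchar(motifs[m])
    hits <- 0; denom <- 0
    for (i in seq_len(length(ch) - w + 1)) {
      win <- paste(ch[i:(i + w - 1)], collapse = "")
      if (!grepl("N", win)) {
        denom <- denom + 1
        if (win == motifs[m]) hits <- hits + 1
      }
    }
    out[m] <- if (denom > 0) hits / denom else 0
  }
  setNames(out, paste0("motif_", motifs))
}

oracle_orf <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  best <- 0
  for (start in seq_len(max(0, n - 5))) {
    if (paste(ch[start:(start + 2)], collapse = "") != "ATG") next
    p <- start + 3
    while (p + 2 <= n) {
      codon <- paste(ch[p:(p + 2)], collapse = "")
      if (codon %in% c("TAA", "TAG", "TGA")) {
        best <- max(best, p + 2 - start + 1)
        break
      }
      p <- p + 3
    }
  }
  c(orf_length = best, orf_prop = best / n)
}

oracle_tandem <- function(seq, max_period = 12, min_copies = 2, min_span = 6) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  covered <- logical(n)
  for (p in seq_len(min(max_period, n - 1))) {
    for (start in seq_len(n - p)) {
      # extend exact matches at lag p from this start
      stop <- start
      while (stop + p <= n && ch[stop] == ch[stop + p]) stop <- stop + 1
      span <- stop - start + p
      if (stop > start && span >= min_copies * p && span >= min_span) {
        covered[start:(start + span - 1)] <- TRUE
      }
    }
  }
  mean(covered)
}

oracle_cons <- function(values) {
  x <- values[!is.na(values)]
  m <- sum(x) / length(x)
  v <- sum((x - m)^2) / length(x)
  c(cons_mean = m, cons_sd = sqrt(v))
}

oracle_cover_fraction <- function(start, end, features) {
  bases <- logical(end - start)
  if (nrow(features)) {
    for (i in seq_len(nrow(features))) {
      for (b in seq.int(start, end - 1)) {
        if (b >= features$start[i] && b < features$end[i]) bases[b - start + 1] <- TRUE
      }
    }
  }
  mean(bases)
}

oracle_bedgraph_query <- function(track_data, chrom, start, end) {
  # naive per-base dictionary
  vals <- rep(NA_real_, end - start)
  for (i in seq_len(nrow(track_data))) {
    if (track_data$chrom[i] != chrom) next
    for (b in seq.int(track_data$start[i], track_data$end[i] - 1)) {
      if (b >= start && b < end) vals[b - start + 1] <- track_data$value[i]
    }
  }
  vals
}

# --- graph-feature enumeration oracle -------------------------------------
# Explicitly walks the path graph: for each unordered root pair within
# distance D and each radius r whose full ball fits, extracts both rooted
# neighborhoods by stepping along edges, canonicalizes (root label + sorted
# outward arms) and hashes with the package's string hash. The pair
# combiner replicates the documented feature-id arithmetic.

oracle_pair_id <- function(r, d, h1, h2, hash_dim) {
  m <- 2147483647; m2 <- 1048573
  lo <- min(h1, h2) %% m2
  hi <- max(h1, h2) %% m2
  k <- ((r * 131 + d) * m2 + lo) %% m
  k <- (k * 8191 + hi) %% m
  k %% hash_dim
}

oracle_graph_features <- function(seq, params) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  nbr_hash <- function(i, r) {
    if (i - r < 1 || i + r > n) return(NA_real_)
    left <- if (r > 0) paste(ch[(i - 1):(i - r)], collapse = "") else ""
    right <- if (r > 0) paste(ch[(i + 1):(i + r)], collapse = "") else ""
    key <- paste0(r, "|", ch[i], "|", min(left, right), "|", max(left, right))
    hash_string(key, params$hash_seed)
  }
  ids <- numeric(0)
  for (r in 0:params$radius) {
    for (i in seq_len(n)) {
      for (j in i:min(n, i + params$distance)) {
        h1 <- nbr_hash(i, r); h2 <- nbr_hash(j, r)
        if (is.na(h1) || is.na(h2)) next
        ids <- c(ids, oracle_pair_id(r, j - i, h1, h2, params$hash_dim))
      }
    }
  }
  tab <- table(ids)
  out <- data.frame(id = as.numeric(names(tab)), count = as.numeric(tab))
  out[order(out$id), ]
}

# Toy feature matrix with one linearly separable dimension plus noise.
separable_features <- function(n_per_class, p_noise = 10, gap = 2, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(2 * n_per_class * (p_noise + 1)), 2 * n_per_class)
    y <- rep(c(1L, 0L), each = n_per_class)
    x[, 1] <- x[, 1] + gap * y
    colnames(x) <- paste0("f", seq_len(ncol(x)))
    list(x = x, y = y)
  })
}
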