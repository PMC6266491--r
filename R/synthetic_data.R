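# Synthetic labeled sequence datasets with controllable class signal, so
# every pipeline stage is testable without genome downloads. Signal
# channels deliberately touch every feature group: GC/motif composition
# drives the basic and graph features, a conservation mean shift drives the
# conservation features, and class-dependent ALU density drives the "other"
# features; variant positions carry no class signal.

#' Configuration of the synthetic dataset generator
#'
#' Defaults define the package's reference simulation: 500 transcripts per
#' class of 200-1000 nt (all above the 200 nt dataset filter), a planted
#' `GTAG` backsplice-like motif at 2.0 vs 0.5 expected copies per 100 nt,
#' base GC probability 0.55 vs 0.45, a mild conservation shift and a
#' doubled ALU rate in positives.
#'
#' @param n_pos,n_neg transcripts per class
#' @param length_range_pos,length_range_neg min/max transcript length (nt)
#' @param motif planted motif (default `"GTAG"`)
#' @param motif_rate_pos,motif_rate_neg expected planted motifs per 100 nt
#' @param gc_pos,gc_neg per-base GC probability of the background
#' @param alu_prob probability that a positive transcript carries an ALU
#'   annotation (negatives get half)
#' @param variant_rate expected variants per base (class-independent)
#' @param conservation_shift added to the positive class's mean
#'   conservation score
#' @param seed integer seed; a fixed seed reproduces the dataset exactly
#' @return a `synthetic_config` list
#' @export
synthetic_config <- function(n_pos = 500L, n_neg = 500L,
                             length_range_pos = c(200L, 1000L),
                             length_range_neg = c(200L, 1000L),
                             motif = "GTAG",
                             motif_rate_pos = 2.0, motif_rate_neg = 0.5,
                             gc_pos = 0.55, gc_neg = 0.45,
                             alu_prob = 0.3, variant_rate = 0.005,
                             conservation_shift = 0.5, seed = 1L) {
  stopifnot(n_pos >= 0, n_neg >= 0,
            motif_rate_pos >= 0, motif_rate_neg >= 0,
            gc_pos > 0, gc_pos < 1, gc_neg > 0, gc_neg < 1,
            alu_prob >= 0, alu_prob <= 1, variant_rate >= 0,
            length_range_pos[1] >= 5, length_range_neg[1] >= 5)
  structure(as.list(environment()), class = "synthetic_config")
}

random_sequence <- function(len, gc) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

plant_motifs <- function(sequence, motif, rate_per_100) {
  len <- nchar(sequence)
  w <- nchar(motif)
  if (len < w) return(sequence)
  k <- rpois(1, rate_per_100 * len / 100)
  if (k == 0) return(sequence)
  at <- sample.int(len - w + 1, min(k, len - w + 1), replace = FALSE)
  for (p in at) substr(sequence, p, p + w - 1) <- motif
  sequence
}

#' Generate a labeled synthetic classification dataset
#'
#' Draws class-specific background sequences (i.i.d. per-base with class GC
#' bias), plants Poisson-distributed motif copies at class rates, places
#' every transcript on a toy multi-chromosome genome (random strand, so BED
#' extraction is exercised), and generates annotation tracks: a segmented
#' conservation track with a class mean shift, ALU repeat intervals at
#' class-dependent density (plus non-ALU decoys), and uniform,
#' class-independent variant positions.
#'
#' @param config a [synthetic_config()]
#' @return a list with `records` (transcript tibble, `label` 1 = positive),
#'   `annotations` (an [annotation_bundle()]) and `genome` (named character
#'   vector of chromosome sequences)
#' @export
generate_classification_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_dataset_impl(config))
}

#' Generate a null dataset with no class signal
#'
#' Both classes are drawn from the positive class's distribution (GC, motif
#' rate, lengths, annotation rates), so the labels carry no information;
#' used for type-I-error / AUC-near-0.5 checks.
#'
#' @param config a [synthetic_config()]
#' @return same structure as [generate_classification_dataset()]
#' @export
generate_null_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  null_cfg <- config
  null_cfg$motif_rate_neg <- config$motif_rate_pos
  null_cfg$gc_neg <- config$gc_pos
  null_cfg$length_range_neg <- config$length_range_pos
  null_cfg$conservation_shift <- 0
  null_cfg$alu_prob_neg_scale <- 1
  withr::with_seed(config$seed, generate_dataset_impl(null_cfg))
}

generate_dataset_impl <- function(config) {
  n <- config$n_pos + config$n_neg
  label <- rep(c(1L, 0L), c(config$n_pos, config$n_neg))
  neg_alu_scale <- config$alu_prob_neg_scale %||% 0.5
  if (n == 0) {
    return(list(records = tibble(id = character(), sequence = character(),
                                 chrom = character(), start = integer(),
                                 end = integer(), strand = character(),
                                 label = integer()),
                annotations = annotation_bundle(),
                genome = character()))
  }
  lens <- integer(n); seqs <- character(n)
  for (i in seq_len(n)) {
    rng <- if (label[i] == 1) config$length_range_pos else config$length_range_neg
    gc <- if (label[i] == 1) config$gc_pos else config$gc_neg
    rate <- if (label[i] == 1) config$motif_rate_pos else config$motif_rate_neg
    lens[i] <- sample(rng[1]:rng[2], 1)
    seqs[i] <- plant_motifs(random_sequence(lens[i], gc), config$motif, rate)
  }
  # lay transcripts onto a toy genome (4 chromosomes, 50 nt random spacers)
  n_chrom <- min(4L, n)
  chrom <- paste0("chr", rep_len(seq_len(n_chrom), n))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  start <- integer(n); end <- integer(n)
  pieces <- setNames(vector("list", n_chrom), paste0("chr", seq_len(n_chrom)))
  offset <- setNames(integer(n_chrom), names(pieces))
  for (i in seq_len(n)) {
    cc <- chrom[i]
    spacer <- random_sequence(50L, 0.5)
    start[i] <- offset[cc] + 50L
    end[i] <- start[i] + lens[i]
    pieces[[cc]] <- c(pieces[[cc]], spacer,
                      if (strand[i] == "+") seqs[i] else revcomp(seqs[i]))
    offset[cc] <- end[i]
  }
  genome <- vapply(pieces, paste, character(1), collapse = "")
  records <- tibble(id = sprintf("tx%04d", seq_len(n)), sequence = seqs,
                    chrom = chrom, start = start, end = end, strand = strand,
                    label = label)
  # conservation: ~50 nt segments over each transcript, class mean shift
  cons <- purrr::map_dfr(seq_len(n), function(i) {
    brk <- unique(c(seq(start[i], end[i], by = 50L), end[i]))
    mu <- if (label[i] == 1) config$conservation_shift else 0
    tibble(chrom = chrom[i], start = brk[-length(brk)], end = brk[-1],
           value = round(rnorm(length(brk) - 1, mean = mu, sd = 1), 4))
  })
  # repeats: ALU intervals at class-dependent rate, plus non-ALU decoys
  reps <- purrr::map_dfr(seq_len(n), function(i) {
    p_alu <- config$alu_prob * (if (label[i] == 1) 1 else neg_alu_scale)
    out <- NULL
    if (runif(1) < p_alu && lens[i] >= 60) {
      w <- min(300L, max(30L, as.integer(lens[i] / 3)))
      s <- start[i] + sample.int(max(1L, lens[i] - w), 1) - 1L
      out <- tibble(chrom = chrom[i], start = s, end = s + w, name = "AluY")
    }
    if (runif(1) < 0.1 && lens[i] >= 60) {
      s <- start[i] + sample.int(lens[i] - 30L, 1) - 1L
      out <- dplyr::bind_rows(out, tibble(chrom = chrom[i], start = s,
                                          end = s + 30L, name = "L1"))
    }
    out
  })
  if (is.null(reps) || nrow(reps) == 0) {
    reps <- tibble(chrom = character(), start = numeric(), end = numeric(),
                   name = character())
  }
  # variants: uniform over each transcript, class-independent
  vars <- purrr::map_dfr(seq_len(n), function(i) {
    k <- rpois(1, config$variant_rate * lens[i])
    if (k == 0) return(NULL)
    tibble(chrom = chrom[i],
           pos = start[i] + sort(sample.int(lens[i], min(k, lens[i]))) - 1)
  })
  if (is.null(vars) || nrow(vars) == 0) {
    vars <- tibble(chrom = character(), pos = numeric())
  }
  list(records = records,
       annotations = annotation_bundle(
         conservation = as_track(cons, "bedgraph"),
         repeats = as_track(reps, "bed"),
         variants = as_track(vars, "vcf")
       ),
       genome = genome)
}

#' Write a synthetic dataset to standard-format files
#'
#' Writes `sequences.fasta`, `intervals.bed` (BED6 with the label in the
#' score column), `genome.fasta`, `conservation.bedgraph`, `repeats.bed`,
#' `variants.vcf` and `labels.tsv` into a directory. Output is
#' byte-identical for identical datasets.
#'
#' @param dataset result of [generate_classification_dataset()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  r <- dataset$records
  write_fasta(r, p("sequences.fasta"))
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", r$chrom, r$start, r$end,
                     r$id, r$label, r$strand), p("intervals.bed"))
  write_fasta(tibble(id = names(dataset$genome), sequence = unname(dataset$genome)),
              p("genome.fasta"))
  ann <- dataset$annotations
  cons <- ann$conservation$data
  writeLines(sprintf("%s\t%d\t%d\t%.4f", cons$chrom, as.integer(cons$start),
                     as.integer(cons$end), cons$value), p("conservation.bedgraph"))
  writeLines(sprintf("%s\t%d\t%d\t%s", ann$repeats$chrom,
                     as.integer(ann$repeats$start), as.integer(ann$repeats$end),
                     ann$repeats$name), p("repeats.bed"))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               sprintf("%s\t%d\t.\tN\tN\t.\t.\t.", ann$variants$chrom,
                       as.integer(ann$variants$pos) + 1L)), p("variants.vcf"))
  writeLines(c("id\tlabel", sprintf("%s\t%d", r$id, r$label)), p("labels.tsv"))
  invisible(dir)
}
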