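# Conservation and "other" features: per-base conservation summaries, ALU
# overlap, tandem-repeat coverage, longest ORF and SNP density.

#' Mean and standard deviation of per-base conservation scores
#'
#' Missing bases (NA, e.g. uncovered positions of the conservation track)
#' are skipped, not zero-filled, since zero is itself a meaningful
#' conservation value. The standard deviation is the population form
#' (divisor n).
#'
#' @param scores numeric vector of per-base scores, NA for missing bases
#' @return named numeric vector `c(cons_mean, cons_sd)`
#' @export
conservation_stats <- function(scores) {
  x <- scores[!is.na(scores)]
  if (length(x) == 0) abort("conservation scores are missing for every base")
  m <- mean(x)
  c(cons_mean = m, cons_sd = sqrt(mean((x - m)^2)))
}

#' Longest open reading frame in the three forward frames
#'
#' Scans the three forward reading frames for `ATG ... {TAA,TAG,TGA}`
#' in-frame; the ORF length includes both the start and the stop codon.
#' Returns 0 when no complete ORF exists. The propensity is the ORF length
#' divided by the sequence length, a standard coding-potential summary for
#' separating protein-coding from noncoding transcripts.
#'
#' @param sequence nucleotide string of length >= 3
#' @return named numeric vector `c(orf_length, orf_prop)`
#' @export
longest_orf <- function(sequence) {
  n <- nchar(sequence)
  if (n < 3) abort("ORF scan needs a sequence of length >= 3")
  best <- 0L
  for (frame in 0:2) {
    starts_at <- seq.int(frame + 1L, n - 2L, by = 3L)
    if (length(starts_at) == 0) next
    codons <- substring(sequence, starts_at, starts_at + 2L)
    atg <- which(codons == "ATG")
    stp <- which(codons %in% c("TAA", "TAG", "TGA"))
    if (length(atg) == 0 || length(stp) == 0) next
    # first in-frame stop at or after each start codon
    nxt <- stp[findInterval(atg - 1L, stp) + 1L]
    ok <- !is.na(nxt)
    if (any(ok)) best <- max(best, (nxt[ok] - atg[ok] + 1L) * 3L)
  }
  c(orf_length = best, orf_prop = best / n)
}

#' Fraction of a sequence covered by exact tandem repeats
#'
#' Finds maximal exact tandem arrays: a period `p <= max_period` repeated in
#' at least `min_copies` consecutive copies (partial trailing copies count
#' toward the span), spanning at least `min_span` bases. Returns the
#' fraction of the sequence covered by the union of all such arrays.
#'
#' @param sequence nucleotide string
#' @param max_period largest repeat unit length considered (nt)
#' @param min_copies minimum number of consecutive copies
#' @param min_span minimum array span (nt)
#' @return a number in `[0, 1]`
#' @examples
#' tandem_repeat_fraction("ACACACAC") # 1
#' tandem_repeat_fraction("ACGT")     # 0
#' @export
tandem_repeat_fraction <- function(sequence, max_period = 12L, min_copies = 2L,
                                   min_span = 6L) {
  n <- nchar(sequence)
  stopifnot(n >= 1, max_period >= 1, min_copies >= 2, min_span >= 1)
  covered <- logical(n)
  ch <- strsplit(sequence, "")[[1]]
  for (p in seq_len(min(max_period, n - 1))) {
    eq <- ch[seq_len(n - p)] == ch[(p + 1):n]
    r <- rle(eq)
    stop_at <- cumsum(r$lengths)
    start_at <- stop_at - r$lengths + 1L
    for (k in which(r$values)) {
      span <- r$lengths[k] + p              # array covers match run plus one period
      if (span >= min_copies * p && span >= min_span) {
        covered[start_at[k]:(stop_at[k] + p)] <- TRUE
      }
    }
  }
  mean(covered)
}

#' Fraction of an interval covered by annotation features
#'
#' Computes the union coverage of all annotation intervals overlapping the
#' query (e.g. the ALU fraction of a transcript from a repeat track).
#'
#' @param chrom,start,end the query interval (0-based half-open)
#' @param features tibble of annotation intervals (`chrom`, `start`, `end`)
#' @return a number in `[0, 1]`; 0 when there are no overlapping features
#' @export
interval_overlap_fraction <- function(chrom, start, end, features) {
  check_intervals(start, end)
  if (is.null(features) || nrow(features) == 0) return(0)
  hit <- features[features$chrom == chrom & features$start < end &
                    features$end > start, , drop = FALSE]
  if (nrow(hit) == 0) return(0)
  s <- pmax(hit$start, start)
  e <- pmin(hit$end, end)
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  covered <- 0
  cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] <= cur_e) cur_e <- max(cur_e, e[i])
    else { covered <- covered + (cur_e - cur_s); cur_s <- s[i]; cur_e <- e[i] }
  }
  covered <- covered + (cur_e - cur_s)
  covered / (end - start)
}

#' Variant density over an interval
#'
#' Number of variant positions falling inside `[start, end)` divided by the
#' interval length.
#'
#' @param chrom,start,end the query interval (0-based half-open)
#' @param variants tibble of variant positions (`chrom`, `pos`, 0-based) or
#'   a numeric vector of positions on `chrom`
#' @return variants per base (in `[0, 1]` when positions are unique)
#' @export
snp_density <- function(chrom, start, end, variants) {
  check_intervals(start, end)
  if (is.null(variants)) return(0)
  pos <- if (is.data.frame(variants)) variants$pos[variants$chrom == chrom]
         else variants
  sum(pos >= start & pos < end) / (end - start)
}
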