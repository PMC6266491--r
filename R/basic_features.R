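# Basic sequence features: length, GC content, the 64 trinucleotide
# frequencies and the four splice-signal motif frequencies (AG, GT, GTAG,
# AGGT). Windows containing N are excluded from both numerator and
# denominator of every frequency.

.trinucs <- do.call(paste0, expand.grid(c("A", "C", "G", "T"),
                                        c("A", "C", "G", "T"),
                                        c("A", "C", "G", "T"))[, 3:1])

.motifs <- c("AG", "GT", "GTAG", "AGGT")

#' GC content of a sequence
#'
#' Fraction of unambiguous bases that are G or C; N bases are excluded from
#' both numerator and denominator.
#'
#' @param sequence nucleotide string over `{A,C,G,T,N}`
#' @return a number in `[0, 1]`
#' @examples
#' gc_content("ATGC")
#' @export
gc_content <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1, nzchar(sequence))
  gc <- stringr::str_count(sequence, "[GC]")
  acgt <- stringr::str_count(sequence, "[ACGT]")
  if (acgt == 0) abort("cannot compute GC content of an all-N sequence")
  gc / acgt
}

#' Overlapping trinucleotide frequencies
#'
#' Counts each of the 64 `A/C/G/T` trinucleotides over all overlapping
#' 3-mer windows and divides by the number of N-free windows (so the 64
#' frequencies sum to 1 for an N-free sequence). Windows containing N are
#' skipped entirely.
#'
#' @param sequence nucleotide string of length >= 3
#' @return named numeric vector of length 64 (`freq_AAA` ... `freq_TTT`,
#'   lexicographic order)
#' @export
trinucleotide_frequencies <- function(sequence) {
  n <- nchar(sequence)
  if (n < 3) abort("trinucleotide frequencies need a sequence of length >= 3")
  windows <- substring(sequence, 1:(n - 2), 3:n)
  hits <- match(windows, .trinucs)          # NA for windows containing N
  denom <- sum(!is.na(hits))
  counts <- tabulate(hits, nbins = 64)
  out <- if (denom > 0) counts / denom else rep(0, 64)
  setNames(out, paste0("freq_", .trinucs))
}

#' Splice-signal motif frequencies (AG, GT, GTAG, AGGT)
#'
#' Overlapping occurrence counts of the four motifs associated with exon
#' junctions and backsplicing, each divided by the number of N-free windows
#' of that motif's length (`length - motif_length + 1` for an N-free
#' sequence).
#'
#' @param sequence nucleotide string of length >= 4
#' @return named numeric vector `c(motif_AG, motif_GT, motif_GTAG, motif_AGGT)`
#' @export
motif_frequencies <- function(sequence) {
  n <- nchar(sequence)
  if (n < 4) abort("motif frequencies need a sequence of length >= 4")
  out <- vapply(.motifs, function(m) {
    w <- nchar(m)
    windows <- substring(sequence, 1:(n - w + 1), w:n)
    valid <- !stringr::str_detect(windows, "N")
    if (!any(valid)) return(0)
    sum(windows[valid] == m) / sum(valid)
  }, numeric(1))
  setNames(out, paste0("motif_", .motifs))
}

#' The 70 basic sequence features of one transcript
#'
#' Concatenates length, the four motif frequencies, GC content and the 64
#' trinucleotide frequencies in the canonical schema order.
#'
#' @param sequence nucleotide string of length >= 4
#' @return named numeric vector of length 70
#' @export
basic_features <- function(sequence) {
  c(length = nchar(sequence),
    motif_frequencies(sequence),
    gc_content = gc_content(sequence),
    trinucleotide_frequencies(sequence))
}

basic_feature_names <- function() {
  c("length", paste0("motif_", .motifs), "gc_content", paste0("freq_", .trinucs))
}
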