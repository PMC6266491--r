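# Internal helpers shared across modules.

# IUPAC nucleotide codes accepted on input; ambiguity codes other than
# A/C/G/T(/U) are collapsed to N so downstream features see {A,C,G,T,N}.
.iupac_chars <- "ACGTUNRYSWKMBDHV"

#' Normalize a raw nucleotide string to the internal {A,C,G,T,N} alphabet
#'
#' Uppercases, maps U to T and collapses IUPAC ambiguity codes to N.
#' @param x character vector of sequences
#' @param what record identifiers used in error messages
#' @return character vector over {A,C,G,T,N}
#' @keywords internal
#' @noRd
normalize_sequence <- function(x, what = seq_along(x)) {
  x <- toupper(x)
  bad <- stringr::str_detect(x, sprintf("[^%s]", .iupac_chars))
  if (any(bad)) {
    abort(sprintf(
      "sequence for record '%s' contains characters outside the IUPAC alphabet",
      what[which(bad)[1]]
    ))
  }
  chartr("URYSWKMBDHV", "TNNNNNNNNNN", x)
}

#' Reverse-complement of sequences over {A,C,G,T,N}
#' @keywords internal
#' @noRd
revcomp <- function(x) {
  vapply(x, function(s) {
    intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", s))))
  }, character(1), USE.NAMES = FALSE)
}

#' Validate a records tibble (id, sequence, optional interval, optional label)
#' @keywords internal
#' @noRd
validate_records <- function(records, need_sequence = TRUE, need_interval = FALSE) {
  if (!is.data.frame(records)) abort("`records` must be a data frame")
  if (!all(c("id") %in% names(records))) abort("`records` must have an `id` column")
  if (anyDuplicated(records$id)) {
    abort(sprintf("duplicate record id '%s'", records$id[duplicated(records$id)][1]))
  }
  if (need_sequence) {
    if (!"sequence" %in% names(records)) abort("`records` must have a `sequence` column")
    if (any(is.na(records$sequence) | !nzchar(records$sequence))) {
      abort("all records must have a non-empty sequence")
    }
  }
  if (need_interval) {
    cols <- c("chrom", "start", "end", "strand")
    if (!all(cols %in% names(records)) || anyNA(records[cols])) {
      abort("records must carry genomic intervals (chrom, start, end, strand)")
    }
    check_intervals(records$start, records$end, records$strand)
  }
  invisible(records)
}

check_intervals <- function(start, end, strand = NULL, where = NULL) {
  bad <- which(start < 0 | start >= end)
  if (length(bad)) {
    loc <- if (is.null(where)) bad[1] else where[bad[1]]
    abort(sprintf("invalid interval at entry %s: need 0 <= start < end", loc))
  }
  if (!is.null(strand) && !all(strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'")
  }
  invisible(TRUE)
}

# Derive a stream of sub-seeds from one user seed, kept within 32-bit range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
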