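#' Read transcript sequences from a FASTA file
#'
#' Reads a (possibly gzipped) multi-record FASTA file into a transcript
#' tibble. Sequences are uppercased, `U` is mapped to `T`, and IUPAC
#' ambiguity codes are collapsed to `N`; record ids are the first
#' whitespace-delimited token of each header line.
#'
#' @param path path to a FASTA file (plain or gzip)
#' @return a tibble with columns `id` and `sequence`, one row per record in
#'   file order
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">tx1 some description", "acgu", ">tx2", "GGTT"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) abort(sprintf("FASTA file '%s' contains no records", path))
  ids <- stringr::str_split_i(names(seqs), "\\s+", 1)
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate FASTA id '%s' in '%s'", ids[duplicated(ids)][1], path))
  }
  out <- tibble(id = ids, sequence = unname(as.character(seqs)))
  if (any(!nzchar(out$sequence))) {
    abort(sprintf("empty sequence for record '%s'", out$id[!nzchar(out$sequence)][1]))
  }
  out$sequence <- normalize_sequence(out$sequence, out$id)
  out
}

#' Write transcript sequences to a FASTA file
#'
#' @param records tibble with `id` and `sequence` columns
#' @param path output path
#' @param width line width for wrapping sequences
#' @return `path`, invisibly
#' @export
write_fasta <- function(records, path, width = 70L) {
  validate_records(records)
  x <- Biostrings::BStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read genomic intervals from a BED file
#'
#' Parses BED (3 to 6 columns, tab-separated, 0-based half-open) into a
#' transcript tibble carrying intervals but no sequence. A missing name
#' column is filled with `chrom:start-end`; a missing strand column defaults
#' to `"+"`.
#'
#' @param path path to a BED file (plain or gzip)
#' @return a tibble with columns `id`, `chrom`, `start`, `end`, `strand`
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") & !startsWith(lines, "#")]
  if (length(lines) == 0) abort(sprintf("BED file '%s' contains no intervals", path))
  fields <- stringr::str_split(lines, "\t")
  n_fields <- lengths(fields)
  if (any(n_fields < 3)) {
    abort(sprintf("malformed BED line %d: fewer than 3 columns", which(n_fields < 3)[1]))
  }
  col <- function(i, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, character(1))
  }
  start <- suppressWarnings(as.numeric(col(2)))
  end <- suppressWarnings(as.numeric(col(3)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) | end != floor(end))
  if (length(bad)) abort(sprintf("malformed BED line %d: non-integer coordinates", bad[1]))
  bad <- which(start < 0 | start >= end)
  if (length(bad)) {
    abort(sprintf("malformed BED line %d: need 0 <= start < end", bad[1]))
  }
  name <- col(4)
  name <- ifelse(is.na(name) | !nzchar(name),
                 sprintf("%s:%d-%d", col(1), as.integer(start), as.integer(end)), name)
  strand <- col(6)
  strand <- ifelse(is.na(strand) | !strand %in% c("+", "-"), "+", strand)
  tibble(
    id = name, chrom = col(1),
    start = as.integer(start), end = as.integer(end), strand = strand
  )
}

#' Read a genome FASTA as a named vector of chromosome sequences
#'
#' @param path path to a genome FASTA
#' @return named character vector, one element per chromosome
#' @export
read_genome <- function(path) {
  g <- read_fasta(path)
  setNames(g$sequence, g$id)
}

#' Extract strand-aware sequences for interval records
#'
#' Fills the `sequence` column of interval records by slicing the supplied
#' genome: plus-strand intervals take `genome[start, end)` directly,
#' minus-strand intervals are reverse-complemented, so every sequence reads
#' 5' to 3' on its own strand.
#'
#' @param records tibble with `chrom`, `start`, `end`, `strand` columns
#'   (e.g. from [read_bed()])
#' @param genome a genome FASTA path or a named character vector of
#'   chromosome sequences
#' @return `records` with a `sequence` column added
#' @export
bed_to_sequences <- function(records, genome) {
  validate_records(records, need_sequence = FALSE, need_interval = TRUE)
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- read_genome(genome)
  }
  missing <- setdiff(unique(records$chrom), names(genome))
  if (length(missing)) {
    abort(sprintf("chromosome '%s' not present in the genome", missing[1]))
  }
  chrom_len <- nchar(genome)[records$chrom]
  oob <- which(records$end > chrom_len)
  if (length(oob)) {
    abort(sprintf("interval for record '%s' extends beyond its chromosome",
                  records$id[oob[1]]))
  }
  seqs <- substring(genome[records$chrom], records$start + 1L, records$end)
  minus <- records$strand == "-"
  seqs[minus] <- revcomp(seqs[minus])
  dplyr::mutate(records, sequence = unname(seqs))
}

#' Filter transcripts by length and genomic exclusion intervals
#'
#' Applies the dataset-construction filters: transcripts shorter than
#' `min_len` nucleotides are removed (length exactly `min_len` is kept), and
#' any record whose interval shares at least one base with an exclusion
#' interval on the same chromosome (strand-agnostic) is removed. Record
#' order is preserved; the result may be empty.
#'
#' @param records transcript tibble; intervals are required only when
#'   `exclusion` is non-empty
#' @param min_len minimum transcript length in nt to keep (default 200)
#' @param exclusion optional tibble of intervals (`chrom`, `start`, `end`) to
#'   exclude by overlap
#' @return the filtered tibble
#' @export
filter_transcripts <- function(records, min_len = 200L, exclusion = NULL) {
  validate_records(records, need_sequence = "sequence" %in% names(records))
  len <- if ("sequence" %in% names(records)) nchar(records$sequence)
         else records$end - records$start
  keep <- len >= min_len
  if (!is.null(exclusion) && nrow(exclusion) > 0) {
    if (!all(c("chrom", "start", "end") %in% names(records))) {
      abort("records need intervals to apply an exclusion filter")
    }
    check_intervals(exclusion$start, exclusion$end)
    overlaps <- vapply(seq_len(nrow(records)), function(i) {
      any(exclusion$chrom == records$chrom[i] &
            exclusion$start < records$end[i] &
            records$start[i] < exclusion$end)
    }, logical(1))
    keep <- keep & !overlaps
  }
  records[keep, , drop = FALSE]
}
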