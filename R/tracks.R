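#' Read an annotation track queryable by genomic interval
#'
#' Supported kinds:
#' * `"bedgraph"`: 4-column bedGraph (`chrom start end value`, 0-based
#'   half-open); queries return per-base values.
#' * `"bed"`: interval features (BED 3-6); queries return overlapping
#'   features.
#' * `"vcf"`: only variant positions are used (CHROM and 1-based POS,
#'   converted to 0-based); queries return positions falling inside the
#'   interval. A plain 2-column `chrom pos` file is also accepted.
#'
#' @param path path to the track file (plain or gzip)
#' @param kind one of `"bedgraph"`, `"bed"`, `"vcf"`
#' @return a `circ_track` object; see [track_query()]
#' @export
read_track <- function(path, kind = c("bedgraph", "bed", "vcf")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")
  idx <- which(keep)
  fields <- stringr::str_split(lines[keep], "[\t ]+")
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), i)))
    if (anyNA(v)) {
      abort(sprintf("malformed %s line %d: bad %s field", kind, idx[which(is.na(v))[1]], what))
    }
    v
  }
  data <- switch(kind,
    bedgraph = {
      if (any(lengths(fields) < 4)) {
        abort(sprintf("malformed bedgraph line %d: need 4 columns",
                      idx[which(lengths(fields) < 4)[1]]))
      }
      tibble(chrom = vapply(fields, `[`, character(1), 1),
             start = num(2, "start"), end = num(3, "end"),
             value = num(4, "value"))
    },
    bed = {
      if (any(lengths(fields) < 3)) {
        abort(sprintf("malformed bed line %d: need 3 columns",
                      idx[which(lengths(fields) < 3)[1]]))
      }
      tibble(chrom = vapply(fields, `[`, character(1), 1),
             start = num(2, "start"), end = num(3, "end"),
             name = vapply(fields, function(f) if (length(f) >= 4) f[4] else ".",
                           character(1)))
    },
    vcf = {
      if (any(lengths(fields) < 2)) {
        abort(sprintf("malformed vcf line %d: need CHROM and POS",
                      idx[which(lengths(fields) < 2)[1]]))
      }
      # VCF POS is 1-based; internal positions are 0-based.
      tibble(chrom = vapply(fields, `[`, character(1), 1),
             pos = num(2, "POS") - 1)
    }
  )
  if (kind %in% c("bedgraph", "bed")) {
    check_intervals(data$start, data$end, where = idx)
  }
  structure(list(kind = kind, data = data), class = "circ_track")
}

#' Build a track object directly from a tibble
#'
#' Convenience constructor used by the synthetic-data generator and tests;
#' equivalent to writing the tibble out and calling [read_track()].
#'
#' @param data tibble in the column layout of [read_track()] for `kind`
#' @param kind one of `"bedgraph"`, `"bed"`, `"vcf"`
#' @return a `circ_track` object
#' @export
as_track <- function(data, kind = c("bedgraph", "bed", "vcf")) {
  kind <- match.arg(kind)
  structure(list(kind = kind, data = as_tibble(data)), class = "circ_track")
}

#' @export
print.circ_track <- function(x, ...) {
  cat(sprintf("<circ_track: %s, %d entries>\n", x$kind, nrow(x$data)))
  invisible(x)
}

#' Query an annotation track over a genomic interval
#'
#' For a bedGraph track, returns the per-base score vector over
#' `[start, end)` with `NA` marking uncovered bases. For a BED track,
#' returns the tibble of features overlapping the interval. For a VCF
#' (positions) track, returns the 0-based positions inside the interval.
#'
#' @param track a `circ_track` from [read_track()] or [as_track()]
#' @param chrom chromosome name
#' @param start,end 0-based half-open interval
#' @return numeric vector (bedgraph), tibble (bed) or numeric positions (vcf)
#' @export
track_query <- function(track, chrom, start, end) {
  stopifnot(inherits(track, "circ_track"))
  check_intervals(start, end)
  d <- track$data
  switch(track$kind,
    bedgraph = {
      vals <- rep(NA_real_, end - start)
      hit <- d[d$chrom == chrom & d$start < end & d$end > start, , drop = FALSE]
      if (nrow(hit)) {
        for (i in seq_len(nrow(hit))) {
          a <- max(hit$start[i], start) - start + 1
          b <- min(hit$end[i], end) - start
          vals[a:b] <- hit$value[i]
        }
      }
      vals
    },
    bed = d[d$chrom == chrom & d$start < end & d$end > start, , drop = FALSE],
    vcf = d$pos[d$chrom == chrom & d$pos >= start & d$pos < end]
  )
}
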