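test_that("FASTA reading normalizes case, RNA alphabet and ambiguity codes", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a some description", "acgu", ">b", "GGRT"), f)
  rec <- read_fasta(f)
  expect_equal(rec$id, c("a", "b"))
  expect_equal(rec$sequence, c("ACGT", "GGNT"))
})

test_that("FASTA reading rejects duplicates, empty files and bad characters", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "GGTT"), f)
  expect_error(read_fasta(f), "duplicate")
  writeLines(character(0), f)
  expect_error(read_fasta(f))
  writeLines(c(">ok", "ACGT", ">bad", "ACXT"), f)
  expect_error(read_fasta(f), "bad")
})

test_that("FASTA write-then-read is the identity on normalized records", {
  withr::local_seed(11)
  rec <- tibble::tibble(
    id = sprintf("s%03d", 1:100),
    sequence = vapply(sample(10:300, 100, replace = TRUE), rand_seq, character(1))
  )
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(rec, f)
  expect_equal(read_fasta(f), rec)
})

test_that("BED parsing handles defaults and reports malformed lines", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t4\ttx1\t0\t+", f)
  expect_equal(read_bed(f),
               tibble::tibble(id = "tx1", chrom = "chr1", start = 0L, end = 4L,
                              strand = "+"))
  writeLines(c("chr1\t0\t4\ttx1\t0\t-", "chr2\t5\t9"), f)
  b <- read_bed(f)
  expect_equal(b$strand, c("-", "+"))          # missing strand defaults to +
  expect_equal(b$id[2], "chr2:5-9")
  writeLines("chr1\t10\t10\tx\t0\t+", f)
  expect_error(read_bed(f), "line 1")
  writeLines(c("chr1\t0\t4\ta\t0\t+", "chr1\t3.5\t9\tb\t0\t+"), f)
  expect_error(read_bed(f), "line 2")
})

test_that("random BED lines round-trip with names preserved", {
  withr::local_seed(5)
  n <- 50
  start <- sample(0:1000, n)
  tab <- tibble::tibble(chrom = sample(paste0("chr", 1:3), n, replace = TRUE),
                        start = start, end = start + sample(1:500, n),
                        id = sprintf("name%02d", 1:n),
                        strand = sample(c("+", "-"), n, replace = TRUE))
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", tab$chrom, tab$start, tab$end,
                     tab$id, tab$strand), f)
  got <- read_bed(f)
  expect_equal(got[c("id", "chrom", "start", "end", "strand")],
               tab[c("id", "chrom", "start", "end", "strand")],
               ignore_attr = TRUE)
})

test_that("interval extraction is strand-aware and validates bounds", {
  genome <- c(chr1 = "ACGTTT")
  rec <- tibble::tibble(id = c("p", "m"), chrom = "chr1", start = 0L, end = 4L,
                        strand = c("+", "-"))
  out <- bed_to_sequences(rec, genome)
  expect_equal(out$sequence, c("ACGT", "ACGT"))   # ACGT is its own revcomp
  expect_equal(nchar(out$sequence), out$end - out$start)

  rec$chrom <- "chrX"
  expect_error(bed_to_sequences(rec, genome), "chrX")
  rec$chrom <- "chr1"; rec$end <- 10L
  expect_error(bed_to_sequences(rec, genome), "beyond")
})

test_that("interval extraction matches an independent slice+revcomp oracle", {
  withr::local_seed(21)
  genome <- c(chr1 = rand_seq(500), chr2 = rand_seq(300))
  n <- 40
  chrom <- sample(names(genome), n, replace = TRUE)
  start <- vapply(chrom, function(cc) sample(0:(nchar(genome[cc]) - 20), 1),
                  numeric(1))
  rec <- tibble::tibble(id = sprintf("r%02d", 1:n), chrom = chrom,
                        start = as.integer(start),
                        end = as.integer(start + sample(1:19, n, replace = TRUE)),
                        strand = sample(c("+", "-"), n, replace = TRUE))
  got <- bed_to_sequences(rec, genome)
  want <- vapply(seq_len(n), function(i) {
    s <- substr(genome[rec$chrom[i]], rec$start[i] + 1, rec$end[i])
    if (rec$strand[i] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    s
  }, character(1))
  expect_equal(got$sequence, unname(want))
})

test_that("transcript filtering keeps the length boundary and drops overlaps", {
  rec <- tibble::tibble(id = c("a", "b", "c"),
                        sequence = vapply(c(150, 200, 250), rand_seq, character(1)))
  expect_equal(filter_transcripts(rec, min_len = 200)$id, c("b", "c"))

  rec2 <- tibble::tibble(id = "x", sequence = rand_seq(200), chrom = "chr1",
                         start = 100L, end = 300L, strand = "+")
  excl <- tibble::tibble(chrom = "chr1", start = 299L, end = 400L)
  expect_equal(nrow(filter_transcripts(rec2, 100, excl)), 0)  # 1-base overlap
  excl$start <- 300L
  expect_equal(nrow(filter_transcripts(rec2, 100, excl)), 1)  # adjacent, kept
})

test_that("exclusion filtering matches a brute-force pairwise check and is idempotent", {
  withr::local_seed(31)
  n <- 60
  start <- sample(0:2000, n)
  rec <- tibble::tibble(id = sprintf("t%02d", 1:n),
                        sequence = vapply(sample(150:400, n, replace = TRUE),
                                          rand_seq, character(1)),
                        chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                        start = start, strand = "+")
  rec$end <- rec$start + nchar(rec$sequence)
  es <- sample(0:2000, 15)
  excl <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 15, replace = TRUE),
                         start = es, end = es + sample(50:300, 15, replace = TRUE))
  got <- filter_transcripts(rec, min_len = 200, exclusion = excl)
  keep <- vapply(seq_len(n), function(i) {
    if (nchar(rec$sequence[i]) < 200) return(FALSE)
    for (j in seq_len(nrow(excl))) {
      if (excl$chrom[j] == rec$chrom[i] &&
          max(rec$start[i], excl$start[j]) < min(rec$end[i], excl$end[j])) {
        return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  expect_equal(got$id, rec$id[keep])
  expect_true(all(got$id %in% rec$id))
  expect_equal(filter_transcripts(got, min_len = 200, exclusion = excl), got)
})

test_that("bedgraph tracks answer per-base queries with missing-value markers", {
  f <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines("chr1\t0\t3\t1.5", f)
  tr <- read_track(f, "bedgraph")
  expect_equal(track_query(tr, "chr1", 0, 3), c(1.5, 1.5, 1.5))
  expect_equal(track_query(tr, "chr1", 2, 5), c(1.5, NA, NA))
  expect_equal(track_query(tr, "chr2", 0, 2), c(NA_real_, NA_real_))
  writeLines("chr1\t0\tthree\t1.5", f)
  expect_error(read_track(f, "bedgraph"), "line 1")
})

test_that("random bedgraph tracks match a naive per-base dictionary oracle", {
  withr::local_seed(41)
  for (rep in 1:5) {
    starts <- sort(sample(0:200, 10)) * 2      # even starts, non-overlapping
    d <- tibble::tibble(chrom = sample(c("c1", "c2"), 10, replace = TRUE),
                        start = starts, end = starts + sample(1:2, 10, replace = TRUE),
                        value = round(runif(10), 3))
    tr <- as_track(d, "bedgraph")
    q0 <- sample(0:300, 1); q1 <- q0 + sample(5:80, 1)
    expect_equal(track_query(tr, "c1", q0, q1),
                 oracle_bedgraph_query(d, "c1", q0, q1))
  }
})

test_that("bed and vcf tracks return overlapping features and contained positions", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t10\t20\tAluY", "chr1\t50\t60\tL1"), f)
  tr <- read_track(f, "bed")
  expect_equal(track_query(tr, "chr1", 15, 55)$name, c("AluY", "L1"))
  expect_equal(nrow(track_query(tr, "chr1", 20, 50)), 0)

  writeLines(c("##fileformat=VCFv4.2", "#CHROM\tPOS", "chr1\t11", "chr1\t100"), f)
  vt <- read_track(f, "vcf")
  expect_equal(track_query(vt, "chr1", 0, 50), 10)  # POS is 1-based
})
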