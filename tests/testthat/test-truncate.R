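hind <- parse_enzyme_spec("A^AGCTT,HindIII")
mbo <- parse_enzyme_spec("^GATC,MboI")

test_that("ligation junctions match the digest/fill-in/ligate construction", {
  # HindIII by hand: digestion leaves ...A / AGCTT..., fill-in copies the
  # AGCT overhang onto each blunt end, ligation joins A+AGCT | AGCT+T
  j <- ligation_junction(hind)
  expect_equal(j$junction, "AAGCTAGCTT")
  expect_equal(j$keep_len_increment, 5L)

  # MboI cuts before GATC: blunt ends GATC|GATC
  j2 <- ligation_junction(mbo)
  expect_equal(j2$junction, "GATCGATC")
  expect_equal(j2$keep_len_increment, 4L)

  # blunt cutter: no overhang, junction is the site itself
  blunt <- parse_enzyme_spec("AGG^CCT,blunt")
  jb <- ligation_junction(blunt)
  expect_equal(jb$junction, "AGGCCT")
  expect_equal(jb$keep_len_increment, 3L)

  # 3' overhang cutters are unsupported
  expect_error(ligation_junction(parse_enzyme_spec("GGTAC^C,KpnI")),
               class = "hicditag_unsupported_enzyme")
})

test_that("reads truncate at the first junction, keeping p + k bases", {
  j <- ligation_junction(hind)
  set.seed(11)
  clean <- gsub("AAGCT", "AACCT", rand_dna(50), fixed = TRUE)
  r <- truncate_read(clean, strrep("F", nchar(clean)), j)
  expect_false(r$truncated)
  expect_equal(r$seq, clean)

  seq <- paste0(substr(clean, 1, 30), "AAGCTAGCTT",
                substr(rand_dna(20), 1, 10))
  qual <- paste(rep(letters[1:10], 5), collapse = "")
  qual <- substr(strrep("ABCDEFGHIJ", 5), 1, nchar(seq))
  r <- truncate_read(seq, qual, j)
  expect_true(r$truncated)
  expect_equal(nchar(r$seq), 35L)
  expect_equal(substr(r$seq, 31, 35), "AAGCT")
  expect_equal(nchar(r$qual), 35L)
  expect_equal(r$qual, substr(qual, 1, 35))

  # read that IS the junction: k bases survive
  r <- truncate_read("AAGCTAGCTT", strrep("I", 10), j)
  expect_true(r$truncated)
  expect_equal(r$seq, "AAGCT")
})

test_that("truncation is idempotent and never lengthens a read", {
  j <- ligation_junction(hind)
  set.seed(12)
  reads <- vapply(1:50, function(i) {
    base <- rand_dna(60)
    if (i %% 2 == 0)
      base <- paste0(substr(base, 1, sample(5:40, 1)), "AAGCTAGCTT",
                     substr(base, 1, 15))
    base
  }, character(1))
  quals <- strrep("I", nchar(reads))
  for (i in seq_along(reads)) {
    r1 <- truncate_read(reads[i], quals[i], j)
    expect_lte(nchar(r1$seq), nchar(reads[i]))
    expect_equal(nchar(r1$seq), nchar(r1$qual))
    r2 <- truncate_read(r1$seq, r1$qual, j)
    expect_false(r2$truncated)
    expect_equal(r2$seq, r1$seq)
  }
})

test_that("junction hits in random sequence occur at the background k-mer rate", {
  j <- ligation_junction(mbo)   # 8-mer: measurable background rate
  set.seed(13)
  n <- 10000L
  len <- 100L
  mat <- matrix(sample(c("A", "C", "G", "T"), n * len, TRUE), nrow = n)
  reads <- apply(mat, 1L, paste, collapse = "")
  hits <- sum(grepl(j$junction, reads, fixed = TRUE))
  p_hit <- 1 - (1 - 0.25^8)^(len - 8 + 1)
  expect_lt(abs(hits - n * p_hit), 5 * sqrt(n * p_hit * (1 - p_hit)) + 1)
})

test_that("paired FASTQ truncation preserves order, ids and qualities", {
  j <- ligation_junction(hind)
  set.seed(14)
  n <- 200L
  mk <- function(withj) {
    seqs <- vapply(seq_len(n), function(i) {
      s <- gsub("AAGCT", "AACCT", rand_dna(70), fixed = TRUE)
      if (withj[i]) s <- paste0(substr(s, 1, 25), "AAGCTAGCTT", substr(s, 36, 60))
      s
    }, character(1))
    list(id = sprintf("rd%04d", seq_len(n)), seq = seqs,
         qual = strrep("I", nchar(seqs)))
  }
  with1 <- seq_len(n) <= 40   # exactly 40 junction-bearing reads in R1
  fq1 <- mk(with1)
  fq2 <- mk(rep(FALSE, n))
  r1 <- tempfile(fileext = ".fastq"); r2 <- tempfile(fileext = ".fastq")
  write_fastq(fq1, r1); write_fastq(fq2, r2)
  o1 <- tempfile(fileext = ".fastq"); o2 <- tempfile(fileext = ".fastq")
  st <- truncate_fastq(r1, r2, j, o1, o2)
  expect_equal(st$r1$reads_truncated, 40L)
  expect_equal(st$r2$reads_truncated, 0L)
  expect_equal(st$r2$fraction_truncated, 0)
  out1 <- read_fastq(o1)
  expect_equal(out1$id, fq1$id)
  expect_equal(nchar(out1$seq), nchar(out1$qual))

  # gzip input gives identical output
  r1gz <- tempfile(fileext = ".fastq.gz")
  write_fastq(fq1, r1gz)
  o1b <- tempfile(fileext = ".fastq")
  truncate_fastq(r1gz, r2, j, o1b, tempfile(fileext = ".fastq"))
  expect_identical(readLines(o1), readLines(o1b))

  # mismatched record counts are a pairing error
  short <- tempfile(fileext = ".fastq")
  write_fastq(lapply(fq2, `[`, 1:10), short)
  expect_error(truncate_fastq(r1, short, j, tempfile(), tempfile()),
               class = "hicditag_pairing_error")

  # malformed FASTQ is a format error
  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@x", "ACGT", "+", "III"), bad)
  expect_error(read_fastq(bad), class = "hicditag_format_error")
})
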