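test_that("enzyme specification strings parse with the caret convention", {
  hind <- parse_enzyme_spec("A^AGCTT,HindIII")
  expect_s3_class(hind, "EnzymeSpec")
  expect_equal(hind$site, "AAGCTT")
  expect_equal(hind$cut_offset, 1L)
  expect_equal(hind$name, "HindIII")

  mbo <- parse_enzyme_spec("^GATC,MboI")
  expect_equal(mbo$site, "GATC")
  expect_equal(mbo$cut_offset, 0L)

  expect_error(parse_enzyme_spec("AAGCTT,HindIII"), class = "hicditag_format_error")
  expect_error(parse_enzyme_spec("A^AG^CTT,X"), class = "hicditag_format_error")
  expect_error(parse_enzyme_spec("A^AGXTT,X"), class = "hicditag_alphabet_error")
  expect_error(parse_enzyme_spec("A^CG,tiny"), class = "hicditag_format_error")
  expect_warning(parse_enzyme_spec("^GACGC,HgaI"), "palindromic")
})

test_that("cut sites match a naive character-scan oracle", {
  hind <- parse_enzyme_spec("A^AGCTT,HindIII")
  mbo <- parse_enzyme_spec("^GATC,MboI")
  hinf <- suppressWarnings(parse_enzyme_spec("G^ANTC,HinfI"))

  expect_equal(find_cut_sites("TTTAAGCTTTTT", hind), 5L)
  expect_equal(find_cut_sites("GATCGATC", mbo), c(1L, 5L))
  expect_equal(find_cut_sites("TTTTTTTT", hind), integer(0))

  set.seed(101)
  for (rep in 1:5) {
    seq <- rand_dna(10000)
    # plant N stretches: must never create a match
    substr(seq, 500, 520) <- strrep("N", 21)
    for (enz in list(hind, mbo, hinf)) {
      expect_equal(find_cut_sites(seq, enz),
                   naive_cut_sites(seq, enz$site, enz$cut_offset),
                   info = enz$name)
    }
  }
})

test_that("digestion tiles each chromosome exactly and counts sites + 1", {
  hind <- parse_enzyme_spec("A^AGCTT,HindIII")

  # no sites: one fragment spanning the chromosome
  set.seed(5)
  plain <- gsub("AAGCTT", "AAGATT", rand_dna(5000), fixed = TRUE)
  map0 <- digest_genome(c(chr = plain), hind)
  expect_equal(nrow(map0$fragments), 1L)
  expect_equal(map0$fragments$start, 1L)
  expect_equal(map0$fragments$end, nchar(plain))

  # single site at a known position
  seq <- plain
  substr(seq, 40, 45) <- "AAGCTT"
  seq <- substr(seq, 1, 100)
  map1 <- digest_genome(c(chr = seq), hind)
  expect_equal(map1$fragments$start, c(1L, 41L))
  expect_equal(map1$fragments$end, c(40L, 100L))

  set.seed(42)
  for (rep in 1:5) {
    genome <- c(a = rand_dna(20000), b = rand_dna(15000))
    map <- digest_genome(genome, hind)
    for (ch in names(genome)) {
      fr <- map$fragments[chrom == ch]
      expect_equal(sum(fr$end - fr$start + 1L), nchar(genome[[ch]]))
      expect_equal(fr$index, seq_len(nrow(fr)))
      expect_equal(nrow(fr), length(find_cut_sites(genome[[ch]], hind)[
        find_cut_sites(genome[[ch]], hind) > 1]) + 1L)
      if (nrow(fr) > 1)
        expect_equal(fr$start[-1], fr$end[-nrow(fr)] + 1L)
    }
  }
})

test_that("adding one non-overlapping site adds exactly one fragment", {
  hind <- parse_enzyme_spec("A^AGCTT,HindIII")
  set.seed(17)
  seq <- gsub("AAGCTT", "AAGATT", rand_dna(8000), fixed = TRUE)
  n0 <- nrow(digest_genome(c(c1 = seq), hind)$fragments)
  substr(seq, 4000, 4005) <- "AAGCTT"
  expect_equal(nrow(digest_genome(c(c1 = seq), hind)$fragments), n0 + 1L)
})

test_that("double digestion attributes boundaries to the creating enzyme", {
  hind <- parse_enzyme_spec("A^AGCTT,HindIII")
  mbo <- parse_enzyme_spec("^GATC,MboI")
  set.seed(23)
  seq <- rand_dna(20000)
  map <- digest_genome(c(chr = seq), hind, mbo)
  cuts1 <- naive_cut_sites(seq, hind$site, hind$cut_offset)
  cuts2 <- naive_cut_sites(seq, mbo$site, mbo$cut_offset)
  internal <- sort(unique(c(cuts1, cuts2)))
  internal <- internal[internal > 1 & internal <= nchar(seq)]
  expect_equal(nrow(map$fragments), length(internal) + 1L)
  fr <- map$fragments
  # a fragment's 5' boundary is re1-created iff its start is a HindIII cut
  expect_equal(fr$re1_end_5p, c(FALSE, fr$start[-1] %in% cuts1))
  expect_equal(fr$re1_end_3p, c((fr$end + 1L)[-nrow(fr)] %in% cuts1, FALSE))
})

test_that("digest maps round-trip through TSV losslessly", {
  hind <- parse_enzyme_spec("A^AGCTT,HindIII")
  mbo <- parse_enzyme_spec("^GATC,MboI")
  set.seed(31)
  map <- digest_genome(c(x = rand_dna(9000), y = rand_dna(4000)), hind, mbo,
                       genome_id = "toyrt")
  path <- tempfile(fileext = ".tsv")
  write_digest(map, path)
  back <- read_digest(path)
  expect_equal(back$genome_id, map$genome_id)
  expect_equal(back$enzyme1$site, map$enzyme1$site)
  expect_equal(back$enzyme2$site, map$enzyme2$site)
  expect_equal(back$chrom_lengths, map$chrom_lengths)
  expect_equal(as.data.frame(back$fragments), as.data.frame(map$fragments))

  # malformed rows are rejected
  lines <- readLines(path)
  row <- strsplit(lines[3], "\t")[[1]]
  row[2:3] <- rev(row[2:3])
  bad <- tempfile(fileext = ".tsv")
  writeLines(c(lines[1:2], paste(row, collapse = "\t"), lines[-(1:3)]), bad)
  expect_error(read_digest(bad), class = "hicditag_format_error")
  expect_error(read_digest(textfile <- {
    f <- tempfile(); writeLines("not a digest", f); f
  }), class = "hicditag_format_error")
})

test_that("a handwritten toy digest file parses to the expected map", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    "# hicditag-digest\tgenome_id=toy3\tre1=A^AGCTT,HindIII\tchrom_lengths=chrZ:300",
    "chrom\tstart\tend\tindex\tre1_end_5p\tre1_end_3p",
    "chrZ\t1\t100\t1\t0\t1",
    "chrZ\t101\t160\t2\t1\t1",
    "chrZ\t161\t300\t3\t1\t0"), f)
  map <- read_digest(f)
  expect_equal(map$genome_id, "toy3")
  expect_equal(map$fragments$start, c(1L, 101L, 161L))
  expect_equal(map$fragments$end, c(100L, 160L, 300L))
  expect_equal(map$chrom_lengths, c(chrZ = 300L))
})
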