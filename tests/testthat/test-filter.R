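test_that("fragment assignment matches a linear-scan oracle", {
  toy <- toy_digest()
  map <- toy$map
  expect_equal(map$fragments$start, c(1L, 101L, 161L))

  # + strand read at position 1 is in fragment 1
  a <- assign_fragment(map, "chrT", 1L, "+", 20L)
  expect_equal(a$frag_index, 1L)
  # - strand read whose 5' base is a fragment end maps to that fragment
  a <- assign_fragment(map, "chrT", 141L, "-", 20L)   # 5' base = 160
  expect_equal(a$frag_index, 2L)
  # boundary starts
  a <- assign_fragment(map, "chrT", 161L, "+", 20L)
  expect_equal(a$frag_index, 3L)

  set.seed(33)
  pos <- sample(280L, 2000L, replace = TRUE)
  strand <- sample(c("+", "-"), 2000L, replace = TRUE)
  res <- assign_fragment(map, rep("chrT", 2000L), pos, strand, 20L)
  fp <- ifelse(strand == "+", pos, pos + 19L)
  oracle <- vapply(fp, function(p) oracle_fragment(map, "chrT", p), integer(1))
  expect_equal(res$frag_index, oracle)

  expect_error(assign_fragment(map, "chrX", 1L, "+", 20L),
               class = "hicditag_reference_mismatch")
  expect_error(assign_fragment(map, "chrT", 290L, "-", 20L),
               class = "hicditag_bounds_error")
})

test_that("theoretical insert size sums per-end distances to the boundary", {
  # symmetric reads starting at the fragment edges of 300 bp fragments
  expect_equal(end_to_boundary("+", 1001L, 1001L, 1300L), 300L)
  expect_equal(end_to_boundary("-", 1300L, 1001L, 1300L), 300L)
  # minimal case: both 5' ends on their ligation-side boundaries
  expect_equal(end_to_boundary("+", 1300L, 1001L, 1300L) +
                 end_to_boundary("-", 2001L, 2001L, 2300L), 2L)
})

test_that("classification agrees with a straight-line rule oracle everywhere", {
  toy <- toy_digest()
  map <- toy$map
  sr <- c(150L, 800L)
  rl <- 20L

  # exhaustive-ish grid over placements of two 20 bp reads on the toy
  # three-fragment chromosome, all strand combinations
  fps <- c(1L, 25L, 81L, 100L, 101L, 120L, 141L, 160L, 161L, 200L, 281L)
  grid <- expand.grid(fp1 = fps, fp2 = fps, s1 = c("+", "-"), s2 = c("+", "-"),
                      stringsAsFactors = FALSE)
  # a 20bp read needs room on its own side
  ok <- with(grid, ifelse(s1 == "+", fp1 <= 281L, fp1 >= 20L) &
                   ifelse(s2 == "+", fp2 <= 281L, fp2 >= 20L))
  grid <- grid[ok, ]
  ditags <- data.table::data.table(
    read_id = sprintf("g%04d", seq_len(nrow(grid))),
    chrom1 = "chrT",
    pos1 = with(grid, ifelse(s1 == "+", fp1, fp1 - rl + 1L)),
    strand1 = grid$s1, len1 = rl,
    chrom2 = "chrT",
    pos2 = with(grid, ifelse(s2 == "+", fp2, fp2 - rl + 1L)),
    strand2 = grid$s2, len2 = rl)
  cls <- classify_ditags(ditags, map, sr)
  oracle <- mapply(oracle_classify,
                   chrom1 = "chrT", fp1 = grid$fp1, strand1 = grid$s1,
                   chrom2 = "chrT", fp2 = grid$fp2, strand2 = grid$s2,
                   MoreArgs = list(map = map, size_range = sr))
  expect_equal(as.character(cls$category), unname(oracle))

  # every di-tag got exactly one category
  expect_false(anyNA(cls$category))

  # permuting input order never changes a di-tag's category
  perm <- sample(nrow(ditags))
  cls2 <- classify_ditags(ditags[perm], map, sr)
  expect_equal(as.character(cls2$category[order(perm)]),
               as.character(cls$category))
})

test_that("trans pairs within the size window are valid", {
  toy <- toy_digest()
  genome2 <- c(toy$genome, chrU = toy$genome[["chrT"]])
  names(genome2) <- c("chrT", "chrU")
  map2 <- digest_genome(genome2, parse_enzyme_spec("A^AGCTT,HindIII"))
  d <- data.table::data.table(read_id = "t1",
                              chrom1 = "chrT", pos1 = 50L, strand1 = "+", len1 = 20L,
                              chrom2 = "chrU", pos2 = 191L, strand2 = "-", len2 = 20L)
  cls <- classify_ditags(d, map2, c(50L, 800L))
  expect_equal(as.character(cls$category), "VALID")
  expect_false(cls$cis)
  # and an undersized trans pair is wrong-size, not contiguous
  d2 <- data.table::copy(d)[, pos2 := 145L]  # dist2 = 4 -> insert 55 < 150
  cls2 <- classify_ditags(d2, map2, c(150L, 800L))
  expect_equal(as.character(cls2$category), "WRONG_SIZE")
})

test_that("filtering conserves counts and preserves order", {
  fix <- sim_fixture()
  filt <- data.table::fread(file.path(fix$run_dir, "filter_stats.tsv"))
  expect_equal(sum(filt$count), fix$res$summary$row$paired)
  planted <- fix$truth[, .N, by = category]
  expect_equal(filt[category == "SAME_CIRCULARISED", count],
               planted[category == "circularised", N])
  expect_equal(filt[category == "VALID", count],
               planted[category %in% c("valid_cis", "valid_trans"), sum(N)])

  # single-category input: everything rejected, count preserved
  toy <- toy_digest()
  circ <- data.table::data.table(
    read_id = paste0("c", 1:5),
    chrom1 = "chrT", pos1 = c(80L, 70L, 60L, 50L, 40L), strand1 = "+", len1 = 20L,
    chrom2 = "chrT", pos2 = c(10L, 12L, 14L, 16L, 18L), strand2 = "-", len2 = 20L)
  res <- filter_ditags(circ, toy$map, c(150L, 800L))
  expect_equal(nrow(res$valid), 0L)
  expect_equal(res$stats$category_counts[["SAME_CIRCULARISED"]], 5L)
  expect_equal(res$stats$pairs_in, 5L)
})

test_that("double-digest checks require cut-site starts and first-enzyme ends", {
  set.seed(44)
  cfg <- sim_config(seed = 44, enzyme2 = "^GATC,MboI",
                    site_spacing = c(150L, 380L),
                    short_site_spacing = c(150L, 380L),
                    chrom_length = 60000L)
  genome <- make_genome(cfg)
  map <- digest_genome(genome, parse_enzyme_spec(cfg$enzyme),
                       parse_enzyme_spec(cfg$enzyme2))
  sim <- simulate_dd_library(genome, map, cfg, n_per_class = 60,
                             out_dir = file.path(tempdir(), "dd_unit"))
  fq1 <- read_fastq(sim$r1)
  fq2 <- read_fastq(sim$r2)
  a1 <- align_builtin_exact(fq1, genome, mate = 1L)
  a2 <- align_builtin_exact(fq2, genome, mate = 2L)
  pr <- pair_reads(a1, a2)
  cls <- classify_ditags(pr$ditags, map, cfg$size_range, mode = "double_digest")
  truth <- sim$truth_dt[match(cls$read_id, read_id)]
  expect_equal(as.character(cls$category) == "VALID",
               truth$dd_class == "compliant")
  expect_true(all(cls$category[truth$dd_class != "compliant"] ==
                  "DOUBLE_DIGEST_INVALID"))
})
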