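test_that("built-in exact aligner agrees with brute-force enumeration", {
  set.seed(21)
  genome <- c(cA = rand_dna(3000), cB = rand_dna(2500))
  # plant a repeated segment across chromosomes
  rep_seg <- substr(genome[["cA"]], 1001, 1050)
  substr(genome[["cB"]], 2001, 2050) <- rep_seg

  reads <- list(
    fwd = substr(genome[["cA"]], 101, 150),
    rev = revcomp(substr(genome[["cB"]], 301, 350)),
    multi = rep_seg,
    multi_rc = revcomp(rep_seg),
    absent = paste0(strrep("ACGT", 12), "GG"),
    short_fwd = substr(genome[["cA"]], 2201, 2240))
  fq <- list(id = names(reads), seq = unlist(reads),
             qual = strrep("I", nchar(unlist(reads))))
  aln <- align_builtin_exact(fq, genome)

  for (i in seq_along(reads)) {
    hits <- oracle_align(fq$seq[i], genome)
    expect_equal(aln$n_hits[i], length(hits), info = fq$id[i])
    expect_equal(aln$status[i],
                 c("unmapped", "unique", "multi")[pmin(length(hits), 2) + 1],
                 info = fq$id[i])
    if (length(hits) == 1L) {
      expect_equal(aln$chrom[i], hits[[1]]$chrom)
      expect_equal(aln$pos[i], hits[[1]]$pos)
      expect_equal(aln$strand[i], hits[[1]]$strand)
    }
  }

  # property check on random planted reads
  set.seed(22)
  for (rep in 1:20) {
    p <- sample(2900, 1)
    s <- substr(genome[["cA"]], p, p + 39)
    if (runif(1) < 0.5) s <- revcomp(s)
    a <- align_builtin_exact(list(id = "r", seq = s, qual = strrep("I", 40)),
                             genome)
    o <- oracle_align(s, genome)
    expect_equal(a$n_hits, length(o))
    if (length(o) == 1L)
      expect_equal(list(a$chrom, a$pos, a$strand),
                   list(o[[1]]$chrom, o[[1]]$pos, o[[1]]$strand))
  }

  # empty input
  empty <- align_builtin_exact(list(id = character(0), seq = character(0),
                                    qual = character(0)), genome)
  expect_equal(nrow(empty), 0L)
})

test_that("uniqueness classification follows the MAPQ / secondary-score rule", {
  sam <- data.table::data.table(
    qname = paste0("q", 1:5),
    flag = c(4L, 0L, 16L, 0L, 0L),
    rname = c("*", "c1", "c1", "c1", "c1"),
    pos = c(0L, 100L, 200L, 300L, 400L),
    mapq = c(0L, 42L, 3L, 42L, 35L),
    cigar = c("*", "50M", "50M", "50M", "50M"),
    seq = "*", qual = "*",
    AS = c(NA, NA, -10L, -5L, -2L),
    XS = c(NA, NA, NA, -5L, -10L))
  expect_equal(classify_uniqueness(sam, "bowtie2"),
               c("unmapped", "unique", "multi", "multi", "unique"))
  expect_equal(classify_uniqueness(sam, "bowtie"),
               c("unmapped", rep("unique", 4)))
})

test_that("SAM round trip recovers alignments and CIGAR reference lengths", {
  expect_equal(hicditag:::cigar_ref_len(c("50M", "10M2D38M", "5S45M", "*")),
               c(50L, 50L, 45L, 0L))
  f <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               "@SQ\tSN:c1\tLN:1000",
               "r1\t0\tc1\t10\t42\t50M\t*\t0\t0\tACGT\tIIII\tAS:i:-3\tXS:i:-9",
               "r2\t16\tc1\t99\t7\t40M\t*\t0\t0\tACGT\tIIII"), f)
  sam <- read_sam(f)
  expect_equal(sam$AS, c(-3L, NA))
  expect_equal(sam$XS, c(-9L, NA))
  aln <- read_sam_alignments(f, mate = 1L)
  expect_equal(aln$status, c("unique", "multi"))
  expect_equal(aln$strand, c("+", NA))
})

test_that("re-pairing keeps both-unique ids and conserves read counts", {
  mk_aln <- function(status, ids, mate) data.table::data.table(
    read_id = ids, mate = mate, status = status,
    chrom = ifelse(status == "unique", "c1", NA_character_),
    pos = ifelse(status == "unique", seq_along(ids) * 100L, NA_integer_),
    strand = ifelse(status == "unique", "+", NA_character_),
    aligned_length = 50L, n_hits = 1L, seq = "A", qual = "I")
  ids <- paste0("p", 1:6)
  a1 <- mk_aln(c("unique", "unique", "unique", "multi", "unmapped", "unique"), ids, 1L)
  a2 <- mk_aln(c("unique", "multi", "unique", "unique", "unique", "unmapped"), ids, 2L)
  pr <- pair_reads(a1, a2)
  expect_equal(pr$stats$pairs_formed, 2L)
  expect_equal(pr$ditags$read_id, c("p1", "p3"))
  with(pr$stats$r1, expect_equal(unique_mapped + multi_mapped + unmapped, reads_in))

  # symmetry: swapping streams swaps ends but preserves the pair set
  pr2 <- pair_reads(a2, a1)
  expect_equal(pr2$stats$pairs_formed, pr$stats$pairs_formed)
  expect_equal(pr2$ditags$read_id, pr$ditags$read_id)
  expect_equal(pr2$ditags$pos1, pr$ditags$pos2)

  expect_error(pair_reads(a1, a2[1:5]), class = "hicditag_pairing_error")
})

test_that("aligner statuses on simulated reads match simulator ground truth", {
  fix <- sim_fixture()
  # reads are error-free genomic sequences: after truncation all must map
  # uniquely, at the planted coordinates
  aln <- align_builtin_exact(file.path(fix$res$out_dir, "trunc_R1.fastq"),
                             fix$genome)
  expect_true(all(aln$status == "unique"))
  tr <- fix$truth[match(aln$read_id, read_id)]
  fp <- ifelse(aln$strand == "+", aln$pos, aln$pos + aln$aligned_length - 1L)
  expect_equal(fp, tr$five_prime1)
  expect_equal(aln$strand, tr$strand1)
  expect_equal(aln$chrom, tr$chrom1)
})
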