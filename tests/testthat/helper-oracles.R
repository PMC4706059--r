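# Independent oracles and shared fixtures. Oracles are deliberately naive
# (character-by-character / linear-scan / scalar rule tables) and share no
# code with the package's implementations.

IUPAC_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

# character-by-character scan with IUPAC expansion; genome N matches nothing
naive_cut_sites <- function(sequence, site, cut_offset) {
  seqc <- strsplit(toupper(sequence), "")[[1]]
  sitec <- strsplit(toupper(site), "")[[1]]
  L <- length(sitec)
  hits <- integer(0)
  for (i in seq_len(length(seqc) - L + 1L)) {
    ok <- TRUE
    for (j in seq_len(L)) {
      if (!(seqc[i + j - 1L] %in% IUPAC_ORACLE[[sitec[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i + cut_offset)
  }
  hits
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# brute-force exact aligner: enumerate every occurrence of the read and its
# reverse complement with fixed-string gregexpr over every chromosome
oracle_align <- function(seq, genome) {
  hits <- list()
  for (ch in names(genome)) {
    for (str in c("+", "-")) {
      pat <- if (str == "+") seq else hicditag::revcomp(seq)
      m <- gregexpr(pat, genome[[ch]], fixed = TRUE)[[1]]
      if (m[1] != -1L)
        for (p in as.integer(m))
          hits[[length(hits) + 1L]] <- list(chrom = ch, pos = p, strand = str)
    }
  }
  hits
}

# linear-scan fragment lookup
oracle_fragment <- function(map, chrom, five_prime) {
  fr <- map$fragments
  for (i in seq_len(nrow(fr))) {
    if (fr$chrom[i] == chrom && fr$start[i] <= five_prime &&
        fr$end[i] >= five_prime) return(fr$index[i])
  }
  NA_integer_
}

# scalar straight-line re-implementation of the classification precedence
oracle_classify <- function(map, chrom1, fp1, strand1, chrom2, fp2, strand2,
                            size_range) {
  fr <- map$fragments
  g1 <- fr[fr$chrom == chrom1 & fr$start <= fp1 & fr$end >= fp1, ]
  g2 <- fr[fr$chrom == chrom2 & fr$start <= fp2 & fr$end >= fp2, ]
  d1 <- if (strand1 == "+") g1$end - fp1 + 1L else fp1 - g1$start + 1L
  d2 <- if (strand2 == "+") g2$end - fp2 + 1L else fp2 - g2$start + 1L
  insert <- d1 + d2
  same_chrom <- chrom1 == chrom2
  opp <- strand1 != strand2
  if (opp) {
    fpp <- if (strand1 == "+") fp1 else fp2
    fpm <- if (strand1 == "-") fp1 else fp2
  } else fpp <- fpm <- NA
  facing <- same_chrom && opp && fpp <= fpm
  away <- same_chrom && opp && fpp > fpm
  if (same_chrom && g1$index == g2$index) {
    if (away) return("SAME_CIRCULARISED")
    if (facing && (fp1 == g1$start || fp1 == g1$end ||
                   fp2 == g2$start || fp2 == g2$end))
      return("SAME_DANGLING")
    return("SAME_INTERNAL")
  }
  if (same_chrom && facing && abs(g1$index - g2$index) == 1L)
    return("RELIGATION")
  if (facing && (fpm - fpp + 1L) >= size_range[1] &&
      (fpm - fpp + 1L) <= size_range[2])
    return("CONTIGUOUS")
  if (insert < size_range[1] || insert > size_range[2]) return("WRONG_SIZE")
  "VALID"
}

# toy genome with HindIII sites at known positions: fragments
# chrT: [1..100], [101..160], [161..300]
toy_digest <- function() {
  set.seed(99)
  seq <- rand_dna(300)
  enz <- parse_enzyme_spec("A^AGCTT,HindIII")
  substr(seq, 100, 105) <- "AAGCTT"   # cut coordinate 101
  substr(seq, 160, 165) <- "AAGCTT"   # cut coordinate 161
  # scrub accidental extra sites
  repeat {
    extra <- setdiff(find_cut_sites(seq, enz), c(101L, 161L))
    if (!length(extra)) break
    p <- extra[1] - enz$cut_offset + 2L
    substr(seq, p, p) <- "C"
  }
  genome <- c(chrT = seq)
  list(genome = genome, map = digest_genome(genome, enz, genome_id = "toy"))
}

# memoised shared simulation so several test files reuse one small library
sim_fixture <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (!is.null(cache$fix)) return(cache$fix)
    dir <- file.path(tempdir(), "hicditag_shared_sim")
    cfg <- sim_config(seed = 7, n_ditags = 800)
    genome <- make_genome(cfg)
    map <- digest_genome(genome, parse_enzyme_spec(cfg$enzyme), genome_id = "sim")
    sim <- simulate_library(genome, map, cfg, dir)
    run_dir <- file.path(tempdir(), "hicditag_shared_run")
    res <- run_pipeline(pipeline_config(
      r1 = sim$r1, r2 = sim$r2, genome = genome, re1 = cfg$enzyme,
      out_dir = run_dir, sample = "shared"))
    cache$fix <- list(cfg = cfg, genome = genome, map = map, sim = sim,
                      truth = sim$truth_dt, run_dir = run_dir, res = res)
    cache$fix
  }
})
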