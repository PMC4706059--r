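# Per-mate alignment and re-pairing into putative di-tags.
#
# Hi-C mates are aligned independently (a valid di-tag is not one contiguous
# genomic sequence) and re-paired afterwards, keeping only read pairs where
# both mates aligned uniquely.

#' Exact built-in aligner
#'
#' Aligns error-free reads by exact substring search of the read and its
#' reverse complement over the genome. A read is `unique` iff it occurs
#' exactly once in total (both strands, all chromosomes), `multi` if more
#' often, `unmapped` if never. This exists so the whole pipeline is testable
#' with zero external dependencies; it is not a general-purpose aligner.
#'
#' Implementation: all genome k-mers (k = shortest read) are indexed once,
#' candidate positions are fetched by the read's leading k-mer (forward and
#' reverse-complement), and candidates are verified by full substring
#' comparison.
#'
#' @param reads FASTQ path or a list as from [read_fastq()].
#' @param genome FASTA path or named character vector.
#' @param mate Mate number (1 or 2) recorded in the output.
#' @return data.table with one row per input read: `read_id`, `mate`,
#'   `status` (`unique`/`multi`/`unmapped`), `chrom`, `pos` (1-based
#'   leftmost), `strand`, `aligned_length`, `n_hits`, `seq`, `qual`.
#'   `chrom`/`pos`/`strand` are from the single hit for unique reads and
#'   `NA` otherwise.
#' @export
align_builtin_exact <- function(reads, genome, mate = 1L) {
  if (is.character(reads)) reads <- read_fastq(reads)
  genome <- as_genome(genome)
  n <- length(reads$seq)
  out <- data.table::data.table(
    read_id = reads$id, mate = as.integer(mate), status = rep("unmapped", n),
    chrom = NA_character_, pos = NA_integer_, strand = NA_character_,
    aligned_length = nchar(reads$seq), n_hits = 0L,
    seq = reads$seq, qual = reads$qual)
  if (n == 0L) return(out[])

  k <- min(nchar(reads$seq))
  # genome k-mer index
  idx <- data.table::rbindlist(lapply(names(genome), function(ch) {
    s <- genome[[ch]]
    np <- nchar(s) - k + 1L
    if (np < 1L) return(NULL)
    data.table::data.table(kmer = substring(s, 1:np, k:(np + k - 1L)),
                           chrom = ch, gpos = 1:np)
  }))
  data.table::setkey(idx, kmer)

  rc <- revcomp(reads$seq)
  queries <- data.table::rbindlist(list(
    data.table::data.table(ri = seq_len(n), strand = "+",
                           kmer = substr(reads$seq, 1L, k), full = reads$seq),
    data.table::data.table(ri = seq_len(n), strand = "-",
                           kmer = substr(rc, 1L, k), full = rc)))
  cand <- idx[queries, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
  if (nrow(cand)) {
    cand[, len := nchar(full)]
    cand <- cand[, ok := substring(genome[chrom], gpos, gpos + len - 1L) == full][ok == TRUE]
  }
  if (nrow(cand)) {
    hits <- cand[, .(n_hits = .N, chrom = chrom[1], pos = gpos[1],
                     strand = strand[1]), by = ri]
    out[hits$ri, `:=`(n_hits = hits$n_hits,
                      status = ifelse(hits$n_hits == 1L, "unique", "multi"))]
    one <- hits[n_hits == 1L]
    out[one$ri, `:=`(chrom = one$chrom, pos = one$pos, strand = one$strand)]
  }
  out[]
}

# Reference-consumed length of a CIGAR string (M/D/N/=/X).
cigar_ref_len <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0L)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- sub("^\\d+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Read a SAM file into a table
#'
#' Minimal text-level SAM parser: header lines are skipped, the mandatory
#' columns are returned together with the `AS`/`XS` integer tags used for
#' uniqueness classification.
#'
#' @param path SAM file path.
#' @return data.table with `qname`, `flag`, `rname`, `pos`, `mapq`, `cigar`,
#'   `seq`, `qual`, `AS`, `XS`.
#' @export
read_sam <- function(path) {
  lines <- read_lines_any(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(data.table::data.table(qname = character(0), flag = integer(0),
                                  rname = character(0), pos = integer(0),
                                  mapq = integer(0), cigar = character(0),
                                  seq = character(0), qual = character(0),
                                  AS = integer(0), XS = integer(0)))
  fields <- data.table::tstrsplit(lines, "\t", fixed = TRUE, keep = 1:11)
  if (length(fields) < 11L || anyNA(fields[[6]]))
    stopf("malformed SAM record in %s", path, class = "hicditag_format_error")
  tag_int <- function(tag) {
    m <- regmatches(lines, regexpr(paste0("\\b", tag, ":i:-?\\d+"), lines))
    v <- rep(NA_integer_, length(lines))
    hit <- grepl(paste0("\\b", tag, ":i:"), lines)
    v[hit] <- as.integer(sub(paste0(tag, ":i:"), "", m))
    v
  }
  data.table::data.table(
    qname = fields[[1]], flag = as.integer(fields[[2]]), rname = fields[[3]],
    pos = as.integer(fields[[4]]), mapq = as.integer(fields[[5]]),
    cigar = fields[[6]], seq = fields[[10]], qual = fields[[11]],
    AS = tag_int("AS"), XS = tag_int("XS"))
}

#' Classify SAM records as unique / multi / unmapped
#'
#' "Unique high-quality" is made precise here (the protocol description
#' leaves it qualitative): in `bowtie2` mode a record is unique iff it is
#' mapped, has `MAPQ >= mapq_min` (default 30), and either carries no
#' secondary-score `XS` tag or its `AS` score is strictly better than `XS`.
#' In `bowtie` mode (aligner invoked with single-best / suppress-multi
#' settings) any reported alignment is unique.
#'
#' @param sam data.table from [read_sam()].
#' @param aligner `"bowtie2"` or `"bowtie"`.
#' @param mapq_min MAPQ threshold for bowtie2 mode.
#' @return Character vector `unique`/`multi`/`unmapped` per record.
#' @export
classify_uniqueness <- function(sam, aligner = c("bowtie2", "bowtie"),
                                mapq_min = 30L) {
  aligner <- match.arg(aligner)
  unmapped <- bitwAnd(sam$flag, 4L) != 0L | sam$rname == "*"
  if (aligner == "bowtie") {
    status <- ifelse(unmapped, "unmapped", "unique")
  } else {
    competitive <- !is.na(sam$XS) & !is.na(sam$AS) & sam$XS >= sam$AS
    uniq <- !unmapped & sam$mapq >= mapq_min & !competitive
    status <- ifelse(unmapped, "unmapped", ifelse(uniq, "unique", "multi"))
  }
  status
}

#' Import single-end SAM alignments as per-mate alignment records
#'
#' Converts primary SAM records into the alignment table used downstream,
#' applying [classify_uniqueness()].
#'
#' @param path SAM path (single-end alignment of one mate file).
#' @param mate Mate number.
#' @inheritParams classify_uniqueness
#' @return data.table in the same shape as [align_builtin_exact()] output.
#' @export
read_sam_alignments <- function(path, mate = 1L, aligner = "bowtie2",
                                mapq_min = 30L) {
  sam <- read_sam(path)
  sam <- sam[bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L]
  status <- classify_uniqueness(sam, aligner, mapq_min)
  data.table::data.table(
    read_id = sam$qname, mate = as.integer(mate), status = status,
    chrom = ifelse(status == "unique", sam$rname, NA_character_),
    pos = ifelse(status == "unique", sam$pos, NA_integer_),
    strand = ifelse(status == "unique",
                    ifelse(bitwAnd(sam$flag, 16L) != 0L, "-", "+"),
                    NA_character_),
    aligned_length = cigar_ref_len(sam$cigar),
    n_hits = NA_integer_, seq = sam$seq, qual = sam$qual)
}

#' Align a mate file with an external aligner
#'
#' Thin subprocess contract to bowtie/bowtie2, invoked in single-end mode so
#' mates are aligned independently. The full command line is logged. This is
#' optional plumbing: the built-in exact aligner covers all synthetic data.
#'
#' @param fastq_path Truncated FASTQ for one mate.
#' @param index_prefix Aligner index prefix.
#' @param out_sam Output SAM path.
#' @param aligner `"bowtie2"` or `"bowtie"`.
#' @param threads Aligner threads.
#' @return `out_sam`, invisibly.
#' @export
align_external <- function(fastq_path, index_prefix, out_sam,
                           aligner = c("bowtie2", "bowtie"), threads = 1L) {
  aligner <- match.arg(aligner)
  exe <- Sys.which(aligner)
  if (exe == "")
    stopf("%s not found on PATH; install it or use aligner = 'builtin'",
          aligner, class = "hicditag_dependency_error")
  args <- if (aligner == "bowtie2") {
    c("-x", index_prefix, "-U", fastq_path, "-S", out_sam,
      "-p", as.character(threads), "--no-unal")
  } else {
    c("-S", "--best", "-m", "1", "-p", as.character(threads),
      index_prefix, fastq_path, out_sam)
  }
  message("running: ", exe, " ", paste(args, collapse = " "))
  code <- system2(exe, args)
  if (code != 0L)
    stopf("%s exited with status %d", aligner, code,
          class = "hicditag_subprocess_error")
  invisible(out_sam)
}

#' Re-pair independently aligned mates into putative di-tags
#'
#' Emits a di-tag for every read id whose both mates aligned uniquely, and
#' counts every read in exactly one of unique/multi/unmapped.
#'
#' @param aln1,aln2 Per-mate alignment tables (FASTQ order), as from
#'   [align_builtin_exact()] or [read_sam_alignments()].
#' @return List with `ditags` (data.table: `read_id`, then `chrom1`, `pos1`,
#'   `strand1`, `len1`, `seq1`, `qual1` and the mate-2 equivalents) and
#'   `stats`, a per-mate `MappingStats` table plus `pairs_formed`.
#' @export
pair_reads <- function(aln1, aln2) {
  if (nrow(aln1) != nrow(aln2) || !setequal(aln1$read_id, aln2$read_id))
    stopf("mate alignment streams carry different read ids",
          class = "hicditag_pairing_error")
  mstats <- function(a) {
    list(reads_in = nrow(a),
         unique_mapped = sum(a$status == "unique"),
         multi_mapped = sum(a$status == "multi"),
         unmapped = sum(a$status == "unmapped"))
  }
  a2 <- aln2[match(aln1$read_id, aln2$read_id)]
  both <- aln1$status == "unique" & a2$status == "unique"
  ditags <- data.table::data.table(
    read_id = aln1$read_id[both],
    chrom1 = aln1$chrom[both], pos1 = aln1$pos[both],
    strand1 = aln1$strand[both], len1 = aln1$aligned_length[both],
    seq1 = aln1$seq[both], qual1 = aln1$qual[both],
    chrom2 = a2$chrom[both], pos2 = a2$pos[both],
    strand2 = a2$strand[both], len2 = a2$aligned_length[both],
    seq2 = a2$seq[both], qual2 = a2$qual[both])
  list(ditags = ditags,
       stats = list(r1 = mstats(aln1), r2 = mstats(aln2),
                    pairs_in = nrow(aln1), pairs_formed = nrow(ditags)))
}
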