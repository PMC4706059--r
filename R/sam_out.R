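# SAM emission of filtered di-tags: mates of one di-tag on adjacent lines.

#' Write di-tags as SAM with mates on adjacent lines
#'
#' Emits one SAM record per mate, read pairs of a di-tag on adjacent lines,
#' with paired-end FLAG bits (paired, mate strand, first/second in pair)
#' set. Alignments are ungapped (`<len>M` CIGAR).
#'
#' @param ditags Di-tag table (from [pair_reads()]/[classify_ditags()]).
#' @param chrom_lengths Named integer vector for the `@SQ` header lines.
#' @param path Output SAM path.
#' @param sample Read-group style sample label written in the header.
#' @return `path`, invisibly.
#' @export
write_ditag_sam <- function(ditags, chrom_lengths, path, sample = "sample") {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths), chrom_lengths),
           sprintf("@PG\tID:hicditag\tPN:hicditag\tSM:%s", sample))
  n <- nrow(ditags)
  if (n == 0L) {
    write_lines_any(hdr, path)
    return(invisible(path))
  }
  flag1 <- 1L + 64L + ifelse(ditags$strand1 == "-", 16L, 0L) +
    ifelse(ditags$strand2 == "-", 32L, 0L)
  flag2 <- 1L + 128L + ifelse(ditags$strand2 == "-", 16L, 0L) +
    ifelse(ditags$strand1 == "-", 32L, 0L)
  seq1 <- if ("seq1" %in% names(ditags)) ditags$seq1 else "*"
  qual1 <- if ("qual1" %in% names(ditags)) ditags$qual1 else "*"
  seq2 <- if ("seq2" %in% names(ditags)) ditags$seq2 else "*"
  qual2 <- if ("qual2" %in% names(ditags)) ditags$qual2 else "*"
  rec1 <- sprintf("%s\t%d\t%s\t%d\t42\t%dM\t%s\t%d\t0\t%s\t%s",
                  ditags$read_id, flag1, ditags$chrom1, ditags$pos1,
                  ditags$len1, ditags$chrom2, ditags$pos2, seq1, qual1)
  rec2 <- sprintf("%s\t%d\t%s\t%d\t42\t%dM\t%s\t%d\t0\t%s\t%s",
                  ditags$read_id, flag2, ditags$chrom2, ditags$pos2,
                  ditags$len2, ditags$chrom1, ditags$pos1, seq2, qual2)
  body <- character(2L * n)
  body[seq(1L, 2L * n, by = 2L)] <- rec1
  body[seq(2L, 2L * n, by = 2L)] <- rec2
  write_lines_any(c(hdr, body), path)
  invisible(path)
}

#' Read adjacent-line paired SAM back into a di-tag table
#'
#' Inverse of [write_ditag_sam()] for round-tripping filtered/deduplicated
#' output.
#'
#' @param path SAM path written by [write_ditag_sam()].
#' @return data.table with `read_id`, per-end `chrom`, `pos`, `strand`,
#'   `len`, `seq`, `qual` and derived `five_prime1/2`.
#' @export
read_ditag_sam <- function(path) {
  sam <- read_sam(path)
  first <- bitwAnd(sam$flag, 64L) != 0L
  s1 <- sam[first]
  s2 <- sam[!first][match(s1$qname, sam[!first]$qname)]
  d <- data.table::data.table(
    read_id = s1$qname,
    chrom1 = s1$rname, pos1 = s1$pos,
    strand1 = ifelse(bitwAnd(s1$flag, 16L) != 0L, "-", "+"),
    len1 = cigar_ref_len(s1$cigar), seq1 = s1$seq, qual1 = s1$qual,
    chrom2 = s2$rname, pos2 = s2$pos,
    strand2 = ifelse(bitwAnd(s2$flag, 16L) != 0L, "-", "+"),
    len2 = cigar_ref_len(s2$cigar), seq2 = s2$seq, qual2 = s2$qual)
  d[, five_prime1 := as.integer(ifelse(strand1 == "+", pos1, pos1 + len1 - 1L))]
  d[, five_prime2 := as.integer(ifelse(strand2 == "+", pos2, pos2 + len2 - 1L))]
  d[]
}
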