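#' Derive the Hi-C ligation-junction sequence
#'
#' The junction is the novel sequence created when two restriction-fragment
#' ends are filled in and blunt-ligated: for a site of length `L` cut at
#' offset `c` (5' overhang or blunt, `c <= L - c`) it is
#' `site[1..c] + core + core + site[L-c+1..L]` where `core` is the overhang
#' `site[c+1..L-c]`. For HindIII (`A^AGCTT`) this yields `AAGCTAGCTT`,
#' a sequence absent from the undigested genome. `keep_len_increment`
#' (`k = L - c`) is the number of junction bases retained with the 5'
#' portion of a truncated read: those bases are genomically contiguous with
#' the read's own restriction fragment, so keeping them maximises alignable
#' sequence.
#'
#' @param enzyme An [EnzymeSpec][parse_enzyme_spec] with a 5' overhang or
#'   blunt cut; 3'-overhang cutters are not supported.
#' @return A `JunctionSpec`: list with `junction`, `keep_len_increment`,
#'   and `enzyme_name`.
#' @examples
#' ligation_junction(parse_enzyme_spec("A^AGCTT,HindIII"))$junction
#' @export
ligation_junction <- function(enzyme) {
  stopifnot(inherits(enzyme, "EnzymeSpec"))
  L <- nchar(enzyme$site)
  c <- enzyme$cut_offset
  if (c > L - c)
    stopf("enzyme %s has a 3' overhang (cut offset %d of %d); only 5'-overhang or blunt cutters are supported",
          enzyme$name, c, L, class = "hicditag_unsupported_enzyme")
  core <- substr(enzyme$site, c + 1L, L - c)
  junction <- paste0(substr(enzyme$site, 1L, c), core, core,
                     substr(enzyme$site, L - c + 1L, L))
  structure(list(junction = junction, keep_len_increment = L - c,
                 enzyme_name = enzyme$name),
            class = "JunctionSpec")
}

#' @export
print.JunctionSpec <- function(x, ...) {
  cat(sprintf("JunctionSpec (%s): %s, keep %d junction bases\n",
              x$enzyme_name, x$junction, x$keep_len_increment))
  invisible(x)
}

# Vectorised core: 0-based offset of the first junction occurrence per read,
# or -1. Junctions with ambiguity codes are matched by base-set expansion.
junction_offsets <- function(seqs, junction) {
  if (length(seqs) == 0L) return(integer(0))
  pat <- site_regex(junction$junction)
  as.integer(regexpr(pat, seqs, perl = TRUE)) - 1L  # negative when absent
}

#' Truncate a single read at the ligation junction
#'
#' If the junction occurs (first occurrence at 0-based offset `p`), the read
#' is cut to its first `p + k` bases (`k = keep_len_increment`), keeping the
#' reconstituted fragment end; otherwise it is returned unchanged.
#'
#' @param seq,qual Read sequence and quality strings of equal length.
#' @param junction A [JunctionSpec][ligation_junction].
#' @return List with `seq`, `qual`, `truncated` (logical).
#' @export
truncate_read <- function(seq, qual, junction) {
  stopifnot(nchar(seq) == nchar(qual))
  off <- junction_offsets(toupper(seq), junction)
  if (off < 0L)
    return(list(seq = seq, qual = qual, truncated = FALSE))
  keep <- off + junction$keep_len_increment
  list(seq = substr(seq, 1L, keep), qual = substr(qual, 1L, keep),
       truncated = TRUE)
}

# Vectorised truncation over a read list; returns the modified list plus a
# per-read truncated flag.
truncate_reads <- function(fq, junction) {
  off <- junction_offsets(fq$seq, junction)
  hit <- off >= 0L
  keep <- ifelse(hit, off + junction$keep_len_increment, nchar(fq$seq))
  fq$seq <- substr(fq$seq, 1L, keep)
  fq$qual <- substr(fq$qual, 1L, keep)
  list(fq = fq, truncated = hit)
}

truncation_stats <- function(fq, truncated, min_len) {
  n <- length(fq$seq)
  nt <- sum(truncated)
  list(reads_total = n,
       reads_truncated = nt,
       fraction_truncated = if (n) nt / n else 0,
       mean_truncated_length = if (nt) mean(nchar(fq$seq[truncated])) else NA_real_,
       reads_below_min_length = sum(truncated & nchar(fq$seq) < min_len))
}

#' Truncate paired FASTQ files at the ligation junction
#'
#' Streams both mate files, truncates each read at the first junction
#' occurrence, and writes the truncated FASTQ preserving record order and
#' identifiers. Reads shorter than `min_len` after truncation are still
#' written but counted in the statistics.
#'
#' @param r1_path,r2_path Input FASTQ files (plain or gzip).
#' @param junction A [JunctionSpec][ligation_junction].
#' @param out1,out2 Output FASTQ paths.
#' @param min_len Minimum post-truncation length flagged in the statistics
#'   (default 20 nt).
#' @return List with per-mate statistics `r1` and `r2`, each holding
#'   `reads_total`, `reads_truncated`, `fraction_truncated`,
#'   `mean_truncated_length` and `reads_below_min_length`.
#' @export
truncate_fastq <- function(r1_path, r2_path, junction, out1, out2,
                           min_len = 20L) {
  fq1 <- read_fastq(r1_path)
  fq2 <- read_fastq(r2_path)
  if (length(fq1$seq) != length(fq2$seq))
    stopf("mate files differ in record count (%d vs %d)",
          length(fq1$seq), length(fq2$seq), class = "hicditag_pairing_error")
  t1 <- truncate_reads(fq1, junction)
  t2 <- truncate_reads(fq2, junction)
  write_fastq(t1$fq, out1)
  write_fastq(t2$fq, out2)
  list(r1 = truncation_stats(t1$fq, t1$truncated, min_len),
       r2 = truncation_stats(t2$fq, t2$truncated, min_len))
}
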