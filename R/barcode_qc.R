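# Barcode concordance of duplicate di-tags.
#
# When one of four 4-nt barcode adapters is ligated randomly to each end of
# a di-tag BEFORE amplification, the barcode pair records the molecule's
# identity: PCR copies of one molecule share their barcode combination,
# whereas independent molecules that happen to coincide draw combinations
# independently (1/16 chance of matching for an ordered equimolar pair).
# Tabulating, per duplicate-group size, the fraction of groups whose
# members all share one combination therefore discriminates PCR duplication
# from coincidental identity.

#' Construct a barcode set
#'
#' @param barcodes Character vector of four distinct 4-nt sequences.
#' @return Character vector of class `BarcodeSet`.
#' @export
barcode_set <- function(barcodes) {
  barcodes <- toupper(barcodes)
  if (length(barcodes) != 4L || anyDuplicated(barcodes) ||
      any(nchar(barcodes) != 4L))
    stopf("a barcode set is four distinct 4-nt sequences",
          class = "hicditag_format_error")
  structure(barcodes, class = "BarcodeSet")
}

#' Extract the barcode from read sequences
#'
#' The barcode is the first four bases of the read.
#'
#' @param seqs Character vector of read sequences (all at least 4 nt).
#' @param set A [barcode_set()].
#' @return data.table with `barcode` (the 4-nt prefix) and `valid`
#'   (prefix is a member of the set).
#' @export
extract_barcode <- function(seqs, set) {
  if (length(seqs) && any(nchar(seqs) < 4L))
    stopf("read(s) shorter than 4 nt: no barcode to extract",
          class = "hicditag_too_short_error")
  bc <- toupper(substr(seqs, 1L, 4L))
  data.table::data.table(barcode = bc, valid = bc %in% set)
}

#' Barcode and combination frequency table for paired reads
#'
#' @param seq1,seq2 Mate-1 and mate-2 read sequences (same length vectors).
#' @param set A [barcode_set()].
#' @return List with `per_barcode` (counts of each set member per mate),
#'   `per_combination` (counts of all 16 ordered combinations among pairs
#'   where both barcodes are valid), `pct_valid` (percentage of pairs with
#'   both barcodes in the set; `NA` when empty).
#' @export
barcode_frequency_table <- function(seq1, seq2, set) {
  stopifnot(length(seq1) == length(seq2))
  b1 <- extract_barcode(seq1, set)
  b2 <- extract_barcode(seq2, set)
  per_barcode <- data.table::data.table(
    barcode = as.character(set),
    mate1 = as.integer(table(factor(b1$barcode[b1$valid], levels = set))),
    mate2 = as.integer(table(factor(b2$barcode[b2$valid], levels = set))))
  combos <- data.table::CJ(bc1 = as.character(set), bc2 = as.character(set))
  both <- b1$valid & b2$valid
  tab <- table(factor(paste(b1$barcode[both], b2$barcode[both]),
                      levels = paste(combos$bc1, combos$bc2)))
  combos[, count := as.integer(tab)]
  list(per_barcode = per_barcode, per_combination = combos,
       pct_valid = if (length(seq1)) 100 * sum(both) / length(seq1) else NA_real_)
}

#' Duplicate-group barcode concordance table
#'
#' Groups di-tags (duplicates retained) by their duplicate key, and for
#' every group size `>= 2` reports how many groups there are and what
#' percentage of them carry a single barcode combination across all copies.
#'
#' @param keys Duplicate keys per di-tag, from [ditag_key()].
#' @param bc1,bc2 Per-di-tag end barcodes (same order as `keys`).
#' @param ordered If `TRUE` (default) the combination is the ordered pair
#'   (end1, end2); if `FALSE` the pair is unordered, which raises the
#'   independent-molecule null above 1/16 by the collision term.
#' @return data.table with `copies`, `n_groups`, `pct_one_combination`,
#'   sorted by `copies`; zero rows when there are no duplicates.
#' @export
duplicate_concordance_table <- function(keys, bc1, bc2, ordered = TRUE) {
  stopifnot(length(keys) == length(bc1), length(keys) == length(bc2))
  combo <- if (ordered) paste(bc1, bc2) else
    paste(pmin(bc1, bc2), pmax(bc1, bc2))
  dt <- data.table::data.table(dkey = keys, combo = combo)
  groups <- dt[, .(copies = .N, one = data.table::uniqueN(combo) == 1L),
               by = "dkey"]
  groups <- groups[copies >= 2L]
  if (nrow(groups) == 0L)
    return(data.table::data.table(copies = integer(0), n_groups = integer(0),
                                  pct_one_combination = numeric(0)))
  out <- groups[, .(n_groups = .N, pct_one_combination = 100 * mean(one)),
                by = copies]
  data.table::setorder(out, copies)
  out[]
}
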