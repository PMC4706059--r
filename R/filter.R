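# Di-tag classification against the in-silico digest.
#
# Each mate's 5' base is placed on a restriction fragment; the geometry of
# the two placements decides whether the pair is a valid Hi-C product or one
# of the protocol artifacts (circularised / dangling end / internal
# fragment / re-ligation / contiguous run / wrong insert size).

DITAG_CATEGORIES <- c("VALID", "SAME_CIRCULARISED", "SAME_DANGLING",
                      "SAME_INTERNAL", "RELIGATION", "CONTIGUOUS",
                      "WRONG_SIZE", "DOUBLE_DIGEST_INVALID")

#' Assign an alignment's 5' base to a restriction fragment
#'
#' The covering fragment of the read's 5' base (`pos` for `+` strand,
#' `pos + aligned_length - 1` for `-` strand) is found by binary search over
#' the fragment starts of the chromosome.
#'
#' @param map A [DigestMap][digest_genome].
#' @param chrom,pos,strand,aligned_length Alignment fields (vectorised).
#' @return data.table with `frag_row` (row in `map$fragments`), `frag_index`,
#'   `frag_start`, `frag_end`, `five_prime`.
#' @export
assign_fragment <- function(map, chrom, pos, strand, aligned_length) {
  stopifnot(inherits(map, "DigestMap"))
  bad_chrom <- !(chrom %in% names(map$chrom_lengths))
  if (any(bad_chrom))
    stopf("chromosome(s) absent from digest map: %s",
          paste(unique(chrom[bad_chrom]), collapse = ", "),
          class = "hicditag_reference_mismatch")
  five_prime <- ifelse(strand == "+", pos, pos + aligned_length - 1L)
  if (any(five_prime < 1L | five_prime > map$chrom_lengths[chrom]))
    stopf("alignment coordinate outside chromosome bounds",
          class = "hicditag_bounds_error")
  fr <- map$fragments
  res <- data.table::data.table(chrom = chrom, five_prime = as.integer(five_prime),
                                frag_row = NA_integer_)
  for (ch in unique(chrom)) {
    rows <- which(fr$chrom == ch)
    sel <- res$chrom == ch
    res$frag_row[sel] <- rows[findInterval(res$five_prime[sel], fr$start[rows])]
  }
  res[, `:=`(frag_index = fr$index[frag_row],
             frag_start = fr$start[frag_row],
             frag_end = fr$end[frag_row])]
  res[]
}

#' Theoretical Hi-C insert size of a di-tag
#'
#' Per end, the distance from the read's 5' base to its fragment's boundary
#' in the read's 3' direction, inclusive (`+` strand:
#' `frag_end - five_prime + 1`; `-` strand: `five_prime - frag_start + 1`);
#' the insert is the sum over both ends. This is the sonication-fragment
#' length the molecule would have had if it was a genuine ligation product
#' of the two assigned fragments.
#'
#' @param strand,five_prime,frag_start,frag_end Per-end vectors.
#' @return Integer vector of per-end distances; sum two ends for the insert.
#' @export
end_to_boundary <- function(strand, five_prime, frag_start, frag_end) {
  as.integer(ifelse(strand == "+", frag_end - five_prime + 1L,
                    five_prime - frag_start + 1L))
}

#' Classify putative di-tags
#'
#' Applies the artifact rules in a fixed precedence order (first match
#' wins):
#' 1. same fragment, reads oriented away from each other: `SAME_CIRCULARISED`
#' 2. same fragment, facing, either 5' base exactly on a fragment boundary:
#'    `SAME_DANGLING`
#' 3. same fragment otherwise: `SAME_INTERNAL`
#' 4. adjacent fragments, facing across the shared boundary: `RELIGATION`
#' 5. same chromosome, facing, outermost genomic span within the
#'    size-selection window: `CONTIGUOUS`
#' 6. insert size outside the window: `WRONG_SIZE`
#' 7. otherwise `VALID` (`cis` if both ends on one chromosome, else `trans`).
#'
#' In `double_digest` mode, two checks run before rule 1 and failing either
#' yields `DOUBLE_DIGEST_INVALID`: each read must begin exactly at a cut
#' coordinate, and each read's ligation-side fragment boundary must have
#' been created by the first enzyme.
#'
#' @param ditags data.table from [pair_reads()].
#' @param map A [DigestMap][digest_genome].
#' @param size_range Length-2 numeric, the experimental size-selection
#'   window in bp (default `c(150, 800)`).
#' @param mode `"sonication"` or `"double_digest"`.
#' @return The input with added columns `frag_index1/2`, `five_prime1/2`,
#'   `dist1/2`, `insert_size`, `category` (factor over the category set) and
#'   `cis` (logical, `NA` unless `VALID`).
#' @export
classify_ditags <- function(ditags, map, size_range = c(150, 800),
                            mode = c("sonication", "double_digest")) {
  mode <- match.arg(mode)
  stopifnot(length(size_range) == 2L, size_range[1] > 0,
            size_range[1] <= size_range[2])
  d <- data.table::copy(ditags)
  if (nrow(d) == 0L) {
    d[, `:=`(frag_index1 = integer(0), frag_index2 = integer(0),
             five_prime1 = integer(0), five_prime2 = integer(0),
             dist1 = integer(0), dist2 = integer(0),
             insert_size = integer(0),
             category = factor(character(0), levels = DITAG_CATEGORIES),
             cis = logical(0))]
    return(d[])
  }
  f1 <- assign_fragment(map, d$chrom1, d$pos1, d$strand1, d$len1)
  f2 <- assign_fragment(map, d$chrom2, d$pos2, d$strand2, d$len2)
  d[, `:=`(frag_index1 = f1$frag_index, frag_index2 = f2$frag_index,
           five_prime1 = f1$five_prime, five_prime2 = f2$five_prime,
           dist1 = end_to_boundary(strand1, f1$five_prime, f1$frag_start, f1$frag_end),
           dist2 = end_to_boundary(strand2, f2$five_prime, f2$frag_start, f2$frag_end))]
  d[, insert_size := dist1 + dist2]

  same_chrom <- d$chrom1 == d$chrom2
  same_frag <- same_chrom & d$frag_index1 == d$frag_index2
  opp <- d$strand1 != d$strand2
  # 5' position of the + and - mate for opposite-strand pairs on one chromosome
  fp_plus <- ifelse(d$strand1 == "+", d$five_prime1, d$five_prime2)
  fp_minus <- ifelse(d$strand1 == "-", d$five_prime1, d$five_prime2)
  facing <- same_chrom & opp & fp_plus <= fp_minus
  away <- same_chrom & opp & fp_plus > fp_minus
  on_boundary <- (d$five_prime1 == f1$frag_start | d$five_prime1 == f1$frag_end |
                  d$five_prime2 == f2$frag_start | d$five_prime2 == f2$frag_end)
  span <- fp_minus - fp_plus + 1L
  in_window <- function(x) x >= size_range[1] & x <= size_range[2]

  cat <- rep(NA_character_, nrow(d))
  if (mode == "double_digest") {
    nfrags <- map$fragments[, .N, by = chrom]
    nf <- setNames(nfrags$N, nfrags$chrom)
    at_cut <- function(strand, fp, f, chrom) {
      ifelse(strand == "+", fp == f$frag_start & f$frag_index > 1L,
             fp == f$frag_end & f$frag_index < nf[chrom])
    }
    re1_side <- function(strand, f) {
      fr <- map$fragments
      ifelse(strand == "+", fr$re1_end_3p[f$frag_row], fr$re1_end_5p[f$frag_row])
    }
    ok <- at_cut(d$strand1, d$five_prime1, f1, d$chrom1) &
          at_cut(d$strand2, d$five_prime2, f2, d$chrom2) &
          re1_side(d$strand1, f1) & re1_side(d$strand2, f2)
    cat[!ok] <- "DOUBLE_DIGEST_INVALID"
  }
  rule <- function(cond, label) cat <<- ifelse(is.na(cat) & cond, label, cat)
  rule(same_frag & away, "SAME_CIRCULARISED")
  rule(same_frag & facing & on_boundary, "SAME_DANGLING")
  rule(same_frag, "SAME_INTERNAL")
  rule(same_chrom & facing & abs(d$frag_index1 - d$frag_index2) == 1L, "RELIGATION")
  rule(same_chrom & facing & in_window(span), "CONTIGUOUS")
  rule(!in_window(d$insert_size), "WRONG_SIZE")
  cat[is.na(cat)] <- "VALID"

  d[, category := factor(cat, levels = DITAG_CATEGORIES)]
  d[, cis := ifelse(category == "VALID", same_chrom, NA)]
  d[]
}

#' Filter classified di-tags down to the valid set
#'
#' @param classified Output of [classify_ditags()] (or a raw di-tag table
#'   plus the classification arguments).
#' @inheritParams classify_ditags
#' @return List with `valid` (VALID rows, input order preserved), `rejects`
#'   (everything else), and `stats`: named per-category counts, `pairs_in`,
#'   and cis/trans counts among the valid set.
#' @export
filter_ditags <- function(classified, map = NULL, size_range = c(150, 800),
                          mode = "sonication") {
  if (!"category" %in% names(classified)) {
    stopifnot(!is.null(map))
    classified <- classify_ditags(classified, map, size_range, mode)
  }
  counts <- table(classified$category)
  valid <- classified[category == "VALID"]
  list(valid = valid,
       rejects = classified[category != "VALID"],
       stats = list(pairs_in = nrow(classified),
                    category_counts = setNames(as.integer(counts), names(counts)),
                    valid_cis = sum(valid$cis),
                    valid_trans = sum(!valid$cis)))
}
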