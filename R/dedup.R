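# PCR-duplicate removal on the valid di-tag set.

#' Canonical duplicate key of a di-tag
#'
#' Two di-tags are PCR duplicates iff their sonication endpoints coincide:
#' the key is the pair of (chrom, 5' position, strand) triples, with the two
#' ends ordered lexicographically so that mate order is irrelevant. Read
#' sequences and lengths are deliberately not part of the key (truncation
#' alters lengths; the endpoints define the molecule).
#'
#' @param ditags Classified di-tag table (needs `chrom1/2`, `five_prime1/2`,
#'   `strand1/2`).
#' @return Character vector of canonical keys.
#' @export
ditag_key <- function(ditags) {
  e1 <- sprintf("%s:%d:%s", ditags$chrom1, ditags$five_prime1, ditags$strand1)
  e2 <- sprintf("%s:%d:%s", ditags$chrom2, ditags$five_prime2, ditags$strand2)
  ifelse(e1 <= e2, paste(e1, e2, sep = "|"), paste(e2, e1, sep = "|"))
}

#' Remove PCR-duplicate di-tags
#'
#' Keeps the first occurrence of every duplicate key (deterministic without
#' comparing qualities) and tallies cis/trans on the unique set.
#'
#' @param valid Valid di-tag table from [filter_ditags()].
#' @return List with `unique` (survivors, input order preserved) and
#'   `stats`: `ditags_in`, `ditags_unique`, `fraction_unique`, `cis_count`,
#'   `trans_count`.
#' @export
dedup_ditags <- function(valid) {
  key <- ditag_key(valid)
  keep <- !duplicated(key)
  uniq <- valid[keep]
  cis <- if ("cis" %in% names(uniq)) sum(uniq$cis, na.rm = TRUE)
         else sum(uniq$chrom1 == uniq$chrom2)
  stats <- list(ditags_in = nrow(valid), ditags_unique = nrow(uniq),
                fraction_unique = if (nrow(valid)) nrow(uniq) / nrow(valid) else NA_real_,
                cis_count = cis, trans_count = nrow(uniq) - cis)
  list(unique = uniq, stats = stats)
}

#' Trans/cis ratio of a deduplicated library
#'
#' A high trans/cis ratio indicates a poor library: spurious ligation events
#' tend to join loci on different chromosomes.
#'
#' @param stats `stats` element from [dedup_ditags()].
#' @return List with `ratio` (trans/cis; `NA` when `cis_count` is 0) and
#'   `trans_pct` (trans percentage of unique di-tags; `NA` when empty).
#' @export
cis_trans_ratio <- function(stats) {
  ratio <- if (stats$cis_count > 0) stats$trans_count / stats$cis_count else NA_real_
  total <- stats$cis_count + stats$trans_count
  trans_pct <- if (total > 0) 100 * stats$trans_count / total else NA_real_
  list(ratio = ratio, trans_pct = trans_pct)
}
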