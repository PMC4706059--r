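# Double-digest protocol simulator.
#
# In the double-digest variant the sonication step is replaced by a second
# restriction digestion, so every read should begin exactly at a cut site
# and a valid di-tag is blunt-ligated between fragment ends created by the
# FIRST enzyme. The simulator emits compliant di-tags plus the two
# violation classes the extra filters must remove: reads not starting at a
# cut coordinate, and di-tags ligated at second-enzyme ends.

#' Simulate a double-digest library with ground truth
#'
#' @param genome Named character vector from [make_genome()] of a
#'   double-digest [sim_config()] (both enzymes planted).
#' @param map Double-digest [DigestMap][digest_genome] of that genome.
#' @param config The [sim_config()] used (needs `read_length`,
#'   `size_range`, `seed`).
#' @param n_per_class Number of di-tags per class.
#' @param classes Subset of `"compliant"`, `"not_cut_start"`,
#'   `"re2_ligation"`.
#' @param out_dir Output directory.
#' @return As [simulate_library()]: FASTQ pair, truth TSV and the truth
#'   data.table with a `dd_class` column.
#' @export
simulate_dd_library <- function(genome, map, config, n_per_class = 100L,
                                classes = c("compliant", "not_cut_start",
                                            "re2_ligation"),
                                out_dir) {
  stopifnot(inherits(map, "DigestMap"), !is.null(map$enzyme2))
  set.seed(config$seed + 2L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rl <- config$read_length
  sr <- config$size_range
  fr <- data.table::copy(map$fragments)
  fr[, len := end - start + 1L]
  fr[, nfrag := .N, by = chrom]
  fr[, interior := index > 1L & index < nfrag]

  # usable fragments: a read must fit and the insert (sum of the two
  # fragment lengths) must be able to land inside the size window
  usable <- fr[interior == TRUE & len >= rl + 12L & len <= sr[2] - rl]
  left_re1 <- usable[re1_end_3p == TRUE]    # ligation side = 3' boundary
  right_re1 <- usable[re1_end_5p == TRUE]
  left_re2 <- usable[re1_end_3p == FALSE]
  right_re2 <- usable[re1_end_5p == FALSE]
  if (min(nrow(left_re1), nrow(right_re1), nrow(left_re2), nrow(right_re2)) < 2L)
    stopf("digest lacks eligible fragments for double-digest simulation",
          class = "hicditag_config_error")

  pick_dd_pair <- function(n, lpool, rpool) {
    out <- NULL
    tries <- 0L
    while (n > 0L && tries < 500L) {
      tries <- tries + 1L
      a <- lpool[sample.int(nrow(lpool), n, replace = TRUE)]
      b <- rpool[sample.int(nrow(rpool), n, replace = TRUE)]
      insert <- a$len + b$len
      ok <- insert >= sr[1] & insert <= sr[2] &
        (a$chrom != b$chrom |
           (abs(a$index - b$index) >= 2L &
              (pmax(a$start, b$start) - pmin(a$end, b$end)) > sr[2] + 1L))
      keep <- which(ok)
      if (length(keep)) {
        out <- data.table::rbindlist(list(out, cbind(
          a[keep, .(ca = chrom, sa = start, ea = end, ia = index, la = len)],
          b[keep, .(cb = chrom, sb = start, eb = end, ib = index, lb = len)])))
        n <- n - length(keep)
      }
    }
    if (n > 0L)
      stopf("cannot find enough eligible double-digest fragment pairs",
            class = "hicditag_config_error")
    out
  }

  mk_class <- function(n, dd_class) {
    p <- switch(dd_class,
                compliant = pick_dd_pair(n, left_re1, right_re1),
                not_cut_start = pick_dd_pair(n, left_re1, right_re1),
                re2_ligation = pick_dd_pair(n, left_re2, right_re2))
    shift <- if (dd_class == "not_cut_start") runif_int(n, 3L, 10L) else 0L
    a_start <- p$sa + shift
    data.table::data.table(
      dd_class = dd_class,
      chrom1 = p$ca, five_prime1 = a_start, strand1 = "+",
      frag_index1 = p$ia,
      chrom2 = p$cb, five_prime2 = p$eb, strand2 = "-",
      frag_index2 = p$ib,
      insert_size = p$la + p$lb,
      seq1 = substring(genome[p$ca], a_start, a_start + rl - 1L),
      seq2 = revcomp(substring(genome[p$cb], p$eb - rl + 1L, p$eb)))
  }

  truth <- data.table::rbindlist(lapply(classes, mk_class, n = n_per_class))
  truth[, read_id := sprintf("D%06d", .I)]
  truth <- truth[sample.int(nrow(truth))]

  r1 <- file.path(out_dir, "dd_R1.fastq")
  r2 <- file.path(out_dir, "dd_R2.fastq")
  write_fastq(list(id = truth$read_id, seq = truth$seq1,
                   qual = strrep("I", nchar(truth$seq1))), r1)
  write_fastq(list(id = truth$read_id, seq = truth$seq2,
                   qual = strrep("I", nchar(truth$seq2))), r2)
  truth_path <- file.path(out_dir, "dd_truth.tsv")
  data.table::fwrite(truth[, !c("seq1", "seq2")], truth_path, sep = "\t")
  list(r1 = r1, r2 = r2, truth = truth_path, truth_dt = truth)
}
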