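# Synthetic Hi-C genome and library simulator.
#
# The simulator is the pipeline's test surface: it emits error-free paired
# reads for every di-tag class with per-read ground truth, so every stage of
# the pipeline can be checked against planted values exactly.
#
# Molecule construction mirrors the fill-in/blunt-ligation chemistry. A
# ligated molecule is `left piece + right piece`, where a piece is a
# genomic segment ending at a restriction-fragment boundary plus (on the
# left piece's 3' side) the filled-in overhang; the junction sequence then
# arises at the seam exactly as in a real library, and a read crossing the
# seam carries the junction and is truncatable back to a perfectly mappable
# genomic prefix. Sonication endpoints are drawn uniformly within the span
# each category's geometry allows, but distances to the ligation boundary
# avoid the narrow window in which a read would cross the seam without
# containing the complete junction (such a read is unmappable by an exact
# aligner and, in real data, maps or not depending on aligner heuristics;
# the simulator keeps ground truth exact instead of modelling that).

#' Simulator configuration
#'
#' Bundles every knob of the synthetic-library generator. Defaults describe
#' a small but realistic sonication-protocol HindIII library: three 150 kb
#' chromosomes, 50 nt reads, a 150-800 bp size-selection window, an
#' artifact mix in which valid pairs dominate but every artifact class is
#' well represented, and no PCR duplication (`pcr_copies = c("1" = 1)`).
#'
#' @param seed Integer seed; the whole simulation is deterministic in it.
#' @param n_chromosomes,chrom_length Genome shape.
#' @param enzyme,enzyme2 Enzyme specification string(s); `enzyme2` switches
#'   the genome to a double-digest layout.
#' @param read_length Read length in nt.
#' @param size_range Size-selection window (bp) used both for drawing valid
#'   insert lengths and, downstream, for filtering.
#' @param proportions Named vector over the eight di-tag classes
#'   (`valid_cis`, `valid_trans`, `circularised`, `dangling`, `internal`,
#'   `religation`, `contiguous`, `wrong_size`); must sum to 1.
#' @param n_ditags Number of distinct molecules (before PCR copying).
#' @param pcr_copies Distribution over per-molecule copy numbers: named
#'   numeric vector, names = copy counts, values = probabilities.
#' @param barcodes Optional [barcode_set()] (or character vector of four
#'   4-mers); when set, each read is prefixed with its barcode.
#' @param barcode_model `"pcr"`: the barcode pair is drawn once per molecule
#'   and inherited by all PCR copies. `"independent"`: each emitted copy
#'   draws its own pair (modelling coincidentally identical molecules).
#' @param barcode_valid_rate Probability that an emitted read keeps its
#'   set barcode; otherwise a random 4-mer outside the set is used.
#' @param site_spacing Range (bp) of random spacing between planted
#'   restriction sites; every fifth spacing is drawn from
#'   `short_site_spacing` so that fragments short enough for
#'   contiguous-run molecules always exist.
#' @param short_site_spacing Range for the planted short spacings.
#' @param min_piece Minimum distance (bp) from any sonication endpoint to
#'   its ligation boundary.
#' @param trunc_prob Probability that a ligated molecule's eligible end is
#'   drawn close enough to the seam for its read to be truncated.
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 3L,
                       chrom_length = 150000L,
                       enzyme = "A^AGCTT,HindIII",
                       enzyme2 = NULL,
                       read_length = 50L,
                       size_range = c(150L, 800L),
                       proportions = c(valid_cis = 0.40, valid_trans = 0.10,
                                       circularised = 0.08, dangling = 0.10,
                                       internal = 0.10, religation = 0.08,
                                       contiguous = 0.07, wrong_size = 0.07),
                       n_ditags = 1000L,
                       pcr_copies = c("1" = 1),
                       barcodes = NULL,
                       barcode_model = c("pcr", "independent"),
                       barcode_valid_rate = 1,
                       site_spacing = c(800L, 3000L),
                       short_site_spacing = c(450L, 650L),
                       min_piece = 30L,
                       trunc_prob = 0.3) {
  barcode_model <- match.arg(barcode_model)
  need <- c("valid_cis", "valid_trans", "circularised", "dangling",
            "internal", "religation", "contiguous", "wrong_size")
  if (!setequal(names(proportions), need) || any(proportions < 0) ||
      abs(sum(proportions) - 1) > 1e-8)
    stopf("proportions must be non-negative over {%s} and sum to 1",
          paste(need, collapse = ", "), class = "hicditag_config_error")
  if (!is.null(barcodes)) barcodes <- barcode_set(barcodes)
  structure(list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = as.integer(chrom_length), enzyme = enzyme,
                 enzyme2 = enzyme2, read_length = as.integer(read_length),
                 size_range = as.integer(size_range),
                 proportions = proportions[need], n_ditags = as.integer(n_ditags),
                 pcr_copies = pcr_copies, barcodes = barcodes,
                 barcode_model = barcode_model,
                 barcode_valid_rate = barcode_valid_rate,
                 site_spacing = as.integer(site_spacing),
                 short_site_spacing = as.integer(short_site_spacing),
                 min_piece = as.integer(min_piece), trunc_prob = trunc_prob),
            class = "SimConfig")
}

# uniform integer draw with (possibly vectorised) bounds; requires lo <= hi
runif_int <- function(n, lo, hi) {
  as.integer(lo + floor(runif(n) * (hi - lo + 1L)))
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic multi-chromosome genome
#'
#' Random A/C/G/T sequence with restriction sites planted at seeded random
#' spacings (plus whatever sites arise by chance in the random background —
#' the digest map is always derived from the final sequence, never from the
#' planting plan). Any chance occurrence of the ligation-junction sequence
#' is mutated away, preserving the junction's defining property of being
#' absent from the unligated genome. Deterministic for a given seed.
#'
#' @param config A [sim_config()].
#' @return Named character vector of chromosome sequences
#'   (`chr1`, `chr2`, ...).
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  enz1 <- parse_enzyme_spec(config$enzyme)
  sites <- enz1$site
  if (!is.null(config$enzyme2))
    sites <- c(sites, parse_enzyme_spec(config$enzyme2)$site)
  junction <- tryCatch(ligation_junction(enz1)$junction,
                       error = function(e) NULL)
  genome <- setNames(vapply(seq_len(config$n_chromosomes), function(i) {
    parts <- character(0)
    total <- 0L
    k <- 0L
    while (total < config$chrom_length) {
      k <- k + 1L
      gap <- if (k %% 5L == 0L)
        runif_int(1L, config$short_site_spacing[1], config$short_site_spacing[2])
      else
        runif_int(1L, config$site_spacing[1], config$site_spacing[2])
      site <- sites[sample.int(length(sites), 1L)]
      parts <- c(parts, random_bases(gap), site)
      total <- total + gap + nchar(site)
    }
    substr(paste(parts, collapse = ""), 1L, config$chrom_length)
  }, character(1)), paste0("chr", seq_len(config$n_chromosomes)))

  if (!is.null(junction)) {
    bases <- c("A", "C", "G", "T")
    for (nm in names(genome)) {
      for (iter in 1:50) {
        hits <- match_starts(genome[[nm]], junction)
        if (!length(hits)) break
        # break each occurrence by flipping its central base
        for (h in hits) {
          p <- h + nchar(junction) %/% 2L
          old <- substr(genome[[nm]], p, p)
          substr(genome[[nm]], p, p) <- sample(setdiff(bases, old), 1L)
        }
      }
      if (length(match_starts(genome[[nm]], junction)))
        stopf("could not sanitise junction occurrences on %s", nm,
              class = "hicditag_config_error")
    }
  }
  genome
}

# Per-category molecule counts: floor + largest remainder, summing exactly n.
category_counts <- function(proportions, n) {
  raw <- proportions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Left/right piece descriptors (see header comment). `end` is "3p"/"5p".
left_piece <- function(genome, oh, chrom, fstart, fend, end, dist) {
  is3 <- rep_len(end == "3p", length(dist))
  seq <- ifelse(is3,
                paste0(substring(genome[chrom], fend - dist + 1L, fend), oh),
                revcomp(substring(genome[chrom], fstart, fstart + dist - 1L)))
  list(seq = seq,
       fp = as.integer(ifelse(is3, fend - dist + 1L, fstart + dist - 1L)),
       strand = ifelse(is3, "+", "-"))
}

right_piece <- function(genome, oh, chrom, fstart, fend, end, dist) {
  is5 <- rep_len(end == "5p", length(dist))
  seq <- ifelse(is5,
                substring(genome[chrom], fstart, fstart + dist - 1L),
                paste0(revcomp(oh),
                       revcomp(substring(genome[chrom], fend - dist + 1L, fend))))
  list(seq = seq,
       fp = as.integer(ifelse(is5, fstart + dist - 1L, fend - dist + 1L)),
       strand = ifelse(is5, "-", "+"))
}

# Draw a ligation-side distance from the safe set: with probability
# trunc_prob in [min_piece, rl - junction_len] (the read will contain the
# full junction and be truncated), else in [rl, cap].
draw_dist <- function(n, min_piece, rl, jlen, cap, trunc_prob) {
  tr <- runif(n) < trunc_prob & (rl - jlen) >= min_piece
  ifelse(tr, runif_int(n, min_piece, rl - jlen), runif_int(n, rl, cap))
}

#' Simulate a Hi-C library with ground truth
#'
#' Constructs `n_ditags` distinct molecules whose read geometry matches the
#' classifier's definition of each planted category, applies the PCR-copy
#' and barcode models, shuffles the emitted pairs, and writes paired FASTQ
#' plus a ground-truth TSV and the generating configuration.
#'
#' Molecule duplicate keys (sonication endpoints) are unique across the
#' library by construction — colliding draws are redrawn — so duplication
#' enters exclusively through the PCR-copy model and the number of distinct
#' keys equals `n_ditags` exactly.
#'
#' @param genome Named character vector from [make_genome()].
#' @param map [DigestMap][digest_genome] of that genome with the same
#'   enzyme(s).
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return List with paths `r1`, `r2`, `truth`, `config` and the truth
#'   data.table (`truth_dt`): one row per emitted read pair carrying the
#'   planted category, per-end coordinates, fragment indices, insert size,
#'   truncation flags, molecule id, copy index and barcodes.
#' @export
simulate_library <- function(genome, map, config, out_dir) {
  stopifnot(inherits(config, "SimConfig"), inherits(map, "DigestMap"))
  set.seed(config$seed + 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  enz <- map$enzyme1
  L <- nchar(enz$site)
  cc <- enz$cut_offset
  oh <- substr(enz$site, cc + 1L, L - cc)          # filled-in overhang
  jlen <- 2L * (L - cc)                            # junction length
  rl <- config$read_length
  mp <- config$min_piece
  sr <- config$size_range
  fr <- data.table::copy(map$fragments)
  fr[, len := end - start + 1L]
  fr[, nfrag := .N, by = chrom]
  fr[, interior := index > 1L & index < nfrag]
  fr[, row := .I]

  big <- fr[interior == TRUE & len >= sr[2]]
  if (nrow(big) < 4L)
    stopf("genome has too few large interior fragments for ligated categories",
          class = "hicditag_config_error")

  counts <- category_counts(config$proportions, config$n_ditags)
  names(counts) <- names(config$proportions)

  pick_rows <- function(dt, n) dt[sample.int(nrow(dt), n, replace = TRUE)]

  # two distinct large interior fragments; cis: same chrom, >= 2 apart, gap
  # beyond the size window; trans: different chromosomes. min_len guarantees
  # either fragment can absorb the largest per-end boundary distance drawn.
  pick_pair <- function(n, cis, min_len = sr[2]) {
    pool <- fr[interior == TRUE & len >= min_len]
    if (nrow(pool) < 4L)
      stopf("too few interior fragments of length >= %d for ligated molecules",
            min_len, class = "hicditag_config_error")
    out <- NULL
    tries <- 0L
    while (n > 0L && tries < 200L) {
      tries <- tries + 1L
      a <- pick_rows(pool, n)
      b <- pick_rows(pool, n)
      ok <- if (cis) {
        a$chrom == b$chrom & abs(a$index - b$index) >= 2L &
          (pmax(a$start, b$start) - pmin(a$end, b$end)) > sr[2] + 1L
      } else a$chrom != b$chrom
      keep <- which(ok)
      if (length(keep)) {
        out <- data.table::rbindlist(list(out, data.table::data.table(
          ca = a$chrom[keep], sa = a$start[keep], ea = a$end[keep],
          ia = a$index[keep], la = a$len[keep],
          cb = b$chrom[keep], sb = b$start[keep], eb = b$end[keep],
          ib = b$index[keep], lb = b$len[keep])))
        n <- n - length(keep)
      }
    }
    if (n > 0L)
      stopf("cannot find enough eligible fragment pairs (cis=%s)", cis,
            class = "hicditag_config_error")
    out
  }

  mk_ligated <- function(pairs, insert_lo, insert_hi, category) {
    n <- nrow(pairs)
    if (n == 0L) return(NULL)
    lend <- sample(c("3p", "5p"), n, replace = TRUE)
    rend <- sample(c("5p", "3p"), n, replace = TRUE)
    if (insert_lo >= sr[1]) {
      # insert within (or above) the window: one side may sit close to the
      # seam (truncating), the other absorbs the rest of the insert
      d1 <- draw_dist(n, mp, rl, jlen, pmin(pairs$la, insert_hi - rl), config$trunc_prob)
      d2 <- runif_int(n, pmax(rl, insert_lo - d1), pmin(pairs$lb, insert_hi - d1))
    } else {
      # undersized inserts: both ends close to the seam
      d1 <- runif_int(n, mp, min(rl - jlen, insert_hi - mp))
      d2 <- runif_int(n, pmax(mp, insert_lo - d1), pmin(rl - jlen, insert_hi - d1))
    }
    lp <- left_piece(genome, oh, pairs$ca, pairs$sa, pairs$ea, lend, d1)
    rp <- right_piece(genome, oh, pairs$cb, pairs$sb, pairs$eb, rend, d2)
    data.table::data.table(
      category = category,
      chrom1 = pairs$ca, five_prime1 = lp$fp, strand1 = lp$strand,
      frag_index1 = pairs$ia, dist1 = d1,
      chrom2 = pairs$cb, five_prime2 = rp$fp, strand2 = rp$strand,
      frag_index2 = pairs$ib, dist2 = d2,
      insert_size = d1 + d2, truncated1 = d1 < rl, truncated2 = d2 < rl,
      molecule = paste0(lp$seq, rp$seq))
  }

  gen_valid <- function(n, cis) {
    if (n == 0L) return(NULL)
    mk_ligated(pick_pair(n, cis), sr[1], sr[2],
               if (cis) "valid_cis" else "valid_trans")
  }

  gen_wrong_size <- function(n) {
    if (n == 0L) return(NULL)
    n_small <- if (2L * mp < sr[1] && rl - jlen > mp) rbinom(1L, n, 0.5) else 0L
    parts <- list()
    if (n_small > 0L)
      parts$small <- mk_ligated(pick_pair(n_small, TRUE),
                                2L * mp, min(sr[1] - 1L, 2L * (rl - jlen)),
                                "wrong_size")
    if (n - n_small > 0L)
      parts$large <- mk_ligated(pick_pair(n - n_small, TRUE,
                                          min_len = sr[2] + 100L),
                                sr[2] + 100L, sr[2] + 600L, "wrong_size")
    data.table::rbindlist(parts)
  }

  gen_circularised <- function(n) {
    if (n == 0L) return(NULL)
    f <- pick_rows(big, n)
    d1 <- draw_dist(n, mp, rl, jlen, pmin(f$len %/% 2L, 350L), config$trunc_prob)
    d2 <- runif_int(n, rl, pmin(f$len - d1, 350L))
    lp <- left_piece(genome, oh, f$chrom, f$start, f$end, "3p", d1)
    rp <- right_piece(genome, oh, f$chrom, f$start, f$end, "5p", d2)
    data.table::data.table(
      category = "circularised",
      chrom1 = f$chrom, five_prime1 = lp$fp, strand1 = "+",
      frag_index1 = f$index, dist1 = d1,
      chrom2 = f$chrom, five_prime2 = rp$fp, strand2 = "-",
      frag_index2 = f$index, dist2 = d2,
      insert_size = d1 + d2, truncated1 = d1 < rl, truncated2 = d2 < rl,
      molecule = paste0(lp$seq, rp$seq))
  }

  # unligated genomic stretch inside one fragment; `boundary` pins one
  # sonication end on the fragment terminus (dangling) or keeps both
  # interior (internal fragment)
  gen_same_frag <- function(n, boundary) {
    if (n == 0L) return(NULL)
    f <- pick_rows(big, n)
    m <- runif_int(n, rl, pmin(f$len - 2L, sr[2]))
    if (boundary) {
      side5 <- runif(n) < 0.5
      a <- as.integer(ifelse(side5, f$start, f$end - m + 1L))
    } else {
      a <- runif_int(n, f$start + 1L, f$end - 1L - m + 1L)
    }
    b <- a + m - 1L
    data.table::data.table(
      category = if (boundary) "dangling" else "internal",
      chrom1 = f$chrom, five_prime1 = a, strand1 = "+",
      frag_index1 = f$index, dist1 = f$end - a + 1L,
      chrom2 = f$chrom, five_prime2 = b, strand2 = "-",
      frag_index2 = f$index, dist2 = b - f$start + 1L,
      insert_size = (f$end - a + 1L) + (b - f$start + 1L),
      truncated1 = FALSE, truncated2 = FALSE,
      molecule = substring(genome[f$chrom], a, b))
  }

  gen_religation <- function(n) {
    if (n == 0L) return(NULL)
    adj <- fr[fr[, c(chrom[-.N] == chrom[-1] & len[-.N] >= 120L & len[-1] >= 120L,
                     FALSE)]]
    if (nrow(adj) == 0L)
      stopf("no adjacent fragment pairs eligible for religation molecules",
            class = "hicditag_config_error")
    f1 <- pick_rows(adj, n)
    f2 <- fr[f1$row + 1L]
    d1 <- draw_dist(n, mp, rl, jlen, pmin(f1$len, 350L), config$trunc_prob)
    d2 <- draw_dist(n, mp, rl, jlen, pmin(f2$len, 350L), config$trunc_prob)
    lp <- left_piece(genome, oh, f1$chrom, f1$start, f1$end, "3p", d1)
    rp <- right_piece(genome, oh, f2$chrom, f2$start, f2$end, "5p", d2)
    data.table::data.table(
      category = "religation",
      chrom1 = f1$chrom, five_prime1 = lp$fp, strand1 = "+",
      frag_index1 = f1$index, dist1 = d1,
      chrom2 = f2$chrom, five_prime2 = rp$fp, strand2 = "-",
      frag_index2 = f2$index, dist2 = d2,
      insert_size = d1 + d2, truncated1 = d1 < rl, truncated2 = d2 < rl,
      molecule = paste0(lp$seq, rp$seq))
  }

  gen_contiguous <- function(n) {
    if (n == 0L) return(NULL)
    mid <- fr[interior == TRUE & len <= sr[2] - 2L * mp - 2L]
    mid <- mid[fr$len[row - 1L] >= sr[1] & fr$len[row + 1L] >= sr[1] &
               fr$chrom[row - 1L] == chrom & fr$chrom[row + 1L] == chrom]
    if (nrow(mid) == 0L)
      stopf("no short interior fragments eligible for contiguous molecules",
            class = "hicditag_config_error")
    f <- pick_rows(mid, n)
    prev <- fr[f$row - 1L]
    nxt <- fr[f$row + 1L]
    da <- runif_int(n, mp, pmin(prev$len, sr[2] - f$len - mp))
    db <- runif_int(n, pmax(mp, sr[1] - f$len - da),
                    pmin(nxt$len, sr[2] - f$len - da))
    a <- prev$end - da + 1L
    b <- nxt$start + db - 1L
    data.table::data.table(
      category = "contiguous",
      chrom1 = f$chrom, five_prime1 = a, strand1 = "+",
      frag_index1 = prev$index, dist1 = da,
      chrom2 = f$chrom, five_prime2 = b, strand2 = "-",
      frag_index2 = nxt$index, dist2 = db,
      insert_size = da + db,   # per-end boundary distances
      truncated1 = FALSE, truncated2 = FALSE,
      molecule = substring(genome[f$chrom], a, b))
  }

  gen_one <- function(category, n) {
    switch(category,
           valid_cis = gen_valid(n, TRUE),
           valid_trans = gen_valid(n, FALSE),
           circularised = gen_circularised(n),
           dangling = gen_same_frag(n, TRUE),
           internal = gen_same_frag(n, FALSE),
           religation = gen_religation(n),
           contiguous = gen_contiguous(n),
           wrong_size = gen_wrong_size(n))
  }

  mols <- data.table::rbindlist(
    lapply(names(counts), function(cat) gen_one(cat, counts[[cat]])))

  # enforce globally unique duplicate keys: redraw colliding molecules
  for (iter in 1:25) {
    key <- ditag_key(mols)
    dup <- which(duplicated(key))
    if (!length(dup)) break
    redo <- mols$category[dup]
    repl <- data.table::rbindlist(
      lapply(split(seq_along(redo), redo),
             function(ix) gen_one(redo[ix[1]], length(ix))))
    mols <- data.table::rbindlist(list(mols[-dup], repl))
  }
  if (anyDuplicated(ditag_key(mols)))
    stopf("could not draw %d molecules with distinct duplicate keys",
          nrow(mols), class = "hicditag_config_error")
  mols[, molecule_id := sprintf("M%06d", .I)]

  # reads from the molecule ends; random mate swap exercises order invariance
  mols[, read_a := substr(molecule, 1L, rl)]
  mols[, read_b := revcomp(substring(molecule, nchar(molecule) - rl + 1L,
                                     nchar(molecule)))]
  swap <- runif(nrow(mols)) < 0.5

  # PCR copy model
  kvals <- as.integer(names(config$pcr_copies))
  copies <- kvals[sample.int(length(kvals), nrow(mols), replace = TRUE,
                             prob = config$pcr_copies)]
  mols[, n_copies := copies]

  emitted <- mols[rep(seq_len(nrow(mols)), copies)]
  emitted[, copy_index := seq_len(.N), by = molecule_id]
  emitted[, read_id := sprintf("%s:%d", molecule_id, copy_index)]
  sw <- rep(swap, copies)
  truth <- data.table::data.table(
    read_id = emitted$read_id, molecule_id = emitted$molecule_id,
    copy_index = emitted$copy_index, category = emitted$category,
    chrom1 = ifelse(sw, emitted$chrom2, emitted$chrom1),
    five_prime1 = ifelse(sw, emitted$five_prime2, emitted$five_prime1),
    strand1 = ifelse(sw, emitted$strand2, emitted$strand1),
    frag_index1 = ifelse(sw, emitted$frag_index2, emitted$frag_index1),
    chrom2 = ifelse(sw, emitted$chrom1, emitted$chrom2),
    five_prime2 = ifelse(sw, emitted$five_prime1, emitted$five_prime2),
    strand2 = ifelse(sw, emitted$strand1, emitted$strand2),
    frag_index2 = ifelse(sw, emitted$frag_index1, emitted$frag_index2),
    insert_size = emitted$insert_size,
    truncated1 = ifelse(sw, emitted$truncated2, emitted$truncated1),
    truncated2 = ifelse(sw, emitted$truncated1, emitted$truncated2),
    seq1 = ifelse(sw, emitted$read_b, emitted$read_a),
    seq2 = ifelse(sw, emitted$read_a, emitted$read_b))

  # barcode model
  if (!is.null(config$barcodes)) {
    set <- as.character(config$barcodes)
    if (config$barcode_model == "pcr") {
      mb1 <- sample(set, nrow(mols), replace = TRUE)
      mb2 <- sample(set, nrow(mols), replace = TRUE)
      truth[, barcode1 := rep(mb1, copies)]
      truth[, barcode2 := rep(mb2, copies)]
    } else {
      truth[, barcode1 := sample(set, .N, replace = TRUE)]
      truth[, barcode2 := sample(set, .N, replace = TRUE)]
    }
    if (config$barcode_valid_rate < 1) {
      spoil <- function(bc) {
        hit <- runif(length(bc)) >= config$barcode_valid_rate
        n_bad <- sum(hit)
        if (n_bad) {
          bad <- vapply(seq_len(n_bad), function(i) {
            repeat {
              cand <- random_bases(4L)
              if (!cand %in% set) return(cand)
            }
          }, character(1))
          bc[hit] <- bad
        }
        bc
      }
      truth[, barcode1 := spoil(barcode1)]
      truth[, barcode2 := spoil(barcode2)]
    }
    truth[, `:=`(seq1 = paste0(barcode1, seq1), seq2 = paste0(barcode2, seq2))]
  } else {
    truth[, `:=`(barcode1 = NA_character_, barcode2 = NA_character_)]
  }

  # shuffle so duplicates are scattered through the files
  truth <- truth[sample.int(nrow(truth))]

  r1 <- file.path(out_dir, "sim_R1.fastq")
  r2 <- file.path(out_dir, "sim_R2.fastq")
  write_fastq(list(id = truth$read_id, seq = truth$seq1,
                   qual = strrep("I", nchar(truth$seq1))), r1)
  write_fastq(list(id = truth$read_id, seq = truth$seq2,
                   qual = strrep("I", nchar(truth$seq2))), r2)
  truth_path <- file.path(out_dir, "sim_truth.tsv")
  data.table::fwrite(truth[, !c("seq1", "seq2")], truth_path, sep = "\t")
  config_path <- file.path(out_dir, "sim_config.yaml")
  cfg <- config
  cfg$barcodes <- if (is.null(cfg$barcodes)) NULL else as.character(cfg$barcodes)
  yaml::write_yaml(unclass(cfg), config_path)
  list(r1 = r1, r2 = r2, truth = truth_path, config = config_path,
       truth_dt = truth)
}
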