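#' Parse a restriction-enzyme specification string
#'
#' Enzyme specifications follow the `"SITE,NAME"` convention where the
#' recognition site carries a caret marking the top-strand cut position,
#' e.g. `"A^AGCTT,HindIII"` (cut after the first base) or `"^GATC,MboI"`
#' (cut before the site). The site may contain IUPAC ambiguity codes.
#'
#' @param spec Character scalar, e.g. `"A^AGCTT,HindIII"`.
#' @return An object of class `EnzymeSpec`: a list with `name`, `site`
#'   (uppercase, caret removed) and `cut_offset` (0-based position of the
#'   cut within the site; `0 <= cut_offset <= nchar(site)`).
#' @examples
#' parse_enzyme_spec("A^AGCTT,HindIII")
#' @export
parse_enzyme_spec <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1L)
  parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
  site_part <- parts[1]
  name <- if (length(parts) >= 2L) parts[2] else ""
  n_caret <- lengths(regmatches(site_part, gregexpr("^", site_part, fixed = TRUE)))
  if (n_caret != 1L)
    stopf("enzyme spec '%s' must contain exactly one caret in the site", spec,
          class = "hicditag_format_error")
  cut_offset <- as.integer(regexpr("^", site_part, fixed = TRUE)) - 1L
  site <- toupper(sub("^", "", site_part, fixed = TRUE))
  L <- nchar(site)
  if (L < 4L)
    stopf("recognition site '%s' shorter than 4 nt", site,
          class = "hicditag_format_error")
  site_regex(site)  # validates the alphabet
  if (!identical(site, revcomp(site)))
    warning(sprintf("recognition site %s is not palindromic; only top-strand cut positions are used", site))
  structure(list(name = name, site = site, cut_offset = cut_offset),
            class = "EnzymeSpec")
}

format_enzyme_spec <- function(enzyme) {
  site <- enzyme$site
  c <- enzyme$cut_offset
  paste0(substr(site, 1L, c), "^", substr(site, c + 1L, nchar(site)),
         if (nzchar(enzyme$name)) paste0(",", enzyme$name) else "")
}

#' @export
print.EnzymeSpec <- function(x, ...) {
  cat(sprintf("EnzymeSpec %s: %s (cut offset %d)\n",
              x$name, format_enzyme_spec(x), x$cut_offset))
  invisible(x)
}

#' Locate restriction cut sites on a sequence
#'
#' Scans the top strand for every (possibly overlapping) occurrence of the
#' recognition site and returns the cut coordinates: the 1-based position of
#' the first base 5' of which the top strand is cleaved. Matching is
#' case-insensitive, IUPAC codes in the site expand to base sets, and `N`
#' in the sequence matches nothing.
#'
#' @param sequence Character scalar of nucleotides.
#' @param enzyme An [EnzymeSpec][parse_enzyme_spec].
#' @return Strictly increasing integer vector of cut coordinates (possibly
#'   empty).
#' @export
find_cut_sites <- function(sequence, enzyme) {
  stopifnot(inherits(enzyme, "EnzymeSpec"), nchar(sequence) > 0L)
  match_starts(sequence, enzyme$site) + enzyme$cut_offset
}

#' Digest a genome in silico into a restriction-fragment map
#'
#' Cuts every chromosome at the top-strand cut coordinates of one or two
#' enzymes and returns the resulting fragment tiling. Fragments are 1-based,
#' inclusive, contiguous and cover each chromosome exactly. In double-digest
#' mode each fragment boundary is tagged with whether it was created by the
#' first enzyme (`re1_end_5p` / `re1_end_3p`); chromosome termini carry
#' `FALSE` since no cut created them.
#'
#' @param genome FASTA file path or named character vector of sequences.
#' @param enzyme1 Primary [EnzymeSpec][parse_enzyme_spec].
#' @param enzyme2 Optional second enzyme for the double-digest protocol.
#' @param genome_id Label stored in the map.
#' @return A `DigestMap`: list with `genome_id`, `enzyme1`, `enzyme2`,
#'   `chrom_lengths`, and `fragments`, a data.table with columns `chrom`,
#'   `start`, `end`, `index`, `re1_end_5p`, `re1_end_3p`.
#' @export
digest_genome <- function(genome, enzyme1, enzyme2 = NULL, genome_id = "genome") {
  genome <- as_genome(genome)
  stopifnot(inherits(enzyme1, "EnzymeSpec"))
  if (!is.null(enzyme2)) stopifnot(inherits(enzyme2, "EnzymeSpec"))
  frag_list <- lapply(names(genome), function(chrom) {
    seq <- genome[[chrom]]
    len <- nchar(seq)
    cuts1 <- find_cut_sites(seq, enzyme1)
    cuts2 <- if (is.null(enzyme2)) integer(0) else find_cut_sites(seq, enzyme2)
    # boundaries strictly inside the chromosome; re1 wins ties
    b <- sort(unique(c(cuts1, cuts2)))
    b <- b[b > 1L & b <= len]
    by_re1 <- b %in% cuts1
    starts <- c(1L, b)
    ends <- c(b - 1L, len)
    data.table::data.table(
      chrom = chrom, start = starts, end = ends,
      index = seq_along(starts),
      re1_end_5p = c(FALSE, by_re1),
      re1_end_3p = c(by_re1, FALSE)
    )
  })
  fragments <- data.table::rbindlist(frag_list)
  structure(list(genome_id = genome_id, enzyme1 = enzyme1, enzyme2 = enzyme2,
                 chrom_lengths = setNames(nchar(genome), names(genome)),
                 fragments = fragments),
            class = "DigestMap")
}

#' @export
print.DigestMap <- function(x, ...) {
  cat(sprintf("DigestMap '%s': %d chromosome(s), %d fragment(s), enzyme %s%s\n",
              x$genome_id, length(x$chrom_lengths), nrow(x$fragments),
              format_enzyme_spec(x$enzyme1),
              if (is.null(x$enzyme2)) "" else paste0(" + ", format_enzyme_spec(x$enzyme2))))
  invisible(x)
}

#' Write / read a digest map as TSV
#'
#' The file starts with a `#`-prefixed header line carrying the genome label
#' and the enzyme specification(s), then a column header and one row per
#' fragment. `read_digest(write_digest(map, f))` is lossless.
#'
#' @param map A `DigestMap` from [digest_genome()].
#' @param path Output file path.
#' @return `write_digest` returns `path` invisibly; `read_digest` returns a
#'   `DigestMap`.
#' @export
write_digest <- function(map, path) {
  stopifnot(inherits(map, "DigestMap"))
  hdr <- paste0("# hicditag-digest\tgenome_id=", map$genome_id,
                "\tre1=", format_enzyme_spec(map$enzyme1),
                if (!is.null(map$enzyme2))
                  paste0("\tre2=", format_enzyme_spec(map$enzyme2)) else "",
                "\tchrom_lengths=",
                paste(sprintf("%s:%d", names(map$chrom_lengths),
                              map$chrom_lengths), collapse = ";"))
  body <- map$fragments[, sprintf("%s\t%d\t%d\t%d\t%d\t%d", chrom, start, end,
                                  index, as.integer(re1_end_5p),
                                  as.integer(re1_end_3p))]
  write_lines_any(c(hdr, "chrom\tstart\tend\tindex\tre1_end_5p\tre1_end_3p", body),
                  path)
  invisible(path)
}

#' @rdname write_digest
#' @export
read_digest <- function(path) {
  lines <- read_lines_any(path)
  if (length(lines) < 2L || !startsWith(lines[1], "# hicditag-digest"))
    stopf("not a hicditag digest file: %s", path, class = "hicditag_format_error")
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  get_field <- function(key) {
    hit <- grep(paste0("^", key, "="), hdr, value = TRUE)
    if (!length(hit)) NULL else sub(paste0("^", key, "="), "", hit[1])
  }
  genome_id <- get_field("genome_id")
  enzyme1 <- parse_enzyme_spec(get_field("re1"))
  re2 <- get_field("re2")
  enzyme2 <- if (is.null(re2)) NULL else parse_enzyme_spec(re2)
  cl <- strsplit(strsplit(get_field("chrom_lengths"), ";", fixed = TRUE)[[1]],
                 ":", fixed = TRUE)
  chrom_lengths <- setNames(as.integer(vapply(cl, `[`, "", 2L)),
                            vapply(cl, `[`, "", 1L))
  if (!identical(strsplit(lines[2], "\t")[[1]],
                 c("chrom", "start", "end", "index", "re1_end_5p", "re1_end_3p")))
    stopf("malformed digest column header in %s", path,
          class = "hicditag_format_error")
  fragments <- data.table::fread(text = lines[-(1:2)], sep = "\t",
                                 header = FALSE,
                                 col.names = c("chrom", "start", "end", "index",
                                               "re1_end_5p", "re1_end_3p"))
  fragments[, `:=`(start = as.integer(start), end = as.integer(end),
                   index = as.integer(index),
                   re1_end_5p = as.logical(re1_end_5p),
                   re1_end_3p = as.logical(re1_end_3p))]
  if (fragments[, any(start > end)])
    stopf("digest file %s contains a fragment with start > end", path,
          class = "hicditag_format_error")
  map <- structure(list(genome_id = genome_id, enzyme1 = enzyme1,
                        enzyme2 = enzyme2, chrom_lengths = chrom_lengths,
                        fragments = fragments),
                   class = "DigestMap")
  validate_digest_map(map)
  map
}

# Tiling invariants: sorted, contiguous, consecutive indices, full coverage.
validate_digest_map <- function(map) {
  fr <- map$fragments
  for (ch in unique(fr$chrom)) {
    f <- fr[chrom == ch]
    if (!identical(f$index, seq_len(nrow(f))))
      stopf("fragment indices not consecutive on %s", ch,
            class = "hicditag_format_error")
    if (f$start[1] != 1L || f$end[nrow(f)] != map$chrom_lengths[[ch]])
      stopf("fragments do not span chromosome %s", ch,
            class = "hicditag_format_error")
    if (nrow(f) > 1L && any(f$start[-1] != f$end[-nrow(f)] + 1L))
      stopf("fragments not contiguous on %s", ch,
            class = "hicditag_format_error")
  }
  invisible(map)
}
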