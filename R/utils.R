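# Internal helpers shared across modules.

#' @import data.table
#' @importFrom stats runif rbinom setNames
#' @importFrom utils head tail
NULL

# IUPAC nucleotide codes -> the base set each matches. Genome 'N' is a
# padding character and must match nothing, so sets never contain N itself.
IUPAC_SETS <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

stopf <- function(fmt, ..., class = "hicditag_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "hicditag_error")))
}

is_gz <- function(path) grepl("\\.gz$", path)

#' Reverse-complement nucleotide strings
#'
#' Vectorised reverse complement over plain character strings, including
#' IUPAC ambiguity codes.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Expand an IUPAC site to a perl regex. With lookahead = TRUE the pattern
# matches at every (possibly overlapping) start position.
site_regex <- function(site, lookahead = FALSE) {
  chars <- strsplit(toupper(site), "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad))
    stopf("site '%s' contains non-IUPAC character(s): %s", site,
          paste(unique(bad), collapse = ", "), class = "hicditag_alphabet_error")
  body <- paste(vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (nchar(set) == 1L) set else paste0("[", set, "]")
  }, character(1)), collapse = "")
  if (lookahead) paste0("(?=", body, ")") else body
}

# 1-based start positions of all (overlapping) occurrences of an IUPAC
# pattern in a single sequence. Case-insensitive; genome N matches nothing.
match_starts <- function(sequence, site) {
  m <- gregexpr(site_regex(site, lookahead = TRUE), toupper(sequence),
                perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

# Read a (possibly gzipped) text file as lines.
read_lines_any <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path, class = "hicditag_io_error")
  con <- if (is_gz(path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con)
}

write_lines_any <- function(lines, path) {
  con <- if (is_gz(path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
}

# Coerce a genome argument (FASTA path, DNAStringSet, or named character
# vector) into a named character vector of uppercase sequences.
as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      is.null(names(genome))) {
    gss <- Biostrings::readDNAStringSet(genome)
    names(gss) <- sub("\\s.*$", "", names(gss))
    genome <- setNames(as.character(gss), names(gss))
  } else if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (!is.character(genome) || is.null(names(genome)) || any(names(genome) == ""))
    stopf("genome must be a FASTA path or a named character vector",
          class = "hicditag_io_error")
  if (anyDuplicated(names(genome)))
    stopf("duplicate chromosome names in genome", class = "hicditag_format_error")
  if (any(nchar(genome) == 0L))
    stopf("empty sequence in genome", class = "hicditag_io_error")
  toupper(genome)
}

# Write a named character vector as wrapped FASTA.
write_fasta <- function(genome, path, width = 70L) {
  lines <- unlist(lapply(names(genome), function(nm) {
    s <- genome[[nm]]
    n <- nchar(s)
    starts <- seq(1L, n, by = width)
    c(paste0(">", nm), substring(s, starts, pmin(starts + width - 1L, n)))
  }), use.names = FALSE)
  write_lines_any(lines, path)
}
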