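# Minimal paired-end FASTQ I/O (4-line records, Phred+33, gzip transparent).

#' Read a FASTQ file
#'
#' @param path FASTQ file, plain or gzip-compressed.
#' @return A list with character vectors `id` (first token of the header,
#'   `@` stripped), `header` (full header line), `seq` and `qual`.
#' @export
read_fastq <- function(path) {
  lines <- read_lines_any(path)
  if (length(lines) %% 4L != 0L)
    stopf("FASTQ %s: line count not a multiple of 4", path,
          class = "hicditag_format_error")
  n <- length(lines) %/% 4L
  if (n == 0L)
    return(list(id = character(0), header = character(0),
                seq = character(0), qual = character(0)))
  at <- seq(1L, length(lines), by = 4L)
  header <- lines[at]
  seq <- lines[at + 1L]
  plus <- lines[at + 2L]
  qual <- lines[at + 3L]
  if (!all(startsWith(header, "@")) || !all(startsWith(plus, "+")))
    stopf("FASTQ %s: malformed record structure", path,
          class = "hicditag_format_error")
  if (!all(nchar(seq) == nchar(qual)))
    stopf("FASTQ %s: sequence/quality length mismatch", path,
          class = "hicditag_format_error")
  id <- sub("\\s.*$", "", substring(header, 2L))
  list(id = id, header = substring(header, 2L), seq = toupper(seq), qual = qual)
}

#' Write a FASTQ file
#'
#' @param fq List as returned by [read_fastq()] (`header` optional).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(fq, path) {
  header <- if (!is.null(fq$header)) fq$header else fq$id
  n <- length(fq$seq)
  lines <- character(4L * n)
  if (n) {
    at <- seq(1L, 4L * n, by = 4L)
    lines[at] <- paste0("@", header)
    lines[at + 1L] <- fq$seq
    lines[at + 2L] <- "+"
    lines[at + 3L] <- fq$qual
  }
  write_lines_any(lines, path)
  invisible(path)
}
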