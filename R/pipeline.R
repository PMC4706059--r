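# Master orchestration: truncate -> map -> pair -> filter -> dedup -> report.
#
# Each stage persists its outputs and statistics into the run directory;
# with resume = TRUE a stage whose outputs already exist is skipped, so an
# interrupted run reuses completed stages.

#' Pipeline configuration
#'
#' Validates and normalises the orchestrator's parameters; every field is
#' echoed verbatim into `run.log` before any stage executes.
#'
#' @param r1,r2 Paired FASTQ inputs (plain or gzip).
#' @param genome FASTA path or named character vector.
#' @param re1 Enzyme specification string (e.g. `"A^AGCTT,HindIII"`).
#' @param re2 Optional second enzyme (double-digest protocol).
#' @param out_dir Run directory (created).
#' @param aligner `"builtin"` (exact aligner), `"bowtie2"`/`"bowtie"`
#'   (external, needs `index_prefix`), or `"none"` (pre-aligned per-mate
#'   SAM via `sam1`/`sam2`).
#' @param index_prefix,sam1,sam2 Aligner inputs, depending on `aligner`.
#' @param size_range Size-selection window (bp).
#' @param mode `"sonication"` or `"double_digest"`.
#' @param truncate Whether to run junction truncation; defaults to `TRUE`
#'   for the sonication protocol and `FALSE` for double digest (no fill-in).
#' @param barcodes Optional [barcode_set()]: barcodes are recorded from the
#'   first 4 nt of every read and trimmed before truncation.
#' @param min_trunc_len Post-truncation length flagged as short.
#' @param mapq_min MAPQ threshold for external-aligner uniqueness.
#' @param keep_rejects Also write the non-valid di-tags as SAM.
#' @param sample Sample label used in report and SAM header.
#' @param resume Reuse existing stage outputs.
#' @return A validated `PipelineConfig` list.
#' @export
pipeline_config <- function(r1, r2, genome, re1, re2 = NULL, out_dir,
                            aligner = c("builtin", "bowtie2", "bowtie", "none"),
                            index_prefix = NULL, sam1 = NULL, sam2 = NULL,
                            size_range = c(150, 800),
                            mode = c("sonication", "double_digest"),
                            truncate = NULL, barcodes = NULL,
                            min_trunc_len = 20L, mapq_min = 30L,
                            keep_rejects = FALSE, sample = "sample",
                            resume = FALSE) {
  aligner <- match.arg(aligner)
  mode <- match.arg(mode)
  enzyme1 <- parse_enzyme_spec(re1)   # fails fast on a bad spec
  enzyme2 <- if (!is.null(re2)) parse_enzyme_spec(re2) else NULL
  if (mode == "double_digest" && is.null(enzyme2))
    stopf("double_digest mode needs a second enzyme (re2)",
          class = "hicditag_config_error")
  if (is.null(truncate)) truncate <- mode == "sonication"
  if (aligner == "none" && (is.null(sam1) || is.null(sam2)))
    stopf("aligner 'none' needs pre-aligned sam1 and sam2",
          class = "hicditag_config_error")
  if (aligner %in% c("bowtie", "bowtie2") && is.null(index_prefix))
    stopf("external aligner needs index_prefix", class = "hicditag_config_error")
  if (!is.null(barcodes)) barcodes <- barcode_set(barcodes)
  structure(list(r1 = r1, r2 = r2, genome = genome, re1 = re1, re2 = re2,
                 enzyme1 = enzyme1, enzyme2 = enzyme2, out_dir = out_dir,
                 aligner = aligner, index_prefix = index_prefix,
                 sam1 = sam1, sam2 = sam2,
                 size_range = as.integer(size_range), mode = mode,
                 truncate = truncate, barcodes = barcodes,
                 min_trunc_len = as.integer(min_trunc_len),
                 mapq_min = as.integer(mapq_min),
                 keep_rejects = keep_rejects, sample = sample,
                 resume = resume),
            class = "PipelineConfig")
}

log_line <- function(path, ...) {
  cat(paste0(paste0(...), "\n"), file = path, append = TRUE)
}

write_kv_tsv <- function(x, path) {
  dt <- data.table::as.data.table(x)
  data.table::fwrite(dt, path, sep = "\t")
}

#' Run the full di-tag processing pipeline
#'
#' Executes truncation, independent per-mate alignment, re-pairing,
#' artifact filtering, PCR de-duplication and report rendering in order,
#' persisting every stage's outputs and statistics under the run directory.
#' A failed run leaves completed stages reusable via `resume = TRUE`.
#'
#' @param config A [pipeline_config()] — or the arguments of
#'   [pipeline_config()] passed through `...`.
#' @param ... Used when `config` is not a `PipelineConfig`.
#' @return Invisibly, a list with the run directory, the per-stage output
#'   paths, and the [summarize_run()] summary.
#' @export
run_pipeline <- function(config, ...) {
  if (!inherits(config, "PipelineConfig"))
    config <- pipeline_config(config, ...)
  for (f in c(config$r1, config$r2))
    if (!file.exists(f)) stopf("input not found: %s", f, class = "hicditag_io_error")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- function(...) file.path(config$out_dir, ...)
  logf <- od("run.log")
  if (!config$resume && file.exists(logf)) file.remove(logf)
  log_line(logf, "hicditag run, package version ",
           as.character(utils::packageVersion("hicditag")))
  cfg_echo <- config[setdiff(names(config), c("enzyme1", "enzyme2"))]
  cfg_echo$barcodes <- if (is.null(cfg_echo$barcodes)) "none" else
    paste(as.character(cfg_echo$barcodes), collapse = ",")
  for (nm in names(cfg_echo))
    log_line(logf, "config ", nm, " = ",
             paste(format(cfg_echo[[nm]]), collapse = " "))
  done <- function(...) config$resume && all(file.exists(od(...)))
  stage <- function(name, outputs, fn) {
    if (done(outputs)) {
      log_line(logf, "stage ", name, ": reusing existing outputs")
      return(FALSE)
    }
    log_line(logf, "stage ", name, ": running")
    tryCatch(fn(), error = function(e) {
      log_line(logf, "stage ", name, " FAILED: ", conditionMessage(e))
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e),
            class = "hicditag_stage_error")
    })
    TRUE
  }

  # digest ------------------------------------------------------------
  stage("digest", "digest.tsv", function() {
    map <- digest_genome(config$genome, config$enzyme1, config$enzyme2,
                         genome_id = config$sample)
    write_digest(map, od("digest.tsv"))
  })
  map <- read_digest(od("digest.tsv"))

  # barcode extraction / trimming -------------------------------------
  r1 <- config$r1
  r2 <- config$r2
  if (!is.null(config$barcodes)) {
    stage("barcodes", c("barcodes.tsv", "nobc_R1.fastq", "nobc_R2.fastq"),
          function() {
      fq1 <- read_fastq(config$r1)
      fq2 <- read_fastq(config$r2)
      b1 <- extract_barcode(fq1$seq, config$barcodes)
      b2 <- extract_barcode(fq2$seq, config$barcodes)
      data.table::fwrite(data.table::data.table(
        read_id = fq1$id, barcode1 = b1$barcode, valid1 = b1$valid,
        barcode2 = b2$barcode, valid2 = b2$valid),
        od("barcodes.tsv"), sep = "\t")
      fq1$seq <- substring(fq1$seq, 5L); fq1$qual <- substring(fq1$qual, 5L)
      fq2$seq <- substring(fq2$seq, 5L); fq2$qual <- substring(fq2$qual, 5L)
      write_fastq(fq1, od("nobc_R1.fastq"))
      write_fastq(fq2, od("nobc_R2.fastq"))
    })
    r1 <- od("nobc_R1.fastq")
    r2 <- od("nobc_R2.fastq")
  }

  # truncate -----------------------------------------------------------
  trunc_out <- c("trunc_R1.fastq", "trunc_R2.fastq", "truncation_stats.tsv")
  stage("truncate", trunc_out, function() {
    if (config$truncate) {
      junction <- ligation_junction(config$enzyme1)
      st <- truncate_fastq(r1, r2, junction, od("trunc_R1.fastq"),
                           od("trunc_R2.fastq"), config$min_trunc_len)
    } else {
      # no fill-in in this protocol: pass reads through unchanged
      fq1 <- read_fastq(r1); fq2 <- read_fastq(r2)
      write_fastq(fq1, od("trunc_R1.fastq"))
      write_fastq(fq2, od("trunc_R2.fastq"))
      st <- list(r1 = truncation_stats(fq1, logical(length(fq1$seq)),
                                       config$min_trunc_len),
                 r2 = truncation_stats(fq2, logical(length(fq2$seq)),
                                       config$min_trunc_len))
    }
    write_kv_tsv(data.table::rbindlist(list(c(mate = 1L, st$r1),
                                            c(mate = 2L, st$r2))),
                 od("truncation_stats.tsv"))
  })

  # map + pair ----------------------------------------------------------
  map_out <- c("ditags.tsv", "mapping_stats.tsv", "pairing_stats.tsv")
  stage("map", map_out, function() {
    alns <- lapply(1:2, function(m) {
      fq <- od(sprintf("trunc_R%d.fastq", m))
      switch(config$aligner,
             builtin = align_builtin_exact(fq, config$genome, mate = m),
             none = read_sam_alignments(if (m == 1L) config$sam1 else config$sam2,
                                        mate = m, mapq_min = config$mapq_min),
             {
               sam <- od(sprintf("aligned_R%d.sam", m))
               align_external(fq, config$index_prefix, sam, config$aligner)
               read_sam_alignments(sam, mate = m, aligner = config$aligner,
                                   mapq_min = config$mapq_min)
             })
    })
    paired <- pair_reads(alns[[1]], alns[[2]])
    data.table::fwrite(paired$ditags, od("ditags.tsv"), sep = "\t")
    write_kv_tsv(data.table::rbindlist(list(c(mate = 1L, paired$stats$r1),
                                            c(mate = 2L, paired$stats$r2))),
                 od("mapping_stats.tsv"))
    write_kv_tsv(paired$stats[c("pairs_in", "pairs_formed")],
                 od("pairing_stats.tsv"))
  })

  # filter ---------------------------------------------------------------
  filter_out <- c("valid.sam", "filter_stats.tsv")
  stage("filter", filter_out, function() {
    ditags <- data.table::fread(od("ditags.tsv"), sep = "\t",
                                colClasses = list(character = c("seq1", "qual1",
                                                                "seq2", "qual2")))
    res <- filter_ditags(ditags, map, config$size_range, config$mode)
    write_ditag_sam(res$valid, map$chrom_lengths, od("valid.sam"),
                    config$sample)
    if (config$keep_rejects)
      write_ditag_sam(res$rejects, map$chrom_lengths, od("rejects.sam"),
                      config$sample)
    counts <- res$stats$category_counts
    write_kv_tsv(data.table::data.table(category = names(counts),
                                        count = counts),
                 od("filter_stats.tsv"))
  })

  # dedup ----------------------------------------------------------------
  dedup_out <- c("dedup.sam", "dedup_stats.tsv")
  stage("dedup", dedup_out, function() {
    valid <- read_ditag_sam(od("valid.sam"))
    dd <- dedup_ditags(valid)
    write_ditag_sam(dd$unique, map$chrom_lengths, od("dedup.sam"),
                    config$sample)
    write_kv_tsv(dd$stats[c("ditags_in", "ditags_unique", "fraction_unique",
                            "cis_count", "trans_count")],
                 od("dedup_stats.tsv"))
  })

  # report ---------------------------------------------------------------
  stage("report", c("hicditag_summary.tsv", "hicditag_report.html"), function() {
    render_report(summarize_run(config$out_dir, config$sample), config$out_dir)
  })

  summary <- summarize_run(config$out_dir, config$sample)
  log_line(logf, "run complete: ", summary$row$paired, " paired, ",
           summary$row$valid, " valid, ", summary$row$unique_ditags, " unique")
  invisible(list(out_dir = config$out_dir,
                 paths = list(digest = od("digest.tsv"),
                              valid_sam = od("valid.sam"),
                              dedup_sam = od("dedup.sam"),
                              report = od("hicditag_report.html"),
                              summary_tsv = od("hicditag_summary.tsv")),
                 summary = summary))
}
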