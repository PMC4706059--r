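# Per-stage statistics aggregation and QC report rendering.
#
# Every count is stored next to its denominator so each percentage can be
# recomputed exactly; the HTML report is a pure function of the summary
# table (re-rendering is byte-identical).

FILTER_REPORT_CATEGORIES <- c(
  VALID = "Valid pairs", SAME_CIRCULARISED = "Circularised",
  SAME_DANGLING = "Dangling ends", SAME_INTERNAL = "Same internal",
  RELIGATION = "Re-ligation", CONTIGUOUS = "Contiguous",
  WRONG_SIZE = "Wrong size", DOUBLE_DIGEST_INVALID = "Double-digest invalid")

pct_of <- function(count, den) ifelse(den > 0, 100 * count / den, 0)

read_stage_tsv <- function(run_dir, file, stage) {
  path <- file.path(run_dir, file)
  if (!file.exists(path))
    stopf("incomplete run: stage '%s' output missing (%s)", stage, file,
          class = "hicditag_incomplete_run")
  data.table::fread(path, sep = "\t")
}

#' Summarise a pipeline run directory
#'
#' Reads the per-stage statistics TSVs written by [run_pipeline()] and
#' aggregates them into a single-row summary with fixed denominators:
#' truncation and mapping rows are percentages of reads per mate, pairing
#' of read pairs in, the di-tag categories of paired di-tags, unique of
#' valid di-tags, and trans of unique di-tags.
#'
#' @param run_dir Pipeline output directory.
#' @param sample Sample label for the summary row.
#' @return A `StageSummary` list: the per-stage tables plus `row`, the
#'   one-row combined data.table with stable column order.
#' @export
summarize_run <- function(run_dir, sample = basename(run_dir)) {
  trunc <- read_stage_tsv(run_dir, "truncation_stats.tsv", "truncate")
  mapping <- read_stage_tsv(run_dir, "mapping_stats.tsv", "map")
  pairing <- read_stage_tsv(run_dir, "pairing_stats.tsv", "pair")
  filt <- read_stage_tsv(run_dir, "filter_stats.tsv", "filter")
  dedup <- read_stage_tsv(run_dir, "dedup_stats.tsv", "dedup")

  row <- data.table::data.table(sample = sample)
  for (m in 1:2) {
    tr <- trunc[mate == m]
    mp <- mapping[mate == m]
    row[, paste0("reads_r", m) := tr$reads_total]
    row[, paste0("truncated_r", m) := tr$reads_truncated]
    row[, paste0("truncated_r", m, "_pct") := pct_of(tr$reads_truncated, tr$reads_total)]
    row[, paste0("unique_map_r", m) := mp$unique_mapped]
    row[, paste0("unique_map_r", m, "_pct") := pct_of(mp$unique_mapped, mp$reads_in)]
    row[, paste0("multi_map_r", m) := mp$multi_mapped]
    row[, paste0("multi_map_r", m, "_pct") := pct_of(mp$multi_mapped, mp$reads_in)]
    row[, paste0("unmapped_r", m) := mp$unmapped]
    row[, paste0("unmapped_r", m, "_pct") := pct_of(mp$unmapped, mp$reads_in)]
  }
  row[, pairs_in := pairing$pairs_in]
  row[, paired := pairing$pairs_formed]
  row[, paired_pct := pct_of(pairing$pairs_formed, pairing$pairs_in)]
  n_paired <- pairing$pairs_formed
  for (cat in names(FILTER_REPORT_CATEGORIES)) {
    cnt <- filt[category == cat, sum(count)]
    nm <- tolower(cat)
    row[, (nm) := cnt]
    row[, paste0(nm, "_pct") := pct_of(cnt, n_paired)]
  }
  row[, unique_ditags := dedup$ditags_unique]
  row[, unique_pct := pct_of(dedup$ditags_unique, dedup$ditags_in)]
  row[, cis := dedup$cis_count]
  row[, trans := dedup$trans_count]
  row[, trans_pct := pct_of(dedup$trans_count, dedup$ditags_unique)]
  row[, trans_cis_ratio := ifelse(dedup$cis_count > 0,
                                  dedup$trans_count / dedup$cis_count, NA_real_)]
  structure(list(sample = sample, truncation = trunc, mapping = mapping,
                 pairing = pairing, filter = filt, dedup = dedup, row = row),
            class = "StageSummary")
}

#' @export
print.StageSummary <- function(x, ...) {
  cat(sprintf("StageSummary '%s': %d pairs in, %d paired, %d valid, %d unique\n",
              x$sample, x$row$pairs_in, x$row$paired, x$row$valid,
              x$row$unique_ditags))
  invisible(x)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(dt) {
  fmt <- function(v) {
    if (is.numeric(v)) {
      ifelse(is.na(v), "NA",
             ifelse(!is.na(v) & v == round(v),
                    format(v, scientific = FALSE, trim = TRUE),
                    sprintf("%.2f", v)))
    } else {
      html_escape(ifelse(is.na(v), "NA", as.character(v)))
    }
  }
  cells <- vapply(dt, fmt, character(nrow(dt)))
  cells <- matrix(cells, nrow = nrow(dt))
  rows <- apply(cells, 1L, function(r)
    paste0("<tr><td>", paste(r, collapse = "</td><td>"), "</td></tr>"))
  paste0("<table><thead><tr><th>",
         paste(html_escape(names(dt)), collapse = "</th><th>"),
         "</th></tr></thead><tbody>", paste(rows, collapse = ""),
         "</tbody></table>")
}

# Inline SVG horizontal bar chart of di-tag category percentages.
svg_category_bars <- function(row) {
  cats <- names(FILTER_REPORT_CATEGORIES)
  pcts <- vapply(cats, function(cat) row[[paste0(tolower(cat), "_pct")]], 0)
  h <- 22L
  bars <- vapply(seq_along(cats), function(i) {
    y <- (i - 1L) * h
    sprintf(paste0('<text x="0" y="%d" font-size="12">%s</text>',
                   '<rect x="130" y="%d" width="%.1f" height="14" fill="#4878a8"/>',
                   '<text x="%.1f" y="%d" font-size="11">%.2f%%</text>'),
            y + 12L, html_escape(FILTER_REPORT_CATEGORIES[[cats[i]]]),
            y + 2L, 3 * pcts[i], 140 + 3 * pcts[i], y + 12L, pcts[i])
  }, character(1))
  sprintf('<svg width="520" height="%d" xmlns="http://www.w3.org/2000/svg">%s</svg>',
          length(cats) * h, paste(bars, collapse = ""))
}

#' Render the QC report
#'
#' Writes a combined one-row-per-sample summary TSV (stable column names
#' and order) and a self-contained static HTML report (inline CSS and SVG,
#' no network assets, no timestamps) listing every stage's statistics and a
#' bar chart of the di-tag categories.
#'
#' @param summaries A `StageSummary` or list of them.
#' @param out_dir Output directory.
#' @return List with `tsv` and `html` paths.
#' @export
render_report <- function(summaries, out_dir) {
  if (inherits(summaries, "StageSummary")) summaries <- list(summaries)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, showWarnings = FALSE, recursive = TRUE))
    stopf("cannot create report directory %s", out_dir,
          class = "hicditag_io_error")
  combined <- data.table::rbindlist(lapply(summaries, `[[`, "row"))
  tsv <- file.path(out_dir, "hicditag_summary.tsv")
  data.table::fwrite(combined, tsv, sep = "\t")

  zero_dens <- combined[, sample[pairs_in == 0 | paired == 0 | unique_ditags == 0]]
  sections <- vapply(summaries, function(s) {
    paste0("<h2>Sample: ", html_escape(s$sample), "</h2>",
           "<h3>Truncation</h3>", html_table(s$truncation),
           "<h3>Mapping</h3>", html_table(s$mapping),
           "<h3>Pairing</h3>", html_table(s$pairing),
           "<h3>Di-tag categories</h3>", html_table(s$filter),
           svg_category_bars(s$row),
           "<h3>Deduplication</h3>", html_table(s$dedup))
  }, character(1))
  html <- paste0(
    "<!DOCTYPE html><html><head><meta charset=\"utf-8\">",
    "<title>hicditag QC report</title><style>",
    "body{font-family:sans-serif;margin:2em;max-width:70em}",
    "table{border-collapse:collapse;margin:0.5em 0}",
    "td,th{border:1px solid #999;padding:2px 8px;font-size:13px;text-align:right}",
    "th{background:#eee}</style></head><body>",
    "<h1>hicditag QC report</h1>",
    "<h2>Combined summary</h2>", html_table(combined),
    paste(sections, collapse = ""),
    "<hr><p style=\"font-size:12px\">Denominators: truncation and mapping ",
    "percentages are of reads per mate; paired of read pairs in; di-tag ",
    "categories of paired di-tags; unique of valid di-tags; trans of unique ",
    "di-tags. Zero denominators are reported as 0",
    if (length(zero_dens)) paste0(" (zero-denominator sample(s): ",
                                  html_escape(paste(zero_dens, collapse = ", ")), ")"),
    ". Template v1.</p></body></html>")
  html_path <- file.path(out_dir, "hicditag_report.html")
  write_lines_any(html, html_path)
  list(tsv = tsv, html = html_path)
}
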