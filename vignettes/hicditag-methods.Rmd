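---
title: "Processing Hi-C di-tags with hicditag: models, filters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing Hi-C di-tags with hicditag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicditag)
```

## The problem

Hi-C and Capture Hi-C libraries sequence *di-tags*: chimeric molecules in
which two restriction fragments that were spatially close in the nucleus
were filled in with biotin, blunt-ligated, sheared and sequenced as a read
pair. Unlike ordinary paired-end data, the two mates of a valid di-tag do
not span one contiguous genomic interval, and a substantial fraction of
any real library consists of molecules the protocol produces as side
products — self-ligated (circularised) fragments, unligated fragments
(dangling ends and internal fragments), re-ligated neighbours, undigested
contigs, molecules outside the size-selection window, and PCR copies.
Leaving these in the data biases every downstream contact analysis, so
they must be recognised and removed at the read level.

`hicditag` implements this read-level processing: junction-aware
truncation, in-silico digestion, independent per-mate alignment and
re-pairing, geometric artifact classification, PCR de-duplication,
barcode-based duplicate diagnostics, and per-stage QC reporting. It stops
exactly where interaction calling starts: no normalisation or statistical
testing is performed.

## The ligation junction and read truncation

For a palindromic restriction site of length $L$ cut at offset $c$ on the
top strand (a 5' overhang or blunt cutter, $c \le L - c$), fill-in and
blunt ligation of two cut ends create the junction sequence

$$J = s_{[1..c]} \; \omega \; \omega \; s_{[L-c+1..L]},\qquad
  \omega = s_{[c+1..L-c]},$$

where $s$ is the site and $\omega$ the filled-in overhang. For HindIII
(`A^AGCTT`) this gives `AAGCTAGCTT`; the junction contains no complete
copy of the original site and is absent from the unligated genome. A read
that crosses the ligation point carries $J$, and everything 3' of the
crossing belongs to the partner fragment, so the read is truncated.

Two choices here were genuinely open and are fixed as follows:

* **Retained length is $p + k$** where $p$ is the junction offset and
  $k = L - c$: the first $k$ junction bases are genomically contiguous
  with the read's own fragment (the real half-site plus the filled
  overhang maps to the reference immediately across the cut), so keeping
  them maximises alignable sequence. Keeping only $p$ bases would discard
  mappable signal; keeping more would append partner-fragment sequence
  that cannot map.
* **First junction occurrence wins** when several occur: the 5'-most
  ligation event delimits the fragment the read actually starts in.
* Matching is an exact string match (IUPAC-aware); no mismatch model is
  applied because reads carrying sequencing errors in the junction
  simply stay untruncated and are then handled by the alignment and
  size filters.

Truncation is idempotent: the retained prefix always ends $c$ bases
before a complete junction copy, so a second pass never fires.

## In-silico digestion

Coordinates are 1-based inclusive throughout (the SAM convention); the
cut coordinate is the position of the first base 5' of which the top
strand is cleaved, and fragment boundaries are placed at cut coordinates:
a chromosome with cuts $b_1 < \dots < b_n$ tiles into fragments
$[1, b_1 - 1], [b_1, b_2 - 1], \dots, [b_n, \mathrm{len}]$. Only
top-strand cut positions are used; for the palindromic cutters the
protocol employs the strands are equivalent, and non-palindromic sites
trigger a warning. Ambiguity codes in the site are matched by base-set
expansion and `N` in the genome matches nothing, which prevents spurious
fragments in padded assemblies. In double-digest mode the boundaries of
both enzymes are merged and each boundary remembers which enzyme created
it. The digest TSV dialect is the package's own (header line with genome
label and enzyme specs, then one row per fragment); round-trip fidelity
is its contract.

## Alignment and re-pairing

Mates are aligned independently in single-end mode and re-paired
afterwards, keeping read pairs in which both mates aligned uniquely.
"Unique and high quality" is made precise as: mapped, MAPQ at least 30
(configurable), and no secondary alignment score equal to or better than
the primary (`XS >= AS`). For bowtie (v1) invoked with single-best,
suppress-multi settings, any reported alignment counts as unique.

The package also ships a built-in **exact aligner**: an exhaustive
substring search of the read and its reverse complement over the genome,
implemented with a k-mer positional index and full verification. A read
is unique iff it occurs exactly once in total. It exists so that the
entire pipeline, including its tests, runs with zero external
dependencies on error-free simulated reads; it is not a general-purpose
aligner and does not model mismatches, gaps or quality.

## Di-tag classification

Each mate's 5' base is assigned to a restriction fragment by binary
search. Per end, the distance to the fragment boundary in the read's 3'
direction (inclusive) is computed; the sum over both ends is the
theoretical insert size — the length the sequenced molecule would have
had as a genuine ligation product. Categories are then decided by the
first matching rule:

1. same fragment, reads pointing away from each other → **circularised**;
2. same fragment, facing, either 5' base exactly on a fragment boundary →
   **dangling end**;
3. same fragment otherwise → **internal fragment**;
4. adjacent fragments, facing across the shared boundary → **re-ligation**;
5. same chromosome, facing, outermost genomic span within the
   size-selection window → **contiguous**;
6. insert size outside the window → **wrong size**;
7. otherwise **valid**, sub-labelled cis or trans.

The precedence order is a design decision: the source protocol lists the
filters without an order, and same-fragment geometry is checked first
because it is independent of the size parameters. Further fixed choices:

* "Overlapping a cut site" (dangling ends) means exact coincidence of the
  read's 5' base with a fragment terminal coordinate — the
  sonication-end-at-cut-site is the biotin-bearing signature, and any
  looser notion of overlap would be arbitrary.
* The contiguous rule uses the outermost span (5' base of the plus-strand
  mate to 5' base of the minus-strand mate, inclusive) against the same
  size-selection window, since an undigested contig is a single
  contiguous molecule of selectable length.
* Fragment assignment uses the 5' base rather than the read midpoint;
  the 5' base is the sonication (or second-cut) endpoint and is needed
  for dangling-end detection anyway.
* Same-fragment pairs on the *same* strand match neither "facing" nor
  "away"; no protocol mechanism produces them from a single fragment, and
  they are binned as internal fragments (uninformative same-fragment
  species) rather than given a category of their own.
* Whether wrong-size should be tested before re-ligation/contiguous is
  not observable from single categories alone; the order above is
  explicit and deterministic, not claimed identical to any other tool.
* The default size-selection window is 150–800 bp — a typical Hi-C
  sonication selection — used only when the experimenter supplies none,
  and always echoed in the run log.

In double-digest mode two checks run before rule 1, and failing either
places the di-tag in an explicit **double-digest invalid** category
(reported alongside the others so that counts stay conserved): every
read must begin exactly at a cut coordinate, and each read's
ligation-side fragment boundary must have been created by the first
enzyme. Junction truncation is skipped by default in this mode because
the protocol variant omits the fill-in.

## De-duplication and barcode diagnostics

Two di-tags are PCR duplicates iff their sonication endpoints coincide:
the duplicate key is the pair of (chromosome, 5' position, strand)
triples with the two ends ordered lexicographically, so mate order is
irrelevant. Sequences and aligned lengths are deliberately excluded —
truncation alters lengths, while the endpoints identify the molecule.
The first-seen copy is kept, which is deterministic without comparing
qualities. Cis/trans composition and the trans/cis ratio are reported on
the unique set; a high trans fraction indicates spurious ligation.

The barcode module reproduces the duplicate-origin diagnostic: when one
of four 4-nt barcode adapters is ligated to each end of every molecule
*before* amplification, PCR copies inherit their molecule's ordered
barcode combination, whereas independent molecules that coincide on the
duplicate key draw combinations independently — matching with
probability $(1/16)^{c-1}$ for $c$ equimolar copies. Tabulating, per
duplicate-group size, the percentage of groups whose members share one
combination therefore separates the two explanations: 100% exactly under
pure PCR duplication, 6.25% for pairs under independence. The
combination is ordered (end1, end2) by default; an unordered variant is
available and raises the independence null by the collision term.
Because the built-in aligner performs exact matching, the pipeline
records and trims barcodes before truncation whenever a barcode set is
configured; this mirrors the trim-then-map handling of real barcoded
libraries.

## The simulator: what it emulates and what it does not

`simulate_library()` is the package's test and acceptance surface. It
constructs molecules whose read geometry satisfies each category's
definition, on a seeded random genome with restriction sites planted at
random spacings (800–3000 bp, with every fifth spacing drawn short,
450–650 bp, so fragments eligible for contiguous molecules always
exist). Ligated molecules are assembled exactly as the chemistry does —
genomic piece, filled-in overhang, partner piece — so the junction arises
at the seam and truncation, alignment and classification can be verified
end to end against per-read ground truth. Occurrences of the junction
sequence arising by chance in the random genome are mutated away,
preserving the junction's defining property.

Deliberate simplifications, and what they mean for the tests:

* **Reads are error-free.** This makes the exact aligner a faithful
  oracle and planted category counts exactly recoverable; it also means
  passing tests say nothing about robustness to sequencing error,
  aligner heuristics, or mismatched junctions in real data.
* **Sonication endpoints are uniform** within each category's allowed
  span — the simplest null satisfying the geometric constraints; real
  libraries have contact-distance decay, GC and fragment-length biases,
  none of which are modelled.
* Endpoint distances to the ligation seam avoid the narrow window
  (between $r - |J|$ and $r$ bases for read length $r$) in which a read
  would cross the seam without containing the complete junction; such a
  read is unmappable by exact matching, and real aligners handle it
  idiosyncratically. Within the window below $r - |J|$ truncation fires,
  so truncation statistics remain exactly predictable per draw.
* **Molecule duplicate keys are unique by construction** (colliding
  draws are redrawn), so duplication enters only through the explicit
  PCR-copy model and dedup survivors equal the number of distinct
  molecules exactly.
* No capture enrichment, no optical duplicates, no adapter read-through.

Default study conditions: three 150 kb chromosomes, HindIII, 50 nt
reads, a 150–800 bp size window, 30 bp minimum endpoint-to-boundary
distance, an artifact mix of 40% valid cis / 10% valid trans / 8%
circularised / 10% dangling / 10% internal / 8% re-ligation / 7%
contiguous / 7% wrong size, and no PCR duplication unless requested.
These sizes keep a 10,000 di-tag end-to-end run around ten seconds on a
single core while leaving every category with hundreds of members.

## Reporting

Every count is stored beside its denominator, with the denominators
fixed as: truncation and mapping percentages per mate's reads, pairing
of read pairs in, category percentages of paired di-tags, unique of
valid di-tags, trans of unique di-tags. The summary TSV is the single
source of truth; the static HTML report (inline CSS and SVG, no
timestamps, no network assets) is a pure function of it and re-renders
byte-identically. Zero denominators report a percentage of 0 and are
flagged in the report footer.

## Numerical and degenerate-input choices

* All coordinates are 1-based inclusive; a cut coordinate of 1 (a site
  at the chromosome start for a `c = 0` cutter) creates no boundary.
* Reads shorter than 20 nt after truncation are written and counted but
  flagged; downstream mapping decides their fate.
* An empty library flows through every stage producing zero counts.
* `cis_trans_ratio` returns `NA` rather than an error when there are no
  cis di-tags.
* Classification is order-independent and pure: permuting input rows
  never changes any di-tag's category.

## Command-line interface

The package functions are the primary interface; a thin `Rscript`
wrapper (`inst/cli/hicditag.R`) exposes `digest`, `truncate`, `run`,
`simulate` and `report` subcommands for shell use, each delegating to
the exported functions with no logic of its own.

## Limitations

Nicking enzymes, 3'-overhang cutters, methylation-sensitive digestion
and star activity are out of scope. The external-aligner contract is
exercised only when bowtie/bowtie2 is installed; the built-in aligner is
the tested default. Multi-fragment chimeric reads are not rescued, and
classification is hard (no probabilistic soft assignment). The HTML
report is static; no interactive widgets are provided.

## A worked example

```{r example}
cfg <- sim_config(seed = 7, n_ditags = 800)
genome <- make_genome(cfg)
map <- digest_genome(genome, parse_enzyme_spec(cfg$enzyme), genome_id = "demo")
map
sim <- simulate_library(genome, map, cfg, file.path(tempdir(), "demo_sim"))
res <- run_pipeline(pipeline_config(
  r1 = sim$r1, r2 = sim$r2, genome = genome, re1 = cfg$enzyme,
  out_dir = file.path(tempdir(), "demo_run"), sample = "demo"))
res$summary
res$summary$row[, c("valid", "valid_pct", "same_dangling_pct", "trans_pct")]
```
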