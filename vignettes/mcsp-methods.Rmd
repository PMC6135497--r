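---
title: "Single-probe capture metabarcoding: models and design choices"
author: "mcsp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-probe capture metabarcoding: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Ichthyoplankton swarms mix the larvae of many fish species that cannot be
told apart morphologically. Hybridization capture with a *single* COI probe
drawn from a clade absent from the study area enriches the barcode fraction
of a bulk DNA library without PCR primer bias: because the probe is roughly
equally divergent from every target species, capture efficiency — and hence
read counts — track species abundance. The computational half of that
protocol is what this package implements:

1. model and curate a species-labelled COI reference database;
2. evaluate candidate probes by genetic *equidistance*;
3. assign capture reads to taxa with a strict-filter local aligner and a
   naive lowest-common-ancestor (LCA) rule;
4. quantify species relative frequencies, decide presence with a
   maxSSS read-count threshold, and characterise sensitivity via
   rarefaction and a read-length benchmark;
5. simulate every input (clades, mock communities, reads) so the whole
   chain is testable without any external download.

## Reference database model

A `ReferenceDB` couples a `Biostrings::DNAStringSet` with a four-rank
lineage (species, genus, family, order) keyed by unique accession.
Sequences are upper-cased and `U -> T` at import; records with characters
outside the IUPAC DNA alphabet or more than 10% `N` are rejected (the
aligner treats any ambiguity code as never matching, so N-rich records
only destroy signal). Two header dialects are read: a tokenized
`accession Genus_epithet` header, and the canonical interchange — a plain
FASTA plus a five-column taxonomy TSV. A species label is counted as
*named* unless it carries an open-nomenclature marker (`sp.`, `cf.`,
`aff.`) or a bare `sp` epithet token; this rule is a package convention,
since "named" has no universal formal definition.

All coordinates in the package are 0-based and half-open, including the
in-silico amplicon extractor, which finds the forward primer site and the
reverse-complemented reverse primer site and returns the spanned product,
primers included. When several site pairs match, the shortest product
longer than twice the primer length wins — the behaviour expected of a
PCR, which favours short amplicons.

## Distances and probe equidistance

Pairwise distances are computed from *per-pair* global alignments
(Needleman–Wunsch with free end gaps; match +1, mismatch −1, gap −2)
rather than from a progressive multiple alignment. For congeneric,
length-conserved barcodes the difference is negligible, and it removes a
heavyweight external dependency; pre-aligned input can be supplied by
passing already-gapped sequences straight to the p-distance counter.
Gap columns and columns containing any ambiguity code are excluded
(pairwise deletion). The p-distance is corrected with the one-parameter
substitution model

$$d = -\tfrac{3}{4}\,\ln\!\bigl(1 - \tfrac{4}{3}p\bigr),$$

defined for \(p < 0.75\); beyond that the correction is saturated and the
package raises an explicit error naming the offending species pair rather
than returning `Inf`.

A candidate probe is summarised against one representative barcode per
species (lowest accession, deterministically) by the mean, sample standard
deviation (\(n-1\)), coefficient of variation
\(\mathrm{CV}\% = 100\,s/\bar d\) and maximum of its per-species
distances. The CV is the equidistance criterion: a probe with low CV
hybridises with comparable efficiency across the whole clade, which keeps
frequency estimates unbiased. `rankProbes()` orders candidates by CV,
breaking ties by smaller maximum and then smaller mean distance — a closer
worst-case species is preferred when spreads are equal.

`segregatingSiteSpacing()` reports, over all species pairs, the mean
per-site difference density and its reciprocal (base pairs per segregating
site). The spacing sets the discriminatory power of short reads: a read
must straddle at least one diagnostic site to be assignable at species
rank.

## The strict-filter assigner

Reads are aligned with an affine-gap Smith–Waterman under BLASTN-like
constants: match +2, mismatch −3, gap open −5, gap extend −2, with
Karlin–Altschul parameters \(\lambda = 0.625\), \(K = 0.41\) converting
raw scores to bits:

$$\text{bits} = \frac{\lambda R - \ln K}{\ln 2}.$$

Under these constants a perfect match of 127 bp is the shortest alignment
reaching 230 bits, so the default bit floor of 230 *encodes* the
requirement that nearly the full length of a ~140 bp read aligns to a
barcode. Three filters gate a hit: bit score ≥ 230, identity ≥ 99%
(counted over all aligned columns, gaps included — a gap column can never
be a match, so indels count against identity), and aligned read fraction
≥ 0.9. All constants are arguments.

A k-mer prefilter (shared exact 11-mer) restricts alignment to plausible
subjects; the package targets desk-scale databases (up to ~10^5
barcodes), not FM-index scale. The prefilter is exact for the reported
hits: any alignment passing 99% identity over ≥ 90% of a ≥ 50 bp read
necessarily contains a long exact stretch, so prefiltered and exhaustive
search agree (this equivalence is tested, not assumed).

Per read, the naive LCA retains hits within 10% of the best bit score
(the common default of interactive assignment tools; the window is an
argument) and assigns the lowest rank at which all retained hits agree,
walking species → genus → family → order. Disagreement at order leaves
the read *hit-unassigned*. Read accounting distinguishes three statuses —
no hit, hit-unassigned, assigned — mirroring how capture efficiency
tables are reported; "with hit" uses a loose 30-bit floor meaning "any
credible local similarity", since assignment-grade alignments are a strict
subset.

Determinism is enforced everywhere ties can arise: cell-level traceback
prefers diagonal, then vertical, then horizontal moves; equal-scoring hits
sort by accession; equal-scoring overlap-alignment end points resolve
towards the bottom-right corner.

### The read-length benchmark

`lengthBenchmark()` tiles one representative barcode per focal species
into non-overlapping fragments of each requested length (tiling is
deterministic; fragment placement is otherwise arbitrary and the numbers
shift slightly with placement), assigns them against the full database,
and reports the percentage of fragments assigned at species rank, the
per-species true-positive rate, and the number of false-positive species.
For lengths at which a 230-bit alignment is arithmetically impossible
(below 127 bp of perfect match), the floor is lowered to the bit score of
a perfect match covering 90% of the read, so the operative filters become
≥ 99% identity over ≥ 90% of the read. Without this scaling a 50 bp
benchmark would be vacuously zero; with it, short-read assignment rates
measure taxonomic resolution, not score arithmetic.

## Quantification

Species profiles count *species-rank* assignments only; reads resolved at
genus or higher are informative about composition but not attributable,
and are excluded from frequencies. Presence is decided per library with
the maxSSS rule: candidate thresholds are the distinct observed read
counts (plus one above the maximum), a species is called present when its
count is ≥ the threshold, and the smallest threshold maximising
sensitivity + specificity against the known composition wins. Ties go to
the smallest threshold — the most sensitive call — because a detection
method should not discard species without evidence. Thresholds operate on
read counts, not frequencies, and are derived per library. The ROC needs
at least one truth-absent candidate; when every candidate species is
truth-present, specificity is undefined and the pipeline falls back to the
unthresholded profile instead of fabricating a specificity of 1.

Profile comparisons pair frequencies over the species union (absent
species contribute 0) and report the Pearson correlation on raw
frequencies — no compositional transform is applied, and both thresholded
and unthresholded comparisons are emitted, since which of the two a
reader wants depends on whether presence filtering is part of their
protocol. Rarefaction reports both subsampled means and the exact
hypergeometric expectation
\(E[S_d] = \sum_s \bigl(1 - \binom{N-n_s}{d}\big/\binom{N}{d}\bigr)\);
the simulation is only there to attach a dispersion to the closed form.
X-fold enrichment is the plain ratio of on-target read percentages
between a captured and an unenriched library.

## Preprocessing pipeline

Demultiplexing matches the first six bases of each read exactly against
the index map (no mismatch tolerance — the strictest reproducible choice),
trims index bases and qualities, and conserves reads: every input read
lands in exactly one bin. The quality filter keeps reads whose arithmetic
mean Phred score is at least 30; the boundary passes. Adapter trimming is
delegated to the standard external tools and the pipeline expects trimmed
input. `runPipeline()` chains the stages, logs a per-stage read ledger
(input → demultiplexed → quality-kept → with hit → assigned) and fails
with the stage named. A thin command-line wrapper
(`inst/scripts/mcsp.R`) exposes the same functions as subcommands.

## What the simulators emulate — and what they do not

`generateSyntheticClade()` mutates a random root down a two-level
star-like hierarchy (genus ancestors, then species tips) under the same
one-parameter substitution model used for distance correction, with the
shared branch length calibrated by root-finding so the *expected* mean
pairwise p-distance hits the target. It reproduces the statistical
features that matter to the assigner — within- vs between-genus
divergence structure, uniform barcode length, one barcode per species —
but not rate heterogeneity across sites, codon structure, indels,
alignment length variation, or database pathologies (mislabelled records,
synonymous species). Passing tests therefore demonstrate correctness of
the machinery under a clean JC world, not robustness to dirty reference
data; the curation operations exist precisely because real databases need
manual repair.

`mockAbundances()` draws community composition the way mock samples are
actually built: Dirichlet(1) weights realised as individual larvae counts
over an equimolar pool (default 102 individuals), every member species
receiving at least one larva. This guarantees each member a relative
abundance of at least 1/102 — as in a physical mock, where a member
species is present by construction — while keeping the composition skewed
and random. Read simulation draws species multinomially, start positions
uniformly, and sequencing errors as i.i.d. substitutions (no indels or
quality-profile errors: capture reads passing a mean-Q30 filter are
dominated by substitutions). All generators are pure functions of their
arguments including the seed.

## Problem sizes and numerical choices

The packaged checks run on a 20-species, 6-genus clade of 650 bp barcodes
at mean pairwise p-distance 0.2 (the package's standing model of a
moderately diverged assemblage), with 10^4 error-free 140 bp reads for
parameter recovery, a 100-species clade for self-assignment, and 50–250 bp
tilings for the length benchmark — sizes chosen so each property is
measured with comfortable statistical margin while the whole suite stays
interactive. Abundance recovery is scored against the generating
abundances; rarefaction against the hypergeometric closed form; the
aligners against an independent dynamic-programming implementation from
Biostrings; maxSSS against an exhaustive integer-threshold scan; the LCA
against brute-force lineage intersection.

Degenerate inputs are errors, not silent values: saturated distances,
empty alignments (no unambiguous shared column), a zero-read profile, a
rarefaction depth beyond the library, a threshold that removes every
species, and a ROC with no negatives all raise or flag explicitly.

## Known limitations

* Distances assume the one-parameter substitution model; no model
  selection or tree building is attempted.
* The assigner works in nucleotide space with contiguous seeds; very
  large databases (≫ 10^5 barcodes) would need an indexed backend.
* Identity is counted over aligned columns including gaps, which is
  stricter than match-column-only conventions; with the 99% filter the
  difference only matters for indel-rich reads.
* Paired-end merging, chimera detection and PCR-duplicate handling are
  out of scope; input reads are assumed merged/trimmed.
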