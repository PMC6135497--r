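# mcsp — metabarcoding by capture using a single COI probe

Fish larvae drift in multi-species ichthyoplankton swarms that cannot be
identified morphologically, and PCR-based metabarcoding of the COI barcode
is biased by primer mismatch across divergent taxa. Hybridization capture
with a **single probe** chosen to be *genetically equidistant* from every
target species sidesteps that bias: capture efficiency is roughly uniform,
so read counts track species abundance. `mcsp` implements the
computational half of that protocol for R, in a Bioconductor style
(S4 classes over `Biostrings`, Rcpp alignment kernels). It is aimed at
molecular ecologists designing capture probes and analysing the resulting
libraries.

## What it computes

**Probe equidistance.** Per-species distances from a candidate probe are
Jukes–Cantor corrected p-distances from pairwise overlap alignments,

d = −(3/4) ln(1 − (4/3) p),

summarised by mean, sample SD, and the coefficient of variation
CV% = 100·sd/mean — the probe-choice criterion (low CV = equidistant =
unbiased capture). `rankProbes()` orders candidates by CV.

**Strict-filter assignment.** Reads are aligned to the reference database
by affine-gap Smith–Waterman under BLASTN-like scoring (+2/−3, gaps 5/2,
λ = 0.625, K = 0.41), with an 11-mer prefilter. A hit must reach
**bit score ≥ 230** (= a perfect match of ≥ 127 bp, i.e. near-full-length
alignment of a ~140 bp read), **identity ≥ 99 %** and **≥ 90 %** of the
read aligned. A naive lowest-common-ancestor rule over the hits within
10 % of the best bit score assigns each read to the lowest agreeing rank
(species → genus → family → order).

**Quantification.** Species-rank reads become relative frequencies;
presence is decided per library by the maxSSS read-count threshold
(maximum sensitivity + specificity against a known composition);
estimated profiles are compared with truth by Pearson correlation;
rarefaction (subsampled and exact hypergeometric) and X-fold enrichment
complete the accounting.

**Simulation.** Seeded generators produce synthetic clades with a target
mean pairwise divergence, mock communities composed like real mocks
(equimolar pools of individuals), and fragmented or error-bearing reads —
so the entire pipeline is testable offline.

## Worked example

```r
library(mcsp)

# a 20-species, 6-genus clade of 650 bp barcodes, mean p-distance 0.2
db <- generateSyntheticClade(20, 650, 0.2, n_genera = 6, seed = 42)
db
#> ReferenceDB with 20 sequences | 20 species ( 20 named ) | 6 genera
#>   sequence length: 650 - 650 bp

# evaluate a consensus probe for equidistance
cm <- Biostrings::consensusMatrix(refSequences(db))[c("A","C","G","T"), ]
probe <- paste(rownames(cm)[apply(cm, 2, which.max)], collapse = "")
probeReport(probe, db, probe_id = "consensus")
#> ProbeReport 'consensus': 20 species | mean 0.1305 | CV 13.68% | max 0.1664

# simulate a mock capture library and run the pipeline against the truth
ab    <- mockAbundances(refSpecies(db), n_larvae = 102, seed = 7)
reads <- simulateCommunityReads(mockCommunity(db, ab), 5000, 140,
                                error_rate = 0.001, seed = 8)
fq <- tempfile(fileext = ".fastq")
writeReadsFastq(reads, fq, index = "ACGTCA")

cfg   <- pipelineConfig(db, c(ACGTCA = "mock"))
truth <- data.frame(species = names(ab), count = round(ab * 102))
res   <- runPipeline(cfg, fq, truth = truth)
#> input: 5000 reads
#> demultiplex: 0 unassigned
#> mock: 5000 demultiplexed -> 5000 Q-kept -> 5000 with hit -> 4951 assigned

res$samples$mock$comparison
#> ComparisonReport: r = 0.9972 over 20 species | sens 1 | spec NA | 0 FP, 0 FN
```

The stage ledger mirrors capture-efficiency accounting: 5000 reads in,
all demultiplexed and Q30-kept, 4951 assigned (the 49 others carry ≥ 2
simulated sequencing errors in 140 bp and fail the 99 % identity filter).
The estimated frequencies correlate with the generating abundances at
r = 0.997 with every species detected and no false positives. `spec NA`
is deliberate: every candidate species is truly present, so specificity
has no negatives to be computed from.

A thin CLI over the same functions ships in `inst/scripts/mcsp.R`
(subcommands `db-stats`, `probe-eval`, `simulate`, `benchmark`, `run`).

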