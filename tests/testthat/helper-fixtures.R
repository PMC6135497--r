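# Shared fixtures and independent oracles, built in code at test time.

randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")

# Hand-built 8-record database with a known 4-rank taxonomy spanning two
# orders, three families, four genera and six species. Sequences are
# mutually unrelated random barcodes (fixed seed) so reads derived from one
# record never cross-hit another.
fixtureDb <- function(seq_len = 650, seed = 404) {
  set.seed(seed)
  tax <- data.frame(
    accession = paste0("FX", 1:8),
    species = c("Alpha_one", "Alpha_one", "Alpha_two", "Beta_one",
                "Gamma_one", "Gamma_two", "Delta_one", "Delta_two"),
    genus  = c("Alpha", "Alpha", "Alpha", "Beta",
               "Gamma", "Gamma", "Delta", "Delta"),
    family = c("FamA", "FamA", "FamA", "FamA",
               "FamB", "FamB", "FamC", "FamC"),
    order  = c("OrdX", "OrdX", "OrdX", "OrdX",
               "OrdX", "OrdX", "OrdY", "OrdY"))
  seqs <- vapply(seq_len(nrow(tax)), function(i) randSeq(seq_len), "")
  ReferenceDB(stats::setNames(seqs, tax$accession), tax)
}

# Independent LCA oracle: compare full root-to-tip lineage paths
# (order -> family -> genus -> species) and return the deepest rank at
# which every path agrees, by prefix intersection from the root down.
bruteLCA <- function(lineages) {
  paths <- lapply(seq_len(nrow(lineages)), function(i)
    c(lineages$order[i], lineages$family[i], lineages$genus[i],
      lineages$species[i]))
  depth <- 0
  for (k in 1:4) {
    labs <- vapply(paths, `[`, "", k)
    if (length(unique(labs)) == 1) depth <- k else break
  }
  if (depth == 0) return(list(status = "hit_unassigned", taxon = "", rank = ""))
  rank <- c("order", "family", "genus", "species")[depth]
  list(status = "assigned", taxon = paths[[1]][depth], rank = rank)
}

# Exhaustive maxSSS oracle: scan every integer threshold from 0 to max+1.
bruteMaxSSS <- function(counts, truth_present) {
  pos <- names(counts) %in% truth_present
  ts <- 0:(max(counts) + 1)
  sss <- vapply(ts, function(t) {
    called <- counts >= t
    sum(called & pos) / sum(pos) + sum(!called & !pos) / sum(!pos)
  }, numeric(1))
  best <- max(sss)
  list(t_star = ts[which(sss == best)[1]], sss_max = best)
}

# Biostrings score oracle for the overlap (free end-gap) aligner.
overlapScoreOracle <- function(a, b, match = 1, mismatch = -1, gap = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  Biostrings::score(Biostrings::pairwiseAlignment(
    a, b, type = "overlap", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = gap))
}

# Biostrings score oracle for the affine-gap local aligner.
localScoreOracle <- function(a, b, match = 2, mismatch = -3,
                             gap_open = 5, gap_extend = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  Biostrings::score(Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend))
}

writeFixtureFasta <- function(headers, seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(paste0(">", headers, "\n", seqs), path)
  path
}
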