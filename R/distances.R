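#' Global pairwise alignment with free end gaps
#'
#' Needleman-Wunsch overlap alignment under a simple scoring scheme
#' (defaults: match +1, mismatch -1, gap -2; end gaps free). Tie-breaks are
#' deterministic: within a cell, a match/mismatch is preferred over a gap
#' and a gap in `a` over a gap in `b`; among equal-scoring end points the
#' one closest to the bottom-right corner wins.
#'
#' @param a,b DNA strings (character).
#' @param match,mismatch,gap Scoring parameters.
#' @return An object of class `PairwiseAlignment`: list with `aligned_a`,
#'   `aligned_b`, `score`, `n_compared_sites`, `n_differences`. Compared
#'   sites exclude gap columns and columns with an ambiguity code on either
#'   side (pairwise deletion).
#' @examples
#' globalAlign("ACT", "ACGT")  # one gap column, 3 compared sites, 0 diffs
#' @export
globalAlign <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  aln <- .nw_overlap_cpp(a, b, match, mismatch, gap)
  structure(aln, class = "PairwiseAlignment")
}

#' @export
print.PairwiseAlignment <- function(x, ...) {
  cat("PairwiseAlignment (overlap): score", x$score, "|",
      x$n_differences, "differences /", x$n_compared_sites,
      "compared sites\n")
  invisible(x)
}

#' Uncorrected p-distance under pairwise deletion
#'
#' @param aln A `PairwiseAlignment` from [globalAlign()] (or any list with
#'   `n_differences` and `n_compared_sites`).
#' @return Proportion of differing sites among compared sites.
#' @export
pDistance <- function(aln) {
  if (aln$n_compared_sites == 0)
    stop("zero comparable sites: sequences share no unambiguous columns")
  aln$n_differences / aln$n_compared_sites
}

#' Jukes-Cantor (1969) distance
#'
#' Corrects a p-distance to expected substitutions per site,
#' d = -(3/4) log(1 - (4/3) p). Defined for 0 <= p < 0.75; at p >= 0.75 the
#' correction is saturated and an error is raised.
#'
#' @param p Proportion(s) of differing sites.
#' @return Distance(s) in substitutions per site.
#' @examples
#' jc69(0.2)  # 0.2326162
#' @export
jc69 <- function(p) {
  if (any(p < 0)) stop("p must be non-negative")
  if (any(p >= 0.75))
    stop("saturation: p >= 0.75 is outside the Jukes-Cantor domain")
  -0.75 * log(1 - (4 / 3) * p)
}

# One representative record per species: lowest accession (lexicographic).
representativePerSpecies <- function(db) {
  tax <- as.data.frame(refTaxonomy(db))
  ord <- order(tax$species, tax$accession)
  tax <- tax[ord, ]
  keep <- tax$accession[!duplicated(tax$species)]
  db[keep]
}

# Summary statistics of a per-species distance vector (sample SD, n-1).
distanceSummary <- function(d) {
  m <- mean(d)
  s <- if (length(d) > 1) sd(d) else 0
  list(mean = m, sd = s,
       cv_percent = if (m > 0) 100 * s / m else 0,
       max_distance = max(d))
}

#' Probe equidistance report
#'
#' Aligns a candidate capture probe against one representative barcode per
#' target species (lowest accession), computes Jukes-Cantor distances, and
#' summarises them: mean, sample standard deviation, coefficient of
#' variation (CV% = 100 sd/mean — the equidistance criterion for probe
#' choice) and maximum. A probe with low CV hybridises with comparable
#' efficiency across the clade, limiting capture bias.
#'
#' @param probe Probe sequence (character), e.g. a COI amplicon.
#' @param targets A [ReferenceDB-class] of target species (>= 2 species).
#' @param probe_id Label for the report.
#' @return An object of class `ProbeReport`: list with `probe_id`,
#'   `per_species_distance` (named numeric), `mean`, `sd`, `cv_percent`,
#'   `max_distance`.
#' @export
probeReport <- function(probe, targets, probe_id = "probe") {
  reps <- representativePerSpecies(targets)
  if (length(reps) < 2) stop("need at least 2 target species")
  tax <- as.data.frame(refTaxonomy(reps))
  seqs <- as.character(refSequences(reps))
  d <- vapply(seq_along(seqs), function(i) {
    p <- tryCatch(pDistance(globalAlign(probe, seqs[i])), error = function(e)
      stop("species ", tax$species[i], ": ", conditionMessage(e)))
    tryCatch(jc69(p), error = function(e)
      stop("species ", tax$species[i], ": ", conditionMessage(e)))
  }, numeric(1))
  names(d) <- tax$species
  out <- c(list(probe_id = probe_id, per_species_distance = d),
           distanceSummary(d))
  structure(out, class = "ProbeReport")
}

#' @export
print.ProbeReport <- function(x, ...) {
  cat("ProbeReport '", x$probe_id, "': ", length(x$per_species_distance),
      " species | mean ", signif(x$mean, 4), " | CV ",
      signif(x$cv_percent, 4), "% | max ", signif(x$max_distance, 4),
      "\n", sep = "")
  invisible(x)
}

#' Rank candidate probes by equidistance
#'
#' Orders candidates by ascending coefficient of variation of their
#' per-species Jukes-Cantor distances; ties are broken by smaller maximum
#' distance, then smaller mean.
#'
#' @param candidates Named character vector (or named list) of candidate
#'   probe sequences.
#' @param targets A [ReferenceDB-class] of target species.
#' @return List of `ProbeReport`s, best candidate first.
#' @export
rankProbes <- function(candidates, targets) {
  if (length(candidates) < 1) stop("need at least one candidate")
  ids <- names(candidates)
  if (is.null(ids)) ids <- paste0("probe", seq_along(candidates))
  reports <- lapply(seq_along(candidates), function(i)
    probeReport(as.character(candidates[[i]]), targets, probe_id = ids[i]))
  cv <- vapply(reports, `[[`, numeric(1), "cv_percent")
  mx <- vapply(reports, `[[`, numeric(1), "max_distance")
  mn <- vapply(reports, `[[`, numeric(1), "mean")
  reports[order(cv, mx, mn)]
}

#' Segregating-site density and spacing between species
#'
#' For every unordered pair of species (one representative barcode each),
#' computes the per-site difference density from a global pairwise
#' alignment, then averages densities over pairs. The mean spacing, the
#' average number of base pairs per segregating site, is the reciprocal of
#' the mean density; it sets the discriminatory power of short reads.
#'
#' @param targets A [ReferenceDB-class] with >= 2 species.
#' @return List with `mean_density` (differences per compared site),
#'   `mean_spacing` (bp per difference; `Inf` when all pairs are
#'   identical) and `n_pairs`.
#' @export
segregatingSiteSpacing <- function(targets) {
  reps <- representativePerSpecies(targets)
  n <- length(reps)
  if (n < 2) stop("need at least 2 species")
  seqs <- as.character(refSequences(reps))
  dens <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      aln <- globalAlign(seqs[i], seqs[j])
      dens <- c(dens, aln$n_differences / aln$n_compared_sites)
    }
  }
  md <- mean(dens)
  list(mean_density = md,
       mean_spacing = if (md > 0) 1 / md else Inf,
       n_pairs = length(dens))
}
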