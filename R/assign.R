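#' BLASTN-like scoring scheme for the read assigner
#'
#' Defaults are the classic nucleotide-BLAST constants (match +2, mismatch
#' -3, gap open -5, gap extend -2, Karlin-Altschul lambda 0.625, K 0.41),
#' under which a bit-score floor of 230 corresponds to a perfect match of
#' about 128 bp — i.e. near-full-length alignment of a ~140 bp read.
#'
#' @param match,mismatch Per-column scores (match > 0 > mismatch).
#' @param gap_open,gap_extend Gap penalties (negative); a gap of length L
#'   costs `|gap_open| + L |gap_extend|`.
#' @param lambda,k_const Karlin-Altschul parameters for the bit-score
#'   conversion `bit = (lambda raw - ln K) / ln 2`.
#' @return A `ScoringScheme` list.
#' @export
scoringScheme <- function(match = 2, mismatch = -3, gap_open = -5,
                          gap_extend = -2, lambda = 0.625, k_const = 0.41) {
  if (!(match > 0 && mismatch < 0)) stop("need match > 0 > mismatch")
  if (gap_open > 0 || gap_extend > 0) stop("gap penalties must be <= 0")
  if (lambda <= 0 || k_const <= 0) stop("lambda and k_const must be > 0")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda,
                 k_const = k_const),
            class = "ScoringScheme")
}

#' Convert a raw alignment score to bits
#'
#' @param raw_score Raw Smith-Waterman score(s).
#' @param scoring A [scoringScheme()].
#' @return Bit score(s): `(lambda raw - ln K) / ln 2`.
#' @examples
#' bitScore(280)  # 140 bp perfect match under the defaults, ~253.8 bits
#' @export
bitScore <- function(raw_score, scoring = scoringScheme()) {
  (scoring$lambda * raw_score - log(scoring$k_const)) / log(2)
}

#' Local alignment of one read against one subject
#'
#' Smith-Waterman with affine gaps under a [scoringScheme()]. Identity is
#' counted over all aligned columns including gap columns; spans are
#' 0-based half-open.
#'
#' @param read,subject DNA strings.
#' @param scoring A [scoringScheme()].
#' @return An `AlignmentHit` list: `raw_score`, `bit_score`, `matches`,
#'   `aligned_cols`, `identity`, `aligned_read_fraction`, `read_span`,
#'   `subject_span`.
#' @export
localAlign <- function(read, subject, scoring = scoringScheme()) {
  read <- toupper(as.character(read))
  subject <- toupper(as.character(subject))
  if (!nzchar(read) || !nzchar(subject)) stop("sequences must be non-empty")
  a <- .sw_affine_cpp(read, subject, scoring$match, scoring$mismatch,
                      scoring$gap_open, scoring$gap_extend)
  structure(list(
    raw_score = a$raw_score,
    bit_score = bitScore(a$raw_score, scoring),
    matches = a$matches, aligned_cols = a$aligned_cols,
    identity = if (a$aligned_cols > 0) a$matches / a$aligned_cols else 0,
    aligned_read_fraction = (a$read_end - a$read_start) / nchar(read),
    read_span = c(a$read_start, a$read_end),
    subject_span = c(a$sub_start, a$sub_end)),
    class = "AlignmentHit")
}

#' @export
print.AlignmentHit <- function(x, ...) {
  cat("AlignmentHit: raw", x$raw_score, "| bits", signif(x$bit_score, 5),
      "| identity", signif(x$identity, 4), "| read fraction",
      signif(x$aligned_read_fraction, 3), "\n")
  invisible(x)
}

readSequences <- function(reads) {
  if (is.data.frame(reads)) {
    list(id = as.character(reads$read_id), seq = toupper(reads$sequence))
  } else {
    ids <- names(reads)
    if (is.null(ids))
      ids <- if (length(reads)) paste0("read", seq_along(reads))
             else character(0)
    list(id = ids, seq = toupper(as.character(reads)))
  }
}

#' Strict-filter alignment search of reads against a reference database
#'
#' Every read is locally aligned against database subjects sharing at least
#' one exact k-mer (the prefilter; disable it for exhaustive search).
#' Hits are kept when they pass all three strict filters: bit score >=
#' `min_bit`, identity >= `min_identity` and aligned read fraction >=
#' `min_read_coverage` (the coverage default 0.9 encodes the requirement
#' that nearly the full read aligns to a barcode). Hits are sorted per read
#' by bit score descending, accession ascending on ties.
#'
#' @param reads Character vector of read sequences (optionally named) or a
#'   read data.frame with `read_id` and `sequence` columns.
#' @param db A non-empty [ReferenceDB-class].
#' @param scoring A [scoringScheme()].
#' @param min_bit Minimum bit score for a kept hit (default 230).
#' @param min_identity Minimum identity over aligned columns (default
#'   0.99).
#' @param min_read_coverage Minimum fraction of the read aligned (default
#'   0.9).
#' @param kmer Prefilter k-mer size (default 11).
#' @param prefilter Require a shared k-mer before aligning (default TRUE).
#' @param keep_all Return sub-threshold hits too, with a logical `kept`
#'   column (used for hit-vs-assigned accounting).
#' @return A data.frame of hits: `read_id`, `subject_accession`,
#'   `raw_score`, `bit_score`, `identity`, `aligned_read_fraction`,
#'   `sub_start`, `sub_end` and (with `keep_all`) `kept`. An empty
#'   data.frame is a valid result.
#' @export
searchReads <- function(reads, db, scoring = scoringScheme(),
                        min_bit = 230, min_identity = 0.99,
                        min_read_coverage = 0.9, kmer = 11,
                        prefilter = TRUE, keep_all = FALSE) {
  if (length(db) == 0) stop("reference database is empty")
  rs <- readSequences(reads)
  hits <- .sw_search_cpp(rs$seq, as.character(refSequences(db)),
                         scoring$match, scoring$mismatch, scoring$gap_open,
                         scoring$gap_extend, as.integer(kmer), prefilter)
  acc <- refAccessions(db)
  out <- data.frame(
    read_id = rs$id[hits$read],
    subject_accession = acc[hits$subject],
    raw_score = hits$raw_score,
    bit_score = bitScore(hits$raw_score, scoring),
    identity = ifelse(hits$aligned_cols > 0,
                      hits$matches / hits$aligned_cols, 0),
    aligned_read_fraction = (hits$read_end - hits$read_start) /
      nchar(rs$seq)[hits$read],
    sub_start = hits$sub_start, sub_end = hits$sub_end,
    stringsAsFactors = FALSE)
  out$kept <- out$bit_score >= min_bit & out$identity >= min_identity &
    out$aligned_read_fraction >= min_read_coverage
  out <- out[order(match(out$read_id, rs$id), -out$bit_score,
                   out$subject_accession), , drop = FALSE]
  rownames(out) <- NULL
  if (!keep_all) {
    out <- out[out$kept, setdiff(colnames(out), "kept"), drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

RANKS <- c("species", "genus", "family", "order")

#' Naive lowest-common-ancestor assignment of one read
#'
#' Retains the hits whose bit score is within `top_percent` of the best hit
#' and assigns the read to the lowest taxonomic rank at which all retained
#' hits agree, walking species, genus, family, order. Disagreement at the
#' order rank leaves the read `hit_unassigned`; an empty hit table yields
#' `no_hit`.
#'
#' @param hits A hit data.frame for one read, as returned by
#'   [searchReads()] (strictly filtered hits).
#' @param db The [ReferenceDB-class] the hits refer to.
#' @param top_percent Retention window below the best bit score (default
#'   0.10).
#' @return An `AssignmentResult` list: `read_id`, `status` (`no_hit`,
#'   `hit_unassigned` or `assigned`), `taxon`, `rank`, `supporting_hits`.
#' @export
naiveLCA <- function(hits, db, top_percent = 0.10) {
  rid <- if (nrow(hits)) hits$read_id[1] else NA_character_
  if (nrow(hits) == 0)
    return(structure(list(read_id = rid, status = "no_hit", taxon = "",
                          rank = "", supporting_hits = 0L),
                     class = "AssignmentResult"))
  best <- max(hits$bit_score)
  ret <- hits[hits$bit_score >= (1 - top_percent) * best, , drop = FALSE]
  tax <- refTaxonomy(db)
  m <- match(ret$subject_accession, as.character(tax$accession))
  if (anyNA(m)) stop("hit subject absent from database index")
  lineages <- as.data.frame(tax[m, RANKS, drop = FALSE])
  for (r in RANKS) {
    labs <- unique(lineages[[r]])
    if (length(labs) == 1)
      return(structure(list(read_id = rid, status = "assigned",
                            taxon = labs, rank = r,
                            supporting_hits = nrow(ret)),
                       class = "AssignmentResult"))
  }
  structure(list(read_id = rid, status = "hit_unassigned", taxon = "",
                 rank = "", supporting_hits = nrow(ret)),
            class = "AssignmentResult")
}

#' Classify a read library against the reference database
#'
#' Runs the strict-filter search and naive LCA over every read and
#' tallies read statuses the way capture-efficiency tables are reported:
#' reads with any similarity to the database ("with hit", bit score >=
#' `min_hit_bit`), reads taxonomically assigned under the strict filters,
#' and reads with no hit.
#'
#' @inheritParams searchReads
#' @param top_percent Naive-LCA retention window.
#' @param min_hit_bit Loose bit-score floor defining "with hit" (default
#'   30 bits, i.e. any credible local similarity).
#' @return A `LibraryClassification` list: `assignments` (data.frame with
#'   `read_id`, `status`, `taxon`, `rank`, `supporting_hits`, `best_bit`,
#'   `best_identity`) and `tallies` (`n_total`, `n_with_hit`, `n_assigned`,
#'   `pct_with_hit`, `pct_assigned`; percentages over `n_total`).
#' @export
classifyLibrary <- function(reads, db, scoring = scoringScheme(),
                            min_bit = 230, min_identity = 0.99,
                            min_read_coverage = 0.9, top_percent = 0.10,
                            kmer = 11, min_hit_bit = 30, prefilter = TRUE) {
  rs <- readSequences(reads)
  n <- length(rs$seq)
  res <- data.frame(read_id = rs$id, status = rep("no_hit", n),
                    taxon = rep("", n), rank = rep("", n),
                    supporting_hits = rep(0L, n),
                    best_bit = rep(NA_real_, n),
                    best_identity = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  if (n == 0) {
    return(structure(list(
      assignments = res,
      tallies = list(n_total = 0L, n_with_hit = 0L, n_assigned = 0L,
                     pct_with_hit = NaN, pct_assigned = NaN)),
      class = "LibraryClassification"))
  }
  if (anyDuplicated(rs$id)) stop("read ids must be unique")
  hits <- searchReads(setNames(rs$seq, rs$id), db, scoring, min_bit,
                      min_identity, min_read_coverage, kmer, prefilter,
                      keep_all = TRUE)
  hits_by <- split(hits, factor(hits$read_id, levels = rs$id))
  for (i in seq_len(n)) {
    h <- hits_by[[i]]
    if (is.null(h) || nrow(h) == 0) next
    res$best_bit[i] <- max(h$bit_score)
    res$best_identity[i] <- h$identity[which.max(h$bit_score)]
    with_hit <- any(h$bit_score >= min_hit_bit)
    kept <- h[h$kept, , drop = FALSE]
    if (nrow(kept) == 0) {
      res$status[i] <- if (with_hit) "hit_unassigned" else "no_hit"
      next
    }
    lca <- naiveLCA(kept, db, top_percent)
    res$status[i] <- lca$status
    res$taxon[i] <- lca$taxon
    res$rank[i] <- lca$rank
    res$supporting_hits[i] <- lca$supporting_hits
  }
  n_with_hit <- sum(!is.na(res$best_bit) & res$best_bit >= min_hit_bit)
  n_assigned <- sum(res$status == "assigned")
  structure(list(
    assignments = res,
    tallies = list(n_total = n, n_with_hit = n_with_hit,
                   n_assigned = n_assigned,
                   pct_with_hit = 100 * n_with_hit / n,
                   pct_assigned = 100 * n_assigned / n)),
    class = "LibraryClassification")
}

#' @export
print.LibraryClassification <- function(x, ...) {
  t <- x$tallies
  cat("LibraryClassification:", t$n_total, "reads |", t$n_with_hit,
      sprintf("with hit (%.1f%%) |", t$pct_with_hit), t$n_assigned,
      sprintf("assigned (%.1f%%)\n", t$pct_assigned))
  invisible(x)
}

#' Write per-read assignments to TSV
#'
#' @param classification A `LibraryClassification`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeAssignmentsTsv <- function(classification, path) {
  write.table(classification$assignments, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read-length assignment benchmark
#'
#' Fragments one representative barcode per focal species (non-overlapping
#' tiling) at each requested length and assigns the fragments against the
#' full database, measuring how taxonomic resolution varies with read
#' length. For lengths too short for the absolute bit-score floor to be
#' expressible, the floor is lowered to the bit score of a perfect match
#' covering `min_read_coverage` of the read, so that the operative filters
#' become >=99% identity over >=90% of the read.
#'
#' @param db The full [ReferenceDB-class] to assign against.
#' @param focal_species Species whose barcodes are fragmented (must be in
#'   `db`).
#' @param lengths Fragment lengths in bp, and/or `"full"`.
#' @inheritParams classifyLibrary
#' @return A data.frame with one row per length: `length`, `n_fragments`,
#'   `pct_assigned_at_species` (percent of fragments assigned at species
#'   rank), `species_tpr` (fraction of focal species recovered as
#'   themselves by at least one fragment), `n_false_positive_species`
#'   (non-focal species appearing in species-rank assignments),
#'   `effective_min_bit`.
#' @export
lengthBenchmark <- function(db, focal_species, lengths = c(50, 100, 140, 250),
                            scoring = scoringScheme(), min_bit = 230,
                            min_identity = 0.99, min_read_coverage = 0.9,
                            top_percent = 0.10, kmer = 11) {
  focal_db <- subsetBySpecies(db, focal_species)
  if (length(focal_db) == 0) stop("no focal species found in db")
  reps <- representativePerSpecies(focal_db)
  focal <- refSpecies(reps)
  n_focal <- length(focal)

  rows <- lapply(lengths, function(L) {
    frags <- fragmentReferences(reps, if (identical(L, "full")) "full"
                                else as.integer(L), mode = "tiling")
    if (nrow(frags) == 0)
      return(data.frame(length = as.character(L), n_fragments = 0L,
                        pct_assigned_at_species = NaN, species_tpr = NaN,
                        n_false_positive_species = NA_integer_,
                        effective_min_bit = NA_real_))
    Lbp <- min(frags$length)
    floor_bits <- bitScore(scoring$match * floor(min_read_coverage * Lbp),
                           scoring)
    eff_min_bit <- min(min_bit, floor_bits)
    cls <- classifyLibrary(frags, db, scoring, min_bit = eff_min_bit,
                           min_identity = min_identity,
                           min_read_coverage = min_read_coverage,
                           top_percent = top_percent, kmer = kmer)
    a <- cls$assignments
    at_species <- a$status == "assigned" & a$rank == "species"
    self <- at_species & a$taxon == frags$truth_species
    detected <- unique(frags$truth_species[self])
    fp <- setdiff(unique(a$taxon[at_species]), focal)
    data.frame(length = as.character(L), n_fragments = nrow(frags),
               pct_assigned_at_species = 100 * mean(at_species),
               species_tpr = length(detected) / n_focal,
               n_false_positive_species = length(fp),
               effective_min_bit = eff_min_bit)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
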