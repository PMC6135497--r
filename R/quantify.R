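#' Build a species profile from read assignments
#'
#' Counts species-rank assignments only (reads resolved at genus or higher
#' do not contribute) and normalises by the total number of species-rank
#' reads.
#'
#' @param assignments A `LibraryClassification` or its `assignments`
#'   data.frame.
#' @return A [CommunityProfile-class]. When no read is assigned at species
#'   rank the profile is empty (flagged with a warning); frequencies are
#'   then undefined.
#' @export
profileFromAssignments <- function(assignments) {
  if (inherits(assignments, "LibraryClassification"))
    assignments <- assignments$assignments
  sp <- assignments$taxon[assignments$status == "assigned" &
                            assignments$rank == "species"]
  if (length(sp) == 0) {
    warning("no species-rank assignments: empty profile")
    return(CommunityProfile())
  }
  tab <- table(sp)
  CommunityProfile(setNames(as.numeric(tab), names(tab)))
}

#' maxSSS presence threshold from a truth composition
#'
#' Chooses the minimum read count for calling a species present by
#' maximising sensitivity plus specificity (maxSSS) against a known
#' composition. Candidate thresholds are the distinct observed counts plus
#' one above the maximum; a species is called present when its count is >=
#' the threshold. Ties in the maximum are resolved towards the smallest
#' threshold (the most sensitive call).
#'
#' @param counts Named numeric vector of read counts over all candidate
#'   species (truth-present species with zero reads may be included as
#'   zeros; truth species absent from `counts` are added with count 0).
#' @param truth_present Character vector of species truly present.
#' @return A `ThresholdResult` list: `roc` (data.frame with `threshold`,
#'   `sensitivity`, `specificity`, `sss`), `t_star`, `sss_max`,
#'   `sens_at_t_star`, `spec_at_t_star`.
#' @examples
#' maxSSSThreshold(c(A = 100, B = 5, C = 2, D = 0), c("A", "B"))$t_star
#' @export
maxSSSThreshold <- function(counts, truth_present) {
  missing_truth <- setdiff(truth_present, names(counts))
  if (length(missing_truth))
    counts <- c(counts, setNames(rep(0, length(missing_truth)),
                                 missing_truth))
  species <- names(counts)
  pos <- species %in% truth_present
  if (!any(pos)) stop("no truth-present species among the candidates")
  if (all(pos))
    stop("specificity undefined: every candidate species is in the truth set")

  thresholds <- sort(unique(c(counts, max(counts) + 1)))
  roc <- do.call(rbind, lapply(thresholds, function(t) {
    called <- counts >= t
    data.frame(threshold = t,
               sensitivity = sum(called & pos) / sum(pos),
               specificity = sum(!called & !pos) / sum(!pos))
  }))
  roc$sss <- roc$sensitivity + roc$specificity
  best <- which(roc$sss == max(roc$sss))[1]  # smallest threshold on ties
  structure(list(roc = roc, t_star = roc$threshold[best],
                 sss_max = roc$sss[best],
                 sens_at_t_star = roc$sensitivity[best],
                 spec_at_t_star = roc$specificity[best]),
            class = "ThresholdResult")
}

#' @export
print.ThresholdResult <- function(x, ...) {
  cat("ThresholdResult: t* =", x$t_star, "| sens",
      signif(x$sens_at_t_star, 3), "| spec", signif(x$spec_at_t_star, 3),
      "| maxSSS", signif(x$sss_max, 4), "\n")
  invisible(x)
}

#' Apply a presence threshold to a profile
#'
#' Species with counts below the threshold are considered absent and
#' removed; frequencies are renormalised over the survivors.
#'
#' @param profile A [CommunityProfile-class].
#' @param t_star Minimum read count (>= 0).
#' @return The filtered, renormalised [CommunityProfile-class]; empty (with
#'   a warning) when no species survives.
#' @export
applyThreshold <- function(profile, t_star) {
  if (t_star < 0) stop("t_star must be >= 0")
  cts <- profileCounts(profile)
  keep <- cts >= t_star
  if (!any(keep)) {
    warning("threshold removes every species: empty profile")
    return(CommunityProfile())
  }
  CommunityProfile(cts[keep])
}

#' Compare an estimated profile with a truth profile
#'
#' Pairs frequencies over the union of species in both profiles (absent
#' species contribute 0), computes the Pearson correlation, and scores
#' presence/absence: sensitivity is the fraction of truth species detected,
#' specificity the fraction of truth-absent candidates correctly not
#' called. When every candidate is truth-present, specificity is undefined
#' (`NA`); when either frequency vector has zero variance the correlation
#' is undefined (`NA`).
#'
#' @param estimated,truth [CommunityProfile-class] objects.
#' @return A `ComparisonReport` list: `pearson_r`, `n_pairs`,
#'   `sensitivity`, `specificity`, `false_positive_species`,
#'   `false_negative_species`.
#' @export
compareProfiles <- function(estimated, truth) {
  fe <- profileFrequencies(estimated)
  ft <- profileFrequencies(truth)
  union_sp <- union(names(ft), names(fe))
  if (length(union_sp) < 2) stop("need at least 2 species across profiles")
  x <- setNames(rep(0, length(union_sp)), union_sp)
  y <- x
  x[names(ft)] <- ft
  y[names(fe)] <- fe
  r <- if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)

  present_true <- names(ft)[profileCounts(truth)[names(ft)] > 0]
  present_est <- names(fe)[profileCounts(estimated)[names(fe)] > 0]
  tp <- intersect(present_est, present_true)
  fp <- setdiff(present_est, present_true)
  fn <- setdiff(present_true, present_est)
  tn_candidates <- setdiff(union_sp, present_true)
  structure(list(
    pearson_r = r, n_pairs = length(union_sp),
    sensitivity = length(tp) / length(present_true),
    specificity = if (length(tn_candidates) == 0) NA_real_
                  else length(setdiff(tn_candidates, fp)) /
                    length(tn_candidates),
    false_positive_species = fp, false_negative_species = fn),
    class = "ComparisonReport")
}

#' @export
print.ComparisonReport <- function(x, ...) {
  cat("ComparisonReport: r =", signif(x$pearson_r, 4), "over", x$n_pairs,
      "species | sens", signif(x$sensitivity, 3), "| spec",
      ifelse(is.na(x$specificity), "NA", signif(x$specificity, 3)),
      "|", length(x$false_positive_species), "FP,",
      length(x$false_negative_species), "FN\n")
  invisible(x)
}

#' Rarefaction of species detections
#'
#' Estimates the expected number of species detected as a function of
#' sequencing depth by subsampling reads without replacement, and also
#' reports the exact hypergeometric expectation
#' E[S_d] = sum_s (1 - C(N - n_s, d) / C(N, d)).
#'
#' @param species_labels_per_read Character vector: the species label of
#'   every assigned read.
#' @param depths Integer depths (each <= total reads).
#' @param n_replicates Subsampling replicates per depth.
#' @param seed RNG seed.
#' @return A data.frame with `depth`, `mean_species` (simulated mean),
#'   `sd_species`, `analytic` (hypergeometric expectation).
#' @export
rarefactionCurve <- function(species_labels_per_read, depths,
                             n_replicates = 200, seed = 1) {
  N <- length(species_labels_per_read)
  depths <- as.integer(depths)
  if (any(depths > N)) stop("depth exceeds the number of reads")
  if (any(depths < 0)) stop("depths must be non-negative")
  ns <- as.numeric(table(species_labels_per_read))

  analytic <- vapply(depths, function(d) {
    sum(1 - exp(lchoose(N - ns, d) - lchoose(N, d)))
  }, numeric(1))

  withSeed(seed, {
    sims <- vapply(depths, function(d) {
      reps <- vapply(seq_len(n_replicates), function(i) {
        length(unique(species_labels_per_read[sample.int(N, d)]))
      }, numeric(1))
      c(mean(reps), sd(reps))
    }, numeric(2))
    data.frame(depth = depths, mean_species = sims[1, ],
               sd_species = sims[2, ], analytic = analytic)
  })
}

#' X-fold enrichment of on-target reads
#'
#' Ratio of the percentage of reads hitting the barcode database in an
#' enriched (captured) library to that in an unenriched shotgun library.
#'
#' @param pct_hit_enriched,pct_hit_unenriched Percentages of reads with a
#'   database hit.
#' @return The enrichment fold.
#' @examples
#' enrichmentFold(50, 0.01)  # 5000-fold
#' @export
enrichmentFold <- function(pct_hit_enriched, pct_hit_unenriched) {
  if (pct_hit_unenriched <= 0)
    stop("unenriched percentage must be positive")
  pct_hit_enriched / pct_hit_unenriched
}
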