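mkAssign <- function(taxa, ranks = "species") {
  n <- length(taxa)
  data.frame(read_id = paste0("r", seq_len(n)),
             status = ifelse(nzchar(taxa), "assigned", "no_hit"),
             taxon = taxa, rank = rep(ranks, length.out = n),
             supporting_hits = 1L, best_bit = 250, best_identity = 1)
}

test_that("profiles count species-rank reads and normalise frequencies", {
  p1 <- profileFromAssignments(mkAssign(rep("Sp_a", 7)))
  expect_equal(unname(profileFrequencies(p1)), 1)
  expect_equal(nAssigned(p1), 7)

  p2 <- profileFromAssignments(mkAssign(c(rep("A", 60), rep("B", 40))))
  expect_equal(profileFrequencies(p2), c(A = 0.6, B = 0.4))

  # genus-rank assignments do not contribute
  mixed <- rbind(mkAssign(rep("A", 5)), mkAssign("GenusX", ranks = "genus"))
  expect_equal(nAssigned(profileFromAssignments(mixed)), 5)

  expect_warning(pe <- profileFromAssignments(mkAssign(rep("", 3))),
                 "empty")
  expect_true(isEmptyProfile(pe))
  expect_length(profileFrequencies(pe), 0)
})

test_that("maxSSS picks the documented thresholds on worked examples", {
  r <- maxSSSThreshold(c(A = 100, B = 5, C = 2, D = 0), c("A", "B"))
  expect_equal(r$t_star, 5)
  expect_equal(r$sens_at_t_star, 1)
  expect_equal(r$spec_at_t_star, 1)
  expect_equal(r$sss_max, 2)

  # absent species all at zero: smallest positive count separates perfectly
  r2 <- maxSSSThreshold(c(A = 30, B = 4, C = 0, D = 0), c("A", "B"))
  expect_equal(r2$t_star, 4)
  expect_equal(r2$sss_max, 2)

  # inseparable counts: ties resolve to the smallest threshold
  r3 <- maxSSSThreshold(c(A = 1, B = 1), "A")
  expect_equal(r3$t_star, 1)
  expect_equal(r3$sss_max, 1)

  # truth species missing from counts enter as zeros (false negatives)
  r4 <- maxSSSThreshold(c(A = 10, B = 3), c("A", "Z"))
  expect_equal(r4$t_star, 10)
  expect_equal(r4$sens_at_t_star, 0.5)
  expect_equal(r4$spec_at_t_star, 1)

  expect_error(maxSSSThreshold(c(A = 2, B = 1), c("A", "B")),
               "specificity undefined")
  expect_error(maxSSSThreshold(c(A = 2), character(0)), "no truth-present")
})

test_that("maxSSS equals the exhaustive integer-threshold oracle", {
  set.seed(91)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    counts <- setNames(rpois(n, sample(c(2, 20, 200), 1)), paste0("s", 1:n))
    truth <- paste0("s", sample(n, sample(1:(n - 1), 1)))
    got <- maxSSSThreshold(counts, truth)
    want <- bruteMaxSSS(counts, truth)
    expect_equal(got$sss_max, want$sss_max)
    # both scans agree on the smallest maximising threshold among
    # achievable cut points
    called_got <- counts >= got$t_star
    called_want <- counts >= want$t_star
    expect_equal(called_got, called_want)
  }
})

test_that("thresholding removes sub-threshold species and renormalises", {
  p <- CommunityProfile(c(A = 100, B = 5, C = 2))
  expect_equal(profileCounts(applyThreshold(p, 1)), profileCounts(p))
  pt <- applyThreshold(p, 5)
  expect_equal(profileCounts(pt), c(A = 100, B = 5))
  expect_equal(profileFrequencies(pt), c(A = 100 / 105, B = 5 / 105))
  expect_equal(sum(profileFrequencies(pt)), 1)
  expect_warning(pe <- applyThreshold(p, 1000), "empty")
  expect_true(isEmptyProfile(pe))
})

test_that("profile comparison computes r, presence scores and FP/FN lists", {
  t_ <- CommunityProfile(c(A = 50, B = 30, C = 20))
  e_same <- CommunityProfile(c(A = 50, B = 30, C = 20))
  same <- compareProfiles(e_same, t_)
  expect_equal(same$pearson_r, 1)
  expect_equal(same$sensitivity, 1)
  expect_true(is.na(same$specificity))  # no truth-absent candidate

  e <- CommunityProfile(c(A = 60, B = 25, C = 15))
  cmp <- compareProfiles(e, t_)
  expect_equal(cmp$pearson_r,
               cor(c(0.5, 0.3, 0.2), c(0.6, 0.25, 0.15)))
  expect_equal(cmp$pearson_r, 0.9928, tolerance = 1e-4)

  # extra and missing species
  e2 <- CommunityProfile(c(A = 70, B = 20, X = 10))
  cmp2 <- compareProfiles(e2, t_)
  expect_equal(cmp2$false_positive_species, "X")
  expect_equal(cmp2$false_negative_species, "C")
  expect_equal(cmp2$sensitivity, 2 / 3)
  expect_equal(cmp2$specificity, 0)  # the one truth-absent candidate is called
  expect_equal(cmp2$n_pairs, 4)

  # zero variance: r undefined
  flat_t <- CommunityProfile(c(A = 10, B = 10))
  flat_e <- CommunityProfile(c(A = 10, B = 10))
  expect_true(is.na(compareProfiles(flat_e, flat_t)$pearson_r))
})

test_that("rarefaction matches the hypergeometric expectation", {
  labels <- rep(c("A", "B"), each = 5)
  rc <- rarefactionCurve(labels, depths = c(1, 10), n_replicates = 300,
                         seed = 2)
  expect_equal(rc$analytic[1], 1.0)       # one read detects one species
  expect_equal(rc$analytic[2], 2.0)       # full depth detects both
  expect_equal(rc$mean_species[2], 2.0)   # depth = N is exact, no sampling
  expect_lt(abs(rc$mean_species[1] - 1.0), 1e-9)  # both depths degenerate

  # a skewed community: simulated mean within 3 SE of the expectation
  set.seed(3)
  labels2 <- sample(rep(paste0("s", 1:8), times = c(40, 20, 10, 8, 6, 4, 2, 1)))
  rc2 <- rarefactionCurve(labels2, depths = c(5, 15, 40, 91),
                          n_replicates = 200, seed = 4)
  expect_equal(rc2$mean_species[4], 8)  # full depth: observed richness
  se <- rc2$sd_species / sqrt(200)
  expect_true(all(abs(rc2$mean_species - rc2$analytic) <=
                    3 * pmax(se, 1e-9)))
  # curve is monotone non-decreasing in depth
  expect_true(all(diff(rc2$analytic) >= 0))
  expect_true(all(diff(rc2$mean_species) >= -1e-9))

  expect_error(rarefactionCurve(labels, depths = 11), "depth")
})

test_that("enrichment fold is a plain ratio of on-target percentages", {
  expect_equal(enrichmentFold(50, 50), 1)
  expect_equal(enrichmentFold(50, 0.01), 5000)
  # homogeneity: scaling both percentages leaves the fold unchanged
  expect_equal(enrichmentFold(0.694 * 13, 0.00012 * 13),
               enrichmentFold(0.694, 0.00012))
  expect_error(enrichmentFold(50, 0), "positive")
})
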