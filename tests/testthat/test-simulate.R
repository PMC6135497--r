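test_that("tiling fragmentation places windows deterministically", {
  db <- ReferenceDB(
    c(s1 = randSeq(700)),
    data.frame(accession = "s1", species = "Sp_a", genus = "G",
               family = "F", order = "O"))
  fr <- fragmentReferences(db, 140, mode = "tiling", step = 140)
  expect_equal(nrow(fr), 5)
  expect_equal(fr$start, c(0, 140, 280, 420, 560))
  expect_true(all(fr$length == 140))
  expect_true(all(fr$truth_species == "Sp_a"))
  # each fragment is the stated substring of its source
  src <- as.character(refSequences(db)[["s1"]])
  expect_equal(fr$sequence,
               substring(src, fr$start + 1, fr$start + fr$length))

  # read_length == sequence length: exactly one fragment, the whole sequence
  fr1 <- fragmentReferences(db, 700, mode = "tiling")
  expect_equal(nrow(fr1), 1)
  expect_equal(fr1$sequence, src)

  # "full" mode yields one read per sequence
  frf <- fragmentReferences(db, "full")
  expect_equal(nrow(frf), 1)
  expect_equal(frf$length, 700)
})

test_that("tiling covers every base when step <= read_length", {
  db <- fixtureDb(617)  # awkward length to exercise the flush window
  for (step in c(80, 100)) {
    fr <- fragmentReferences(db, 100, mode = "tiling", step = step)
    for (acc in refAccessions(db)) {
      f <- fr[fr$source_accession == acc, ]
      covered <- rep(FALSE, 617)
      for (k in seq_len(nrow(f)))
        covered[(f$start[k] + 1):(f$start[k] + f$length[k])] <- TRUE
      expect_true(all(covered))
    }
  }
})

test_that("random fragmentation is a pure function of the seed", {
  db <- fixtureDb(300)
  f1 <- fragmentReferences(db, 50, mode = "random", n_per_seq = 4, seed = 9)
  f2 <- fragmentReferences(db, 50, mode = "random", n_per_seq = 4, seed = 9)
  f3 <- fragmentReferences(db, 50, mode = "random", n_per_seq = 4, seed = 10)
  expect_identical(f1, f2)
  expect_false(identical(f1$start, f3$start))
  expect_error(fragmentReferences(db, 50, mode = "random", n_per_seq = 0),
               "n_per_seq")

  # sequences shorter than the read length are skipped with a report
  short_db <- ReferenceDB(
    c(a = randSeq(40), b = randSeq(300)),
    data.frame(accession = c("a", "b"), species = c("S1", "S2"),
               genus = c("G1", "G2"), family = "F", order = "O"))
  expect_message(fr <- fragmentReferences(short_db, 100, mode = "tiling"),
                 "skipped")
  expect_equal(attr(fr, "skipped"), "a")
  expect_true(all(fr$source_accession == "b"))
})

test_that("synthetic clades hit their calibrated mean pairwise distance", {
  # zero divergence: all sequences identical
  db0 <- generateSyntheticClade(5, 200, 0, n_genera = 2, seed = 1)
  expect_equal(length(unique(as.character(refSequences(db0)))), 1)

  # target 0.2: realized mean p-distance within 15% relative error
  db <- generateSyntheticClade(10, 650, 0.2, n_genera = 3, seed = 8)
  seqs <- as.character(refSequences(db))
  p <- c()
  for (i in 1:9) for (j in (i + 1):10)
    p <- c(p, pDistance(globalAlign(seqs[i], seqs[j])))
  expect_gt(mean(p), 0.17)
  expect_lt(mean(p), 0.23)

  # determinism and RNG hygiene
  expect_identical(
    as.character(refSequences(generateSyntheticClade(6, 100, 0.1, 2, seed = 3))),
    as.character(refSequences(generateSyntheticClade(6, 100, 0.1, 2, seed = 3))))
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generateSyntheticClade(4, 80, 0.1, 2, seed = 5))
  expect_equal(runif(1), before)

  expect_error(generateSyntheticClade(1, 100, 0.1), "at least 2")
  expect_error(generateSyntheticClade(5, 100, 0.7), "0.6")
})

test_that("community reads follow the abundance vector and error model", {
  db <- fixtureDb(650)
  # single-species community: all truth labels are that species
  mc1 <- mockCommunity(db, c(Beta_one = 1))
  r1 <- simulateCommunityReads(mc1, 50, 140, 0, seed = 2)
  expect_true(all(r1$truth_species == "Beta_one"))

  # error-free reads are exact substrings of their source
  seqs <- as.character(refSequences(db))
  names(seqs) <- refAccessions(db)
  mc <- mockCommunity(db, c(Alpha_one = 0.7, Beta_one = 0.3))
  rr <- simulateCommunityReads(mc, 300, 140, 0, seed = 4)
  ok <- vapply(seq_len(nrow(rr)), function(i) {
    substring(seqs[rr$source_accession[i]], rr$start[i] + 1,
              rr$start[i] + 140) == rr$sequence[i]
  }, logical(1))
  expect_true(all(ok))

  # species counts land inside the central 99% binomial region
  n <- 10000
  big <- simulateCommunityReads(mc, n, 140, 0, seed = 6)
  nA <- sum(big$truth_species == "Alpha_one")
  expect_gte(nA, qbinom(0.005, n, 0.7))
  expect_lte(nA, qbinom(0.995, n, 0.7))

  # determinism
  expect_identical(simulateCommunityReads(mc, 100, 140, 0.01, seed = 7),
                   simulateCommunityReads(mc, 100, 140, 0.01, seed = 7))

  # substitution errors change about error_rate of the bases
  err <- simulateCommunityReads(mc, 200, 140, 0.05, seed = 8)
  n_mut <- vapply(seq_len(nrow(err)), function(i) {
    truth <- substring(seqs[err$source_accession[i]], err$start[i] + 1,
                       err$start[i] + 140)
    sum(utf8ToInt(truth) != utf8ToInt(err$sequence[i]))
  }, numeric(1))
  expect_gt(mean(n_mut) / 140, 0.03)
  expect_lt(mean(n_mut) / 140, 0.07)
})

test_that("mock abundances model an equimolar pool of individuals", {
  ab <- mockAbundances(paste0("s", 1:15), n_larvae = 102, seed = 9)
  expect_equal(sum(ab), 1)
  expect_true(all(ab >= 1 / 102))               # every member is present
  expect_equal(ab * 102, round(ab * 102))       # integer larvae counts
  expect_identical(ab, mockAbundances(paste0("s", 1:15), 102, seed = 9))
  expect_error(mockAbundances(paste0("s", 1:10), n_larvae = 5),
               "one larva")
})

test_that("empirical read frequencies converge to the abundances", {
  db <- generateSyntheticClade(6, 400, 0.2, n_genera = 2, seed = 12)
  ab <- c(0.4, 0.25, 0.15, 0.1, 0.07, 0.03)
  names(ab) <- refSpecies(db)
  mc <- mockCommunity(db, ab)
  n <- 1e5
  rr <- simulateCommunityReads(mc, n, 100, 0, seed = 13)
  freq <- table(factor(rr$truth_species, levels = names(ab))) / n
  dev <- abs(as.numeric(freq) - ab)
  expect_true(all(dev < 3 * sqrt(ab * (1 - ab) / n)))
})

test_that("read output formats round-trip", {
  db <- fixtureDb(200)
  mc <- mockCommunity(db, c(Alpha_one = 0.5, Gamma_one = 0.5))
  rr <- simulateCommunityReads(mc, 20, 80, 0, seed = 3)

  fq <- tempfile(fileext = ".fastq")
  writeReadsFastq(rr, fq, index = "AACCGG")
  back <- readFastqReads(fq)
  expect_equal(nrow(back), 20)
  expect_true(all(substr(back$sequence, 1, 6) == "AACCGG"))
  expect_equal(substring(back$sequence, 7), rr$sequence)
  expect_true(all(back$quality == strrep("I", 86)))

  tsv <- tempfile(fileext = ".tsv")
  writeTruthTsv(rr, tsv)
  tt <- read.table(tsv, sep = "\t", header = TRUE)
  expect_equal(tt$truth_species, rr$truth_species)
})
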