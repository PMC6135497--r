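test_that("local alignment scores, identity and bit conversion are exact", {
  set.seed(41)
  sub <- randSeq(650)
  read <- substr(sub, 101, 240)  # 140 bp exact match
  h <- localAlign(read, sub)
  expect_equal(h$raw_score, 280)
  expect_equal(h$bit_score, (0.625 * 280 - log(0.41)) / log(2))
  expect_equal(h$bit_score, 253.7579, tolerance = 1e-4)
  expect_equal(h$identity, 1)
  expect_equal(h$aligned_read_fraction, 1)
  expect_equal(h$subject_span, c(100, 240))

  # one mismatch in 140 columns: identity 139/140 = 0.9929, passes 99%
  read2 <- read
  old <- substr(read2, 70, 70)
  substr(read2, 70, 70) <- setdiff(c("A", "C", "G", "T"), old)[1]
  h2 <- localAlign(read2, sub)
  expect_equal(h2$aligned_cols, 140)
  expect_equal(h2$identity, 139 / 140)
  expect_gte(h2$identity, 0.99)
  expect_equal(h2$raw_score, 139 * 2 - 3)

  # unrelated sequences score far below the 230-bit filter
  h3 <- localAlign(randSeq(140), randSeq(650))
  expect_lt(h3$bit_score, 100)
})

test_that("local alignment score equals the Biostrings oracle", {
  set.seed(42)
  for (i in 1:20) {
    a <- randSeq(sample(40:120, 1))
    b <- randSeq(sample(100:300, 1))
    # include related pairs: plant a shared block
    if (i %% 2 == 0) {
      block <- substr(b, 11, 10 + min(60, nchar(a)))
      substr(a, 1, nchar(block)) <- block
    }
    expect_equal(localAlign(a, b)$raw_score, localScoreOracle(a, b))
  }
})

test_that("search returns filtered, sorted hits with strict boundaries", {
  db <- fixtureDb(650)
  seqs <- as.character(refSequences(db))

  # a read unique to one reference: that reference is the sole kept hit
  read <- substr(seqs[4], 201, 340)
  hits <- searchReads(read, db)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$subject_accession, "FX4")

  # a region shared verbatim by two references: two tied top hits
  db2 <- db
  shared <- unname(substr(seqs[1], 1, 650))
  db2 <- curateDb(db, remove = "FX2",
                  add = ReferenceDB(c(FX2b = shared),
                    data.frame(accession = "FX2b", species = "Alpha_one",
                               genus = "Alpha", family = "FamA",
                               order = "OrdX")))
  read2 <- substr(shared, 301, 440)
  hits2 <- searchReads(read2, db2)
  expect_equal(nrow(hits2), 2)
  expect_equal(hits2$bit_score[1], hits2$bit_score[2])
  expect_equal(sort(hits2$subject_accession), c("FX1", "FX2b"))
  # ties sorted by accession
  expect_equal(hits2$subject_accession, c("FX1", "FX2b"))

  # the bit filter is >=: a 126 bp perfect match (228.5 bits) is excluded,
  # a 127 bp one (230.3 bits) kept
  r126 <- substr(seqs[5], 1, 126)
  r127 <- substr(seqs[5], 1, 127)
  expect_lt(bitScore(2 * 126), 230)
  expect_equal(nrow(searchReads(r126, db)), 0)
  expect_equal(nrow(searchReads(r127, db)), 1)
})

test_that("naive LCA agrees with brute-force lineage intersection", {
  db <- fixtureDb(650)
  tax <- as.data.frame(refTaxonomy(db))
  mkhits <- function(accs, bits) {
    n <- length(accs)
    data.frame(read_id = rep("r1", n), subject_accession = accs,
               raw_score = rep(0, n), bit_score = bits,
               identity = rep(1, n), aligned_read_fraction = rep(1, n),
               sub_start = rep(0, n), sub_end = rep(10, n))
  }
  # fixed cases walking each rank
  one_sp <- naiveLCA(mkhits(c("FX1", "FX2"), c(250, 250)), db)
  expect_equal(one_sp$status, "assigned")
  expect_equal(one_sp$taxon, "Alpha_one")
  expect_equal(one_sp$rank, "species")

  genus <- naiveLCA(mkhits(c("FX1", "FX3"), c(250, 245)), db)
  expect_equal(genus$taxon, "Alpha")
  expect_equal(genus$rank, "genus")

  family <- naiveLCA(mkhits(c("FX1", "FX4"), c(250, 250)), db)
  expect_equal(family$taxon, "FamA")
  expect_equal(family$rank, "family")

  order_ <- naiveLCA(mkhits(c("FX1", "FX5"), c(250, 250)), db)
  expect_equal(order_$taxon, "OrdX")
  expect_equal(order_$rank, "order")

  cross <- naiveLCA(mkhits(c("FX1", "FX7"), c(250, 250)), db)
  expect_equal(cross$status, "hit_unassigned")

  # the top-percent window drops weak hits before the LCA
  windowed <- naiveLCA(mkhits(c("FX1", "FX7"), c(250, 220)), db)
  expect_equal(windowed$rank, "species")
  expect_equal(windowed$supporting_hits, 1)

  expect_equal(naiveLCA(mkhits(character(0), numeric(0)), db)$status,
               "no_hit")

  # randomized hit sets vs the independent oracle
  set.seed(77)
  for (i in 1:100) {
    k <- sample(1:6, 1)
    accs <- sample(refAccessions(db), k)
    bits <- runif(k, 240, 260)
    got <- naiveLCA(mkhits(accs, bits), db)
    keep <- bits >= 0.9 * max(bits)
    want <- bruteLCA(tax[match(accs[keep], tax$accession), ])
    expect_equal(got$status, want$status)
    expect_equal(got$taxon, want$taxon)
    expect_equal(got$rank, want$rank)
  }
})

test_that("k-mer prefiltered search equals exhaustive alignment", {
  db <- generateSyntheticClade(30, 400, 0.2, n_genera = 10, seed = 19)
  frags <- fragmentReferences(db, 140, mode = "random", n_per_seq = 1,
                              seed = 20)
  pre <- searchReads(frags, db, prefilter = TRUE)
  exh <- searchReads(frags, db, prefilter = FALSE)
  expect_equal(pre, exh)
  # and sub-threshold hit tables agree wherever a k-mer is shared
  pre_all <- searchReads(frags, db, prefilter = TRUE, keep_all = TRUE)
  exh_all <- searchReads(frags, db, prefilter = FALSE, keep_all = TRUE)
  key <- function(d) paste(d$read_id, d$subject_accession)
  expect_true(all(key(pre_all) %in% key(exh_all)))
})

test_that("library classification tallies statuses correctly", {
  # zero reads
  db <- fixtureDb(650)
  cls0 <- classifyLibrary(character(0), db)
  expect_equal(cls0$tallies$n_total, 0)
  expect_equal(cls0$tallies$n_assigned, 0)

  # constructed mix: 2 assigned, 3 hit-but-unassignable, 5 no-hit
  seqs <- as.character(refSequences(db))
  set.seed(55)
  assigned <- c(substr(seqs[1], 1, 140), substr(seqs[4], 101, 240))
  half <- vapply(c(5, 6, 7), function(i)
    paste0(substr(seqs[i], 1, 70), randSeq(70)), "")
  nohit <- vapply(1:5, function(i) randSeq(140), "")
  reads <- unname(c(assigned, half, nohit))
  cls <- classifyLibrary(reads, db)
  expect_equal(cls$tallies$n_total, 10)
  expect_equal(cls$tallies$n_assigned, 2)
  expect_equal(cls$tallies$n_with_hit, 5)
  expect_equal(cls$tallies$pct_with_hit, 50)
  expect_equal(cls$tallies$pct_assigned, 20)
  expect_equal(sum(cls$assignments$status == "hit_unassigned"), 3)
  expect_equal(sum(cls$assignments$status == "no_hit"), 5)
  # tallies nest: assigned <= with hit <= total
  expect_lte(cls$tallies$n_assigned, cls$tallies$n_with_hit)
  expect_lte(cls$tallies$n_with_hit, cls$tallies$n_total)
})

test_that("tightening filters never increases hit or assigned counts", {
  db <- generateSyntheticClade(12, 500, 0.15, n_genera = 4, seed = 29)
  mc <- mockCommunity(db, setNames(rep(1 / 12, 12), refSpecies(db)))
  reads <- simulateCommunityReads(mc, 60, 140, 0.01, seed = 30)
  grid_bit <- c(150, 230, 260)
  grid_id <- c(0.95, 0.99, 1)
  prev_assigned <- Inf
  for (mb in grid_bit) {
    cls <- classifyLibrary(reads, db, min_bit = mb)
    expect_lte(cls$tallies$n_assigned, prev_assigned)
    prev_assigned <- cls$tallies$n_assigned
  }
  prev_assigned <- Inf
  for (mi in grid_id) {
    cls <- classifyLibrary(reads, db, min_identity = mi)
    expect_lte(cls$tallies$n_assigned, prev_assigned)
    prev_assigned <- cls$tallies$n_assigned
  }
})

test_that("unique fragments self-assign to their source species", {
  db <- generateSyntheticClade(15, 500, 0.2, n_genera = 5, seed = 31)
  frags <- fragmentReferences(db, 140, mode = "random", n_per_seq = 2,
                              seed = 32)
  cls <- classifyLibrary(frags, db)
  a <- cls$assignments
  sp <- a$status == "assigned" & a$rank == "species"
  expect_true(all(a$taxon[sp] == frags$truth_species[sp]))
  expect_gt(mean(sp), 0.9)
})

test_that("the length benchmark reports resolution per fragment size", {
  # single-species database: everything self-assigns
  one <- fixtureDb(650)[1]
  b1 <- lengthBenchmark(one, "Alpha_one", lengths = c(140))
  expect_equal(b1$pct_assigned_at_species, 100)
  expect_equal(b1$species_tpr, 1)
  expect_equal(b1$n_false_positive_species, 0)

  # synthetic clade, error-free tiling: perfect recovery at 140 bp
  db <- generateSyntheticClade(20, 650, 0.2, n_genera = 6, seed = 42)
  bm <- lengthBenchmark(db, refSpecies(db), lengths = c(50, 140))
  expect_equal(bm$species_tpr, c(1, 1))
  expect_equal(bm$n_false_positive_species, c(0, 0))
  # the short length runs under a lowered, coverage-based floor
  expect_lt(bm$effective_min_bit[1], bm$effective_min_bit[2])
  expect_lte(bm$effective_min_bit[2], 230)
  # resolution does not decrease with fragment length
  expect_lte(bm$pct_assigned_at_species[1], bm$pct_assigned_at_species[2])
})
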