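# Run expr with a fixed RNG seed, restoring the caller's RNG state after.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

BASES <- c("A", "C", "G", "T")

# Jukes-Cantor substitution along a branch of length t (subs/site): each
# site changes with probability 3/4 (1 - exp(-4t/3)), uniformly to one of
# the three alternative bases. Caller owns the RNG state.
mutateJC <- function(seq_chars, t) {
  if (t <= 0) return(seq_chars)
  p <- 0.75 * (1 - exp(-4 * t / 3))
  hit <- runif(length(seq_chars)) < p
  n <- sum(hit)
  if (n > 0) {
    cur <- seq_chars[hit]
    shift <- sample.int(3, n, replace = TRUE)
    idx <- (match(cur, BASES) - 1L + shift) %% 4L + 1L
    seq_chars[hit] <- BASES[idx]
  }
  seq_chars
}

# Expected p-distance between two tips separated by total path length T.
expectedP <- function(T) 0.75 * (1 - exp(-4 * T / 3))

#' Generate a synthetic reference clade
#'
#' Emulates the statistical structure of a one-barcode-per-species COI
#' reference set: a random root sequence is mutated independently down a
#' star-like two-level hierarchy (genus ancestors, then species tips) under
#' a Jukes-Cantor substitution process. The shared branch length is
#' calibrated so the expected mean pairwise p-distance over all species
#' pairs equals `mean_pairwise_distance`.
#'
#' @param n_species Number of species (>= 2); one sequence each.
#' @param seq_length Barcode length in bp.
#' @param mean_pairwise_distance Target mean pairwise p-distance
#'   (0 <= d < 0.6). 0 yields identical sequences.
#' @param n_genera Number of genera; species are assigned round-robin.
#' @param seed RNG seed; the generator is a pure function of its arguments.
#' @return A [ReferenceDB-class] with synthesized lineage labels
#'   (`GenusXX_speciesYYY`), genera grouped into families, one order.
#' @examples
#' db <- generateSyntheticClade(10, 600, 0.2, n_genera = 4, seed = 1)
#' dbStats(db)
#' @export
generateSyntheticClade <- function(n_species, seq_length = 650,
                                   mean_pairwise_distance = 0.2,
                                   n_genera = max(1, n_species %/% 3),
                                   seed = 1) {
  if (n_species < 2) stop("need at least 2 species")
  if (mean_pairwise_distance < 0 || mean_pairwise_distance >= 0.6)
    stop("mean_pairwise_distance must be in [0, 0.6)")
  withSeed(seed, {
    genus_of <- ((seq_len(n_species) - 1L) %% n_genera) + 1L
    # fraction of species pairs sharing a genus
    tab <- tabulate(genus_of, n_genera)
    n_pairs <- n_species * (n_species - 1) / 2
    f_within <- sum(tab * (tab - 1) / 2) / n_pairs
    D <- mean_pairwise_distance
    t <- 0
    if (D > 0) {
      # tips in one genus are 2t apart, across genera 4t
      obj <- function(t) f_within * expectedP(2 * t) +
        (1 - f_within) * expectedP(4 * t) - D
      t <- uniroot(obj, c(1e-9, 10), tol = 1e-12)$root
    }
    root <- sample(BASES, seq_length, replace = TRUE)
    genus_anc <- lapply(seq_len(n_genera), function(g) mutateJC(root, t))
    seqs <- character(n_species)
    for (i in seq_len(n_species))
      seqs[i] <- paste(mutateJC(genus_anc[[genus_of[i]]], t), collapse = "")

    n_fam <- max(1L, ceiling(n_genera / 3))
    fam_of_genus <- ((seq_len(n_genera) - 1L) %% n_fam) + 1L
    genus_lab <- sprintf("Genus%02d", genus_of)
    tax <- data.frame(
      accession = sprintf("SYN%04d", seq_len(n_species)),
      species = sprintf("Genus%02d_species%03d", genus_of,
                        seq_len(n_species)),
      genus = genus_lab,
      family = sprintf("Family%02d", fam_of_genus[genus_of]),
      order = "SynthOrder")
    ReferenceDB(setNames(seqs, tax$accession), tax)
  })
}

#' Fragment reference sequences into reads
#'
#' Cuts each reference barcode into fragments of a fixed length, emulating
#' partial sequences of known origin. In `tiling` mode windows start at
#' offsets 0, step, 2 step, ... plus a final window flush with the 3' end
#' (so every base is covered when step <= read_length); in `random` mode
#' `n_per_seq` start positions are drawn uniformly. Sequences shorter than
#' `read_length` are skipped and reported via the `"skipped"` attribute.
#'
#' @param db A [ReferenceDB-class].
#' @param read_length Fragment length in bp, or `"full"` for one read per
#'   sequence.
#' @param mode `"tiling"` or `"random"`.
#' @param step Tiling step in bp (default: `read_length`, non-overlapping).
#' @param n_per_seq Fragments per sequence in random mode.
#' @param seed RNG seed (random mode).
#' @return A data.frame with columns `read_id`, `source_accession`,
#'   `source_species`, `start` (0-based), `length`, `sequence`,
#'   `truth_species`.
#' @export
fragmentReferences <- function(db, read_length, mode = c("tiling", "random"),
                               step = NULL, n_per_seq = 1, seed = 1) {
  mode <- match.arg(mode)
  tax <- as.data.frame(refTaxonomy(db))
  seqs <- as.character(refSequences(db))
  widths <- nchar(seqs)

  if (identical(read_length, "full")) {
    out <- data.frame(
      read_id = paste0(tax$accession, "_full"),
      source_accession = tax$accession, source_species = tax$species,
      start = 0L, length = widths, sequence = unname(seqs),
      truth_species = tax$species, stringsAsFactors = FALSE)
    attr(out, "skipped") <- character(0)
    return(out)
  }

  read_length <- as.integer(read_length)
  if (read_length <= 0) stop("read_length must be positive")
  usable <- widths >= read_length
  skipped <- tax$accession[!usable]
  if (length(skipped))
    message(length(skipped), " sequence(s) shorter than ", read_length,
            " bp skipped")

  starts_of <- function(w) {
    if (mode == "tiling") {
      if (is.null(step)) step <- read_length
      if (step <= 0) stop("step must be positive")
      s <- seq.int(0L, w - read_length, by = step)
      unique(c(s, w - read_length))  # flush window covers the 3' end
    } else {
      if (n_per_seq <= 0) stop("n_per_seq must be positive in random mode")
      as.integer(floor(runif(n_per_seq, 0, w - read_length + 1)))
    }
  }

  build <- function() {
    pieces <- lapply(which(usable), function(i) {
      st <- starts_of(widths[i])
      data.frame(
        read_id = paste0(tax$accession[i], "_", seq_along(st), "_", st),
        source_accession = tax$accession[i],
        source_species = tax$species[i],
        start = st, length = read_length,
        sequence = substring(seqs[i], st + 1L, st + read_length),
        truth_species = tax$species[i], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, c(pieces,
                            list(make.row.names = FALSE)))
    if (is.null(out))
      out <- data.frame(read_id = character(), source_accession = character(),
                        source_species = character(), start = integer(),
                        length = integer(), sequence = character(),
                        truth_species = character())
    attr(out, "skipped") <- skipped
    out
  }
  if (mode == "random") withSeed(seed, build()) else build()
}

#' Draw mock-community relative abundances
#'
#' Emulates how mock samples are actually composed: a pool of individually
#' identified larvae mixed in equimolar quantities. Dirichlet(1) weights
#' are realised as larvae counts over a pool of `n_larvae` individuals,
#' with every member species receiving at least one larva, so that every
#' species has relative abundance >= 1/`n_larvae` — as in a real mock,
#' where a member species is by construction physically present.
#'
#' @param species Character vector of member species labels.
#' @param n_larvae Number of pooled individuals (default 102, a typical
#'   mock batch).
#' @param seed RNG seed.
#' @return Named numeric vector of relative abundances summing to 1.
#' @export
mockAbundances <- function(species, n_larvae = 102, seed = 1) {
  k <- length(species)
  if (k < 1) stop("need at least one species")
  if (n_larvae < k) stop("need at least one larva per species")
  withSeed(seed, {
    w <- rgamma(k, shape = 1)
    extra <- if (n_larvae > k)
      as.vector(rmultinom(1, n_larvae - k, w / sum(w))) else 0
    setNames((1 + extra) / n_larvae, species)
  })
}

#' Simulate reads from a mock community
#'
#' Draws reads from a known species abundance vector: species are sampled
#' multinomially, a source barcode uniformly within each species, start
#' positions uniformly along the barcode, and sequencing errors as i.i.d.
#' per-base substitutions (uniform over the three alternatives). Truth
#' labels are retained for parameter-recovery analyses.
#'
#' @param community A [MockCommunity-class].
#' @param n_reads Number of reads (> 0).
#' @param read_length Read length in bp; every member barcode must be at
#'   least this long.
#' @param error_rate Per-base substitution probability (0 <= e < 0.25).
#' @param seed RNG seed.
#' @return A data.frame with the same columns as [fragmentReferences()].
#' @export
simulateCommunityReads <- function(community, n_reads, read_length = 140,
                                   error_rate = 0, seed = 1) {
  if (n_reads <= 0) stop("n_reads must be positive")
  if (error_rate < 0 || error_rate >= 0.25)
    stop("error_rate must be in [0, 0.25)")
  ab <- communityAbundance(community)
  db <- communityDb(community)
  tax <- as.data.frame(refTaxonomy(db))
  seqs <- as.character(refSequences(db))
  widths <- nchar(seqs)
  if (any(widths < read_length))
    stop("member barcode(s) shorter than read_length")

  withSeed(seed, {
    counts <- as.vector(rmultinom(1, n_reads, ab))
    sp_idx <- rep.int(seq_along(ab), counts)
    sp_idx <- sample(sp_idx)  # shuffle read order
    rec_idx <- vapply(sp_idx, function(s) {
      cand <- which(tax$species == names(ab)[s])
      if (length(cand) == 1) cand else sample(cand, 1)
    }, integer(1))
    st <- as.integer(floor(runif(n_reads, 0, widths[rec_idx] - read_length + 1)))
    rd <- substring(seqs[rec_idx], st + 1L, st + read_length)
    if (error_rate > 0) {
      n_err <- rbinom(n_reads, read_length, error_rate)
      for (i in which(n_err > 0)) {
        pos <- sample.int(read_length, n_err[i])
        ch <- strsplit(rd[i], "")[[1]]
        shift <- sample.int(3, n_err[i], replace = TRUE)
        ch[pos] <- BASES[(match(ch[pos], BASES) - 1L + shift) %% 4L + 1L]
        rd[i] <- paste(ch, collapse = "")
      }
    }
    data.frame(
      read_id = sprintf("simread%06d", seq_len(n_reads)),
      source_accession = tax$accession[rec_idx],
      source_species = tax$species[rec_idx],
      start = st, length = read_length, sequence = rd,
      truth_species = tax$species[rec_idx], stringsAsFactors = FALSE)
  })
}

#' Write simulated reads to FASTQ/FASTA and the truth table to TSV
#'
#' FASTQ qualities are constant Q40 (`"I"`, Phred+33). An optional fixed
#' 6-bp index can be prepended to every read (with Q40 qualities) to
#' emulate internally indexed capture libraries for the demultiplexer.
#'
#' @param reads A read data.frame from [fragmentReferences()] or
#'   [simulateCommunityReads()].
#' @param path Output file path.
#' @param index Optional 6-bp index to prepend to each read.
#' @return `path`, invisibly.
#' @export
writeReadsFastq <- function(reads, path, index = NULL) {
  seqs <- reads$sequence
  if (!is.null(index)) {
    if (nchar(index) != 6) stop("index must be exactly 6 bp")
    seqs <- paste0(index, seqs)
  }
  qual <- strrep("I", nchar(seqs))
  writeLines(paste0("@", reads$read_id, "\n", seqs, "\n+\n", qual), path)
  invisible(path)
}

#' @rdname writeReadsFastq
#' @export
writeReadsFasta <- function(reads, path) {
  writeLines(paste0(">", reads$read_id, "\n", reads$sequence), path)
  invisible(path)
}

#' @rdname writeReadsFastq
#' @export
writeTruthTsv <- function(reads, path) {
  write.table(reads[, c("read_id", "truth_species", "source_accession",
                        "start", "length")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
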