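#' Read a FASTQ file into a read table
#'
#' Phred+33 qualities. The pipeline represents reads as a plain data.frame
#' (`read_id`, `sequence`, `quality`) so every stage is easily inspectable.
#'
#' @param path FASTQ path.
#' @return A data.frame with columns `read_id`, `sequence`, `quality`.
#' @export
readFastqReads <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0)
    return(data.frame(read_id = character(), sequence = character(),
                      quality = character()))
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ: line count not a multiple of 4")
  ids <- sub("^@", "", lines[seq(1, length(lines), by = 4)])
  ids <- sub("\\s.*$", "", ids)
  seqs <- toupper(lines[seq(2, length(lines), by = 4)])
  quals <- lines[seq(4, length(lines), by = 4)]
  if (any(nchar(seqs) != nchar(quals)))
    stop("FASTQ sequence/quality length mismatch")
  data.frame(read_id = ids, sequence = seqs, quality = quals,
             stringsAsFactors = FALSE)
}

#' Demultiplex reads on a 6-bp internal index
#'
#' Routes each read by exact match of its first 6 bases against the index
#' map; matching reads have the index trimmed from sequence and qualities.
#' Non-matching reads (including reads shorter than 6 bp) land in the
#' unassigned bin. Every input read lands in exactly one bin.
#'
#' @param reads A read data.frame from [readFastqReads()].
#' @param index_map Named character vector mapping 6-bp index -> sample
#'   name; indexes must be unique and exactly 6 bp.
#' @return A list: `samples` (named list of read data.frames, one per
#'   sample, trimmed) and `unassigned` (read data.frame).
#' @export
demultiplexReads <- function(reads, index_map) {
  idx <- names(index_map)
  if (is.null(idx) || any(nchar(idx) != 6))
    stop("indexes must be exactly 6 bp")
  if (anyDuplicated(idx)) stop("duplicate index in map")
  if (anyDuplicated(index_map)) stop("duplicate sample name in map")
  prefix <- substr(reads$sequence, 1, 6)
  sample <- index_map[ifelse(nchar(reads$sequence) >= 6, prefix, NA)]
  samples <- lapply(setNames(seq_along(index_map), index_map), function(i) {
    sel <- which(!is.na(sample) & sample == index_map[i])
    out <- reads[sel, , drop = FALSE]
    out$sequence <- substring(out$sequence, 7)
    out$quality <- substring(out$quality, 7)
    rownames(out) <- NULL
    out
  })
  unassigned <- reads[is.na(sample), , drop = FALSE]
  rownames(unassigned) <- NULL
  list(samples = samples, unassigned = unassigned)
}

#' Filter reads on mean base quality
#'
#' Keeps reads whose arithmetic mean Phred score is at least `min_mean_q`
#' (the boundary is kept: a mean of exactly 30 passes a Q30 filter).
#'
#' @param reads A read data.frame.
#' @param min_mean_q Minimum mean Phred quality (default 30).
#' @return A list: `kept` (read data.frame) and `n_discarded`.
#' @export
qualityFilterReads <- function(reads, min_mean_q = 30) {
  if (nrow(reads) == 0) return(list(kept = reads, n_discarded = 0L))
  if (any(nchar(reads$sequence) != nchar(reads$quality)))
    stop("sequence/quality length mismatch")
  meanq <- vapply(reads$quality, function(q) {
    if (!nzchar(q)) return(-Inf)
    mean(utf8ToInt(q) - 33L)
  }, numeric(1), USE.NAMES = FALSE)
  keep <- meanq >= min_mean_q
  kept <- reads[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, n_discarded = sum(!keep))
}

#' Pipeline configuration
#'
#' Bundles the reference database, demultiplexing index map and every
#' assignment threshold, with the capture workflow's values as defaults
#' (mean quality 30, bit score 230, identity 99%).
#'
#' @param db A [ReferenceDB-class].
#' @param index_map Named character vector: 6-bp index -> sample name.
#' @param min_mean_q Mean-quality floor.
#' @param scoring A [scoringScheme()].
#' @param min_bit,min_identity,min_read_coverage,top_percent,min_hit_bit
#'   Assignment filters, see [classifyLibrary()].
#' @param seed RNG seed for any stochastic downstream step.
#' @return A validated `PipelineConfig` list.
#' @export
pipelineConfig <- function(db, index_map, min_mean_q = 30,
                           scoring = scoringScheme(), min_bit = 230,
                           min_identity = 0.99, min_read_coverage = 0.9,
                           top_percent = 0.10, min_hit_bit = 30, seed = 1) {
  if (!is(db, "ReferenceDB")) stop("db must be a ReferenceDB")
  if (length(index_map) == 0 || is.null(names(index_map)))
    stop("index_map must be a named character vector (index -> sample)")
  if (any(nchar(names(index_map)) != 6))
    stop("indexes must be exactly 6 bp")
  if (anyDuplicated(names(index_map))) stop("duplicate index in map")
  if (min_identity <= 0 || min_identity > 1)
    stop("min_identity must be in (0, 1]")
  if (min_mean_q < 0) stop("min_mean_q must be >= 0")
  structure(list(db = db, index_map = index_map, min_mean_q = min_mean_q,
                 scoring = scoring, min_bit = min_bit,
                 min_identity = min_identity,
                 min_read_coverage = min_read_coverage,
                 top_percent = top_percent, min_hit_bit = min_hit_bit,
                 seed = seed),
            class = "PipelineConfig")
}

truthProfile <- function(truth) {
  if (inherits(truth, "CommunityProfile")) return(truth)
  if (is.character(truth) && length(truth) == 1 && file.exists(truth))
    truth <- read.table(truth, sep = "\t", header = TRUE,
                        colClasses = c("character", "numeric"))
  if (is.data.frame(truth)) {
    if (!all(c("species", "count") %in% colnames(truth)))
      stop("truth table needs 'species' and 'count' columns")
    return(CommunityProfile(setNames(as.numeric(truth$count),
                                     truth$species)))
  }
  CommunityProfile(truth)
}

stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the capture metabarcoding pipeline end to end
#'
#' Demultiplexes, quality-filters, assigns and quantifies one FASTQ of
#' internally indexed capture reads, mirroring the standard accounting of
#' capture experiments: a per-stage read ledger (input, demultiplexed,
#' quality-kept, with hit, assigned) is logged to stderr and returned.
#' With a truth composition, the maxSSS read-count threshold is derived per
#' sample, applied, and the thresholded and unthresholded frequency
#' profiles are both compared with the truth.
#'
#' @param config A [pipelineConfig()].
#' @param fastq Path to a FASTQ file, or a read data.frame.
#' @param truth Optional truth composition: a TSV path or data.frame with
#'   `species` and `count` columns, a named count vector, or a
#'   [CommunityProfile-class]. Either one truth for all samples or a named
#'   list keyed by sample.
#' @param quiet Suppress the stderr stage log.
#' @return A list with `ledger` (per-sample stage counts), `n_unassigned`
#'   (demultiplexing), and `samples`: per sample a list with `tallies`,
#'   `assignments`, `profile`, and when truth is supplied `threshold`
#'   (`ThresholdResult`), `profile_thresholded`, `comparison`
#'   (thresholded vs truth) and `comparison_unthresholded`.
#' @export
runPipeline <- function(config, fastq, truth = NULL, quiet = FALSE) {
  if (!inherits(config, "PipelineConfig")) stop("config must be a PipelineConfig")
  say <- function(...) if (!quiet) message(...)
  reads <- stageTry("input",
    if (is.character(fastq)) readFastqReads(fastq) else fastq)
  say("input: ", nrow(reads), " reads")

  demux <- stageTry("demultiplex", demultiplexReads(reads, config$index_map))
  say("demultiplex: ", nrow(demux$unassigned), " unassigned")

  set.seed(config$seed)
  samples <- list()
  ledger <- list()
  for (s in names(demux$samples)) {
    dreads <- demux$samples[[s]]
    qc <- stageTry("quality_filter",
                   qualityFilterReads(dreads, config$min_mean_q))
    cls <- stageTry("assign", classifyLibrary(
      qc$kept, config$db, config$scoring, min_bit = config$min_bit,
      min_identity = config$min_identity,
      min_read_coverage = config$min_read_coverage,
      top_percent = config$top_percent, min_hit_bit = config$min_hit_bit))
    prof <- stageTry("quantify", suppressWarnings(
      profileFromAssignments(cls)))
    out <- list(tallies = cls$tallies, assignments = cls$assignments,
                profile = prof)

    this_truth <- if (is.list(truth) && !is.data.frame(truth) &&
                      !inherits(truth, "CommunityProfile"))
      truth[[s]] else truth
    if (!is.null(this_truth)) {
      tp <- stageTry("truth", truthProfile(this_truth))
      counts <- profileCounts(prof)
      cand <- union(names(counts), names(profileCounts(tp)))
      full <- setNames(rep(0, length(cand)), cand)
      full[names(counts)] <- counts
      present <- names(profileCounts(tp))[profileCounts(tp) > 0]
      # with no truth-absent candidate the ROC has no negatives; fall back
      # to an unthresholded profile rather than aborting the sample
      thr <- if (all(names(full) %in% present)) NULL
             else stageTry("maxSSS", maxSSSThreshold(full, present))
      prof_t <- if (is.null(thr)) prof
                else stageTry("threshold", suppressWarnings(
                  applyThreshold(prof, thr$t_star)))
      if (is.null(thr))
        say(s, ": all candidate species are truth-present; ",
            "no threshold applied")
      out$threshold <- thr
      out$profile_thresholded <- prof_t
      out$comparison <- stageTry("compare", compareProfiles(prof_t, tp))
      out$comparison_unthresholded <-
        stageTry("compare", compareProfiles(prof, tp))
    }
    samples[[s]] <- out
    ledger[[s]] <- data.frame(
      sample = s, n_demultiplexed = nrow(dreads),
      n_quality_kept = nrow(qc$kept),
      n_with_hit = cls$tallies$n_with_hit,
      n_assigned = cls$tallies$n_assigned)
    say(s, ": ", nrow(dreads), " demultiplexed -> ", nrow(qc$kept),
        " Q-kept -> ", cls$tallies$n_with_hit, " with hit -> ",
        cls$tallies$n_assigned, " assigned")
  }
  ledger <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(sample = character(), n_demultiplexed = integer(),
               n_quality_kept = integer(), n_with_hit = integer(),
               n_assigned = integer())
  rownames(ledger) <- NULL
  list(ledger = ledger, n_unassigned = nrow(demux$unassigned),
       samples = samples)
}
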