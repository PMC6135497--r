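#' Read a species-labelled reference FASTA
#'
#' Builds a [ReferenceDB-class] from a barcode FASTA plus taxonomy. Two
#' header dialects are supported: `scheme = "tsv"` (the canonical
#' interchange) takes the accession as the first whitespace-separated header
#' token and looks the lineage up in a taxonomy table; `scheme = "header"`
#' parses headers of the form `accession Genus_epithet`, taking the genus
#' from the species label and filling family/order with `"unknown"`.
#'
#' Sequences are upper-cased and U is converted to T at import. Records
#' whose sequence contains characters outside the IUPAC DNA alphabet, or
#' more than `max_n_frac` N bases, are rejected; the rejection count is
#' reported in the `"rejected"` attribute and a warning.
#'
#' @param fasta_path Path to the FASTA file.
#' @param taxonomy For `scheme = "tsv"`: a data.frame or TSV path with
#'   columns `accession`, `species`, `genus`, `family`, `order`.
#' @param scheme `"tsv"` or `"header"`.
#' @param max_n_frac Maximum tolerated fraction of N bases per record.
#' @return A [ReferenceDB-class]; attributes `"rejected"` (number of records
#'   dropped) and `"rejected_accessions"`.
#' @export
readReferenceFasta <- function(fasta_path, taxonomy = NULL,
                               scheme = c("tsv", "header"),
                               max_n_frac = 0.1) {
  scheme <- match.arg(scheme)
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  seqs <- Biostrings::readBStringSet(fasta_path)
  if (length(seqs) == 0) {
    warning("empty FASTA: returning an empty ReferenceDB")
    db <- emptyReferenceDB()
    attr(db, "rejected") <- 0L
    return(db)
  }
  headers <- names(seqs)
  acc <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  if (anyNA(acc) || any(!nzchar(acc)))
    stop("FASTA header not parseable to an accession")
  if (anyDuplicated(acc))
    stop("duplicate accession in FASTA: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))

  raw <- toupper(as.character(seqs))
  raw <- gsub("U", "T", raw, fixed = TRUE)
  ok_alpha <- !grepl("[^ACGTRYSWKMBDHVN]", raw)
  n_frac <- vapply(raw, function(s) {
    nchar(gsub("[^N]", "", s)) / nchar(s)
  }, numeric(1), USE.NAMES = FALSE)
  keep <- ok_alpha & nzchar(raw) & n_frac <= max_n_frac

  if (scheme == "header") {
    second <- vapply(strsplit(headers, "\\s+"), function(x) {
      if (length(x) >= 2) x[2] else NA_character_
    }, character(1))
    if (anyNA(second))
      stop("header scheme requires 'accession species_label' headers")
    genus <- vapply(strsplit(second, "_"), `[`, character(1), 1L)
    tax <- data.frame(accession = acc, species = second, genus = genus,
                      family = "unknown", order = "unknown")
  } else {
    if (is.null(taxonomy))
      stop("scheme 'tsv' requires a taxonomy table or path")
    tax_tab <- if (is.character(taxonomy)) readTaxonomyTsv(taxonomy)
               else as.data.frame(taxonomy)
    m <- match(acc, tax_tab$accession)
    if (anyNA(m))
      stop("accessions missing from taxonomy: ",
           paste(head(acc[is.na(m)], 5), collapse = ", "))
    tax <- tax_tab[m, c("accession", "species", "genus", "family", "order")]
  }

  n_rej <- sum(!keep)
  if (n_rej > 0)
    warning(n_rej, " record(s) rejected (alphabet or >",
            round(100 * max_n_frac), "% N)")
  db <- ReferenceDB(
    Biostrings::DNAStringSet(setNames(raw[keep], acc[keep])),
    tax[keep, , drop = FALSE])
  attr(db, "rejected") <- n_rej
  attr(db, "rejected_accessions") <- acc[!keep]
  db
}

emptyReferenceDB <- function() {
  ReferenceDB(Biostrings::DNAStringSet(),
              data.frame(accession = character(), species = character(),
                         genus = character(), family = character(),
                         order = character()))
}

#' Write a ReferenceDB back to FASTA (+ taxonomy TSV)
#'
#' @param db A [ReferenceDB-class].
#' @param fasta_path Output FASTA path (headers are bare accessions).
#' @param taxonomy_path Optional output path for the 5-column taxonomy TSV.
#' @return `fasta_path`, invisibly.
#' @export
writeReferenceFasta <- function(db, fasta_path, taxonomy_path = NULL) {
  Biostrings::writeXStringSet(refSequences(db), fasta_path)
  if (!is.null(taxonomy_path))
    writeTaxonomyTsv(refTaxonomy(db), taxonomy_path)
  invisible(fasta_path)
}

#' Read / write the taxonomy interchange TSV
#'
#' Tab-separated, with header line: accession, species, genus, family,
#' order.
#'
#' @param path File path.
#' @return `readTaxonomyTsv`: a data.frame.
#' @export
readTaxonomyTsv <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    colClasses = "character", quote = "")
  need <- c("accession", "species", "genus", "family", "order")
  if (!all(need %in% colnames(tab)))
    stop("taxonomy TSV must have columns: ", paste(need, collapse = ", "))
  tab
}

#' @rdname readTaxonomyTsv
#' @param taxonomy A taxonomy data.frame/DataFrame.
#' @export
writeTaxonomyTsv <- function(taxonomy, path) {
  write.table(as.data.frame(taxonomy), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Fold a species label for matching
#'
#' Lower-cases and replaces runs of spaces with a single underscore, so that
#' "Danio rerio" and "danio_rerio" compare equal.
#'
#' @param x Character vector of species labels.
#' @return Folded labels.
#' @export
foldSpeciesLabel <- function(x) {
  gsub(" +", "_", tolower(trimws(x)))
}

# A species label is "named" unless it carries an open-nomenclature marker
# (sp., cf., aff.) or a bare "sp" token as the epithet (e.g. Genus_sp_3).
isNamedSpecies <- function(labels) {
  f <- foldSpeciesLabel(labels)
  open_nom <- grepl("(^|_)(sp|cf|aff)\\.", f)
  bare_sp <- grepl("(^|_)sp(_|$|[0-9])", f)
  !(open_nom | bare_sp)
}

#' Summary statistics of a reference database
#'
#' Counts are computed from distinct lineage labels. A species is "named"
#' unless its label carries an open-nomenclature marker (`sp.`, `cf.`,
#' `aff.`) or a bare `sp` epithet token.
#'
#' @param db A [ReferenceDB-class].
#' @return A list with `n_sequences`, `n_species`, `n_named_species`,
#'   `n_genera`.
#' @examples
#' db <- ReferenceDB(c(a = "ACGT", b = "ACGT", c = "ACGA"),
#'   data.frame(accession = c("a", "b", "c"),
#'              species = c("X_one", "X_one", "Y sp. 3"),
#'              genus = c("X", "X", "Y"), family = "F", order = "O"))
#' dbStats(db)  # 3 sequences, 2 species, 1 named, 2 genera
#' @export
dbStats <- function(db) {
  tax <- refTaxonomy(db)
  sp <- unique(as.character(tax$species))
  list(n_sequences = length(db),
       n_species = length(sp),
       n_named_species = sum(isNamedSpecies(sp)),
       n_genera = length(unique(as.character(tax$genus))))
}

#' Subset a reference database by species list
#'
#' Matching is performed on folded labels (case / space-vs-underscore
#' insensitive). Labels not present in the database are reported via the
#' `"missing_species"` attribute and a message.
#'
#' @param db A [ReferenceDB-class].
#' @param species Character vector of species labels to keep.
#' @return The restricted [ReferenceDB-class] (possibly empty).
#' @export
subsetBySpecies <- function(db, species) {
  want <- foldSpeciesLabel(species)
  have <- foldSpeciesLabel(refTaxonomy(db)$species)
  keep <- have %in% want
  missing <- species[!(want %in% unique(have))]
  if (length(missing))
    message(length(missing), " species label(s) not found in the database")
  out <- if (any(keep)) db[which(keep)] else emptyReferenceDB()
  attr(out, "missing_species") <- missing
  out
}

#' Curate a reference database
#'
#' Applies a manual removal list and/or adds records, emitting a curation
#' log (one line per action) in the `"curation_log"` attribute. Removing an
#' absent accession is reported, not an error; adding a duplicate accession
#' is an error.
#'
#' @param db A [ReferenceDB-class].
#' @param remove Character vector of accessions to drop.
#' @param add Optional [ReferenceDB-class] (or NULL) whose records are
#'   appended.
#' @return The curated [ReferenceDB-class].
#' @export
curateDb <- function(db, remove = character(), add = NULL) {
  log <- character()
  acc <- refAccessions(db)
  hit <- remove %in% acc
  if (any(!hit))
    log <- c(log, paste("absent, not removed:", remove[!hit]))
  if (any(hit)) {
    log <- c(log, paste("removed:", remove[hit]))
    db <- db[which(!(acc %in% remove))]
  }
  if (!is.null(add) && length(add) > 0) {
    dup <- refAccessions(add) %in% refAccessions(db)
    if (any(dup))
      stop("cannot add duplicate accession: ",
           paste(refAccessions(add)[dup], collapse = ", "))
    db <- ReferenceDB(
      c(refSequences(db), refSequences(add)),
      rbind(as.data.frame(refTaxonomy(db)), as.data.frame(refTaxonomy(add))))
    log <- c(log, paste("added:", refAccessions(add)))
  }
  if (length(log) == 0) log <- "no curation actions"
  attr(db, "curation_log") <- log
  db
}

#' In-silico PCR amplicon extraction
#'
#' Locates the forward primer on the plus strand and the reverse primer as
#' its reverse complement downstream, and returns the spanned product
#' (primers included) with 0-based half-open coordinates. When several site
#' pairs exist, the shortest product longer than twice the primer length
#' wins. Primer matching tolerates up to `max_mismatch` mismatches and
#' honours IUPAC ambiguity codes in the primers.
#'
#' @param template A DNA string (character or `DNAString`) or a
#'   [ReferenceDB-class] together with `accession`.
#' @param fwd_primer,rev_primer Primer sequences, 5'->3', at least 15 bp.
#' @param max_mismatch Maximum mismatches tolerated per primer site.
#' @param accession When `template` is a `ReferenceDB`, which record to use.
#' @return A list: `sequence` (the product), `start`, `end` (0-based
#'   half-open on the template plus strand), `length`.
#' @examples
#' tpl <- paste0(strrep("A", 10), "TCAACCAACCACAAAGACATTGGCAC",
#'               strrep("G", 30),
#'               as.character(Biostrings::reverseComplement(
#'                 Biostrings::DNAString("TAGACTTCTGGGTGGCCAAAGAATCA"))),
#'               strrep("A", 10))
#' amp <- extractAmplicon(tpl, "TCAACCAACCACAAAGACATTGGCAC",
#'                        "TAGACTTCTGGGTGGCCAAAGAATCA")
#' amp$length
#' @export
extractAmplicon <- function(template, fwd_primer, rev_primer,
                            max_mismatch = 2, accession = NULL) {
  if (is(template, "ReferenceDB")) {
    if (is.null(accession)) stop("accession required with a ReferenceDB")
    template <- as.character(refSequences(template)[[accession]])
  }
  template <- toupper(as.character(template))
  fwd_primer <- toupper(fwd_primer)
  rev_primer <- toupper(rev_primer)
  if (nchar(fwd_primer) < 15 || nchar(rev_primer) < 15)
    stop("primers must be at least 15 bp")
  if (max_mismatch < 0) stop("max_mismatch must be >= 0")

  subj <- Biostrings::DNAString(template)
  fwd_hits <- Biostrings::matchPattern(
    Biostrings::DNAString(fwd_primer), subj,
    max.mismatch = max_mismatch, fixed = FALSE)
  rc_rev <- Biostrings::reverseComplement(Biostrings::DNAString(rev_primer))
  rev_hits <- Biostrings::matchPattern(
    rc_rev, subj, max.mismatch = max_mismatch, fixed = FALSE)
  if (length(fwd_hits) == 0 || length(rev_hits) == 0)
    stop("no amplicon: primer site not found within ", max_mismatch,
         " mismatch(es)")

  starts <- BiocGenerics::start(fwd_hits) - 1L   # 0-based
  ends <- BiocGenerics::end(rev_hits)            # half-open
  min_len <- 2L * max(nchar(fwd_primer), nchar(rev_primer))
  combos <- expand.grid(start = starts, end = ends)
  combos$len <- combos$end - combos$start
  combos <- combos[combos$len > min_len, , drop = FALSE]
  if (nrow(combos) == 0)
    stop("no amplicon: no primer pair yields a product longer than ",
         min_len, " bp")
  best <- combos[order(combos$len, combos$start), ][1, ]
  list(sequence = substr(template, best$start + 1L, best$end),
       start = as.integer(best$start), end = as.integer(best$end),
       length = as.integer(best$len))
}
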