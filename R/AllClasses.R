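#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings DNAStringSet
NULL

#' Species-labelled COI reference database
#'
#' A `ReferenceDB` couples a [Biostrings::DNAStringSet] of barcode sequences
#' with a four-rank taxonomy (species, genus, family, order) keyed by
#' accession. It is the search target of the read assigner and the substrate
#' of all distance computations. Sequences are stored upper-case with U
#' converted to T; accessions are unique.
#'
#' @slot sequences A [Biostrings::DNAStringSet] named by accession.
#' @slot taxonomy A [S4Vectors::DataFrame] with columns `accession`,
#'   `species`, `genus`, `family`, `order`, parallel to `sequences`.
#'
#' @seealso [readReferenceFasta()], [dbStats()], [subsetBySpecies()],
#'   [curateDb()]
#' @export
setClass("ReferenceDB",
  representation(sequences = "DNAStringSet", taxonomy = "DataFrame"))

setValidity("ReferenceDB", function(object) {
  tax <- object@taxonomy
  msg <- character()
  need <- c("accession", "species", "genus", "family", "order")
  if (!all(need %in% colnames(tax)))
    return(paste("taxonomy must have columns:", paste(need, collapse = ", ")))
  if (length(object@sequences) != nrow(tax))
    msg <- c(msg, "sequences and taxonomy must be parallel")
  else if (length(object@sequences) > 0) {
    if (!identical(names(object@sequences), as.character(tax$accession)))
      msg <- c(msg, "sequence names must equal taxonomy accessions")
    if (anyDuplicated(tax$accession))
      msg <- c(msg, "accessions must be unique")
    if (any(!nzchar(tax$species)) || any(is.na(tax$species)))
      msg <- c(msg, "species labels must be non-empty")
    if (any(!nzchar(tax$genus)) || any(is.na(tax$genus)))
      msg <- c(msg, "genus labels must be non-empty")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ReferenceDB
#'
#' @param sequences A [Biostrings::DNAStringSet] (or character vector) named
#'   by accession.
#' @param taxonomy A data.frame or DataFrame with columns `accession`,
#'   `species`, `genus`, `family`, `order`; `family`/`order` may be
#'   `"unknown"`.
#' @return A [ReferenceDB-class] object.
#' @examples
#' db <- ReferenceDB(
#'   Biostrings::DNAStringSet(c(a1 = "ACGTACGT", a2 = "ACGTACGA")),
#'   data.frame(accession = c("a1", "a2"),
#'              species = c("Genus_one", "Genus_two"),
#'              genus = "Genus", family = "Fam", order = "Ord"))
#' dbStats(db)
#' @export
ReferenceDB <- function(sequences, taxonomy) {
  if (is.character(sequences))
    sequences <- Biostrings::DNAStringSet(sequences)
  taxonomy <- S4Vectors::DataFrame(lapply(taxonomy, as.character))
  rownames(taxonomy) <- NULL
  new("ReferenceDB", sequences = sequences, taxonomy = taxonomy)
}

#' @describeIn ReferenceDB Number of records.
#' @param x A `ReferenceDB`.
#' @export
setMethod("length", "ReferenceDB", function(x) length(x@sequences))

#' Accessors for ReferenceDB
#'
#' `refSequences` returns the barcode sequences, `refTaxonomy` the taxonomy
#' table, `refAccessions` the accession keys and `refSpecies` the distinct
#' species labels (in order of first appearance).
#'
#' @param x A [ReferenceDB-class].
#' @return `refSequences`: a `DNAStringSet`; `refTaxonomy`: a `DataFrame`;
#'   `refAccessions`, `refSpecies`: character vectors.
#' @export
refSequences <- function(x) x@sequences

#' @rdname refSequences
#' @export
refTaxonomy <- function(x) x@taxonomy

#' @rdname refSequences
#' @export
refAccessions <- function(x) as.character(x@taxonomy$accession)

#' @rdname refSequences
#' @export
refSpecies <- function(x) unique(as.character(x@taxonomy$species))

#' @describeIn ReferenceDB Subset records by index, logical or accession.
#' @param i Index vector.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "ReferenceDB", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, refAccessions(x))
  if (anyNA(i)) stop("unknown accession in subset")
  new("ReferenceDB", sequences = x@sequences[i], taxonomy = x@taxonomy[i, ])
})

setMethod("show", "ReferenceDB", function(object) {
  st <- dbStats(object)
  cat("ReferenceDB with", st$n_sequences, "sequences |",
      st$n_species, "species (", st$n_named_species, "named ) |",
      st$n_genera, "genera\n")
  if (length(object) > 0) {
    w <- Biostrings::width(object@sequences)
    cat("  sequence length:", min(w), "-", max(w), "bp\n")
  }
})

#' Per-library species read-count profile
#'
#' A `CommunityProfile` holds the species-rank read counts of one library
#' and derives relative frequencies by normalising over the total number of
#' species-rank reads. A profile whose counts are all zero is "empty":
#' frequencies are then undefined (`NaN`).
#'
#' @slot counts Named numeric vector of read counts (one entry per species).
#' @seealso [profileFromAssignments()], [applyThreshold()],
#'   [compareProfiles()]
#' @export
setClass("CommunityProfile", representation(counts = "numeric"))

setValidity("CommunityProfile", function(object) {
  cts <- object@counts
  if (length(cts) && (is.null(names(cts)) || any(!nzchar(names(cts)))))
    return("counts must be named by species")
  if (anyDuplicated(names(cts))) return("species names must be unique")
  if (any(is.na(cts)) || any(cts < 0)) return("counts must be non-negative")
  TRUE
})

#' @rdname CommunityProfile-class
#' @param counts Named numeric vector of species read counts.
#' @return A `CommunityProfile`.
#' @examples
#' p <- CommunityProfile(c(A = 60, B = 40))
#' profileFrequencies(p)
#' @export
CommunityProfile <- function(counts = numeric()) {
  new("CommunityProfile", counts = counts)
}

#' Accessors for CommunityProfile
#'
#' @param x A [CommunityProfile-class].
#' @return `profileCounts`: named counts; `profileFrequencies`: counts
#'   normalised to sum to one (NaN when the profile is empty);
#'   `nAssigned`: total species-rank reads; `isEmptyProfile`: logical.
#' @export
profileCounts <- function(x) x@counts

#' @rdname profileCounts
#' @export
profileFrequencies <- function(x) {
  tot <- sum(x@counts)
  if (tot == 0) {
    f <- rep(NaN, length(x@counts))
    names(f) <- names(x@counts)
    f
  } else x@counts / tot
}

#' @rdname profileCounts
#' @export
nAssigned <- function(x) sum(x@counts)

#' @rdname profileCounts
#' @export
isEmptyProfile <- function(x) sum(x@counts) == 0

setMethod("show", "CommunityProfile", function(object) {
  cat("CommunityProfile:", length(object@counts), "species,",
      sum(object@counts), "species-rank reads\n")
  if (length(object@counts)) {
    f <- sort(profileFrequencies(object), decreasing = TRUE)
    top <- utils::head(f, 5)
    cat(paste0("  ", names(top), ": ", signif(top, 3), collapse = "\n"), "\n")
  }
})

#' Mock community with known composition
#'
#' A `MockCommunity` pairs a relative-abundance vector (summing to one) with
#' the reference records of its member species. It is the ground truth for
#' simulated capture libraries, emulating pools of individually identified
#' DNAs mixed in known proportions.
#'
#' @slot db A [ReferenceDB-class] restricted to the member species.
#' @slot abundance Named numeric vector of relative abundances (> 0,
#'   summing to 1).
#' @seealso [mockCommunity()], [simulateCommunityReads()]
#' @export
setClass("MockCommunity",
  representation(db = "ReferenceDB", abundance = "numeric"))

setValidity("MockCommunity", function(object) {
  ab <- object@abundance
  if (length(ab) == 0) return("community must have at least one member")
  if (is.null(names(ab)) || any(!nzchar(names(ab))))
    return("abundances must be named by species")
  if (any(ab <= 0)) return("abundances must be positive")
  if (abs(sum(ab) - 1) > 1e-9) return("abundances must sum to 1")
  sp <- refSpecies(object@db)
  if (!all(names(ab) %in% sp))
    return("every member species needs at least one reference sequence")
  TRUE
})

#' Construct a MockCommunity
#'
#' @param db A [ReferenceDB-class] containing (at least) the member species.
#' @param abundance Named numeric vector of relative abundances; it is
#'   renormalised to sum to 1.
#' @return A [MockCommunity-class].
#' @export
mockCommunity <- function(db, abundance) {
  abundance <- abundance / sum(abundance)
  keep <- refTaxonomy(db)$species %in% names(abundance)
  new("MockCommunity", db = db[which(keep)], abundance = abundance)
}

#' @rdname mockCommunity
#' @param x A `MockCommunity`.
#' @export
communityAbundance <- function(x) x@abundance

#' @rdname mockCommunity
#' @export
communityDb <- function(x) x@db

setMethod("show", "MockCommunity", function(object) {
  cat("MockCommunity with", length(object@abundance), "species\n")
})
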