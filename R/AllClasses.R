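#' @import methods
NULL

BARCODE_ALPHABET <- c("A", "C", "G", "T", "N", "-", "?")

#' LocusAlignment: one aligned barcode locus
#'
#' An aligned set of sequences for a single barcode locus, stored as a
#' character matrix with one row per specimen and one column per alignment
#' position. The alphabet is restricted to \code{A,C,G,T,N,-,?} (uppercase):
#' \code{-} is an alignment gap (an inferred indel), \code{?} marks a
#' missing/unsampled stretch (used to pad specimens that lack a locus in a
#' supermatrix), and \code{N} is an ambiguous base call. For distance
#' computation all three are treated as non-determinate and removed pairwise;
#' on input/output they are preserved distinctly.
#'
#' @slot locus Single locus name, e.g. \code{"rbcL"}.
#' @slot seqs Character matrix of single uppercase characters; rownames are
#'   specimen ids (unique within the alignment).
#'
#' @seealso [readLocusAlignment()], [alignmentFromStrings()]
#' @export
setClass("LocusAlignment", representation(locus = "character", seqs = "matrix"))

setValidity("LocusAlignment", function(object) {
  if (length(object@locus) != 1L || !nzchar(object@locus))
    return("'locus' must be a single non-empty string")
  m <- object@seqs
  if (!is.character(m) || nrow(m) < 1L || ncol(m) < 1L)
    return("'seqs' must be a non-empty character matrix")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    return("specimen ids (rownames) must be present and unique")
  bad <- setdiff(unique(as.vector(m)), BARCODE_ALPHABET)
  if (length(bad))
    return(sprintf("illegal characters in alignment: %s",
                   paste(sQuote(bad), collapse = ", ")))
  TRUE
})

#' BarcodeDataset: specimens plus per-locus alignments
#'
#' The central container of the package: a table of specimens with their a
#' priori taxonomic assignments, and one [LocusAlignment] per sequenced
#' locus. A specimen may lack any given locus (sequence recovery below 100%
#' is the rule, not the exception, for plant barcodes); every specimen id
#' appearing in an alignment must exist in the specimen table.
#'
#' @slot specimens data.frame with columns \code{specimen_id},
#'   \code{species}, \code{genus} and optionally \code{note}.
#' @slot alignments Named list of [LocusAlignment] objects (names = loci).
#'
#' @seealso [barcodeDataset()], [simulateDataset()], [recoveryReport()]
#' @export
setClass("BarcodeDataset",
         representation(specimens = "data.frame", alignments = "list"))

setValidity("BarcodeDataset", function(object) {
  sp <- object@specimens
  need <- c("specimen_id", "species", "genus")
  if (!all(need %in% names(sp)))
    return(sprintf("specimen table must have columns %s",
                   paste(need, collapse = ", ")))
  if (anyDuplicated(sp$specimen_id))
    return("duplicate specimen_id in specimen table")
  bin <- grepl("^\\S+\\s+\\S", sp$species)
  tok <- sub("\\s.*$", "", sp$species)
  bad <- bin & tok != sp$genus
  if (any(bad))
    return(sprintf("genus/species mismatch for %s (genus must equal the generic epithet)",
                   paste(sQuote(sp$specimen_id[bad]), collapse = ", ")))
  if (length(object@alignments)) {
    if (is.null(names(object@alignments)) || anyDuplicated(names(object@alignments)))
      return("alignments must be uniquely named by locus")
    for (nm in names(object@alignments)) {
      a <- object@alignments[[nm]]
      if (!is(a, "LocusAlignment"))
        return("alignments must be LocusAlignment objects")
      if (!identical(a@locus, nm))
        return(sprintf("alignment name %s disagrees with its locus slot %s",
                       sQuote(nm), sQuote(a@locus)))
      orphan <- setdiff(rownames(a@seqs), sp$specimen_id)
      if (length(orphan))
        return(sprintf("alignment %s contains specimens absent from metadata: %s",
                       sQuote(nm), paste(sQuote(orphan), collapse = ", ")))
    }
  }
  TRUE
})

#' Supermatrix: concatenated multi-locus alignment
#'
#' Column-wise concatenation of several locus alignments over the union of
#' their specimens. Missing loci are padded with \code{?}. Partitions are
#' recorded as 0-based half-open column intervals in input-locus order;
#' they are disjoint, contiguous and cover all sequence columns. An optional
#' indel block (see [simpleIndelCoding()]) holds binary gap characters; it is
#' export-only and never enters distance computation.
#'
#' @slot alignment A [LocusAlignment] with locus \code{"concat"}.
#' @slot partitions Named list, locus -> integer c(start, end), 0-based
#'   half-open.
#' @slot indels Character matrix of \code{"0"}, \code{"1"}, \code{"?"} (one
#'   column per coded gap), or a 0-column matrix when no indel block was
#'   attached.
#'
#' @seealso [concatenateLoci()], [extractLocus()], [writeSupermatrix()]
#' @export
setClass("Supermatrix",
         representation(alignment = "LocusAlignment", partitions = "list",
                        indels = "matrix"))

setValidity("Supermatrix", function(object) {
  p <- object@partitions
  if (!length(p) || is.null(names(p))) return("partitions must be a named list")
  b <- do.call(rbind, p)
  if (any(b[, 1] >= b[, 2])) return("empty partition interval")
  if (b[1, 1] != 0L) return("partitions must start at column 0")
  if (nrow(b) > 1L && any(b[-1, 1] != b[-nrow(b), 2]))
    return("partitions must be contiguous and in order")
  if (b[nrow(b), 2] != ncol(object@alignment@seqs))
    return("partitions must cover all sequence columns")
  TRUE
})

#' SyntheticTruth: generator truth registry
#'
#' True species labels and the registry of planted label swaps emitted by
#' [simulateDataset()]. This is the oracle against which the
#' misidentification-flagging workflow is validated: a perfect run flags
#' exactly the swapped specimens and proposes their true species.
#'
#' @slot trueSpecies Named character vector, specimen id -> true species.
#' @slot swaps data.frame with columns \code{specimen_id}, \code{original}
#'   (true species) and \code{assigned} (the wrong label it was given).
#'
#' @export
setClass("SyntheticTruth",
         representation(trueSpecies = "character", swaps = "data.frame"))

setValidity("SyntheticTruth", function(object) {
  sw <- object@swaps
  if (!all(c("specimen_id", "original", "assigned") %in% names(sw)))
    return("swaps must have columns specimen_id, original, assigned")
  if (nrow(sw) && any(sw$original == sw$assigned))
    return("a planted swap must change the label")
  TRUE
})
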