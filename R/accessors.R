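#' Accessors for BarcodeEval classes
#'
#' Small generic accessors so downstream code never touches slots directly.
#'
#' @param x A [LocusAlignment], [BarcodeDataset] or [Supermatrix].
#' @return `locusName()` the locus string; `specimenIds()` the specimen ids;
#'   `alignmentWidth()` the number of alignment columns; `alignments()` the
#'   named list of [LocusAlignment]s; `lociNames()` the locus names;
#'   `specimenTable()` the specimen data.frame; `seqStrings()` a named
#'   character vector of whole-sequence strings; `partitions()` the named
#'   list of 0-based half-open column intervals; `indelBlock()` the coded
#'   indel matrix.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("locusName", function(x) standardGeneric("locusName"))
#' @rdname accessors
#' @export
setGeneric("specimenIds", function(x) standardGeneric("specimenIds"))
#' @rdname accessors
#' @export
setGeneric("alignmentWidth", function(x) standardGeneric("alignmentWidth"))
#' @rdname accessors
#' @export
setGeneric("alignments", function(x) standardGeneric("alignments"))
#' @rdname accessors
#' @export
setGeneric("lociNames", function(x) standardGeneric("lociNames"))
#' @rdname accessors
#' @export
setGeneric("specimenTable", function(x) standardGeneric("specimenTable"))
#' @rdname accessors
#' @export
setGeneric("seqStrings", function(x) standardGeneric("seqStrings"))
#' @rdname accessors
#' @export
setGeneric("partitions", function(x) standardGeneric("partitions"))
#' @rdname accessors
#' @export
setGeneric("indelBlock", function(x) standardGeneric("indelBlock"))

#' @rdname accessors
setMethod("locusName", "LocusAlignment", function(x) x@locus)
#' @rdname accessors
setMethod("specimenIds", "LocusAlignment", function(x) rownames(x@seqs))
#' @rdname accessors
setMethod("alignmentWidth", "LocusAlignment", function(x) ncol(x@seqs))
#' @rdname accessors
setMethod("seqStrings", "LocusAlignment", function(x) {
  out <- apply(x@seqs, 1L, paste, collapse = "")
  names(out) <- rownames(x@seqs)
  out
})

#' @rdname accessors
setMethod("specimenIds", "BarcodeDataset", function(x) x@specimens$specimen_id)
#' @rdname accessors
setMethod("alignments", "BarcodeDataset", function(x) x@alignments)
#' @rdname accessors
setMethod("lociNames", "BarcodeDataset", function(x) names(x@alignments))
#' @rdname accessors
setMethod("specimenTable", "BarcodeDataset", function(x) x@specimens)

#' @rdname accessors
setMethod("specimenIds", "Supermatrix", function(x) rownames(x@alignment@seqs))
#' @rdname accessors
setMethod("alignmentWidth", "Supermatrix", function(x) ncol(x@alignment@seqs))
#' @rdname accessors
setMethod("partitions", "Supermatrix", function(x) x@partitions)
#' @rdname accessors
setMethod("indelBlock", "Supermatrix", function(x) x@indels)
#' @rdname accessors
setMethod("lociNames", "Supermatrix", function(x) names(x@partitions))
#' @rdname accessors
setMethod("seqStrings", "Supermatrix", function(x) seqStrings(x@alignment))

#' @export
#' @rdname accessors
#' @param ... unused.
as.matrix.LocusAlignment <- function(x, ...) x@seqs

setMethod("show", "LocusAlignment", function(object) {
  cat(sprintf("LocusAlignment '%s': %d specimens x %d columns\n",
              object@locus, nrow(object@seqs), ncol(object@seqs)))
})

setMethod("show", "BarcodeDataset", function(object) {
  sp <- object@specimens
  cat(sprintf("BarcodeDataset: %d specimens, %d species, %d genera\n",
              nrow(sp), length(unique(sp$species)), length(unique(sp$genus))))
  for (nm in names(object@alignments)) {
    a <- object@alignments[[nm]]
    cat(sprintf("  %-12s %4d seqs, %4d bp\n", nm, nrow(a@seqs), ncol(a@seqs)))
  }
})

setMethod("show", "Supermatrix", function(object) {
  cat(sprintf("Supermatrix: %d specimens x %d columns, %d partitions, %d indel characters\n",
              nrow(object@alignment@seqs), ncol(object@alignment@seqs),
              length(object@partitions), ncol(object@indels)))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d specimens, %d planted label swaps\n",
              length(object@trueSpecies), nrow(object@swaps)))
})

#' Construct a LocusAlignment from whole-sequence strings
#'
#' @param seqs Named character vector of equal-length aligned sequences.
#' @param locus Locus name.
#' @return A [LocusAlignment].
#' @examples
#' alignmentFromStrings(c(s1 = "ACGT-", s2 = "ACGTA"), "rbcL")
#' @export
alignmentFromStrings <- function(seqs, locus) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must be uniquely named by specimen id")
  w <- nchar(seqs)
  if (length(unique(w)) != 1L)
    stop(sprintf("alignment shape error for locus '%s': sequence lengths differ (%s)",
                 locus, paste(sort(unique(w)), collapse = ", ")))
  m <- matrix(unlist(strsplit(toupper(seqs), "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), byrow = TRUE,
              dimnames = list(names(seqs), NULL))
  new("LocusAlignment", locus = locus, seqs = m)
}

#' Assemble a BarcodeDataset
#'
#' @param specimens data.frame with columns \code{specimen_id},
#'   \code{species}, \code{genus} (see [readSpecimenTable()]).
#' @param alignments List of [LocusAlignment] objects; names default to each
#'   alignment's locus.
#' @return A validated [BarcodeDataset].
#' @export
barcodeDataset <- function(specimens, alignments = list()) {
  if (length(alignments) && is.null(names(alignments)))
    names(alignments) <- vapply(alignments, locusName, "")
  specimens$specimen_id <- as.character(specimens$specimen_id)
  specimens$species <- as.character(specimens$species)
  specimens$genus <- as.character(specimens$genus)
  new("BarcodeDataset", specimens = specimens, alignments = alignments)
}
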