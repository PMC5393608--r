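#' Similarity scoring configuration
#'
#' Scoring used to rank database hits, standing in for a local blastn
#' search: Smith-Waterman local alignment of gap-stripped sequences with
#' blastn-like parameters (match +1, mismatch -2, gap open 2.5, gap extend
#' 2.5). Scores only rank hits; no E-values are computed. `band` restricts
#' the dynamic programme to a diagonal band (widened automatically by the
#' length difference of the pair), the same kind of heuristic BLAST itself
#' applies; set `band = 0` for the exact full alignment.
#'
#' @param match,mismatch,gapOpen,gapExtend Alignment scores/penalties.
#' @param band Half-width of the DP band; 0 disables banding.
#' @return A list of scoring parameters.
#' @export
similarityScoring <- function(match = 1, mismatch = -2, gapOpen = 2.5,
                              gapExtend = 2.5, band = 64L) {
  list(match = match, mismatch = mismatch, gapOpen = gapOpen,
       gapExtend = gapExtend, band = as.integer(band))
}

# Gap-stripped (unaligned) sequence of each specimen over a marker set:
# per-locus blocks concatenated, '-' and '?' removed. Specimens with no
# sequenced locus in the set are omitted.
.strippedSeqs <- function(dataset, markerSet) {
  alns <- alignments(dataset)
  miss <- setdiff(markerSet, names(alns))
  if (length(miss))
    stop(sprintf("marker set refers to loci absent from dataset: %s",
                 paste(sQuote(miss), collapse = ", ")))
  ids <- specimenIds(dataset)
  pieces <- lapply(markerSet, function(nm) {
    s <- seqStrings(alns[[nm]])
    s <- gsub("[-?]", "", s)
    out <- stats::setNames(rep("", length(ids)), ids)
    out[names(s)] <- s
    out
  })
  combined <- do.call(paste0, pieces)
  names(combined) <- ids
  combined[nzchar(combined)]
}

# Full symmetric local-alignment score matrix for a marker set.
.scoreMatrix <- function(dataset, markerSet, scoring = similarityScoring()) {
  seqs <- .strippedSeqs(dataset, markerSet)
  if (length(seqs) < 2L)
    stop("need at least 2 specimens with sequence for this marker set")
  sc <- .sw_score_all(unname(seqs), scoring$match, scoring$mismatch,
                      scoring$gapOpen, scoring$gapExtend, scoring$band)
  dimnames(sc) <- list(names(seqs), names(seqs))
  sc
}

# Hit list for one query given a precomputed score matrix and the species
# map. Self-exclusion follows the reference-database rule: the query itself
# is excluded from the candidate list only when its species has >= 2
# sequenced individuals for this marker set; a singleton species keeps its
# own perfect self-hit.
.hitsFromScores <- function(query, scores, speciesOf) {
  ids <- rownames(scores)
  conspecifics <- ids[speciesOf[ids] == speciesOf[[query]]]
  cand <- if (length(conspecifics) >= 2L) setdiff(ids, query) else ids
  s <- scores[query, cand]
  ord <- order(-s, cand)
  hits <- data.frame(subject = cand[ord], score = unname(s[ord]),
                     stringsAsFactors = FALSE)
  top <- hits$subject[hits$score == hits$score[1L]]
  structure(list(query = query, hits = hits, top = top), class = "barcode_hits")
}

#' @export
print.barcode_hits <- function(x, ...) {
  cat(sprintf("Best hits for '%s' (top set: %s)\n", x$query,
              paste(x$top, collapse = ", ")))
  print(utils::head(x$hits, 5L))
  invisible(x)
}

#' Best database hits for a query specimen
#'
#' Scores the query against every other reference sequence for the marker
#' set (local alignment, see [similarityScoring()]) and returns the hits
#' sorted by score (ties broken by specimen id). The `top` element holds
#' every subject sharing the maximal score -- the "top matching hit" set of
#' the similarity-based success criterion.
#'
#' @param query Specimen id (must carry at least one locus of the set).
#' @param dataset A [BarcodeDataset].
#' @param markerSet Character vector of locus names.
#' @param scoring See [similarityScoring()].
#' @return An object of class `barcode_hits`: list with `query`, `hits`
#'   (data.frame subject/score) and `top`.
#' @export
bestHits <- function(query, dataset, markerSet = lociNames(dataset),
                     scoring = similarityScoring()) {
  scores <- .scoreMatrix(dataset, markerSet, scoring)
  if (!query %in% rownames(scores))
    stop(sprintf("query %s has no sequence for marker set %s",
                 sQuote(query), paste(markerSet, collapse = "+")))
  sp <- specimenTable(dataset)
  speciesOf <- stats::setNames(sp$species, sp$specimen_id)
  .hitsFromScores(query, scores, speciesOf)
}
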