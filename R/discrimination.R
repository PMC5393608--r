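.markerLabel <- function(markerSet) paste(markerSet, collapse = "+")

.taxonOf <- function(dataset, level = c("species", "genus")) {
  level <- match.arg(level)
  sp <- specimenTable(dataset)
  stats::setNames(if (level == "species") sp$species else sp$genus,
                  sp$specimen_id)
}

.record <- function(taxon, level, method, markerSet, cohort, success, reason) {
  data.frame(taxon = taxon, level = level, method = method,
             marker_set = .markerLabel(markerSet), cohort = cohort,
             success = success, reason = reason, stringsAsFactors = FALSE)
}

#' Similarity-based discrimination per taxon
#'
#' The best-hit success criterion: a species (or genus) succeeds for a
#' marker set when \emph{every} one of its sequenced individuals has a top
#' hit set consisting entirely of conspecific (congeneric) individuals.
#' Ties at the top score are strict: a single heterospecific member of the
#' top set fails the taxon. The query itself is excluded from the reference
#' when its species has two or more sequenced individuals; a singleton
#' species therefore hits itself and succeeds vacuously at species level
#' (set `vacuousSingletons = FALSE` to score singletons as failures instead
#' -- the treatment of these vacuous self-hits is a reporting choice, not
#' part of the criterion). Cohort `"n2"` restricts the evaluated taxa to
#' those with at least two individuals carrying the marker set.
#'
#' @param dataset A [BarcodeDataset].
#' @param markerSet Character vector of locus names.
#' @param level `"species"` or `"genus"`.
#' @param cohort `"n1"` (all sequenced taxa) or `"n2"`.
#' @param scoring See [similarityScoring()].
#' @param vacuousSingletons Count self-hitting singleton species as
#'   successes in the `"n1"` cohort (default `TRUE`).
#' @param scores Optional precomputed score matrix (internal reuse).
#' @return data.frame of discrimination records (one row per evaluated
#'   taxon) with columns `taxon`, `level`, `method`, `marker_set`, `cohort`,
#'   `success`, `reason`, plus a `"dropped"` attribute naming taxa with no
#'   sequence for the marker set.
#' @export
similaritySuccess <- function(dataset, markerSet = lociNames(dataset),
                              level = c("species", "genus"),
                              cohort = c("n1", "n2"),
                              scoring = similarityScoring(),
                              vacuousSingletons = TRUE,
                              scores = NULL) {
  level <- match.arg(level)
  cohort <- match.arg(cohort)
  if (is.null(scores)) scores <- .scoreMatrix(dataset, markerSet, scoring)
  ids <- rownames(scores)
  sp <- specimenTable(dataset)
  speciesOf <- stats::setNames(sp$species, sp$specimen_id)
  taxonOf <- .taxonOf(dataset, level)
  counts <- table(taxonOf[ids])
  taxa <- sort(names(counts))
  if (cohort == "n2") taxa <- taxa[counts[taxa] >= 2L]
  dropped <- setdiff(unique(taxonOf), names(counts))
  recs <- lapply(taxa, function(tx) {
    members <- ids[taxonOf[ids] == tx]
    if (length(members) == 1L) {
      spc <- speciesOf[[members]]
      selfRetained <- sum(speciesOf[ids] == spc) < 2L
      if (selfRetained && !vacuousSingletons)
        return(.record(tx, level, "similarity", markerSet, cohort, FALSE,
                       "singleton self-hit not counted"))
    }
    for (q in members) {
      top <- .hitsFromScores(q, scores, speciesOf)$top
      ok <- taxonOf[top] == tx
      if (!all(ok))
        return(.record(tx, level, "similarity", markerSet, cohort, FALSE,
                       sprintf("%s top hit includes %s (%s)", q,
                               top[!ok][1L], taxonOf[[top[!ok][1L]]])))
    }
    .record(tx, level, "similarity", markerSet, cohort, TRUE, "")
  })
  out <- do.call(rbind, recs)
  if (is.null(out)) out <- .record(character(0), character(0), character(0),
                                   character(0), character(0), logical(0),
                                   character(0))
  attr(out, "dropped") <- dropped
  out
}

#' Tree-based discrimination per taxon
#'
#' The monophyly success criterion: a taxon succeeds when all of its
#' individuals present in the tree form a single clade with bootstrap
#' support strictly above `threshold` (see [hasSupportedMonophyly()]).
#' Taxa represented by fewer than two leaves cannot be tested for monophyly
#' and are excluded (this is why tree-based analyses are inherently
#' "n >= 2"); the genus criterion mirrors the species criterion one rank
#' up.
#'
#' @param tree A support-annotated `phylo` from [bootstrapSupport()], whose
#'   leaves are specimen ids of `dataset`.
#' @param dataset A [BarcodeDataset].
#' @param level `"species"` or `"genus"`.
#' @param threshold Bootstrap support threshold (strict comparison).
#' @param markerSet Locus names, recorded in the output only.
#' @param cohort Cohort label recorded in the output.
#' @return data.frame of discrimination records, with attribute
#'   `"dropped"` naming excluded singletons and taxa absent from the tree.
#' @export
treeSuccess <- function(tree, dataset, level = c("species", "genus"),
                        threshold = 50, markerSet = lociNames(dataset),
                        cohort = "n2") {
  level <- match.arg(level)
  taxonOf <- .taxonOf(dataset, level)
  inTree <- intersect(names(taxonOf), tree$tip.label)
  counts <- table(taxonOf[inTree])
  taxa <- sort(names(counts)[counts >= 2L])
  dropped <- setdiff(unique(taxonOf), taxa)
  recs <- lapply(taxa, function(tx) {
    members <- inTree[taxonOf[inTree] == tx]
    ok <- hasSupportedMonophyly(tree, members, threshold)
    .record(tx, level, "tree", markerSet, cohort, ok,
            if (ok) "" else "not a supported clade")
  })
  out <- do.call(rbind, recs)
  if (is.null(out)) out <- .record(character(0), character(0), character(0),
                                   character(0), character(0), logical(0),
                                   character(0))
  attr(out, "dropped") <- dropped
  out
}

#' Discrimination rate from a set of records
#'
#' @param records data.frame of discrimination records sharing one
#'   level/method/marker set/cohort combination.
#' @return List with `rate` (successes/total), `successes`, `total`.
#' @examples
#' r <- data.frame(success = c(TRUE, TRUE, FALSE, TRUE))
#' discriminationRate(r)$rate  # 0.75
#' @export
discriminationRate <- function(records) {
  if (!nrow(records)) stop("no records: rate undefined")
  list(rate = mean(records$success), successes = sum(records$success),
       total = nrow(records))
}
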