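# Placement audit: which specimens does the molecular evidence place
# outside their a priori species?
#
# Per marker set the evidence is a bootstrap-annotated NJ tree plus the
# best-hit lists. For one specimen s with labeled conspecific set S
# (assigned species, >= 2 members including s):
#
#   1. If S is supported-monophyletic, everyone in it is exonerated.
#   2. Otherwise locate the species' *core*: the union of the largest
#      supported clades wholly contained in S (singletons count as size-1
#      clades). A coherent core (size >= 2) represents where the species
#      "really is" on the tree; members of the core are exonerated, and so
#      is any specimen whose top hits or smallest supported clade
#      neighbourhood reach a core member. A specimen outside all of that is
#      a violation, with the neighbourhood's majority species as the
#      proposed identity.
#   3. If no coherent core exists (the labeled species is scattered), a
#      specimen is only flagged when its neighbourhood is label-unanimous
#      for a single other species and contains no labeled conspecific --
#      the conservative reading of "nested within another species".
#
# A specimen is flagged when at least `quorum` marker-set analyses agree on
# a violation; the proposed species is the majority proposal across the
# agreeing marker sets (ties broken by best-hit score, then name). This is
# the operational form of the reciprocal-illumination loop: flags are an
# audit report for morphological re-examination, never an automatic
# relabeling.

# Smallest supported bipartition side containing `id` with >= 2 other
# leaves; character(0) when none exists.
.cladeNeighbors <- function(sides, id, threshold) {
  best <- NULL
  for (s in sides) {
    if (is.na(s$support) || s$support <= threshold) next
    if (!(id %in% s$side) || length(s$side) < 3L) next
    if (is.null(best) || length(s$side) < length(best)) best <- s$side
  }
  if (is.null(best)) character(0) else setdiff(best, id)
}

# Union of maximum-size supported clades wholly contained in `members`;
# returns list(core = ids, maxSize = k). Singleton leaves are size-1 clades.
.speciesCore <- function(sides, members, threshold) {
  cands <- list()
  for (s in sides) {
    if (is.na(s$support) || s$support <= threshold) next
    if (all(s$side %in% members)) cands[[length(cands) + 1L]] <- s$side
  }
  sizes <- if (length(cands)) lengths(cands) else integer(0)
  maxSize <- max(1L, sizes)
  if (maxSize == 1L) return(list(core = members, maxSize = 1L))
  core <- unique(unlist(cands[sizes == maxSize], use.names = FALSE))
  list(core = core, maxSize = maxSize)
}

.majority <- function(labels) {
  if (!length(labels)) return(NA_character_)
  tab <- sort(table(labels), decreasing = TRUE)
  top <- names(tab)[tab == tab[1L]]
  if (length(top) > 1L) NA_character_ else top
}

# One marker set's violations. Returns a data.frame:
# specimen_id, nearest_species, score, reason.
.auditMarkerSet <- function(dataset, markerSet, threshold, replicates, seed,
                            model, scoring) {
  sm <- concatenateLoci(dataset, loci = markerSet)
  tree <- bootstrapSupport(sm, model = model, replicates = replicates,
                           seed = seed)
  sides <- .treeSides(tree)
  scores <- .scoreMatrix(dataset, markerSet, scoring)
  ids <- intersect(tree$tip.label, rownames(scores))
  sp <- specimenTable(dataset)
  speciesOf <- stats::setNames(sp$species, sp$specimen_id)
  viol <- list()
  deferred <- list()
  for (spc in unique(speciesOf[ids])) {
    S <- ids[speciesOf[ids] == spc]
    if (length(S) < 2L) next
    if (hasSupportedMonophyly(tree, S, threshold)) next
    core <- .speciesCore(sides, S, threshold)
    for (s in S) {
      if (core$maxSize >= 2L && s %in% core$core) next
      hl <- .hitsFromScores(s, scores, speciesOf)
      nb <- .cladeNeighbors(sides, s, threshold)
      reach <- union(hl$top, nb)
      if (core$maxSize >= 2L) {
        if (any(core$core %in% reach)) next
        viol[[length(viol) + 1L]] <- list(
          id = s, hl = hl, nb = nb, S = S,
          reason = "outside the supported core of its assigned species")
      } else {
        if (any(S %in% reach)) next
        # scattered species: flag only a coherent foreign placement, i.e.
        # neighbourhood unanimous for one other species; deferred cases are
        # re-examined below once fellow violators are known, since a
        # mislabeled neighbour's label cannot break unanimity
        deferred[[length(deferred) + 1L]] <- list(
          id = s, hl = hl, nb = nb, S = S, spc = spc,
          reason = "assigned species scattered; nested in another species")
      }
    }
  }
  repeat {
    violIds <- vapply(viol, `[[`, "", "id")
    promoted <- FALSE
    keep <- logical(length(deferred))
    for (k in seq_along(deferred)) {
      v <- deferred[[k]]
      labs <- unique(speciesOf[setdiff(v$nb, c(v$S, violIds))])
      if (length(labs) == 1L && labs != v$spc) {
        viol[[length(viol) + 1L]] <- v[c("id", "hl", "nb", "S", "reason")]
        promoted <- TRUE
      } else keep[k] <- TRUE
    }
    deferred <- deferred[keep]
    if (!promoted || !length(deferred)) break
  }
  if (!length(viol))
    return(data.frame(specimen_id = character(0),
                      nearest_species = character(0), score = numeric(0),
                      reason = character(0), stringsAsFactors = FALSE))
  # Proposals in a second pass: a fellow violator is itself mislabeled, so
  # its label never informs a proposed identity.
  violIds <- vapply(viol, `[[`, "", "id")
  out <- lapply(viol, function(v) {
    others <- setdiff(violIds, v$id)
    pool <- setdiff(v$nb, c(v$S, others))
    prop <- .majority(speciesOf[pool])
    if (is.na(prop))
      prop <- .majority(speciesOf[setdiff(v$hl$top, c(v$S, others))])
    if (is.na(prop)) {
      topOk <- setdiff(v$hl$hits$subject, c(v$S, others))
      prop <- if (length(topOk)) speciesOf[[topOk[1L]]] else NA_character_
    }
    if (is.na(prop)) return(NULL)
    data.frame(specimen_id = v$id, nearest_species = unname(prop),
               score = v$hl$hits$score[1L], reason = v$reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}

#' Flag potentially misidentified specimens
#'
#' Cross-checks every specimen's a priori species label against its
#' molecular placement under several marker-set analyses (by default each
#' single locus plus the all-locus combination, mirroring the practice of
#' examining the core-barcode trees and the combined supermatrix tree) and
#' flags the specimens that at least `quorum` analyses place outside their
#' assigned species, together with a proposed identity. The output is an
#' audit report meant for morphological re-examination of the flagged
#' vouchers; nothing is relabeled automatically.
#'
#' @param dataset A [BarcodeDataset].
#' @param markerSets List of character vectors of locus names. Default:
#'   each single locus, plus the combination of all loci when there are at
#'   least two.
#' @param quorum Minimum number of marker-set analyses that must agree on a
#'   violation (default 2).
#' @param threshold Bootstrap support threshold for "supported" clades.
#' @param replicates Bootstrap replicates per marker-set tree.
#' @param seed Seed; marker set k uses `seed + k - 1`.
#' @param model Distance model for the NJ trees.
#' @param scoring Similarity scoring, see [similarityScoring()].
#' @return List with elements:
#'   \describe{
#'     \item{flags}{data.frame `specimen_id`, `assigned_species`,
#'       `proposed_species`, `n_markers_agreeing`.}
#'     \item{evidence}{data.frame of every per-marker-set violation
#'       (`marker_set`, `specimen_id`, `nearest_species`, `score`,
#'       `reason`), including sub-quorum ones.}
#'     \item{insufficient}{Specimen ids whose available marker sets number
#'       fewer than `quorum` (audited, never flagged).}
#'   }
#' @export
flagMisidentifications <- function(dataset,
                                   markerSets = NULL,
                                   quorum = 2L,
                                   threshold = 50,
                                   replicates = 1000L,
                                   seed = 1L,
                                   model = "k2p",
                                   scoring = similarityScoring()) {
  loci <- lociNames(dataset)
  if (is.null(markerSets)) {
    markerSets <- as.list(loci)
    if (length(loci) >= 2L) markerSets <- c(markerSets, list(loci))
  }
  evid <- list()
  for (k in seq_along(markerSets)) {
    ms <- markerSets[[k]]
    v <- .auditMarkerSet(dataset, ms, threshold, replicates,
                         seed + k - 1L, model, scoring)
    if (nrow(v)) v$marker_set <- .markerLabel(ms)
    evid[[k]] <- v
  }
  evid <- do.call(rbind, evid[vapply(evid, nrow, 1L) > 0])
  if (is.null(evid))
    evid <- data.frame(specimen_id = character(0),
                       nearest_species = character(0), score = numeric(0),
                       reason = character(0), marker_set = character(0),
                       stringsAsFactors = FALSE)
  # availability: marker sets for which the specimen has sequence
  sp <- specimenTable(dataset)
  avail <- vapply(sp$specimen_id, function(id) {
    sum(vapply(markerSets, function(ms)
      any(vapply(ms, function(l)
        id %in% specimenIds(alignments(dataset)[[l]]), TRUE)), TRUE))
  }, 1L)
  insufficient <- sp$specimen_id[avail < quorum]
  flags <- list()
  for (id in setdiff(unique(evid$specimen_id), insufficient)) {
    e <- evid[evid$specimen_id == id, , drop = FALSE]
    if (nrow(e) < quorum) next
    prop <- .majority(e$nearest_species)
    if (is.na(prop)) {
      e <- e[order(-e$score, e$nearest_species), , drop = FALSE]
      prop <- e$nearest_species[1L]
    }
    flags[[length(flags) + 1L]] <- data.frame(
      specimen_id = id,
      assigned_species = sp$species[sp$specimen_id == id],
      proposed_species = prop,
      n_markers_agreeing = nrow(e), stringsAsFactors = FALSE)
  }
  flags <- if (length(flags)) do.call(rbind, flags)
  else data.frame(specimen_id = character(0), assigned_species = character(0),
                  proposed_species = character(0),
                  n_markers_agreeing = integer(0), stringsAsFactors = FALSE)
  flags <- flags[order(flags$specimen_id), , drop = FALSE]
  rownames(flags) <- NULL
  list(flags = flags, evidence = evid, insufficient = insufficient)
}

#' Write flagged specimens as an original-vs-proposed table
#'
#' A two-column audit table (original determination, proposed
#' determination) plus the supporting columns, for the morphological
#' re-examination step.
#'
#' @param flags The `flags` element of [flagMisidentifications()]'s output.
#' @param path Output TSV path.
#' @export
writeFlagTable <- function(flags, path) {
  out <- data.frame(
    original = paste(flags$assigned_species, flags$specimen_id),
    proposed = paste(flags$proposed_species, flags$specimen_id),
    n_markers_agreeing = flags$n_markers_agreeing)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
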