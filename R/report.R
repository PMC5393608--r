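#' Percentage with half-up rounding to one decimal
#'
#' The arithmetic used throughout recovery and discrimination tables:
#' `100 * successes / sampled`, rounded half-up to one decimal place (so
#' 381/412 prints as 92.5). R's own `round()` rounds half to even, which
#' would disagree with the usual printed tables on exact halves.
#'
#' @param successes Non-negative integer count of successes.
#' @param sampled Positive integer total.
#' @return The percentage, one decimal.
#' @examples
#' computeRate(381, 412)  # 92.5
#' computeRate(44, 409)   # 10.8
#' @export
computeRate <- function(successes, sampled) {
  if (length(sampled) != 1L || sampled <= 0)
    stop("'sampled' must be a positive count")
  if (successes < 0 || successes > sampled)
    stop("'successes' must lie in [0, sampled]")
  floor(1000 * successes / sampled + 0.5) / 10
}

#' Sequence recovery report per locus
#'
#' For every locus: how many individuals carry a sequence, and how many
#' species and genera are represented by at least one sequenced individual,
#' with percentages relative to the sampled totals.
#'
#' @param dataset A [BarcodeDataset].
#' @return data.frame, one row per locus, with count and `_pct` columns for
#'   individuals, species and genera.
#' @export
recoveryReport <- function(dataset) {
  sp <- specimenTable(dataset)
  nInd <- nrow(sp)
  nSpecies <- length(unique(sp$species))
  nGenera <- length(unique(sp$genus))
  if (!length(lociNames(dataset))) stop("dataset has no loci")
  rows <- lapply(lociNames(dataset), function(nm) {
    ids <- specimenIds(alignments(dataset)[[nm]])
    have <- sp[sp$specimen_id %in% ids, , drop = FALSE]
    data.frame(locus = nm,
               individuals = nrow(have), sampled_individuals = nInd,
               individuals_pct = computeRate(nrow(have), nInd),
               species = length(unique(have$species)),
               sampled_species = nSpecies,
               species_pct = computeRate(length(unique(have$species)), nSpecies),
               genera = length(unique(have$genus)),
               sampled_genera = nGenera,
               genera_pct = computeRate(length(unique(have$genus)), nGenera),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full discrimination evaluation over marker sets
#'
#' For every requested marker set this builds the concatenated supermatrix,
#' the bootstrap-annotated NJ tree, and the local-alignment hit lists, then
#' scores both success criteria at both taxonomic levels and both cohorts,
#' returning the rates table alongside the per-taxon records and the trees.
#' Everything is deterministic given the dataset, the configuration and the
#' seed. Dropped taxa (no sequence for a marker set, singleton exclusions)
#' are collected in a structured log, never silently discarded.
#'
#' @param dataset A [BarcodeDataset].
#' @param markerSets List of locus-name vectors. Default: each single locus,
#'   then cumulative combinations in dataset locus order (L1+L2, L1+L2+L3,
#'   ...), the usual way barcoding studies report combinations.
#' @param levels,cohorts Which taxonomic levels and cohorts to evaluate.
#' @param model Distance model for NJ (see [distanceMatrix()]).
#' @param replicates Bootstrap replicates.
#' @param threshold Bootstrap support threshold for the monophyly criterion.
#' @param seed Seed; marker set k uses `seed + k - 1`.
#' @param scoring Similarity scoring, see [similarityScoring()].
#' @return List with `rates` (data.frame: marker_set, method, level, cohort,
#'   successes, total, rate_pct), `records` (all per-taxon records),
#'   `trees` (named list of support trees) and `log` (data.frame of dropped
#'   taxa with reasons).
#' @export
evaluateDataset <- function(dataset,
                            markerSets = NULL,
                            levels = c("species", "genus"),
                            cohorts = c("n1", "n2"),
                            model = "k2p",
                            replicates = 1000L,
                            threshold = 50,
                            seed = 1L,
                            scoring = similarityScoring()) {
  loci <- lociNames(dataset)
  if (is.null(markerSets)) {
    markerSets <- as.list(loci)
    if (length(loci) >= 2L)
      markerSets <- c(markerSets,
                      lapply(2:length(loci), function(k) loci[1:k]))
  }
  rates <- list(); records <- list(); trees <- list(); logs <- list()
  for (k in seq_along(markerSets)) {
    ms <- markerSets[[k]]
    lab <- .markerLabel(ms)
    sm <- concatenateLoci(dataset, loci = ms)
    tree <- bootstrapSupport(sm, model = model, replicates = replicates,
                             seed = seed + k - 1L)
    trees[[lab]] <- tree
    scores <- .scoreMatrix(dataset, ms, scoring)
    for (lv in levels) {
      for (co in cohorts) {
        recS <- similaritySuccess(dataset, ms, level = lv, cohort = co,
                                  scoring = scoring, scores = scores)
        rs <- discriminationRate(recS)
        rates[[length(rates) + 1L]] <- data.frame(
          marker_set = lab, method = "similarity", level = lv, cohort = co,
          successes = rs$successes, total = rs$total,
          rate_pct = computeRate(rs$successes, rs$total))
        records[[length(records) + 1L]] <- recS
        if (length(attr(recS, "dropped")))
          logs[[length(logs) + 1L]] <- data.frame(
            marker_set = lab, method = "similarity", level = lv, cohort = co,
            taxon = attr(recS, "dropped"), reason = "no sequence for marker set")
      }
      recT <- treeSuccess(tree, dataset, level = lv, threshold = threshold,
                          markerSet = ms, cohort = "n2")
      rt <- discriminationRate(recT)
      rates[[length(rates) + 1L]] <- data.frame(
        marker_set = lab, method = "tree", level = lv, cohort = "n2",
        successes = rt$successes, total = rt$total,
        rate_pct = computeRate(rt$successes, rt$total))
      records[[length(records) + 1L]] <- recT
      if (length(attr(recT, "dropped")))
        logs[[length(logs) + 1L]] <- data.frame(
          marker_set = lab, method = "tree", level = lv, cohort = "n2",
          taxon = attr(recT, "dropped"),
          reason = "singleton or absent from tree")
    }
  }
  list(rates = do.call(rbind, rates),
       records = do.call(rbind, records),
       trees = trees,
       log = if (length(logs)) do.call(rbind, logs)
             else data.frame(marker_set = character(0), method = character(0),
                             level = character(0), cohort = character(0),
                             taxon = character(0), reason = character(0)))
}

#' Writers for evaluation outputs
#'
#' `writeRecords()` writes per-taxon discrimination records as TSV;
#' `writeRatesJson()` writes the rates table as JSON keyed by
#' marker set / method / level / cohort.
#'
#' @param records,rates Outputs of [evaluateDataset()].
#' @param path Output path.
#' @export
writeRecords <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeRecords
#' @export
writeRatesJson <- function(rates, path) {
  jsonlite::write_json(rates, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
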