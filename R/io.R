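#' Read an aligned FASTA file as a LocusAlignment
#'
#' Records may wrap over lines; lowercase is normalised to uppercase. The
#' specimen id is the header token up to the first whitespace (the common
#' voucher-coded FASTA convention); the remainder of the header is ignored.
#' Only \code{A,C,G,T,N,-,?} are accepted.
#'
#' @param path Path to an aligned FASTA file.
#' @param locus Locus name to attach, e.g. \code{"matK"}.
#' @return A [LocusAlignment].
#' @examples
#' fa <- system.file("extdata", "toy_rbcL.fasta", package = "BarcodeEval")
#' readLocusAlignment(fa, "rbcL")
#' @export
readLocusAlignment <- function(path, locus) {
  raw <- readLines(path, warn = FALSE)
  seqlines <- raw[!startsWith(trimws(raw), ">")]
  residues <- gsub("[ACGTNacgtn?[:space:]-]", "", seqlines)
  if (any(nzchar(residues)))
    stop(sprintf("illegal character(s) in '%s': %s", path,
                 paste(sQuote(unique(strsplit(paste(residues, collapse = ""),
                                              "")[[1]])), collapse = ", ")))
  x <- ape::read.FASTA(path)
  if (!length(x)) stop(sprintf("no FASTA records in '%s'", path))
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate specimen id(s) in '%s': %s", path,
                 paste(sQuote(unique(ids[duplicated(ids)])), collapse = ", ")))
  ch <- as.character(x)
  len <- lengths(ch)
  if (length(unique(len)) != 1L)
    stop(sprintf("alignment shape error in '%s': record lengths %s",
                 path, paste(sort(unique(len)), collapse = ", ")))
  m <- toupper(do.call(rbind, ch))
  rownames(m) <- ids
  new("LocusAlignment", locus = locus, seqs = m)
}

#' Write a LocusAlignment (or any named sequence set) as FASTA
#'
#' @param x A [LocusAlignment].
#' @param path Output file path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
writeLocusAlignment <- function(x, path, width = 70L) {
  seqs <- seqStrings(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read the specimen metadata table
#'
#' A tab-separated table with header columns \code{specimen_id},
#' \code{species} and \code{genus} (additional columns are kept; a
#' \code{note} column, if present, carries free-text collection notes).
#' Whitespace is trimmed. When a species name is a binomial the genus column
#' must equal its generic epithet.
#'
#' @param path Path to a TSV file.
#' @return data.frame of specimens, one row each.
#' @examples
#' tsv <- system.file("extdata", "toy_specimens.tsv", package = "BarcodeEval")
#' readSpecimenTable(tsv)
#' @export
readSpecimenTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("specimen_id", "species", "genus")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("metadata is missing required column(s): %s",
                 paste(miss, collapse = ", ")))
  for (nm in names(df))
    if (is.character(df[[nm]])) df[[nm]] <- trimws(df[[nm]])
  if (anyDuplicated(df$specimen_id))
    stop(sprintf("duplicate specimen_id in metadata: %s",
                 paste(sQuote(unique(df$specimen_id[duplicated(df$specimen_id)])),
                       collapse = ", ")))
  bin <- grepl("^\\S+\\s+\\S", df$species)
  tok <- sub("\\s.*$", "", df$species)
  bad <- bin & tok != df$genus
  if (any(bad))
    stop(sprintf("genus does not match the generic epithet for: %s",
                 paste(sQuote(df$specimen_id[bad]), collapse = ", ")))
  df
}

#' @rdname readSpecimenTable
#' @param df Specimen data.frame.
#' @export
writeSpecimenTable <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write support trees in Newick format
#'
#' Trees are `ape::phylo` objects; bootstrap supports (integers 0-100) live
#' in `node.label`, the convention understood by common tree viewers.
#' Writing then reading preserves the bipartition set, branch lengths and
#' supports.
#'
#' @param path Newick file path.
#' @return `readSupportTree()` a `phylo`; `writeSupportTree()` `path`,
#'   invisibly.
#' @export
readSupportTree <- function(path) {
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)),
                 error = function(e) stop(sprintf("malformed Newick in '%s': %s",
                                                  path, conditionMessage(e))))
  if (is.null(tr)) stop(sprintf("malformed Newick in '%s'", path))
  tr
}

#' @rdname readSupportTree
#' @param tree A `phylo` object (>= 2 leaves).
#' @export
writeSupportTree <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L) stop("tree must have at least 2 leaves")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a whole simulated dataset to disk
#'
#' Emits the same formats the readers consume: one aligned FASTA per locus,
#' a specimen TSV, and (when truth is given) a JSON truth registry.
#'
#' @param dataset A [BarcodeDataset].
#' @param dir Output directory (created if needed).
#' @param truth Optional [SyntheticTruth].
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(dataset, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeSpecimenTable(specimenTable(dataset), file.path(dir, "specimens.tsv"))
  for (nm in lociNames(dataset))
    writeLocusAlignment(alignments(dataset)[[nm]],
                        file.path(dir, paste0(nm, ".fasta")))
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(true_species = as.list(truth@trueSpecies),
           swaps = truth@swaps),
      file.path(dir, "truth.json"), auto_unbox = TRUE)
  }
  invisible(dir)
}

#' Read a dataset directory written by [writeDataset()]
#'
#' @param dir Directory containing \code{specimens.tsv} and one
#'   \code{<locus>.fasta} per locus.
#' @param loci Optional locus names; defaults to every \code{*.fasta} file.
#' @return A [BarcodeDataset].
#' @export
readDataset <- function(dir, loci = NULL) {
  sp <- readSpecimenTable(file.path(dir, "specimens.tsv"))
  if (is.null(loci)) {
    loci <- sub("\\.fasta$", "", list.files(dir, pattern = "\\.fasta$"))
  }
  aln <- lapply(loci, function(nm)
    readLocusAlignment(file.path(dir, paste0(nm, ".fasta")), nm))
  names(aln) <- loci
  barcodeDataset(sp, aln)
}
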