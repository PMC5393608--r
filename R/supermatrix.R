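#' Concatenate locus alignments into a supermatrix
#'
#' Builds the multi-locus supermatrix: one row per specimen appearing in at
#' least one of the chosen loci, columns stacked in input-locus order, and
#' \code{?} filling the block of every locus a specimen lacks (sequence
#' recovery below 100\% leaves such holes in any real barcode study).
#' Partition boundaries are recorded as 0-based half-open intervals.
#'
#' @param x A [BarcodeDataset] or a list of [LocusAlignment]s.
#' @param loci Locus names to include, in concatenation order. Defaults to
#'   all loci of `x`.
#' @param specimens Optional specimen ids fixing the row set and order;
#'   defaults to all specimens (in dataset order) with at least one chosen
#'   locus.
#' @param indels If `TRUE`, append a simple-indel-coded binary block
#'   computed per locus (see [simpleIndelCoding()]); the block is carried in
#'   the `indels` slot for export and never enters distance computation.
#' @return A [Supermatrix].
#' @examples
#' a <- alignmentFromStrings(c(s1 = "ACG", s2 = "ACT"), "L1")
#' b <- alignmentFromStrings(c(s1 = "TTTT", s3 = "TTTA"), "L2")
#' sm <- concatenateLoci(list(a, b))
#' alignmentWidth(sm)   # 7
#' partitions(sm)       # L1 [0,3), L2 [3,7)
#' @export
concatenateLoci <- function(x, loci = NULL, specimens = NULL, indels = FALSE) {
  alns <- if (is(x, "BarcodeDataset")) alignments(x) else x
  if (!length(alns)) stop("no loci to concatenate")
  if (is.null(names(alns)))
    names(alns) <- vapply(alns, locusName, "")
  if (is.null(loci)) loci <- names(alns)
  miss <- setdiff(loci, names(alns))
  if (length(miss))
    stop(sprintf("locus not in dataset: %s", paste(sQuote(miss), collapse = ", ")))
  alns <- alns[loci]
  present <- unique(unlist(lapply(alns, specimenIds), use.names = FALSE))
  if (is.null(specimens)) {
    specimens <- if (is(x, "BarcodeDataset"))
      intersect(specimenIds(x), present) else present
  } else {
    specimens <- as.character(specimens)
  }
  if (!length(specimens)) stop("no specimens carry any of the chosen loci")
  widths <- vapply(alns, alignmentWidth, 1L)
  ends <- cumsum(widths)
  starts <- c(0L, ends[-length(ends)])
  parts <- Map(function(s, e) c(s, e), starts, ends)
  names(parts) <- loci
  big <- matrix("?", nrow = length(specimens), ncol = sum(widths),
                dimnames = list(specimens, NULL))
  for (i in seq_along(alns)) {
    a <- alns[[i]]
    ids <- intersect(specimens, specimenIds(a))
    big[ids, (starts[i] + 1L):ends[i]] <- a@seqs[ids, , drop = FALSE]
  }
  ind <- matrix(character(0), nrow = length(specimens), ncol = 0,
                dimnames = list(specimens, NULL))
  if (isTRUE(indels)) {
    blocks <- lapply(loci, function(nm) {
      ic <- simpleIndelCoding(alns[[nm]])
      if (ncol(ic)) colnames(ic) <- paste(nm, colnames(ic), sep = ".")
      full <- matrix("?", nrow = length(specimens), ncol = ncol(ic),
                     dimnames = list(specimens, colnames(ic)))
      full[intersect(specimens, rownames(ic)), ] <-
        ic[intersect(specimens, rownames(ic)), , drop = FALSE]
      full
    })
    ind <- do.call(cbind, c(list(ind), blocks))
  }
  new("Supermatrix",
      alignment = new("LocusAlignment", locus = "concat", seqs = big),
      partitions = parts, indels = ind)
}

#' Extract one locus back out of a supermatrix
#'
#' Returns the partition's columns as a [LocusAlignment], dropping specimens
#' whose entire block is \code{?} padding (i.e. specimens that never had the
#' locus), so that concatenation followed by extraction round-trips the
#' original alignments exactly.
#'
#' @param sm A [Supermatrix].
#' @param locus Locus name.
#' @return A [LocusAlignment].
#' @export
extractLocus <- function(sm, locus) {
  p <- partitions(sm)[[locus]]
  if (is.null(p)) stop(sprintf("no partition named %s", sQuote(locus)))
  m <- sm@alignment@seqs[, (p[1] + 1L):p[2], drop = FALSE]
  keep <- rowSums(m != "?") > 0L
  new("LocusAlignment", locus = locus, seqs = m[keep, , drop = FALSE])
}

# Maximal '-' runs of one row as an integer matrix [start, end] (1-based,
# inclusive), plus which runs touch the alignment ends.
.gapRuns <- function(chars) {
  r <- rle(chars == "-")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

#' Simple indel coding of alignment gaps
#'
#' Recodes shared alignment gaps as binary presence/absence characters
#' (the simple indel coding of Simmons & Ochoterena, as implemented by the
#' classic Gapcoder program). Every distinct \emph{internal} gap span --
#' identical start and end columns across the sequences bearing it --
#' becomes one character. A sequence scores \code{1} when it bears exactly
#' that gap, \code{0} when it has residues across the span, and \code{?}
#' when its own gap strictly contains the span or overlaps it without
#' coinciding, or when the span falls in a terminal missing region
#' (leading/trailing gaps or \code{?} padding, which represent recovery
#' failure, not indel events, and are never coded).
#'
#' @param aln A [LocusAlignment].
#' @return Character matrix of \code{"0"}, \code{"1"}, \code{"?"}; one row
#'   per sequence, one column per coded gap, named \code{g<start>_<end>}
#'   (1-based inclusive columns). Zero columns when the alignment has no
#'   internal gaps.
#' @export
simpleIndelCoding <- function(aln) {
  m <- if (is(aln, "LocusAlignment")) aln@seqs else aln
  n <- nrow(m); L <- ncol(m)
  runs <- vector("list", n)
  termmask <- matrix(FALSE, n, L)  # terminal missing region per sequence
  for (i in seq_len(n)) {
    ch <- m[i, ]
    nd <- ch %in% c("-", "?", "N")
    lead <- cumsum(!nd) == 0L
    trail <- rev(cumsum(rev(!nd)) == 0L)
    termmask[i, ] <- (lead | trail) & nd
    rr <- .gapRuns(ch)
    if (nrow(rr)) {
      internal <- !(lead[rr[, "start"]] | trail[rr[, "end"]])
      rr <- rr[internal, , drop = FALSE]
    }
    runs[[i]] <- rr
  }
  allruns <- unique(do.call(rbind, runs))
  if (is.null(allruns) || nrow(allruns) == 0L)
    return(matrix(character(0), nrow = n, ncol = 0,
                  dimnames = list(rownames(m), NULL)))
  allruns <- allruns[order(allruns[, "start"], allruns[, "end"]), , drop = FALSE]
  out <- matrix("0", nrow = n, ncol = nrow(allruns),
                dimnames = list(rownames(m),
                                paste0("g", allruns[, "start"], "_", allruns[, "end"])))
  for (i in seq_len(n)) {
    rr <- runs[[i]]
    for (k in seq_len(nrow(allruns))) {
      s <- allruns[k, "start"]; e <- allruns[k, "end"]
      if (nrow(rr) && any(rr[, "start"] == s & rr[, "end"] == e)) {
        out[i, k] <- "1"
      } else if (nrow(rr) && any(rr[, "start"] <= e & rr[, "end"] >= s)) {
        out[i, k] <- "?"   # overlapping or enclosing, non-identical gap
      } else if (any(termmask[i, s:e])) {
        out[i, k] <- "?"   # span lies in a terminal missing region
      }
    }
  }
  out
}

#' Write a supermatrix: FASTA, partition file, and indel block
#'
#' `writeSupermatrix()` writes the concatenated alignment as FASTA plus a
#' RAxML-style partition file (`DNA, locus = start-end` with 1-based
#' inclusive columns). `writeIndelMatrix()` writes the 0/1/? indel block as
#' a simple NEXUS standard-data block.
#'
#' @param sm A [Supermatrix].
#' @param fasta,partition,path Output paths.
#' @return The main output path, invisibly.
#' @export
writeSupermatrix <- function(sm, fasta, partition = NULL) {
  writeLocusAlignment(sm@alignment, fasta)
  if (!is.null(partition)) {
    p <- partitions(sm)
    lines <- vapply(names(p), function(nm)
      sprintf("DNA, %s = %d-%d", nm, p[[nm]][1] + 1L, p[[nm]][2]), "")
    writeLines(lines, partition)
  }
  invisible(fasta)
}

#' @rdname writeSupermatrix
#' @export
writeIndelMatrix <- function(sm, path) {
  ind <- indelBlock(sm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#NEXUS", "BEGIN DATA;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(ind), ncol(ind)),
               "  FORMAT DATATYPE=STANDARD MISSING=? SYMBOLS=\"01\";",
               "  MATRIX"), con)
  if (ncol(ind)) {
    rows <- apply(ind, 1L, paste, collapse = "")
    writeLines(sprintf("    %s %s", format(rownames(ind)), rows), con)
  }
  writeLines(c("  ;", "END;"), con)
  invisible(path)
}
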