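DETERMINATE <- c("A", "C", "G", "T")

.comparable <- function(a, b) {
  a %in% DETERMINATE & b %in% DETERMINATE
}

.as_chars <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) strsplit(toupper(x), "", fixed = TRUE)[[1]]
  else toupper(x)
}

#' Pairwise genetic distances between two aligned sequences
#'
#' Distances are computed over the columns where both sequences carry a
#' determinate base (pairwise deletion of \code{-}, \code{N} and \code{?}).
#' `pDistance()` is the uncorrected proportion of differing sites;
#' `jcDistance()` applies the Jukes-Cantor correction
#' \eqn{-\frac{3}{4}\ln(1-\frac{4}{3}p)}; `k2pDistance()` is the Kimura
#' two-parameter distance
#' \deqn{d = -\tfrac12 \ln\big[(1-2P-Q)\sqrt{1-2Q}\big]}
#' with \eqn{P} and \eqn{Q} the transition and transversion proportions.
#' `NA` is returned when no comparable columns remain or the correction's
#' domain is violated (saturation).
#'
#' @param a,b Aligned sequences of equal length: character vectors of single
#'   characters, or single strings.
#' @return A non-negative number, or `NA` when undefined.
#' @examples
#' pDistance("ACGT", "ACGA")    # 0.25
#' k2pDistance("ACGT", "ACGT")  # 0
#' @export
pDistance <- function(a, b) {
  a <- .as_chars(a); b <- .as_chars(b)
  stopifnot(length(a) == length(b))
  keep <- .comparable(a, b)
  n <- sum(keep)
  if (n == 0L) return(NA_real_)
  sum(a[keep] != b[keep]) / n
}

#' @rdname pDistance
#' @export
k2pDistance <- function(a, b) {
  a <- .as_chars(a); b <- .as_chars(b)
  stopifnot(length(a) == length(b))
  keep <- .comparable(a, b)
  n <- sum(keep)
  if (n == 0L) return(NA_real_)
  a <- a[keep]; b <- b[keep]
  diff <- a != b
  # transitions: A<->G, C<->T
  purine <- c("A", "G")
  ts <- diff & ((a %in% purine) == (b %in% purine))
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1 * sqrt(w2))
}

#' @rdname pDistance
#' @export
jcDistance <- function(a, b) {
  p <- pDistance(a, b)
  if (is.na(p)) return(NA_real_)
  w <- 1 - 4 * p / 3
  if (w <= 0) return(NA_real_)
  -0.75 * log(w)
}

.MODEL_MAP <- c(k2p = "K80", K80 = "K80", p = "raw", raw = "raw",
                jc = "JC69", JC69 = "JC69")

#' Pairwise distance matrix for an alignment
#'
#' Computes all pairwise distances under the chosen substitution model with
#' pairwise deletion of gaps, \code{N} and \code{?}. The default model is
#' K2P, the DNA-barcoding community convention; uncorrected p-distances and
#' JC69 are selectable. Undefined pairs (no shared determinate columns, or
#' correction domain violated) are, under the default policy, imputed with
#' the maximum defined distance plus a small increment so that
#' neighbour-joining stays runnable on sparse supermatrices; the affected
#' pairs are recorded in the \code{"undefined_pairs"} attribute for audit.
#'
#' @param x A [LocusAlignment], [Supermatrix], or character matrix of
#'   aligned single characters with specimen rownames.
#' @param model One of \code{"k2p"} (default), \code{"p"}, \code{"jc"} (the
#'   dist.dna names \code{"K80"}, \code{"raw"}, \code{"JC69"} are accepted
#'   too).
#' @param undefined Policy for undefined pairs: \code{"impute"} (default,
#'   see above) or \code{"fail"}.
#' @param epsilon Increment added to the maximum defined distance when
#'   imputing.
#' @return A symmetric numeric matrix with zero diagonal, specimen ids as
#'   dimnames, and attribute \code{"undefined_pairs"} (two-column character
#'   matrix, possibly empty).
#' @export
distanceMatrix <- function(x, model = c("k2p", "p", "jc", "K80", "raw", "JC69"),
                           undefined = c("impute", "fail"), epsilon = 1e-4) {
  model <- .MODEL_MAP[[match.arg(model)]]
  undefined <- match.arg(undefined)
  m <- if (is(x, "Supermatrix")) x@alignment@seqs
       else if (is(x, "LocusAlignment")) x@seqs
       else x
  if (nrow(m) < 2L) stop("need at least 2 sequences")
  d <- .dist_from_charmat(m, model)
  bad <- which(!is.finite(d) & upper.tri(d), arr.ind = TRUE)
  und <- cbind(rownames(d)[bad[, 1]], colnames(d)[bad[, 2]])
  colnames(und) <- c("id1", "id2")
  if (nrow(und)) {
    if (undefined == "fail")
      stop(sprintf("undefined distance for pair(s): %s",
                   paste(und[, 1], und[, 2], sep = "~", collapse = ", ")))
    mx <- suppressWarnings(max(d[is.finite(d)]))
    if (!is.finite(mx)) stop("all pairwise distances are undefined")
    d[!is.finite(d)] <- mx + epsilon
    diag(d) <- 0
  }
  attr(d, "undefined_pairs") <- und
  d
}

# dist.dna (ape, C implementation) is the engine; the exported pair
# functions above are its closed-form counterpart and the two are held in
# agreement by tests.
.dist_from_charmat <- function(m, model) {
  db <- ape::as.DNAbin(tolower(m))
  d <- suppressWarnings(ape::dist.dna(db, model = model,
                                      pairwise.deletion = TRUE,
                                      as.matrix = TRUE))
  diag(d) <- 0
  d
}

#' Write a distance matrix as a PHYLIP-like square TSV
#'
#' @param d Symmetric distance matrix with id dimnames.
#' @param path Output path.
#' @export
writeDistanceMatrix <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(d)), con)
  utils::write.table(format(d, digits = 10, trim = TRUE), con, sep = "\t",
                     quote = FALSE, col.names = FALSE)
  invisible(path)
}
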