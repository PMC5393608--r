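#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining (via the C implementation in
#' \pkg{ape}), with negative estimated branch lengths clamped to zero.
#' Branch lengths are not used by any discrimination criterion in this
#' package; clamping only keeps exported trees displayable. For two taxa the
#' tree is the single edge split evenly between the two pendant branches.
#'
#' @param d Symmetric distance matrix (specimen ids as dimnames) or
#'   `dist` object; all entries must be defined (see [distanceMatrix()]'s
#'   imputation policy).
#' @return An unrooted `phylo` tree.
#' @export
neighborJoining <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) < 2L) stop("need at least 2 taxa")
  if (any(!is.finite(m))) stop("undefined entries in distance matrix")
  if (nrow(m) == 2L) {
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
               edge.length = rep(m[1, 2] / 2, 2),
               tip.label = rownames(m), Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(m))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Neighbour-joining with nonparametric bootstrap supports
#'
#' Builds the reference NJ tree on the full alignment, then resamples
#' alignment columns with replacement `replicates` times, rebuilds the NJ
#' tree from each resample, and annotates each internal edge of the
#' reference tree with the percentage of replicates containing the same
#' bipartition (rounded to the nearest integer, stored in `node.label`).
#' One seed drives all resampling, so identical inputs and seed give
#' identical supports.
#'
#' @param x A [LocusAlignment], [Supermatrix], or aligned character matrix
#'   (>= 3 sequences).
#' @param model Distance model, see [distanceMatrix()].
#' @param replicates Number of bootstrap replicates (>= 1; 1000 is the
#'   conventional default, smaller values are fine for simulation studies).
#' @param seed Integer seed for the column resampler.
#' @return A `phylo` with integer supports (0-100) in `node.label`.
#' @export
bootstrapSupport <- function(x, model = "k2p", replicates = 1000L, seed = 1L) {
  if (replicates < 1L) stop("replicates must be a positive integer")
  m <- if (is(x, "Supermatrix")) x@alignment@seqs
       else if (is(x, "LocusAlignment")) x@seqs
       else x
  if (nrow(m) < 3L) stop("need at least 3 sequences for bootstrap supports")
  ref <- neighborJoining(distanceMatrix(m, model = model))
  reps <- vector("list", replicates)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  for (r in seq_len(replicates)) {
    idx <- sample.int(ncol(m), replace = TRUE)
    reps[[r]] <- neighborJoining(distanceMatrix(m[, idx, drop = FALSE],
                                                model = model))
  }
  counts <- ape::prop.clades(ref, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  ref$node.label <- as.character(as.integer(round(100 * counts / replicates)))
  ref
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# All bipartition sides of an unrooted tree: every internal node's clade of
# the (arbitrarily rooted) phylo representation *and* its complement, each
# carrying the node's support. Returns a list of records with tip-name
# vector `side`, numeric `support`, and the internal node number.
.treeSides <- function(tree) {
  ntip <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  labs <- tree$node.label
  out <- list()
  for (k in seq_along(parts)) {
    node <- ntip + k
    sup <- if (!is.null(labs) && nzchar(labs[k]) && !is.na(labs[k]))
      suppressWarnings(as.numeric(labs[k])) else NA_real_
    side <- tree$tip.label[parts[[k]]]
    comp <- setdiff(tree$tip.label, side)
    if (length(side) < ntip)
      out[[length(out) + 1L]] <- list(node = node, side = side, support = sup)
    if (length(comp) >= 1L && length(comp) < ntip)
      out[[length(out) + 1L]] <- list(node = node, side = comp, support = sup)
  }
  out
}

#' Test bootstrap-supported monophyly of a leaf set
#'
#' The tree-based success criterion: the given leaves succeed when they form
#' one side of a bipartition of the unrooted tree \emph{and} the edge
#' defining that bipartition has bootstrap support strictly greater than
#' `threshold`. Singletons, and sets leaving fewer than two leaves outside,
#' correspond to trivial (pendant) bipartitions and return `TRUE` with the
#' support condition vacuously satisfied. A tree without any `node.label`
#' (no bootstrap was run) is scored on topology alone.
#'
#' @param tree A `phylo`, typically from [bootstrapSupport()].
#' @param leaves Character vector of leaf labels (non-empty, all present in
#'   the tree).
#' @param threshold Support threshold; the comparison is strict (`>`), per
#'   the usual "greater than 50\%" criterion.
#' @return `TRUE` or `FALSE`.
#' @examples
#' tr <- ape::read.tree(text = "((a1:1,a2:1)75:1,(b1:1,b2:1)60:1);")
#' hasSupportedMonophyly(tr, c("a1", "a2"), 50)  # TRUE
#' hasSupportedMonophyly(tr, c("a1", "b1"), 50)  # FALSE
#' @export
hasSupportedMonophyly <- function(tree, leaves, threshold = 50) {
  stopifnot(inherits(tree, "phylo"))
  leaves <- unique(as.character(leaves))
  if (!length(leaves)) stop("'leaves' must be non-empty")
  unknown <- setdiff(leaves, tree$tip.label)
  if (length(unknown))
    stop(sprintf("leaf id(s) not in tree: %s",
                 paste(sQuote(unknown), collapse = ", ")))
  n <- length(tree$tip.label)
  k <- length(leaves)
  if (k == 1L || k >= n - 1L) return(TRUE)  # trivial bipartitions
  hit <- .findBipartition(tree, leaves)
  if (is.null(hit)) return(FALSE)
  if (is.null(tree$node.label)) return(TRUE)
  sup <- hit$support
  if (is.na(sup)) return(FALSE)
  sup > threshold
}

# Locate the bipartition {leaves | rest} in an unrooted tree; returns the
# side record (with support) or NULL. Either the leaf set or its complement
# must be a clade of the rooted representation.
.findBipartition <- function(tree, leaves) {
  sides <- .treeSides(tree)
  comp <- setdiff(tree$tip.label, leaves)
  for (s in sides) {
    if (length(s$side) == length(leaves) && setequal(s$side, leaves)) return(s)
    if (length(s$side) == length(comp) && setequal(s$side, comp)) return(s)
  }
  NULL
}
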