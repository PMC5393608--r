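# Builders used across the suite.

mkAln <- function(seqs, locus = "L1") alignmentFromStrings(seqs, locus)

mkDataset <- function(species, seqs, locus = "L1") {
  # species: named character (id -> "Genus species"); seqs: named strings
  meta <- data.frame(specimen_id = names(species),
                     species = unname(species),
                     genus = sub("\\s.*$", "", species),
                     stringsAsFactors = FALSE)
  barcodeDataset(meta, list(mkAln(seqs, locus)))
}

# Random unrooted binary tree with positive branch lengths and its additive
# (path-length) distance matrix.
randomAdditive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE, br = function(k) runif(k, 0.1, 1))
  tr$tip.label <- paste0("t", seq_len(n))
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# Random sequences: common ancestor plus per-tip random substitutions.
randomSeqPair <- function(L, nmut, seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  a <- sample(bases, L, TRUE)
  b <- a
  i <- sample(L, nmut)
  b[i] <- sample(bases, nmut, TRUE)
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

# Brute-force check that `leaves` forms a bipartition side of the unrooted
# tree, independent of the package's implementation: enumerate every edge,
# compute the leaf set below it by walking the edge table.
oracleBipartition <- function(tree, leaves) {
  ntip <- length(tree$tip.label)
  below <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, below), use.names = FALSE)
  }
  all.sets <- lapply(tree$edge[, 2], below)
  for (s in all.sets) {
    if (setequal(s, leaves)) return(TRUE)
    if (setequal(s, setdiff(tree$tip.label, leaves))) return(TRUE)
  }
  FALSE
}
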