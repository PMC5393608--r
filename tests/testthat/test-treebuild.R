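test_that("NJ handles the smallest cases exactly", {
  d2 <- matrix(c(0, .3, .3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  tr <- neighborJoining(d2)
  expect_setequal(tr$tip.label, c("a", "b"))
  expect_equal(sum(tr$edge.length), 0.3)

  # three-point formulas: d(AB)=2, d(AC)=4, d(BC)=4 -> pendants 1, 1, 3
  d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighborJoining(d3)
  len <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
})

test_that("NJ recovers the 4-taxon additive split and path lengths", {
  gen <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  d <- ape::cophenetic.phylo(gen)
  tr <- neighborJoining(d)
  expect_true(oracleBipartition(tr, c("A", "B")))
  expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-9)
  # brute force: of all 3 unrooted 4-taxon topologies, AB|CD fits best
  tops <- list(c("A", "B"), c("A", "C"), c("A", "D"))
  rss <- vapply(tops, function(pair) {
    txt <- sprintf("((%s:1,%s:1):1,(%s:1,%s:1):1);", pair[1], pair[2],
                   setdiff(c("A", "B", "C", "D"), pair)[1],
                   setdiff(c("A", "B", "C", "D"), pair)[2])
    t0 <- ape::read.tree(text = txt)
    f <- stats::optim(rep(1, length(t0$edge.length)), function(b) {
      t0$edge.length <- pmax(b, 0)
      sum((ape::cophenetic.phylo(t0)[rownames(d), colnames(d)] - d)^2)
    }, method = "BFGS")
    f$value
  }, 1)
  expect_equal(which.min(rss), 1L)
  expect_lt(rss[1], 1e-8)
})

test_that("negative estimated branch lengths are clamped to zero", {
  # a famously non-metric matrix that drives one NJ branch negative
  d <- matrix(c(0, 3, 9, 9,
                3, 0, 9, 9,
                9, 9, 0, 1,
                9, 9, 1, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- 8.9; d["b", "a"] <- 8.9  # distort
  tr <- neighborJoining(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap supports are deterministic, bounded, and saturate on a clean split", {
  set.seed(33)
  base <- sample(c("A", "C", "G", "T"), 500, TRUE)
  mutate <- function(x, n) { i <- sample(length(x), n)
    x[i] <- sample(c("A", "C", "G", "T"), n, TRUE); x }
  gA <- mutate(base, 100)  # two groups, between-divergence ~0.2
  seqs <- c(lapply(1:4, function(i) mutate(base, 5)),
            lapply(1:4, function(i) mutate(gA, 5)))
  m <- do.call(rbind, lapply(seqs, identity))
  rownames(m) <- c(paste0("a", 1:4), paste0("b", 1:4))
  aln <- mkAln(apply(m, 1, paste, collapse = ""))

  tr1 <- bootstrapSupport(aln, replicates = 100, seed = 5)
  tr2 <- bootstrapSupport(aln, replicates = 100, seed = 5)
  expect_identical(ape::write.tree(tr1), ape::write.tree(tr2))
  sup <- as.integer(tr1$node.label[nzchar(tr1$node.label)])
  expect_true(all(sup >= 0 & sup <= 100))
  expect_true(hasSupportedMonophyly(tr1, paste0("a", 1:4), 50))
  grp <- BarcodeEval:::.findBipartition(tr1, paste0("a", 1:4))
  expect_equal(grp$support, 100)

  # support for the split is invariant to taxon order
  perm <- c(5, 2, 7, 1, 8, 3, 6, 4)
  alnP <- mkAln(apply(m[perm, ], 1, paste, collapse = ""))
  trP <- bootstrapSupport(alnP, replicates = 100, seed = 5)
  expect_equal(BarcodeEval:::.findBipartition(trP, paste0("a", 1:4))$support, 100)
})

test_that("supported-monophyly reads bipartitions and thresholds strictly", {
  tr <- ape::read.tree(text = "((a1,a2)75,(b1,b2)60);")
  expect_true(hasSupportedMonophyly(tr, c("a1", "a2"), 50))
  expect_false(hasSupportedMonophyly(tr, c("a1", "b1"), 50))
  tr45 <- ape::read.tree(text = "((a1,a2)45,(b1,b2)45);")
  expect_false(hasSupportedMonophyly(tr45, c("a1", "a2"), 50))
  expect_false(hasSupportedMonophyly(tr, c("a1", "a2"), 75))  # strict >
  expect_true(hasSupportedMonophyly(tr, "a1", 50))            # singleton
  expect_true(hasSupportedMonophyly(tr, c("a1", "a2", "b1"), 50)) # n-1 trivial
  expect_error(hasSupportedMonophyly(tr, c("a1", "zz"), 50), "zz")
})

test_that("monophyly detection agrees with edge-walking enumeration", {
  set.seed(202)
  for (i in 1:60) {
    n <- sample(4:10, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    tr$node.label <- NULL
    k <- sample(2:(n - 2), 1)
    leaves <- sample(tr$tip.label, k)
    expect_equal(hasSupportedMonophyly(tr, leaves, 50),
                 oracleBipartition(tr, leaves),
                 info = sprintf("iter %d", i))
  }
})
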