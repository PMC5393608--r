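# A 5-specimen toy with a planted intruder: x is labeled species A but its
# sequence sits in species B's cluster (identical to b1).
intruderDataset <- function() {
  base <- strrep("ACGTT", 12)
  bseq <- paste0(strrep("TGCAA", 6), substr(base, 31, 60))  # far from A
  mut <- function(s, pos, to) { substr(s, pos, pos) <- to; s }
  mkDataset(
    species = c(a1 = "Gen alpha", a2 = "Gen alpha", x = "Gen alpha",
                b1 = "Gen beta", b2 = "Gen beta"),
    seqs = c(a1 = base, a2 = mut(base, 7, "A"),
             x = bseq, b1 = bseq, b2 = mut(bseq, 11, "G")))
}

test_that("a conspecific identical sequence is the unique top hit", {
  ds <- mkDataset(
    species = c(q = "Gen alpha", c1 = "Gen alpha",
                h1 = "Gen beta", h2 = "Gen beta"),
    seqs = c(q = strrep("ACGTTGCAAC", 6),
             c1 = strrep("ACGTTGCAAC", 6),
             h1 = strrep("ACGTTGCTTC", 6),   # ~10% divergent
             h2 = strrep("ACCTTGCTTC", 6)))
  hl <- bestHits("q", ds)
  expect_equal(hl$top, "c1")
  expect_equal(hl$hits$subject[1], "c1")
  expect_true(all(diff(hl$hits$score) <= 0))  # non-increasing
})

test_that("self-exclusion applies only when conspecifics exist", {
  ds <- mkDataset(
    species = c(solo = "Gen alpha", b1 = "Gen beta", b2 = "Gen beta"),
    seqs = c(solo = strrep("ACGTTGCAAC", 6),
             b1 = strrep("ACGTTGCTTC", 6),
             b2 = strrep("ACGTTGCTTC", 6)))
  expect_equal(bestHits("solo", ds)$top, "solo")  # singleton keeps self-hit
  expect_false("b1" %in% bestHits("b1", ds)$hits$subject)  # excluded
})

test_that("equal scores put both subjects in the top set", {
  base <- strrep("ACGTTGCAAC", 6)
  mut <- function(s, pos, to) { substr(s, pos, pos) <- to; s }
  ds <- mkDataset(
    species = c(q = "Gen alpha", c1 = "Gen alpha", h1 = "Gen beta",
                c2 = "Gen alpha"),
    seqs = c(q = base, c1 = mut(base, 6, "A"), h1 = mut(base, 26, "A"),
             c2 = mut(mut(base, 6, "A"), 26, "A")))
  hl <- bestHits("q", ds)
  expect_setequal(hl$top, c("c1", "h1"))
})

test_that("banded and exact local alignment scores agree on homologous pairs", {
  set.seed(77)
  for (i in 1:25) {
    p <- randomSeqPair(300, 25, seed = 300 + i)
    s1 <- BarcodeEval:::.sw_score_pair(p$a, p$b, 1, -2, 2.5, 2.5, 64L)
    s0 <- BarcodeEval:::.sw_score_pair(p$a, p$b, 1, -2, 2.5, 2.5, 0L)
    expect_equal(s1, s0)
  }
})

test_that("similarity success demands an all-conspecific top set", {
  # perfect barcode gap: both species succeed
  ds <- mkDataset(
    species = c(a1 = "Gen alpha", a2 = "Gen alpha",
                b1 = "Gen beta", b2 = "Gen beta"),
    seqs = c(a1 = strrep("ACGTTGCAAC", 6), a2 = strrep("ACGTTGCAAC", 6),
             b1 = strrep("ACGTTGCTTC", 6), b2 = strrep("ACGTTGCTTC", 6)))
  rec <- similaritySuccess(ds, "L1", level = "species", cohort = "n2")
  expect_equal(nrow(rec), 2L)
  expect_true(all(rec$success))
  expect_equal(discriminationRate(rec)$rate, 1)

  # the intruder fails both its labeled species and the invaded one
  rec <- similaritySuccess(intruderDataset(), "L1", level = "species",
                           cohort = "n1")
  expect_false(rec$success[rec$taxon == "Gen alpha"])
  expect_false(rec$success[rec$taxon == "Gen beta"])
  expect_match(rec$reason[rec$taxon == "Gen alpha"], "x|b1|b2")
  # ... but genus level is untouched (same genus throughout)
  recG <- similaritySuccess(intruderDataset(), "L1", level = "genus")
  expect_true(all(recG$success))
})

test_that("singleton species succeed vacuously in n1 unless switched off", {
  ds <- mkDataset(
    species = c(solo = "Gen alpha", b1 = "Gen beta", b2 = "Gen beta"),
    seqs = c(solo = strrep("ACGTTGCAAC", 6),
             b1 = strrep("ACGTTGCTTC", 6), b2 = strrep("ACGTTGCTTC", 6)))
  r1 <- similaritySuccess(ds, "L1", cohort = "n1")
  expect_true(r1$success[r1$taxon == "Gen alpha"])
  r0 <- similaritySuccess(ds, "L1", cohort = "n1", vacuousSingletons = FALSE)
  expect_false(r0$success[r0$taxon == "Gen alpha"])
  r2 <- similaritySuccess(ds, "L1", cohort = "n2")
  expect_false("Gen alpha" %in% r2$taxon)  # singleton excluded from n2
})

test_that("queries lacking the marker set are rejected, absent loci named", {
  ds <- intruderDataset()
  expect_error(bestHits("a1", ds, "nope"), "nope")
  expect_error(bestHits("ghost", ds, "L1"), "ghost")
})
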