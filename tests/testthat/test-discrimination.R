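.dsFromTaxa <- function(species) {
  # dataset with metadata only (tree-based tests never touch sequences)
  meta <- data.frame(specimen_id = names(species), species = unname(species),
                     genus = sub("\\s.*$", "", species),
                     stringsAsFactors = FALSE)
  barcodeDataset(meta)
}

test_that("tree criterion scores supported monophyly per species", {
  tr <- ape::read.tree(text = "((a1,a2)90,((b1,b2)80,c1)70);")
  ds <- .dsFromTaxa(c(a1 = "Gen alpha", a2 = "Gen alpha",
                      b1 = "Gen beta", b2 = "Gen beta", c1 = "Gen gamma"))
  rec <- treeSuccess(tr, ds, level = "species")
  expect_setequal(rec$taxon, c("Gen alpha", "Gen beta"))  # singleton dropped
  expect_true(all(rec$success))
  expect_true("Gen gamma" %in% attr(rec, "dropped"))

  tr2 <- ape::read.tree(text = "((a1,b1)90,(a2,b2)90);")
  ds2 <- .dsFromTaxa(c(a1 = "Gen alpha", a2 = "Gen alpha",
                       b1 = "Gen beta", b2 = "Gen beta"))
  rec2 <- treeSuccess(tr2, ds2, level = "species")
  expect_false(any(rec2$success))
})

test_that("genus criterion mirrors the species criterion one rank up", {
  # Beta is split across the tree; Alpha and Gamma form supported clades.
  tr <- ape::read.tree(
    text = "(((gA1,gA2)95,gB1)80,((gB2,gB3)90,(gC1,gC2)85)70);")
  ds <- .dsFromTaxa(c(gA1 = "Alpha s1", gA2 = "Alpha s2",
                      gB1 = "Beta s1", gB2 = "Beta s2", gB3 = "Beta s2",
                      gC1 = "Gamma s1", gC2 = "Gamma s2"))
  rec <- treeSuccess(tr, ds, level = "genus")
  expect_true(rec$success[rec$taxon == "Alpha"])
  expect_true(rec$success[rec$taxon == "Gamma"])
  expect_false(rec$success[rec$taxon == "Beta"])
})

test_that("monophyly is read on the unrooted tree: a two-taxon split serves both sides", {
  # the single internal edge of a 4-leaf tree defines both genus groups
  tr <- ape::read.tree(text = "(((gA1,gA2)95,gB1)40,gB2);")
  expect_true(hasSupportedMonophyly(tr, c("gA1", "gA2"), 50))
  expect_true(hasSupportedMonophyly(tr, c("gB1", "gB2"), 50))
})

test_that("discrimination rates are plain success fractions", {
  r <- data.frame(success = c(rep(TRUE, 5), rep(FALSE, 3)))
  out <- discriminationRate(r)
  expect_equal(out$rate, 0.625)
  expect_equal(out$successes, 5)
  expect_equal(out$total, 8)
  expect_equal(discriminationRate(data.frame(success = rep(FALSE, 5)))$rate, 0)
  expect_equal(discriminationRate(data.frame(success = rep(TRUE, 4)))$rate, 1)
  expect_error(discriminationRate(data.frame(success = logical(0))), "undefined")
})

test_that("cohort totals nest: tree <= n2 <= n1", {
  sim <- simulateDataset(simulationConfig(
    nGenera = 3L, speciesPerGenus = 4L, individualsRange = c(1L, 4L),
    loci = data.frame(name = "L1", length = 300L, rate = 1,
                      indelRate = 0.1, missingness = 0.15),
    interSpecies = 0.05, intraSpecies = 0.005, seed = 91L))
  ds <- sim$dataset
  sc <- BarcodeEval:::.scoreMatrix(ds, "L1")
  n1 <- similaritySuccess(ds, "L1", cohort = "n1", scores = sc)
  n2 <- similaritySuccess(ds, "L1", cohort = "n2", scores = sc)
  tre <- treeSuccess(bootstrapSupport(alignments(ds)$L1, replicates = 20,
                                      seed = 2), ds)
  expect_lte(nrow(n2), nrow(n1))
  expect_lte(nrow(tre), nrow(n2))
  for (rec in list(n1, n2, tre)) {
    rate <- discriminationRate(rec)$rate
    expect_gte(rate, 0); expect_lte(rate, 1)
  }
})

test_that("discrimination rates are invariant to relabeling two species", {
  sim <- simulateDataset(simulationConfig(
    nGenera = 2L, speciesPerGenus = 3L, individualsRange = c(2L, 3L),
    loci = data.frame(name = "L1", length = 300L, rate = 1,
                      indelRate = 0, missingness = 0),
    interSpecies = 0.02, intraSpecies = 0.008, seed = 17L))
  ds <- sim$dataset
  sp <- specimenTable(ds)
  two <- unique(sp$species)[1:2]
  swapped <- sp
  swapped$species[sp$species == two[1]] <- two[2]
  swapped$species[sp$species == two[2]] <- two[1]
  swapped$genus <- sub("\\s.*$", "", swapped$species)
  ds2 <- barcodeDataset(swapped, alignments(ds))

  r1 <- discriminationRate(similaritySuccess(ds, "L1", cohort = "n1"))
  r2 <- discriminationRate(similaritySuccess(ds2, "L1", cohort = "n1"))
  expect_equal(r1, r2)
  tr1 <- bootstrapSupport(alignments(ds)$L1, replicates = 50, seed = 4)
  expect_equal(discriminationRate(treeSuccess(tr1, ds)),
               discriminationRate(treeSuccess(tr1, ds2)))
})
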