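smallGapConfig <- function(seed, swapRate = 0) {
  simulationConfig(
    nGenera = 4L, speciesPerGenus = 3L, individualsRange = c(3L, 3L),
    loci = data.frame(name = c("locA", "locB"), length = c(300L, 300L),
                      rate = c(0.8, 1.2), indelRate = c(0.1, 0.1),
                      missingness = c(0, 0)),
    interSpecies = 0.05, intraSpecies = 0.002,
    interGenusMultiplier = 2, swapRate = swapRate, seed = seed)
}

test_that("no swaps means no flags", {
  sim <- simulateDataset(smallGapConfig(seed = 21))
  out <- flagMisidentifications(sim$dataset, replicates = 50, seed = 5)
  expect_equal(nrow(out$flags), 0L)
  expect_equal(length(out$insufficient), 0L)
})

test_that("a single planted swap is flagged with its true species proposed", {
  found <- 0L
  for (seed in c(101L, 202L, 303L)) {
    sim <- simulateDataset(smallGapConfig(seed = seed, swapRate = 0.03))
    truth <- sim$truth
    out <- flagMisidentifications(sim$dataset, replicates = 50, seed = 5)
    expect_setequal(out$flags$specimen_id, truth@swaps$specimen_id)
    if (nrow(truth@swaps)) {
      found <- found + 1L
      m <- merge(out$flags, truth@swaps, by = "specimen_id")
      expect_equal(m$proposed_species, m$original)
      expect_equal(m$assigned_species, m$assigned)
    }
  }
  expect_gte(found, 1L)  # at least one seed actually planted a swap
})

test_that("a violation on fewer than quorum marker sets is evidence, not a flag", {
  # Hand-built: specimen 'x' is labeled species alpha; its locA sequence
  # sits inside species beta's cluster, while its locB sequence is a normal
  # alpha sequence. With marker sets {locA}, {locB}, {locA+locB} and the
  # long locB dominating the combination, only the locA analysis sees a
  # violation -> below the default quorum of 2.
  mut <- function(s, pos) {
    for (p in pos) substr(s, p, p) <- "T"
    s
  }
  baseA_alpha <- strrep("ACGGACGAAC", 6)
  baseA_beta <- mut(baseA_alpha, c(2, 9, 14, 22, 28, 33, 41, 47, 55))
  baseB_alpha <- strrep("GGCATCGTAC", 24)
  baseB_beta <- mut(baseB_alpha, seq(3, 230, by = 12))
  species <- c(a1 = "Gen alpha", a2 = "Gen alpha", a3 = "Gen alpha",
               x = "Gen alpha",
               b1 = "Gen beta", b2 = "Gen beta", b3 = "Gen beta",
               c1 = "Gen gamma", c2 = "Gen gamma", c3 = "Gen gamma")
  baseA_gamma <- mut(baseA_alpha, c(5, 11, 19, 25, 31, 39, 45, 52, 58))
  baseB_gamma <- mut(baseB_alpha, seq(7, 234, by = 12))
  jitter <- function(s, p) mut(s, p)
  locA <- c(a1 = baseA_alpha, a2 = jitter(baseA_alpha, 30), a3 = jitter(baseA_alpha, 36),
            x = baseA_beta,
            b1 = baseA_beta, b2 = jitter(baseA_beta, 30), b3 = jitter(baseA_beta, 36),
            c1 = baseA_gamma, c2 = jitter(baseA_gamma, 30), c3 = jitter(baseA_gamma, 36))
  locB <- c(a1 = baseB_alpha, a2 = jitter(baseB_alpha, 100), a3 = jitter(baseB_alpha, 110),
            x = jitter(baseB_alpha, 120),
            b1 = baseB_beta, b2 = jitter(baseB_beta, 100), b3 = jitter(baseB_beta, 110),
            c1 = baseB_gamma, c2 = jitter(baseB_gamma, 100), c3 = jitter(baseB_gamma, 110))
  meta <- data.frame(specimen_id = names(species), species = unname(species),
                     genus = "Gen", stringsAsFactors = FALSE)
  ds <- barcodeDataset(meta, list(alignmentFromStrings(locA, "locA"),
                                  alignmentFromStrings(locB, "locB")))
  out <- flagMisidentifications(ds, replicates = 100, seed = 3)
  expect_false("x" %in% out$flags$specimen_id)           # sub-quorum
  ev <- out$evidence
  expect_true(any(ev$specimen_id == "x" & ev$marker_set == "locA"))
  expect_equal(ev$nearest_species[ev$specimen_id == "x" &
                                  ev$marker_set == "locA"], "Gen beta")
})

test_that("specimens lacking enough marker sets are audited, not flagged", {
  sim <- simulateDataset(smallGapConfig(seed = 77))
  ds <- sim$dataset
  # strip one specimen down to a single locus
  sp <- specimenTable(ds)
  victim <- sp$specimen_id[1]
  alns <- alignments(ds)
  keep <- setdiff(specimenIds(alns$locB), victim)
  alns$locB <- alignmentFromStrings(seqStrings(alns$locB)[keep], "locB")
  ds2 <- barcodeDataset(sp, alns)
  out <- flagMisidentifications(ds2, replicates = 30, seed = 5,
                                markerSets = list("locA", "locB"),
                                quorum = 2L)
  expect_true(victim %in% out$insufficient)
  expect_false(victim %in% out$flags$specimen_id)
})
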