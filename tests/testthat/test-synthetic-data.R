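test_that("planted variant counts follow the configured density", {
  cfg <- SimulationConfig(genomeLength = 1e5, snpDensity = 1 / 150,
                          seed = 21)
  sim <- simulateStrainGenomes(cfg)
  v <- variantRecords(sim$variants)
  lambda <- 1e5 / 150
  # 99% Poisson interval around the expected count
  expect_gte(nrow(v), qpois(0.005, lambda))
  expect_lte(nrow(v), qpois(0.995, lambda))
  # configured indel fraction, within binomial error
  isIndel <- nchar(v$ref) != nchar(v$alt)
  expect_lt(abs(mean(isIndel) - cfg@indelFraction),
            3 * sqrt(0.1 * 0.9 / nrow(v)))
  expect_true(all(v$ref != v$alt))
  # records never overlap on the reference
  ends <- v$pos + nchar(v$ref) - 1
  expect_true(all(v$pos[-1] > ends[-nrow(v)]))
})

test_that("degenerate variant configurations behave as documented", {
  cfg0 <- SimulationConfig(genomeLength = 1e4, snpDensity = 0, seed = 1)
  expect_equal(nrow(variantRecords(simulateStrainGenomes(cfg0)$variants)),
               0)
  cfgErr <- SimulationConfig(genomeLength = 1000, snpDensity = 1e-4,
                             seed = 1)
  expect_error(simulateStrainGenomes(cfgErr), "no variants plantable")
  cfgInd <- SimulationConfig(genomeLength = 2e4, indelFraction = 1,
                             seed = 2)
  v <- variantRecords(simulateStrainGenomes(cfgInd)$variants)
  expect_true(all(nchar(v$ref) != nchar(v$alt)))
})

test_that("same seed reproduces genomes, counts and reads byte for
          byte", {
  cfg <- SimulationConfig(genomeLength = 2e4, nFeatures = 100, seed = 3)
  s1 <- simulateStrainGenomes(cfg)
  s2 <- simulateStrainGenomes(cfg)
  expect_identical(as.character(s1$reference), as.character(s2$reference))
  expect_identical(variantRecords(s1$variants), variantRecords(s2$variants))
  t1 <- makeTruthTable(cfg)
  expect_identical(
    SummarizedExperiment::assay(simulateDesignCounts(t1, cfg)),
    SummarizedExperiment::assay(simulateDesignCounts(t1, cfg)))
  cfgB <- SimulationConfig(genomeLength = 2e4, nFeatures = 100, seed = 4)
  expect_false(identical(as.character(s1$reference),
                         as.character(simulateStrainGenomes(cfgB)$reference)))
})

test_that("read simulator covers variants at the enumerated rate and
          honors depth 0", {
  cfg <- SimulationConfig(genomeLength = 50000, indelFraction = 0,
                          seed = 23)
  sim <- simulateStrainGenomes(cfg)
  pgA <- buildPseudogenome(sim$reference, VariantTable(), strain = "A")
  pgB <- buildPseudogenome(sim$reference, sim$variants, strain = "B")
  peaks <- simulateFeatures(cfg, n = 40, width = 1000)
  expect_equal(nrow(simulateReads(pgA, pgB, peaks, cfg, nReads = 0)), 0)

  n <- 8000
  reads <- simulateReads(pgA, pgB, peaks, cfg, nReads = n)
  # reads are exact substrings of their source haplotype
  i <- which(reads$trueHap == "B")[1:50]
  bSeq <- as.character(genomeSequence(pgB)[[1]])
  expect_true(all(vapply(i, function(k) {
    st <- mapPositions(coordinateMap(pgB), "chrS", reads$refStart[k],
                       "to_strain")$pos
    substring(bSeq, st, st + nchar(reads$seq[k]) - 1) == reads$seq[k]
  }, TRUE)))

  # exact enumeration oracle for the variant-spanning fraction: over every
  # legal read start in every feature, the fraction of 40-mers covering a
  # SNP; compared against the closed form 1 - (1 - d)^L as a sanity bound
  v <- variantRecords(sim$variants)
  pExp <- mean(unlist(lapply(seq_along(peaks), function(f) {
    s0 <- GenomicRanges::start(peaks)[f]
    e0 <- GenomicRanges::end(peaks)[f] - cfg@readLength + 1
    starts <- s0:e0
    vapply(starts, function(st)
      any(v$pos >= st & v$pos <= st + cfg@readLength - 1), TRUE)
  })))
  pObs <- mean(reads$informative)
  expect_lt(abs(pObs - pExp), 3 * sqrt(pExp * (1 - pExp) / n))
  pClosed <- 1 - (1 - cfg@snpDensity)^cfg@readLength
  expect_lt(abs(pExp - pClosed), 0.05)
})

test_that("design counts enforce the planted class semantics through
          their generating means", {
  cfg <- SimulationConfig(nFeatures = 3000, seed = 24)
  truth <- makeTruthTable(cfg)
  se <- simulateDesignCounts(truth, cfg)
  counts <- SummarizedExperiment::assay(se)
  cd <- SummarizedExperiment::colData(se)
  grpMean <- function(arm, grp)
    rowMeans(counts[, cd$arm == arm & cd$group == grp, drop = FALSE])
  ratio <- function(arm) {
    r <- log2(grpMean(arm, "A") / grpMean(arm, "B"))
    ifelse(truth$true_direction == "B", -r, r)
  }
  avgRatio <- function(cls, arm) mean(ratio(arm)[truth$true_class == cls])

  # same: all arms at the configured NB mean, no bias anywhere
  sameMean <- rowMeans(counts[truth$true_class == "same",
                              cd$arm == "F0", drop = FALSE])
  nSame <- sum(truth$true_class == "same") * sum(cd$arm == "F0")
  seMean <- sqrt((500 + 0.05 * 500^2) / nSame)
  expect_lt(abs(mean(sameMean) - 500), 3 * seMean)
  expect_lt(abs(avgRatio("same", "F0")), 0.1)

  # cis: planted fold change in every arm
  for (arm in c("F0", "F1_allele", "F0_NSG", "F1_NSG_allele"))
    expect_lt(abs(avgRatio("cis", arm) - cfg@effectLog2fc), 0.15)
  # trans environmental: F0 only; the chimera contrast is balanced
  expect_lt(abs(avgRatio("trans_environmental", "F0") - 2), 0.15)
  expect_lt(abs(avgRatio("trans_environmental", "F0_NSG")), 0.1)
  expect_lt(abs(avgRatio("trans_environmental", "F1_allele")), 0.1)
  # trans cell-autonomous: persists in the chimera, no allelic bias
  expect_lt(abs(avgRatio("trans_cellautonomous", "F0_NSG") - 2), 0.2)
  expect_lt(abs(avgRatio("trans_cellautonomous", "F1_NSG_allele")), 0.1)
  # mixed: allelic arms only
  expect_lt(abs(avgRatio("mixed", "F1_allele") - 2), 0.15)
  expect_lt(abs(avgRatio("mixed", "F0")), 0.1)

  expect_error(simulateDesignCounts(
    data.frame(feature_id = "x", true_class = "bogus",
               true_direction = "A"), cfg), "unknown class")
})

test_that("ligand network simulator plants one enriched ligand and is
          seed-deterministic", {
  cfg <- SimulationConfig(seed = 25)
  l1 <- simulateLigandNetwork(20, 200, enrichment = 1, config = cfg)
  l2 <- simulateLigandNetwork(20, 200, enrichment = 1, config = cfg)
  expect_identical(l1$prior, l2$prior)
  l3 <- simulateLigandNetwork(20, 200, enrichment = 1,
                              config = SimulationConfig(seed = 26))
  expect_false(identical(l1$prior, l3$prior))
  expect_error(simulateLigandNetwork(1, 100, config = cfg), "at least 2")

  # planted enrichment elevates the active ligand's prior on the DE set
  onTarget <- mean(l1$prior[l1$activeLigand, l1$deGenes])
  offTarget <- mean(l1$prior[l1$activeLigand,
                             setdiff(colnames(l1$prior), l1$deGenes)])
  expect_gt(onTarget - offTarget, 0.5)

  # with enrichment 0 the active ligand is indistinguishable
  l0 <- simulateLigandNetwork(20, 200, enrichment = 0, config = cfg)
  sc <- scoreLigandActivity(l0$prior, l0$deGenes, colnames(l0$prior))
  expect_gt(min(rank(-sc)[l0$activeLigand], na.rm = TRUE), 0)
  expect_lt(abs(mean(sc)), 0.1)
})
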