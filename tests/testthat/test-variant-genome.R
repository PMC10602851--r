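test_that("pseudogenome substitution, splicing and coordinate maps follow
          the variant records", {
  # single SNP
  pg <- buildPseudogenome(tinyRef("ACGTACGT"),
                          tinyVariants(list(pos = 2, ref = "C", alt = "A")))
  expect_equal(as.character(genomeSequence(pg))[["chr1"]], "AAGTACGT")

  # empty table: identity
  pg0 <- buildPseudogenome(tinyRef("ACGTACGT"), VariantTable(),
                           strain = "B")
  expect_equal(as.character(genomeSequence(pg0))[["chr1"]], "ACGTACGT")
  m <- mapPositions(coordinateMap(pg0), "chr1", 1:8, "to_strain")
  expect_equal(m$pos, 1:8)
  expect_false(any(m$deleted))

  # insertion: ACGT + (pos 2, C -> CTT) = ACTTGT; ref pos 3 -> strain pos 5
  pgI <- buildPseudogenome(tinyRef("ACGT"),
                           tinyVariants(list(pos = 2, ref = "C",
                                             alt = "CTT")))
  expect_equal(as.character(genomeSequence(pgI))[["chr1"]], "ACTTGT")
  expect_equal(mapPositions(coordinateMap(pgI), "chr1", 3, "to_strain")$pos,
               5)

  # deletion: ACGTAC + (pos 2, CGT -> C) = ACAC; deleted ref positions snap
  pgD <- buildPseudogenome(tinyRef("ACGTAC"),
                           tinyVariants(list(pos = 2, ref = "CGT",
                                             alt = "C")))
  expect_equal(as.character(genomeSequence(pgD))[["chr1"]], "ACAC")
  md <- mapPositions(coordinateMap(pgD), "chr1", c(3, 4, 5), "to_strain")
  expect_equal(md$pos, c(2, 2, 3))
  expect_equal(md$deleted, c(TRUE, TRUE, FALSE))

  # corrupt VCF: ref-allele mismatch names chrom:pos
  expect_error(
    buildPseudogenome(tinyRef("ACGTACGT"),
                      tinyVariants(list(pos = 2, ref = "G", alt = "A"))),
    "chr1:2")
})

test_that("pseudogenome length invariant holds exactly on simulated
          genomes", {
  cfg <- SimulationConfig(genomeLength = 20000, seed = 5)
  sim <- simulateStrainGenomes(cfg)
  pg <- buildPseudogenome(sim$reference, sim$variants)
  v <- variantRecords(sim$variants)
  expect_equal(unname(Biostrings::width(genomeSequence(pg))),
               20000 + sum(nchar(v$alt) - nchar(v$ref)))
})

test_that("coordinate round trips are exact on random intervals", {
  cfg <- SimulationConfig(genomeLength = 50000, seed = 6)
  sim <- simulateStrainGenomes(cfg)
  map <- coordinateMap(buildPseudogenome(sim$reference, sim$variants))
  set.seed(42)
  starts <- sample(49000, 1000)
  gr <- GenomicRanges::GRanges("chrS",
                               IRanges::IRanges(starts, starts + 99))
  sh <- shiftInterval(map, gr, "to_strain")
  ok <- !sh$deletedStart & !sh$deletedEnd
  back <- shiftInterval(map, sh[ok], "to_reference")
  expect_gt(sum(ok), 900)
  expect_equal(GenomicRanges::start(back), starts[ok])
  expect_equal(GenomicRanges::end(back), starts[ok] + 99)

  # identity map leaves intervals unchanged
  mapId <- coordinateMap(buildPseudogenome(sim$reference, VariantTable(),
                                           strain = "A"))
  shId <- shiftInterval(mapId, gr, "to_strain")
  expect_equal(GenomicRanges::start(shId), starts)

  # intervals right of an insertion shift back by its length
  pgI <- buildPseudogenome(tinyRef("ACGTACGTAC"),
                           tinyVariants(list(pos = 2, ref = "C",
                                             alt = "CTT")))
  gr2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(8, 9))
  backI <- shiftInterval(coordinateMap(pgI), gr2, "to_reference")
  expect_equal(GenomicRanges::start(backI), 6)
  expect_equal(GenomicRanges::end(backI), 7)
})

test_that("allele assignment follows the perfect-match spanning-variant
          rule", {
  ref <- tinyRef(paste(rep("ACGTTGCA", 8), collapse = ""))  # 64 bp
  vt <- tinyVariants(list(pos = 20, ref = "T", alt = "C"))
  pgA <- buildPseudogenome(ref, VariantTable(), strain = "A")
  pgB <- buildPseudogenome(ref, vt, strain = "B")
  refSeq <- as.character(ref[[1]])
  bSeq <- as.character(genomeSequence(pgB)[[1]])

  reads <- data.frame(
    read_id = c("spanA", "spanB", "nospan", "errA"),
    chrom = "chr1",
    refStart = c(15, 15, 40, 15),
    seq = c(substring(refSeq, 15, 30),        # A haplotype over the SNP
            substring(bSeq, 15, 30),          # B haplotype over the SNP
            substring(refSeq, 40, 55),        # no variant in span
            sub("T", "G", substring(refSeq, 15, 30))))  # sequencing error
  asn <- assignReadAllele(reads, pgA, pgB, vt)
  expect_equal(asn$label,
               c("allele_A", "allele_B", "unassigned", "unassigned"))
  expect_true(all(asn$n_variants_spanned[asn$label != "unassigned"] >= 1))
})

test_that("error-free simulated reads assign with perfect precision and
          recall", {
  cfg <- SimulationConfig(genomeLength = 30000, seed = 7)
  sim <- simulateStrainGenomes(cfg)
  pgA <- buildPseudogenome(sim$reference, VariantTable(), strain = "A")
  pgB <- buildPseudogenome(sim$reference, sim$variants, strain = "B")
  peaks <- simulateFeatures(cfg, n = 20, width = 1000)
  reads <- simulateReads(pgA, pgB, peaks, cfg, nReads = 2000)
  asn <- assignReadAllele(reads, pgA, pgB, sim$variants)
  assigned <- asn$label != "unassigned"
  expect_true(all(asn$label[assigned] ==
                    paste0("allele_", reads$trueHap[assigned])))
  expect_true(all(assigned[reads$informative]))
  expect_false(any(assigned[!reads$informative]))
})

test_that("sequencing errors at the discriminating base leave reads
          unassigned, never misassigned", {
  cfg <- SimulationConfig(genomeLength = 30000, seed = 8, errorRate = 0.02)
  sim <- simulateStrainGenomes(cfg)
  pgA <- buildPseudogenome(sim$reference, VariantTable(), strain = "A")
  pgB <- buildPseudogenome(sim$reference, sim$variants, strain = "B")
  peaks <- simulateFeatures(cfg, n = 20, width = 1000)
  reads <- simulateReads(pgA, pgB, peaks, cfg, nReads = 1000)
  asn <- assignReadAllele(reads, pgA, pgB, sim$variants)
  assigned <- asn$label != "unassigned"
  # errors reduce recall but can never flip a read to the wrong allele
  expect_true(all(asn$label[assigned] ==
                    paste0("allele_", reads$trueHap[assigned])))
  expect_lt(mean(assigned[reads$informative]), 1)
})

test_that("extractPeakSequences returns fixed-width windows in the
          strain frame", {
  cfg <- SimulationConfig(genomeLength = 20000, seed = 9)
  sim <- simulateStrainGenomes(cfg)
  pgA <- buildPseudogenome(sim$reference, VariantTable(), strain = "A")
  pgB <- buildPseudogenome(sim$reference, sim$variants, strain = "B")
  peaks <- simulateFeatures(cfg, n = 15, width = 600)
  sA <- extractPeakSequences(pgA, peaks, width = 200)
  sB <- extractPeakSequences(pgB, peaks, width = 200)
  expect_true(all(Biostrings::width(sA) == 200))
  expect_true(all(Biostrings::width(sB) == 200))

  # peaks in variant-free central windows are identical between strains
  v <- variantRecords(sim$variants)
  vr <- GenomicRanges::GRanges(v$chrom,
                               IRanges::IRanges(v$pos, v$pos +
                                                  nchar(v$ref) - 1))
  mid <- floor((GenomicRanges::start(peaks) + GenomicRanges::end(peaks)) / 2)
  central <- GenomicRanges::GRanges("chrS",
                                    IRanges::IRanges(mid - 110, mid + 110))
  clean <- GenomicRanges::countOverlaps(central, vr) == 0
  common <- intersect(names(sA), names(sB))
  cleanIds <- intersect(common, names(peaks)[clean])
  dirtyIds <- setdiff(common, names(peaks)[clean])
  expect_true(all(as.character(sA[cleanIds]) == as.character(sB[cleanIds])))
  expect_gt(length(dirtyIds), 0)
  expect_true(any(as.character(sA[dirtyIds]) != as.character(sB[dirtyIds])))
})

test_that("SAM ingestion keeps only perfectly matching primary
          alignments", {
  sam <- c("@HD\tVN:1.6",
           "r1\t0\tchr1\t10\t60\t8M\t*\t0\t0\tACGTACGT\tFFFFFFFF\tNM:i:0",
           "r2\t0\tchr1\t12\t60\t7M1S\t*\t0\t0\tACGTACGT\tFFFFFFFF",
           "r3\t256\tchr1\t14\t60\t8M\t*\t0\t0\tACGTACGT\tFFFFFFFF",
           "r4\t0\tchr1\t16\t60\t8M\t*\t0\t0\tACGTACGT\tFFFFFFFF\tNM:i:1",
           "r5\t4\t*\t0\t0\t*\t*\t0\t0\tACGTACGT\tFFFFFFFF")
  path <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, path)
  reads <- readSamReads(path)
  expect_equal(reads$read_id, "r1")
  expect_equal(reads$refStart, 10L)
})
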