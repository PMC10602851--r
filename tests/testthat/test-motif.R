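test_that("maximal PWM score equals the brute-force oracle and is
          reverse-complement invariant", {
  set.seed(51)
  pwms <- makeMotifSet(10, seed = 51)
  for (k in 1:100) {
    pwm <- pwms[[sample(10, 1)]]
    s <- randomSeq(sample(30:200, 1))
    expect_equal(maxPwmScore(s, pwm), bruteMaxScore(s, pwm),
                 tolerance = 1e-10)
  }
  s <- randomSeq(120)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  for (id in names(pwms)[1:5])
    expect_equal(maxPwmScore(s, pwms[[id]]), maxPwmScore(rc, pwms[[id]]),
                 tolerance = 1e-10)

  # a sequence containing the consensus attains the per-column maximum sum
  pwm <- pwms[[1]]
  cons <- paste(c("A", "C", "G", "T")[apply(pwm, 2, which.max)],
                collapse = "")
  seqC <- paste0(randomSeq(40), cons, randomSeq(40))
  expect_gte(maxPwmScore(seqC, pwm) + 1e-9,
             sum(apply(pwmLogOdds(pwm), 2, max)))
  expect_error(maxPwmScore("ACG", pwm), "shorter")

  # N bases contribute the background expectation (zero log-odds)
  expect_equal(maxPwmScore(strrep("N", 50), pwm), 0)
})

test_that("JASPAR reading handles both dialects and round-trips", {
  pwms <- makeMotifSet(3, seed = 52)
  path <- tempfile(fileext = ".jaspar")
  writeJasparMotifs(pwms, path)
  back <- readJasparMotifs(path)
  expect_equal(names(back), names(pwms))
  for (id in names(pwms))
    expect_equal(back[[id]], pwms[[id]], tolerance = 1e-6,
                 ignore_attr = TRUE)

  # bare 4-line dialect
  bare <- c(">M1 M1", "4 0 0", "0 4 0", "0 0 4", "0 0 0")
  path2 <- tempfile(fileext = ".txt")
  writeLines(bare, path2)
  m <- readJasparMotifs(path2)[["M1"]]
  expect_equal(dim(m), c(4L, 3L))
  expect_equal(unname(m[, 1]), c(1, 0, 0, 0))
})

test_that("motif landscape plants intact matches and score-destroying
          substitutions as configured", {
  pwms <- makeMotifSet(5, seed = 53)
  cfg <- SimulationConfig(seed = 53)
  target <- names(pwms)[1]
  lo <- pwmLogOdds(pwms[[target]])

  # mutated fraction 0: the target's max score is identical within every
  # pair (background substitutions sit outside the embedded motif)
  ml0 <- simulateMotifLandscape(pwms, nPairs = 50, mutatedFraction = 0,
                                config = cfg)
  d0 <- vapply(seq_len(50), function(i)
    maxPwmScore(ml0$pairs$positive[i], pwms[[target]], lo) -
      maxPwmScore(ml0$pairs$negative[i], pwms[[target]], lo), 0)
  expect_true(all(abs(d0) < 1e-9))

  # mutated fraction 0.75: ~300/400 pairs score strictly lower in the
  # negative sequence
  ml <- simulateMotifLandscape(pwms, nPairs = 400, mutatedFraction = 0.75,
                               config = cfg)
  d <- vapply(seq_len(400), function(i)
    maxPwmScore(ml$pairs$positive[i], pwms[[target]], lo) -
      maxPwmScore(ml$pairs$negative[i], pwms[[target]], lo), 0)
  expect_equal(sum(ml$truth$mutated), 300)
  expect_true(all(d[ml$truth$mutated] > 0))
  expect_equal(sum(d > 1e-9), 300)
})

test_that("the paired signed-rank statistic flags the planted motif and
          degrades gracefully", {
  pwms <- makeMotifSet(12, seed = 54)
  cfg <- SimulationConfig(seed = 54)
  ml <- simulateMotifLandscape(pwms, nPairs = 150, mutatedFraction = 0.75,
                               config = cfg)
  res <- motifMutationTest(ml$pairs, pwms)
  target <- names(pwms)[1]
  expect_equal(res$pwm[which.min(res$p)], target)
  expect_lt(res$p[res$pwm == target], 1e-6)
  expect_gt(res$median_diff[res$pwm == target], 0)
  # BH q is monotone in p
  ord <- order(res$p)
  expect_true(all(diff(res$q[ord]) >= -1e-12))

  # swapping positive and negative negates the median and keeps p
  swapped <- ml$pairs
  names(swapped)[names(swapped) == "positive"] <- "tmp"
  names(swapped)[names(swapped) == "negative"] <- "positive"
  names(swapped)[names(swapped) == "tmp"] <- "negative"
  res2 <- motifMutationTest(swapped, pwms[target])
  expect_equal(res2$median_diff, -res$median_diff[res$pwm == target],
               tolerance = 1e-9)
  expect_equal(res2$p, res$p[res$pwm == target], tolerance = 1e-9)

  # identical pairs are untestable
  same <- data.frame(pair_id = "p1", positive = randomSeq(100))
  same$negative <- same$positive
  resNA <- motifMutationTest(same, pwms[1])
  expect_true(is.na(resNA$p))
  expect_equal(resNA$n_nonzero_pairs, 0L)
})

test_that("sequence pairs concatenate all ordered strain comparisons", {
  cfg <- SimulationConfig(genomeLength = 30000, seed = 55)
  sim <- simulateStrainGenomes(cfg)
  genomes <- list(
    A = buildPseudogenome(sim$reference, VariantTable(), strain = "A"),
    B = buildPseudogenome(sim$reference, sim$variants, strain = "B"))
  peaks <- simulateFeatures(cfg, n = 10, width = 600)
  sets <- list(A_B = peaks[1:4], B_A = peaks[5:10])
  pairs <- buildSequencePairs(sets, genomes, width = 200)
  expect_equal(nrow(pairs), 10)
  expect_equal(as.integer(table(pairs$comparison)[c("A_B", "B_A")]),
               c(4L, 6L))
  expect_true(all(nchar(pairs$positive) == 200))
  # a peak with no variants in its window yields identical sequences
  expect_true(any(pairs$positive == pairs$negative) ||
                all(pairs$positive != pairs$negative))
})

test_that("variant-frequency rows recover planted local variation", {
  cfg <- SimulationConfig(genomeLength = 2e5, seed = 56)
  sim <- simulateStrainGenomes(cfg)
  peaks <- simulateFeatures(cfg, n = 190, width = 1000)
  se <- simulateVariantPeakCounts(peaks, sim$variants, cfg)
  d <- nbDifferential(se, c("group", "A", "B"))
  vf <- variantFrequencyByFoldChange(peaks, list(ATAC = d), sim$variants)
  expect_equal(rownames(vf), c("similar", ">2", ">4", ">8"))
  vals <- vf[, "ATAC"]
  # monotone non-decreasing across cutoffs when effects are variant-driven
  expect_true(all(diff(vals[!is.na(vals)]) >= 0))
  # every differential peak carries a planted variant
  expect_gt(vals[">2"], 95)
  # the similar row sits at the background variant rate of the truth
  truthBg <- mean(SummarizedExperiment::rowData(se)$hasVariant[
    SummarizedExperiment::rowData(se)$plantedLfc == 0])
  n0 <- attr(vf, "n")["similar", "ATAC"]
  expect_lt(abs(vals["similar"] / 100 - truthBg),
            3 * sqrt(truthBg * (1 - truthBg) / n0) + 0.02)
  # no variants anywhere: all rows zero
  vf0 <- variantFrequencyByFoldChange(peaks, list(ATAC = d),
                                      VariantTable())
  expect_true(all(vf0[!is.na(vf0)] == 0))
})
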