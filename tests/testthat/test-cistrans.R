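test_that("cis/trans classification follows the two-axis quadrant logic", {
  ids <- paste0("g", 1:6)
  f0 <- makeDiff(ids, c(2, 2, 0.1, 0.1, 2, 2),
                 c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))
  f1 <- makeDiff(ids, c(1.8, 0.2, 1.5, 0.1, -1.8, 1.8),
                 c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE))
  out <- classifyCisTrans(f0, f1)
  expect_equal(out$class,
               c("cis", "trans", "mixed", "same", "discordant", "cis"))
  expect_equal(out$direction[1:4], c("A", "A", "A", "none"))
  # every tested feature gets exactly one class
  expect_equal(nrow(out), 6)
  expect_false(anyNA(out$class))

  # swapping allele labels flips directions, preserves class membership
  f0s <- f0; f0s$log2fc <- -f0s$log2fc
  f1s <- f1; f1s$log2fc <- -f1s$log2fc
  sw <- classifyCisTrans(f0s, f1s)
  expect_equal(sw$class, out$class)
  flip <- c(A = "B", B = "A", none = "none")
  expect_equal(sw$direction, unname(flip[out$direction]))

  # features missing from one input are excluded with a warning
  expect_warning(classifyCisTrans(f0[1:4, ], f1), "excluded")
})

test_that("autonomy decomposition follows the cis -> environmental ->
          cell-autonomous decision list", {
  ids <- paste0("g", 1:5)
  f0 <- makeDiff(ids, rep(2, 5), c(TRUE, TRUE, TRUE, TRUE, FALSE))
  f0Nsg <- makeDiff(ids, c(0.1, 0.1, 2, 2, 0.1),
                    c(FALSE, FALSE, TRUE, TRUE, FALSE))
  f1Nsg <- makeDiff(ids, c(1.8, 0.1, 0.1, -1.8, 0.1),
                    c(TRUE, FALSE, FALSE, TRUE, FALSE))
  out <- classifyAutonomy(f0, f0Nsg, f1Nsg)
  # g1: allelic bias in the F1 chimera, same sign -> cis
  # g2: difference gone in the F0 chimera -> environmental
  # g3: persists in F0 chimera, no allelic imbalance -> cell-autonomous
  # g4: persists but discordant allelic bias -> unresolved
  # g5: not strain-specific in F0 -> not classified at all
  expect_equal(out$calls$class,
               c("cis", "trans_environmental", "trans_cellautonomous",
                 "unresolved"))
  expect_equal(out$calls$feature_id, ids[1:4])
  expect_equal(unname(out$proportions), c(0.5, 0.5))
})

test_that("stimulus responses split into shared, strain-specific and
          nonresponsive", {
  ids <- paste0("g", 1:4)
  respA <- makeDiff(ids, c(6, 5, 0.2, 0.1),
                    c(TRUE, TRUE, FALSE, FALSE))
  respB <- makeDiff(ids, c(5.8, 0.2, 4, 0.1),
                    c(TRUE, FALSE, TRUE, FALSE))
  out <- classifyStimulusResponse(respA, respB)
  expect_equal(out$label, c("shared_response", "strainA_specific",
                            "strainB_specific", "nonresponsive"))
})

test_that("basal partitioning keys on the non-responsive strain's
          baseline", {
  ids <- paste0("g", 1:3)
  resp <- data.frame(feature_id = ids,
                     label = rep("strainA_specific", 3))
  # log2fc of A over B at baseline; B is the non-responsive strain
  basal <- makeDiff(ids, c(0.1, -2, 2), c(FALSE, TRUE, TRUE))
  out <- partitionBasalState(resp, basal)
  expect_equal(out$category, c("equal_basal", "high_basal", "low_basal"))

  # non-strain-specific features are rejected
  respMix <- data.frame(feature_id = c(ids, "g4"),
                        label = c(rep("strainA_specific", 3),
                                  "shared_response"))
  out2 <- partitionBasalState(respMix, basal)
  expect_false("g4" %in% out2$feature_id)
})

test_that("basal-by-regulation association is Pearson chi-squared without
          continuity correction", {
  # exactly proportional table: no association
  basal <- data.frame(feature_id = paste0("g", 1:40),
                      category = rep(c("equal_basal", "high_basal"),
                                     each = 20))
  reg <- data.frame(feature_id = paste0("g", 1:40),
                    class = rep(c("cis", "trans", "cis", "trans"),
                                each = 10))
  out <- basalCisTransAssociation(basal, reg)
  expect_equal(out$chi2, 0)
  expect_equal(out$p, 1)
  expect_equal(out$df, 1)

  # hand-computed 2x2 [[30,10],[10,30]]: chi2 = 20, p ~ 7.7e-6
  basal2 <- data.frame(feature_id = paste0("g", 1:80),
                       category = rep(c("equal_basal", "high_basal"),
                                      each = 40))
  reg2 <- data.frame(feature_id = paste0("g", 1:80),
                     class = rep(c("cis", "trans", "cis", "trans"),
                                 times = c(30, 10, 10, 30)))
  out2 <- basalCisTransAssociation(basal2, reg2)
  expect_equal(out2$chi2, 20)
  expect_equal(out2$p, 7.744216e-06, tolerance = 1e-4)

  expect_error(basalCisTransAssociation(
    data.frame(feature_id = "x", category = "equal_basal"),
    data.frame(feature_id = "y", class = "cis")), "empty intersection")
})

test_that("regulation classes recover planted truth on the full design
          simulation", {
  cfg <- SimulationConfig(
    nFeatures = 600, seed = 33,
    classProportions = c(cis = 0.25, trans_environmental = 0.25,
                         mixed = 0.25, same = 0.25))
  truth <- makeTruthTable(cfg)
  se <- simulateDesignCounts(truth, cfg, arms = c("F0", "F1_allele"))
  dF0 <- nbDifferential(se[, se$arm == "F0"], c("group", "A", "B"))
  dF1 <- nbDifferential(se[, se$arm == "F1_allele"], c("group", "A", "B"),
                        paired = TRUE)
  reg <- classifyCisTrans(dF0, dF1)
  tm <- merge(truth, reg, by = "feature_id")
  tm$coarse <- sub("trans_environmental", "trans", tm$true_class)
  rec <- vapply(c("cis", "trans", "mixed", "same"), function(k)
    mean(tm$class[tm$coarse == k] == k), 0)
  expect_true(all(rec > 0.85))
  # the classes partition the tested universe
  expect_equal(sum(table(reg$class)), nrow(reg))
  expect_equal(nrow(reg), cfg@nFeatures)
  # direction recovery for regulated features
  called <- tm[tm$class %in% c("cis", "trans", "mixed"), ]
  expect_gt(mean(called$direction == called$true_direction), 0.95)
})
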