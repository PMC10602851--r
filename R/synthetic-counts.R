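#' Draw a truth table of planted regulation classes
#'
#' Assigns each feature one regulation class from the configured mixture
#' (\code{cis}, \code{trans_environmental}, \code{trans_cellautonomous},
#' \code{mixed}, \code{same}) and, for regulated classes, the favored
#' strain.
#'
#' @param config a \linkS4class{SimulationConfig}
#' @param nFeatures number of features (default \code{config@nFeatures})
#' @return data.frame with columns \code{feature_id}, \code{true_class},
#'   \code{true_direction} (\code{"A"}, \code{"B"} or \code{"none"}),
#'   \code{planted_motif_mutation} (\code{NA}; reserved)
#' @export
makeTruthTable <- function(config, nFeatures = config@nFeatures) {
  set.seed(config@seed + 3L)
  n <- as.integer(nFeatures)
  cls <- sample(names(config@classProportions), n, replace = TRUE,
                prob = config@classProportions)
  dir <- ifelse(cls == "same", "none", sample(c("A", "B"), n, replace = TRUE))
  data.frame(feature_id = sprintf("feat%05d", seq_len(n)),
             true_class = cls, true_direction = dir,
             planted_motif_mutation = NA_character_)
}

## Per-arm bias indicator for each regulation class. An arm is "biased" when
## its A:B (or allelic) contrast carries the planted fold change.
classBiasPattern <- function(cls) {
  switch(cls,
    cis                  = c(F0 = TRUE,  F1_allele = TRUE,
                             F0_NSG = TRUE,  F1_NSG_allele = TRUE),
    trans_environmental  = c(F0 = TRUE,  F1_allele = FALSE,
                             F0_NSG = FALSE, F1_NSG_allele = FALSE),
    trans_cellautonomous = c(F0 = TRUE,  F1_allele = FALSE,
                             F0_NSG = TRUE,  F1_NSG_allele = FALSE),
    mixed                = c(F0 = FALSE, F1_allele = TRUE,
                             F0_NSG = FALSE, F1_NSG_allele = TRUE),
    same                 = c(F0 = FALSE, F1_allele = FALSE,
                             F0_NSG = FALSE, F1_NSG_allele = FALSE),
    stop("unknown class label: ", cls))
}

#' Simulate design-arm count matrices with planted regulation classes
#'
#' Generates negative-binomial counts (\code{var = mu + alpha mu^2}) for
#' the full experimental design: parental F0 strains, F1 hybrid alleles,
#' F0 chimera (NSG host) strains and F1 chimera alleles. Class semantics
#' are enforced through the generating means: \code{cis} features carry
#' the planted fold change in every arm's contrast,
#' \code{trans_environmental} only in F0, \code{trans_cellautonomous} in
#' F0 and F0-NSG but neither allelic arm, \code{mixed} only in the allelic
#' arms, and \code{same} nowhere. Strain arms are centered on
#' \code{meanDepth}; allelic arms on \code{meanDepth / 2} per allele. The
#' planted ratio is applied symmetrically (favored group times
#' \code{2^(lfc/2)}, other divided by it).
#'
#' @param truth truth table from \code{\link{makeTruthTable}}
#' @param config a \linkS4class{SimulationConfig} (needs \code{reps >= 2})
#' @param arms design arms to generate
#' @return a \link[SummarizedExperiment]{SummarizedExperiment} with assay
#'   \code{"counts"}, the truth table as \code{rowData}, and a
#'   \code{colData} design (\code{arm}, \code{group}, \code{replicate},
#'   \code{treatment})
#' @export
simulateDesignCounts <- function(truth, config,
                                 arms = c("F0", "F1_allele", "F0_NSG",
                                          "F1_NSG_allele")) {
  stopifnot(is(config, "SimulationConfig"))
  if (config@reps < 2)
    stop("at least 2 replicates per arm are required")
  set.seed(config@seed + 4L)
  n <- nrow(truth)
  half <- 2^(config@effectLog2fc / 2)
  size <- 1 / config@nbDispersion

  design <- expand.grid(replicate = seq_len(config@reps),
                        group = c("A", "B"), arm = arms,
                        stringsAsFactors = FALSE)[, 3:1]
  design$treatment <- "basal"
  design$sample <- paste(design$arm, design$group, design$replicate, sep = "_")

  bias <- t(vapply(truth$true_class, classBiasPattern, logical(4)))
  counts <- matrix(0L, n, nrow(design),
                   dimnames = list(truth$feature_id, design$sample))
  for (j in seq_len(nrow(design))) {
    arm <- design$arm[j]
    base <- if (grepl("allele", arm)) config@meanDepth / 2 else config@meanDepth
    fold <- ifelse(bias[, arm],
                   ifelse(truth$true_direction == design$group[j], half,
                          1 / half),
                   1)
    counts[, j] <- rnbinom(n, mu = base * fold, size = size)
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = truth,
    colData = S4Vectors::DataFrame(design, row.names = design$sample))
}

#' Simulate stimulus-response counts on basal-state archetypes
#'
#' Generates basal and stimulated counts for two parental strains plus an
#' F1 allelic arm under stimulation, with planted response categories
#' (shared, strain-specific, nonresponsive). Strain-specific responders
#' additionally carry a basal-state archetype — \code{low_basal} (the
#' non-responsive strain starts below the responsive strain),
#' \code{equal_basal}, or \code{high_basal} (the non-responsive strain is
#' already high at baseline) — and a regulation class (\code{cis}: the
#' stimulated strain difference is mirrored by the F1 alleles;
#' \code{trans}: the alleles are balanced). The probability of \code{cis}
#' can depend on the basal category, planting a basal-state by cis/trans
#' association.
#'
#' @param config a \linkS4class{SimulationConfig}; \code{responseLog2fc}
#'   sets the stimulated fold change, \code{effectLog2fc} the basal offset
#' @param nFeatures number of features
#' @param categoryProportions mixture over \code{shared},
#'   \code{A_specific}, \code{B_specific}, \code{nonresponsive}
#' @param basalProportions mixture over \code{low_basal},
#'   \code{equal_basal}, \code{high_basal} for strain-specific responders
#' @param cisGivenBasal per-category probability that a strain-specific
#'   responder is \code{cis} regulated
#' @return list with \code{se}: a
#'   \link[SummarizedExperiment]{SummarizedExperiment} (strain arms with
#'   \code{treatment} basal/LPS, plus \code{F1_allele} samples under LPS)
#'   whose \code{rowData} is the truth, and \code{truth}: the same truth
#'   as a data.frame
#' @export
simulateStimulusCounts <- function(config, nFeatures = 400,
                                   categoryProportions = c(
                                     shared = 0.10, A_specific = 0.125,
                                     B_specific = 0.125,
                                     nonresponsive = 0.65),
                                   basalProportions = c(
                                     low_basal = 0.15, equal_basal = 0.60,
                                     high_basal = 0.25),
                                   cisGivenBasal = c(
                                     low_basal = 0.25, equal_basal = 0.75,
                                     high_basal = 0.25)) {
  set.seed(config@seed + 5L)
  n <- as.integer(nFeatures)
  mu <- config@meanDepth
  size <- 1 / config@nbDispersion
  rr <- 2^config@responseLog2fc
  bb <- 2^config@effectLog2fc

  cat_ <- sample(names(categoryProportions), n, replace = TRUE,
                 prob = categoryProportions)
  specific <- cat_ %in% c("A_specific", "B_specific")
  basal <- rep(NA_character_, n)
  basal[specific] <- sample(names(basalProportions), sum(specific),
                            replace = TRUE, prob = basalProportions)
  reg <- rep(NA_character_, n)
  reg[specific] <- ifelse(runif(sum(specific)) <
                            cisGivenBasal[basal[specific]], "cis", "trans")

  # generating means per strain and state
  basalA <- basalB <- rep(mu, n)
  trtA <- trtB <- rep(mu, n)
  respStrainA <- cat_ %in% c("shared", "A_specific")
  respStrainB <- cat_ %in% c("shared", "B_specific")
  trtA[respStrainA] <- mu * rr
  trtB[respStrainB] <- mu * rr
  nonResp <- ifelse(cat_ == "A_specific", "B",
                    ifelse(cat_ == "B_specific", "A", NA))
  hi <- specific & basal %in% "high_basal"
  lo <- specific & basal %in% "low_basal"
  basalA[hi & nonResp == "A"] <- mu * bb
  basalB[hi & nonResp == "B"] <- mu * bb
  basalA[lo & nonResp == "A"] <- mu / bb
  basalB[lo & nonResp == "B"] <- mu / bb
  trtA[specific & nonResp == "A"] <- basalA[specific & nonResp == "A"]
  trtB[specific & nonResp == "B"] <- basalB[specific & nonResp == "B"]

  # F1 alleles under stimulation: cis mirrors the strain contrast,
  # trans balances the alleles at the mean stimulated level
  alleleA <- alleleB <- (trtA + trtB) / 4
  isCis <- specific & reg == "cis"
  alleleA[isCis] <- trtA[isCis] / 2
  alleleB[isCis] <- trtB[isCis] / 2

  design <- rbind(
    expand.grid(replicate = seq_len(config@reps), group = c("A", "B"),
                treatment = c("basal", "LPS"), arm = "F0",
                stringsAsFactors = FALSE),
    expand.grid(replicate = seq_len(config@reps), group = c("A", "B"),
                treatment = "LPS", arm = "F1_allele",
                stringsAsFactors = FALSE))
  design <- design[, c("arm", "group", "replicate", "treatment")]
  design$sample <- paste(design$arm, design$group, design$treatment,
                         design$replicate, sep = "_")
  ids <- sprintf("gene%05d", seq_len(n))
  counts <- matrix(0L, n, nrow(design), dimnames = list(ids, design$sample))
  for (j in seq_len(nrow(design))) {
    m <- if (design$arm[j] == "F1_allele") {
      if (design$group[j] == "A") alleleA else alleleB
    } else if (design$treatment[j] == "basal") {
      if (design$group[j] == "A") basalA else basalB
    } else {
      if (design$group[j] == "A") trtA else trtB
    }
    counts[, j] <- rnbinom(n, mu = m, size = size)
  }
  truth <- data.frame(feature_id = ids, response_class = cat_,
                      basal_category = basal, regulation = reg,
                      responsive_strain = ifelse(cat_ == "A_specific", "A",
                                          ifelse(cat_ == "B_specific", "B",
                                                 NA)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = truth,
    colData = S4Vectors::DataFrame(design, row.names = design$sample))
  list(se = se, truth = truth)
}

#' Simulate variant-driven differential peak counts
#'
#' Plants strain-differential accessibility only at peaks that harbor a
#' variant within their central window: a configurable fraction of
#' variant-bearing peaks receives a planted fold change (magnitudes drawn
#' from \code{plantedLfcs}, direction random), all remaining peaks are
#' strain-similar. Used to exercise the variant-frequency-by-fold-change
#' summary, where the differential rows should recover 100% local
#' variation and the similar row the genomic background rate.
#'
#' @param peaks reference-frame \link[GenomicRanges]{GRanges}
#' @param variants a \linkS4class{VariantTable}
#' @param config a \linkS4class{SimulationConfig}
#' @param diffFraction fraction of variant-bearing peaks made differential
#' @param plantedLfcs planted |log2FC| magnitudes sampled per peak
#' @param window central window (bases) in which a variant marks the peak
#' @return a \link[SummarizedExperiment]{SummarizedExperiment} (two strain
#'   groups, \code{config@reps} replicates) with \code{rowData} columns
#'   \code{hasVariant} and \code{plantedLfc}
#' @export
simulateVariantPeakCounts <- function(peaks, variants, config,
                                      diffFraction = 0.5,
                                      plantedLfcs = c(1.5, 2.5, 3.5),
                                      window = 200) {
  set.seed(config@seed + 6L)
  v <- variantRecords(variants)
  mid <- floor((GenomicRanges::start(peaks) + GenomicRanges::end(peaks)) / 2)
  central <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(peaks),
    IRanges::IRanges(mid - window / 2, mid + window / 2 - 1))
  hasVar <- if (nrow(v)) {
    vr <- GenomicRanges::GRanges(
      v$chrom, IRanges::IRanges(v$pos, v$pos + pmax(nchar(v$ref),
                                                    nchar(v$alt)) - 1))
    GenomicRanges::countOverlaps(central, vr) > 0
  } else rep(FALSE, length(peaks))
  n <- length(peaks)
  lfc <- rep(0, n)
  idx <- which(hasVar)
  nd <- round(diffFraction * length(idx))
  if (nd > 0) {
    sel <- sample(idx, nd)
    lfc[sel] <- sample(plantedLfcs, nd, replace = TRUE) *
      sample(c(-1, 1), nd, replace = TRUE)
  }
  size <- 1 / config@nbDispersion
  design <- expand.grid(replicate = seq_len(config@reps),
                        group = c("A", "B"), stringsAsFactors = FALSE)
  design$arm <- "F0"; design$treatment <- "basal"
  design$sample <- paste("F0", design$group, design$replicate, sep = "_")
  ids <- if (!is.null(names(peaks))) names(peaks)
         else paste0("peak", seq_len(n))
  counts <- matrix(0L, n, nrow(design), dimnames = list(ids, design$sample))
  for (j in seq_len(nrow(design))) {
    sgn <- if (design$group[j] == "A") 1 else -1
    counts[, j] <- rnbinom(n, mu = config@meanDepth * 2^(sgn * lfc / 2),
                           size = size)
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = data.frame(feature_id = ids, hasVariant = hasVar,
                         plantedLfc = lfc),
    colData = S4Vectors::DataFrame(design, row.names = design$sample))
}
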