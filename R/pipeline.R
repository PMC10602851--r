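configToList <- function(config) {
  list(genomeLength = config@genomeLength, chromName = config@chromName,
       snpDensity = config@snpDensity, indelFraction = config@indelFraction,
       maxIndelLen = config@maxIndelLen, nFeatures = config@nFeatures,
       featureWidth = config@featureWidth, readLength = config@readLength,
       errorRate = config@errorRate, meanDepth = config@meanDepth,
       nbDispersion = config@nbDispersion,
       effectLog2fc = config@effectLog2fc,
       responseLog2fc = config@responseLog2fc,
       classProportions = as.list(config@classProportions),
       reps = config@reps, seed = config@seed)
}

configFromList <- function(x) {
  SimulationConfig(genomeLength = x$genomeLength, chromName = x$chromName,
                   snpDensity = x$snpDensity,
                   indelFraction = x$indelFraction,
                   maxIndelLen = x$maxIndelLen, nFeatures = x$nFeatures,
                   featureWidth = x$featureWidth,
                   readLength = x$readLength, errorRate = x$errorRate,
                   meanDepth = x$meanDepth,
                   nbDispersion = x$nbDispersion,
                   effectLog2fc = x$effectLog2fc,
                   responseLog2fc = x$responseLog2fc,
                   classProportions = unlist(x$classProportions),
                   reps = x$reps, seed = x$seed)
}

fixtureMeta <- function(config) {
  c(seed = as.character(config@seed),
    config = configHash(paste(deparse(configToList(config)),
                              collapse = "")))
}

## number of genome-anchored peaks that fit the configured genome
nGenomePeaks <- function(config, cap = 96) {
  min(floor(config@genomeLength / (config@featureWidth + 2)) - 1, cap)
}

#' Generate the on-disk synthetic fixture bundle
#'
#' Writes every input the pipeline consumes — reference FASTA, strain VCF,
#' peak BED, simulated reads, design-arm and stimulus count matrices with
#' sample metadata, variant-driven peak counts, JASPAR motif library with
#' paired sequences, ligand network tables — along with all planted truth
#' tables and the configuration, so \code{\link{runPipeline}} can execute
#' end to end from plain-text files.
#'
#' @param dir output directory (created; must be empty unless
#'   \code{overwrite})
#' @param config a \linkS4class{SimulationConfig}; the seed fully
#'   determines the bundle
#' @param nReads simulated reads for the allele-assignment stage
#' @param nMotifPairs,mutatedFraction motif landscape scale
#' @param nLigands,nLigandGenes ligand network scale
#' @param overwrite allow writing into a non-empty directory
#' @return invisibly, the named vector of written paths
#' @export
generateFixtures <- function(dir, config = SimulationConfig(),
                             nReads = 10000, nMotifPairs = 200,
                             mutatedFraction = 0.75, nLigands = 50,
                             nLigandGenes = 500, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite)
    stop("directory ", dir, " is not empty; pass overwrite = TRUE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- fixtureMeta(config)
  p <- function(f) file.path(dir, f)

  yaml::write_yaml(configToList(config), p("config.yaml"))

  sim <- simulateStrainGenomes(config)
  Biostrings::writeXStringSet(sim$reference, p("reference.fa"))
  writeVariantVcf(sim$variants, p("variants.vcf"),
                  setNames(config@genomeLength, config@chromName))
  peaks <- simulateFeatures(config, n = nGenomePeaks(config))
  writePeaksBed(peaks, p("peaks.bed"))

  pgA <- buildPseudogenome(sim$reference, VariantTable(), strain = "A")
  pgB <- buildPseudogenome(sim$reference, sim$variants, strain = "B")
  reads <- simulateReads(pgA, pgB, peaks, config, nReads = nReads)
  writeTsv(reads, p("reads.tsv"), meta)

  truth <- makeTruthTable(config)
  se <- simulateDesignCounts(truth, config)
  writeCountsTsv(SummarizedExperiment::assay(se), p("counts.tsv"), meta)
  writeTsv(as.data.frame(SummarizedExperiment::colData(se)),
           p("samples.tsv"), meta)
  writeTsv(truth, p("truth_classes.tsv"), meta)

  stim <- simulateStimulusCounts(config)
  writeCountsTsv(SummarizedExperiment::assay(stim$se),
                 p("stim_counts.tsv"), meta)
  writeTsv(as.data.frame(SummarizedExperiment::colData(stim$se)),
           p("stim_samples.tsv"), meta)
  writeTsv(stim$truth, p("stim_truth.tsv"), meta)

  pwms <- makeMotifSet(20, seed = config@seed + 9L)
  writeJasparMotifs(pwms, p("pwms.jaspar"))
  ml <- simulateMotifLandscape(pwms, nPairs = nMotifPairs,
                               mutatedFraction = mutatedFraction,
                               config = config)
  writeTsv(ml$pairs, p("motif_pairs.tsv"), meta)
  writeTsv(ml$truth, p("motif_truth.tsv"), meta)

  atac <- simulateVariantPeakCounts(peaks, sim$variants, config)
  writeCountsTsv(SummarizedExperiment::assay(atac), p("atac_counts.tsv"),
                 meta)
  writeTsv(as.data.frame(SummarizedExperiment::colData(atac)),
           p("atac_samples.tsv"), meta)
  writeTsv(as.data.frame(SummarizedExperiment::rowData(atac)),
           p("atac_truth.tsv"), meta)

  lig <- simulateLigandNetwork(nLigands, nLigandGenes, config = config)
  writeTsv(data.frame(ligand = rownames(lig$prior), lig$prior,
                      check.names = FALSE), p("ligand_prior.tsv"), meta)
  writeTsv(lig$receptorMap, p("ligand_receptors.tsv"), meta)
  writeTsv(data.frame(ligand = rownames(lig$senderTpm), lig$senderTpm),
           p("sender_tpm.tsv"), meta)
  writeTsv(data.frame(gene = names(lig$receiverTpm),
                      tpm = lig$receiverTpm), p("receiver_tpm.tsv"), meta)
  writeTsv(data.frame(gene = lig$deGenes), p("ligand_de.tsv"), meta)
  writeTsv(data.frame(active_ligand = lig$activeLigand),
           p("ligand_truth.tsv"), meta)

  files <- list.files(dir, full.names = TRUE)
  invisible(setNames(files, basename(files)))
}

armDiff <- function(counts, design, arm, contrast, thresholds,
                    paired = FALSE) {
  sel <- design$arm == arm
  nbDifferential(counts[, design$sample[sel], drop = FALSE], contrast,
                 design = design[sel, , drop = FALSE],
                 thresholds = thresholds, paired = paired)
}

#' Run the full pipeline on a fixture bundle
#'
#' Executes the stages in dependency order — pseudogenome construction and
#' allelic read assignment; per-arm differential/allelic-bias tests;
#' cis/trans and autonomy classification; stimulus-response
#' classification, basal-state partition and basal-by-regulation
#' association; motif-mutation testing; variant-frequency summary; ligand
#' activity scoring; recovery evaluation against the planted truth — and
#' writes one tab-delimited table per result plus a run manifest. Every
#' output carries the run seed and a config hash in its header. A failed
#' stage aborts, leaving a manifest that records the failure point.
#'
#' @param fixtureDir directory written by \code{\link{generateFixtures}}
#' @param outDir output directory (created)
#' @param thresholds a \linkS4class{Thresholds}
#' @return invisibly, the manifest list
#' @export
runPipeline <- function(fixtureDir, outDir, thresholds = Thresholds()) {
  need <- c("config.yaml", "reference.fa", "variants.vcf", "peaks.bed",
            "reads.tsv", "counts.tsv", "samples.tsv", "stim_counts.tsv",
            "stim_samples.tsv", "pwms.jaspar", "motif_pairs.tsv",
            "atac_counts.tsv", "atac_samples.tsv", "ligand_prior.tsv",
            "ligand_receptors.tsv", "sender_tpm.tsv", "receiver_tpm.tsv",
            "ligand_de.tsv")
  missing <- need[!file.exists(file.path(fixtureDir, need))]
  if (length(missing))
    stop("missing fixture file(s): ", paste(missing, collapse = ", "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  config <- configFromList(yaml::read_yaml(file.path(fixtureDir,
                                                     "config.yaml")))
  meta <- fixtureMeta(config)
  fx <- function(f) file.path(fixtureDir, f)
  out <- function(f) file.path(outDir, f)
  manifest <- list(seed = config@seed, config = unname(meta["config"]),
                   stages = list())
  finishStage <- function(name, n) {
    manifest$stages[[name]] <<- list(status = "complete", n = n)
  }
  writeManifest <- function() {
    yaml::write_yaml(manifest, out("manifest.yaml"))
  }
  runStage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      writeManifest()
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  env <- new.env()
  runStage("pseudogenome", {
    ref <- Biostrings::readDNAStringSet(fx("reference.fa"))
    names(ref) <- vapply(strsplit(names(ref), "\\s+"), `[[`, "", 1)
    env$variants <- readVariantVcf(fx("variants.vcf"))
    env$pgA <- buildPseudogenome(ref, VariantTable(), strain = "A")
    env$pgB <- buildPseudogenome(ref, env$variants, strain = "B")
    env$peaks <- readPeaksBed(fx("peaks.bed"))
    finishStage("pseudogenome", nrow(variantRecords(env$variants)))
  })
  runStage("assign", {
    reads <- readTsv(fx("reads.tsv"))
    env$assign <- assignReadAllele(reads, env$pgA, env$pgB, env$variants)
    writeTsv(env$assign, out("assignments.tsv"), meta)
    finishStage("assign", nrow(env$assign))
  })
  runStage("differential", {
    counts <- readCountsTsv(fx("counts.tsv"))
    design <- readTsv(fx("samples.tsv"))
    gc <- c("group", "A", "B")
    env$dF0 <- armDiff(counts, design, "F0", gc, thresholds)
    env$dF1 <- armDiff(counts, design, "F1_allele", gc, thresholds,
                       paired = TRUE)
    env$dF0N <- armDiff(counts, design, "F0_NSG", gc, thresholds)
    env$dF1N <- armDiff(counts, design, "F1_NSG_allele", gc, thresholds,
                        paired = TRUE)
    writeTsv(env$dF0, out("diff_F0.tsv"), meta)
    writeTsv(env$dF1, out("diff_F1_allele.tsv"), meta)
    writeTsv(env$dF0N, out("diff_F0_NSG.tsv"), meta)
    writeTsv(env$dF1N, out("diff_F1_NSG_allele.tsv"), meta)
    finishStage("differential", nrow(env$dF0))
  })
  runStage("cistrans", {
    env$reg <- classifyCisTrans(env$dF0, env$dF1, thresholds)
    writeTsv(env$reg, out("cistrans_calls.tsv"), meta)
    finishStage("cistrans", nrow(env$reg))
  })
  runStage("autonomy", {
    env$aut <- classifyAutonomy(env$dF0, env$dF0N, env$dF1N, thresholds)
    writeTsv(env$aut$calls, out("autonomy_calls.tsv"), meta)
    writeTsv(data.frame(class = names(env$aut$proportions),
                        proportion = unname(env$aut$proportions)),
             out("autonomy_proportions.tsv"), meta)
    finishStage("autonomy", nrow(env$aut$calls))
  })
  runStage("stimulus", {
    counts <- readCountsTsv(fx("stim_counts.tsv"))
    design <- readTsv(fx("stim_samples.tsv"))
    subDiff <- function(sel, contrast, paired = FALSE)
      nbDifferential(counts[, design$sample[sel], drop = FALSE], contrast,
                     design = design[sel, , drop = FALSE],
                     thresholds = thresholds, paired = paired)
    respA <- subDiff(design$arm == "F0" & design$group == "A",
                     c("treatment", "LPS", "basal"))
    respB <- subDiff(design$arm == "F0" & design$group == "B",
                     c("treatment", "LPS", "basal"))
    basal <- subDiff(design$arm == "F0" & design$treatment == "basal",
                     c("group", "A", "B"))
    lpsF0 <- subDiff(design$arm == "F0" & design$treatment == "LPS",
                     c("group", "A", "B"))
    lpsF1 <- subDiff(design$arm == "F1_allele", c("group", "A", "B"),
                     paired = TRUE)
    env$resp <- classifyStimulusResponse(respA, respB, thresholds)
    env$basalCat <- partitionBasalState(env$resp, basal, thresholds)
    env$lpsReg <- classifyCisTrans(lpsF0, lpsF1, thresholds)
    env$assoc <- basalCisTransAssociation(env$basalCat, env$lpsReg)
    writeTsv(env$resp, out("lps_response.tsv"), meta)
    writeTsv(env$basalCat, out("basal_categories.tsv"), meta)
    writeTsv(env$lpsReg, out("lps_cistrans.tsv"), meta)
    writeTsv(as.data.frame(env$assoc$table),
             out("basal_association_table.tsv"), meta)
    writeTsv(data.frame(chi2 = env$assoc$chi2, df = env$assoc$df,
                        p = env$assoc$p),
             out("basal_association.tsv"), meta)
    finishStage("stimulus", nrow(env$basalCat))
  })
  runStage("motif", {
    pwms <- readJasparMotifs(fx("pwms.jaspar"))
    pairs <- readTsv(fx("motif_pairs.tsv"))
    env$motif <- motifMutationTest(pairs, pwms)
    writeTsv(env$motif, out("motif_results.tsv"), meta)
    finishStage("motif", nrow(env$motif))
  })
  runStage("varfreq", {
    counts <- readCountsTsv(fx("atac_counts.tsv"))
    design <- readTsv(fx("atac_samples.tsv"))
    d <- nbDifferential(counts, c("group", "A", "B"), design = design,
                        thresholds = thresholds)
    vf <- variantFrequencyByFoldChange(env$peaks, list(ATAC = d),
                                       env$variants,
                                       thresholds = thresholds)
    env$varfreq <- vf
    writeTsv(data.frame(row = rownames(vf), vf, n = attr(vf, "n")[, 1],
                        check.names = FALSE),
             out("variant_frequency.tsv"), meta)
    finishStage("varfreq", nrow(vf))
  })
  runStage("ligand", {
    pr <- readTsv(fx("ligand_prior.tsv"))
    prior <- as.matrix(pr[, -1]); rownames(prior) <- pr[[1]]
    recmap <- readTsv(fx("ligand_receptors.tsv"))
    snd <- readTsv(fx("sender_tpm.tsv"))
    senderTpm <- as.matrix(snd[, -1]); rownames(senderTpm) <- snd[[1]]
    rcv <- readTsv(fx("receiver_tpm.tsv"))
    receiverTpm <- setNames(rcv$tpm, rcv$gene)
    de <- readTsv(fx("ligand_de.tsv"))$gene
    kept <- filterCandidateLigands(prior, senderTpm, receiverTpm, recmap,
                                   tpmFloor = thresholds@ligandTpmFloor)
    expressed <- intersect(
      names(receiverTpm)[receiverTpm > thresholds@ligandTpmFloor],
      colnames(prior))
    targets <- intersect(de, expressed)
    scores <- scoreLigandActivity(prior, targets, expressed, kept)
    env$ligand <- data.frame(ligand = names(scores),
                             pearson = unname(scores))
    env$ligand <- env$ligand[order(-env$ligand$pearson), ]
    writeTsv(env$ligand, out("ligand_scores.tsv"), meta)
    finishStage("ligand", nrow(env$ligand))
  })
  runStage("evaluate", {
    env$scorecard <- evaluateRecovery(fixtureDir, outDir)
    finishStage("evaluate", nrow(env$scorecard))
  })
  writeManifest()
  invisible(manifest)
}

#' Score pipeline outputs against the planted truth
#'
#' Compares the pipeline's result tables with the fixture bundle's truth
#' tables and emits a scorecard: allelic-assignment precision and recall,
#' regulation-class macro recall, recovered autonomy proportions, the
#' planted motif's rank and p, basal-partition accuracy and association
#' p, and the planted ligand's rank.
#'
#' @param fixtureDir fixture bundle directory
#' @param outDir pipeline output directory (results must exist)
#' @return data.frame scorecard (\code{metric}, \code{value}), also
#'   written to \code{outDir/scorecard.tsv}
#' @export
evaluateRecovery <- function(fixtureDir, outDir) {
  fx <- function(f) readTsv(file.path(fixtureDir, f))
  ot <- function(f) readTsv(file.path(outDir, f))
  sc <- list()

  reads <- fx("reads.tsv")
  asn <- ot("assignments.tsv")
  m <- merge(reads, asn, by = "read_id")
  assigned <- m$label != "unassigned"
  correct <- m$label == paste0("allele_", m$trueHap)
  sc$assignment_precision <- if (any(assigned))
    mean(correct[assigned]) else NA
  sc$assignment_recall <- mean(assigned[m$informative])

  truth <- fx("truth_classes.tsv")
  reg <- ot("cistrans_calls.tsv")
  tm <- merge(truth, reg, by = "feature_id")
  tm$coarse <- ifelse(grepl("^trans", tm$true_class), "trans",
                      tm$true_class)
  rec <- vapply(c("cis", "trans", "mixed", "same"), function(k)
    mean(tm$class[tm$coarse == k] == k), 0)
  sc$cistrans_macro_recall <- mean(rec)

  props <- ot("autonomy_proportions.tsv")
  sc$autonomy_environmental <-
    props$proportion[props$class == "environmental"]
  sc$autonomy_cellautonomous <-
    props$proportion[props$class == "cellautonomous"]

  mt <- fx("motif_truth.tsv")
  target <- unique(mt$planted_motif_mutation[!is.na(mt$planted_motif_mutation)])
  mo <- ot("motif_results.tsv")
  if (length(target)) {
    sc$motif_target_rank <- rank(mo$p, ties.method = "min")[mo$pwm == target]
    sc$motif_target_log10p <- log10(mo$p[mo$pwm == target])
  }

  st <- fx("stim_truth.tsv")
  bc <- ot("basal_categories.tsv")
  bm <- merge(st, bc, by = "feature_id")
  bm <- bm[!is.na(bm$basal_category), , drop = FALSE]
  sc$basal_partition_accuracy <- mean(bm$category == bm$basal_category)
  sc$basal_association_p <- ot("basal_association.tsv")$p

  lt <- fx("ligand_truth.tsv")$active_ligand
  ls <- ot("ligand_scores.tsv")
  sc$ligand_active_rank <- which(ls$ligand == lt)

  scorecard <- data.frame(metric = names(sc),
                          value = unname(vapply(sc, as.numeric, 0)))
  writeTsv(scorecard, file.path(outDir, "scorecard.tsv"))
  scorecard
}
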