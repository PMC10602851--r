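#' @import methods
#' @importFrom stats rnbinom rpois runif rbinom rlnorm rgamma rnorm median var
#'   p.adjust pnorm chisq.test wilcox.test cor sd setNames model.matrix
#'   quantile lm coef complete.cases
#' @importFrom utils read.delim write.table head
NULL

setClassUnion("integerOrNumeric", c("integer", "numeric"))

#' Simulation configuration
#'
#' Holds every tunable parameter of the synthetic-data generator: haplotype
#' geometry (genome length, variant density, indel fraction and maximum
#' length), the read simulator (read length, sequencing error rate), the
#' count simulator (features, replicates, negative-binomial mean and
#' dispersion, planted absolute log2 fold change, class mixture), and the
#' seed that fully determines all output.
#'
#' The negative-binomial parameterization is \code{var = mu + alpha * mu^2}
#' with a single dispersion \code{nbDispersion} (alpha).
#'
#' @slot genomeLength reference length in bases
#' @slot chromName chromosome name used throughout the synthetic genome
#' @slot snpDensity expected variants per base between the two haplotypes
#' @slot indelFraction fraction of variants that are indels, in [0,1]
#' @slot maxIndelLen maximum inserted/deleted length in bases
#' @slot nFeatures number of simulated features (genes or peaks)
#' @slot featureWidth width in bases of simulated features
#' @slot readLength simulated read length in bases
#' @slot errorRate per-base substitution error rate for simulated reads
#' @slot meanDepth expected counts per feature (NB mean mu)
#' @slot nbDispersion NB dispersion alpha
#' @slot effectLog2fc planted absolute log2 fold change for biased features
#' @slot responseLog2fc planted log2 fold change of stimulus responses
#' @slot classProportions named fractions over regulation classes
#'   (\code{cis}, \code{trans_environmental}, \code{trans_cellautonomous},
#'   \code{mixed}, \code{same}); must sum to 1
#' @slot reps replicates per design arm and group
#' @slot seed integer seed; same seed and config give byte-identical output
#' @export
setClass("SimulationConfig", representation(
  genomeLength    = "integerOrNumeric",
  chromName       = "character",
  snpDensity      = "numeric",
  indelFraction   = "numeric",
  maxIndelLen     = "integerOrNumeric",
  nFeatures       = "integerOrNumeric",
  featureWidth    = "integerOrNumeric",
  readLength      = "integerOrNumeric",
  errorRate       = "numeric",
  meanDepth       = "numeric",
  nbDispersion    = "numeric",
  effectLog2fc    = "numeric",
  responseLog2fc  = "numeric",
  classProportions = "numeric",
  reps            = "integerOrNumeric",
  seed            = "integerOrNumeric"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  frac <- c(indelFraction = object@indelFraction, errorRate = object@errorRate)
  bad <- frac < 0 | frac > 1
  if (any(bad))
    msg <- c(msg, paste0(names(frac)[bad], " must lie in [0,1]"))
  if (abs(sum(object@classProportions) - 1) > 1e-8)
    msg <- c(msg, "classProportions must sum to 1")
  if (any(object@classProportions < 0))
    msg <- c(msg, "classProportions must be non-negative")
  known <- c("cis", "trans_environmental", "trans_cellautonomous", "mixed", "same")
  if (!all(names(object@classProportions) %in% known))
    msg <- c(msg, paste("unknown class label in classProportions; allowed:",
                        paste(known, collapse = ", ")))
  pos <- c(genomeLength = object@genomeLength, nFeatures = object@nFeatures,
           featureWidth = object@featureWidth, readLength = object@readLength,
           meanDepth = object@meanDepth, nbDispersion = object@nbDispersion,
           reps = object@reps, maxIndelLen = object@maxIndelLen)
  if (any(pos <= 0))
    msg <- c(msg, paste0(names(pos)[pos <= 0], " must be positive"))
  if (object@snpDensity < 0) msg <- c(msg, "snpDensity must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' Defaults are the package's reference study conditions: a 100-kb
#' haplotype pair differing at 1 variant per 150 bp (10% indels, up to
#' 6 bp), 2,000 features at NB mean 500 with dispersion 0.05, planted
#' |log2FC| of 2, 3 replicates per arm, and a balanced regulation-class
#' mixture whose trans mass is split 60:40 between environmental and
#' cell-autonomous effects.
#'
#' @param genomeLength,chromName,snpDensity,indelFraction,maxIndelLen
#'   haplotype geometry; see slots
#' @param nFeatures,featureWidth,readLength,errorRate feature/read geometry
#' @param meanDepth,nbDispersion,effectLog2fc,responseLog2fc count model
#' @param classProportions named mixture over regulation classes
#' @param reps replicates per arm and group
#' @param seed integer seed
#' @return a validated \linkS4class{SimulationConfig}
#' @examples
#' cfg <- SimulationConfig(genomeLength = 2e4, seed = 7)
#' @export
SimulationConfig <- function(genomeLength = 1e5, chromName = "chrS",
                             snpDensity = 1 / 150, indelFraction = 0.1,
                             maxIndelLen = 6, nFeatures = 2000,
                             featureWidth = 1000, readLength = 40,
                             errorRate = 0, meanDepth = 500,
                             nbDispersion = 0.05, effectLog2fc = 2,
                             responseLog2fc = 5,
                             classProportions = c(cis = 0.25,
                                                  trans_environmental = 0.15,
                                                  trans_cellautonomous = 0.10,
                                                  mixed = 0.25, same = 0.25),
                             reps = 3, seed = 1) {
  new("SimulationConfig", genomeLength = genomeLength, chromName = chromName,
      snpDensity = snpDensity, indelFraction = indelFraction,
      maxIndelLen = maxIndelLen, nFeatures = nFeatures,
      featureWidth = featureWidth, readLength = readLength,
      errorRate = errorRate, meanDepth = meanDepth,
      nbDispersion = nbDispersion, effectLog2fc = effectLog2fc,
      responseLog2fc = responseLog2fc, classProportions = classProportions,
      reps = reps, seed = seed)
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat("  genome:", object@genomeLength, "bp (", object@chromName, "),",
      "variant density", signif(object@snpDensity, 3),
      ", indel fraction", object@indelFraction, "\n")
  cat("  counts:", object@nFeatures, "features, NB(mu =", object@meanDepth,
      ", alpha =", object@nbDispersion, "), |log2FC| =", object@effectLog2fc,
      ",", object@reps, "reps/arm\n")
  cat("  classes:",
      paste(names(object@classProportions), object@classProportions,
            sep = "=", collapse = " "), "\n")
  cat("  seed:", object@seed, "\n")
})

#' Analysis thresholds
#'
#' The significance and abundance cutoffs used throughout the differential
#' and classification machinery. All comparisons against these values are
#' strict inequalities.
#'
#' @slot fcThreshold absolute log2 fold-change cutoff (default 1)
#' @slot alpha adjusted-p cutoff (default 0.05)
#' @slot minTpm TPM expression floor for RNA features (default 8)
#' @slot minTags normalized-tag floor defining accessible peaks (default 16)
#' @slot activeTags normalized-tag floor defining active peaks (default 32)
#' @slot tagNormTotal per-library normalized tag total (default 1e7)
#' @slot tpmTotal TPM column total (1e6)
#' @slot ligandTpmFloor TPM floor for ligand/receptor expression (default 10)
#' @slot targetLog2fc log2 fold-change floor for ligand target genes
#'   (default 2)
#' @export
setClass("Thresholds", representation(
  fcThreshold = "numeric", alpha = "numeric", minTpm = "numeric",
  minTags = "numeric", activeTags = "numeric", tagNormTotal = "numeric",
  tpmTotal = "numeric", ligandTpmFloor = "numeric", targetLog2fc = "numeric"))

setValidity("Thresholds", function(object) {
  v <- c(object@fcThreshold, object@alpha, object@minTpm, object@minTags,
         object@activeTags, object@tagNormTotal, object@tpmTotal,
         object@ligandTpmFloor, object@targetLog2fc)
  if (any(v <= 0)) "all thresholds must be positive" else TRUE
})

#' Construct a Thresholds object
#'
#' @param fcThreshold,alpha,minTpm,minTags,activeTags,tagNormTotal,tpmTotal,ligandTpmFloor,targetLog2fc
#'   see the class slots for meanings and defaults
#' @return a validated \linkS4class{Thresholds}
#' @examples
#' th <- Thresholds()
#' th <- Thresholds(alpha = 0.01)
#' @export
Thresholds <- function(fcThreshold = 1, alpha = 0.05, minTpm = 8,
                       minTags = 16, activeTags = 32, tagNormTotal = 1e7,
                       tpmTotal = 1e6, ligandTpmFloor = 10,
                       targetLog2fc = 2) {
  new("Thresholds", fcThreshold = fcThreshold, alpha = alpha,
      minTpm = minTpm, minTags = minTags, activeTags = activeTags,
      tagNormTotal = tagNormTotal, tpmTotal = tpmTotal,
      ligandTpmFloor = ligandTpmFloor, targetLog2fc = targetLog2fc)
}

setMethod("show", "Thresholds", function(object) {
  cat("Thresholds: |log2FC| >", object@fcThreshold, ", padj <", object@alpha,
      "\n  TPM >", object@minTpm, "; tags >", object@minTags,
      "(accessible), >", object@activeTags, "(active)",
      "\n  ligand/receptor TPM >", object@ligandTpmFloor,
      ", target log2FC >", object@targetLog2fc, "\n")
})

#' Per-strain variant table
#'
#' SNP and short-indel alleles anchored to 1-based reference coordinates,
#' VCF-style: indel records share their first (anchor) base between REF and
#' ALT. Records are sorted by (chrom, pos) and may not overlap on the
#' reference within a strain.
#'
#' @slot variants data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{ref}, \code{alt}, \code{strain}
#' @export
setClass("VariantTable", representation(variants = "data.frame"))

setValidity("VariantTable", function(object) {
  v <- object@variants
  need <- c("chrom", "pos", "ref", "alt", "strain")
  if (!all(need %in% names(v)))
    return(paste("variants must have columns:", paste(need, collapse = ", ")))
  if (nrow(v) == 0) return(TRUE)
  if (!all(grepl("^[ACGT]+$", v$ref)) || !all(grepl("^[ACGT]+$", v$alt)))
    return("alleles must be uppercase strings over A, C, G, T")
  if (any(v$ref == v$alt)) return("alt alleles must differ from ref")
  if (any(v$pos < 1)) return("positions are 1-based and must be >= 1")
  for (s in unique(v$strain)) {
    vs <- v[v$strain == s, , drop = FALSE]
    for (ch in unique(vs$chrom)) {
      vc <- vs[vs$chrom == ch, , drop = FALSE]
      if (is.unsorted(vc$pos, strictly = TRUE))
        return("records must be sorted by (chrom, pos) with unique positions")
      if (nrow(vc) > 1) {
        ends <- vc$pos + nchar(vc$ref) - 1
        if (any(vc$pos[-1] <= ends[-nrow(vc)]))
          return("variant records overlap on the reference")
      }
    }
  }
  TRUE
})

#' Construct a VariantTable
#'
#' @param variants data.frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{strain}; rows are sorted internally
#' @return a validated \linkS4class{VariantTable}
#' @export
VariantTable <- function(variants = data.frame(chrom = character(),
                                               pos = integer(),
                                               ref = character(),
                                               alt = character(),
                                               strain = character())) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (nrow(variants))
    variants <- variants[order(variants$strain, variants$chrom, variants$pos), ,
                         drop = FALSE]
  rownames(variants) <- NULL
  variants$pos <- as.integer(variants$pos)
  new("VariantTable", variants = variants)
}

setMethod("show", "VariantTable", function(object) {
  v <- object@variants
  cat("VariantTable:", nrow(v), "records,",
      length(unique(v$strain)), "strain(s)\n")
  if (nrow(v)) {
    isIndel <- nchar(v$ref) != nchar(v$alt)
    cat("  SNVs:", sum(!isIndel), " indels:", sum(isIndel), "\n")
    print(head(v, 4))
  }
})

#' @describeIn VariantTable-class the underlying records as a data.frame
#' @param x a VariantTable
#' @export
variantRecords <- function(x) {
  stopifnot(is(x, "VariantTable"))
  x@variants
}

#' @describeIn VariantTable-class subset records to one strain
#' @param strain strain identifier
#' @export
variantsForStrain <- function(x, strain) {
  VariantTable(x@variants[x@variants$strain == strain, , drop = FALSE])
}

#' Reference/strain coordinate map
#'
#' Piecewise offset map between reference and strain coordinate frames,
#' stored as one alignment block per variant (reference span, strain span).
#' Mapping is strictly monotone on positions that exist in both frames;
#' positions deleted in the destination frame snap to the nearest left
#' anchor and are flagged.
#'
#' @slot blocks named list (per chrom) of data.frames with columns
#'   \code{refStart}, \code{refLen}, \code{strainStart}, \code{strainLen}
#' @slot refLengths,strainLengths named chromosome lengths in each frame
#' @export
setClass("CoordinateMap", representation(
  blocks = "list", refLengths = "numeric", strainLengths = "numeric"))

setValidity("CoordinateMap", function(object) {
  for (ch in names(object@blocks)) {
    b <- object@blocks[[ch]]
    if (nrow(b) > 1 &&
        (is.unsorted(b$refStart, strictly = TRUE) ||
         is.unsorted(b$strainStart, strictly = TRUE)))
      return("blocks must be strictly increasing in both frames")
  }
  if (!identical(sort(names(object@refLengths)),
                 sort(names(object@strainLengths))))
    return("refLengths and strainLengths must cover the same chromosomes")
  TRUE
})

setMethod("show", "CoordinateMap", function(object) {
  nb <- sum(vapply(object@blocks, nrow, 0L))
  cat("CoordinateMap:", length(object@refLengths), "chromosome(s),",
      nb, "variant block(s)\n")
  for (ch in names(object@refLengths))
    cat("  ", ch, ": reference ", object@refLengths[[ch]], " bp -> strain ",
        object@strainLengths[[ch]], " bp\n", sep = "")
})

#' Strain pseudogenome
#'
#' A strain's haplotype sequence obtained by substituting its SNP and indel
#' alleles into the reference, together with the coordinate map relating
#' the two frames and provenance.
#'
#' @slot sequence \link[Biostrings]{DNAStringSet} of per-chromosome sequence
#' @slot strain strain identifier
#' @slot sourceId identifier of the source reference assembly
#' @slot map the \linkS4class{CoordinateMap} produced alongside the sequence
#' @export
setClass("PseudoGenome", representation(
  sequence = "ANY", strain = "character", sourceId = "character",
  map = "CoordinateMap"))

setValidity("PseudoGenome", function(object) {
  if (!is(object@sequence, "DNAStringSet"))
    return("sequence must be a DNAStringSet")
  w <- Biostrings::width(object@sequence)
  names(w) <- names(object@sequence)
  sl <- object@map@strainLengths[names(w)]
  if (any(w != sl))
    return("sequence lengths disagree with the coordinate map")
  TRUE
})

setMethod("show", "PseudoGenome", function(object) {
  cat("PseudoGenome for strain", object@strain,
      "(source:", paste0(object@sourceId, ")"), "\n")
  show(object@map)
})

#' @describeIn PseudoGenome-class the haplotype sequence
#' @param x a PseudoGenome
#' @export
genomeSequence <- function(x) {
  stopifnot(is(x, "PseudoGenome"))
  x@sequence
}

#' @describeIn PseudoGenome-class the reference/strain coordinate map
#' @export
coordinateMap <- function(x) {
  stopifnot(is(x, "PseudoGenome"))
  x@map
}

#' @describeIn PseudoGenome-class the strain identifier
#' @export
strainId <- function(x) {
  stopifnot(is(x, "PseudoGenome"))
  x@strain
}
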