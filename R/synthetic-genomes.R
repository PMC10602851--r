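randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a reference and per-strain variant tables
#'
#' Generates a random reference haplotype and plants SNPs and short indels
#' for the variant-carrying strain at the configured density. Strain
#' \code{"A"} is the reference haplotype itself (no variants), mirroring
#' the common practice of using the reference assembly as one strain's
#' genome; strain \code{"B"} carries all planted variants, so the
#' between-strain differences equal B's table. The variant count is
#' Poisson(\code{snpDensity * genomeLength}); indels (VCF-style, anchor
#' base shared) are capped at \code{maxIndelLen} bases and records never
#' overlap.
#'
#' @param config a \linkS4class{SimulationConfig}
#' @return list with elements \code{reference}
#'   (\link[Biostrings]{DNAStringSet}), \code{variants}
#'   (\linkS4class{VariantTable} for strain B) and \code{strains}
#'   (\code{c("A","B")})
#' @export
simulateStrainGenomes <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  if (config@genomeLength < 1000)
    stop("genomeLength must be >= 1000")
  set.seed(config@seed)
  L <- as.integer(config@genomeLength)
  ch <- config@chromName
  refSeq <- randomDna(L)
  reference <- Biostrings::DNAStringSet(setNames(refSeq, ch))

  expected <- config@snpDensity * L
  if (config@snpDensity == 0) {
    return(list(reference = reference, variants = VariantTable(),
                strains = c("A", "B")))
  }
  if (expected < 1)
    stop("no variants plantable: snpDensity * genomeLength < 1")
  nVar <- rpois(1, expected)
  if (nVar == 0)
    return(list(reference = reference, variants = VariantTable(),
                strains = c("A", "B")))

  # positions must leave room for the longest ref allele and never overlap
  gap <- as.integer(config@maxIndelLen) + 1L
  lo <- 2L
  hi <- L - gap
  pos <- sort(sample(lo:hi, nVar, replace = FALSE))
  for (iter in 1:200) {
    tooClose <- c(FALSE, diff(pos) <= gap)
    if (!any(tooClose)) break
    pos[tooClose] <- sample(lo:hi, sum(tooClose), replace = FALSE)
    pos <- sort(pos)
    pos <- pos[!duplicated(pos)]
    while (length(pos) < nVar) {
      pos <- sort(unique(c(pos, sample(lo:hi, nVar - length(pos)))))
    }
  }

  isIndel <- runif(nVar) < config@indelFraction
  ref <- alt <- character(nVar)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(nVar)) {
    anchor <- substring(refSeq, pos[i], pos[i])
    if (!isIndel[i]) {
      ref[i] <- anchor
      alt[i] <- sample(setdiff(bases, anchor), 1)
    } else {
      len <- sample(seq_len(config@maxIndelLen), 1)
      if (runif(1) < 0.5) {  # insertion in strain B
        ref[i] <- anchor
        alt[i] <- paste0(anchor, randomDna(len))
      } else {               # deletion in strain B
        ref[i] <- substring(refSeq, pos[i], pos[i] + len)
        alt[i] <- anchor
      }
    }
  }
  vt <- VariantTable(data.frame(chrom = ch, pos = pos, ref = ref, alt = alt,
                                strain = "B"))
  list(reference = reference, variants = vt, strains = c("A", "B"))
}

#' Lay out non-overlapping features across the synthetic genome
#'
#' Places \code{n} windows of the configured width at evenly spaced,
#' jittered reference positions. Used both as "peaks" for tag counting and
#' as the regions read pairs are drawn from.
#'
#' @param config a \linkS4class{SimulationConfig}
#' @param n number of features (default \code{config@nFeatures})
#' @param width feature width (default \code{config@featureWidth})
#' @return a named \link[GenomicRanges]{GRanges} in reference coordinates
#' @export
simulateFeatures <- function(config, n = config@nFeatures,
                             width = config@featureWidth) {
  set.seed(config@seed + 1L)
  L <- as.integer(config@genomeLength)
  n <- as.integer(n); width <- as.integer(width)
  slot <- L / n
  if (slot < width + 2)
    stop("genome too short for ", n, " non-overlapping features of width ",
         width)
  jitter <- floor(runif(n, 0, slot - width - 1))
  starts <- as.integer(floor((seq_len(n) - 1) * slot) + 1L + jitter)
  gr <- GenomicRanges::GRanges(config@chromName,
                               IRanges::IRanges(starts,
                                                width = width))
  names(gr) <- sprintf("feat%05d", seq_len(n))
  gr
}

#' Simulate error-free (or error-injected) reads from both haplotypes
#'
#' Draws reads uniformly from the supplied features, choosing the source
#' haplotype at random, and records the hidden truth: the source haplotype
#' and whether the read is allele-informative (its sequence differs from
#' the homologous span of the other haplotype). Reads are exact substrings
#' of the source haplotype unless \code{config@errorRate > 0}, in which
#' case uniform substitution errors are injected after the truth columns
#' are computed.
#'
#' @param genomeA,genomeB the two strain \linkS4class{PseudoGenome}s
#' @param features reference-frame \link[GenomicRanges]{GRanges} to draw
#'   reads from; every feature must be wider than the read length
#' @param config a \linkS4class{SimulationConfig}
#' @param nReads total number of reads
#' @return data.frame with columns \code{read_id}, \code{chrom},
#'   \code{refStart}, \code{seq}, \code{trueHap} (\code{"A"}/\code{"B"}),
#'   \code{informative} (logical truth: spans a discriminating position)
#' @export
simulateReads <- function(genomeA, genomeB, features, config,
                          nReads = 10000) {
  set.seed(config@seed + 2L)
  L <- as.integer(config@readLength)
  if (any(GenomicRanges::width(features) <= L))
    stop("readLength must be smaller than every feature width")
  if (any(GenomicRanges::end(features) >
          coordinateMap(genomeA)@refLengths[
            as.character(GenomicRanges::seqnames(features))]))
    stop("feature outside genome bounds")
  if (nReads == 0)
    return(data.frame(read_id = character(), chrom = character(),
                      refStart = integer(), seq = character(),
                      trueHap = character(), informative = logical()))
  genomes <- list(A = genomeA, B = genomeB)
  featIdx <- sample(length(features), nReads, replace = TRUE)
  hap <- sample(c("A", "B"), nReads, replace = TRUE)
  ch <- as.character(GenomicRanges::seqnames(features))[featIdx]
  out <- data.frame(read_id = sprintf("read%06d", seq_len(nReads)),
                    chrom = ch, refStart = NA_integer_,
                    seq = NA_character_, trueHap = hap,
                    informative = NA)
  for (h in c("A", "B")) {
    g <- genomes[[h]]
    other <- genomes[[setdiff(c("A", "B"), h)]]
    sel <- which(hap == h)
    if (!length(sel)) next
    fsel <- features[featIdx[sel]]
    fShift <- shiftInterval(coordinateMap(g), fsel, "to_strain")
    lo <- GenomicRanges::start(fShift)
    hi <- GenomicRanges::end(fShift) - L + 1L
    hi <- pmax(hi, lo)
    gseqs <- genomeSequence(g)
    oseqs <- genomeSequence(other)
    for (cc in unique(out$chrom[sel])) {
      idx <- sel[out$chrom[sel] == cc]
      csel <- which(out$chrom[sel] == cc)
      gseq <- as.character(gseqs[[cc]])
      oseq <- as.character(oseqs[[cc]])
      st <- lo[csel] + floor(runif(length(idx)) * (hi[csel] - lo[csel] + 1L))
      # a read start must exist in the reference frame so the assignment
      # machinery sees an invertible anchor; resample starts that fall
      # inside strain-only insertions
      for (iter in 1:50) {
        back <- mapPositions(coordinateMap(g), cc, st, "to_reference")
        bad <- back$deleted
        if (!any(bad)) break
        st[bad] <- lo[csel][bad] +
          floor(runif(sum(bad)) * (hi[csel][bad] - lo[csel][bad] + 1L))
      }
      out$refStart[idx] <- back$pos
      out$seq[idx] <- substring(gseq, st, st + L - 1L)
      oPos <- mapPositions(coordinateMap(other), cc, back$pos, "to_strain")$pos
      oSub <- substring(oseq, oPos, oPos + L - 1L)
      out$informative[idx] <- oSub != out$seq[idx]
    }
  }
  if (config@errorRate > 0) {
    bases <- c("A", "C", "G", "T")
    for (i in seq_len(nReads)) {
      hit <- which(runif(L) < config@errorRate)
      if (!length(hit)) next
      s <- strsplit(out$seq[i], "")[[1]]
      for (j in hit) s[j] <- sample(setdiff(bases, s[j]), 1)
      out$seq[i] <- paste(s, collapse = "")
    }
  }
  out
}
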