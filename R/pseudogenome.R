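#' Build a strain pseudogenome and its coordinate map
#'
#' Substitutes a strain's SNP alleles and splices its indel alleles into the
#' reference sequence, producing the strain haplotype and an invertible
#' piecewise coordinate map between the reference and strain frames. Every
#' record's REF allele is checked against the reference sequence; a mismatch
#' aborts with the offending \code{chrom:pos}, the signature of a corrupt
#' variant file.
#'
#' The strain sequence length always equals
#' \code{reference length + sum(nchar(alt) - nchar(ref))}.
#'
#' @param reference a named \link[Biostrings]{DNAStringSet} (or single
#'   \code{DNAString}, taken as chromosome \code{"chr1"})
#' @param variants a \linkS4class{VariantTable}; if it carries several
#'   strains, \code{strain} selects one
#' @param strain strain to build; defaults to the single strain present
#'   (or the value of \code{strain} with an empty table)
#' @param sourceId provenance label for the reference assembly
#' @return a \linkS4class{PseudoGenome} whose \code{\link{coordinateMap}}
#'   relates reference and strain coordinates
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGT"))
#' vt <- VariantTable(data.frame(chrom = "chr1", pos = 2, ref = "C",
#'                               alt = "A", strain = "B"))
#' pg <- buildPseudogenome(ref, vt)
#' as.character(genomeSequence(pg))  # "AAGTACGT"
#' @export
buildPseudogenome <- function(reference, variants, strain = NULL,
                              sourceId = "reference") {
  if (is(reference, "DNAString"))
    reference <- Biostrings::DNAStringSet(c(chr1 = as.character(reference)))
  if (is.character(reference))
    reference <- Biostrings::DNAStringSet(reference)
  if (is.null(names(reference)))
    names(reference) <- paste0("chr", seq_along(reference))
  v <- variantRecords(variants)
  if (is.null(strain)) {
    strain <- if (nrow(v)) unique(v$strain) else "strain"
    if (length(strain) > 1)
      stop("variants carry several strains; pass `strain` explicitly")
  }
  v <- v[v$strain == strain | nrow(v) == 0, , drop = FALSE]

  blocks <- list()
  seqs <- character(length(reference))
  names(seqs) <- names(reference)
  refLengths <- strainLengths <- setNames(numeric(length(reference)),
                                          names(reference))
  for (ch in names(reference)) {
    refSeq <- as.character(reference[[ch]])
    refLen <- nchar(refSeq)
    vc <- v[v$chrom == ch, , drop = FALSE]
    vc <- vc[order(vc$pos), , drop = FALSE]
    if (nrow(vc)) {
      obs <- substring(refSeq, vc$pos, vc$pos + nchar(vc$ref) - 1)
      bad <- which(obs != vc$ref)
      if (length(bad))
        stop("ref allele mismatch at ", ch, ":", vc$pos[bad[1]],
             " (expected '", vc$ref[bad[1]], "', reference has '",
             obs[bad[1]], "')")
      if (any(vc$pos + nchar(vc$ref) - 1 > refLen))
        stop("variant extends past the end of ", ch)
    }
    parts <- character(2 * nrow(vc) + 1)
    cursor <- 1L           # next unwritten reference position
    offset <- 0L           # cumulative strain - reference offset
    strainStarts <- integer(nrow(vc))
    if (nrow(vc)) for (i in seq_len(nrow(vc))) {
      parts[2 * i - 1] <- substring(refSeq, cursor, vc$pos[i] - 1L)
      parts[2 * i] <- vc$alt[i]
      strainStarts[i] <- vc$pos[i] + offset
      offset <- offset + nchar(vc$alt[i]) - nchar(vc$ref[i])
      cursor <- vc$pos[i] + nchar(vc$ref[i])
    }
    parts[length(parts)] <- substring(refSeq, cursor, refLen)
    seqs[[ch]] <- paste(parts, collapse = "")
    blocks[[ch]] <- data.frame(refStart = vc$pos,
                               refLen = nchar(vc$ref),
                               strainStart = strainStarts,
                               strainLen = nchar(vc$alt))
    refLengths[[ch]] <- refLen
    strainLengths[[ch]] <- refLen + offset
    stopifnot(nchar(seqs[[ch]]) == strainLengths[[ch]])
  }
  map <- new("CoordinateMap", blocks = blocks, refLengths = refLengths,
             strainLengths = strainLengths)
  new("PseudoGenome", sequence = Biostrings::DNAStringSet(seqs),
      strain = strain, sourceId = sourceId, map = map)
}

#' Map positions between reference and strain frames
#'
#' Maps 1-based positions through a \linkS4class{CoordinateMap}. Positions
#' that do not exist in the destination frame (bases deleted in the strain,
#' or bases inserted in the strain when mapping back to the reference) snap
#' to the nearest left anchor and are flagged \code{deleted}. The map is
#' the identity outside variant blocks and round-trips exactly on all
#' non-deleted positions.
#'
#' @param map a \linkS4class{CoordinateMap}
#' @param chrom chromosome name
#' @param pos integer vector of 1-based positions in the source frame
#' @param direction \code{"to_strain"} (reference input) or
#'   \code{"to_reference"} (strain input)
#' @return data.frame with columns \code{pos} (mapped) and \code{deleted}
#' @export
mapPositions <- function(map, chrom, pos,
                         direction = c("to_strain", "to_reference")) {
  direction <- match.arg(direction)
  if (!chrom %in% names(map@refLengths))
    stop("unknown chromosome: ", chrom)
  b <- map@blocks[[chrom]]
  if (direction == "to_strain") {
    srcStart <- b$refStart;    srcLen <- b$refLen
    dstStart <- b$strainStart; dstLen <- b$strainLen
  } else {
    srcStart <- b$strainStart; srcLen <- b$strainLen
    dstStart <- b$refStart;    dstLen <- b$refLen
  }
  out <- pos
  deleted <- logical(length(pos))
  if (length(srcStart)) {
    i <- findInterval(pos, srcStart)
    inBlock <- i > 0 & pos < srcStart[pmax(i, 1)] + srcLen[pmax(i, 1)]
    after <- i > 0 & !inBlock
    if (any(after)) {
      j <- i[after]
      out[after] <- pos[after] +
        (dstStart[j] + dstLen[j]) - (srcStart[j] + srcLen[j])
    }
    if (any(inBlock)) {
      j <- i[inBlock]
      k <- pos[inBlock] - srcStart[j]
      fits <- k < dstLen[j]
      out[inBlock] <- ifelse(fits, dstStart[j] + k, dstStart[j] + dstLen[j] - 1)
      deleted[inBlock] <- !fits
    }
  }
  data.frame(pos = out, deleted = deleted)
}

#' Shift intervals between coordinate frames
#'
#' Lifts genomic intervals through a \linkS4class{CoordinateMap}, mapping
#' both endpoints with \code{\link{mapPositions}}. Endpoint positions absent
#' from the destination frame snap left and are flagged.
#'
#' @param map a \linkS4class{CoordinateMap}
#' @param intervals a \link[GenomicRanges]{GRanges} (1-based, inclusive)
#' @param direction \code{"to_strain"} or \code{"to_reference"}
#' @return a GRanges in the destination frame with logical metadata columns
#'   \code{deletedStart} and \code{deletedEnd}
#' @export
shiftInterval <- function(map, intervals,
                          direction = c("to_strain", "to_reference")) {
  direction <- match.arg(direction)
  ch <- as.character(GenomicRanges::seqnames(intervals))
  starts <- GenomicRanges::start(intervals)
  ends <- GenomicRanges::end(intervals)
  ns <- ne <- integer(length(intervals))
  ds <- de <- logical(length(intervals))
  for (cc in unique(ch)) {
    sel <- ch == cc
    ms <- mapPositions(map, cc, starts[sel], direction)
    me <- mapPositions(map, cc, ends[sel], direction)
    ns[sel] <- ms$pos; ds[sel] <- ms$deleted
    ne[sel] <- me$pos; de[sel] <- me$deleted
  }
  out <- GenomicRanges::GRanges(ch, IRanges::IRanges(ns, pmax(ns, ne)))
  names(out) <- names(intervals)
  S4Vectors::mcols(out)$deletedStart <- ds
  S4Vectors::mcols(out)$deletedEnd <- de
  out
}

## Differing positions between two strains as reference-frame spans.
## With one strain identical to the reference this is simply the other
## strain's variant spans; in general it is the union of records not shared
## identically by both strains.
pairwiseDifferenceSpans <- function(variants, strainA, strainB) {
  v <- variantRecords(variants)
  v <- v[v$strain %in% c(strainA, strainB), , drop = FALSE]
  if (!nrow(v))
    return(GenomicRanges::GRanges())
  key <- paste(v$chrom, v$pos, v$ref, v$alt)
  shared <- key[v$strain == strainA][key[v$strain == strainA] %in%
                                       key[v$strain == strainB]]
  v <- v[!key %in% shared, , drop = FALSE]
  if (!nrow(v))
    return(GenomicRanges::GRanges())
  GenomicRanges::reduce(GenomicRanges::GRanges(
    v$chrom, IRanges::IRanges(v$pos, v$pos + pmax(nchar(v$ref),
                                                  nchar(v$alt)) - 1)))
}

#' Assign reads to alleles by the perfect-match spanning-variant rule
#'
#' A read (given with its mapped reference-frame start) is assigned to an
#' allele if and only if it matches that strain's haplotype exactly over the
#' homologous span, spans at least one position where the two strains
#' differ, and does not also match the other haplotype. Reads matching both
#' haplotypes (uninformative, or ambiguous near indel edges) or neither
#' (e.g. carrying a sequencing error at the discriminating base) are
#' \code{unassigned}; uninformative reads are never errors.
#'
#' @param reads data.frame with columns \code{read_id}, \code{chrom},
#'   \code{refStart} (1-based reference-frame start) and \code{seq}
#' @param genomeA,genomeB the two strain \linkS4class{PseudoGenome}s
#' @param variants \linkS4class{VariantTable} carrying both strains'
#'   records (used to count variants spanned)
#' @return data.frame with columns \code{read_id}, \code{label}
#'   (\code{allele_A}, \code{allele_B} or \code{unassigned}) and
#'   \code{n_variants_spanned}
#' @export
assignReadAllele <- function(reads, genomeA, genomeB, variants) {
  stopifnot(all(c("read_id", "chrom", "refStart", "seq") %in% names(reads)))
  n <- nrow(reads)
  lens <- nchar(reads$seq)
  matchGenome <- function(g) {
    seqs <- genomeSequence(g)
    ok <- logical(n)
    refEnd <- rep(NA_integer_, n)
    for (ch in unique(reads$chrom)) {
      sel <- which(reads$chrom == ch)
      if (!ch %in% names(seqs)) next
      gseq <- as.character(seqs[[ch]])
      m <- mapPositions(coordinateMap(g), ch, reads$refStart[sel], "to_strain")
      st <- m$pos
      en <- st + lens[sel] - 1L
      inb <- st >= 1 & en <= nchar(gseq)
      sub <- rep(NA_character_, length(sel))
      sub[inb] <- substring(gseq, st[inb], en[inb])
      ok[sel] <- !is.na(sub) & sub == reads$seq[sel]
      back <- mapPositions(coordinateMap(g), ch, en, "to_reference")
      refEnd[sel] <- back$pos
    }
    list(ok = ok, refEnd = refEnd)
  }
  mA <- matchGenome(genomeA)
  mB <- matchGenome(genomeB)
  label <- rep("unassigned", n)
  label[mA$ok & !mB$ok] <- "allele_A"
  label[mB$ok & !mA$ok] <- "allele_B"

  diffs <- pairwiseDifferenceSpans(variants, strainId(genomeA),
                                   strainId(genomeB))
  refEnd <- ifelse(label == "allele_B", mB$refEnd, mA$refEnd)
  refEnd[is.na(refEnd)] <- reads$refStart[is.na(refEnd)] +
    lens[is.na(refEnd)] - 1L
  spans <- GenomicRanges::GRanges(reads$chrom,
                                  IRanges::IRanges(reads$refStart,
                                                   pmax(reads$refStart, refEnd)))
  nSpan <- if (length(diffs)) GenomicRanges::countOverlaps(spans, diffs)
           else integer(n)
  data.frame(read_id = reads$read_id, label = label,
             n_variants_spanned = as.integer(nSpan))
}

#' Extract fixed-width peak sequences in a strain's own frame
#'
#' Lifts each peak midpoint from reference coordinates into the strain
#' frame and extracts exactly \code{width} bases of the strain haplotype
#' centered there. Peaks whose midpoint is deleted in the strain frame, or
#' whose window would run off the chromosome, are skipped with a warning.
#'
#' @param genome a \linkS4class{PseudoGenome}
#' @param peaks a \link[GenomicRanges]{GRanges} in reference coordinates
#' @param width window width in bases (default 200)
#' @return a named \link[Biostrings]{DNAStringSet}, one entry per usable
#'   peak, every sequence of length \code{width}
#' @export
extractPeakSequences <- function(genome, peaks, width = 200) {
  stopifnot(width > 0)
  map <- coordinateMap(genome)
  seqs <- genomeSequence(genome)
  ch <- as.character(GenomicRanges::seqnames(peaks))
  mid <- floor((GenomicRanges::start(peaks) + GenomicRanges::end(peaks)) / 2)
  ids <- if (!is.null(names(peaks))) names(peaks)
         else paste0("peak", seq_along(peaks))
  out <- setNames(rep(NA_character_, length(peaks)), ids)
  skipped <- 0L
  for (cc in unique(ch)) {
    sel <- which(ch == cc)
    m <- mapPositions(map, cc, mid[sel], "to_strain")
    st <- m$pos - floor(width / 2)
    en <- st + width - 1L
    ok <- !m$deleted & st >= 1 & en <= nchar(as.character(seqs[[cc]]))
    skipped <- skipped + sum(!ok)
    out[sel[ok]] <- substring(as.character(seqs[[cc]]), st[ok], en[ok])
  }
  if (skipped)
    warning(skipped, " peak(s) skipped (midpoint deleted in strain frame ",
            "or window out of bounds)")
  Biostrings::DNAStringSet(out[!is.na(out)])
}

#' Read reads from a SAM file, keeping only perfect primary alignments
#'
#' Minimal ingestion of plain-text SAM for the perfect-match assignment
#' rule: only primary alignments (FLAG bits 0x4, 0x100 and 0x800 unset)
#' whose CIGAR is a single full-length match (\code{<len>M}) and whose
#' optional \code{NM} tag, if present, is 0 are kept. Alignment nuance
#' beyond this is deliberately ignored because only perfectly matching
#' reads can be allele-informative.
#'
#' @param path path to a SAM text file
#' @return data.frame with columns \code{read_id}, \code{chrom},
#'   \code{refStart}, \code{seq}, suitable for
#'   \code{\link{assignReadAllele}}
#' @export
readSamReads <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(data.frame(read_id = character(), chrom = character(),
                      refStart = integer(), seq = character()))
  f <- strsplit(lines, "\t")
  get <- function(i) vapply(f, `[[`, "", i)
  flag <- as.integer(get(2))
  cigar <- get(6)
  seq <- get(10)
  nm <- vapply(f, function(x) {
    tag <- grep("^NM:i:", x, value = TRUE)
    if (length(tag)) as.integer(sub("^NM:i:", "", tag[1])) else 0L
  }, 0L)
  keep <- bitwAnd(flag, 0x4) == 0 & bitwAnd(flag, 0x100) == 0 &
    bitwAnd(flag, 0x800) == 0 &
    cigar == paste0(nchar(seq), "M") & nm == 0L
  data.frame(read_id = get(1)[keep], chrom = get(3)[keep],
             refStart = as.integer(get(4))[keep], seq = seq[keep])
}
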