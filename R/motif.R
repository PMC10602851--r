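revcompStr <- function(s) {
  vapply(strsplit(chartr("ACGTN", "TGCAN", s), ""), function(x)
    paste(rev(x), collapse = ""), "")
}

#' Read motifs in JASPAR format
#'
#' Parses both common JASPAR dialects: the bracketed matrix form
#' (\code{A [ 1 2 3 ]}) and the bare 4-line form (one row of numbers per
#' base, rows in A, C, G, T order). Counts (or frequencies) are
#' normalized to per-position probabilities.
#'
#' @param path path to a JASPAR-format motif file
#' @return named list of 4 x width probability matrices (rownames
#'   A, C, G, T), each position summing to 1
#' @export
readJasparMotifs <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no motif headers ('>') found in ", path)
  out <- list()
  bounds <- c(starts, length(lines) + 1L)
  for (i in seq_along(starts)) {
    header <- sub("^>\\s*", "", lines[starts[i]])
    id <- strsplit(header, "\\s+")[[1]][1]
    body <- lines[(starts[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(body) < 4) stop("motif ", id, ": expected 4 matrix rows")
    body <- body[1:4]
    rows <- lapply(body, function(l) {
      l <- sub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("\\[|\\]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1)
      stop("motif ", id, ": ragged matrix rows")
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    m <- sweep(m, 2, colSums(m), "/")
    out[[id]] <- m
  }
  out
}

#' Write motifs in JASPAR (bracketed) format
#'
#' @param motifs named list of 4 x width numeric matrices
#' @param path output path
#' @export
writeJasparMotifs <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(motifs)) {
    m <- motifs[[id]]
    writeLines(paste0(">", id, " ", id), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(paste0(b, " [ ", paste(format(m[b, ], trim = TRUE),
                                        collapse = " "), " ]"), con)
  }
}

#' Log-odds matrix of a probability PWM
#'
#' Adds a pseudocount to every cell, renormalizes columns, and takes
#' log2 odds against the background base frequencies. N bases score 0
#' (the background expectation) during scanning.
#'
#' @param pwm 4 x width probability matrix (rownames A, C, G, T)
#' @param pseudocount added to every cell before renormalization
#'   (default 0.01)
#' @param background base frequencies (default uniform 0.25)
#' @return 4 x width log2-odds matrix
#' @export
pwmLogOdds <- function(pwm, pseudocount = 0.01,
                       background = rep(0.25, 4)) {
  m <- pwm + pseudocount
  m <- sweep(m, 2, colSums(m), "/")
  log2(m / background)
}

scanOneStrand <- function(codes, lo) {
  w <- ncol(lo)
  nw <- length(codes) - w + 1L
  s <- numeric(nw)
  for (j in seq_len(w)) {
    v <- lo[, j][codes[j:(j + nw - 1L)]]
    v[is.na(v)] <- 0
    s <- s + v
  }
  s
}

#' Maximal PWM log-odds score of a sequence
#'
#' Maximum over all windows on both strands of the summed log2-odds. By
#' strand symmetry the score of a sequence equals that of its reverse
#' complement.
#'
#' @param sequence character string (or \code{DNAString}) over ACGTN; must
#'   be at least as long as the motif
#' @param pwm 4 x width probability matrix
#' @param logOdds optional precomputed \code{\link{pwmLogOdds}} matrix
#' @return the maximal log2-odds window score
#' @export
maxPwmScore <- function(sequence, pwm, logOdds = NULL) {
  s <- toupper(as.character(sequence))
  if (is.null(logOdds)) logOdds <- pwmLogOdds(pwm)
  w <- ncol(logOdds)
  if (nchar(s) < w)
    stop("sequence shorter than motif width (", w, ")")
  codes <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
  rcodes <- rev(5L - codes)   # reverse complement; NA stays NA
  max(scanOneStrand(codes, logOdds), scanOneStrand(rcodes, logOdds))
}

#' Build positive/negative sequence pairs from differential peaks
#'
#' For each ordered strain comparison (X with higher signal than Y), one
#' pair per differential peak: the positive sequence is extracted from
#' X's genome frame and the negative from Y's, both centered on the peak
#' midpoint. All comparisons are concatenated into one pair list (six
#' ordered comparisons for three strains, two for two).
#'
#' @param diffPeakSets named list of \link[GenomicRanges]{GRanges}
#'   (reference frame), names \code{"X_Y"} meaning higher in X than Y
#' @param genomes named list of per-strain \linkS4class{PseudoGenome}s
#' @param width extracted window width (default 200)
#' @return data.frame with \code{pair_id}, \code{comparison},
#'   \code{positive}, \code{negative}
#' @export
buildSequencePairs <- function(diffPeakSets, genomes, width = 200) {
  out <- list()
  for (cmp in names(diffPeakSets)) {
    xy <- strsplit(cmp, "_")[[1]]
    if (!all(xy %in% names(genomes)))
      stop("comparison ", cmp, " names unknown strains")
    peaks <- diffPeakSets[[cmp]]
    if (!length(peaks)) next
    if (is.null(names(peaks))) names(peaks) <- paste0("p", seq_along(peaks))
    pos <- extractPeakSequences(genomes[[xy[1]]], peaks, width)
    neg <- extractPeakSequences(genomes[[xy[2]]], peaks, width)
    keep <- intersect(names(pos), names(neg))
    if (!length(keep)) next
    out[[cmp]] <- data.frame(
      pair_id = paste(cmp, keep, sep = ":"), comparison = cmp,
      positive = as.character(pos[keep]), negative = as.character(neg[keep]))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Paired motif-mutation statistic over a PWM library
#'
#' For each motif, scores every pair's positive and negative sequence by
#' \code{\link{maxPwmScore}} and tests the paired differences (positive
#' minus negative) against a null centered on zero with a two-sided
#' Wilcoxon signed-rank test; zero differences are dropped first (their
#' count is reported). Motifs whose differences are all zero are
#' untestable (p = NA). Benjamini-Hochberg q values are reported across
#' motifs alongside the raw p.
#'
#' @param pairs data.frame with columns \code{positive} and
#'   \code{negative} (see \code{\link{buildSequencePairs}})
#' @param pwms named list of probability matrices
#' @param pseudocount,background passed to \code{\link{pwmLogOdds}}
#' @return data.frame, one row per motif: \code{pwm},
#'   \code{n_pairs_total}, \code{n_nonzero_pairs}, \code{median_diff},
#'   \code{statistic}, \code{p}, \code{q}
#' @export
motifMutationTest <- function(pairs, pwms, pseudocount = 0.01,
                              background = rep(0.25, 4)) {
  stopifnot(nrow(pairs) >= 1)
  n <- nrow(pairs)
  res <- data.frame(pwm = names(pwms), n_pairs_total = n,
                    n_nonzero_pairs = NA_integer_,
                    median_diff = NA_real_, statistic = NA_real_,
                    p = NA_real_)
  for (i in seq_along(pwms)) {
    lo <- pwmLogOdds(pwms[[i]], pseudocount, background)
    sp <- vapply(pairs$positive, maxPwmScore, 0, pwm = pwms[[i]],
                 logOdds = lo, USE.NAMES = FALSE)
    sn <- vapply(pairs$negative, maxPwmScore, 0, pwm = pwms[[i]],
                 logOdds = lo, USE.NAMES = FALSE)
    d <- sp - sn
    nz <- d[abs(d) > 1e-9]
    res$n_nonzero_pairs[i] <- length(nz)
    if (!length(nz)) next
    res$median_diff[i] <- median(nz)
    # exact signed-rank null for small samples (the normal approximation
    # is poorly calibrated below ~25 nonzero pairs), approximation above
    wt <- suppressWarnings(wilcox.test(nz, mu = 0,
                                       exact = length(nz) < 50,
                                       correct = TRUE))
    res$statistic[i] <- unname(wt$statistic)
    res$p[i] <- wt$p.value
  }
  res$q <- p.adjust(res$p, method = "BH")
  res
}

#' Variant frequency by fold-change cutoff
#'
#' For each assay, stratifies peaks into a strain-similar row
#' (\code{|log2FC| <= fcThreshold} and not significant) and rows of
#' increasing fold-change cutoff (significant and \code{|log2FC| >
#' log2(cutoff)}), then reports the percentage of peaks in each row that
#' harbor at least one variant within the central \code{window} bases of
#' the peak (\code{[mid - window/2, mid + window/2)}).
#'
#' @param peaks named \link[GenomicRanges]{GRanges}; names must match the
#'   diff results' \code{feature_id}
#' @param diffList named list (per assay) of \code{\link{nbDifferential}}
#'   results over the same peak universe
#' @param variants a \linkS4class{VariantTable}
#' @param window central window in bases (default 200)
#' @param cutoffs fold-change cutoffs (default 2, 4, 8)
#' @param thresholds a \linkS4class{Thresholds}
#' @return matrix of percentages, rows \code{similar, >2, >4, >8} by
#'   assay columns, with attribute \code{"n"} giving row sizes; empty rows
#'   are NA
#' @export
variantFrequencyByFoldChange <- function(peaks, diffList, variants,
                                         window = 200, cutoffs = c(2, 4, 8),
                                         thresholds = Thresholds()) {
  v <- variantRecords(variants)
  mid <- floor((GenomicRanges::start(peaks) + GenomicRanges::end(peaks)) / 2)
  central <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(peaks),
    IRanges::IRanges(mid - floor(window / 2),
                     mid + ceiling(window / 2) - 1))
  hasVar <- if (nrow(v)) {
    vr <- GenomicRanges::GRanges(
      v$chrom, IRanges::IRanges(v$pos, v$pos + pmax(nchar(v$ref),
                                                    nchar(v$alt)) - 1))
    GenomicRanges::countOverlaps(central, vr) > 0
  } else rep(FALSE, length(peaks))
  names(hasVar) <- names(peaks)
  rows <- c("similar", paste0(">", cutoffs))
  out <- matrix(NA_real_, length(rows), length(diffList),
                dimnames = list(rows, names(diffList)))
  sizes <- out
  for (a in names(diffList)) {
    d <- diffList[[a]]
    hv <- hasVar[d$feature_id]
    padj <- ifelse(is.na(d$padj), 1, d$padj)
    inRow <- list(similar = abs(d$log2fc) <= thresholds@fcThreshold &
                    padj >= thresholds@alpha)
    for (co in cutoffs)
      inRow[[paste0(">", co)]] <- d$significant & abs(d$log2fc) > log2(co)
    for (r in rows) {
      sel <- inRow[[r]] & !is.na(inRow[[r]])
      sizes[r, a] <- sum(sel)
      if (sum(sel)) out[r, a] <- 100 * mean(hv[sel])
    }
  }
  attr(out, "n") <- sizes
  out
}
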