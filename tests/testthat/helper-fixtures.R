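## Shared builders for unit tests. Everything is generated in code; no
## fixture files on disk.

tinyRef <- function(seq = "ACGTACGT", chrom = "chr1") {
  Biostrings::DNAStringSet(setNames(seq, chrom))
}

tinyVariants <- function(..., strain = "B", chrom = "chr1") {
  recs <- list(...)
  VariantTable(data.frame(
    chrom = chrom,
    pos = vapply(recs, `[[`, 0, "pos"),
    ref = vapply(recs, `[[`, "", "ref"),
    alt = vapply(recs, `[[`, "", "alt"),
    strain = strain))
}

## Minimal differential-result table with the columns the classifiers use
makeDiff <- function(feature_id, log2fc, significant,
                     padj = ifelse(significant, 1e-4, 0.5)) {
  data.frame(feature_id = feature_id, baseMean = 100, log2fc = log2fc,
             lfcSE = 0.1, stat = log2fc / 0.1, p = padj, padj = padj,
             filterPass = TRUE, significant = significant)
}

## Independent brute-force oracle for the maximal PWM score: explicit
## double loop over windows and strands with its own log-odds arithmetic.
bruteMaxScore <- function(seq, pwm, pseudocount = 0.01, bg = 0.25) {
  m <- pwm + pseudocount
  m <- sweep(m, 2, colSums(m), "/")
  lo <- log2(m / bg)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- strsplit(seq, "")[[1]]
  w <- ncol(lo)
  best <- -Inf
  for (i in seq_len(length(chars) - w + 1)) {
    fwd <- 0; rev_ <- 0
    for (j in seq_len(w)) {
      bF <- chars[i + j - 1]
      if (bF %in% rownames(lo)) fwd <- fwd + lo[bF, j]
      bR <- comp[[chars[i + w - j]]]
      if (bR %in% rownames(lo)) rev_ <- rev_ + lo[bR, j]
    }
    best <- max(best, fwd, rev_)
  }
  best
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")
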