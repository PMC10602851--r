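rowVarsBase <- function(x) {
  m <- rowMeans(x)
  rowSums((x - m)^2) / (ncol(x) - 1)
}

#' Count read 5' positions in fixed windows around feature midpoints
#'
#' A read contributes to a feature iff its 5' position lies in
#' \code{[mid - window/2, mid + window/2)} (half-open; a read exactly at
#' \code{mid + window/2} is excluded), and is counted once per feature.
#'
#' @param reads data.frame with columns \code{chrom}, \code{pos} (1-based
#'   5' position) and optionally \code{sample}; all reads lacking a
#'   \code{sample} column form one library
#' @param features a \link[GenomicRanges]{GRanges}
#' @param window window width in bases (default 1000)
#' @return integer matrix, features x samples
#' @export
countInWindows <- function(reads, features, window = 1000) {
  stopifnot(window > 0)
  mid <- floor((GenomicRanges::start(features) +
                  GenomicRanges::end(features)) / 2)
  win <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(features),
    IRanges::IRanges(mid - floor(window / 2),
                     mid + ceiling(window / 2) - 1))
  ids <- if (!is.null(names(features))) names(features)
         else paste0("feat", seq_along(features))
  if (!"sample" %in% names(reads))
    reads$sample <- rep("sample1", nrow(reads))
  samples <- sort(unique(reads$sample))
  out <- matrix(0L, length(features), length(samples),
                dimnames = list(ids, samples))
  if (!nrow(reads)) return(out)
  pts <- GenomicRanges::GRanges(reads$chrom,
                                IRanges::IRanges(reads$pos, width = 1))
  for (s in samples) {
    out[, s] <- GenomicRanges::countOverlaps(win, pts[reads$sample == s])
  }
  out
}

#' Scale each library to a fixed tag total
#'
#' Rescales every column so its sum equals \code{total}, the conventional
#' tag normalization for comparing peak signal across libraries.
#'
#' @param counts numeric matrix, features x samples
#' @param total target per-library total (default 1e7)
#' @return matrix of normalized tags; columns sum to \code{total}
#' @export
normalizeTags <- function(counts, total = 1e7) {
  cs <- colSums(counts)
  if (any(cs == 0)) stop("zero-depth sample: ",
                         paste(colnames(counts)[cs == 0], collapse = ", "))
  sweep(counts, 2, total / cs, "*")
}

#' Transcripts per million
#'
#' \code{TPM_i = 1e6 * (c_i / len_i) / sum_j (c_j / len_j)}; every column
#' sums to 1e6.
#'
#' @param counts numeric matrix, features x samples
#' @param lengths feature lengths in bases (recycled across samples)
#' @param total column total (default 1e6)
#' @return TPM matrix
#' @export
computeTpm <- function(counts, lengths, total = 1e6) {
  stopifnot(length(lengths) == nrow(counts), all(lengths > 0))
  r <- counts / lengths
  cs <- colSums(r)
  if (any(cs == 0)) stop("all-zero sample: ",
                         paste(colnames(counts)[cs == 0], collapse = ", "))
  sweep(r, 2, total / cs, "*")
}

## DESeq-style median-of-ratios size factors, with a column-sum fallback
## when no feature is positive in every sample.
medianOfRatios <- function(counts) {
  logGeo <- rowMeans(log(counts))
  use <- is.finite(logGeo)
  if (sum(use) >= 10) {
    sf <- apply(counts[use, , drop = FALSE], 2, function(col)
      exp(median(log(col[col > 0]) - logGeo[use][col > 0])))
  } else {
    cs <- colSums(counts)
    sf <- cs / exp(mean(log(cs)))
  }
  sf / exp(mean(log(sf)))
}

## Mean-dispersion trend: per-feature method-of-moments estimates are
## regressed on 1/mu (the DESeq parametric form) when the mean spread
## allows, otherwise pooled into a flat trend.
dispersionTrend <- function(amom, baseMean) {
  a <- pmax(amom, 0)
  ok <- is.finite(a) & baseMean > 1
  if (sum(ok) >= 50 && sd(log(baseMean[ok])) > 0.1) {
    fit <- tryCatch(lm(a[ok] ~ I(1 / baseMean[ok])), error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- pmax(coef(fit), 0)
      tr <- cf[1] + cf[2] / baseMean
      flat <- mean(a[ok])
      tr[!is.finite(tr)] <- flat
      return(pmax(tr, 1e-8))
    }
  }
  rep(max(mean(a[ok]), 1e-8), length(amom))
}

#' Negative-binomial Wald test for differential signal or allelic bias
#'
#' The package's internal differential engine, a deliberate simplification
#' of the DESeq2 workflow: median-of-ratios size factors; per-feature
#' method-of-moments NB dispersion shrunk toward a fitted mean-dispersion
#' trend (floor 1e-8); a Wald test on the contrast coefficient of a
#' per-feature NB log-linear model with the dispersion held at its shrunk
#' value; Benjamini-Hochberg correction across features passing the
#' abundance filter. Allelic-bias contrasts in F1 arms use the same
#' machinery with alleles as groups, optionally paired within biological
#' replicate via \code{paired = TRUE} (a replicate covariate).
#'
#' Significance requires all three of: abundance filter passed,
#' \code{padj < alpha}, and \code{|log2FC| > fcThreshold} (strict
#' inequalities).
#'
#' @param object a \link[SummarizedExperiment]{SummarizedExperiment} with a
#'   \code{"counts"} assay, or a count matrix (then supply \code{design})
#' @param contrast \code{c(variable, group1, group2)}; log2FC is
#'   group1 over group2
#' @param design data.frame of sample covariates when \code{object} is a
#'   matrix; must contain the contrast variable (and \code{replicate} if
#'   \code{paired})
#' @param thresholds a \linkS4class{Thresholds}
#' @param paired add a replicate covariate, pairing groups within
#'   biological replicate
#' @param filter abundance filter applied before BH: \code{"none"},
#'   \code{"tags"} (mean normalized tags > \code{minTags}) or \code{"tpm"}
#'   (mean TPM > \code{minTpm}; needs \code{lengths})
#' @param lengths feature lengths for the TPM filter
#' @return data.frame with one row per feature: \code{feature_id},
#'   \code{baseMean}, \code{log2fc}, \code{lfcSE}, \code{stat}, \code{p},
#'   \code{padj} (NA for filtered features) and \code{significant}
#' @examples
#' cfg <- SimulationConfig(nFeatures = 50, seed = 2)
#' se <- simulateDesignCounts(makeTruthTable(cfg), cfg, arms = "F0")
#' res <- nbDifferential(se, c("group", "A", "B"))
#' table(res$significant)
#' @export
nbDifferential <- function(object, contrast, design = NULL,
                           thresholds = Thresholds(), paired = FALSE,
                           filter = c("none", "tags", "tpm"),
                           lengths = NULL) {
  filter <- match.arg(filter)
  if (is(object, "SummarizedExperiment")) {
    counts <- SummarizedExperiment::assay(object, "counts")
    design <- as.data.frame(SummarizedExperiment::colData(object))
  } else counts <- as.matrix(object)
  stopifnot(length(contrast) == 3, !is.null(design),
            contrast[1] %in% names(design))
  sel <- design[[contrast[1]]] %in% contrast[2:3]
  counts <- counts[, sel, drop = FALSE]
  design <- design[sel, , drop = FALSE]
  grp <- factor(design[[contrast[1]]], levels = c(contrast[3], contrast[2]))
  if (any(table(grp) < 2))
    stop("both contrast groups need >= 2 replicates")
  if (any(vapply(split(seq_along(grp), grp),
                 function(j) all(counts[, j] == 0), TRUE)))
    stop("degenerate contrast: one group has zero counts for every feature")

  sf <- medianOfRatios(counts)
  norm <- sweep(counts, 2, sf, "/")
  baseMean <- rowMeans(norm)

  grpIdx <- split(seq_along(grp), grp)
  mm <- vapply(grpIdx, function(j) rowMeans(norm[, j, drop = FALSE]),
               numeric(nrow(counts)))
  vv <- vapply(grpIdx, function(j) rowVarsBase(norm[, j, drop = FALSE]),
               numeric(nrow(counts)))
  amom <- rowMeans((vv - mm) / mm^2)
  atr <- dispersionTrend(amom, baseMean)
  alphaShrunk <- pmax(0.9 * atr + 0.1 * pmax(amom, 0, na.rm = FALSE), 1e-8)
  alphaShrunk[!is.finite(alphaShrunk)] <- pmax(atr[!is.finite(alphaShrunk)],
                                               1e-8)

  X <- if (paired) {
    stopifnot("replicate" %in% names(design))
    model.matrix(~ factor(design$replicate) + grp)
  } else model.matrix(~ grp)
  k <- ncol(X)
  off <- log(sf)
  n <- nrow(counts)
  beta <- se <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    y <- counts[i, ]
    if (all(y == 0)) next
    fam <- MASS::negative.binomial(theta = 1 / alphaShrunk[i])
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X, y, family = fam, offset = off,
                                      control = list(maxit = 50))),
      error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) next
    muHat <- fam$linkinv(drop(X %*% fit$coefficients) + off)
    w <- muHat^2 / fam$variance(muHat)
    info <- crossprod(X, X * w)
    V <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(V) || V[k, k] <= 0) next
    beta[i] <- fit$coefficients[k]
    se[i] <- sqrt(V[k, k])
  }
  log2fc <- beta / log(2)
  stat <- beta / se
  p <- 2 * pnorm(-abs(stat))

  pass <- switch(filter,
    none = rep(TRUE, n),
    tags = rowMeans(normalizeTags(counts, thresholds@tagNormTotal)) >
      thresholds@minTags,
    tpm = {
      stopifnot(!is.null(lengths))
      rowMeans(computeTpm(counts, lengths, thresholds@tpmTotal)) >
        thresholds@minTpm
    })
  padj <- rep(NA_real_, n)
  padj[pass] <- p.adjust(p[pass], method = "BH")
  significant <- pass & !is.na(padj) & padj < thresholds@alpha &
    !is.na(log2fc) & abs(log2fc) > thresholds@fcThreshold
  out <- data.frame(
    feature_id = if (!is.null(rownames(counts))) rownames(counts)
                 else paste0("feat", seq_len(n)),
    baseMean = baseMean, log2fc = log2fc, lfcSE = se / log(2),
    stat = stat, p = p, padj = padj, filterPass = pass,
    significant = significant, row.names = NULL)
  attr(out, "contrast") <- contrast
  attr(out, "thresholds") <- thresholds
  out
}

#' Call strain-specific features from all pairwise contrasts
#'
#' A feature is strain-X-specific iff it is significantly higher in X than
#' in each of the other strains. Input names encode the contrast
#' orientation as \code{"X_Y"} (log2FC of X over Y).
#'
#' @param pairwise named list of \code{\link{nbDifferential}} results, one
#'   per unordered strain pair, names like \code{"A_B"}
#' @param strains character vector of strain labels
#' @return data.frame with \code{feature_id} and \code{label} (a strain or
#'   \code{"none"})
#' @export
callStrainSpecific <- function(pairwise, strains) {
  ids <- lapply(pairwise, `[[`, "feature_id")
  if (length(unique(ids)) != 1)
    stop("inconsistent feature universes across pairwise results")
  ids <- ids[[1]]
  pairs <- strsplit(names(pairwise), "_")
  higher <- matrix(FALSE, length(ids), length(strains),
                   dimnames = list(NULL, strains))
  counted <- setNames(integer(length(strains)), strains)
  for (i in seq_along(pairwise)) {
    d <- pairwise[[i]]
    x <- pairs[[i]][1]; y <- pairs[[i]][2]
    hx <- d$significant & d$log2fc > 0
    hy <- d$significant & d$log2fc < 0
    higher[, x] <- if (counted[x] == 0) hx else higher[, x] & hx
    higher[, y] <- if (counted[y] == 0) hy else higher[, y] & hy
    counted[x] <- counted[x] + 1L
    counted[y] <- counted[y] + 1L
  }
  if (any(counted < length(strains) - 1))
    stop("all pairwise results among the strains must be supplied")
  label <- rep("none", length(ids))
  for (s in strains) label[higher[, s]] <- s
  data.frame(feature_id = ids, label = label)
}

#' Classify peaks as accessible and/or active
#'
#' Accessible: mean normalized open-chromatin tags strictly above
#' \code{minTags}. Active: mean normalized acetylation tags strictly above
#' \code{activeTags}. Both thresholds are on the per-library normalized
#' tag scale.
#'
#' @param atacTags,k27acTags per-peak mean normalized tags (numeric
#'   vectors, or matrices with one column per strain and a shared feature
#'   universe)
#' @param thresholds a \linkS4class{Thresholds}
#' @return character vector (or matrix) over \code{\{"accessible",
#'   "active", "both", "neither"\}}
#' @export
callAccessibleActive <- function(atacTags, k27acTags,
                                 thresholds = Thresholds()) {
  stopifnot(length(atacTags) == length(k27acTags))
  acc <- atacTags > thresholds@minTags
  act <- k27acTags > thresholds@activeTags
  out <- ifelse(acc & act, "both",
         ifelse(acc, "accessible",
         ifelse(act, "active", "neither")))
  out
}
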