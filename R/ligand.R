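#' Filter candidate ligands by sender and receiver expression
#'
#' A ligand is retained iff it is expressed by at least one sender cell
#' type strictly above the TPM floor AND its receptor is expressed by the
#' receiver strictly above the floor. Ligands flagged exempt (e.g.
#' hormonal ligands whose source lies outside the profiled niche) are
#' always retained. Ligands absent from the prior are skipped with a
#' warning; ligands lacking a receptor mapping are excluded unless
#' exempt.
#'
#' @param prior ligands x genes matrix of non-negative regulatory
#'   potential scores
#' @param senderTpm matrix of ligand TPM, ligands x sender cell types
#' @param receiverTpm named vector of receiver-cell TPM per gene
#' @param receptorMap data.frame with columns \code{ligand},
#'   \code{receptor}
#' @param exempt character vector of filter-exempt ligand ids
#' @param tpmFloor strict lower bound (default 10)
#' @return character vector of retained ligand ids
#' @export
filterCandidateLigands <- function(prior, senderTpm, receiverTpm,
                                   receptorMap, exempt = character(),
                                   tpmFloor = 10) {
  lig <- rownames(senderTpm)
  missing <- setdiff(lig, rownames(prior))
  if (length(missing)) {
    warning("ligand(s) absent from prior, skipped: ",
            paste(missing, collapse = ", "))
    lig <- setdiff(lig, missing)
  }
  keep <- character()
  for (l in lig) {
    if (l %in% exempt) { keep <- c(keep, l); next }
    senderOk <- any(senderTpm[l, ] > tpmFloor)
    rec <- receptorMap$receptor[receptorMap$ligand == l]
    recOk <- length(rec) > 0 &&
      any(!is.na(receiverTpm[rec]) & receiverTpm[rec] > tpmFloor)
    if (senderOk && recOk) keep <- c(keep, l)
  }
  keep
}

#' Define target and background gene sets for ligand scoring
#'
#' Targets are receiver genes significantly higher in the strain in any
#' pairwise comparison (strict \code{padj < alpha}, \code{log2FC >
#' targetLog2fc}) and expressed above the TPM floor; the background is
#' every receiver gene expressed above the floor.
#'
#' @param diffList list of \code{\link{nbDifferential}} results, oriented
#'   so positive log2FC means higher in the strain of interest
#' @param receiverTpm named vector of receiver TPM per gene
#' @param thresholds a \linkS4class{Thresholds} (\code{targetLog2fc},
#'   \code{alpha}, \code{ligandTpmFloor})
#' @return list with \code{targets} and \code{background} (character
#'   vectors of gene ids; targets are a subset of expressed genes)
#' @export
defineTargetsAndBackground <- function(diffList, receiverTpm,
                                       thresholds = Thresholds()) {
  expressed <- names(receiverTpm)[receiverTpm > thresholds@ligandTpmFloor]
  targets <- character()
  for (d in diffList) {
    hit <- !is.na(d$padj) & d$padj < thresholds@alpha &
      d$log2fc > thresholds@targetLog2fc
    targets <- union(targets, d$feature_id[hit])
  }
  targets <- intersect(targets, expressed)
  if (!length(targets)) stop("empty target set")
  list(targets = targets, background = expressed)
}

#' Score ligand activity by prior-target correlation
#'
#' Over the union of background and target genes, each ligand's activity
#' is the Pearson correlation between its prior regulatory-potential
#' scores and the 0/1 indicator of target membership. Ligands whose prior
#' vector has zero variance over the universe score NA.
#'
#' @param prior ligands x genes matrix
#' @param targets target gene ids
#' @param background background gene ids (>= 10 required)
#' @param ligands ligand subset to score (default: all rows of the prior)
#' @return named numeric vector of Pearson scores
#' @export
scoreLigandActivity <- function(prior, targets, background,
                                ligands = rownames(prior)) {
  stopifnot(length(background) >= 10)
  universe <- union(background, targets)
  universe <- intersect(universe, colnames(prior))
  ind <- as.numeric(universe %in% targets)
  out <- setNames(rep(NA_real_, length(ligands)), ligands)
  for (l in ligands) {
    v <- prior[l, universe]
    if (sd(v) > 0 && sd(ind) > 0) out[l] <- cor(v, ind)
  }
  out
}

#' Z-score ligand activities across strains
#'
#' Normalizes each ligand's per-strain scores to mean 0 and unit standard
#' deviation across strains, making activities comparable between
#' ligands of different baseline connectivity. Ligands scored in fewer
#' than two strains, or with identical scores in every strain, get NA
#' (with a warning in the degenerate-sd case).
#'
#' @param scores ligands x strains numeric matrix of Pearson scores
#' @return matrix of the same shape; each non-NA row has mean 0, sd 1
#' @export
zscoreAcrossStrains <- function(scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 2) {
    out <- scores; out[] <- NA_real_
    return(out)
  }
  out <- t(apply(scores, 1, function(x) {
    ok <- !is.na(x)
    if (sum(ok) < 2) return(rep(NA_real_, length(x)))
    s <- sd(x[ok])
    if (s == 0) {
      warning("zero variance across strains; z-scores set to NA")
      return(rep(NA_real_, length(x)))
    }
    (x - mean(x[ok])) / s
  }))
  dimnames(out) <- dimnames(scores)
  out
}
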