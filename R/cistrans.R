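#' Classify features into cis / trans / mixed / same regulation
#'
#' Crosses the parental (F0) strain contrast with the F1 hybrid allelic
#' contrast. A feature is \code{cis} when the strain difference is
#' conserved at the allelic level (significant in both comparisons with
#' the same sign), \code{trans} when the parental difference vanishes in
#' the hybrid (significant in F0 only), \code{mixed} when allelic bias
#' appears without a parental difference, \code{same} when neither
#' comparison is significant, and \code{discordant} when both are
#' significant with opposite signs (the two-axis scheme is silent on this
#' case; labelling it explicitly avoids calling it \code{cis}).
#'
#' "Conserved at the allelic level" is significance plus sign agreement,
#' not fold-change equality; the allelic/parental magnitude ratio is
#' emitted as an annotation (\code{magnitude_ratio}) but never used for
#' classing.
#'
#' @param f0 \code{\link{nbDifferential}} result for the parental strain
#'   contrast (A over B)
#' @param f1Allelic \code{\link{nbDifferential}} result for the F1 allelic
#'   contrast (allele A over allele B)
#' @param thresholds a \linkS4class{Thresholds} (classification uses the
#'   \code{significant} column already present in the inputs)
#' @return data.frame with \code{feature_id}, \code{class},
#'   \code{direction} (favored strain or \code{"none"}),
#'   \code{f0_log2fc}, \code{f1_allelic_log2fc}, \code{magnitude_ratio}
#' @export
classifyCisTrans <- function(f0, f1Allelic, thresholds = Thresholds()) {
  common <- intersect(f0$feature_id, f1Allelic$feature_id)
  dropped <- length(union(f0$feature_id, f1Allelic$feature_id)) -
    length(common)
  if (dropped)
    warning(dropped, " feature(s) missing from one input were excluded")
  a <- f0[match(common, f0$feature_id), ]
  b <- f1Allelic[match(common, f1Allelic$feature_id), ]
  sa <- a$significant
  sb <- b$significant
  sameSign <- sign(a$log2fc) == sign(b$log2fc)
  cls <- ifelse(sa & sb & sameSign, "cis",
         ifelse(sa & sb, "discordant",
         ifelse(sa, "trans",
         ifelse(sb, "mixed", "same"))))
  lead <- ifelse(cls %in% c("mixed"), b$log2fc, a$log2fc)
  dir <- ifelse(cls == "same", "none", ifelse(lead > 0, "A", "B"))
  data.frame(feature_id = common, class = cls, direction = dir,
             f0_log2fc = a$log2fc, f1_allelic_log2fc = b$log2fc,
             magnitude_ratio = b$log2fc / a$log2fc)
}

#' Decompose trans effects into environmental and cell-autonomous parts
#'
#' For features with a parental strain difference, the chimera designs
#' separate where the effect originates. Donor cells of both strains
#' engrafted into a common immunodeficient host share one tissue
#' environment, and F1 donor cells additionally share one nucleus. The
#' decision list, evaluated in order, is:
#' \enumerate{
#'   \item \code{cis} - significant allelic bias in the F1 chimera with
#'     the same sign as the parental difference;
#'   \item \code{trans_environmental} - the parental difference disappears
#'     in the F0 chimera (the effect required the parental tissue
#'     environment);
#'   \item \code{trans_cellautonomous} - the difference persists in the F0
#'     chimera but shows no allelic imbalance in the F1 chimera (the
#'     effect travels with the cell, upstream of its own loci);
#'   \item \code{unresolved} otherwise.
#' }
#'
#' @param f0 parental contrast (\code{\link{nbDifferential}} result); only
#'   features significant here are classified
#' @param f0Nsg F0 chimera strain contrast
#' @param f1NsgAllelic F1 chimera allelic contrast
#' @param thresholds a \linkS4class{Thresholds}
#' @return list with \code{calls} (data.frame \code{feature_id},
#'   \code{class}) and \code{proportions} (environmental vs
#'   cell-autonomous fractions among trans calls)
#' @export
classifyAutonomy <- function(f0, f0Nsg, f1NsgAllelic,
                             thresholds = Thresholds()) {
  for (nm in c("f0Nsg", "f1NsgAllelic"))
    if (is.null(get(nm))) stop("missing arm: ", nm)
  ids <- f0$feature_id[f0$significant]
  a <- f0[match(ids, f0$feature_id), ]
  g <- f0Nsg[match(ids, f0Nsg$feature_id), ]
  h <- f1NsgAllelic[match(ids, f1NsgAllelic$feature_id), ]
  if (anyNA(g$feature_id) || anyNA(h$feature_id))
    stop("missing arm coverage for strain-specific features")
  cls <- rep("unresolved", length(ids))
  isCis <- h$significant & sign(h$log2fc) == sign(a$log2fc)
  cls[isCis] <- "cis"
  env <- !isCis & !g$significant
  cls[env] <- "trans_environmental"
  ca <- !isCis & g$significant & !h$significant
  cls[ca] <- "trans_cellautonomous"
  nTrans <- sum(env) + sum(ca)
  props <- c(environmental = if (nTrans) sum(env) / nTrans else NA_real_,
             cellautonomous = if (nTrans) sum(ca) / nTrans else NA_real_)
  list(calls = data.frame(feature_id = ids, class = cls),
       proportions = props)
}

#' Classify stimulus responses as shared or strain-specific
#'
#' A strain is responsive for a feature when its treated-versus-basal
#' contrast is significant. Responsive in both strains with the same sign
#' is a shared response; responsive in exactly one strain is
#' strain-specific; in neither, nonresponsive. (Both-significant with
#' opposite signs is also reported as shared_response = FALSE cases:
#' such features are labelled by the strain with the larger absolute
#' change being excluded — they are rare and kept as
#' \code{discordant_response}.)
#'
#' @param respA,respB per-strain treated-vs-basal
#'   \code{\link{nbDifferential}} results
#' @param thresholds a \linkS4class{Thresholds}
#' @return data.frame with \code{feature_id}, \code{label} in
#'   \code{\{shared_response, strainA_specific, strainB_specific,
#'   nonresponsive, discordant_response\}}, and the two response log2FCs
#' @export
classifyStimulusResponse <- function(respA, respB,
                                     thresholds = Thresholds()) {
  common <- intersect(respA$feature_id, respB$feature_id)
  a <- respA[match(common, respA$feature_id), ]
  b <- respB[match(common, respB$feature_id), ]
  sa <- a$significant; sb <- b$significant
  lab <- ifelse(sa & sb & sign(a$log2fc) == sign(b$log2fc), "shared_response",
         ifelse(sa & sb, "discordant_response",
         ifelse(sa, "strainA_specific",
         ifelse(sb, "strainB_specific", "nonresponsive"))))
  data.frame(feature_id = common, label = lab,
             strainA_log2fc = a$log2fc, strainB_log2fc = b$log2fc)
}

#' Partition strain-specific responses by basal state
#'
#' Sorts strain-specific stimulus-responsive features by the baseline
#' level of the \emph{non-responsive} strain relative to the responsive
#' one: \code{equal_basal} when the untreated strains do not differ
#' significantly, \code{high_basal} when the non-responsive strain is
#' already significantly higher at baseline, \code{low_basal} when it is
#' significantly lower. Features that are not strain-specific responsive
#' are rejected (dropped).
#'
#' @param response output of \code{\link{classifyStimulusResponse}}
#' @param basalDiff \code{\link{nbDifferential}} result comparing the two
#'   untreated strains (log2FC of strain A over strain B)
#' @param thresholds a \linkS4class{Thresholds}
#' @return data.frame with \code{feature_id}, \code{category},
#'   \code{responsive_strain}
#' @export
partitionBasalState <- function(response, basalDiff,
                                thresholds = Thresholds()) {
  keep <- response$label %in% c("strainA_specific", "strainB_specific")
  r <- response[keep, , drop = FALSE]
  d <- basalDiff[match(r$feature_id, basalDiff$feature_id), ]
  if (anyNA(d$feature_id))
    stop("basalDiff does not cover all strain-specific responsive features")
  respStrain <- ifelse(r$label == "strainA_specific", "A", "B")
  # log2fc is A over B; the non-responsive strain is higher at baseline
  # when the fold change points away from the responsive strain
  nonRespHigher <- ifelse(respStrain == "A", d$log2fc < 0, d$log2fc > 0)
  cat_ <- ifelse(!d$significant, "equal_basal",
          ifelse(nonRespHigher, "high_basal", "low_basal"))
  data.frame(feature_id = r$feature_id, category = cat_,
             responsive_strain = respStrain)
}

#' Test association between basal state and cis/trans regulation
#'
#' Builds the contingency table of basal category by regulation class over
#' the intersection of the two feature sets and applies a Pearson
#' chi-squared test (no continuity correction). An exactly proportional
#' table gives chi2 = 0, p = 1.
#'
#' @param basal output of \code{\link{partitionBasalState}}
#' @param reg output of \code{\link{classifyCisTrans}} (or any data.frame
#'   with \code{feature_id} and \code{class})
#' @param classes regulation classes retained in the table
#' @return list with \code{table} (observed counts), \code{chi2},
#'   \code{df}, \code{p}
#' @export
basalCisTransAssociation <- function(basal, reg,
                                     classes = c("cis", "trans", "mixed")) {
  m <- merge(basal[, c("feature_id", "category")],
             reg[, c("feature_id", "class")], by = "feature_id")
  m <- m[m$class %in% classes, , drop = FALSE]
  if (!nrow(m)) stop("empty intersection of basal and regulation calls")
  tab <- table(factor(m$category), factor(m$class))
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("need >= 2 non-empty basal categories and regulation classes")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(table = tab, chi2 = unname(ct$statistic),
       df = unname(ct$parameter), p = ct$p.value)
}
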