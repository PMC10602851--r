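#' Simulate a ligand-target prior with one planted active ligand
#'
#' Builds a non-negative ligand x gene regulatory-potential matrix
#' (gamma-distributed baseline), a ligand-receptor map, sender and
#' receiver TPM tables whose values straddle the expression filter, a
#' differentially expressed target gene set, and one planted active
#' ligand whose prior scores on the target set are elevated by
#' \code{enrichment}. With \code{enrichment = 0} the active ligand is
#' indistinguishable from the decoys.
#'
#' @param nLigands number of ligands (>= 2)
#' @param nGenes receiver gene universe size
#' @param deFraction fraction of genes in the differentially expressed
#'   target set
#' @param enrichment additive prior-score elevation of the active ligand
#'   on target genes (default 1)
#' @param config a \linkS4class{SimulationConfig} (seed source)
#' @param tpmFloor the expression filter the TPM values straddle
#' @return list with \code{prior}, \code{receptorMap}, \code{senderTpm}
#'   (ligands x 3 sender cell types), \code{receiverTpm} (named vector
#'   over genes and receptors), \code{deGenes}, \code{activeLigand}
#' @export
simulateLigandNetwork <- function(nLigands = 100, nGenes = 1000,
                                  deFraction = 0.1, enrichment = 1,
                                  config = SimulationConfig(),
                                  tpmFloor = 10) {
  if (nLigands < 2) stop("need at least 2 ligands")
  set.seed(config@seed + 8L)
  genes <- sprintf("gene%04d", seq_len(nGenes))
  ligands <- sprintf("ligand%03d", seq_len(nLigands))
  receptors <- sprintf("receptor%03d", seq_len(nLigands))
  prior <- matrix(rgamma(nLigands * nGenes, shape = 1, scale = 0.25),
                  nLigands, nGenes, dimnames = list(ligands, genes))
  deGenes <- sample(genes, round(deFraction * nGenes))
  active <- sample(ligands, 1)
  prior[active, deGenes] <- prior[active, deGenes] + enrichment
  # TPM values straddle the floor: most entries above, a tail below
  senderTpm <- matrix(rlnorm(nLigands * 3, log(30), 0.9), nLigands, 3,
                      dimnames = list(ligands,
                                      c("hepatocyte", "LSEC", "stellate")))
  receiverTpm <- setNames(rlnorm(nGenes + nLigands, log(30), 0.9),
                          c(genes, receptors))
  list(prior = prior,
       receptorMap = data.frame(ligand = ligands, receptor = receptors),
       senderTpm = senderTpm, receiverTpm = receiverTpm,
       deGenes = deGenes, activeLigand = active)
}
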