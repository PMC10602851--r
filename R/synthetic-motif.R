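#' Generate a library of random position weight matrices
#'
#' Draws sharply peaked probability matrices: each position has one
#' dominant base (probability drawn from \code{dominantRange}) with the
#' remainder spread uniformly. The first motif id is conventionally used
#' as the planted target; the rest serve as decoys.
#'
#' @param n number of motifs
#' @param widths candidate motif widths, sampled per motif
#' @param dominantRange range of the dominant-base probability
#' @param seed integer seed
#' @return named list of 4 x width probability matrices
#' @export
makeMotifSet <- function(n, widths = 8:12, dominantRange = c(0.80, 0.95),
                         seed = 1) {
  set.seed(seed)
  out <- list()
  for (i in seq_len(n)) {
    w <- sample(widths, 1)
    m <- matrix(0, 4, w, dimnames = list(c("A", "C", "G", "T"), NULL))
    dom <- sample(1:4, w, replace = TRUE)
    p <- runif(w, dominantRange[1], dominantRange[2])
    for (j in seq_len(w)) {
      m[, j] <- (1 - p[j]) / 3
      m[dom[j], j] <- p[j]
    }
    out[[sprintf("M%03d", i)]] <- m
  }
  out
}

#' Simulate paired positive/negative sequences with planted motif
#' mutations
#'
#' Emulates homologous enhancer sequence pairs from two strains: every
#' positive sequence carries an intact embedded match (the consensus) of
#' the target motif at a random position and strand; the negative
#' sequence is its homolog, differing by background substitutions planted
#' outside the motif at the configured inter-strain density and — in
#' \code{mutatedFraction} of pairs — by one consensus-destroying
#' substitution inside the motif (the dominant base of the most
#' informative position is replaced by the least likely base). With
#' \code{mutatedFraction = 0} the target motif's maximal score is
#' identical in both sequences of every pair.
#'
#' @param pwms motif library (see \code{\link{makeMotifSet}})
#' @param targetId id of the planted motif (default: first)
#' @param nPairs number of sequence pairs
#' @param mutatedFraction fraction of pairs whose negative sequence
#'   carries the consensus-destroying substitution
#' @param config a \linkS4class{SimulationConfig}; \code{snpDensity} sets
#'   the background substitution density, \code{seed} the randomness
#' @param seqLen pair sequence length in bases (default 200)
#' @return list with \code{pairs} (data.frame \code{pair_id},
#'   \code{positive}, \code{negative}, \code{comparison}) and
#'   \code{truth} (data.frame \code{pair_id}, \code{mutated},
#'   \code{planted_motif_mutation})
#' @export
simulateMotifLandscape <- function(pwms, targetId = names(pwms)[1],
                                   nPairs, mutatedFraction, config,
                                   seqLen = 200) {
  set.seed(config@seed + 7L)
  pwm <- pwms[[targetId]]
  w <- ncol(pwm)
  if (w >= seqLen) stop("motif width must be smaller than sequence length")
  bases <- c("A", "C", "G", "T")
  consensus <- bases[apply(pwm, 2, which.max)]
  lo <- pwmLogOdds(pwm)
  maxAttain <- sum(apply(lo, 2, max))
  # draw a high-scoring motif instance (an intact match that is still the
  # sequence's best-scoring window); instances vary across pairs the way
  # real bound sites do
  drawInstance <- function() {
    for (try in 1:20) {
      inst <- vapply(seq_len(w), function(j)
        sample(bases, 1, prob = pwm[, j]), "")
      sc <- sum(lo[cbind(match(inst, bases), seq_len(w))])
      if (sc >= maxAttain - 6) return(inst)
    }
    consensus
  }
  mutated <- rep(FALSE, nPairs)
  if (mutatedFraction > 0)
    mutated[sample(nPairs, round(mutatedFraction * nPairs))] <- TRUE

  pos <- neg <- character(nPairs)
  for (i in seq_len(nPairs)) {
    s <- strsplit(randomDna(seqLen), "")[[1]]
    at <- sample(seq_len(seqLen - w + 1), 1)
    minus <- runif(1) < 0.5
    inst <- drawInstance()
    emb <- if (minus) strsplit(revcompStr(paste(inst, collapse = "")),
                               "")[[1]] else inst
    s[at:(at + w - 1)] <- emb
    sNeg <- s
    # background inter-strain substitutions outside the embedded motif,
    # assigned to either strain's sequence so decoy score differences are
    # sign-symmetric
    nBg <- rpois(1, config@snpDensity * seqLen)
    if (nBg > 0) {
      cand <- setdiff(seq_len(seqLen), at:(at + w - 1))
      hit <- sample(cand, min(nBg, length(cand)))
      for (p in hit) {
        if (runif(1) < 0.5) sNeg[p] <- sample(setdiff(bases, sNeg[p]), 1)
        else s[p] <- sample(setdiff(bases, s[p]), 1)
      }
    }
    if (mutated[i]) {
      # destroy the consensus: a column carrying its dominant base loses
      # it to a random non-dominant base (column and base vary per pair,
      # as real inter-strain variants do)
      domCols <- which(inst == consensus)
      col <- if (length(domCols)) domCols[sample(length(domCols), 1)]
             else sample(w, 1)
      newBase <- sample(setdiff(bases, consensus[col]), 1)
      p <- if (minus) at + w - col else at + col - 1
      sNeg[p] <- if (minus) chartr("ACGT", "TGCA", newBase) else newBase
      # balance the variant burden: the positive strain receives one
      # compensatory substitution outside the motif, so decoy score
      # differences stay centered on zero
      cand <- setdiff(seq_len(seqLen), at:(at + w - 1))
      q <- sample(cand, 1)
      s[q] <- sample(setdiff(bases, s[q]), 1)
    }
    pos[i] <- paste(s, collapse = "")
    neg[i] <- paste(sNeg, collapse = "")
  }
  ids <- sprintf("pair%05d", seq_len(nPairs))
  list(pairs = data.frame(pair_id = ids, comparison = "A_B",
                          positive = pos, negative = neg),
       truth = data.frame(pair_id = ids, mutated = mutated,
                          planted_motif_mutation =
                            ifelse(mutated, targetId, NA_character_)))
}
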