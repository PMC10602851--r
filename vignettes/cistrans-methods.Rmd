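---
title: "Decomposing strain-specific regulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing strain-specific regulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cistrans)
```

## The problem

Natural genetic variation between inbred strains changes gene expression
and chromatin state through two fundamentally different routes. A *cis*
effect is local: a SNP or short indel alters a regulatory element, and
only the allele carrying it responds. A *trans* effect is diffusible: the
variant changes the abundance or activity of some upstream factor —
a transcription factor, a signaling pathway, or a ligand produced by
another cell type — and both alleles respond equally. Trans effects
divide further into *cell-autonomous* ones (originating inside the cell,
e.g. altered signaling) and *non-cell-autonomous* (environmental) ones
(originating in the tissue, e.g. a niche ligand produced at different
levels by neighboring cell types).

Three experimental designs separate these routes:

* **F0 (parental)** — two inbred strains, each in its own body. Any
  regulatory route can produce a strain difference.
* **F1 hybrid** — both genomes in one nucleus, one environment. Only cis
  effects survive as *allelic imbalance*, read out by assigning
  sequencing reads to their parental haplotype at positions where the
  genomes differ.
* **Chimera (immunodeficient host)** — donor cells of either strain (F0
  chimera) or F1 hybrid donor cells (F1 chimera) engrafted into a common
  host tissue. The chimera removes strain-specific environmental
  signals while leaving cell-intrinsic differences in place.

This package implements the full inferential chain over these designs:
variant-aware pseudogenomes and allelic read assignment, an internal
negative-binomial (NB) differential test, the cis/trans/mixed/same
classification, the environmental/cell-autonomous decomposition,
motif-mutation association, variant-frequency summaries, basal-state
partitioning of stimulus responses, and ligand-activity scoring — plus a
synthetic-data module that generates every input with planted truth so
the chain is testable end to end without external downloads.

## Pseudogenomes and allelic reads

`buildPseudogenome()` substitutes one strain's SNP alleles and splices
its indels into the reference, producing the strain haplotype together
with an invertible `CoordinateMap`. The map is piecewise-constant between
variant blocks, strictly monotone on positions present in both frames,
and snaps positions deleted in the destination frame to the nearest left
anchor with a flag. Internally the package works in the conventional
dialect of each format: VCF positions are 1-based with indel records
sharing their anchor base, BED intervals are 0-based half-open, and all
in-memory intervals are 1-based inclusive `GRanges`.

`assignReadAllele()` applies the perfect-match rule: a read (with its
mapped reference-frame start) is assigned to an allele iff it matches
that haplotype exactly over the homologous span — obtained through the
coordinate map, so indel-length differences are handled — spans at least
one discriminating position, and does not also match the other
haplotype. Reads matching both frames (possible near indel edges) are
conservatively unassigned; a sequencing error at the discriminating base
fails the exact match for both haplotypes and likewise yields
`unassigned`, never a misassignment. On error-free simulated reads the
assignment is exact: precision and recall are both 1 by construction of
the rule, which the test suite verifies on 10,000 reads.

## The internal NB differential engine

`nbDifferential()` is a deliberate simplification of the DESeq2
workflow, self-contained and calibration-tested rather than numerically
identical to it:

1. **Size factors** — median-of-ratios against per-feature geometric
   means, with a column-total fallback when fewer than ten features are
   positive everywhere. Median-of-ratios assumes most features are
   unchanged between groups; the synthetic generators respect this
   (responders are a minority), as do real transcriptomes.
2. **Dispersion** — per-feature method-of-moments estimates
   (`var = mu + alpha mu^2`) pooled within groups, then shrunk toward a
   mean–dispersion trend `alpha(mu) = a0 + a1/mu` fitted across features
   (flat when the mean spread is too small to fit a trend). The shrunk
   value is `0.9 * trend + 0.1 * max(MoM, 0)`, floored at `1e-8`. The
   heavy trend weight is what keeps the Wald test calibrated at n = 3:
   because the per-feature dispersion is effectively pooled, the Wald
   statistic is close to standard normal rather than t-distributed with
   few degrees of freedom. On 5,000 null features (mu = 500,
   alpha = 0.05, 3 vs 3) the fraction of p < 0.05 is 0.050–0.056 across
   seeds.
3. **Wald test** — a per-feature NB log-linear model with the dispersion
   held fixed at its shrunk value (`MASS::negative.binomial` family,
   log-link, size-factor offsets). Allelic contrasts set
   `paired = TRUE`, which adds a replicate covariate so alleles are
   compared within biological replicate; the data do not say whether the
   original analyses paired alleles within replicate, so pairing is this
   package's documented choice (it can only help, and is exact when
   replicate effects are absent).
4. **Filtering and correction** — an abundance filter (mean TPM > 8 for
   expression, mean normalized tags > 16 for peaks; strict inequalities
   wherever a threshold is quoted as ">") is applied before
   Benjamini–Hochberg correction; filtered features carry `padj = NA`.
   A call is significant iff the filter passed, `padj < 0.05`, and
   `|log2FC| > 1` (all configurable through `Thresholds()`).

## Classification rules

`classifyCisTrans()` crosses the F0 strain contrast with the F1 allelic
contrast: **cis** = significant in both with the same sign ("conserved
at the allelic level" is operationalized as significance plus sign
agreement, not fold-change equality; the allelic/parental magnitude
ratio is emitted as an annotation only); **trans** = significant in F0
only; **mixed** = allelic bias without a parental difference; **same** =
neither; **discordant** = both significant with opposite signs — the
two-axis scheme is silent on this rare case, and labelling it explicitly
avoids mislabelling it cis.

`classifyAutonomy()` is a decision list evaluated in order over features
with a parental difference: (1) allelic bias in the F1 chimera with the
parental sign → **cis** (sign agreement is enforced; an opposite-sign
allelic bias is evidence against a simple cis route, so such features
fall through to **unresolved**); (2) difference absent in the F0 chimera
→ **trans environmental**; (3) difference persists in the F0 chimera
with no F1-chimera allelic imbalance → **trans cell-autonomous**;
otherwise **unresolved**. Resolving cis first mirrors the logic that
allelic imbalance is the most direct evidence available. Overlap
universes for cross-design comparisons are supplied by the caller rather
than hard-coded; every classifier takes explicit differential-result
inputs.

`classifyStimulusResponse()` and `partitionBasalState()` handle
treatment designs: a strain is responsive when its treated-vs-basal
contrast is significant; strain-specific responders are then sorted by
the *non-responsive* strain's baseline into `low_basal`, `equal_basal`
and `high_basal`. No separate thresholds exist for this partition in the
underlying analyses, so the global significance thresholds are reused.
`basalCisTransAssociation()` tests basal category against regulation
class with a Pearson chi-squared statistic, no continuity correction.

## Motif-mutation association

`maxPwmScore()` scores a sequence against a PWM as the maximum summed
log2-odds window over both strands. Background base frequencies are
uniform (0.25) and a pseudocount of 0.01 is added per cell before
log-odds; `N` bases contribute 0 (the background expectation). Maxima
are taken independently per sequence — the literal reading of "max motif
score" — rather than at matched window positions.

`motifMutationTest()` takes homologous positive/negative sequence pairs
(positive from the strain with higher signal) and tests the paired
differences of maximal scores against a null centered on zero with a
two-sided Wilcoxon signed-rank test. Zero differences are dropped (the
classical treatment; their count is reported) and a motif with no
nonzero differences is untestable (`p = NA`). The exact signed-rank
distribution is used below 50 nonzero pairs — the normal approximation
is poorly calibrated there — and the corrected approximation above.
Benjamini–Hochberg q-values are reported across motifs alongside raw p;
ranking and display use raw p, with q available.

## Ligand-activity scoring

The ligand–target prior is an input, not a computation: reconstructing a
signaling-network propagation from public pathway databases is out of
scope, and the inferential content here is the expression filtering plus
correlation scoring. `filterCandidateLigands()` keeps a ligand iff some
sender cell type expresses it strictly above 10 TPM and its receptor is
expressed by the receiver strictly above 10 TPM; hormone-like ligands
whose source is not profiled can be exempted. Target genes are those
significantly higher in a strain in any pairwise comparison with
`log2FC > 2` — the quoted "log (fold change) > 2" is ambiguous about its
base, so the literal log2 reading is the default and the cutoff is
exposed in `Thresholds()` — and expressed above 10 TPM; the background
is every expressed receiver gene. `scoreLigandActivity()` is the Pearson
correlation between a ligand's prior scores and the target-membership
indicator over the union of background and targets, and
`zscoreAcrossStrains()` standardizes each ligand's scores across strains
to mean 0, sd 1.

## What the synthetic data emulate — and what they do not

`SimulationConfig()` defaults define the package's reference study
conditions, chosen once: a 100-kb haplotype pair differing at 1 variant
per 150 bp with 10% indels of up to 6 bp (structural variants are out of
scope, matching the SNP/short-indel scope of pseudogenome mapping);
error-free 40-bp reads; NB counts at mean 500 with dispersion 0.05,
planted |log2FC| = 2 (the "twofold and significant" regime), 3
replicates per arm; stimulus responses at |log2FC| = 5, in the tens-fold
range typical of acute inflammatory induction; responders a minority
(65% of genes nonresponsive) so that size-factor estimation is
well-posed; and trans mass split 60:40 between environmental and
cell-autonomous routes. F1 allelic counts are generated directly at the
count level (each allele at half the total mean) rather than through the
read simulator — read-level simulation is reserved for testing the
assignment machinery itself, which keeps the two concerns separate and
runtimes at desk scale.

Class semantics are enforced through generating means, so planted truth
is verifiable by inspection without statistics: cis features carry the
planted ratio in every arm's contrast, environmental-trans only in F0,
cell-autonomous-trans in F0 and the F0 chimera but no allelic arm, mixed
only in the allelic arms.

The motif landscape embeds, per pair, a high-scoring instance drawn from
the target PWM (rejection-sampled to remain the sequence's best window),
plants background substitutions outside the motif at the inter-strain
density with random strain assignment, and — in the mutated fraction —
replaces one dominant base of the embedded instance in the negative
sequence with a random non-dominant base, adding one compensatory
background substitution to the positive sequence so both strains carry
an equal expected variant burden. These choices keep decoy score
differences sign-symmetric; with a fixed consensus and a fixed mutated
column, decoy motifs acquire consistent-sign offsets and spurious
significance, which is an artifact of an over-regular simulation rather
than a property of the statistic.

Deliberately **not** modeled: sequencing-error profiles beyond a uniform
substitution rate, fragment-length models, GC bias, duplicates and
mappability artifacts; per-feature dispersion variation (a single alpha
governs all features); correlated regulatory programs across features;
motif families with correlated binding models. Passing recovery tests on
these simulations therefore demonstrates the correctness and calibration
of the inferential chain under its own assumptions — not robustness to
every artifact of real sequencing data.

## Numerical choices and edge cases

* Strict inequalities at every quoted threshold (a peak with exactly 16
  normalized tags is not accessible; a ligand at exactly 10 TPM is
  excluded).
* Dispersion floor `1e-8`; trend fitted only when means span enough
  range (sd of log mean > 0.1, at least 50 usable features), otherwise a
  pooled flat trend.
* Degenerate contrasts (one group entirely zero across features) and
  zero-depth libraries are errors; a feature with identical counts in
  both groups gives log2FC = 0, p = 1.
* Reads exactly matching both haplotypes are unassigned (conservative
  tie-break); peaks whose midpoint is deleted in a strain frame are
  skipped with a warning during sequence extraction.
* Exactly proportional contingency tables give chi2 = 0, p = 1; empty
  basal/regulation intersections are errors.
* All generators derive their randomness from `SimulationConfig@seed`
  via fixed offsets, so one seed determines the entire fixture bundle
  and pipeline output byte for byte.

## Pipeline and problem sizes

`generateFixtures()` writes the complete plain-text input bundle (FASTA,
VCF, BED, count and metadata tables, JASPAR motifs, ligand network,
truth tables); `runPipeline()` executes all stages in dependency order,
writes one table per result with a seed/config-hash header, and records
a manifest; `evaluateRecovery()` scores the outputs against planted
truth. These functions, with the vignette and the exported API, are the
package's interface; there is no separate shell executable.

Default evaluation sizes are chosen for desk-scale runs: 2,000 features
for class recovery, 5,000 for calibration, 600 for the autonomy split,
400 pairs against 50 decoys for the motif statistic (with 200
reduced-scale replicates of 150 pairs for decoy calibration), 1,600
genes for the basal partition, and 100 replicates of a 100-ligand
network. The full test suite runs in about two minutes; the acceptance
script in about ninety seconds.

## Known limitations

* The NB engine is not DESeq2: no empirical-Bayes dispersion posterior,
  no fold-change shrinkage prior by default, no outlier handling (Cook's
  distance) or independent filtering. Exact numerical agreement with
  DESeq2 is a non-goal; a cross-check test verifies directional and
  call-level concordance.
* At large pair counts the motif decoy null retains a slight
  anti-conservative tilt (a few percent excess below p = 0.05 at 400
  pairs): a planted motif's neighborhood is never perfectly exchangeable
  for motifs partially resembling it. The planted motif's signal exceeds
  decoys by dozens of orders of magnitude, so ranking is unaffected.
* Dispersion estimation ignores covariates beyond the contrast groups;
  in paired allelic designs replicate effects inflate the within-group
  variance estimate slightly, which is conservative.
* The continuous share of cis versus trans per feature is not estimated
  — classes are categorical, as the underlying F0/F1 comparison cannot
  quantify relative effect sizes.
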