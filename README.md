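# cistrans

Decomposition of strain-specific gene regulation into *cis*, *trans*,
mixed, environmental (non-cell-autonomous) and cell-autonomous
components, for epigenomic and transcriptomic studies that combine
parental inbred strains, F1 hybrids, and bone-marrow chimera designs.
Written for regulatory genomicists who want the full inferential chain —
from variant-aware read assignment to categorical regulation calls —
as tested, reusable R functions.

## The science

A noncoding variant can act in **cis** (only the allele carrying it
responds) or in **trans** (a diffusible factor changes, and both alleles
respond). In an F1 hybrid both parental genomes share one nucleus and
one environment, so a parental difference that is *conserved at the
allelic level* is cis and one that *vanishes* is trans. Engrafting donor
cells into a common immunodeficient host removes strain-specific tissue
signals, splitting trans effects further: differences that disappear in
the chimera are **environmental**, differences that persist in the F0
chimera but show no allelic imbalance in the F1 chimera are
**cell-autonomous**.

For a feature with parental contrast *F0* and allelic contrast *F1*
(significance: BH-adjusted *P* < 0.05 and |log2FC| > 1, after an
abundance filter):

| F0 significant | F1 significant (same sign) | class |
|---|---|---|
| yes | yes | cis |
| yes | no | trans |
| no | yes | mixed |
| no | no | same |
| yes | yes, opposite sign | discordant |

Around this core the package provides: pseudogenome construction with
invertible coordinate maps and perfect-match allelic read assignment; an
internal negative-binomial Wald test (median-of-ratios size factors,
trend-shrunk method-of-moments dispersion); maximal-PWM-score
motif-mutation association tested by paired two-sided Wilcoxon
signed-rank against a zero-centered null; variant-frequency-by-fold-change
summaries; basal-state partitioning of stimulus responses with a Pearson
chi-squared association test; and ligand-activity scoring (Pearson
correlation of a ligand–target prior with target membership, under
strict >10 TPM sender/receiver filters). A synthetic-data module
generates every input with planted ground truth, so the whole chain is
testable without any download. See the methods vignette
(`vignettes/cistrans-methods.Rmd`) for models, assumptions and
numerical choices.

## Worked example

Generate a complete synthetic study at the reference conditions (100-kb
haplotype pair at 1 variant/150 bp, 2,000 features, NB counts with
mean 500 and dispersion 0.05, planted |log2FC| = 2, trans effects split
60:40 environmental:cell-autonomous), run the pipeline, and score it
against the planted truth:

```r
library(cistrans)
cfg <- SimulationConfig(seed = 42)   # reference study conditions
fx  <- file.path(tempdir(), "bundle")
out <- file.path(tempdir(), "results")
generateFixtures(fx, cfg)
runPipeline(fx, out)
print(readTsv(file.path(out, "scorecard.tsv")), digits = 3)
#>                      metric     value
#> 1      assignment_precision  1.00e+00
#> 2         assignment_recall  1.00e+00
#> 3     cistrans_macro_recall  9.99e-01
#> 4    autonomy_environmental  5.91e-01
#> 5   autonomy_cellautonomous  4.09e-01
#> 6         motif_target_rank  1.00e+00
#> 7       motif_target_log10p -2.55e+01
#> 8  basal_partition_accuracy  1.00e+00
#> 9       basal_association_p  2.75e-08
#> 10       ligand_active_rank  1.00e+00
```

Reading the scorecard: every variant-spanning read was assigned to its
true haplotype and no read was misassigned (`assignment_*` = 1);
averaged over the four regulation classes, 99.9% of features were called
as planted; the recovered environmental:cell-autonomous split is
59:41 against a planted 60:40; the planted motif ranks first among the
decoy PWMs at *P* ≈ 10⁻²⁵·⁵; all strain-specific stimulus responders
were sorted into their true basal category, and the planted association
between basal state and cis/trans regulation is detected at
*P* ≈ 3 × 10⁻⁸; the planted active ligand ranks first.

The per-feature regulation calls are plain tables:

```r
reg <- readTsv(file.path(out, "cistrans_calls.tsv"))
table(reg$class)
#>        cis discordant      mixed       same      trans
#>        486          1        504        524        485
```

Individual stages are ordinary functions (`buildPseudogenome()`,
`assignReadAllele()`, `nbDifferential()`, `classifyCisTrans()`,
`classifyAutonomy()`, `motifMutationTest()`, `scoreLigandActivity()`,
...) that accept standard containers (`DNAStringSet`, `GRanges`,
`SummarizedExperiment`, data.frames) and can be composed without the
pipeline wrapper.

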