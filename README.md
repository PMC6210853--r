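# HCCrisk

Molecular risk scoring and subclassification of hepatocellular carcinoma
(HCC) from six binary tumor alterations, with the statistics used to
evaluate the score and a calibrated synthetic-cohort generator so the whole
pipeline runs and is tested without patient data.

## What it computes

A minority of HCCs disseminates after curative treatment (resection,
transplantation) and would benefit from systemic therapy. This package
implements a characterization of that subset from alterations assayable in
routine material:

- **Six binary events per tumor:** *CTNNB1*, *TP53* and *TERT*-promoter
  mutation; promoter hypermethylation of an 8-gene tumor-suppressor panel
  (APC, CDKN2A, RASSF1A, HIC-1, GSTP1, RUNX3, SOCS1, PRDM2); global
  hypomethylation of the repetitive elements Alu, LINE-1 and SAT2; and high
  fractional allelic loss, FAL = 100 × (imbalanced / informative
  microsatellite loci), binarized at the cohort median. Methylation calls
  are hierarchical-clustering calls (Ward/Euclidean, k = 2), transferable to
  new samples through a pooled Z-score calibration with a ROC-selected
  threshold on the Alu + LINE-1 + SAT2 Z-score sum.
- **Molecular subclasses A1/A2/B1/B2:** correspondence analysis of the
  complete disjunctive table of the six events, Ward clustering of the 2-D
  sample coordinates, cluster labels from TSG-hypermethylation (B vs A) and
  high-FAL (subscript 1 vs 2) prevalences.
- **The molecular risk score:**

  count = [*CTNNB1* wild-type] + [*TP53* mutant] + [FAL ≥ median] + [global hypomethylation]

  with count ≥ 3 defining the *aggressive molecular pattern*; a
  three-factor variant (count ≥ 2, copy-number alteration fraction ≥ 39% as
  the high-FAL surrogate) serves TCGA-style inputs where repeat-element
  methylation is unavailable.
- **Cohort statistics:** uncorrected Pearson chi-square / Fisher exact
  association scans with pairwise deletion of missing clinical levels,
  Kaplan–Meier estimation and the two-group log-rank test for
  recurrence-free survival.

Data live in an S4 `HccCohort` (a `SummarizedExperiment` holding the
11-marker methylation assay, clinical covariates and mutation flags in
`colData`, plus microsatellite and optional copy-number slots), read and
written as plain TSV (`readCohort()` / `writeCohort()`); mutation calls can
also be derived from a MAF subset (`readMafMutations()`).

## Worked example

```r
library(HCCrisk)

gen      <- generateCohort(generatorConfig(n = 125, seed = 7))
features <- callFeatures(gen$cohort)
round(attr(features, "fal_threshold"), 1)
#> [1] 26.4                     # this cohort's median FAL (%)

sub <- subclassify(features)
table(sub$subclass)
#> A1 A2 B1 B2
#> 15 22 40 48

scores <- scoreCohort(features)
#> scoreCohort (four_factor): 36 aggressive, 89 mild

cl  <- clinicalData(gen$cohort)
agg <- scores$pattern == "aggressive"
logrankTest(cl$rfs_months[agg], cl$recurrence_event[agg],
            cl$rfs_months[!agg], cl$recurrence_event[!agg])
#>  Two-group log-rank test
#> chisq = 11.852, df = 1, p-value = 0.000576
```

The 36 tumors carrying ≥ 3 risk factors recur markedly earlier than the 89
with ≤ 2 — the separation the score is built to detect (the generator's
recurrence hazard scales 2.2-fold per true risk factor, so this is a
positive-control recovery, not a clinical result). `runPipeline(outDir,
config)` performs the same stages end to end and writes every intermediate
table plus a manifest.

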