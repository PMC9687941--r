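# pharmacorank

Prioritizes the proteins associated with a disease by shared-function
frequency and turns the resulting scores into ranked drug-repositioning
candidates, each with a predicted probability-like "pertinency" score.

It is aimed at computational drug-discovery groups who have (or can
simulate) four association tables — protein function annotations,
protein–disease associations, drug–target pairs, and drug–indication
records — plus a Disease Ontology OBO file, and who want an objective,
reproducible ranking of which disease proteins are the most promising
medication targets and which marketed drugs might be repositioned onto
them.

## The method

For one disease with $p$ proteins and one annotation type (UniProt
keywords, a GO namespace, EC numbers, InterPro, …), every specific
function $f$ gets the count $\mu(f)$ of dataset proteins carrying it. A
protein's raw priority score is the dot product of its binary annotation
profile $\rho$ with $\mu$ — the sum of the popularity, within the disease,
of its own functions. Raw scores are normalized by
$\eta = \sqrt{p^2 + a^2}$ (where $a$ is the number of distinct functions
of that type in the dataset) and by $\beta$, the mean number of functions
of that type per protein; the final priority is the mean of the normalized
scores over the usable annotation types.

Priority is then calibrated against **pertinency** — the fraction of
proteins in a score range that are already targeted by phase-4,
non-withdrawn medications indicated for the disease (via ICD→DOID
cross-references). Pooled scores are cut into six equal bins, pertinency
is estimated on six disease folds per bin, and a second-degree polynomial
$y = c_2 x^2 + c_1 x + c_0$ is fitted by inverse-variance weighted least
squares. The fitted curve predicts, for any scored protein, the
probability-like relevance of its drugs to the disease; a two-snapshot
indication comparison supplies an empirical decision threshold
(conventionally 0.1). ROC/AUC validation with per-annotation-type ablation
backs the choice of vocabularies (SUPERFAMILY and ChEBI are excluded by
default).

## Worked example

A three-protein micro-dataset with one annotation type, where A carries
{f1, f2}, B {f1}, and C {f3}:

```r
library(pharmacorank)
cat1 <- functionTypeCatalog("uniprot_keyword")
ann <- annotationTable(data.frame(
  protein_id = c("A", "A", "B", "C"),
  function_type = "uniprot_keyword",
  function_id = c("f1", "f2", "f1", "f3")), cat1)
ds <- proteinDiseaseDataset("DOID:1", c("A", "B", "C"))
finalPriority(ds, ann)
#>   disease_id protein_id  priority n_types_used
#> 1     DOID:1          A 0.5303301            1
#> 2     DOID:1          B 0.3535534            1
#> 3     DOID:1          C 0.1767767            1
normalizationFactors(ds, ann)
#>     function_type a      eta     beta
#> 1 uniprot_keyword 3 4.242641 1.333333
```

A shares f1 and adds f2 (raw $2+1=3$), so it outranks B (raw 2) and C
(raw 1, its function being unshared); the factors are
$\eta = \sqrt{3^2+3^2} = 4.24$ and $\beta = 4/3$ annotations per protein.

The full pipeline on synthetic data with a planted "druggable core"
(disease cores share annotation-pool functions and receive most of the
drugs and indications):

```r
din <- tempfile()
simulateInputs(din, seed = 1)          # 100 diseases, enrichment 8
res <- runAll(din, tempfile(), seed = 1)
meanAucTtest(res$roc$auc)
#>   n_diseases  mean_auc   sd_auc     p_value
#> 1        100 0.7327981 0.135858 2.22266e-31
res$model
#> PertinencyModel: y = 245.0055 x^2 -15.5167 x +0.2903  (r = 0.9681)
res$threshold
#> [1] 0.1
```

The priority score separates drug-targeted core proteins from the
periphery (mean AUC 0.73 across 100 diseases, overwhelmingly above the
chance value 0.5), the quadratic calibration tracks the bin pertinencies
(r = 0.97; the large $c_2$ reflects the narrow synthetic score range),
and the snapshot comparison recommends the 0.1 pertinency threshold.
`topCandidates(res$repositioning, k)` then lists the highest-pertinency
candidate drugs across all diseases. Output files (`scored.tsv`,
`roc.tsv`, `model.json`, `ratios.tsv`, `repositioning.tsv`,
`manifest.json`) land in the output directory and are byte-identical
across runs with the same seed.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/pharmacorank.R` (subcommands `simulate`, `run-all`,
`predict`).

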