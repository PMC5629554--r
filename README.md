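# oncodrug

Network analysis and repurposing of the FDA-approved anticancer
pharmacopoeia (1949–2014), for computational pharmacologists and
drug-repurposing researchers.

The package ships a curated catalog of the 150 anticancer drugs approved in
that window — 61 cytotoxic and 89 targeted agents, with approval years,
cancer-class indications, delivery modes and target genes — and implements
the analyses a network-pharmacology study runs on such a catalog:

* **Catalog analytics** — approval trends by decade, delivery-mode splits,
  Pearson correlation between annual category and delivery counts, and a
  location/family breakdown of the 102 protein targets.
* **Networks** — the drug–cancer bipartite network and the
  cancer–drug–target tripartite network, with degree summaries
  (mean/min/max/skewness), degree-bin breakdowns, two-sample
  Kolmogorov–Smirnov comparisons, and export to edge-TSV, SIF or GraphML.
* **Common-target repurposing** — the guilt-by-association transfer rule:
  if drugs *A* and *B* share a gene target and *B* is approved for cancer
  *D*, then (*A*, *D*) is proposed unless already approved. Predictions are
  evaluated against a clinical-trial count table. An exhaustive brute-force
  enumerator serves as an independent oracle for the indexed predictor.
* **Target genetics** — upper-tail hypergeometric enrichment
  P(X ≥ k | N, K, n) of targets in cancer genes, the four-way
  TargetCancer/TargetOnly/CancerOnly/Other gene-set partition, per-gene
  somatic mutation frequencies from MAF-like tables, K-S and chi-squared
  comparisons across gene sets.
* **Synthetic generators** — seeded catalogs, mutation tables and trial
  tables with known ground truth, so every stage is testable offline.

## Worked example

```r
library(oncodrug)

cat150 <- load_catalog(od_example("drugs.tsv"), od_example("cancers.tsv"),
                       od_example("target_annotations.tsv"))
summarize_catalog(cat150)
#> <od_catalog_summary> 150 drugs: 61 cytotoxic, 89 targeted
#> delivery: single 96, combination 22, both 32
#>   1941-1990: 34 drugs
#>   1991-2000: 38 drugs
#>   2001-2010: 42 drugs
#>   2011-2014: 36 drugs

net <- build_drug_cancer_network(cat150)
net
#> <od_bipartite> 183 nodes (150 drugs, 33 cancers), 248 edges
degree_summary(net, "drug")
#> <od_degree_summary> 150 nodes; degree mean 1.65, range 1-11, skewness 3.37

build_cancer_drug_target_network(cat150)
#> <od_tripartite> 214 nodes (89 drugs, 102 targets, 23 cancers), 313 edges (118 drug-cancer + 195 drug-target)

p <- predict_common_target(cat150)
evaluate_support(p, read_trial_counts(od_example("trial_counts.tsv")),
                 cat150$cancers)
#> <od_prediction_report> 133 predictions over 52 drugs and 16 cancers
#>   supported by >=1 trial: 115; unsupported: 18
#>   top association: Thalidomide - Lymphoma (174 trials)
```

Reading the output: most approvals are post-1990 and targeted agents
dominate recent years; the average drug treats 1.65 cancer classes but the
distribution is strongly right-skewed (doxorubicin tops out at 11). The
transfer rule proposes 133 drug–cancer pairs never approved, and all but a
handful already have registered clinical trials — thalidomide in lymphoma
alone has 174. The report also lists the two pairs on which the shipped
trial table and the recomputed predictions disagree (see the methods
vignette, `vignettes/oncodrug-methods.Rmd`, for why).

The whole pipeline runs from one call:

```r
report <- run_pipeline(run_config(
  catalog = od_example("drugs.tsv"), cancers = od_example("cancers.tsv"),
  annotations = od_example("target_annotations.tsv"),
  trials = od_example("trial_counts.tsv"), out_dir = "out"))
render_report(report, "out/report.md", "markdown")
```

A thin shell wrapper with `run` / `predict` / `simulate` subcommands is
installed at `inst/scripts/oncodrug`.

## Data notes

The fixtures under `inst/extdata/fda2014/` are plain TSV. The per-gene
target-annotation table is a reconstruction that matches the published
category totals exactly (the original per-gene assignment is not published);
it is marked as such in the file. Mutation tables, cancer-gene lists and
oncogene/tumor-suppressor lists are user-supplied inputs; miniature
synthetic stand-ins are generated in the tests.
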