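---
title: "Methods: catalog networks, common-target repurposing, and target genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: catalog networks, common-target repurposing, and target genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncodrug)
```

## The curated catalog and what it models

`oncodrug` analyses the anticancer pharmacopoeia approved by the FDA between
1949 and 2014: 150 drugs, split by mechanism of action into 61 cytotoxic
agents (alkylators, anti-microtubule agents, topoisomerase inhibitors — drugs
that kill rapidly dividing cells) and 89 targeted agents (kinase inhibitors,
monoclonal antibodies, hormone therapies — drugs acting on a specific
molecular target). Each drug record carries its initial approval year, its
cancer-class indications (mapped to 33 higher-level classes such as
*Leukemia* or *Breast cancer*), its delivery mode (given alone, only within
combination regimens, or both), and its printed target tokens.

Target cells in such curations mix gene symbols with mechanism phrases:
`"TOP2A; DNA synthesis"` names one protein target and one mode of action.
`gene_targets()` therefore strips the five mechanism tokens
(`DNA synthesis`, `RNA synthesis`, `Protein synthesis`, `Unknown`,
`Biological`, matched case-insensitively) before any network or prediction
step. Two consequences matter:

* the targeted drugs act on exactly 102 distinct protein targets, and drugs
  sharing only a mechanism phrase (e.g. two alkylators) are *not* linked;
* `BCR-ABL` is kept as a single fusion-target token, as the curation prints
  it; splitting it into BCR and ABL1 would change the target universe
  (ABL1 also appears on its own, as a regorafenib target).

The shipped per-gene annotation table (subcellular location, family,
subfamily for the 102 targets) is a **reconstruction**: the published
classification reports only category totals (45 plasma-membrane targets, 58
enzymes, 28 tyrosine kinases, ...), so we assigned each gene a cell from
standard annotation knowledge such that every published marginal count is
matched exactly. A handful of placements are forced by the margins rather
than by biology (FRK sits in a serine/threonine-kinase slot because the
margins allow only 28 tyrosine-kinase slots for 29 tyrosine-kinase-family
genes); none of the summary statistics depend on which individual gene fills
which slot. The file carries a comment line saying it is reconstructed.

The shipped drug table records doxorubicin as deliverable both as a single
agent and in combination, consistent with the catalog-wide delivery totals
(96 single / 22 combination / 32 both) and with its clinical use.

## Networks and degree statistics

Two undirected networks are built from the catalog:

* the **drug–cancer** network: one node per drug and per indicated cancer
  class, one edge per approved association (183 nodes, 248 edges on the
  shipped catalog);
* the **cancer–drug–target** network over the targeted drugs only: 89 drugs,
  their 102 gene targets and 23 indicated cancer classes, with 118
  drug–cancer and 195 drug–target edges.

Degree is the number of incident edges regardless of partner class.
Duplicate associations collapse to one edge (edges are associations, not
multiplicities). For tripartite drug nodes, `degree_summary()` accepts an
edge-type filter so a drug's *target degree* and *cancer degree* can be
reported separately. Skewness is the conventional sample skewness g1; the
drug-degree distribution is strongly right-skewed (g1 ≈ 3.4), i.e. most
drugs treat one cancer class and a few (doxorubicin, 11 classes) treat many.

Degree distributions are compared with the two-sample Kolmogorov–Smirnov
test. Degrees are heavily tied small integers, so the exact small-sample
p-value is undefined; we report the **asymptotic** p-value and suppress the
tie warning by design. The default is two-sided; the one-sided alternative
is exposed because the published comparison of cytotoxic versus targeted
drug degrees (mean 2.13 vs 1.33) corresponds to the one-sided tail
exp(−2d²·nm/(n+m)) = 0.0378, while the two-sided value is 0.0755 — the
choice is a reporting convention, not a different statistic.

Annual-trend correlations (`delivery_correlation()`) are Pearson
correlations between two annual count series covering **every** calendar
year from the first to the last approval (zero-filled, n = 66 years for the
shipped catalog), with the usual two-sided t-transform p-value. Under this
convention, targeted approvals track single-agent delivery at r = 0.93; the
corresponding cytotoxic/combination correlations are weaker and sensitive
to the year window, so only the strong association is asserted in tests.

## Common-target repurposing

The predictor is the guilt-by-association transfer rule: if targeted drugs
A and B share at least one gene target and B is approved for cancer D, then
(A, D) is proposed unless A is already approved for D. All ordered pairs of
distinct targeted drugs are enumerated, so transfers run in both
directions. Proposals are deduplicated on (drug, cancer), merging the
supporting shared targets and source drugs. Cytotoxic drugs never
participate: mechanism tokens are not targets.

On the shipped catalog this yields 133 novel associations over 52 drugs and
16 cancer classes, with 70 of the 89 targeted drugs sharing at least one
target. `brute_force_predict()` re-derives the same pairs with a literal
triple loop and no indexing; the equivalence of the two routes is asserted
on the shipped catalog and on randomized synthetic catalogs.

`evaluate_support()` joins predictions to a clinical-trial count table and
tallies how many have at least one registered trial. The shipped trial
table is kept verbatim, and it disagrees with the recomputed predictions on
exactly one pair in each direction: it lists axitinib–kidney cancer (an
*approved* indication of axitinib, hence not novel under the transfer rule)
and omits afatinib–breast cancer, which the rule necessarily produces via
ERBB2 shared with four approved breast-cancer drugs. The report therefore
exposes `unmatched_predictions` and `unused_trials` instead of silently
reconciling; with the verbatim table the recomputed support split is
115 supported / 18 unsupported against the published 116 / 17. Missing
trial counts default to zero with a warning so user-supplied catalogs
without a trial table still evaluate.

## Target genetics

Targets are contrasted with a cancer-gene list (a Cancer Gene Census style
input; the real Census and the high-confidence oncogene/tumor-suppressor
lists are user-supplied inputs, not redistributed) through:

* `hypergeometric_enrichment()` — the upper-tail probability
  P(X ≥ k) for k overlap among n targets, K category genes, population N.
  With the published inputs (32 of 102 targets among 594 cancer genes,
  N = 20,729 protein-coding genes) the tail probability is 8.80 × 10⁻²⁵,
  cross-checked against exhaustive summation of the mass function. The
  published figure for these inputs is 3.57 × 10⁻²⁵; no parameterisation of
  the stated counts reproduces it exactly, so the implementation keeps the
  faithful computation and the discrepancy is documented rather than fitted.
* `partition_gene_sets()` — the four-way partition into TargetCancer,
  TargetOnly, CancerOnly and Other genes. The first two partition the
  targets; the last two are restricted to genes observed in the mutation
  table, mirroring how a mutation-data-bounded universe is defined.
* `mutation_frequency()` — a gene's frequency is the percentage of
  **all profiled samples** (the `#n_samples=` header directive, 3,268 in
  the emulated Pan-Cancer setting) carrying at least one record of the gene
  in the included variant classes. Duplicate (sample, gene) records count
  once; genes absent from the table score 0. All seven variant classes are
  included by default — silent mutations are listed among the retained
  classes in the source data description without an exclusion statement —
  and a flag removes them for sensitivity analyses.
* `compare_frequency_sets()` / `threshold_fraction()` — pairwise asymptotic
  K-S tests on per-gene frequency vectors, and the fraction of genes at or
  above a threshold (default 2%) with 2×2 chi-squared tests. The
  chi-squared uses no continuity correction by default (consistent with the
  magnitudes reported for such comparisons); Yates correction is a flag.

The published set means (2.41 / 1.19 / 1.85 / 0.97 %) require the original
TCGA Pan-Cancer mutation table and the July-2016 Census snapshot, neither
of which is redistributable here; they are used instead as *planted truth*
in the synthetic generator, and the tests verify recovery.

## The synthetic generators

`generate_catalog()` emulates the curated table's structure: 150 drugs by
default, targeted with probability 89/150, approval years uniform on
1949–2014, indications per drug and targets per drug following shifted
geometric distributions with means 1.65 and 2.19 — the observed mean drug
degree and mean target degree, giving the right-skewed degree profile the
real catalog shows. Cytotoxic drugs receive a mechanism token (plus,
sometimes, a gene) so that the mechanism-exclusion path is exercised.
Names are deterministic templates (`DRUG0001`, `GENE0001`, `CANCER01`) so
fixtures and diffs are stable.

`generate_mutation_table()` plants per-sample Bernoulli mutation rates per
gene set (defaults: the four published set means over 3,268 samples and the
published set sizes 32/70/537/20,308) and returns the truth map for
recovery tests. Variant classes are uniform over the seven classes and
cohorts are assigned round-robin over the 12 cohort codes. What it does
*not* emulate: cohort-specific mutation burdens and signatures, mutual
exclusivity, gene length effects, or hypermutators — so passing recovery
tests show the statistics are computed correctly, not that real Pan-Cancer
data would reproduce the published means.

`generate_trial_counts()` marks each prediction supported with probability
116/133 (the observed supported fraction) and draws positive counts from a
shifted geometric. All generators consume a single integer seed through one
scoped RNG context (`withr::with_seed`), so identical specs serialize
byte-identically and no global random state leaks.

## Numerical conventions and test scale

* Percentages print rounded half away from zero (23/102 → 23%), matching
  the source tables; means print to two decimals.
* Period counts use closed year intervals; the default bins are 1941–1990,
  1991–2000, 2001–2010, 2011–2014.
* Degree summaries are invariant to row order; tie handling in K-S tests is
  asymptotic throughout.
* The predictor/oracle equivalence is tested on 100 random catalogs of 10 to
  200 drugs; the hypergeometric implementation is checked against exhaustive
  summation for populations up to 50 at 10⁻¹⁰ relative tolerance; K-S
  statistics are checked against the brute-force maximal ECDF gap for
  samples up to 50; rate recovery uses the full 3,268-sample depth with
  moderate gene-set sizes (32/70/150/300), and the K-S power check runs 100
  seeded replicates of 500-gene sets. These sizes keep the whole suite in
  the tens of seconds while leaving the estimates' standard errors far
  below the tested tolerances.

## Known limitations

* The catalog ends at 2014 and is not re-curated from current FDA labels.
* Predictions are unranked; trial counts annotate but do not score them.
* The per-gene annotation table is a margin-exact reconstruction, not the
  original per-gene curation.
* Cancer classes are the curation's 33 higher-level labels; transfers at a
  finer indication granularity (histology, line of therapy) are out of
  scope.
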