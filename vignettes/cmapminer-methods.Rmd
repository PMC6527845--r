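---
title: "Methods: literature scoring, probe reannotation, meta-analysis and the drug-gene connectivity map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: literature scoring, probe reannotation, meta-analysis and the drug-gene connectivity map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmapminer)
```

cmapminer assembles a disease-centred catalogue of candidate genes and drugs
from two evidence streams — a literature corpus and a compendium of
microarray expression datasets — and fuses them into a drug-gene
connectivity map. This vignette explains each model, its assumptions, the
tunable parameters and the design choices made where the procedure was
genuinely open.

## Literature scoring

Abstracts are segmented into sentences and scanned with three dictionary
lexicons (disease, gene, drug; an optional fourth "event" category is used
for display highlighting only). Matching is case-insensitive and
word-boundary-delimited, with ASCII alphanumerics as word characters, so
hyphens delimit tokens ("EGFR-positive" matches "EGFR"). Overlapping
matches are resolved longest-first ("TP53BP1" suppresses a contained
"TP53"); a synonym shared by several canonical entities produces one hit
per entity, preserving ambiguity for curation rather than resolving it
silently.

Each sentence is classified by which categories it contains, giving
per-abstract counts: `N_c` sentences with a disease term and a gene or drug
term; `N_hnc` with disease terms only; `N_gene` / `N_drug` with gene / drug
terms but no disease term. The gene-disease association score of an
abstract is

```
SGD = N_c * w_c + FLAG_gene * N_hnc * w_hnc + FLAG_hnc * N_gene * w_gene
```

with the drug-disease score `SDD` defined analogously. `FLAG_gene` and
`FLAG_drug` are 1 iff the abstract mentions any gene / drug.

Design choices in this module:

* **"Only" means "no disease term".** A strict reading of "sentences
  containing only gene-relevant terms" would zero `N_gene` whenever any
  other term class appears; we instead count sentences with a gene term and
  no disease term. Sentences with both a gene and a drug term but no
  disease term count toward both `N_gene` and `N_drug`.
* **`FLAG_hnc`** is not given a definition by the scoring formula's
  surrounding text; by symmetry with the other flags it is set to 1 iff any
  disease term occurs in the abstract. Since mined corpora are usually
  retrieved by disease keywords (making the flag nearly always 1), an
  `"always-on"` rule is available as an explicit toggle.
* **Weights** default to `w_c = 10`, `w_hnc = w_gene = w_drug = 1`.
  Co-occurrence within a sentence is the strongest signal; only relative
  weight order affects the ranking (scores are linear in the weights), so
  the absolute scale is arbitrary.
* **Per-entity scoring.** To rank candidates, the counts are recomputed per
  candidate entity: for gene g, `N_c` counts sentences containing a disease
  term and g itself, and `N_hnc` the disease sentences without g. A single
  entity-agnostic abstract score could not order entities. Totals are
  summed over abstracts, with `min_score = 1` by default — the stage is
  deliberately recall-oriented because its output feeds manual curation,
  not a final call. The threshold can be applied per-entity (default) or
  per-abstract.
* **Sentence segmentation** splits at terminal punctuation followed by
  whitespace and an uppercase letter or digit, protected by a packaged,
  user-extensible abbreviation list and a single-initial guard. If a title
  is prepended to the abstract text it simply becomes sentence 0.

## Probe reannotation

Probe-to-genome alignments arrive as BLAT PSL records (21 columns, 0-based
half-open coordinates — the convention used internally everywhere; GTF's
1-based closed coordinates are converted at the parser boundary).
Alignments are kept when they have at most one mismatch, no gap openings,
and similarity strictly greater than 90. The PSL format does not define a
"similarity score", so it is computed as `100 * matches / query_size`;
because reasonable alternatives (e.g. percent identity over the aligned
span) are also 0-100 scales thresholded at 90, the formula is a replaceable
function hook.

Affymetrix probe sets (25-mers) are collapsed before assignment: a set is
retained iff some run of at least 3 perfectly matching probes on one
chromosome/strand has consecutive starts no more than `adjacency_gap_bp`
apart. "Adjacent" has no universal definition; the default of 200 bp
reflects that a probe set tiles a short target region, and the parameter is
exposed. Features that survive filtering at more than one locus
(multi-mappers, or probe sets qualifying at two loci) are dropped entirely:
a probe that does not correspond to a unique genomic position cannot be
assigned a unique gene.

Assignment is by strand-aware genomic overlap (a flag relaxes the strand
requirement): one overlapping gene assigns directly; a coding gene beats
any number of overlapping lncRNAs (coding priority, recorded in the
output's provenance columns); two or more coding genes — or two or more
lncRNAs with no coding gene — make the feature ambiguous and it is dropped.
Overlap queries use GenomicRanges; the test suite checks the result against
an independent all-pairs interval scan.

## Expression normalization

Matrices are log2-transformed iff they appear to be on the linear scale.
The detection heuristic — transform iff the matrix maximum exceeds 50 — is
deliberately simple: log2 microarray intensities rarely exceed ~20 while
linear-scale values run to tens of thousands, so anything between is
already suspicious and the threshold is configurable and logged. A
pseudocount `eps = 1` guards zeros. The log step runs before quantile
normalization, matching the usual practice of normalizing log-scale
intensities.

Quantile normalization replaces the value at rank r of every column with
the mean over columns of the r-th order statistics, forcing all columns
onto one empirical distribution. Ties receive the mean of the tied target
values via average ranks. Rows containing any NA are excluded from the
target computation and returned as NA — the simplest contract that
preserves the defining property (identical sorted columns, exact to
1e-12) on complete rows. The implementation is the package's own; the test
suite cross-checks it against limma's on tie-free matrices.

Probe-level values collapse to genes by the arithmetic mean of mapped
probes, per sample; this commutes with sample subsetting and is checked
against a group-by oracle.

## Differential expression and meta-aggregation

Each dataset is tested per gene with a two-sample moderated t: the pooled
per-gene variance is shrunk toward a prior fitted across genes by moment-
matching the mean and variance of log-variances under the scaled-F
hierarchy (prior degrees of freedom `d0` via a Newton inversion of the
trigamma function, prior variance `s0^2`), and the statistic is referred to
a t distribution on `d0 + n1 + n2 - 2` degrees of freedom. Setting
`prior_df = 0` recovers the classical equal-variance t exactly (tested at
1e-9); when the observed spread of log-variances does not exceed sampling
noise, `d0 = Inf` and all gene variances shrink to `s0^2`. Genes with zero
variance in both groups get `t = 0, p = 1` — conservative, and it keeps the
output complete. The implementation is written here; limma, which uses the
same empirical-Bayes scheme, serves as an independent cross-check in the
tests (agreement to ~1e-14 on shared inputs).

Significance is the raw two-sided `p < 0.05`, strict, with no multiple-
testing gate — the per-dataset calls feed a rank-based meta-analysis rather
than standing alone — though a Benjamini-Hochberg column is emitted for
users. Contrasts supported: tumor vs normal, HPV-positive vs negative,
smoker vs non-smoker; groups need at least 2 samples each and other labels
are excluded with a logged count.

Datasets are integrated by robust rank aggregation. Per dataset, genes are
ranked by log2 fold change (descending for the "up" list, ascending for
"down"; ties get average ranks) and normalized by that dataset's gene
count. Under the null a gene's normalized ranks are uniform, so its k-th
smallest rank follows Beta(k, n-k+1); the aggregation-rank (AR) score is
the Bonferroni-corrected minimum over k of that beta CDF:

```
rho = min(1, n * min_k pbeta(r_(k), k, n - k + 1))
```

`n` is per-gene — the number of datasets in which the gene is measured — so
platform coverage differences are not penalized. The displayed meta-score
is `-log10(rho)` signed by direction (a labelled convention for the
heatmap-style summary, not part of the statistic); raw rho is always kept.
Tests verify the score against a binomial-tail evaluation of the beta
order-statistic CDF and its conservativeness under a uniform null.

## Drug-gene connectivity

For gene g and drug d the corpus yields document frequencies: `df_gd`
abstracts mentioning both, `df_g` and `df_d` the marginals, `P` the corpus
size — abstract-level presence, unweighted by SGD/SDD. The connectivity
score is the regularized log-odds

```
theta_gd = ln((df_gd * P + lambda) / (df_g * df_d + lambda)) * (1 + Corr_gd)
```

with `lambda = 1` keeping the ratio defined at zero counts. `Corr_gd` is
the average absolute Pearson correlation between the expression of drug d's
annotated targets and gene g: a flat mean over all (target, dataset) pairs
where both genes are measured with nonzero variance (a per-dataset-means
alternative is exposed as an option), computed on all samples of each
dataset by default. A target that is g itself contributes `|r| = 1`,
capturing the direct-target case; a drug with no usable target pairs gets
`Corr_gd = 0`. Since `(1 + Corr_gd)` multiplies the log term, it also
deepens negative log-odds; no clamping is applied, and the long-format
output retains every component per cell for audit.

## Synthetic data: what it emulates and what it does not

All generators are pure functions of a master seed, with labelled
substreams so adding one generator call never perturbs another; outputs are
byte-identical across runs.

* **Corpus**: 200 abstracts of 4-8 template sentences. Five planted genes
  (among 50 background genes) co-occur with disease terms in half the
  abstracts; background genes appear in gene-only sentences at rate 0.1 per
  gene per abstract (capped at 3 per abstract); six drugs appear in
  drug-disease sentences; one planted drug-gene pair co-occurs with a
  disease term in 20% of abstracts. Sentences are minimal
  subject-verb-object templates: the generator exercises counting and
  scoring, not named-entity recognition — real abstracts bring ambiguity,
  nested symbols and non-ASCII text that these tests deliberately do not
  probe.
* **Expression**: 3 datasets of 200 genes, 10 tumor + 10 normal samples,
  baseline N(8, 1) log2 values. Twenty planted DE genes are shifted by 2
  log2 units in tumors (alternating sign); the planted correlated pair is
  `y = x + N(0, 0.5^2)`, giving the analytic correlation
  `1/sqrt(1 + sigma^2)`. DE genes are disjoint from the correlated pair so
  truth labels stay unconfounded. Real microarray features absent here:
  probe-level noise, batch effects, correlated gene modules,
  platform-dependent dynamic range — so passing tests demonstrate the
  statistics, not robustness to those artefacts.
* **Probe fixture**: an authored toy chromosome with one decoy per filter
  rule (two mismatches, a gap, similarity exactly 90, a multi-mapper, a
  strand mismatch), the coding-over-lncRNA priority case, a coding-coding
  ambiguity, and Affymetrix sets that pass, fail the three-probe rule, and
  fail the adjacency rule. Truth records the intended outcome per feature.

These defaults are the package's reference study conditions; the test suite
and the acceptance script run at exactly these sizes (2,000-gene null and
500-gene power simulations for the DE calibration, 1,000 x 4 uniform-null
ranks for the aggregation check), which keep the full suite under a minute
on one CPU.

## Numerical notes and limitations

* Normalized ranks and rho live in (0, 1]; inputs outside it are rejected,
  and rho is capped at 1.
* Ranking ties break by total score, then abstract support, then
  lexicographically — deterministic output under permutation of inputs.
* The log-scale heuristic can mis-fire on unusual dynamic ranges; the
  threshold is a parameter and the decision is reported.
* The moderated-t prior assumes exchangeable gene variances; strong
  mean-variance trends (as in RNA-seq counts) are out of scope, as are
  covariate adjustment and paired designs.
* The connectivity score inherits literature biases: heavily studied
  entities have large marginals, deflating theta for genuinely linked but
  popular pairs; the per-cell component columns exist precisely so such
  cases can be audited.
* The command-line wrapper (`inst/cli/cmapminer.R`) is a thin shell over
  the exported functions; no computation lives only there.
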