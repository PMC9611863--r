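---
title: "Screening expression panels for tissue-specific genes and validating them by qPCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening expression panels for tissue-specific genes and validating them by qPCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuespec)
```

# The problem

Public expression atlases (Human Protein Atlas, GTEx, ENCODE, Illumina Body
Map) publish per-tissue median expression of every human gene in TPM.
A recurring task is to ask, for a gene family of interest, which members are
*tissue-specific*: expressed meaningfully in one tissue and essentially
nowhere else. Because the atlases differ in tissue coverage, sample counts
and collection protocol, a call made in a single database is fragile; a
robust screen requires the same gene to pass in several independent
databases. The motivating application is the C2H2 zinc-finger family
(HGNC group 28, ~700 genes), where the testis carries by far the largest
tissue-specific fraction, and where testis-specific members are candidate
markers of germ cell tumors. `tissuespec` implements that whole workflow —
screening, cross-database consensus, qPCR validation statistics, and
co-expression clustering — against both real exports and synthetic data
with known ground truth.

# The specificity statistic

For gene $g$ with TPM vector $x$ over tissues and target tissue $t$, the
screen uses the **inverted specificity ratio**

$$ r(g, t) \;=\; \max_{j \ne t} \frac{x_j}{x_t}, $$

the reciprocal of the worst-case fold advantage of the target tissue.
Working with the inverted ratio rather than $\min_j x_t / x_j$ avoids
division by zero when the gene is silent in other tissues: a gene expressed
only in the target tissue gets $r = 0$, the strongest possible call, instead
of an undefined value. A gene is called specific to $t$ when

1. $x_t \ge$ `tpm_min` (default **5 TPM**) — the candidacy floor, and
2. $r(g, t) \le$ `inv_ratio_max` (default **1/3**, i.e. at least a 3-fold
   margin over *every* other tissue).

Both comparisons are inclusive at the boundary ("at least"). Two
equivalent parameterizations of the fold rule circulate: "minimum direct
fold at least 3" and "inverted ratio not exceeding 0.3". They differ in a
thin band ($0.3 < r \le 1/3$), and the published nine-gene testis consensus
contains a gene (ZSCAN5A in HPA, $11.3/34.6 \approx 0.327$) that passes
only under the $1/3$ reading, so `screen_config()` defaults to
`inv_ratio_max = 1/fold_min` exactly; the stricter 0.3 cap remains available
as an explicit override. Tissues are taken as the columns of the matrix
as-is — sub-tissues such as individual brain regions are *not* aggregated,
because the rule compares against every other column individually.

A separate, lower floor (`active_tpm`, default 3 TPM) feeds
`count_active()`, which only counts in how many tissues a gene is
transcribed at all; it takes no part in the specificity call.

# Cross-database consensus

`run_screen_pipeline()` screens one panel per database, intersects the
per-database specific sets by gene ID (`intersect_gene_sets()` keeps the
full $2^D - 1$-region Venn partition, not just the core), and then applies
a second, stricter consensus filter: the minimum across databases of the
direct fold $x_t / \max_{j \ne t} x_j$ must **exceed** 1.5
(`consensus_fold_filter()`, strict inequality, with fold over a silent
background counted as infinite). Genes absent from any one database cannot
satisfy "in all databases" and are excluded and reported, rather than
imputed — the atlases genuinely differ in which family members they
quantify, and an absent measurement is not evidence of specificity.
Joins are by stable gene ID (Ensembl-style); symbols are display-only.

The package ships the published per-database testis summaries of the nine
consensus genes (`published_testis_summaries()`) as a plain-text fixture.
`summaries_to_minipanels()` rebuilds two-column panels from them (target
tissue plus a pseudo-tissue holding the published maximum over other
tissues); this is lossless for the screen because the decision depends on
the other tissues only through their maximum.

```{r}
run_screen_pipeline(summaries_to_minipanels(published_testis_summaries()),
                    "testis")
```

# qPCR relative quantification

Validation data are quantification-cycle (Cq) tables with technical
replicates. Replicates are averaged on the Cq scale first (the
conventional order; a spread above 0.5 cycles is flagged, not discarded),
then converted to a relative abundance against the *geometric mean* of two
reference transcripts (18S rRNA and GAPDH by default):

$$ \mathrm{level} \;=\; E^{\,\overline{Cq}_{\mathrm{ref}} - Cq_{\mathrm{target}}}, $$

with amplification efficiency fixed at $E = 2$ (100% per cycle; a per-call
`efficiency` argument exists, but no calibration-curve machinery is
provided). The geometric-mean construction makes the level invariant to
any sample-wide Cq shift — loading and reverse-transcription efficiency
cancel — and one cycle on the target alone is exactly a two-fold change.
No inter-plate calibrators are modelled; samples are assumed co-run. The
$2^{\Delta Cq}$ model is a modelling choice of this package: it is the
standard reading of geometric-mean reference normalization, fixed here as
the contract rather than inferred from any particular instrument.

# Cohort statistics

`run_cohort_analysis()` compares tumor against normal levels per gene with
rank tests only (expression levels are heavily skewed and the tests must
be invariant to monotone rescaling): Mann–Whitney for independent groups,
Wilcoxon signed-rank for patient-matched tumor/adjacent pairs, two-sided
throughout, $\alpha$ left to the caller. Both kernels delegate to
`stats::wilcox.test` with the exact/approximate switch made explicit and
deterministic: exact null distributions for combined $n \le 12$ without
ties, otherwise the normal approximation with midrank tie correction and
continuity correction. The test suite cross-checks the exact paths against
full enumeration (all rank assignments; all $2^n$ sign patterns) for every
group shape up to combined $n = 8$.

The headline comparison pools healthy-control with tumor-adjacent normal
samples ("pooled", the default), because adjacent tissue is the natural
clinical comparator; `normal_group = "control"` restricts to healthy
parenchyma only. Comparisons run separately per histology stratum (germ,
non-germ, all), controls joining the normal side of every stratum since
they carry no tumor histology. Fold changes are ratios of group medians;
a zero denominator median reports `Inf` with a flag. Strata with fewer
than two samples on either side are skipped and logged, never silently
estimated. No multiple-testing correction is applied across genes — the
intended use is a handful of pre-selected candidates; callers screening
many genes should adjust downstream.

# Co-expression clustering

Transcriptional consistency across a large sample collection is analyzed
with Spearman correlation (midranks; a constant gene gets $\rho = 0$ plus
a flag rather than NA, keeping the matrix complete) and the **sign-blind
distance** $d = 1 - |\rho|$: strong correlation of either sign is
closeness, since coherent anti-regulation is still co-regulation.
Clustering is agglomerative with complete linkage (`stats::hclust`), whose
merge heights are monotone; the dendrogram is diagnosed by the cophenetic
correlation and the number of clusters is chosen by **mean silhouette
width** on the precomputed distance, ties broken to the smallest $k$.
A single transparent index was preferred over index-ensemble packages:
it is reproducible from first principles, and on the kind of data this
workflow targets the plausible answers (2–3 clusters) are separated
clearly enough that an ensemble adds dependency weight, not information.
Merge ties essentially never occur on continuous correlation distances;
where they do, `hclust`'s deterministic order applies, so repeated runs
give identical trees. Dendrograms export to Newick with branch lengths
equal to merge-height differences.

# Synthetic data: what it emulates, and what it does not

Every stage is testable offline through three generators, all pure
functions of (config, seed):

* **`generate_panels()`** — several correlated pseudo-databases over the
  same genes: a shared log-normal background (defaults meanlog 0.5,
  sdlog 1.0 on the natural-log scale — a heavy right tail with most mass
  in the 0.5–5 TPM range, the shape of real per-tissue TPM summaries),
  per-database log-normal jitter (sdlog 0.2), and planted target-specific
  genes. Planting is enforced *by construction after the jitter*: a
  planted gene's target value is set to
  $\max(5,\ \mathrm{fold} \times \max(\mathrm{others})) \times U(1, 1.3)$
  in every database, and any background gene that drifts above a 1.5-fold
  target advantage is pulled back under that cap. Recovery tests are
  therefore sharp — the screen must find exactly the planted set, with
  zero tolerance — rather than probabilistic.
* **`generate_qpcr_cohort()`** — reference genes at a base Cq of 15 plus a
  per-sample Gaussian loading shift (sd 0.5 cycles) that the normalization
  must cancel; target genes with log-normal biological spread (sd 0.5 on
  the log2 scale) around a unit baseline; planted genes suppressed by a
  configurable fold in germ-histology tumors; replicate noise sd 0.1
  cycles, three replicates. Default arm sizes mirror a realistic
  orchiectomy series: 2 healthy controls, 27 germ tumors with 7 adjacent
  normals (6 patient pairs), 4 non-germ tumors with 4 adjacent normals
  (3 pairs). Controls carry `histology = NA` — healthy parenchyma has no
  tumor histology — and join the normal side of every stratum.
* **`generate_correlated_blocks()`** — genes sharing a per-block latent
  sample factor, $x = \rho_w z_b + \sigma \varepsilon$, optionally with a
  fraction of sign-flipped genes to exercise the sign-blind distance.
  With $\sigma = 0$ the within-block Spearman correlation is exactly 1.

What the generators deliberately do **not** emulate: read-level sequencing
noise and normalization artifacts (TPM matrices are drawn directly),
correlated background co-expression modules, tissue-shared expression
programs, batch structure between qPCR plates, or PCR inhibition and
efficiency drift. Passing the recovery tests shows the decision rules and
statistics are implemented correctly and are sharp under their stated
assumptions; it does not certify performance on real atlas exports, where
boundary genes genuinely move between database versions.

# Numerical choices and degenerate inputs

* Even-count medians are the mean of the central pair, matching the
  half-values (4.25, 0.95, ...) seen in published per-database summaries.
* A zero target TPM makes the inverted ratio undefined and raises an
  error; such genes can never reach the 5-TPM floor anyway.
* Panels reject NA unless the reader is told what they mean
  (`na_action = "drop"` with a warning, `"zero"`, or `"error"`).
* GCT/TSV writers emit the shortest decimal form that round-trips through
  `as.numeric`, so read–write–read is the identity.
* All-zero paired differences give a degenerate signed-rank result
  (p = 1, flagged); all-equal distance matrices flag the cophenetic
  correlation as undefined rather than returning 0/0.
* Test and acceptance problem sizes — 100-gene x 20-tissue panels,
  100 recovery seeds, 2000 null cohorts at 8 vs 8, 8-point clustering
  oracles — were chosen so each property is measured with comfortable
  statistical margin while the whole suite runs in seconds.

# Limitations

The screen is a thresholding rule, not an estimator with uncertainty: it
inherits the atlases' averaging choices and is sensitive to genes sitting
exactly at a boundary, which is precisely why the cross-database consensus
and the wet-lab validation stages exist. The qPCR model assumes perfect
doubling and co-run samples. Cluster-number selection by silhouette is one
defensible index among several; on weakly structured data the selected
$k$ should be read as a suggestion, supported by the cophenetic
diagnostic, not a sharp inference.
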