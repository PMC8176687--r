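---
title: "Classifying expression inheritance modes in reciprocal crosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying expression inheritance modes in reciprocal crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossmode)
```

## The design and the question

A reciprocal-cross expression study profiles four genetic groups: two
purebreds and the two F1 crosses that differ only in which breed supplied
the sire. `crossmode` uses the digit convention 1 = Bt×Bt, 2 = Bi×Bt,
3 = Bt×Bi, 4 = Bi×Bi (sire first), with Bt the taurine and Bi the
indicine breed. Note that under this labeling group 2's *dam* is Bt and
group 3's dam is Bi; the maternal/paternal rule definitions below are
only self-consistent with this mapping, which is why the package fixes it
in `genetic_groups()` rather than leaving it configurable.

For each gene that is differentially expressed between the purebreds, the
question is how the two alleles combine in the crosses. On the log2 CPM
scale with group means $m_1..m_4$, define the six pairwise absolute
differences $d_{ij} = |m_i - m_j|$ and normalize each by the purebred
separation $d_{14}$. Equivalently, place each cross on the purebred axis:

$$ r_g = \frac{m_g - m_4}{m_1 - m_4}, \qquad g \in \{2, 3\}, $$

so $r_g = 1$ means "at the Bt purebred level" and $r_g = 0$ "at the Bi
level". The key statistic is the reciprocal-cross separation ratio
$d_{23}/d_{14} = |r_2 - r_3|$.

## The rule system

With thresholds $\theta_{hi} = 0.8$ and $\theta_{lo} = 0.2$ the default
(`consistent`) mode partitions the $(r_2, r_3)$ plane into mutually
exclusive regions:

* **Maternal**: $|r_2 - r_3| > \theta_{hi}$, $r_2 > 1 - \theta_{lo}$,
  $r_3 < \theta_{lo}$ — each cross tracks its dam.
* **Paternal**: $|r_2 - r_3| > \theta_{hi}$, $r_3 > 1 - \theta_{lo}$,
  $r_2 < \theta_{lo}$ — each cross tracks its sire.
* **Taurine dominant**: $|r_2 - r_3| < \theta_{lo}$ and both
  $r_g > 1 - \theta_{lo}$ — both crosses at the Bt level. *Activation*
  if Bt is the high expresser ($m_1 > m_4$), *inhibition* otherwise.
* **Indicine dominant**: $|r_2 - r_3| < \theta_{lo}$ and both
  $r_g < \theta_{lo}$; activation/inhibition by whether Bi is the high
  expresser.
* **Additive**: $|r_2 - r_3| < \theta_{lo}$ and both $r_g$ in the closed
  central band $[\theta_{lo},\, 1 - \theta_{lo}]$.
* **Complex**: anything else.

Maternal and paternal calls carry a taurine/indicine flavor given by
which purebred is the high expresser. Boundary conventions are strict
inequalities for the $\theta$ conditions and a closed interval for the
additive band; grid-enumeration tests verify the regions are pairwise
disjoint and match an independently coded rule table.

The published inequality sets that motivated this system are also
available verbatim as `mode = "as_printed"`, evaluated in printed order
with first match winning. Two caveats make that mode audit-only: the
printed dominant rules (`diff2–4/diff1–4 < 0.8` and the like) admit
additive geometries, and no additive rule is defined at all, so additive
genes surface as dominant or complex. The printed list also repeats its
final label with contradictory sub-conditions; by symmetry with the
taurine dominant pair, the second occurrence is treated as indicine
dominant *activation*. The default mode replaces the dominant-rule
inequalities with explicit proximity-to-the-dominant-parent conditions
($r_g > 1-\theta_{lo}$, resp. $< \theta_{lo}$) and adds the additive
band; this is the package's own consolidation of rules whose printed
form was not mutually exclusive.

### Numerical guards and degenerate inputs

Ratios blow up when the purebreds are barely separated, so classification
requires $d_{14} \ge$ `min_d14` (default 0.5 log2 units, about a 1.4-fold
purebred difference); genes failing the guard are `UNCLASSIFIED`, which
is a guard outcome rather than a biological class. Because the guard is
an absolute log2 separation it is deliberately *not* scale-invariant,
while the rule regions themselves are invariant to adding a constant to
all four means or multiplying them by a positive constant (tested). In
practice the guard rarely binds because, as in the motivating analysis,
classification is restricted to purebred DEGs. A completely flat profile
($d_{14} = 0$) has undefined ratios and is likewise `UNCLASSIFIED`.

The classifier is a pure function of the diff-ratio set, the sign of
$m_1 - m_4$ and the thresholds. `pairwise_diffs()` carries the signed
relative positions `rel2`, `rel3` alongside the six absolute differences
and five ratios because the absolute ratios alone do not determine on
which side of a purebred a cross sits.

## Expression preprocessing

The preprocessing stages follow standard bulk RNA-seq practice:

* **CPM filter** — genes below 0.5 CPM in all but `min_samples - 1`
  samples are removed. How many samples must pass is not dictated by the
  threshold itself; the default (3) is the size of the smallest design
  cell per tissue and sex, so a gene expressed in a single full cell
  survives. The filter is applied per run; for per-tissue analyses pass
  the tissue's columns.
* **TMM normalization** — `tmm_factors()` delegates to edgeR's
  trimmed-mean-of-M-values implementation with the method's canonical
  constants (30% M-trim, 5% A-trim, reference = sample whose scaled upper
  quartile is closest to the mean upper quartile), then rescales to
  geometric mean exactly 1. A step-by-step reimplementation of the
  trimmed, inverse-variance-weighted mean serves as the independent
  oracle in the test suite.
* **log-CPM** — defined as $\log_2(\mathrm{CPM} + 0.5)$. This form is
  finite at zero counts and exactly invariant to doubling a sample's
  counts and library size together, and a hand calculation can check any
  entry. The prior compresses differences for genes below a few CPM,
  which slightly biases their diff-ratios toward zero; such genes are
  typically excluded by the expression filter anyway.
* **Batch centering** — `batch_center()` wraps limma's
  `removeBatchEffect` (per-gene least squares with sum-coded batch
  columns, preserving tissue/group/sex structure), with a rank check
  that warns and no-ops on batch components confounded with preserved
  factors. On balanced designs group contrasts are unchanged to 1e-9.
* **MDS** — pairwise sample distances are the root-mean-square of the
  top 500 largest absolute log2 fold changes per pair (leading fold
  change, pairwise selection), embedded with classical scaling.
  Coordinates are defined up to rotation/reflection, so tests compare
  distances, never axes.

## Differential expression

`de_test()` performs a per-gene Welch two-sample t-test on log2 CPM,
pooling sexes, with Benjamini–Hochberg adjustment within the contrast.
This is a deliberate, documented stand-in for moderated linear-model
pipelines (voom-style precision weights and empirical-Bayes variance
shrinkage are out of scope); the DE stage sits behind a single interface
so a different engine can be substituted. Two consequences are worth
knowing:

* At $n = 6$ per group the Welch/Satterthwaite test is mildly
  conservative — on ideal iid normal null data the rejection fraction at
  $p < 0.05$ sits just below 0.05 rather than at it. The calibration
  tests therefore judge the mean per-simulation rejection fraction at the
  binomial tolerance of a single 1000-gene simulation, and enforce the
  tighter pooled precision only against anti-conservatism, the direction
  that would invalidate FDR control.
* Without variance moderation, power at small effects is below what
  limma-voom would give; the planted-effect power tests use effects of
  4 log2 units where the difference is immaterial.

DEG selection uses a strict inequality at the FDR boundary
($q < 0.05$) and a non-strict fold-change filter ($|\mathrm{log_2FC}|
\ge 1$ for "FC ≥ 2"), matching the conventions of the motivating
analysis. "FC ≥ 2" is interpreted on the mean log2 CPM difference.
`degs_across_tissues()` enumerates all Venn regions of per-tissue DEG
sets; `pairwise_group_deg_counts()` tabulates the six informative
contrasts among the four groups.

## The synthetic-data generator

`sim_config()` + `assign_gene_truth()` + `simulate_counts()` emulate the
study design at desk scale: 5 tissues × 4 groups × 2 sexes × 3
replicates = 120 samples, 24 per tissue. Genes draw a category
(default proportions: 60% null, 30% additive, 1% each of the eight
parental/dominance classes, 2% complex — mirroring a DEG population that
is ~90% additive with a small parent-of-origin minority while keeping
every class testable), a signed breed effect with $|e| \sim U(1, 4)$
log2 units, a baseline $\sim N(5, 2)$ log2 CPM, and a log-normal
negative-binomial dispersion centred at 0.05 — typical bulk RNA-seq
values. Category geometry fixes the noiseless group means (additive =
midpoint; maternal/paternal = dam's/sire's purebred level; dominant =
the dominant breed's level); complex genes rejection-sample cross
positions outside every rule region, since the complex class is shown
but never parametrized in the motivating work. Counts are negative
binomial with mean = library size × the gene's share of total abundance,
so expected column sums equal the library sizes.

Deliberate simplifications:

* Library sizes are log-normal around 1–3 million reads, not the tens of
  millions of a production study — CPM-based inference is scale-free, but
  the count level at a given CPM threshold is much lower here, so
  low-expression behaviour is exercised more than in deep data.
* Tissue, sex and batch effects are independent per-gene Gaussian shifts
  (SD 2, 0.2 and 0.5 log2 respectively) that do not interact with
  inheritance mode; the motivating analysis removes batch and ignores
  sex.
* No read-level structure: no isoforms, no GC/length bias, no correlated
  gene modules, no allele-specific counts. Passing tests therefore show
  the pipeline's statistical machinery is correct under its own model,
  not that real cattle data would classify with the same accuracy.

Recovery behaviour under this model is characterized in the test suite:
noiseless profiles classify back to their planted categories exactly,
and at dispersion 0.05, effects ≥ 2 log2 and $n = 6$/group, at least 90%
of planted parental/dominance genes are recovered across 20 simulation
seeds.

## Genomic context analyses

`neighbor_pairs()` finds lncRNA/coding-gene pairs within 100 kb on the
same chromosome, with distance = the gap between closest gene ends on
1-based closed intervals (0 if overlapping or adjacent; the threshold is
inclusive; a 0-based BED import flag is provided). "Opposite
transcriptional direction" is interpreted as opposite DE fold-change
sign, not opposite strand — the comparison is between DE lncRNAs and DE
genes. Because a lncRNA can have several neighbours, both denominators
are reported: the fraction of opposite pairs and the fraction of lncRNAs
whose usable pairs are majority-opposite. Pairs with a zero or missing
fold change are excluded and counted separately.

`fisher_enrichment()` is a one-sided hypergeometric over-representation
test per gene set (sets intersected with the stated universe first) with
BH adjustment across sets. Gene-set names are opaque strings from user
GMT files; no ontology database is queried.

## Pipeline and reproducibility

`run_pipeline()` executes simulate → normalize → DE → classify →
context with stage toggles, validating dependencies (classification
requires the DE stage, since calls are only made for purebred DEGs). A
single top-level seed deterministically derives per-stage seeds, and all
artifacts are plain text written with fixed formatting, so a rerun with
the same config is byte-identical (checked by checksum in the tests).
All thresholds default to the conventional values (CPM 0.5, FDR 0.05,
FC 2, $\theta$ 0.8/0.2, 100 kb) and are echoed into the JSON run report.

Test problem sizes (hundreds to a couple of thousand genes, 20-replicate
simulations) were chosen so that the full suite characterizes every
statistical property in well under a minute on one core; they are stated
in each test and can be scaled up freely.

## Known limitations

* The DE stage is an unmoderated Welch test; see above.
* Additivity has no published numeric definition ("approximately
  midway"); the closed central band $[\theta_{lo}, 1-\theta_{lo}]$ is
  this package's operationalization and is flagged as such.
* The taurine/indicine flavor of maternal/paternal calls is decided by
  the sign of $m_1 - m_4$ alone.
* Allele-specific (read-level) imprinting calls are out of scope: bulk
  counts cannot assign transcripts to a parental haplotype.
* `UNCLASSIFIED` rates rise as `min_d14` approaches the DE effect sizes;
  the guard should stay well below the fold-change filter in use.
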