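---
title: "Detecting pathways non-randomly targeted by copy-number alterations"
author: "cnapath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting pathways non-randomly targeted by copy-number alterations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnapath)
```

## The question

Tumor genomes accumulate somatic copy-number alterations (CNAs) —
amplified and deleted segments — but individual driver genes are often hit
in only a minority of patients. The hypothesis behind this package is that
selection acts at the level of biologic *pathways*: different patients can
disable or activate the same process through different member genes, so a
pathway can be targeted across most of a cohort even when no single gene
is. `cnapath` asks, for each pathway in a curated collection, whether the
genes altered by CNAs land in it more often than chance placement of the
same number of alterations would predict, and whether the pathway's state
separates patient outcome.

## The statistic

Let $G$ be the number of genes quantified on the platform (a whole-genome
platform has roughly $G = 24{,}000$), $N_i$ the number of those genes in
pathway $i$ (typically 2–80), and $M_j$ the number of genes altered in
sample $j$ under the chosen hit definition (by default any alteration,
amplification or deletion alike). If alterations were placed at random,
the number $k_{ij}$ of altered genes falling in pathway $i$ would be
hypergeometric:

$$P(X = k) = \frac{\binom{N_i}{k}\binom{G-N_i}{M_j-k}}{\binom{G}{M_j}},$$

and the per-sample evidence of targeting is the inclusive upper tail

$$p_{ij} = P(X \ge k_{ij}),$$

implemented via `pathwaySamplePvalue()` on top of R's log-space
hypergeometric routines. Because $M_j$ and $N_i$ enter the null for every
sample and pathway, the score self-adjusts for both per-sample alteration
load and pathway size: a large pathway needs proportionally more hits for
the same surprise.

Population-level targeting combines the per-sample p-values with Fisher's
omnibus statistic

$$X_i = -2 \sum_j \ln p_{ij},$$

referred to the upper tail of a $\chi^2$ distribution, and the family of
pathway p-values is controlled by Bonferroni correction: with $m$
pathways at family-wise level $\alpha$ the significance threshold is
$\alpha/m$ (for $\alpha = 0.05$ and $m = 566$, $8.834\times10^{-5}$).

### Choices the formulas leave open

* **Tail convention.** We use the inclusive tail $P(X \ge k)$, so that the
  observed count itself is evidence and $k = 0$ always yields $p = 1$;
  `tail = "exclusive"` gives $P(X > k)$ for comparison.
* **Degrees of freedom.** Standard theory for Fisher's method assigns two
  degrees of freedom per combined p-value, so the default is
  `df_mode = "two_per_sample"` ($2n$ df for $n$ samples). A literal
  one-df-per-sample variant (`"one_per_sample"`) is offered as a switch;
  it is not the textbook calibration and is off by default.
* **Hit definition.** Amplification and deletion both count as targeting
  events by default (`any_alteration`), since either can serve a tumor's
  ends; single-state analyses are available.
* **Universe.** Every gene on the platform belongs to the sampling frame,
  including altered genes that sit in no pathway. Pathway genes missing
  from the universe are dropped with a logged count.
* **Numerics.** Tail probabilities are computed in log space; per-sample
  p-values below `1e-300` are clamped (with a warning) before the log
  transform so the omnibus statistic stays finite.

### Calibration under discreteness — a deliberate conservatism

Fisher's method assumes continuous uniform null p-values. Hypergeometric
p-values are discrete, and at realistic parameters (a 5% alteration rate
over a 2,000-gene universe gives expected pathway hit counts of roughly
0.1–4) the discreteness is substantial: the null $p_{ij}$ are
super-uniform, each sample's $-2\ln p_{ij}$ is stochastically smaller
than its $\chi^2_2$ reference, and the deficit compounds over a cohort.
The test suite measures this directly on simulated null cohorts: the
fraction of pathways below $p = 0.05$ falls far below the nominal 5%,
for small pathways especially. The population test is therefore
*conservative* — it never over-states significance, and a rejection can
be trusted — but its p-values should not be read as exactly uniform under
the null, and power for very small pathways is limited. We regard this as
a property of the method itself (any discrete-p Fisher combination
behaves this way) and do not apply continuity corrections, which would
trade the guaranteed error control for approximate calibration.

## From array CGH segments to gene-level calls

Array CGH reports copy number at the resolution of BAC clones, whose
genomic mappings are often incomplete. Three coordinate systems are
reconciled before any counting:

1. **Raw** clone positions, as mapped.
2. **Expanded** positions (`expandBacs()`): clones are grown toward a
   165 kb total span — a typical span of fully end-mapped clones — unless
   both end sequences are mapped or the raw span already reaches 100 kb.
   A single-anchored clone grows only away from its anchor; an unanchored
   clone grows symmetrically. Growth proceeds in multi-pass rounds of at
   most 1 kb per side (configurable), so the space between closely mapped
   neighbours is assigned equally to the clones competing for it; when
   one side is blocked, the shortfall is compensated on the free side.
   The round-based increment is our algorithmic realisation of the
   stated *outcome* (equal assignment of intervening space): each round
   a clone may claim at most its fair share (ceiling to the left clone)
   of the gap remaining between the facing edges, so two competitors
   meet at the midpoint while a competitor that stops early releases the
   remainder to its neighbour.
3. **Extended** positions (`extendBacs()`): remaining inter-clone gaps
   are split at their midpoint (an odd base goes to the left clone, a
   deterministic tie-break), producing pseudo-tiling coverage in which
   any genomic region belongs to exactly one clone. By default the
   outermost clones stop at the boundary of the arrayed span; a
   `bounds = "chromosome"` switch tiles to the chromosome ends instead.

Overlapping raw mappings are resolved first (`resolveBacOverlaps()`): a
clone lying entirely inside a larger one is marked a duplicate and adopts
the container's final coordinates; partial overlaps freeze the
overlapping ends, which then behave like anchored ends for both expansion
and extension. Freezing is applied only to the ends actually involved in
an overlap; the clone's other end remains free against third parties.

Genes are associated with clones (`associateGeneBac()`) when they
overlap, the clone spans at least one third of the gene (guarding against
insubstantial overlaps by broad gene mappings), and — under extended
coordinates — at least half the gene lies inside the clone's tile, which
makes the assignment exclusive. The knife-edge case of a gene split
exactly in half across a tile border satisfies the 50% rule on both
sides; we keep the larger overlap and break exact ties toward the
leftmost clone. `genesInAlteredSegments()` then overlays per-sample
altered segments on each gene's assigned tile (or on the gene interval
itself for platforms with gene-level segments), calling `+1`/`-1`/`0`;
when one gene meets both an amplified and a deleted segment in the same
sample, the state with the larger total overlap wins and exact ties are
called `0` with a warning.

All coordinates are 0-based half-open in files and converted to the
1-based closed `GRanges` convention on ingest; strand is ignored
throughout, as copy number is strand-agnostic.

## Outcome association

Per-sample pathway state scores (e.g. externally computed activity and
consistency metrics — their computation is out of scope here) drive a
two-group stratification per pathway (`stratifyTwoGroups()`). The
clustering algorithm behind the published two-group split is not
specified, so the default is two-cluster k-means on standardized scores
with ten restarts under a fixed seed; a median split and a Ward
hierarchical cut are provided as alternatives, and group 1 is always the
higher-scoring group so labels are comparable across methods. Either
one metric or several jointly may drive the split. Separation is tested
with the Kaplan–Meier estimator and the two-group log-rank test
(`kmCurve()`, `logrankTest()`, both thin wrappers over the survival
package; censored subjects at an event time remain at risk, the standard
convention). `survivalScreen()` iterates the test over pathways and
reports both raw flags at $p<\alpha$ and Bonferroni-adjusted flags,
mirroring the two-stage reporting used when screening hundreds of
pathways.

A known small-sample limitation, quantified by the test suite: the
log-rank chi-square reference is a large-sample approximation. On
cohorts of eight or fewer subjects its p-value can differ from the exact
permutation distribution of the same statistic by more than 0.1 — the
permutation distribution has at most $\binom{8}{4}=70$ support points —
so for very small groups an exact or permutation test should be
preferred. Power is ample at practical sizes: the suite verifies >80%
rejection at a three-fold hazard with 200 subjects.

## What the synthetic cohorts emulate

The generators (`simulationConfig()` and friends) exist so that every
module is testable without any external download. Their defaults are the
study conditions used throughout the tests:

| parameter | default | meaning |
|---|---|---|
| `G` | 2000 | gene universe (desk-scale stand-in for ~24,000) |
| `n_pathways` | 100 | pathway collection size |
| `pathway_size_range` | 2–80 | spans the sizes seen in curated collections |
| `n_samples` | 100 | cohort size, same order as a 145-patient study |
| `background_rate` | 0.05 | expected altered fraction per sample |
| `planted_sample_fraction` | 0.9 | a driver strikes most, not all, subjects |
| `amp_del_ratio` | 0.5 | amplifications vs deletions among hits |
| `hazard_ratio` | 3 | survival effect between pathway-state groups |
| `baseline_hazard` | 0.1 | reference-group event rate per unit time |
| `censor_rate` | 0.2 | target censored fraction |

Background alterations are gene-wise independent by default; a
`"segment"` mode plants contiguous runs of altered genes (geometric run
length, mean 20) to emulate the segmental structure of real CGH calls.
Planted driver pathways receive excess hits gene-by-gene in a random 90%
of samples, reproducing the observed pattern in which different subjects
target the same pathway through different member genes. Toy genomes lay
clones at irregular spacing with mixed anchoring and inject contained and
partially overlapping clone pairs — the pathologies the coordinate code
must resolve — and place genes centrally within each clone so extended
tiles always capture their genes.

What the generators deliberately do **not** emulate: chromosome-arm-level
biology, recurrent breakpoints, correlation between alteration state and
expression, or any real cohort's alteration spectrum. Passing tests
therefore demonstrate correctness of the statistics and coordinate
algebra under controlled structure, not biological validity on any
particular dataset.

All generators are deterministic given the mandatory seed, and every
randomised routine restores the caller's RNG state, so pipeline reruns of
one configuration are byte-identical (the provenance log deliberately
contains no timestamps).

## Problem sizes used by the shipped checks

The unit suite exercises exhaustive enumeration oracles up to a
12-gene universe, per-base overlay oracles on toy genomes of ≤ 60 genes,
200 null-cohort replicates and 100 planted-recovery replicates at the
default generator scale, and 200 survival power simulations — sizes
chosen so the whole suite completes in a few minutes on one CPU while
keeping Monte-Carlo error small against each tolerance.

## Known limitations

* The population test is conservative for small pathways (discreteness,
  above); ranking by p-value remains informative, absolute calibration
  does not hold.
* Overlapping gene content between pathways is not modelled: pathways are
  tested marginally, and correlated pathways will co-score.
* Sequence-level mapping (BLAT, clone registries, genome-build liftover)
  is out of scope; coordinates are taken as given in the input files.
* No competing-risks modelling; separate endpoints are handled by
  running the screen per (time, event) pair.
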