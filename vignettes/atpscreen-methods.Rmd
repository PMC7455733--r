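---
title: "Models and methods behind atpscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind atpscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atpscreen)
```

# Overview

`atpscreen` analyzes pooled CRISPRi/a screens read out by sorting cells on
a FRET ATP biosensor into their highest and lowest ATP quartiles and deep
sequencing the sgRNA cassettes in each pool. This vignette records the
statistical model, the tunable parameters and why their defaults are what
they are, what the synthetic-data generator does and does not emulate, and
the design decisions taken where the procedure left genuine freedom.

# The scoring model

## Normalization and the sgRNA phenotype

For each sequenced sample, guide counts are normalized to the **total
count of nontargeting guides** in that sample (not the sample total):

$$v_i = \frac{c_i + c_0}{\sum_{j \in \mathrm{NT}} (c_j + c_0)}$$

with pseudocount $c_0 = 1$. Nontargeting guides have no phenotype, so
their total is the natural invariant yardstick: normalizing to it makes
an sgRNA's abundance comparable across pools even when true hits distort
the pool composition, and it is invariant under global rescaling of the
sample (sequencing depth). The pseudocount keeps logarithms finite at
zero counts; at screen depth (hundreds of reads per guide) it is
negligible. The field's screens generally do not state a zero-count
policy, so this is declared here: default 1, configurable.

The per-guide phenotype is the log2 enrichment
$\log_2(v_{\mathrm{high}} / v_{\mathrm{low}})$, computed per replicate and
averaged across replicates. Guides with fewer than `min_counts = 10`
summed raw reads across a fraction pair are set missing for that
replicate — a minimal depth filter, configurable to 0 because the
original analysis states none.

## Dead-sensor artifact exclusion

The screen's control arm repeats everything with a "dead" sensor that
cannot bind ATP: any guide with a phenotype there responds to something
other than ATP (fluorophore maturation, FRET geometry, sorting bias).
Guides whose replicate-averaged dead-sensor phenotype lies beyond
**2 standard deviations** of the nontargeting dead-sensor distribution
are flagged with a direction and excluded from gene summaries, from the
nontargeting reference statistics, and from the quasi-gene pool.

## The gene phenotype: top 3 of 10

A gene's phenotype is the signed mean of its **three strongest eligible
guides**. With ~10 guides per gene of widely varying efficacy, the top-3
statistic rewards concordance among the best guides while ignoring the
inert tail. "Strongest" is by absolute value by default, because the
screen reports both directions; an alternative `mode = "dominant"`
restricts ranking to the direction holding the majority of eligible
guides (ties broken toward the larger top-3 mean), which resists a
single strong opposite-direction outlier. With fewer than 3 eligible
guides, the mean of the remainder is reported with a low-confidence
flag; ranking ties break lexicographically by sgRNA id so results are
deterministic.

# The null model and hit calling

## Quasi-genes

Because the gene phenotype is a top-3 order statistic, its null
distribution is *not* the nontargeting guide distribution — it is wider
and asymmetric. The correct null is built by resampling: each
**quasi-gene** draws 10 nontargeting guide phenotypes (without
replacement within a quasi-gene, with replacement across quasi-genes) and
is summarized with exactly the same top-3 rule. One quasi-gene per
targeting gene gives a null of matched size. Gene Z-scores are computed
against the quasi-gene mean and SD, and the quasi-gene hit rate under any
rule estimates the screen's false-positive rate:
$\mathrm{specificity} = 100\,(1 - \text{quasi hits}/n_{\text{quasi}})$.
Quasi-gene sampling is seeded and reproducible.

## Condition-specific guide-count rules

The default hit definitions count guides beyond **3 SD** of the
(artifact-free, replicate-averaged) nontargeting guide distribution, per
direction:

* **respiratory**: ≥ 2 guides beyond; genes meeting the same rule in the
  same direction on the dead sensor are excluded (gene-level exclusion);
* **glycolytic / basal** (narrower nontargeting distributions): ≥ 3
  guides beyond, counted after removing individual guides flagged at
  2 SD on the dead sensor (per-guide removal).

"Beyond 3 SD" is direction-aware: above mean + 3 SD for high-ATP, below
mean − 3 SD for low-ATP, evaluated separately. Both the guide-count call
and the |Z| > 3 quasi-null call are reported; the guide-count rule is the
default hit list definition, with the Z-score always alongside.

One structural property worth knowing: under the respiratory gene-level
mode, a gene containing a *single* artifact guide keeps that guide in its
live count (only a gene-level dead phenotype triggers exclusion), so such
genes have an elevated false-positive rate relative to quasi-genes, which
are assembled from artifact-free nontargeting guides. This mirrors the
published procedure; the per-guide-removal mode does not have this
property.

## Mann–Whitney concordance

Each gene can be assigned a two-sided Mann–Whitney p-value comparing its
guide phenotypes to the nontargeting guides; low p means the guide set is
concordantly displaced, raising confidence. Exact enumeration is used for
small untied samples (so 3 fully separated guides against 3 controls give
exactly p = 2/20 = 0.10), the normal approximation with tie and
continuity correction otherwise; complete ties return p = 1. Applied as
an optional filter at α = 0.05, it can only remove hits (monotone
filtering) — it trades a substantial fraction of hits for a small gain
in specificity, which is why it is optional rather than default.

# The synthetic screen generator

## Model

Each cell's sort statistic is Gaussian: standard normal for null guides,
shifted by $\delta_{\text{guide}}$ (in population-SD units) for
perturbed ones. The sort threshold is the fixed quartile of the *null*
population — hits are rare, so their effect on the empirical quartile is
ignored, which makes the expected phenotype exactly

$$E[\text{phenotype}] = \log_2 \frac{1 - F(z_q - \delta)}{F(-z_q - \delta)},$$

with $F$ the standard normal CDF and $z_q$ the upper-$q$ quantile
(`expected_log2_enrichment()`). This closed form is the oracle against
which the simulator and the scoring chain are tested; it is antisymmetric
in $\delta$ and strictly increasing.

Sequencing is multinomial per fraction sample with probabilities
proportional to guide abundance times the guide's probability of sorting
into that fraction; optional Dirichlet-multinomial overdispersion is
available but off by default. The dead channel applies artifact shifts
only; the live channel applies ATP effects plus artifacts.

## Defaults and what they emulate

| parameter | default | rationale |
|---|---|---|
| guides/gene | 10 | the screened sublibrary design |
| nontargeting guides | 1,400 | ~1,400 per sublibrary in the screen |
| sort fraction $q$ | 0.25 | quartile sorting |
| reads/guide/fraction | 400 | ≥200 cells/guide collected; read depth is a free parameter of the same order |
| replicates | 2 | replicate-pair analysis of the screen figures |
| guide efficacy | Beta(5, 2) | most CRISPRi guides achieve strong knockdown, with a weak tail; `NULL` fixes efficacy at 1 for oracle tests |
| abundance spread | lognormal, σ = 0.3 | mild representation skew typical of pooled libraries (set once; not tuned) |
| artifact fraction | 1% of guides, ±0.5 SD shift, both channels | rare FRET artifacts large enough for the dead channel to flag |

## What a green test does not establish

The generator emulates sorting statistics and sequencing noise, not
biology: no pharmacology of the substrate conditions, no cell-cycle or
cell-size structure, no FACS optics or gate impurity, no PCR jackpotting
(unless overdispersion is switched on), and the one-dimensional sort
statistic stands in for the FRET ratio itself. Passing tests establish
that the *pipeline arithmetic and statistics* behave as specified under a
faithful noise model — not that any biological conclusion is correct.

# Derived assays

Paired assays (pre/post growth, high/low MitoTracker, high/low ATP after
production blockade) reuse the same normalization and report **linear
fold changes** (`log2` columns alongside); nontargeting guides center at
1 by construction. In the generator, growth rates multiply post-sample
abundance directly; for sort-type assays a content/consumption
multiplier $m$ maps to a sort shift of $\log_2 m$ SD units (so a doubled
mitochondrial content shifts the sort by +1 SD, and a fast ATP consumer,
$m > 1$, is depleted from the high-ATP pool post-blockade).

The **consumption phenotype** is the ratio of the post-depletion to
pre-depletion ATP phenotype. A ratio of two log-scale quantities is
unstable near a zero denominator, so values with |pre| < 0.05 log2 units
are flagged undefined and excluded from hit calling rather than silently
producing huge ratios; a difference-mode reading (post − pre) is
available behind a switch. Hits in derived assays are guides beyond 3 SD
of the mini-library's nontargeting guides.

## ROUT outlier removal and correlation

Correlations (e.g. growth vs ATP phenotype) are computed after ROUT-style
outlier removal: a robust line is fitted by iteratively reweighted least
squares with Lorentzian weights $1/(1 + (r/\mathrm{RSDR})^2)$, where RSDR
is the 68.27th percentile of |residuals| with the $n/(n-2)$
small-sample correction; scaled residuals get two-tailed t-tail p-values
and a Benjamini–Hochberg step at Q = 1% (the method's conventional
default) selects outliers. Fewer than 5 points: no removal, with a
warning. The Pearson coefficient and the F-test p-value for nonzero
slope are then computed on retained points. The BH step is a standard
FDR selection; the originally published procedure's exact stepwise
detail is not reproduced verbatim, but both control the same error rate
and agree on unambiguous fixtures (collinear data untouched, gross
outliers always removed).

# Isotope correction

Natural ¹³C makes a tracer-labeled isotopologue M+j bleed into measured
masses M+i (i ≥ j): each of the $n-j$ unlabeled carbons is ¹³C with
probability $p_{13}$, so the mixing matrix has binomial columns
$M_{ij} = \binom{n-j}{i-j} p_{13}^{\,i-j} (1-p_{13})^{\,n-i}$ —
lower-triangular and column-stochastic. The default
$p_{13} = 0.0107$ is the standard natural abundance; only carbon is
corrected (no ²H/¹⁵N/¹⁸O, no tracer-purity term), matching the stated
scope of the original processing.

The corrected distribution solves $Mx = y$ under $x \ge 0$ by
Lawson–Hanson nonnegative least squares: on noisy measurements plain
back-substitution produces negative isotopologues, which NNLS clips while
staying closest to the data in least squares; exact back-substitution is
available behind a flag for noiseless synthetic inputs. Pool size is the
sum over isotopologues (per cell when a cell number is given);
fractional labeling is $\sum_i i\,x_i / (n \sum_i x_i)$.

# Numerical and design choices

* `expected_log2_enrichment` is evaluated in log space
  (`pnorm(log.p = TRUE)`) so phenotypes remain finite and accurate for
  large |δ|.
* All output tables serialize doubles at 17 significant digits, making
  write→read the identity and repeated writes byte-identical.
* Tie-breaks everywhere (top-k ranking, hit direction when both
  directions qualify) are deterministic: lexicographic by id, then larger
  guide count.
* Guides present in the count matrix but absent from the library are an
  error (mis-joined files), not silently dropped; library guides missing
  from counts become zero rows with a warning.
* The quasi-gene count defaults to the number of targeting genes;
  "specificity" is 1 − quasi-hit fraction (the natural reading of a
  false-positive-rate estimate from a matched null), not a precision over
  called hits.
* RNG: each simulator/null constructor takes an explicit integer seed and
  is fully reproducible from it; derived sub-draws (replicates, channels)
  consume a single stream in a fixed order.

# Known limitations

* The respiratory gene-level dead exclusion cannot remove genes whose
  hit count is reached with the help of a single artifact guide (see
  above); consumers wanting stricter behavior can run any condition with
  `dead_exclusion_mode = "per_guide_removal"`.
* Specificity estimates inherit quasi-gene granularity: with 3,000
  quasi-genes the resolution is ~0.033%.
* The Mann–Whitney normal approximation is used whenever ties exist,
  which with heavily discretized phenotypes (very low counts) can be
  slightly anticonservative.
* The simulator's fixed-threshold sort assumes hits are rare; screens
  where a large fraction of guides shift the readout would shift the
  empirical quartile and bias phenotypes toward zero.
* NNLS is an active-set method on tiny systems here (≤ ~50 unknowns);
  it is not intended for profiles with hundreds of carbons.
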