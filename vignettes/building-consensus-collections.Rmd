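---
title: "Building consensus gene-set collections: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building consensus gene-set collections: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genesetforge)
```

`genesetforge` turns two-group expression microarray comparisons into
direction-split gene sets, consensus signatures across studies, and
enrichment results. This vignette explains the statistical machinery stage
by stage, states every tunable with its default and rationale, and records
the design decisions that were genuinely open.

## The synthetic generative model

All testing rests on a generator whose ground truth is known.
`generate_probe_experiment()` simulates probe-level intensities as

$$I_{ps} = 2^{\,\mu_{g(p)} + a_p + \delta_{g(p)}\,\beta\,\mathbb{1}[s \in \text{group 1}] + \sum_b \lambda_{g(p)b} z_{bs} + \varepsilon_{ps}} + B_{ps},$$

where $\mu_g \sim N(8, 1.5^2)$ is the gene baseline (log2), $a_p \sim
N(0, 0.7^2)$ a fixed per-probe affinity, $\delta_g \in \{-1, 0, 1\}$ the
true direction with effect size $\beta$ (`effect_log2fc`, default 1.0
log2), $z_{bs}$ centred two-level batch assignments balanced within each
group with gene-specific loadings $\lambda \sim N(0,
\texttt{batch\_sd}^2)$, $\varepsilon \sim N(0, \texttt{noise\_sd}^2)$
per-probe residual noise, and $B_{ps} \sim N(50, 5^2)$ an additive optical
background. Two housekeeping control transcripts carry 25 probes each with
5′/middle/3′ position labels, and 200 pure background probes anchor the
background estimate.

Defaults describe a small, clean array series: 1000 genes × 11 probes
(the probe count of the classic 3′ chips), 4 samples per group, 50 genes
up- and 50 downregulated. Two defaults deserve justification:

* **`noise_sd = 0.25`.** Residual per-probe noise after normalization on
  real arrays of this class is roughly 0.2–0.3 log2 units. The choice also
  keeps the series consistent with the quality thresholds the battery
  enforces: the RLE spread of a summarized clean sample scales as
  $1.25\,\sigma/\sqrt{P}$, so at $P = 11$ a residual SD much above ~0.3
  would push every clean array over the hard 0.2 RLE limit — a series that
  noisy would genuinely fail the battery, which is the battery working as
  intended, not a test condition. Power and recovery checks are run
  additionally at the harsher `noise_sd = 0.5`.
* **Differential genes are drawn from the expressed half of baselines.**
  A transcript whose probes sit at the optical background cannot carry a
  measurable fold change — the additive background floor destroys it — so
  injecting effects there would create ground truth the data do not
  contain. Restricting the pool to baselines at or above the median keeps
  injected effects physically recoverable; it also reflects how detectable
  differential expression behaves on real arrays.

Five failure modes emulate the damage classes the QC battery targets:
background shifts of $20 \times$ severity, whole-array scaling by
$2^{\text{severity}}$, silencing of $\min(0.9, 0.15 \times
\text{severity})$ of genes, a multiplicative $2^{-\text{severity}(1 -
\text{position})}$ degradation gradient along the 5′→3′ probe position
(making the 3′/5′ ratio a monotone function of severity), and residual
noise multiplied by the severity. What the generator does **not** emulate:
binary scanner files, spatial artefacts, mismatch probes, probe-sequence
effects, correlated biological replicate structure, and cross-platform
differences. Tests passing on this generator therefore demonstrate that
the *rules* of the pipeline behave as specified, not that any particular
real dataset is clean.

## Quality control

Single-array metrics: average background (mean of background probes),
scale factor ($500 / $ 2%-trimmed mean of non-background intensities; only
its ratio across samples matters), percent present (fraction of probe sets
whose median probe intensity exceeds the 95th percentile of that sample's
background probes — a background-quantile detection call that preserves
the metric's role of comparability across a series without mismatch
probes), and 3′/5′ intensity ratios of the two housekeeping controls.
Multi-array metrics: RLE (per-gene log2 deviation from the across-sample
median; per-sample median and IQR) and NUSE (median-polish residual
standard errors, $\text{RMS residual}/\sqrt{P}$, normalized per gene by
their across-sample median; per-sample median). Both are computed from one
median-polish pass over all genes.

The battery (`apply_battery()`) treats background, scale factor and
percent present as *pairwise* metrics — the nominal rule limits the
difference between any two arrays of a series — implemented as deviation
from the series median: an all-pairs rule flags both members of a
discordant pair, whereas the median reference isolates the outlier, and
the choice of reference is otherwise open. Ratio, NUSE and RLE-spread
thresholds are absolute (1.25, 3.0, 1.1, 0.2). No numeric threshold exists
for the RLE *median*, so it is reported for inspection but never flagged
on. The thresholds themselves are the standard recommended values and are
all tunable through `qc_thresholds()`.

## Preprocessing

`background_adjust()` subtracts the per-sample mode of the
background-probe distribution (kernel density peak) and floors at 1 so
log2 stays defined. This replaces the convolution background model of
full RMA deliberately: the downstream contract — injected effects
recoverable, detection calibrated — is validated by the property suite,
and mode subtraction keeps the step transparent. `quantile_normalize()`
(limma's mean-of-order-statistics with tie averaging) operates on log2
intensities, which stabilizes the order statistics. Summarization fits
log2 intensity = overall + probe effect + sample effect per gene by Tukey
median polish, rows (probes) first — Tukey's original sweep order, fixed
here because the algorithm is otherwise under-determined — with at most 10
sweeps and a tolerance of 0.01 on the change in total absolute residual
(`stats::medpolish`'s convergence measure).

One consequence worth knowing: forcing identical distributions compresses
genuine group differences when a noticeable fraction of genes moves. With
10% of genes shifted by 1 log2 unit, recovered fold changes are ~5%
smaller than injected, and at very low noise this also lifts the realized
false-discovery proportion above its nominal level. This is a real,
documented property of quantile normalization, not an implementation
artefact; the recovery tests therefore assert per-gene coverage and a
small mean bias rather than exact unbiasedness.

## Differential expression

`low_expression_filter()` removes the `floor(0.25 × n)` genes with the
lowest mean log2 expression (ties broken lexicographically by identifier,
so the result is deterministic), applied per comparison — the unit of
analysis — before moderation. `moderated_t_test()` is limma's
empirical-Bayes moderated t: per-gene variances shrunk towards a prior
fitted by moment matching on the log variances, p values from the
moderated t with augmented degrees of freedom, B the log posterior odds of
differential expression at a prior proportion of 0.01. B is monotone in
|t| at equal residual df, which is what makes it a stable ranking score;
limits behave as expected (heterogeneous variances → effectively ordinary
t; homogeneous → pooled variance). Adjustment is Benjamini–Hochberg
(`bh_adjust()`, validated against a brute-force min-over-suffix oracle in
the tests). Inclusion rules: adjusted p < 0.05, at most 300 genes per
comparison ranked by B (ties: smaller raw p, then identifier), split by
fold-change sign; a zero fold change joins neither set. Only two-group
comparisons are supported — every collection entry is a group1-vs-group2
contrast by construction.

## Batch handling

`estimate_surrogates()` protects the contrast by residualizing against the
groups, then asks how many singular components of the residuals exceed
chance. Chance is calibrated by parallel analysis with a permutation p
value: each gene's values are independently permuted across samples on the
*raw* matrix and the permuted matrix is residualized before its SVD —
permuting the residuals themselves would break their within-group zero-sum
constraints and deflate the null, turning every dataset into a detection.
A component is kept while $p = (1 + \#\{d^{\text{null}} \ge d\}) / (1 +
\texttt{n\_perm}) \le 0.05$, and never more than `max_sv = 2` components
are kept — the cap guards against overcorrection regardless of what the
detector says.

Each retained surrogate starts as a right singular vector of the
residuals, which can only span the part of a batch vector orthogonal to
the groups. Its group-aligned component is then reconstructed from the
genes: regressing per-gene group differences on per-gene residual loadings
estimates how much apparent group effect rides on the latent factor. This
matters whenever a batch is partially aligned with the groups — without
it, removal leaves the aligned part of the batch inside the group
estimates, and strong effects near the batch scale can flip sign.
`remove_surrogates()` fits each gene on group + surrogates jointly and
subtracts only the surrogate contribution, so the group effect itself is
never regressed away; surrogates collinear with the group design are
dropped with a warning (a fully confounded batch is not correctable by any
method). Because pre-subtracting k fitted covariates silently consumes k
residual degrees of freedom, `moderated_t_test(df_lost = k)` rescales the
residual variance to its unbiased value and reduces the df before
moderation; the pipeline threads this through automatically. Without that
accounting, p values after correction are anticonservative.

## Consensus construction

For a comparison studied by several groups, `consensus_build()` counts,
per gene, the studies whose up set contains it (U) and whose down set
contains it (D). The denominator k is the number of *studies* contributing
at least one set — not the number of sets — because support is evidence
per study, and an empty set is a study that looked and found nothing
(it counts in k but can contribute no genes). Eligibility requires ≥ 8
sets with ≥ 4 per direction. For each threshold τ ∈ {0.30, 0.50, 0.70}:

* up: U/k ≥ τ and D = 0;
* down: D/k ≥ τ and U = 0;
* same: (U+D)/k ≥ τ and min(U, D) = 0.

Direction consistency is strict by default — any opposing-direction
appearance excludes a gene from all categories; a relaxed majority rule is
available as `strict = FALSE` for users who prefer tolerance, but
"consistently dysregulated" reads as zero tolerance and that is the
default. Support comparisons use integer arithmetic
($100\,U \ge \text{pct}\,k$), so a gene in exactly 3 of 10 studies meets
the 30% threshold with no floating-point edge case. Three categories ×
three thresholds give exactly 9 consensus sets per eligible comparison,
nested within category (70% ⊆ 50% ⊆ 30%), with up ∪ down ⊆ same.

## Enrichment

`hypergeometric_enrich()` requires an explicit universe — typically the
genes actually tested in the DE stage — because silently inferring the
background is the classic over-representation pitfall. It reports the
upper-tail hypergeometric p, BH adjustment across the tested sets, the
odds ratio, and a combined score $-\ln(p) \times z$ where z standardizes
the set's observed rank against its rank distribution under seeded random
queries of the same size; sets that rank better than their own chance
behaviour score higher. Gene matching is exact by default with a
case-insensitive option, because collections routinely mix upper-case
human and mixed-case mouse symbols.

`gsea_running_sum()` walks the ranked profile accumulating
$|s|^{\text{weight}}$ (normalized over the set members present) on hits
and $-1/(N - m)$ on misses; the enrichment score is the signed maximum
deviation. At weight 0 it reduces to the Kolmogorov–Smirnov statistic and
is invariant under monotone rescaling of the scores.
`gsea_significance()` uses gene-label permutation (the package consumes
ranked lists, not expression matrices, at this stage, so phenotype
permutation is out of scope), a +1-corrected p so p is never zero, NES by
the same-sign null mean, and the ratio-of-tails FDR over the pooled
normalized null.

## Numerical and degenerate-input conventions

* Median polish: 10 sweeps, tolerance 0.01 (total absolute residual);
  1-probe genes pass through as-is in summaries and are excluded from NUSE
  (no residual information).
* RLE/NUSE need ≥ 3 samples; the across-sample median is degenerate below
  that and the functions refuse to run.
* Zero-variance genes are handled by the moderation prior and counted in
  a message.
* GMT: UTF-8, `\n` endings, line-level duplicate symbols deduplicated
  keeping first occurrence, empty sets written as `name<TAB>info`, exact
  round-trip guaranteed.
* Name grammar: the last `_v_` splits the two group labels (group labels
  therefore must not contain `_v_`, enforced at construction); after the
  `___` separator the first token is the species and the last numeric
  token the set ID, with everything between kept as opaque descriptor
  tokens in order — no attempt is made to type them as age/tissue/sex,
  since the convention allows any order.
* Every stochastic entry point takes a seed and restores the caller's RNG
  state; pipeline reruns with the same inputs and seed produce
  byte-identical GMT output.

## Problem sizes used by the test suite

The suite validates the rules at sizes a laptop runs in about two
minutes: QC battery sweeps use 250-gene series over 20 seeds per failure
mode; recovery and calibration use 600–2000 genes over 5–10 seeds; the
extraction arithmetic check builds all 578 comparisons (1156 sets) from
shortcut DE tables; consensus logic is cross-checked against a per-gene
counting oracle on collections of up to 10 studies; enrichment statistics
are verified against exhaustive enumeration (universes up to 12 genes), a
literal running-sum walk, and an external implementation where available.

## Known limitations

* The preprocessing chain is a deliberately transparent stand-in for full
  RMA: mode-subtraction background, no probe-sequence correction. Its
  contract is effect recovery and calibrated detection, which the suite
  enforces; absolute expression values are not comparable to RMA output.
* Quantile normalization compresses effects under widespread differential
  expression (see above).
* Surrogate detection is limited to two-group designs and at most two
  components; a batch fully confounded with the groups is detected as
  collinear and left uncorrected, with a warning.
* Consensus membership is binary per study; no effect sizes are pooled
  and no meta-analytic p value is computed — agreement, not magnitude, is
  the criterion.
* Cross-platform normalization is out of scope: collections mixing
  platforms should be built per platform and merged at the GMT level
  (`merge_collections()`), which is how the distributable collection is
  assembled.
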