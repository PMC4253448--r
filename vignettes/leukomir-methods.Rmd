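---
title: "Methods: immune-cell-subset miRNome analysis with planted-truth simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immune-cell-subset miRNome analysis with planted-truth simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leukomir)
```

# The analysis problem

Blood-borne miRNA signatures discriminate many diseases, but whole blood is a
mixture: five sortable leukocyte populations (CD3+ T cells, CD14+ monocytes,
CD15+ granulocytes, CD19+ B cells, CD56+ NK cells) plus erythrocytes,
platelets and extracellular vesicles all contribute miRNA. `leukomir`
implements the full analysis used to dissect such signatures when each
population is profiled separately on miRNA microarrays for a case/control
cohort: which miRNAs mark each cell type, which are deregulated by disease
within each cell type, how much of the whole-blood profile the sorted
subsets explain, and how well each subset's miRNome classifies disease
status.

Because raw arrays for such designs are rarely deposited, the package ships
a synthetic-cohort generator with complete ground truth. Every stage of the
pipeline is validated by recovering what the generator planted.

# Preprocessing

Arrays carry replicate probes (40 per miRNA by default). The total
expression value of miRNA $m$ on array $s$ is the plain sum of its probe
signals, $x_{ms} = \sum_{p \in m} g_{ps}$. Arrays are then quantile
normalized jointly: each column is mapped onto the across-array mean of
order statistics, so every sample shares one empirical distribution.
Normalization runs on the linear scale, before the log transform, and spans
all arrays of a run (sorted subsets and whole blood together) because the
downstream cluster analysis views them in one map; a `per_cell_type` scope
exists for runs where joint normalization is undesirable.

Two numerical choices matter here:

* **Ties.** A group of tied values within a column receives the mean of the
  target order statistics over the ranks the group occupies. This keeps
  ties tied, preserves each column's internal ranking, and (unlike
  interpolation rules) is exactly the average the rank range implies. Tied
  blocks are common because undetected signals are exact zeros.
* **Log floor.** Expression is analysed as $\log_2 \max(x, c)$ with
  $c = 1$, so undetected signals sit at 0 on the log scale rather than at
  $-\infty$.

A miRNA is *detected* on an array when its aggregated linear signal strictly
exceeds a threshold (default 0, i.e. any nonzero signal). Vendor
feature-extraction detection flags, when present in the probe table, take
precedence (OR over a miRNA's probes). No general-purpose definition of
"detected" exists for summed probe signals, so the threshold is exposed as
`detection.threshold` and documented rather than asserted.

# Differential expression

Each two-group contrast uses the independent two-tailed $t$ test per miRNA.
Welch's unequal-variance form is the default — it is the default of the
surrounding statistical environment and is safer at $n = 7$ per group — with
the pooled-variance Student form available via `var_equal = TRUE`. Rows that
are constant in both groups get $t = 0$, $p = 1$ when the constants agree;
when they disagree the standard error is zero, the row is flagged
`degenerate` and reported at the smallest positive double rather than an
undefined ratio.

P values are adjusted per contrast with the Benjamini–Hochberg step-up
procedure over the tested universe. The tested universe defaults to miRNAs
detected in at least one sample of either group (`tested = "detected"`);
adjusting over all array features instead is one switch away
(`tested = "all"`) because the choice changes adjusted p values and should
be visible, not implicit.

Reported *candidates* for a contrast are miRNAs with raw $p < 0.05$ that are
detected in **every** sample of at least one group. The raw-p fallback
exists because at $n = 7$ versus $7$ the adjusted tests of
condition contrasts are expected to come up empty (the package's null-cohort
tests quantify exactly this); the detection clause keeps noise-only rows
out. Candidates from several contrasts combine into a union report: one row
per miRNA, one raw-p column per contrast, and an overlap count — the shape
in which multi-contrast deregulation (e.g. a ubiquitous oncomiR) is usually
displayed.

# Cell-type-specific miRNA sets

The core specificity algorithm works per condition:

1. Run all $\binom{5}{2} = 10$ pairwise contrasts between the sorted
   subsets (whole blood never takes part).
2. **Candidate set** of cell type $c$: miRNAs with BH-adjusted $p < 0.05$
   in *every* pair involving $c$.
3. **Disjointification**: any miRNA appearing in two or more candidate sets
   is removed from all of them, leaving five mutually disjoint specific
   sets.

Two interpretation choices are explicit:

* Significance in each comparison is read as a p-value criterion only; a
  `strict_direction` mode additionally requires the miRNA to sit
  consistently above (or consistently below) every other subset. Both are
  implemented; the default is the permissive reading, because the
  step-2 description is stated purely in terms of adjusted significance.
* BH adjustment is per pairwise contrast (10 separate families per
  condition), matching the per-comparison construction; pooling across
  pairs would couple the families.

Ties at the threshold are excluded (strict `<`).

Grouped contrasts compare fixed immunological partitions of the five
subsets — lineage (myeloid CD15/CD14 vs lymphoid CD3/CD19/CD56), line of
defense (innate CD15/CD14/CD56 vs adaptive CD3/CD19), function (antigen
presenting CD19/CD14 vs cytotoxic CD3/CD56) — with the tested universe
restricted to miRNAs detected in all samples of at least one side and
significance at BH-adjusted $p < 0.05$. The overlap of two conditions'
significant sets is partitioned into exclusive/shared-same-direction/
shared-opposite-direction, the content of the usual Venn display.

# Whole blood as a mixture

Physically, whole-blood signal is close to a convex combination of its
cellular compartments. Per donor $d$ the package fits

$$y_m^{(d)} = \beta_0 + \sum_c \beta_c \, x_{mc}^{(d)} + \varepsilon_m$$

across miRNAs $m$, where $y$ is the donor's whole-blood profile and
$x_{\cdot c}$ the donor's sorted-subset profiles. Choices and their
rationale:

* **Scale.** Default is the normalized log2 scale, the scale of the rest of
  the analysis; a linear-scale mode exists because mixing is linear in raw
  signal. The deliberate mismatch (physical mixing is linear, measurement
  noise is log-scale) is what limits a log-scale linear model on real-like
  data — the package reproduces that qualitative behavior rather than
  hiding it.
* **Intercept** included by default; removable.
* **Observations** are the miRNAs detected in at least one of the donor's
  arrays; rows undetected everywhere are degenerate zeros in both $y$ and
  $X$ and would only dilute the fit.
* **Nonnegativity.** `mode = "nnls"` constrains the subset coefficients to
  $\ge 0$ (the intercept stays free, implemented by splitting it into two
  nonnegative columns); with an interior OLS solution the two modes agree.
* Rank-deficient designs (duplicated subset profiles) are flagged and
  solved by the minimum-norm pseudoinverse instead of failing.

Alongside the fit, the package reports per-donor Pearson correlations
between each subset profile and whole blood over all miRNAs, summarized as
a min–max band, and *presence discordance*: miRNAs detected in every
whole-blood sample of a condition but in no sorted-subset sample
(`wb_only` — the footprint of compartments outside the sorted populations)
and miRNAs detected in more than 90% of subset samples but in no
whole-blood sample (`subset_only`). The 90% default is strict `>` on the
fraction, and the whole-blood clause is all-samples, making `wb_only`
deliberately conservative.

# Classification

Disease status within one cell type is classified by a linear-kernel SVM
(`e1071`, cost 1, features standardized on the training fold) under
leave-one-out cross-validation; sensitivity is recall on the disease class,
specificity recall on controls. Two feature regimes:

* `as_published`: the feature list is fixed before cross-validation —
  either supplied, or computed once on **all** samples by the candidate
  filter. This mirrors the common published protocol and is optimistically
  biased, because the left-out sample participates in feature selection.
  The package provides it deliberately and labels the bias.
* `nested`: the identical candidate filter re-runs inside every training
  fold. This is the leakage-free estimate, and on null data it sits at
  chance while `as_published` does not — a contrast the test suite asserts.

The 20-repetition knob exists for protocol parity; with a deterministic
solver and fixed features every repetition is identical, and the package's
tests assert that too. Prediction falls back to the training-fold majority
class (ties toward control) when a fold selects no features or only
constant ones.

# Clustering

Unsupervised structure uses the classic display pipeline: select the 50
miRNAs with the highest variance across the samples of interest (unbiased
$n-1$ variance, ties broken lexicographically for determinism), then
complete-linkage hierarchical clustering on Euclidean distances, rows and
columns independently. Cutting the sample tree into $k$ groups and scoring
label purity (majority fraction per cluster) operationalizes statements
like "samples cluster perfectly by cell type". The variance ranking runs on
log2 values by default; the scale is a parameter because the choice is not
canonical.

# Pathway over-representation

The validated targets of a miRNA set are the union of the per-miRNA target
sets from a user-supplied map (e.g. a miRWalk export); the reference
universe is the union of targets of *all* miRNAs on the array, never a
hard-coded genome, so the null respects the array's annotation coverage.
Each pathway is tested with the one-sided upper-tail hypergeometric
probability of its overlap with the target set, BH-adjusted across pathways
within one query. A reporting filter keeps pathways containing at least 10%
of the query's targets (inclusive $\ge$). Live database access is out of
scope; annotations are files.

# The synthetic cohort generator

`synthetic_config()` encodes the emulated study conditions: 7 donors per
condition, five sorted subsets plus whole blood per donor (84 arrays), 1205
miRNAs, 40 replicate probes. On top of a log-normal baseline (log2 mean 7,
sd 2; a 45% "silent" fraction at background level emulates the large
never-detected portion of an array) the generator plants:

* **Markers**: 20 miRNAs per subset, elevated by 4 log2 units in their own
  cell type — strong, clean cell identity.
* **Disease effects**: 10 miRNAs per subset at ±1.5 log2 units in cancer
  donors of that subset only, plus **one universal miRNA** at +1.5 in every
  subset *and* whole blood, emulating a ubiquitously up-regulated oncomiR.
  Disease-effect miRNAs are drawn from well-expressed baselines, since the
  reporting filter requires detection in all samples of a group and the
  miRNAs this models are abundant.
* **Whole blood** as the weighted sum of the donor's realized linear subset
  signals (textbook leukocyte proportions: CD15 0.55, CD3 0.20, CD14 0.08,
  CD19 0.07, CD56 0.05) plus a **hidden component**: 15 miRNAs expressed in
  no subset, contributed at the remaining weight (0.05) from a bright
  profile (log2 mean 13) — erythrocyte/platelet-like species that are among
  the most abundant in whole blood. Whole-blood measurement noise is
  mean-one multiplicative log-normal, so mixing noise does not inflate
  totals and linear-scale weight recovery is unbiased. The universal
  disease effect multiplies the hidden contribution too, so whole blood
  shows the full planted fold change.
* **Censoring**: linear values below 50 are set to 0, defining the
  detection ground truth.
* Probe expansion splits each value into replicate probe signals
  (Dirichlet-style, CV 0.1) that sum back exactly.

Everything derives from one seed through R's default Mersenne–Twister
stream; the generator saves and restores the caller's RNG state. The truth
object records the marker map, the disease-effect table, per-donor mixture
weights, hidden ids and profile, and the detection mask, so every pipeline
stage has an oracle.

What the generator does *not* emulate: probe cross-hybridization and
sequence identity, batch and spatial artifacts, donor-specific cell-count
variation (mixture weights are shared across donors by default), and
correlated co-regulation between miRNAs. Passing recovery tests therefore
demonstrates correctness of the algorithms under the designed statistical
structure, not performance on any particular real cohort.

When scoring marker recovery, the expected specific sets are
condition-aware: under the control condition they are exactly the planted
markers; under cancer they additionally include the single-subset disease
miRNAs, which are genuinely cell-type specific in patients. This mirrors
how patient-derived and control-derived specific sets differ in real
cohorts.

# Verification strategy and problem sizes

The test suite validates each operation against an independent brute-force
oracle on randomized instances (naive quantile normalization; the literal
BH step-up definition; `stats::t.test`; explicit hypergeometric pmf
summation; an $O(n^3)$ complete-linkage agglomerator; plain set algebra),
against hand-computed worked examples, and end to end by planted-truth
recovery. Recovery checks run on full-scale cohorts (1205 miRNAs, 84
arrays) across 10–50 seeds per property; the oracle-equivalence loops use
hundreds of small random instances per operation. One statistical subtlety
is asserted as such: under the global null, the BH procedure leaves a
single comparison free of discoveries with probability $\approx 1 - q$, so
the zero-discovery rate is evaluated per comparison (expected ≈ 0.95 at
$q = 0.05$), not jointly across all six comparisons of a cohort.

`scripts/acceptance.R` recomputes the pipeline's headline quantities from
scratch on freshly generated cohorts and writes them as JSON; see the
README for how to run it.

# Known limitations

* The specificity algorithm's permissive significance reading can admit a
  miRNA that is above some subsets and below others; use
  `strict_direction = TRUE` when directional coherence matters.
* Per-donor OLS weight estimates are noisy under multiplicative noise on a
  heavy-tailed linear scale (a few bright miRNAs dominate the fit); the
  across-donor mean is the stable estimator and is what the acceptance
  script reports.
* `as_published` classification is intentionally optimistic; treat its
  output as protocol replication, not as a performance estimate.
* Detection is threshold-based unless vendor flags are supplied; counts of
  "detected" miRNAs depend directly on that threshold.
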