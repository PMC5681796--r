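---
title: "Methods: whole-blood miRNA panel analysis in mirpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-blood miRNA panel analysis in mirpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirpanel)
```

## The analysis problem

`mirpanel` implements the analysis of a targeted whole-blood miRNA
qRT-PCR panel measured across three clinical groups: healthy controls
(HC), patients with seropositive rheumatoid arthritis (RA), and their
ACPA-positive, asymptomatic first-degree relatives (FDR, in the cohort
sense — throughout this package the false-discovery-rate quantity is
always called Q). The scientific questions are (i) which miRNAs are
differentially expressed between groups, and (ii) how well a single
miRNA separates two groups when used as a classification biomarker.

The observable is the cycle threshold Ct: the PCR cycle at which a
reaction's fluorescence crosses threshold. One cycle corresponds to one
doubling of template, so Ct is a log2-scale quantity and **lower Ct
means more transcript**. A reaction that never crosses threshold is a
nondetect ("Undetermined"), and reactions with Ct above 35 cycles are
treated as undetectable.

## The normalization cascade

Four stages, in order, implemented by `normalize_cohort()`:

1. **Detectability filter** (`detectability_filter()`). Ct values above
   the limit (default 35, *inclusive*: Ct = 35.0 is detectable) and
   nondetects become missing. An assay missing in more than half the
   samples (configurable) is dropped panel-wide. On the default
   35-assay panel with two non-amplifying members this leaves the 33
   analyzed targets.
2. **Reference Ct** (`reference_ct()`). The per-sample arithmetic mean
   of the chosen reference pair (RNU48 and RNU6B by default). The
   arithmetic mean of Ct values corresponds to the geometric mean of
   linear quantities, the standard for multi-reference normalization.
3. **delta-Ct** (`delta_ct()`):
   `dCt(s, a) = Ct(s, a) - refCt(s)`. Any per-sample additive offset —
   RNA input, RT efficiency — cancels here exactly.
4. **Global-mean centering** (`global_mean_normalize()`):
   `ndCt(s, a) = dCt(s, a) - mean_a'{dCt(s, a')}`, the mean running
   over the global-mean set. By construction each sample's mean over
   that set is zero (to 1e-9). Samples with less than 80% of the mean
   set observed are excluded rather than centered on too little
   information.

The **global-mean set** defaults to all retained target assays,
excluding the two chosen references but *including* candidate controls
that were not chosen (RNU44, U6, miR-16), since those are analyzed as
targets. Both this composition and the alternative that excludes them
are supported via the `mean_set` argument; neither choice can be read
off the source data, so the default is the more inclusive one and is
recorded in the output provenance.

Fold changes use the delta-delta-Ct statistic on group **medians**:
`ddCt = median(case) - median(control)`, `ratio = 2^(-ddCt)`, reported
in the signed reciprocal convention (ratios below 1 as negative
reciprocals, so 0.5 prints as -2 and no value lies in (-1, 1)).

A note on the reference formula: the source protocol's printed formula
contains a stray minus sign ("mean (Ct{RNU48} - Ct(RNU6B)"), but a
*difference* of two reference Cts is not a reference level and would
not cancel loading offsets; the accompanying prose ("average Ct value
of RNU48 and RNU6B") is unambiguous, and the arithmetic mean is what
this package implements.

### Offset invariance, and its one exception

Adding an arbitrary constant to *all* assays of a sample (references
included) leaves the normalized matrix, fold changes, KS distances and
AUCs unchanged to 1e-9 — the tests verify this end to end. The single
exception is censoring: an additive offset can push a reaction across
the absolute Ct = 35 limit, changing which values exist downstream.
That is intended behavior of the filter (absolute detectability is a
property of the reaction, not of the normalized scale), so the
invariance tests disable censoring and the property is stated for the
cascade downstream of the filter.

### Known limitation: fold compression under unbalanced panels

Global-mean centering assumes expression changes average out across the
panel. When they do not — e.g. a panel enriched for miRNAs upregulated
in disease — each case sample's global mean absorbs the average shift,
and every estimated fold is compressed by `2^(mean log2 shift)`. With
effects injected from the packaged comparison table, the RA-vs-HC
column has mean log2 shift 0.277, so a true 3.96-fold change is
estimated near 3.27; the FDR-vs-HC column is nearly balanced (mean
0.058) and estimates are nearly unbiased. This is a property of the
published normalization strategy itself, not of this implementation;
the synthetic-cohort tests document it quantitatively. Censoring of
strongly downregulated assays (whose Ct rises past the limit in case
samples) perturbs those samples' global means and adds a second, smaller
distortion of the same kind.

## Reference-gene stability

Five candidate endogenous controls (RNU48, RNU6B, RNU44, U6, miR-16)
are ranked by four methods, all operating directly on Ct (already log2
scale; no linearization):

- **geNorm** (`genorm_m()`): `M(j)` is the mean over partners k of the
  sample SD of `Ct_j - Ct_k`; iterative elimination of the highest-M
  candidate down to a final pair. Ties eliminate the lexicographically
  later name, making the order deterministic.
- **Comparative delta-Ct** (`comparative_dct_stability()`): the same
  pairwise-difference SDs without elimination.
- **BestKeeper** (`bestkeeper_stats()`): the candidate's raw Ct SD, and
  its Pearson correlation with the BestKeeper index (per-sample mean of
  candidate Cts). Ranking uses the SD (ascending); r is descriptive
  only, because the four-method aggregate needs one scalar per method.
  A constant candidate has undefined r and ranks best by SD.
- **NormFinder** (`normfinder_stability()`): the published two-level
  variance decomposition on log-scale data — per candidate and group,
  an intragroup variance from the two-way (gene x sample) residuals
  with the G/(G-2) inflation, and a shrunken intergroup deviation;
  the stability value adds the absolute shrunken deviation to the
  intragroup standard error. With unequal group sizes, cross-group
  averages are weighted by group degrees of freedom. A single group
  falls back to an intragroup-only variant, flagged in the output.
  Rank agreement on clean synthetic data, not bit-identity with any
  particular web implementation, is the contract.

Aggregate rank (`aggregate_ranks()`) is the geometric mean of the four
per-method ranks (shared-minimum ties), with aggregate ties broken by
geNorm M and then name; the chosen pair is the two lowest. All methods
refuse to run with fewer than 4 samples, and a nondetect among
candidates is a hard error directing the user to impute or exclude
upstream. The pipeline defaults to the *forced* pair RNU48 + RNU6B —
the study's final choice — because the source reports only the chosen
pair, not its four per-method scores; `auto_refs = TRUE` switches to
the stability-driven choice.

## Differential expression

Per miRNA and comparison, on normalized delta-Ct values with pairwise
deletion (at least 2 observations per side):

- **Mann-Whitney U** (`mann_whitney()`): exact enumeration P when
  `n_x + n_y <= 12` with no ties, otherwise the normal approximation
  with tie and continuity corrections. Two identical samples give
  P = 1. The exact branch is verified against full enumeration of all
  `C(m+n, m)` splits for every size up to 6.
- **Benjamini-Hochberg** (`bh_adjust()`): step-up adjustment; the
  family is the miRNA panel *within one comparison* (33 tests),
  matching per-comparison significance reporting.
- Both flags are emitted: raw `P < 0.05` and adjusted `Q < 0.04`. The
  packaged comparison table's significant sets correspond to the raw
  threshold (13 RA-vs-HC, 10 FDR-vs-HC); strict BH at Q < 0.04 on the
  printed P columns yields fewer, a documented discrepancy in the
  source material on which this package takes no position — it reports
  both.
- **Fold rank**: descending signed fold within each comparison, ties
  sharing the minimum rank and then ordered by name.
- **Kruskal-Wallis + Dunn** (`kruskal_dunn()`) for three-group
  contrasts: tie-corrected H, Dunn z on pooled ranks with tie-corrected
  variance; pairwise P unadjusted (no adjustment is prescribed for the
  post hoc in the source protocol), with a BH column alongside.
- **Spearman** (`spearman_cor()`): rank-Pearson rho, asymptotic t
  approximation, undefined under zero rank variance.

## Biomarker evaluation: KS cutoff and ROC

For one marker and two groups (`evaluate_marker()`):

- The **signed KS score** `D` evaluates
  `F_case(t) - F_control(t)` at every pooled observed value and takes
  the signed value of maximum magnitude; `|D|` equals the classical
  two-sample KS statistic, and `D` is positive when the case ECDF lies
  above the control ECDF (cases shifted toward lower delta-Ct = higher
  expression), giving the score's [-1, 1] range. Ties in `|diff|`
  resolve toward the smallest threshold. The **cutoff** is reported as
  that observed delta-Ct value, not a midpoint.
- **Classification at the cutoff** is inclusive on the case side
  (<= for `lower_is_positive`); the direction is inferred from the
  sign of the median difference unless overridden.
- The **ROC** sweeps thresholds over pooled values from (0,0) to (1,1)
  and integrates by trapezoid; the AUC equals `U/(n1 n2)` from the
  Mann-Whitney statistic, a cross-module identity the tests assert.
- `|D| > 0.5` marks a significant separation.

Printed cohort-level values from the source study (KS distances
0.59/0.75/0.49, AUC 0.8072/0.9350/0.7507, the 92%/67% operating
points) derive from raw Ct data that were never deposited; they are
consistency-checked against group sizes in spirit (11/12 = 92%) but
cannot be, and are not, numerically reproduced here.

## Summary structure

`build_fold_matrix()` assembles signed folds as log2 ratios across
comparisons; `hierarchical_order()` clusters rows with Euclidean
distance and average linkage by default — the original heat-map tool's
settings are unstated, so these standard defaults are configurable and
no dendrogram fidelity is promised — and `volcano_coords()` emits
(log2 fold, -log10 P) pairs with the P = 0.05 guide. All outputs are
data; no figure rendering is part of the contract.

## The synthetic cohort generator

`generate_cohort()` draws
`Ct(s, a) = baseline(a) - effect(a, g) + offset(s) + noise`, with

| parameter | default | meaning |
|---|---|---|
| `group_sizes` | 12 HC / 18 RA / 12 FDR | the study design |
| `baseline_ct` | Uniform(18, 32) per assay | typical expressed-miRNA Ct range |
| `group_effects` | 0 | log2 expression shifts vs HC; positive = lower Ct |
| `sample_offset_sd` | 0.8 Ct | per-sample loading offset, shared across all assays of a sample |
| `noise_sd` | 0.25 Ct | per-reaction technical noise, typical TaqMan replicate variation |
| `nondetect_ct` | 35 | censoring threshold (applied downstream, not by the generator) |

The per-sample offset is exactly what reference subtraction and
global-mean centering are designed to remove, so its SD is deliberately
large relative to the noise. The generator emits above-limit values as
numeric so tests can toggle censoring independently.
`effects_from_fixture()` converts the packaged signed folds to log2
shifts for the RA and FDR groups, making the packaged comparison table
the generative truth for end-to-end tests. The source cohort provides
no estimate of its technical variance, so the noise defaults are
field-typical values, chosen once, not inferred quantities.

What the generator does *not* emulate: amplification-efficiency
variation between assays (the efficiency-2 delta-delta-Ct model is
assumed throughout), probe chemistry, technical replicates (one Ct per
sample-assay, as the data model assumes), correlated miRNA co-regulation,
and non-Gaussian outliers. Passing tests therefore demonstrate
correctness of the pipeline's algebra and statistics under the stated
model, not robustness to every failure mode of real qPCR data.

## Problem sizes and numerical conventions

The shipped test suite and acceptance analysis use: 20 seeded cohorts
for fold-recovery (medians across seeds of per-cohort estimates — the
same aggregation as the study-level targets), 500 null panels for the
5% calibration check of the Mann-Whitney rejection rate (band 0.04 to
0.06, covering rank-test discreteness plus Monte-Carlo error), 200
random instances for the exact-test enumeration oracle, and 50 each
for the BH, KS, and AUC oracles. These sizes were chosen to make the
Monte-Carlo error small relative to each tolerance while keeping the
default suite fast.

Numerical conventions collected in one place: detectability is
inclusive (Ct <= limit); the global-mean floor is 80% observed;
stability methods need >= 4 samples and >= 3 candidates (2 for the
pairwise-only methods); geNorm elimination drops the lexicographically
later name on ties; fold ranks share the minimum on ties; KS cutoff
ties resolve to the smallest threshold; case-side classification is
inclusive; signed folds never lie in (-1, 1); and every I/O round trip
is value-identical (17 significant digits).
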