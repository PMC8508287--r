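---
title: "Methods: the Translational Index pipeline and Loewe synergy scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Translational Index pipeline and Loewe synergy scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyTI)
```

# The experiment this package models

Polysome profiling separates a cytoplasmic lysate on a sucrose gradient and
sequences two RNA pools per condition: total **cytoplasmic** mRNA and mRNA
engaged by **polysomes**. Comparing the polysomal-to-cytoplasmic ratio of a
gene between treated (T) and non-treated (NT) cells reads out a change in
*translational efficiency* that is separate from any change in transcript
abundance. The pipeline takes a gene × sample count matrix covering the four
groups {cytoplasmic, polysomal} × {NT, T} and produces, per gene, a
Translational Index with significance and a three-way regulation class.

# The Translational Index

For gene $g$, with group means $\bar{y}_{f,c}(g)$ of normalized counts in
fraction $f$ and condition $c$,

$$\mathrm{TI}(g) = \frac{x_1}{x_2}, \qquad
  x_1 = \frac{\bar{y}_{\mathrm{poly},T}}{\bar{y}_{\mathrm{cyto},T}}, \quad
  x_2 = \frac{\bar{y}_{\mathrm{poly},NT}}{\bar{y}_{\mathrm{cyto},NT}},$$

reported throughout as $\log_2 \mathrm{TI}$. Being a ratio of ratios, the TI
is invariant to per-sample library-size rescaling and to any constant
polysome-loading factor (the overall efficiency with which polysomal
libraries capture material); the test suite checks both invariances
explicitly.

## The fold cut-off is linear

Genes are called regulated when $|\log_2 \mathrm{TI}| \ge \log_2 1.5
\approx 0.585$ and FDR $< 0.05$. The 1.5 cut-off is interpreted on the
**linear** fold scale: typical reported TI values for clearly repressed
genes (e.g. $-0.99$, $-0.54$) and a plausible genome-wide range of roughly
$-2$ to $+2.5$ only make sense as $\log_2$ quantities, and a cut-off of 1.5
*on the log scale* would contradict calling a $-0.54$ gene repressed. Both
`fold_cutoff` and `alpha` are configurable in `ti_config()`.

# Normalization and the expression filter

Size factors are median-of-ratios: for sample $s$, the median over genes of
$y_{gs} / (\prod_s y_{gs})^{1/S}$, computed over genes with no zero count,
then rescaled so the factors' geometric mean is 1. This anchors
normalization in the unregulated majority of genes. **Assumption**: most
genes are unregulated in every library. If a majority of genes shift in one
fraction (for instance, a global translational collapse concentrated in the
polysomal-T libraries), the median absorbs part of the shift and every TI
is biased; the test suite demonstrates this failure mode deliberately, and
analyses of globally-shifted translatomes should treat the TI as relative
to the median gene.

"Expressed" is a normalized-abundance floor: a gene is kept when its
normalized mean is at least `expression_min_mean` (default 10) in **all
four** groups, boundary inclusive. This guarantees the four group means are
positive, so $\log_2 \mathrm{TI}$ is always finite on the filtered set;
genes failing the floor are excluded, never imputed or clamped.

# Significance: an exact permutation test of the interaction

The natural null hypothesis is *no fraction × condition interaction*: the
gene's polysome engagement ratio is the same in T and NT. The test
statistic is the observed $\log_2 \mathrm{TI}$ recomputed under permuted
condition labels. Labels are permuted across the replicate index **within
each fraction**; when both fractions carry the same $(n_T, n_{NT})$ design
— always true for this package's simulated designs — one label permutation
is applied jointly to both fractions, which cancels condition main effects
(transcriptional regulation) out of the permutation distribution. When the
number of distinct assignments $\binom{n_T + n_{NT}}{n_T}$ is at most
`n_permutations` (default 10,000) the enumeration is exhaustive and
$p = \#\{|t_\pi| \ge |t_{obs}|\}/N_{perm}$ with the identity included;
otherwise Monte-Carlo sampling with the standard
$p = (1 + \#extreme)/(1 + B)$ and an explicit seed.

## Discreteness and replicate numbers

Permutation p-values are discrete, and because the label complement negates
the statistic exactly, two-sided p-values come in pairs: the smallest
achievable p is $2/N_{perm}$. Three replicates per group give
$\binom{6}{3} = 20$ assignments and a floor of $0.1$ — **no gene can reach
BH-FDR < 0.05 in a 3+3 exhaustive design**, regardless of effect size. This
is a structural property of assumption-light permutation inference at small
$n$, not a bug; parametric count models buy smaller p-values at 3+3 by
assuming a distribution. Consequences adopted throughout the package:

* Type-I calibration is measured on simulations with 5 replicates/group
  ($\binom{10}{5} = 252$ assignments, granularity $2/252 \approx 0.008$),
  chosen so the permutation null has resolution below the 0.05 level being
  measured.
* The workflow scripts under `analysis/` simulate 8 replicates/group, which
  pushes the test into Monte-Carlo mode (resolution $\sim 10^{-4}$) so the
  BH step can make discoveries.
* With 3 replicates the pipeline still runs end to end and estimates every
  $\log_2 \mathrm{TI}$ accurately; it simply declares nothing significant
  at FDR 0.05, which the recovery tests document explicitly.

BH adjustment is the standard step-up (`stats::p.adjust`), checked in the
tests against an independently written implementation. BH also interacts
with the discrete floor as a cliff: calls appear only once the count of
genes at the floor exceeds $\alpha^{-1} m \, p_{floor}$.

# Transcriptional classification and the cross-table

Transcriptional regulation is measured on the cytoplasmic fractions alone:
$\log_2(\bar{y}_{cyto,T}/\bar{y}_{cyto,NT})$ with the same within-fraction
permutation test and, by default, the same fold/FDR thresholds (no separate
thresholds are established for the transcriptional arm; they remain
independently configurable). `cross_classify()` tabulates translational ×
transcriptional classes as a 3×3 table with row percentages to one decimal.
All three transcriptional cells of every row are always reported, so row
percentages sum to 100 within rounding.

# 5'TOP motif calling

A 5' terminal oligopyrimidine tract is called when the cap-adjacent base
(position 1 of the supplied 5'UTR, which is by contract the transcription
start site) is a C and the maximal run of pyrimidines starting there has
length ≥ 5 — the initial C plus at least 4 more C/T. Decisions taken where
the motif description is soft:

* the run length **includes** the initial C;
* the conventional "about 4–15 pyrimidines" upper bound is **not** a
  disqualifier — longer tracts remain TOP calls (the run length is
  reported for filtering);
* a downstream G-rich region (fraction of G ≥ 0.5 in the 10 bases after
  the run) is reported as `g_rich_downstream` but never gates the call,
  G-richness being a frequent, not defining, feature;
* an N at position 1 yields a negative call with an explanatory reason.

The scanner is equivalent to the regular expression `^C[CT]{4,}` and is
tested against it on random sequences. Set enrichment against a reference
TOP catalogue is the hypergeometric upper tail
$P(X \ge \mathrm{both})$ (one-sided over-representation by default;
two-sided available via Fisher's exact test).

# Assay metrics

Deliberately minimal arithmetic, exposed as functions so analyses are
auditable: dual-luciferase ratio (firefly/Renilla), fold change versus a
positive control, trapezoidal AUC on raw time points (no smoothing or
regridding — the transparent default when an instrument's own summary
method is proprietary), and percent inhibition $100(1 - t/c)$.

# Loewe synergy

Dose–response surfaces are matrices of effects normalized to untreated
control = 1 (inhibition lowers the value), with dose-0 margins present.
Monotherapies are modelled by the four-parameter Hill curve

$$E(d) = E_\infty + \frac{E_0 - E_\infty}{1 + (d/EC_{50})^h},$$

fitted by bounded Levenberg–Marquardt least squares with multi-start over
log-spaced $EC_{50}$ seeds (bounds: $E_0 \in [0.8, 1.2]$,
$E_\infty \in [0, 1.2]$, $h \in [0.1, 10]$ — the data are normalized, so
baselines far from 1 indicate a plating problem rather than pharmacology).
Flat responses raise a degenerate flag and refuse the inverse. The Loewe
expected effect at $(a, b)$ solves

$$\frac{a}{D_A(E)} + \frac{b}{D_B(E)} = 1,$$

where $D_X(E)$ is the closed-form Hill inverse; the root is found by
bisection to $10^{-9}$ in $E$, treating an effect unreachable by one drug
as contributing 0 (equivalent dose → ∞). Margins of the expected surface
are evaluated directly from the fitted curves, so margin consistency is
exact. Correctness anchors: the sham combination (a drug against itself)
satisfies $E(d, d) = E_{mono}(2d)$ and scores ≈ 0 everywhere; a synthetic
surface with a known effect offset injected into its combination cells is
scored back at exactly $-100 \times$ the offset.

The score is $100 \times (\text{expected} - \text{observed})$ percentage
points of control: positive = synergy, 0 = additive, negative =
antagonism. The published analyses this mirrors report only the sign
convention and graphical surfaces, so the linear 100-point scaling is this
package's own convention, chosen for interpretability, not a reconstruction
of any proprietary score. The ±5-point verdict band is a reporting
convenience, configurable, and carries no inferential weight; with
replicate surfaces a per-cell test would be appropriate, and is not
implemented here.

# The synthetic-data generator

`simulate_counts()` draws negative-binomial counts with variance
$\mu + \alpha\mu^2$ and mean

$$\mu(g, s) = \text{base}_g \cdot sf_s \cdot 2^{\,txn_g [c = T]} \cdot
  \rho^{[f = poly]} \cdot 2^{\,te_g [c = T \wedge f = poly]},$$

i.e. transcriptional effects move both fractions, translational effects
move only the treated polysomal group — exactly the quantity the TI
measures. Defaults (all overridable in `sim_config()`): 3 replicates/group
as in a typical profiling design; te class proportions
up:down:stable = 0.015:0.047:0.938, echoing a translatome with ~6% of genes
deregulated, three-quarters of them down; effect magnitudes uniform on
[0.7, 2.5] in $|\log_2|$, matching an observed TI range of about −2 to
+2.5; base abundance lognormal(6, 1) counts; dispersion uniform on
[0.05, 0.2] (typical RNA-seq); library-size factors uniform on [0.7, 1.3];
polysome-loading factor $\rho = 0.8$, kept configurable purely to prove it
cancels. TOP membership has prevalence 0.25 in the te-up class and 0.02
elsewhere, mirroring the strong concentration of TOP mRNAs among
translationally activated genes.

What the generator deliberately does **not** emulate: gene–gene
correlation, batch effects, GC/length biases, isoform mixtures, UTR
secondary structure, or read-level error. Passing tests therefore
demonstrate calibration and recovery under the model's own assumptions —
they do not certify performance on real libraries, where normalization
anchoring and dispersion estimation are the first things to re-examine.

# Problem sizes used in the checks

The automated checks simulate 2,000 genes for recovery and type-I
calibration (3, 5 or 6 replicates/group as motivated above), scan 10,000
random sequences against the regex oracle, enumerate hypergeometric tails
for all universes ≤ 12, and score 6×6 dose surfaces; the analysis workflow
simulates 4,000 genes × 8 replicates. These sizes give Monte-Carlo error
comfortably inside the asserted tolerances while keeping a full run in the
minutes range on one core.

# Known limitations

* Median-of-ratios normalization assumes an unregulated majority per
  library (see above).
* The permutation test needs ≥ 2 replicates per group and is powerless at
  FDR 0.05 in exhaustive 3+3 designs (see discreteness discussion); it
  also assumes exchangeability of replicates within a fraction.
* TI group means use no pseudocount; near-threshold genes with highly
  dispersed counts have noisy TIs, which the permutation test (not the
  point estimate) accounts for.
* The Loewe construction requires monotone inhibitory margins; mixed
  agonist/antagonist responses are rejected rather than modelled.
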