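---
title: "Methods: reference-gene stability analysis in refstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-gene stability analysis in refstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

Relative RT-qPCR quantification divides every target-gene signal by a
normalization factor built from one or more reference genes, on the
assumption that those references are constant across samples. That
assumption has to be demonstrated, not asserted: a panel of candidate
genes is profiled across the sample set and ranked by expression
stability, and the top-ranked genes become the references. `refstab`
implements the standard battery of stability algorithms together with the
quality control and calibration steps that precede them, plus a synthetic
generator that makes the whole pipeline falsifiable at desk scale.

## From wells to a matrix

The raw unit is one well: a (gene, sample, replicate, run) tuple with a
Cq value or a non-detect. Two QC rules are applied before anything else:

* **Replicate filter.** Wells with Cq above `max_cq` (default 35 cycles)
  or with no amplification are excluded, then surviving replicates are
  averaged arithmetically per (gene, sample). Filtering at replicate
  level rather than after averaging is deliberate — it is the stricter
  reading, and it prevents a single failed well from dragging a cell mean
  over the cutoff. Every exclusion is logged with a closed-vocabulary
  reason, and counts are conserved (wells in = survivors + exclusions).
* **Contamination verdicts.** Negative controls (no-template, no-RT) that
  amplify above `max_cq` are recorded as `negligible`; at or below it,
  `fail`. A fail is reported, never auto-excluded: late-amplifying
  controls are routinely judged tolerable relative to 1 ng template
  reactions, and that judgement belongs to the analyst.

Technical variability is summarised as coefficients of variation
(sample SD with the n−1 denominator, divided by the mean, in percent):
within-run replicate CV averaged per gene (intra-assay) and the CV of
per-run means across runs (inter-assay).

## Standard curves and efficiency

For each gene a dilution series (default study design: 10-fold steps) is
fitted by OLS of mean Cq on log10(amount); replicates are averaged per
amount first, so each concentration contributes one point regardless of
replicate count. Efficiency is `E = (10^(-1/slope) - 1) × 100`, reported
unclamped — values outside 90–110% carry a warning but real assays do sit
outside that window. `select_linear_range()` addresses the two standard
failure modes, non-detects at the dilute end and saturation at the
concentrated end: every contiguous sub-range with at least `min_points`
(default 4) usable amounts is fitted and the highest R² wins, with ties
resolved toward the wider range and then the range containing larger
amounts, preserving dynamic range. A saturated (constant-Cq) sub-range has
undefined R² from the regression summary and is scored 0.

## The Cq-to-quantity transform

Stability algorithms other than BestKeeper and ΔCt operate on relative
log2 quantities: `logq[g,s] = (min_u Cq[g,u] − Cq[g,s]) · log2(E_g)`.
Anchoring at each gene's minimum Cq is pure numerical hygiene — any
per-gene constant cancels in every downstream statistic, and the anchor
keeps all values in (−∞, 0] with the per-gene maximum at exactly 0. The
amplification factor `E_g` defaults to exactly 2 rather than to measured
efficiencies: calibration and stability screening are separate
experiments, and a default of 2 keeps the stability stage reproducible
without a calibration file. Measured factors (`1 + efficiency/100`) can be
supplied per gene.

## The four base algorithms

**geNorm.** `V_jk = SD_s(logq[j,s] − logq[k,s])` and `M_j = mean_k V_jk`.
The gene with the largest M is removed and M recomputed until two genes
remain; those two are inseparable by construction (their mutual ratio is
the only evidence left) and share rank 1.5. Each gene's reported value is
its M at removal. Equal values share averaged order-based ranks, so the
all-identical degenerate panel ranks everyone equally. The companion
statistic `V(n/n+1)` — the SD across samples of the difference between
log2 normalization factors built from the top n and top n+1 genes — is
provided with the conventional 0.15 threshold for deciding how many
references suffice.

**Comparative ΔCt.** The same pairwise-SD construction applied directly
to Cq. With a common amplification factor of 2 it coincides exactly with
first-pass geNorm M — an identity the test suite asserts to 1e-10 on
random matrices, since it is a sharp regression test for both
implementations.

**BestKeeper.** Descriptive statistics on raw Cq. The dispersion
"SD (± Cq)" follows the original tool's convention of the mean absolute
deviation from the arithmetic mean (`dispersion = "sd"` switches to the
n−1 SD); genes with dispersion above 1 cycle are flagged inconsistent.
The BestKeeper index is the per-sample geometric mean of all genes' Cq,
and each gene is Pearson-correlated against it. Because it works on raw
Cq, BestKeeper is the one algorithm sensitive to per-sample loading
shifts — the invariance tests assert this asymmetry in both directions.

**NormFinder.** On the additive model `y[g,s] = α_g + β_s + ε[g,s]`, the
naive per-gene residual mean square `u_g` from the two-way decomposition
is contaminated by the other genes' noise through the per-sample means;
with k genes, `E[u_g] = σ²_g(1 − 2/k) + Σσ²/k²`, so
`σ̂²_g = max(0, k/(k−2) · (u_g − U/(k(k−1))))` with `U = Σu_g` is
unbiased for `σ²_g`. The ungrouped stability value is `σ̂_g`. With groups,
the variance is estimated within each group and combined with the
inter-group deviation `d` of the gene's sample-centred profile as
`mean over groups of (|d| + sqrt(σ̂²_grp / n_grp))`. The original
empirical-Bayes shrinkage of `d` is not applied: without replicated
group-level data to set the shrinkage weight the simple combination is
the more transparent and testable choice. Two numerical caveats are worth
stating. First, the matrix must be complete — the two-way decomposition
has no principled treatment of holes, so callers subset to complete
samples (the pipeline does this automatically, with a message). Second,
the `max(0, ·)` truncation and the concavity of the square root make
`σ̂_g` a biased estimate of very small σ: when `σ²_g` is small relative
to the estimator's own sampling noise (driven by the leakage term
`Σσ²/k²`), a sizable fraction of draws truncates at zero and the mean of
`σ̂_g` falls noticeably below σ even though `σ̂²_g` is unbiased where
truncation is inactive. This is a property of the estimator itself, not
of the implementation; the test suite measures it directly.

All four algorithms emit "lower = more stable" values and fractional
(average) ranks, so the rank vectors are directly comparable. Pairwise
statistics (geNorm, ΔCt, BestKeeper correlations) use pairwise-complete
samples with a minimum overlap of 3.

## Consensus

The RefFinder-style aggregate takes each gene's four base ranks and
reports their geometric mean, itself ranked ascending. The final
consensus sums the five rank vectors — the four base algorithms *and* the
aggregate. The double-counting is intentional: it mirrors the common
published procedure of treating the web aggregator as a fifth voter, and
the package documents rather than repairs it. Ties in the rank sum break
by geometric-mean rank, then lexicographic gene id, and the tie-break
used is recorded in the output rather than claimed to match any external
tool. Inter-algorithm agreement is the Pearson correlation between rank
vectors (numerically a Spearman-type statistic, since the inputs are
ranks), with two-sided p-values from the t-transform on G−2 degrees of
freedom; a value-based correlation is available as a sensitivity flag.

## The synthetic generator

`simulation_config()` defaults describe the study design the package is
built around: 12 candidate genes × 25 cell lines in triplicate, with
subgroups "ovarian" (11), "colon" (9) and "other" (5). Latent log2
expression is `x[g,s] = −(β_s + d_g,grp(s) + ε_g,s)`: a shared loading
shift `β_s ~ N(0, 1)` (about one Cq cycle of common input variation,
the scale of routine RNA-input differences), per-group offsets `d`, and
per-gene biological noise `ε`. Three genes are planted stable (noise SD
0.1 log2 units, no group offset), eight span a 0.5–1.5 noise gradient,
and one is confounded — quiet within groups (SD 0.2) but shifted +1 log2
unit in the colon subgroup, the failure mode that marginal-variance
methods under-penalise. The latent scale maps to cycles through each
gene's amplification factor; replicate noise of 0.15 cycles reproduces
intra-assay CVs well under 1% at Cq ≈ 20; baselines span Cq 18–28; and a
hard detection threshold turns any replicate above Cq 35 into a
non-detect, exercising the QC path. All draws flow from one seeded
generator in a fixed order (shifts, biological noise, replicate noise),
so a config is a complete, reproducible description of a dataset.

What the generator deliberately does not emulate: raw fluorescence or
melting curves (the pipeline starts at Cq), stochastic detection near the
limit (dropout is a hard threshold), heavy-tailed or correlated
biological noise, plate-position effects, and between-run drift (single
run by default). Passing the planted-recovery test therefore shows the
algorithms separate stability classes under the additive Gaussian model
they all assume — it does not certify performance on real panels whose
noise violates that model.

## Validation scales and numerical choices

The test suite runs at fixed, seeded sizes chosen to keep the full run in
tens of seconds while leaving comfortable statistical margins: 200
generated panels for planted-set recovery (the top-3 must match the
planted trio in ≥ 95%), 500 Monte-Carlo replicates for estimator-recovery
checks at k = 6 genes × n = 100 samples, 100 random matrices for the
geNorm/ΔCt identity at tolerance 1e-10, and 500 replicates for
standard-curve slope unbiasedness (|mean bias| < 3 SE). R² ties in range
selection are compared at 1e-12; stability identities at 1e-10; exact
arithmetic contracts (means, CV, efficiency algebra) at machine
precision. Degenerate inputs fail loudly and early: fewer than 3 genes
(geNorm/ΔCt), fewer than 4 (NormFinder, whose k/(k−2) correction needs
k > 2 with margin), incomplete matrices in NormFinder, non-positive Cq in
BestKeeper, constant rank vectors in the correlation.

## Known limitations

* Rankings, not guarantees: all algorithms assume no coordinated
  regulation across the candidate panel; a panel of co-regulated genes
  ranks confidently and wrongly, which no statistic here can detect.
* The NormFinder small-σ bias described above: SD-scale estimates of
  genes much quieter than the panel's aggregate noise are conservative
  (biased low), so very stable genes look slightly less stable than they
  are — the ranking is typically unaffected, the absolute value is.
* The grouped NormFinder combination is the unshrunk `|d| + SE` form;
  with very small groups it over-penalises genes whose group deviation is
  mostly sampling noise.
* geNorm cannot separate its final pair, and its removal order among
  near-tied genes is decided by floating-point comparison; ranks beyond
  the top pair are stable but the recorded removal order among ties is
  not meaningful.
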