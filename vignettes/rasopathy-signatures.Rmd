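---
title: "Deriving and validating RASopathy PBMC transcriptional signatures"
author: "rasosig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating RASopathy PBMC transcriptional signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rasosig)
```

# The analysis problem

Germline mutations in RAS-MAPK pathway genes (the RASopathies — here the
Noonan-syndrome genes *PTPN11* and *SOS1*, and the *SHOC2* mutation causing
Noonan-like syndrome with loose anagen hair) perturb intracellular signalling
in ways that leave transcriptional footprints in peripheral blood mononuclear
cells (PBMCs). Given an Illumina BeadChip-style probe × sample intensity
matrix with per-probe/per-sample detection p-values, and a sample sheet with
group labels (control, PTPN11, SOS1, SHOC2), ages, sexes and differential
leukocyte fractions, `rasosig` derives, for each mutation group and for the
pooled "RASopathy" cohort, a differential-expression *signature* and
validates it three ways: a Monte Carlo permutation estimate of the
false-positive fraction, a full leave-one-out (LOO) classification analysis,
and unsupervised clustering. Signatures are then mined locally for gene-set
over-representation and transcription-factor (TF) / target circuits against
user-supplied GMT collections.

The pipeline stages, in order:

1. scaling, log2 transformation, and detection filtering;
2. removal of probes correlated with age, sex or leukocyte composition;
3. log2-ratio transformation and triple-criterion signature selection for the
   four case-versus-control comparisons;
4. permutation-based false-discovery estimation;
5. full leave-one-out classification.

# Preprocessing

**Scaling and log transform.** Each sample column of a linear-scale matrix is
rescaled to a common target mean (default: the global mean intensity), then
log2-transformed (`scaleAndLog()`). Intensities are floored at 1 beforehand.
Cubic-spline normalisation is assumed already applied by the scanner
software; the package never re-does it.

**Detection filter.** A probe is kept when its detection p-value is below
0.01 in at least 50% of the samples *of at least one group*
(`detectionFilter()`, all three parameters configurable). Requiring detection
within a group rather than overall protects probes expressed only in the
small mutation groups (SOS1 has 6 samples, SHOC2 has 5). The thresholds are a
design choice of this package: the exact upstream rule is not public, and
p < 0.01 in half the samples of a group is a common BeadStudio-era
convention.

**Confounder filter.** Bulk PBMC expression tracks cell composition and
demographics, so each probe is tested against seven covariates: age
(Pearson), sex (point-biserial, i.e. Pearson against a 0/1 code) and the five
differential leukocyte fractions (Pearson). A probe is removed when *any* of
the seven association p-values falls below `alpha = 0.01`
(`confoundFilter()`). P-values rather than raw correlation magnitudes are
used so the rule adapts to the cohort size; both the threshold and the
covariate list are exposed. Probes with constant values have undefined
correlations; they are retained and noted in the filter report rather than
silently dropped. The report records which confounder triggered each removal.

**Log2 ratios.** `toLog2Ratio()` subtracts, per probe, the mean over
control-group samples, so control rows are zero-mean and case entries read
directly as log2 fold changes versus the control average. The control mean is
the natural reference: it makes the heatmap's control block centre on zero
and the case blocks show signed regulation.

# The triple selection criterion

For one comparison (case groups vs controls), a probe enters the signature
iff **all three** hold, with strict inequalities:

* fold change: |mean case log2 ratio − mean control log2 ratio| > 0.5;
* two-sample t-test p < 0.01 (Welch by default; pooled Student available);
* signal-to-noise ratio |SNR| > 0.5, where
  SNR = (mean_case − mean_control) / (sd_case + sd_control)
  with unbiased (n−1) standard deviations — the Golub-style discriminative
  statistic standard in expression classification.

Defaults live in `signatureThresholds()`. Welch is the default t-test because
group variances are not assumed equal between a 5-sample mutation group and
21 controls. Degenerate inputs are pinned down explicitly: two constant
groups give SNR 0 when means agree and signed infinity otherwise (infinite
SNR always passes a magnitude threshold but is excluded from LOO weights,
where a finite weight is required).

The fold-change term is computed as the case-minus-control difference of
log2-ratio means. When the ratio reference is the comparison's own control
group — the primary analysis — this equals the mean case log2 ratio exactly;
the difference form stays well defined under label permutation and inside
cross-validation folds, where the reference group changes, and per-probe
constant shifts cancel from every downstream score.

The four comparisons (`defaultComparisons()`) are: the pooled NS+NS/LAH
cohort (all three mutation groups) vs controls, then each of PTPN11, SOS1 and
SHOC2 alone vs controls.

# Permutation estimate of the false-positive fraction

`permutationFDR()` shuffles the case/control labels among the samples of the
comparison (group-size preserving — the permuted case arm always has the
original size), re-runs the full triple criterion, and records the null hit
count; the false-positive fraction is estimated as
mean(null hits) / observed hits, with 2000 permutations by default. Zero
observed hits yield an `NA` estimate with the null counts still returned for
audit. Two choices worth making explicit:

* the confounder filter is *not* re-run per permutation: it does not use the
  group labels, so it is permutation-invariant;
* the denominator is the observed hit count (the standard FDR reading), not
  the probe total.

Permutations are drawn over a sample-id-ordered pool, so the estimate is
invariant to the row and column order of the input under a fixed seed.

# Leave-one-out weighted-voting classification

`looClassify()` removes each sample in turn, re-derives all four signatures
on the remaining samples, and scores the held-out sample once per signature
with a Golub-style weighted vote

score = Σ_g w_g (x_g − b_g) / Σ_g |w_g|,

where w_g is the probe's training-fold SNR and b_g the midpoint of the two
training group means. Positive scores vote for the case group; the
normalisation makes scores invariant to probe order and to uniform rescaling
of the weights. The held-out sample contributes to no training statistic —
perturbing it can never change its own fold's signatures or weights (this is
asserted by an exact test). Folds whose re-derived signature is empty score 0
and are flagged rather than failing the run. The weighted vote is the
canonical construction for SNR-selected signatures; it is isolated behind
`weightedScore()` so alternatives can be swapped.

`scoreSeparation()` then applies a two-sided Welch t-test to one signature's
scores between two groups and reports the threshold maximising balanced
accuracy (ties resolved to the midpoint of the tied interval). Constant
scores yield p = 1 with a degenerate flag.

# Gene-set enrichment and TF/target circuits

External web tools (keyword, kinase-substrate, interactor and TF-binding-site
databases) are deliberately out of scope; their statistics are reimplemented
locally over user-supplied GMT collections (`readGMT()`).

* `hypergeomEnrich()` computes the upper-tail hypergeometric probability of
  the observed overlap between signature genes and each set. The universe
  defaults to the union of the sets, but the pipeline passes the
  detected-and-unconfounded probe list: that is the hypothesis space the
  signature was selected from, and a whole-genome universe would overstate
  enrichment. `enrichSignature()` adds direction stratification (all / up /
  down), mirroring analyses run separately on up- and downregulated genes.
* `circuitDetect()` searches for TFs that are themselves in the signature
  with at least `minTargets` of their annotated targets also present, and
  tests the targets' direction split with an exact two-sided binomial test
  (p0 = 0.5). A circuit is flagged when that bias has p < 0.05. The binomial
  test is this package's operationalisation of "targets preferentially
  down-modulated"; orientation (targets concordant or anti-correlated with
  the TF) is reported, never filtered, since both patterns are biologically
  meaningful.

# Unsupervised structure

`clusterSamples()` clusters samples on 1 − Pearson correlation with Ward
(`ward.D2`) linkage and cuts the tree at k = 4, mirroring the four
transcriptional subgroups this design anticipates; each cluster × group cell
gets a one-sided Fisher exact enrichment p-value. Ward linkage is the
default on purpose: on weakly correlated profiles, average/single linkage
place their last (highest) merges on outlier singletons, so a k = 4 cut
returns one blob plus three outliers; Ward's variance-minimising merges
produce balanced clusters that track group structure. Average linkage and
the other `hclust` methods remain one argument away. A constant matrix makes
correlation undefined; the function falls back to Euclidean distance with a
warning. `exportHeatmap()` renders the signature-block heatmap (columns
ordered control → PTPN11 → SOS1 → SHOC2, diverging palette centred at zero)
and always writes the plotted values as TSV next to the image.

# The synthetic-data generator

Patient microarray data were never deposited, so `simulatePBMC()` generates
matrices with the statistical structure the analysis assumes:

x_gs = μ_g + δ_g·sign_g·[s ∈ group(g)] + β·c_s·[g confound probe] + ε_gs,

with μ_g ~ N(8, 1.5²) log2 baseline intensities, ε_gs ~ N(0, residualSd²),
planted signature probes per mutation group, and confounder-correlated probes
whose slope is β log2 units per confounder SD. Defaults are the study
conditions: 20,589 probes; 21/17/6/5 samples; planted per-group signatures of
225 (PTPN11), 73 (SOS1) and 1407 (SHOC2) probes mirroring the gene-specific
signature sizes; a two-fold effect (1.0 log2) over 0.5 log2 residual noise;
150/150/200 age/sex/leukocyte confound probes with β = 0.5.

Confounder distributions are not documented for the original cohort, so the
generator uses what is realistic for a paediatric blood study: age uniform on
2–18 years, sex Bernoulli(0.5), and the five leukocyte fractions Dirichlet
with concentration (55, 35, 6, 3, 1) — the typical neutrophil / lymphocyte /
monocyte / eosinophil / basophil differential. Detection p-values are
Uniform(0, 0.01) for detected probe/sample pairs and Uniform(0.05, 1) for
dropouts; probes in the lowest 70% of baseline intensity drop out of 80% of
samples, calibrated so the detected-and-unconfounded throughput lands near
the ~5,600-of-20,589 range typical of PBMC BeadChips. Planted signature and
confounder probes are drawn from the expressed pool — differential expression
is only observable in detected probes. Noise is homoscedastic by default; an
inverse-gamma per-probe variance option (`probeVarShape`) is provided because
real array data are heteroscedastic.

What the generator does *not* emulate — and therefore what passing tests do
not certify about real data: probe–probe correlation beyond the planted
block structure, partially overlapping signatures between mutation groups
(planted sets are disjoint), batch effects, intensity-dependent variance
coupling, or bead-level artefacts. Tests on these simulations demonstrate
statistical correctness of the machinery, not biological validity of any
particular signature.

# Numerical and design notes

* Ties at thresholds are resolved strictly (`>` and `<`), matching the
  criterion definitions.
* Signature entries are sorted by decreasing |SNR|; directions are derived
  from the sign of the mean log2 ratio and validated by the class.
* `permutationFDR()` can exceed 1 on null data (observed hits at the noise
  level); it is an estimate of a fraction, not a probability, and is reported
  as computed.
* All stochastic stages take explicit integer seeds; the pipeline derives
  per-comparison permutation seeds as seed + comparison index, and re-running
  an identical configuration reproduces every output byte.
* Test and acceptance problem sizes are the package's own choices: 5000-probe
  simulations with 20 replicates for calibration checks, 200 permutations for
  FDR calibration (the production default stays 2000), and 10–40 replicates
  for power and null-rate checks.

# Known limitations

* **Naive significance of LOO score separation is optimistic.** Re-running
  the whole selection + LOO pipeline on label-permuted (or globally null)
  data and t-testing the re-derived scores rejects far above the nominal
  rate (~50% at p < 0.05 on this design, measured over 40 null replicates):
  leave-one-out scores of selection-based classifiers are not independent
  samples, and the selection imprints group structure on them — the
  well-known difficulty of variance estimation for cross-validation. The
  calibrated check, implemented in the acceptance suite, permutes group
  labels against the *fixed* scores, which restores the nominal 5% rate.
  Score-separation p-values on real labels should therefore be read as
  descriptive strength-of-separation summaries, not calibrated hypothesis
  tests.
* The permutation FDR estimate inherits Monte Carlo noise of order
  1/√(permutations × hits); with very small signatures it is unstable, and
  with zero hits it is undefined (`NA`).
* Probe-to-gene mapping is assumed 1:1; collapsing multiple probes per gene
  is out of scope.
* The enrichment machinery replaces, but cannot reproduce, 2011-era external
  databases; results depend entirely on the GMT collections supplied.
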