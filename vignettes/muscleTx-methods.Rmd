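---
title: "muscleTx: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{muscleTx: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muscleTx)
```

# The experimental setting

muscleTx analyzes a cross-sectional glucose-stimulation experiment on
flight (pectoralis) muscle: animals are sampled at baseline (T0) and at 30
and 60 minutes after an oral glucose bolus, and bulk RNA-seq counts are
obtained per animal. The default design is 4 baseline, 3 early and 5 late
animals. Because each animal is sampled once, there is no within-animal
pairing across timepoints; every contrast is between group means.

The central question the package answers is: *which curated candidate
genes (fiber-type, calcium-handling, redox, stress and regeneration
markers) respond to the stimulation beyond ordinary transcriptional
noise?* The yardstick for "ordinary noise" is empirical — a panel of 13
housekeeping genes (`defaultHkPanel()`: Actb, Gusb, Hprt1, Ipo8, Ppia,
Rpl13a, Rpl19, Rps13, Rps18, Rps23, Tbp, Tubb, Ywhag) assumed stable
across conditions.

# Normalization

Counts are scaled to counts per million (`computeCPM()`) and
log-transformed with a pseudocount (`log2Transform()`, default
`log2(CPM + 1)`; the pseudocount is not dictated by any upstream
convention, so we use the standard choice bounded at 0 for absent genes
and record it in the object's metadata). Low-expression filtering
(`filterLowExpression()`) defaults to CPM >= 1 in at least
`min(group sizes)` samples; the exact rule used by any given upstream
dataset is rarely recoverable, so both knobs are configurable and the
removed genes are reported.

"Normalization to the housekeeping panel" is implemented as per-sample
subtraction of the panel's mean log2CPM (`hkCenter()`), equivalent to
dividing CPM by the panel's geometric mean. This is recorded as the
`log2cpm_hk_centered` scale and is the pipeline default
(`center_on_hk: true`); whether centering feeds the delta computation or
only the baseline comparison is genuinely open, so both paths are
supported and the choice is written into the scoring metadata. Note that
because the panel mean is subtracted per sample, centering cancels in any
within-sample pairwise comparison and shifts all deltas of a timepoint by
a common constant — which the empirical null then absorbs; the default is
therefore safe on both paths.

# The responsiveness statistic

For gene $g$ and timepoint $t$,
$$\Delta_{g,t} = \overline{\log_2\mathrm{CPM}}_{g,t} -
  \overline{\log_2\mathrm{CPM}}_{g,T0},$$
means taken over the samples of each group (`groupMeanDelta()`). The
housekeeping deltas at $t$ give the empirical null
$(\mu_{HK,t}, \sigma_{HK,t})$ (`nullSummary()`; sample sd, $n-1$
denominator — with 13 panel genes the denominator choice is material, so
it is stated in the output metadata), and each candidate is standardized:
$$z_{g,t} = \frac{\Delta_{g,t} - \mu_{HK,t}}{\sigma_{HK,t}}.$$
Two-sided p-values use the standard normal reference (`twoTailedP()`),
Benjamini–Hochberg correction is applied jointly across all candidate ×
timepoint tests (`bhAdjust()`; the family is configurable to
per-timepoint), and genes with FDR $q < 0.05$ are called responsive.

Two caveats are deliberate properties of this design rather than bugs:

* **Small-panel miscalibration.** $\mu_{HK}$ and $\sigma_{HK}$ are
  estimates from 13 genes, so $z$ has heavier-than-normal tails: if
  candidate and housekeeping deltas truly shared one normal distribution,
  $z \approx \sqrt{14/13}\, t_{12}$ and the type-I rate at nominal 0.05
  is about 0.083. The acceptance suite asserts this stays below 0.10; a
  $t_{n_{HK}-1}$ reference is available via `reference = "t"` but the
  normal reference is the default because it is what the statistic's
  definition implies.
* **Dispersion mismatch.** Housekeeping genes are *chosen* for stability,
  so their delta spread understates that of an average candidate; the
  statistic is a screening score against the stable-transcription
  baseline, not a frequentist test of the candidate's own null.

The baseline question ("is this candidate expressed above housekeeping
level at all?") is answered by an exact Wilcoxon signed-rank test
(`wilcoxonSignedRank()`) pairing the candidate's per-sample log2CPM with
the per-sample panel mean. Pairing uses all samples by default — the
constitutive-expression claim is about the tissue, not one timepoint, and
a 4-sample baseline-only test cannot reach two-sided p < 0.10 — and is
restrictable via `baselineSamples`. Zero differences are dropped
(Wilcoxon's convention), ties get midranks, the exact two-sided p is
computed from the full $2^n$ sign-assignment distribution (via a
generating-function convolution, so it remains exact with ties) up to
n = 25 and by a tie-corrected, continuity-corrected normal approximation
above. An `elevated` call requires both p < alpha and a positive median
paired difference.

# DEG filtering, enrichment, and functional modules

Upstream differential-expression output (edgeR-style tables) is an
*input*: the package's contribution there is thresholding and everything
downstream, not the GLM. `filterDegs()` applies strict inequalities
(`|log2FC| > thr` AND `q < thr`), defaulting in the pipeline to the
stricter 1.5 / 0.01 pair used for module construction; `contrastOverlap()`
gives the exact two-set Venn partition of DEG sets.

`ora()` is a classical hypergeometric over-representation test against a
local GMT annotation (`readGmt()`); the background is the annotation's
declared universe (configurable), since an unstated background is the
most common source of irreproducible enrichment numbers. Sources such as
KEGG/Reactome/PANTHER/OMIM are merged by concatenating GMTs with
source-prefixed term ids.

Module construction follows "cluster genes by shared enrichment
profiles": each gene's profile is its set of enriched terms
(`geneTermProfiles()`; falling back to the full annotation when nothing
is enriched, and switchable to all-annotated-terms mode), pairwise
distance is 1 − Jaccard, and agglomerative clustering (average linkage;
both configurable) is cut at k = 4 modules — four because the analysis
this emulates reports four major functional modules; k is a parameter,
not a discovery. No specific clustering algorithm is canonical for this
step; average-linkage hclust was chosen as the deterministic, standard
default. Genes are processed in lexicographic order and modules are
renumbered by their smallest member, so results are independent of input
order. *Secondary* (shared) membership — the asterisked genes of a
module figure — has no published definition; we reconstruct it as
Jaccard(gene profile, union of the module's term profiles) >= 0.2, and
flag it as a reconstruction in the documentation. `moduleVenn()` counts
genes per exclusive region of the resulting membership sets.

# Fiber-type paralogs and growth kinetics

`fiberProfile()` compares fast- vs slow-twitch paralog pairs (default
list: Myh1/Myh7, Myh4/Myh7, Myl1/Myl3, Casq1/Casq2, Atp2a1/Atp2a2,
Tnnt3/Tnnt1) by classical paired t-tests across individuals on log2CPM,
reporting medians and calling the dominant paralog. "Not detected"
defaults to zero counts in every sample (CPM floor configurable), because
no detection floor is canonical; a pair with identical values across
samples takes a degenerate-variance path and recommends a sign test.

`doublingTimeTwoPoint()` and `doublingTimeFit()` implement
$DT = \Delta t \ln 2 / \ln(N_2/N_1)$ and the log-linear least-squares fit
$\ln N = \ln N_0 + kt$, $DT = \ln 2 / k$, with $r^2$ on the log scale.
The regression (not a nonlinear exponential fit) was chosen because it is
closed-form and deterministic; both estimators coincide exactly on any
noiseless exponential, which the tests exploit. Declining series return
negative DT with a decline flag rather than an error.

# The synthetic-data generator

`simulateCounts()` draws gene counts as negative binomial with mean
$\mathrm{libsize}_s \cdot 2^{\mu_g + \Delta_{g,t}} / Z_t$ (relative
abundances renormalized per timepoint) and variance
$\mu + \mu^2/\mathrm{size}$ — the mean/dispersion parameterization is
stated because conventions differ. Defaults emulate the study conditions:
group sizes 4/3/5, a 13-gene housekeeping panel carrying the default
panel's names with zero planted effect and a 10-fold inflated size
parameter (stability), baseline log2 abundance uniform on [2, 9],
dispersion 20, library sizes log-uniform on [5e5, 2e6] so that CPM
normalization genuinely matters. `simulateAnnotation()` plants modules as
annotation blocks (within-module annotation probability 0.8, background
0.05, 40 genes, 4 modules, 40 terms); `simulateDegTable()` emits
truth-tagged DEG rows (planted log2FC + Gaussian noise; alternative rows
get q = 1e-3, null rows q ~ U(0,1)). `simulateStudy()` writes the whole
input set plus a JSON truth file under one seed; everything is
deterministic given the seed.

What the generator does *not* emulate: batch effects, per-gene outlier
dispersions, correlated genes, length bias, or alignment artifacts.
Passing recovery tests therefore demonstrates that the statistics do what
they claim under their own assumptions — not that those assumptions hold
in any particular tissue dataset.

# Calibration and recovery checks

The acceptance suite (and `scripts/acceptance.R`) verifies, at fixed
seeds:

* housekeeping self-standardization (z of the panel against its own null
  has mean 0, sd 1, exactly);
* marginal null calibration — 5000 null candidates, each standardized
  against its own simulated 500-gene panel, give KS-uniform raw p-values
  (per-candidate panels, because conditioning 5000 p-values on a single
  estimated $\hat\sigma$ measures that panel's estimation luck rather
  than the statistic);
* the documented small-panel type-I rate (< 0.10 at nominal 0.05,
  n_hk = 13);
* sensitivity >= 0.95 for planted 6-sigma effects at FDR < 0.05 over 200
  delta-level replicates;
* planted-module recovery with ARI >= 0.9 at generator defaults;
* oracle equivalence of BH (1000 random vectors vs an O(n²) step-up),
  the exact Wilcoxon p (vs literal $2^n$ enumeration for all n <= 10) and
  the hypergeometric tail (vs binomial-coefficient sums, N <= 30);
* doubling-time round trips (noiseless to 1e-6; noisy within 0.5 h over
  200 replicates);
* byte-identical pipeline reruns and CPM / Venn conservation laws.

Problem sizes in the checks (e.g. 400-gene pipeline runs, 150–500
samples per group in law-of-large-numbers checks) were chosen as the
smallest sizes at which the asymptotic statements they probe are
meaningfully tested.

# Known limitations

* The empirical-null z is a screening statistic; its p-values inherit the
  panel's sampling noise and the housekeeping-vs-candidate dispersion
  mismatch discussed above.
* TPM ingestion is out of scope: the statistic is defined on log2CPM and
  the package consumes raw counts only.
* DEG production (dispersion estimation, GLM testing) is upstream;
  truth-tagged simulated tables stand in for it during testing.
* Secondary module membership is a reconstruction of an informally
  defined notion; treat shared-gene calls as descriptive.
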