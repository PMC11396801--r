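---
title: "Reference-gene selection and validation for RT-qPCR: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-gene selection and validation for RT-qPCR: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(refstab)
library(dplyr)
```

RT-qPCR fold changes are only as good as the reference genes they are
normalized to. This vignette explains the statistical machinery `refstab`
implements, the assumptions behind each method, the parameters that matter,
and the design choices made where the literature leaves the procedure
under-specified. It is the package's account of its own science; every number
shown here is computed by the code as it runs.

## Data model

The unit of observation is one well: a cycle-threshold value `ct` for a
`gene` in a biological sample identified by `(treatment, timepoint,
replicate)`. Ct is the PCR cycle at which fluorescence crosses the detection
threshold; it is inversely and *logarithmically* related to template
abundance — one cycle is a factor of `1 + E` in input, a factor of 2 for
perfect chemistry. Everything downstream leans on that log-scale fact:

* replicate averaging uses the **arithmetic mean of Ct** (`aggregate_replicates()`),
  which is a geometric mean on the abundance scale — the natural average for
  ratio-scale data;
* stability statistics computed on Ct differences are statistics of log
  expression ratios.

Valid Ct values are finite and in (0, 45] (a 40–45-cycle run cannot produce
more). Missing wells are tolerated at the replicate level: a cell keeps the
mean of whatever replicates remain (flagged `partial`), and a gene missing an
entire aggregated cell is excluded from stability analysis for that subset
with a warning rather than silently imputed. `screen_ct_range()` reports
wells outside a plausibility band (default 10–40 cycles) without modifying
anything: screening is a report, not a filter.

## Efficiency calibration

A `base`-fold serial dilution (default 5-fold, levels 5^0 … 5^−4) gives Ct as
a linear function of log10 relative concentration. `fit_standard_curve()`
fits ordinary least squares — replicate wells enter as individual points, not
pre-averaged, so R² reflects replicate scatter — and converts the slope k to
amplification efficiency

$$E = 10^{-1/k} - 1,$$

so k = −3.3219 is exactly E = 100% (perfect doubling). Note the −1: E is the
*excess* amplification per cycle, and instrument software that prints
"efficiency 102.6%" uses this convention. R² is the squared Pearson
correlation of the fit. `primer_qc()` applies the conventional acceptance
rules, 0.90 ≤ E ≤ 1.20 and R² ≥ 0.99, both bounds inclusive; a non-negative
slope leaves E undefined and fails QC automatically.

```{r}
tibble(primer = "perfect", level = 0:4, ct = 18 + (0:4) * log2(5)) |>
  fit_standard_curve(base = 5) |>
  primer_qc()
```

## The four stability statistics

All four methods score each candidate gene so that **lower is more stable**,
and convert scores to ranks with average-rank ties. They make different
assumptions and fail differently, which is exactly why a consensus exists.

### geNorm

`genorm()` first transforms aggregated Ct to relative quantities
Q = (1+E)^(Ct_min − Ct), per gene, so the best-expressed sample has Q = 1
(with the default E = 1 this is Q = 2^−ΔCt). For genes *j*, *k* the pairwise
variation V_jk is the SD over samples of log2(Q_j/Q_k); gene *j*'s stability
M_j is the mean of V_jk over all partners. The least stable gene is removed
and M recomputed until two genes remain.

Two genes whose expression moves in proportion have constant log-ratio and
V_jk = 0 regardless of how wildly both move — geNorm measures *co-stability*,
not constancy. The flip side: the final two genes cannot be separated (their
M values are identical, the lone pairwise SD), so both receive average rank
1.5, and a panel of genes that are all scalar multiples of one profile is
degenerate (all M = 0); the package flags this with a warning rather than
inventing an order. Reported M is the value at each gene's exclusion round,
matching the published stepwise charts; `stepwise = FALSE` gives single-pass
M.

The pairwise-variation curve compares normalization factors (geometric means
of Q) built from the top *n* and *n+1* genes: V_n = SD over samples of
log2(NF_n/NF_{n+1}). The smallest *n* with V_n below the threshold (default
0.15, the value in universal use) is the recommended number of reference
genes; if no V passes, all J genes are recommended with a warning.

### NormFinder-style variance decomposition

`normfinder()` works on Ct directly (already log-scale). Each sample column
is centred by its cross-gene mean, removing sample-loading differences; the
residual w_gs carries gene *g*'s deviation from the panel consensus in sample
*s*. With one group the stability value is simply SD(w_g·). With groups
(treatments, by default), per-group mean deviations z are shrunk towards zero
by an empirical-Bayes factor γ²/(γ² + σ²/n), where γ² is the between-group
variance component (truncated at zero) and σ²/n the group's sampling
variance; the stability value averages |shrunken bias| + sampling
uncertainty over groups.

The originally published estimator leaves small-sample constants unstated,
so this package fixes one explicit, documented variant (two-way centering,
shrinkage, truncation) and claims agreement with the original tool at the
rank level only. Unlike geNorm, the method penalises *systematic
between-group* movement specifically — a gene that shifts 2 cycles between
treatments but is quiet within them is exactly what it catches, and such a
gene can fool geNorm if a partner co-shifts.

### BestKeeper

`bestkeeper()` is deliberately primitive: per-gene arithmetic mean Ct, sample
SD (n−1), and CV% = 100·SD/mean of the raw aggregated Ct. A gene with SD > 1
cycle (strictly greater; SD exactly 1 is kept) is flagged unstable and
unsuitable for normalization. Because it looks at raw Ct, it is the only
method here that does *not* cancel sample-loading effects — by design: gross
input variation shows up here and nowhere else. Flagged genes still receive
ranks (ascending SD, CV% breaking ties) so the consensus can include them;
the flag travels alongside. The full published procedure's index — the
geometric mean of surviving candidates' Ct per sample, with per-gene Pearson
correlations against it — is computed when at least 3 genes survive the SD
filter. A `mad = TRUE` flag switches the dispersion to the original tool's
mean absolute deviation.

### Comparative ΔCt

`delta_ct_stability()` scores gene *g* by the mean over partners *h* of
SD(Ct_g − Ct_h). On perfect-doubling data this is algebraically identical to
geNorm's single-pass M (the log2-ratio of Q values *is* the negative Ct
difference up to a constant), which the test suite asserts on random
instances; the two differ only through geNorm's stepwise exclusion and
efficiency correction.

## Consensus

`aggregate_ranks()` combines per-method ranks by geometric mean with equal
weights — the internal weighting of the popular web tool is unpublished, so
equal weights are the single documented interpretation — and `best_pair()`
returns the top two, consistent with the V < 0.15 analysis that two
references suffice in typical designs. The geometric mean of ranks is
monotone (improving one rank never hurts) and bounded by the contributing
ranks, both asserted as properties in the tests.

## Expression profiling and significance

`relative_expression()` implements 2^−ΔΔCT per biological replicate:
ΔCt_s = Ct_target,s − mean(Ct_references,s), ΔΔCt_s subtracts the mean ΔCt
over the calibrator replicates (default: the 0 h sample of the *same*
treatment), and RQ_s = 2^−ΔΔCt_s. Averaging reference Ct arithmetically is
the geometric mean of their linear quantities — the same normalization-factor
convention geNorm uses. With per-gene efficiencies supplied, the
efficiency-corrected ratio replaces the base-2 powers; setting every E = 1
reproduces 2^−ΔΔCT exactly (a test asserts bitwise agreement). Profiles
report mean ± SEM of RQ over replicates.

`timepoint_significance()` tests each timepoint against baseline on **log2**
RQ — equivalently on −ΔΔCt — because fold changes are approximately
log-normal and the log scale makes "2× up" and "2× down" symmetric. The
default is the pooled-variance (Student) t-test: replicates at both
timepoints come from the same protocol and instrument, the equal-variance
assumption is reasonable, and with the typical 3 replicates per group the
Welch approximation is badly conservative (its true level at nominal 5% is
about 3.2% at n = 3, measured by simulation), costing power exactly where
qPCR has little to spare. Welch remains available (`var_equal = FALSE`). No
multiple-testing correction is applied by default, matching the
per-timepoint-stars convention of the field; `p_adjust = "BH"` turns on
Benjamini–Hochberg.

`normalizer_concordance()` quantifies what using a bad reference does:
pairwise Pearson correlation of log2 trajectories from different normalizer
choices, plus agreement of the peak timepoint per treatment. Stable
normalizers agree near r = 1; a drifting reference tilts every trajectory by
its own drift, lowering the correlation and — the diagnostic signature —
moving the apparent peak.

## The synthetic-data generator

Because raw Ct tables from published screening studies are rarely deposited,
the package ships a generator (`simulate_ct()`) whose defaults emulate a
realistic plant abiotic-stress screening design, with ground truth attached:

* **Design**: 5 treatments (MeJA, EtH, SA at 0/3/6/12/24/48 h; high and low
  temperature at 0/6/12/24/36/48 h), 3 biological replicates — 90 samples.
* **Gene model**: Ct = baseline + designed shift + loading + noise.
  Baselines sit in the 17–25 band where most transcripts fall; replicate
  noise is Gaussian on the Ct scale with SD 0.15 cycles (typical
  well-to-well reproducibility); the per-sample loading term (SD 0.3
  cycles, shared by all genes of a sample) models cDNA input variation —
  precisely the nuisance normalization exists to remove.
* **Roles**: `stable` genes have zero designed shift (CDC6, NCBP2 in the
  built-in panel, noise SD 0.10); `time_drifting` and `group_biased` genes
  carry deterministic shifts; `target` genes follow designed log2
  fold-change trajectories (the SA treatment peaks every target at 3 h then
  declines, the temperature treatments suppress or transiently induce, and
  so on). The designed-unstable candidate PP2A drifts 2 cycles over each
  time course.

One generator subtlety is worth recording: the intermediate unstable
candidates are given *distinct* sign patterns over treatments and distinct
drift directions/shapes. Unstable genes that all moved in lockstep would
have constant pairwise log-ratios and look mutually stable to geNorm and
ΔCt — a correlated-instability artifact no panel of independently
misbehaving genes shows. Decorrelating the designed effects keeps the
generator's truth labels meaningful for *all* four methods.

Determinism: the RNG is seeded once per dataset, and noise is generated by
scaling standard normal draws, so RNG consumption does not depend on the SD
values — datasets generated with different noise or loading settings but the
same seed share their random sequence, which is what makes the
loading-invariance tests exact.

What the generator does **not** emulate: amplification-curve artifacts
(primer dimers, plateau effects), heavy-tailed or outlier contamination
(available behind `noise` settings but off by default), correlated technical
replicates, inhibitor-driven heteroscedasticity, and between-run batch
effects. Passing the recovery tests therefore demonstrates that the
algorithms correctly rank designed stability under idealized Gaussian
conditions — it does not certify performance on pathological field data.

## Numerical choices and degenerate inputs

* Ties anywhere in ranking use average ranks; residual ties in *output
  listings* (not scores) break deterministically by gene name.
* geNorm's stepwise exclusion breaks exact M ties by gene name, making the
  exclusion order reproducible.
* Zero-variance edge cases are answered exactly: constant genes get SD 0 and
  rank 1 in BestKeeper; identical replicate sets give p = 1 (not an error)
  in the timepoint test; two replicate groups with zero variance and
  different means give p = 0.
* The NormFinder shrinkage factor is defined as 0 when both γ² and the
  sampling variance vanish (a completely constant panel) instead of 0/0.
* Oracle agreement in the test suite is asserted to |Δ| < 10⁻⁹; designed
  efficiencies are recovered from noiseless dilution series to 10⁻⁶ or
  better.

## Problem sizes

The simulation studies in the tests and the acceptance script use the full
90-sample design with the 12-candidate panel: 100 seeded studies for the
recovery rates, 20 random 6-gene × 12-sample instances for oracle
equivalence, and 1000 null trials (3 replicates per group) for the type-I
error check — sizes chosen to estimate the rates to a few percent while
keeping a complete run in tens of seconds on a single core.

## Known limitations

* The NormFinder variant is faithful at the rank level, not the
  decimal-value level, to the originally distributed tool.
* geNorm cannot rank its final pair; the consensus inherits a 1.5/1.5 tie
  from it, resolved only by the other three methods.
* BestKeeper's SD is sensitive to genuine global input variation (by
  design); on data with large loading effects its ranks disagree with the
  loading-invariant methods, and the consensus should be read with that in
  mind.
* 2^−ΔΔCT assumes the calibrator condition is measured in every treatment;
  designs without a 0 h (or other within-treatment calibrator) sample need a
  different anchoring.
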