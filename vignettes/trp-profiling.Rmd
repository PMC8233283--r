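---
title: "Methods: calcium responder analysis and expression quantification with trpkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calcium responder analysis and expression quantification with trpkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trpkit)
```

trpkit quantifies TRP-channel expression and function in developing
placental tissue and trophoblast cultures along three arms: Fura-2
calcium-imaging analysis (calibration, per-cell responder classification,
cohort aggregation), qRT-PCR relative quantification, and RPKM-based
RNA-seq heatmap matrices. This vignette is the package's account of the
models behind each arm, the tunable parameters, and the design choices
made where conventions differ between laboratories.

## Fura-2 calibration

Fura-2 is a ratiometric indicator: excitation alternates between 340 and
380 nm and the emission ratio $R = F_{340}/F_{380}$ increases with
intracellular calcium. After subtracting a per-experiment background level
from each channel, absolute calcium follows the standard ratiometric
calibration

$$[\mathrm{Ca}^{2+}]_i = K_d \,\beta\, \frac{R - R_{min}}{R_{max} - R},$$

with $K_d$ the Fura-2/Ca$^{2+}$ dissociation constant (default 225 nM,
the common literature value for the intracellular environment), $R_{min}$
and $R_{max}$ the ratios at zero and saturating calcium, and $\beta$ the
ratio of $F_{380}$ at zero versus saturating calcium. $R_{min}$,
$R_{max}$ and $\beta$ are rig-dependent and normally measured in situ
with ionomycin/EGTA; `calibration_params()` accepts those constants
rather than estimating them (in-situ calibration routines are out of
scope). The defaults ($R_{min} = 0.5$, $R_{max} = 6$, $\beta = 8$) are
typical epifluorescence values and are shared with the synthetic
generator so that simulation and analysis invert each other exactly.

Numerical conventions:

* Background is a per-experiment scalar per wavelength — the simplest
  model consistent with a stable imaging field; it is kept pluggable by
  editing the background table of a `trace_set`.
* Corrected $F_{380} \le 0$ makes the ratio meaningless; such frames are
  flagged invalid and excluded rather than silently ratioed.
* $R \le R_{min}$ (rest-level noise) is clamped to 0 nM; $R \ge R_{max}$
  is flagged saturated and dropped, because a near-singular denominator
  would otherwise inject arbitrarily large values into the derivative
  statistics used downstream.

On $(R_{min}, R_{max})$ calcium is strictly increasing in $R$ and the
pair `calcium_to_ratio()` / `ratio_to_calcium()` is an exact algebraic
inverse; the test suite verifies the round trip to $10^{-9}$ relative
error over $10^4$ random parameter draws.

## Responder classification

A cell counts as a responder to an agonist when **both** of these hold
over the protocol windows:

1. **Amplitude criterion** — the calcium rise during the application
   window (peak minus baseline-window calcium) *exceeds* 50 nM, and
2. **Derivative criterion** — the highest value of the trace derivative
   within the application window *exceeds* three times the SD of the
   derivative during the baseline window.

Both inequalities are strict: an amplitude of exactly 50 nM is not a
response. The defaults (50 nM, 3×) sit in `responder_thresholds()` and
can be changed per analysis.

Choices the rule's prose leaves open, and what the package does:

* **Baseline statistic.** The baseline calcium is the *mean* over the
  baseline window (median available via `baseline_stat = "median"`).
* **Derivative estimation.** Traces are smoothed with a centered moving
  average (default width 3 samples; the window shrinks symmetrically at
  the trace ends, so constants and linear ramps are differentiated
  exactly) and then differentiated by central finite differences, with
  one-sided differences at the endpoints. Without any smoothing the
  derivative criterion is dominated by frame-to-frame noise; width 3 is
  the lightest filter that stabilizes it. Set `smoothing_window = 1` to
  switch smoothing off.
* **Baseline-derivative SD.** Population SD (divide by $n$) over the
  baseline window; `sd_denominator = "sample"` switches to $n-1$.
* **Viability filter.** Ionomycin is applied at the end of every
  experiment as a positive control; cells that fail to rise during the
  ionomycin window *can* be excluded (`viability_filter = TRUE`,
  threshold 50 nM) but are **not** excluded by default, since a positive
  control does not by itself imply an exclusion rule.
* **Peak search** spans the full stated application window with no
  onset-latency trimming.

`classify_responders()` is tested against a literal, loop-by-loop
re-evaluation of the rule text on a thousand randomized short traces; the
two never disagree.

## Cohort aggregation and tests

`summarize_experiments()` counts responders per (experiment, agonist);
`pool_cohort()` reports both conventions in circulation: the mean ± SEM
of per-experiment fractions (the headline convention for statements like
"65 ± 16 % of cells") and the pooled-count percentage
$100 \sum r_i / \sum n_i$ (the convention behind legend counts such as
"956 of 1470 cells"). Percentages are kept at full precision and rounded
only for display.

Group comparisons delegate to the standard implementations: Student and
paired *t* tests, Wilcoxon/Mann–Whitney, and Fisher's exact test on
responder counts (verified against a hypergeometric enumeration on all
2×2 tables with total ≤ 30). Paired vectors with zero-variance
differences have an undefined *t* statistic; `compare_groups()` reports a
"no difference" result with statistic 0 rather than a numeric p. An
optional normality gate uses the D'Agostino–Pearson omnibus $K^2$
statistic — implemented in the package because no installed R package
provides it, and validated against reference values of the same
statistic — to fall back from *t* to Mann–Whitney.

For many-to-one trends across conditions (e.g. gestational days against
E10.5), `multi_group_trend()` runs one-way ANOVA followed by Dunnett's
procedure (via multcomp) on the values as supplied — for qPCR this should
be ΔCt values, never fold changes, since fold changes are log-normal by
construction. The non-parametric route gates on Kruskal–Wallis and then
performs pairwise Wilcoxon tests against the control with Holm
adjustment; this is a substitute for Dunn's joint-rank test, which no
installed package provides, and is labeled as such in the output
(`method = "kruskal_wilcoxon_holm"`).

## qPCR relative quantification

All quantities derive from threshold cycles (Ct):

$$\Delta Ct = \bar{Ct}_{gene} - \mathrm{geomean}(\bar{Ct}_{HK_1}, \bar{Ct}_{HK_2}),
\qquad \text{rel. expression} = 2^{-\Delta Ct},$$

with housekeeping sets *Actb*+*Gapdh* (tissue, primary trophoblasts) or
*Actb*+*Sdha* (mTSC). The geometric mean is applied to the housekeeping
**Ct values themselves** — the literal reading of the formula above; the
alternative convention (geometric mean of the relative quantities, i.e.
arithmetic mean of Cts) is a one-line change but is not the default.
Replicate Cts (triplicates by convention) are averaged per (sample, gene)
before ΔCt; replicates at or above the detection floor (Ct ≥ 40,
configurable) are dropped, and a gene with no detected replicate is
`not_detected`. Whether undetected replicates should instead be imputed
is genuinely open; dropping is the conservative choice.

Categorization normalizes to the reference channel Trpm7 — abundantly and
stably expressed, hence usable as a "housekeeping channel" — using the
mean Trpm7 ΔCt over all conditions in scope:
$\% = 100 \cdot 2^{-(\Delta Ct - \overline{\Delta Ct}_{Trpm7})}$. Bands:

| percent of Trpm7 | category |
|---|---|
| > 100 | high |
| 5–100 | moderate |
| 1–5 | low |
| < 1 | below_detection |

The published band edges touch ("5–100 %", "1–5 %") without stating
openness; the package closes each band on its lower edge and puts 100 %
in `moderate`, so the map is a total monotone step function.

Fold changes are $2^{-\Delta\Delta Ct}$ against either the Trpm7
reference or a baseline condition (e.g. E10.5); the baseline condition
itself always yields 1, and a ΔCt drop of $\log_2 10 \approx 3.32$
cycles yields exactly tenfold. Strain contrasts report the per-gene
percent difference of relative expression across shared conditions, with
SEM.

## RNA-seq heatmap matrices

Counts are normalized to reads per kilobase of transcript per million
mapped reads,
$RPKM = \text{counts} / (L_{kb} \cdot N_{millions})$, where $N$ is the
**total mapped reads** of the sample (which may exceed the in-matrix
column sum) and $L$ is an explicit per-gene input — exon-union versus
transcript length is a pipeline-dependent definition the caller owns.
Heatmap matrices are $\log_2(RPKM + 1)$ with each row centered on its
mean ("mean row-centered log2 RPKM"); the pseudocount (default 1) keeps
zeros finite and row means of the result are 0 by construction.
Differential expression proper is out of scope: `simple_fold_table()`
offers only a clearly-labeled naive log2 fold-change/Wilcoxon/BH ranking
and is not a DESeq2 replacement.

## The synthetic-data generator

No raw recordings ship with the package, so `simulate_calcium_traces()`
generates ground-truth-labeled inputs with the statistical structure the
analysis assumes:

* latent calcium starts at ~100 nM (the textbook resting level),
* responders (default fraction 0.65, matching a strong-agonist cohort)
  add an agonist-locked rise with first-order kinetics (default
  $\tau_{rise} = 2$ s, $\tau_{decay} = 20$ s — free parameters, not
  empirical claims, since response kinetics are rarely reported
  quantitatively),
* responder amplitudes are normal (150 ± 25 nM, truncated at 0);
  non-responders draw amplitudes uniformly in [0, 25] nM so the 50 nM
  rule is unambiguous at the default 5 nM noise,
* every cell rises during ionomycin (used to test the viability filter),
* noise is additive Gaussian on the **latent calcium** before inversion
  to fluorescence — the simplest model consistent with example traces;
  the inversion path is pluggable if a fluorescence-domain noise model is
  wanted,
* the latent trace is inverted through the calibration equation into
  $F_{340}/F_{380}$, scaled by an optional ratio-preserving photobleach
  factor, and offset by the per-experiment background.

Because the generator inverts the exact calibration equation,
`calibrate_traces()` recovers the latent trace to floating-point
precision at zero noise — that round trip is what makes every downstream
stage testable without data. What the generator does **not** emulate:
optics and shot noise, ROI segmentation, focus drift, cell size
heterogeneity, oscillatory or multi-phasic responses. Passing tests
therefore demonstrate correctness of the *analysis arithmetic and
decision rules*, not robustness to every artifact of real recordings.

Ct-table and count-matrix generators are exact in expectation by
construction: target Cts are placed at
$geomean(HK) + \Delta Ct_{Trpm7} - \log_2(\text{fraction})$, and counts
are negative binomial with mean $RPKM \cdot L_{kb} \cdot N_{millions}$
(dispersion 0.1 by default).

All generators are pure functions of (configuration, seed).

## Problem sizes and verification

The package verifies itself at sizes chosen to be statistically
meaningful yet quick: classifier recovery uses 500 simulated cells (5
experiments × 100 cells) at 5 nM noise, where sensitivity and specificity
against ground truth are both ≥ 0.95 by a wide margin; the calibration
round trip uses $10^4$ random parameter draws; the classifier-vs-literal
oracle uses 1000 randomized ≤ 20-sample traces; Fisher's exact is checked
against enumeration on all ~32,000 2×2 tables with total ≤ 30. The
published pooled responder counts (mibefradil 1302/1336, THC 956/1470,
GSK1016790A 43/1475, THC+RR 43/889 in primary cells and 63/803 in
differentiated mTSC) are reproduced as 97 %, 65 %, 3 %, 5 % and 8 % by
`pool_cohort()`.

## Known limitations

* Amplitude-domain statements that depend on raw recordings (e.g. cohort
  amplitude means of specific experiments) cannot be reproduced, only the
  machinery that would compute them.
* Single-wavelength (non-ratiometric) analysis, oscillation detection and
  multi-peak deconvolution are not implemented.
* qPCR efficiency correction (Pfaffl-style) and standard-curve
  quantification are out of scope; perfect doubling per cycle is assumed.
* The Dunn's-test substitute (Holm-adjusted pairwise Wilcoxon) is more
  conservative than Dunn's joint-rank procedure at small n.
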