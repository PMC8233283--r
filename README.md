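# trpkit

Quantitative analysis of TRP-channel expression and function in placental
and trophoblast biology: Fura-2 calcium-imaging responder analysis, qPCR
relative quantification, and RPKM heatmap matrices — with seeded
synthetic-data generators so every stage is testable without raw
recordings.

It is written for labs that record agonist-challenge calcium traces from
trophoblast (or any adherent) cell preparations and need a reproducible,
scriptable path from raw dual-wavelength fluorescence to cohort-level
responder statistics, plus the companion expression arms (qRT-PCR and
bulk RNA-seq) used to decide which channels are worth probing
pharmacologically.

## What it computes

**Calcium arm.** Background-corrected ratios $R = F_{340}/F_{380}$ are
converted to absolute calcium with the ratiometric calibration

$$[\mathrm{Ca}^{2+}]_i = K_d\,\beta\,\frac{R - R_{min}}{R_{max} - R}
\qquad (K_d = 225\ \mathrm{nM\ by\ default}),$$

and each cell is classified as a responder to an agonist when its calcium
rise in the application window exceeds 50 nM **and** the peak trace
derivative in that window exceeds 3× the SD of the baseline-window
derivative (both strictly). Per-experiment responder fractions are pooled
into mean ± SEM and pooled-count percentages, with Fisher/t/Mann-Whitney
and Dunnett-style many-to-one comparisons on top.

**qPCR arm.** $\Delta Ct = \bar{Ct}_{gene} -
\mathrm{geomean}(Ct_{housekeeping})$, relative expression $2^{-\Delta Ct}$,
percent-of-Trpm7 with the four-band categorization (> 100 % high,
5–100 % moderate, 1–5 % low, < 1 % below detection), and
$2^{-\Delta\Delta Ct}$ fold changes against a baseline condition or the
Trpm7 reference.

**RNA-seq arm.** $RPKM = counts/(L_{kb}\cdot N_{millions})$ and
"mean row-centered log2 RPKM" heatmap matrices
($\log_2(RPKM+1)$, rows centered on their means).

## Worked example

```r
library(trpkit)

## simulate a 6-experiment agonist-challenge cohort and analyze it
cfg <- trace_sim_config(n_cells = 80, n_experiments = 6, seed = 7)
sim <- simulate_calcium_traces(cfg, default_windows("THC"))
ca  <- calibrate_traces(sim$traces, cfg$params)
calls <- classify_responders(ca, default_windows("THC"))
calls
#> Responder calls: 480 cell x agonist entries ( 0 excluded )
#>   THC: 295 / 480 responders (61.5%)

pool_cohort(summarize_experiments(calls))
#> Cohort summary
#>   THC: 61% pooled (295 of 480 cells); mean 61 +/- 2% over 6 experiments

amp <- amplitude_table(calls)   # responders only
round(c(mean = mean(amp$amplitude), sem = sd(amp$amplitude) / sqrt(nrow(amp))))
#> mean  sem
#>  161    1
```

61 % of simulated cells respond to the agonist (the generator's true
fraction is 0.65; a 61 % draw at these sample sizes is within sampling
error) with a mean response amplitude of 161 ± 1 nM against a configured
150 ± 25 nM amplitude distribution — the upward shift is the expected
peak-over-noise bias of a max statistic.

```r
## qPCR: relative expression and Trpm7-referenced categories
ct  <- simulate_ct_table(c(Trpv2 = 1.5, Trpv4 = 0.2, Trpc1 = 0.02,
                           Trpm2 = 0.005), ct_noise_sd = 0.15, seed = 7)
res <- percent_of_trpm7(relative_expression(ct))
res[, c("gene", "rel_expression", "percent_of_reference", "category")]
#>    gene rel_expression percent_of_reference        category
#> 1 Trpm7       0.029480              100.000        moderate
#> 2 Trpv2       0.037860              128.429            high
#> 3 Trpv4       0.005183               17.582        moderate
#> 4 Trpc1       0.000621                2.108             low
#> 5 Trpm2       0.000142                0.482 below_detection
```

Each gene lands in the category its simulated fraction of Trpm7 dictates
(1.5× → high, 0.2 → moderate, 0.02 → low, 0.005 → below detection),
with percent-of-Trpm7 values scattered around the design values by the
0.15-cycle replicate noise.

A command-line front end covering simulation, trace analysis, qPCR and
heatmap export lives at `inst/cli/trpkit.R`
(`Rscript inst/cli/trpkit.R analyze-traces --traces t.csv ...`).

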