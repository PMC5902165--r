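# circamyo

Circadian rhythm detection for bulk RNA-seq time courses of human skeletal
muscle, in two complementary designs:

- **In vivo** (several donors biopsied around the clock): a harmonic
  (cosinor) regression with a donor random intercept,
  `y = mu + a cos(2*pi*t/24) + b sin(2*pi*t/24) + u_donor + e`, fitted by
  maximum likelihood separately to the intronic (pre-mRNA, nascent
  transcription) and exonic (mRNA) signal of every gene. Rhythmicity is
  tested by likelihood ratio against the harmonic-free null (chi-squared,
  df = 2) with Benjamini–Hochberg adjustment; genes are grouped as
  `R-I.R-E` / `R-I` / `R-E` / `NR` by the layer(s) at which they cycle.
  The exon/intron ratio provides an mRNA half-life proxy, and rhythmic
  genes are phase-binned for hypergeometric motif enrichment.
- **In vitro** (synchronized primary myotubes, 2 donors × siControl/siCLOCK
  × 25 time points over 48 h): each gene × condition curve is LOESS-smoothed
  and summarized by ten shape measures, classified as circadian / one peak /
  linear / cloud by a self-trained random forest anchored on eleven core
  clock genes, and each gene is assigned to one of 16 combinatorial
  rhythmicity models over its four condition-curves (model 1 = rhythmic in
  all four, model 16 = in none). Amplitude blunting under CLOCK knockdown is
  quantified by a paired t-test on log10 amplitudes.

A synthetic-data generator (`gen_in_vivo()`, `gen_in_vitro()`,
`gen_toy_annotation()`, `gen_motif_memberships()`) reproduces both study
designs with known ground truth — including the kinetic coupling of the two
expression layers through first-order mRNA turnover
(attenuation `k/sqrt(k^2+w^2)`, delay `atan2(w,k)/w`) — so the entire
pipeline is testable without external data.

## Worked example

Simulate the in vivo design and run the full arm:

```r
library(circamyo)
sim <- gen_in_vivo(300, prop_rhythmic = 0.4, rng_seed = 7)
res <- run_invivo(sim$exonic_counts, sim$intronic_counts,
                  sim$samples, sim$lengths)
cat(res$log, sep = "\n")
#> input: 300 genes, 60 samples
#> filter mean_counts: 0 genes
#> filter mean_exonic_log2rpkm: 0 genes
#> filter intronic_masked: 0 genes
#> testable genes: 300
#> groups: NR=177, R-E=3, R-I=50, R-I.R-E=70

head(res$fits$intronic[, c("gene_id", "amplitude", "phase_h", "q")], 4)
#>     gene_id amplitude   phase_h            q
#> 1 gene00001 1.9626668  8.996806 4.426156e-15
#> 2 gene00002 1.1918734 16.392787 9.934712e-08
#> 3 gene00003 0.7505378 21.768581 5.458384e-05
#> 4 gene00004 0.5388366  8.491623 8.978529e-03
```

120 of the 300 genes were generated with a planted 24-h rhythm in
transcription; the fits recover them as `R-I` (rhythmic pre-mRNA only —
long-lived mRNAs damp the oscillation away) or `R-I.R-E` (both layers),
with `amplitude` the log2 peak-to-trough and `phase_h` the clock time of
the fitted peak. The handful of `R-E` calls at a 5% FDR are the expected
false positives on the exonic layer.

The in vitro arm runs analogously from a log2 RPKM matrix and sample sheet:

```r
sim <- gen_in_vitro(2000, rng_seed = 11)
res <- run_invitro(sim$expr, sim$samples, config = default_config(rng_seed = 11))
table(res$models$model)   # gene counts per rhythmicity model, 1..16
res$amp_comparison        # siCLOCK vs siControl log10 amplitude change
```

A thin command-line wrapper with `simulate`, `invivo` and `invitro`
subcommands lives in `inst/cli/circamyo.R`; the spec'd `compare` step is the
`compare_rhythmic_sets()` function. See
`vignettes/rhythm-detection-methods.Rmd` for the models, parameter defaults
and design choices.

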