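# intronsmith

Intron-mediated tuning of synthetic gene expression in budding yeast, as a
reusable analysis pipeline.

When a native *S. cerevisiae* intron interrupts a fluorescent reporter, the
expression of the reporter becomes a read-out of how well that intron is
spliced. `intronsmith` implements every computational stage of such a
reporter-library study:

* **Trace processing** — raw plate-reader OD/YFP time series are smoothed
  with a zero-phase order-4 Butterworth filter (normalized cutoff 0.15),
  background- and medium-corrected,
  `norm(t) = (YFP_i − YFP_ref) / (OD_i − OD_blank)`, masked to `NaN` near
  zero, and classified *spliced* when the self-crossing signal-to-noise
  ratio `sd(filtered) / sd(raw − filtered)` exceeds 5 within the first 6 h
  and at most half the values are `NaN`. Replicates merge by majority
  (3 of 4); splicing efficiency is expression relative to the intron-less
  reference strain.
* **Sequence features** — sliding-window GC content (50 nt) and local RNA
  folding energy (40 nt) around both splice sites, splice-signal distances,
  PWM motif scores, and secondary-structure graph distances. Folding is
  pluggable: a built-in maximum-pairing proxy with an exact oracle, or
  ViennaRNA's `RNAfold`.
* **Motif discovery** — hypergeometric k-mer enrichment (6–8-mers) between
  high- and low-expression introns with BH FDR, PPM construction from
  occurrences, positional enrichment against a motif-permutation null, and
  clan merging at probability-matrix similarity > 0.6.
* **Predictor assembly** — greedy forward selection maximizing the Spearman
  correlation of an OLS fit with expression, a feature-count-adjusted
  correlation, permutation empirical p-values, and 80/20 cross-validation
  that rebuilds the feature database (including motif discovery) inside
  every training fold.
* **Synthetic data** — libraries with known ground truth (canonical
  `GTATGT`/`TACTAAC`/`AG` signals, RPG/non-RPG length classes, planted
  motifs, logistic growth, calibrated noise) so the whole pipeline is
  testable end to end with no downloads.

## Worked example

Simulate a small library spanning the expression range, process the traces
and read off the splicing-efficiency indices:

```r
library(intronsmith)

strains <- data.frame(id = sprintf("S%02d", 1:8),
                      true_efficiency = c(0, 0.01, 0.05, 0.2, 0.4, 0.6, 1.0, 1.2))
plate <- simulate_plate_timeseries(strains, plate_design(n_replicates = 4, seed = 42))
res <- process_plate(plate)
res[res$role == "YiFP", c("strain", "snr", "nan_fraction", "spliced", "splicing_efficiency")]
```

```
  strain      snr nan_fraction spliced splicing_efficiency
1    S01  0.41100    0.5489691   FALSE        9.110271e-05
2    S02 23.51756    0.0000000    TRUE        1.006000e-02
3    S03 69.27000    0.0000000    TRUE        5.005793e-02
4    S04 89.34764    0.0000000    TRUE        1.998648e-01
5    S05 92.82462    0.0000000    TRUE        4.002607e-01
6    S06 92.91968    0.0000000    TRUE        6.007819e-01
7    S07 92.68621    0.0000000    TRUE        1.001033e+00
8    S08 91.98642    0.0000000    TRUE        1.202912e+00
```

The zero-efficiency strain sits at the noise floor (SNR ≈ 0.4, the
low-pass filter's band ratio) and is called non-spliced; every strain from
efficiency 0.01 upward clears SNR 5, and the measured splicing-efficiency
index recovers the simulated ground truth across two orders of magnitude.

On a full 240-intron library with a planted linear ground truth, the greedy
predictor recovers all three planted drivers among its first five picks:

```r
lib <- simulate_recovery_library(240, seed = 11)
cfg <- feature_config(gc_offsets = c(-30L,-12L,-6L,0L,3L,12L,30L),
                      fe_offsets = c(-30L,-12L,-6L,0L,3L,12L,30L),
                      include_structure = FALSE)
X <- build_feature_matrix(lib$constructs, lib$motif_set, cfg)
greedy_assemble(X, lib$efficiency)
#> <regressor_model> 5 features, n = 240, target = mean_expression
#>   final Spearman 0.904 (adjusted 0.902); first: motif_enh_TTTATGCT,
#>   motif_sil_TTTGTGTA, fe_5ss_+3, gc_5ss_+0, fe_5ss_+12
```

`run_pipeline(pipeline_config(seed = 1), "out/")` chains all stages —
simulate, process, features, motifs, fit, cross-validate — and writes
FASTA/TSV/CSV/MEME/JSON artifacts plus a manifest.

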