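# inscount

Quantification pipeline for digital molecular-barcode expression assays
(nCounter-style), built around the code set used to measure the
*C. elegans* insulin-like gene family: 43 target probes (40 insulin-like
genes plus *daf-2*, *daf-16* and *sod-3*), 10 positive-control spike-ins at
known fmol amounts, and 8 negative-control probes against foreign
sequences.

In these assays, total RNA is hybridized in solution with barcoded probe
pairs and individual barcodes are counted optically — no amplification, no
enzymes. The statistical consequences drive everything in this package:
counts are (over-dispersed) Poisson, nonspecific background is estimated
from negative controls, spike-ins anchor between-sample normalization, and
sensitivity and precision both scale with the mass of RNA hybridized.

## What the package computes

For a probes × samples count matrix `Y` with code-set classes
{target, positive, negative}:

* **Normalization** — per-sample factors
  `f_i = mean_j(P_j) / P_i`, where `P_i` is sample *i*'s positive-control
  count sum; optionally a second step rescaling target rows so per-sample
  target sums `T_i` are equal (total-content normalization).
* **Background** — threshold `T = mean(neg) + k·SD(neg)` pooled over
  negative-control probes × samples in scope (default `k = 3`), or a
  deletion-calibrated threshold `T = max_g(residual mean_g) + k·SD`
  (default `k = 4`) from strains in which a target gene is deleted,
  bounding cross-hybridization within the gene family. A probe is
  *detected* when its replicate mean strictly exceeds `T`.
* **QC** — spike-in standard curves (OLS of log10 count on log10 fmol),
  per-gene replicate CV% (`100·SD/mean`), input-mass titration summaries
  with fold-ratios between masses, replicate-group averaging, and
  cross-platform concordance (Pearson r of log10 gene × group means).
* **Stage profiling** — replicate mean ± SD per gene across the life
  cycle (embryo, L1 arrest, 12–48 h larvae, 60 h adults, dauer),
  fold-changes as ratios of stage means, and rule-based classification of
  expression patterns (embryo-specific, arrest-enriched, adult-enriched,
  larval-peaking, broadly expressed, below background).
* **qPCR cross-validation** — genomic-DNA standard curves
  (`Ct = a + b·log10(copies)`, efficiency `E = 10^(−1/b)`), Ct→copy
  conversion, reference-gene normalization (geometric mean of *rpl-12*
  and *rpl-19*), and per-gene shape comparison against the count platform.
* **Synthetic generator** — a seeded Poisson-lognormal simulator of the
  whole assay (mass-linear targets, mass-independent spike-ins, background
  that doubles between 1 and 10 µg, deletion strains with residual
  cross-hybridization, planted life-cycle patterns) so every stage is
  testable against ground truth.

## Worked example

```r
library(inscount)

config <- synthetic_config(seed = 1)
raw  <- simulate_titration(config, masses = c(0.1, 1, 10), n_replicates = 3)
norm <- normalize_positive_controls(raw)
ts   <- titration_summary(norm$counts)
ts
#> <titration_summary> mean counts per probe class by RNA mass (ug):
#>                0.1        1        10
#> positive    5651.4   5651.4    5651.4
#> negative      25.2     24.5      50.0
#> target       244.5   2287.3   22298.5
#> sum_counts 67229.0 155065.2 1015748.4
ts$fold("target", 1, 0.1)    # 9.36
ts$fold("target", 10, 0.1)   # 91.20
```

After normalization the positive-control row is constant by construction
(the spike-ins are mass-independent), average target counts scale
~10-fold per 10-fold of input RNA, and negative-control background
roughly doubles at 10 µg — the titration behaviour the assay model
encodes.

```r
panel <- data.frame(gene_id = c("ins-4", "ins-5", "ins-6"),
                    deletion_mean = c(31, 124, 137),
                    deletion_sd   = c(2, 55, 53))
deletion_threshold(panel, k = 4)$threshold                        # 349
deletion_threshold(panel, k = 4, rounding = "ceil_to_100")$threshold  # 400

lc  <- simulate_life_cycle(config)
n2  <- normalize_target_sum(normalize_positive_controls(lc$counts)$counts)$counts
prof <- stage_profile(n2, threshold = negative_control_threshold(n2)$threshold)
fold_change(prof, "sod-3", "L1_arrest", c("12h", "24h", "36h", "48h"))  # 7.38
fold_change(prof, "sod-3", "dauer",     c("12h", "24h", "36h", "48h"))  # 28.21
table(classify_patterns(prof)$label)
#>    adult_enriched   arrest_enriched  below_background broadly_expressed
#>                 2                 7                 3                19
#>   embryo_specific    larval_peaking
#>                 4                 8
```

The deletion panel reproduces the residual-count arithmetic
(`137 + 4·53 = 349`, conservatively rounded to a 400-count operating
cutoff), and the simulated life cycle — which plants a *sod-3*-like gene
up-regulated 10× in L1 arrest and 30× in dauer relative to developing
larvae — is recovered through the full normalize → background → profile →
classify pipeline (here 7.4× and 28.2× under 3 biological replicates of
noise; all 43 planted pattern labels are recovered exactly at this seed).

An end-to-end run from a YAML config:

```r
cfg <- validate_config(list(seed = 1, simulate = list(preset = "lifecycle"),
                            outdir = "run1"))
run_pipeline(cfg)   # writes normalized counts, thresholds, detection
                    # tables, profiles, labels and a JSON manifest
```

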