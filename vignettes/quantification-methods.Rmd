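---
title: "Methods: quantifying barcode-count expression data with inscount"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying barcode-count expression data with inscount}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inscount)
```

## The assay and its statistical model

Digital barcode-count platforms hybridize total RNA in solution with a
fixed *code set* of probe pairs and count optically decoded barcodes, one
count per captured molecule. Three probe classes structure everything:

* **targets** measure the organism's transcripts; their expected counts
  are proportional to the transcript's abundance and to the mass of total
  RNA hybridized;
* **positive controls** are synthetic transcripts included in the code set
  itself at known fmol amounts, so their counts are independent of the
  RNA input and anchor both the standard curve and between-sample
  normalization;
* **negative controls** are probes against foreign sequences with no
  spiked transcript; their counts estimate nonspecific background.

`inscount` models an observed count as a Poisson draw around an expected
value with a multiplicative efficiency term. For target probe $g$ in a
replicate at RNA mass $m$ (µg):

$$\lambda_{g} = a_g \, m \, u_{g} + b(m), \qquad
  y_{g} \sim \mathrm{Poisson}(\lambda_{g}),$$

where $a_g$ is the gene's abundance (expected counts per µg), $u_{g}$ is
a lognormal efficiency factor with mean 1 and CV $\tau$, and $b(m)$ is
nonspecific background. Positive controls have
$\lambda_j = c \cdot \mathrm{fmol}_j + b(m)$ with $c$ counts per fmol,
independent of $m$; negative controls have $\lambda = b(m)$. The compound
Poisson-lognormal form matters at both ends of the count range: at low
counts the Poisson term dominates (CV $\approx 1/\sqrt{\lambda}$), while
at high counts the CV flattens at the multiplicative floor $\tau$ that
pure Poisson noise cannot produce. Per-gene technical CV is therefore
approximately $\sqrt{1/\lambda + \tau^2}$ and decreases with input mass.

Background is flat at $b_0$ up to 1 µg and doubles by 10 µg
(log-linear in between): at low masses the negatives show no mass trend,
while a large excess of RNA drives additional nonspecific binding. With
no RNA at all, $b(0) = b_0$: probe-level background exists independent of
the sample, so target probes behave like negative controls in a no-RNA
hybridization.

## Normalization

Two steps, strictly ordered by a state machine
(`raw → positive_normalized → target_sum_normalized`):

1. **Positive-control normalization** multiplies every count in sample
   $i$ by $f_i = \bar P / P_i$, where $P_i$ is the sample's
   positive-control sum and $\bar P$ the mean over samples. Because the
   spike-ins are part of the code set, $f_i$ absorbs sample-to-sample
   differences in hybridization, binding and imaging efficiency. The sum
   (not a geometric mean) is used as the per-sample summary, and the mean
   of per-sample sums (not a designated reference sample) as the common
   reference: the choice of reference constant cancels out of every
   downstream ratio, so any positive constant is observationally
   equivalent; the mean keeps the count scale unchanged on average.
2. **Target-sum normalization** (optional; used for biological
   comparisons such as life-cycle profiling, not for mass titrations,
   where target totals differ by design) rescales only the target rows so
   per-sample target sums are equal. It assumes total target mRNA content
   is comparable across samples. Control rows pass through bit-identical.

Housekeeping-gene normalization is exposed as an explicit unimplemented
stub: this code set contains no invariant genes.

After either step the equalized per-sample summary has coefficient of
variation below $10^{-9}$ across samples — the working definition of
"equalized" used by the tests.

## Background thresholds and detection

Two estimators produce a `background_model`:

* `negative_control_threshold()`: $T = \text{mean} + k \cdot \text{SD}$
  of the negative-control counts in scope, **pooled over probes ×
  samples** with the sample SD ($n-1$). Pooling is deliberate: with 8
  negative probes and 3 replicates, per-probe SDs are unstable, and the
  assay needs one cutoff per condition. Default $k = 3$.
* `deletion_threshold()`: cross-hybridization within a gene family can
  exceed what foreign-sequence negatives see. Residual counts measured
  for probes whose target gene is deleted bound it empirically:
  $T = \max_g(\text{residual mean}_g) + k \cdot \text{SD}$ of the summary
  attaining that max (default $k = 4$), with an explicit rounding policy
  (`none`, `ceil_to_50`, `ceil_to_100`). The reference residual panel for
  this code set — {31 ± 2, 124 ± 55, 137 ± 53} counts after deleting
  *ins-4*, *ins-5* and *ins-6* — gives 137 + 4·53 = 349 unrounded, and
  400 when rounded up to the next hundred as a conservative operating
  cutoff at 3 µg; the package exposes the policy rather than hard-coding
  either figure.

Detection uses **strict inequality** — "detected above background" — so a
count exactly at the threshold is conservatively not detected. The
default statistic is the mean over the replicates in scope
(`group_mean`); `per_sample` tests each replicate. Detection is monotone
by construction: thresholds nondecreasing in $k$, detected sets shrinking
in $k$ and growing in abundance. These invariants are tested
property-style against brute-force recounts.

## QC benchmarks

* **Standard curves**: OLS of $\log_{10}(\text{count})$ on
  $\log_{10}(\text{fmol})$ via `stats::lm`. Points with nonpositive
  counts are excluded with a warning (a spike at the detection boundary
  can drop out of a replicate); fewer than two usable points or a single
  distinct amount is an error, not a degenerate fit.
* **Replicate CV**: per gene and group, $100 \cdot \text{SD}/\text{mean}$
  with the sample SD. A zero mean leaves the CV *undefined* — flagged and
  excluded from the per-group median, never reported as 0, which would
  fake perfect precision exactly where the assay saw nothing.
* **Titration summary**: per mass level, the mean count over probes ×
  replicates within each class plus the per-hybridization total, and
  fold-ratios of class means between masses.
* **Concordance**: gene × group means from two platforms are aligned,
  flattened into one scatter (matching how such comparisons are plotted),
  and correlated with Pearson's $r$ (Spearman by flag) on the
  $\log_{10}$ scale by default. Zero or negative values on the log scale
  are excluded pairwise with a warning rather than pseudocounted:
  pseudocounts distort precisely the near-background low end where the
  two platforms disagree most.

## Stage profiling and pattern classification

`stage_profile()` reports replicate mean, SD and $n$ per gene across the
eight canonical stages (embryo, L1 arrest, 12 h, 24 h, 36 h, 48 h, 60 h,
dauer). Fold-changes are **ratios of means of stage means**
(not means of ratios): stage means are the plotted, interpreted quantity,
and the reciprocal identity
$F(A,B) \cdot F(B,A) = 1$ holds exactly.

`classify_patterns()` formalizes qualitative pattern language into six
mutually exclusive labels evaluated in precedence order (below background;
embryo-specific; adult-enriched; arrest-enriched; larval-peaking;
broadly expressed), with rules stated in `?classify_patterns`. Choices
worth making explicit:

* the "developing larvae" reference set is {12, 24, 36, 48 h}; the 60 h
  point is excluded because it mixes adults with their early embryos;
* the minimum fold separation defaults to $F_{\min} = 3$, enough to
  separate clear on/off patterns from replicate noise at the CVs this
  assay produces, and configurable because the boundary genes are
  genuinely ambiguous;
* rules are homogeneous of degree zero: rescaling all counts and the
  threshold $T$ by one constant leaves labels unchanged;
* exact peak ties resolve to the earlier stage;
* classification is restricted to target probes when the profile carries
  its code set, and probes with a known specificity problem (the
  *ins-13* probe reports *acdh-2*) propagate their flag into the output
  rather than being silently dropped.

Borderline genes can legitimately disagree with qualitative descriptions
made by eye; the classifier reports its supporting statistics
(peak stage, peak fold) so such calls can be audited rather than
suppressed.

## qPCR cross-validation

Standard curves regress Ct on $\log_{10}$ copies of a genomic-DNA
dilution series (≥ 3 points spanning ≥ 2 decades); efficiency is
$E = 10^{-1/\text{slope}}$, so perfect doubling corresponds to slope
$-1/\log_{10} 2 \approx -3.3219$. A nonnegative slope is rejected
outright; efficiencies outside $(1, 2.2]$ are flagged but returned.
`ct_to_copies()` inverts the curve and warns on extrapolation beyond the
fitted dilution range instead of refusing.

Reference normalization divides each sample's copy numbers by the
geometric mean of its reference genes (*rpl-12*, *rpl-19*), rescaled so
the mean reference factor across samples is 1. The geometric mean is the
standard scale-symmetric aggregate when no combination rule is otherwise
specified; the choice is recorded in output metadata. The rescaling keeps
results on the copy scale but makes the global constant data-dependent,
so exact invariance to per-sample scaling holds for within-sample
relative abundances (and up to that shared constant otherwise) — the
tests assert exactly these forms.

Cross-platform profile comparison first scales each platform's per-gene
profile to its own mean (counts and copies are incommensurate; only shape
is comparable), correlates log-shapes across shared stages, and flags
stages where one platform moves ≥ 2-fold while the other stays under
1.3-fold. Zero-variance profiles yield an NA correlation with a flag, not
a number.

## The synthetic generator: what it emulates, and what it does not

`synthetic_config()` fixes the study conditions: 43 targets, 10 positive
spike-ins on a 2-fold ladder from 0.1 fmol, 8 negatives; mean target
abundance 2240 counts/µg with per-gene abundances spread log-uniformly
over three decades; $b_0 = 24$ counts; 550 counts/fmol (placing the mean
positive-control count near 5.6 × 10³ and the smallest spike near the
detection boundary); technical CV $\tau = 0.08$; an additional biological
replicate CV of 0.15; residual cross-hybridization fraction
$\rho = 0.05$ for deletion strains. These defaults were calibrated once
against the titration behaviour of the insulin-like code set and are not
tuning knobs; every one is overridable for sensitivity analyses.

Design notes:

* the efficiency factor $u$ is drawn independently **per probe and
  replicate**. A factor shared across probes within a replicate would
  make per-gene CVs perfectly correlated across genes and would be
  removed entirely by positive-control normalization; per-probe draws
  give each gene the $\sqrt{1/\lambda + \tau^2}$ CV the model intends;
* deletion strains replace only the deleted gene's specific signal with
  $\rho \, a_g \, m$, redrawn on a separate RNG stream so every other
  probe is bit-identical to the paired wild-type run — cross-hybridization
  scales with the deleted gene's own wild-type expression, the simplest
  mechanism consistent with low-expressed genes leaving low residuals;
* the planted life-cycle profiles include one gene of every pattern
  class, a *sod-3*-like gene at exactly 10× (L1 arrest) and 30× (dauer)
  its developing-larvae level, and broadly expressed genes carrying most
  of the target content so per-stage target totals stay near-constant —
  the premise under which target-sum normalization is valid;
* determinism: all draws derive from the config seed through fixed
  per-purpose streams, so identical config + seed reproduce outputs
  bit-for-bit, including across titration masses simulated separately.

What the generator does **not** emulate: sequence-level
cross-hybridization thermodynamics, probe-specific affinity differences
(each gene has one abundance, not a probe response), instrument optics
and barcode mis-assignment, count saturation at very high totals, and
RNA-preparation covariance between genes. Passing tests on synthetic data
therefore demonstrate that the *procedures* are correct under the model's
assumptions — not that real data satisfy those assumptions.

## Numerical choices and degenerate inputs

* Delimited output is formatted to 15 significant digits so write → read
  round-trips reproduce doubles (contract: ≥ 12 digits) and a second
  write is byte-identical; comma vs tab is sniffed from the header line.
* Raw counts admit no missing values — digital counting reports a count
  for every probe — and negative or non-numeric cells are format errors
  with coordinates.
* Equalization tolerance $10^{-9}$ (relative) defines normalization
  success; fits on exactly log-linear data recover parameters to
  $10^{-9}$.
* $R^2$ is computed from residuals directly rather than via
  `summary.lm`, which warns on the exactly collinear inputs the tests
  legitimately use; a zero-variance response yields `NA`.
* All errors are classed conditions (`validation_error`, `format_error`,
  `normalization_error`, `state_error`, `model_error`, `fit_error`,
  `config_error`, …) so callers can branch on failure mode, and pipeline
  configs reject unknown keys by name instead of ignoring them.

## Problem sizes

The test suite and the acceptance script run the full code set
(61 probes) with 3 replicates per condition for end-to-end checks —
seconds of runtime — and scale selected statistical checks up only where
estimator noise requires it (e.g. 12 replicates for CV-vs-mass ordering,
tens of replicates for distribution-equality checks). Oracle-equivalence
properties are exercised on random matrices up to 100 × 100.

## Known limitations

* The pipeline driver computes negative-control or fixed thresholds;
  deletion-calibrated thresholds are derived separately from a deletion
  panel with `deletion_threshold()` and supplied as a fixed cutoff.
* Lane/cartridge batch correction, variance-stabilizing transforms,
  probit/logistic limit-of-detection modeling and FDR-based detection are
  out of scope, as are ΔΔCt relative quantification and primer design on
  the qPCR side.
* Spreadsheet workbooks are not parsed; supplementary-style three-sheet
  layouts (raw / means / SDs) are handled as three delimited text files,
  with the caller declaring the normalization state of pre-normalized
  sheets.
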