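---
title: "Summary-data Mendelian randomization: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Summary-data Mendelian randomization: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smrpipe)
```

## The estimand and the estimator

Let $z$ be a SNP's genotype dosage, $x$ the expression of a gene, and $y$
a trait. Two regressions, fitted in *different* samples and published only
as summary statistics, give $b_{zx}$ (the eQTL effect of $z$ on $x$) and
$b_{zy}$ (the GWAS effect of $z$ on $y$). If $z$ affects $y$ only through
$x$ — no direct (pleiotropic) path and no confounding of the $z$–$x$ or
$z$–$y$ relations, which the random assortment of alleles supplies — then
the path rule gives $b_{zy} = b_{xy}\, b_{zx}$, so

$$ \hat b_{xy} = \frac{\hat b_{zy}}{\hat b_{zx}}. $$

This Wald ratio coincides exactly (not asymptotically) with
single-instrument two-stage least squares computed on the cohort that
produced the summaries, because both reduce to
$\mathrm{cov}(z,y)/\mathrm{cov}(z,x)$. The package exploits this identity
as its strongest correctness check: `smr()` applied to summaries computed
from a simulated cohort must agree with `lm`-based two-stage least squares
on the same cohort to numerical precision (observed agreement is at the
$10^{-16}$ level; the test tolerance is $10^{-10}$).

Significance does not use the delta-method SE. Following the SMR
convention, the statistic combines the two z-scores,

$$ T_{\mathrm{SMR}}
   = \frac{z_{zy}^2\, z_{zx}^2}{z_{zy}^2 + z_{zx}^2},
   \qquad z_{zy} = b_{zy}/se_{zy},\; z_{zx} = b_{zx}/se_{zx}, $$

referred to $\chi^2_1$. Because $T \le \min(z_{zy}^2, z_{zx}^2)$, a probe
whose eQTL signal is marginal cannot reach a smaller p-value than the eQTL
evidence itself supports — the statistic degrades gracefully exactly where
the ratio estimator is least stable. The p-value is
$P(\chi^2_1 > T) = 2\{1 - \Phi(\sqrt{T})\}$, computed with
`pchisq(..., lower.tail = FALSE)`.

The delta-method standard error
$|b_{xy}|\sqrt{(se_{zy}/b_{zy})^2 + (se_{zx}/b_{zx})^2}$ is reported for
interval construction. It is a first-order approximation: with an
instrument of strength $|z_{zx}| = 10$ it is accurate to about 1% against
the sampling standard deviation of the ratio, and intervals built from it
cover at close to nominal rates in the package's replicate studies. With
weak instruments the ratio's sampling distribution becomes heavy-tailed
and the delta SE understates uncertainty — one reason instrument selection
applies a stringent threshold in the first place.

## Instrument selection and tunable parameters

- **`p_eqtl_instrument` (default `5e-8`)** — a probe's instrument is its
  smallest-p eQTL SNP among those below this threshold; probes with none
  are skipped, never forced into an unstable ratio. The default is the
  conventional genome-wide significance level; no authoritative value
  exists for probe-level eQTL selection, so it is exposed as
  configuration. Ties on p are broken by larger $|z_{zx}|$, then by
  lexicographically smallest SNP id, making selection deterministic.
- **`harmonize_options()`** — the GWAS effect allele is the reference.
  eQTL records with the same allele pair are copied; swapped pairs have
  their effect negated and frequency complemented; anything else is
  dropped as `allele_mismatch`. `drop_palindromic` (default `TRUE`) drops
  A/T and C/G SNPs, whose strand cannot be resolved from summary data —
  no frequency-based strand inference is attempted, since it is most
  error-prone exactly for the palindromic SNPs it would be needed for.
  `max_freq_diff` (default `0.2`) drops SNPs whose aligned effect-allele
  frequencies disagree by more than 0.2, a coarse guard against
  mislabelled variants; the check is skipped when either source omits
  frequencies.
- **Significance policies** (`apply_significance()`): Bonferroni at
  `alpha / n_tested`, Benjamini–Hochberg step-up at `alpha`, or a fixed
  cutoff. The comparison is inclusive (`p <= cutoff`), matching the
  step-up convention; the realized cutoff is recorded in every report so
  per-experiment accounting is reproducible from the outputs alone.

## What the generator simulates — and what it does not

`simulate_cohort()` draws, per individual, genotypes
$g_j \sim \mathrm{Binomial}(2, \mathrm{maf}_j)$ (Hardy–Weinberg, no LD),
expression $x = \sum_j b_{zx,j} g_j + \varepsilon_x$ and trait
$y = b_{xy} x + b_{\mathrm{direct}} \sum_j g_j + \varepsilon_y$ with
Gaussian noise. Three scenarios fix the causal structure: `causal`
($b_{\mathrm{direct}} = 0$), `pleiotropy` ($b_{xy} = 0$,
$b_{\mathrm{direct}} \ne 0$, the estimator's failure mode — it converges
to $b_{\mathrm{direct}}/b_{zx}$, not 0), and `null` (both 0). Summary
statistics are the closed-form simple-regression slope, SE and
normal-approximation p-value per SNP — the same quantities public
consortium files contain; the normal rather than t reference matches how
such files are produced and is negligible at the simulated sample sizes.

Defaults (n = 5000 individuals, maf = 0.3, $b_{zx} = 0.5$ expression-SD
per allele, $b_{xy} = 0.3$, unit noise SDs) describe a strong cis-eQTL
(roughly 10% of expression variance) and a moderate causal effect —
the regime in which summary-data MR is actually applied, since weak-eQTL
probes are excluded by design. Replicate studies in the test suite and
acceptance script use 200 causal replicates (seeds derived from the run
seed) for recovery and coverage, 2,000 null replicates of n = 1000 for
type-I calibration, and $10^7$ Monte-Carlo draws for the chi-square tail;
these sizes keep every run well inside interactive time while leaving
Monte-Carlo error far below the tolerances tested.

Real summary data differ in ways the generator deliberately omits: LD
between SNPs (so real "top eQTL" instruments tag rather than pinpoint
causal variants), case-control traits on the liability scale, shared
samples between GWAS and eQTL studies, population stratification, and
multi-gene regulatory networks. Passing tests therefore certify the
estimator's arithmetic, calibration and bookkeeping under the stated
model — not robustness to LD or pleiotropy in real cohorts. Heterogeneity
diagnostics that address LD-sharing (e.g. multi-SNP tests) are outside
this package's scope.

## Numerical and degenerate-input choices

- Genotype regressions are computed from centered cross-products; a
  monomorphic SNP (zero genotype variance) is skipped with a warning
  rather than producing `NaN`.
- A constant outcome yields slope 0 with p = 1; p-values are clamped to
  stay within $(0, 1]$ so the record remains schema-valid.
- `b_zx = 0` at a selected instrument flags the result as
  `weak_instrument` with `NA` estimate instead of dropping it silently.
- Summary files are written with `%.17g` precision so read-after-write
  reproduces every double bit-for-bit; result tables render p-values in
  scientific notation with four significant digits.
- All simulation randomness flows through a single integer seed per
  scenario; the RNG state of the calling session is saved and restored,
  so library code never perturbs user-level reproducibility.

## Design decisions where the design was open

The input dialect (tab-delimited, mandatory header, name-bound columns)
is the package's own convention, chosen to be self-describing and close
to common GWAS ".ma"-style files. Repetition counting treats each
significant (SNP, probe, experiment) triple as one occurrence — the only
unit under which a single SNP can accumulate multiple counts within one
experiment via different probes — and reports distinct-SNP and
distinct-gene counts alongside occurrence totals, since multi-experiment
overlap makes the two genuinely different numbers. Reference gene lists
for known/novel flagging are consumed as local one-symbol-per-line files,
matched case-insensitively; no online database is queried.

## Known limitations

Single-instrument only; no LD-aware multi-SNP extension and no
heterogeneity test to separate causality from linkage. The delta-method
interval is first-order. The pipeline is sequential; experiment grids of
the size the package targets (tens of dataset pairs) run in seconds, so
parallel execution is not provided.
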