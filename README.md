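# smrpipe

Summary-data Mendelian randomization (SMR) for integrating GWAS and eQTL
summary statistics.

## The problem

Genome-wide association studies report thousands of SNP–trait associations,
but linkage disequilibrium makes it hard to tell which gene a hit acts
through. If a SNP *z* also regulates the expression *x* of a nearby gene
(a cis-eQTL), the SNP can serve as an instrumental variable for the effect
of that gene's expression on the trait *y*: alleles are randomized at
meiosis, so the estimate is free of the non-genetic confounding that
plagues observational expression–trait correlations.

With `b_zx` the SNP's per-allele effect on expression (from an eQTL study)
and `b_zy` its effect on the trait (from a GWAS), the SMR estimate of the
expression-to-trait effect is the Wald ratio

```
b_xy = b_zy / b_zx
```

which is algebraically identical to single-instrument two-stage least
squares on individual-level data. Significance uses the approximate
chi-square statistic on 1 df combining both z-scores
(`z_zy = b_zy/se_zy`, `z_zx = b_zx/se_zx`):

```
T_SMR = (z_zy^2 * z_zx^2) / (z_zy^2 + z_zx^2),    p = P(chi^2_1 > T_SMR)
```

`T_SMR` is bounded by the smaller squared z-score, so a weak instrument
can never manufacture significance. A delta-method standard error
`|b_xy| * sqrt((se_zy/b_zy)^2 + (se_zx/b_zx)^2)` accompanies the estimate.

The package is written for analysts who have only summary statistics —
per-SNP effect, SE, p, allele pair and frequency — from one or more GWAS
and one or more probe-level eQTL studies, and want probe-by-probe causal
candidates plus cross-experiment bookkeeping (which SNPs and genes recur
among significant results across dataset pairs).

## What's inside

- `read_gwas_summary()` / `read_eqtl_summary()` — validated readers for
  tab-delimited summary tables (header columns `SNP A1 A2 freq b se p n`,
  plus `probe gene` for eQTL; any column order).
- `harmonize_datasets()` — puts both sources on the GWAS effect allele,
  flipping eQTL signs where alleles are swapped, dropping palindromic
  SNPs, irreconcilable allele pairs and frequency mismatches, with a
  full drop ledger.
- `smr()` — the central fit: per probe, selects the top cis-eQTL SNP below
  the instrument threshold (default `5e-8`) and computes `b_xy`, its SE,
  `T_SMR` and `p_SMR`. Returns a classed object with `print`, `summary`,
  `coef`, `confint` and `plot` methods.
- `apply_significance()`, `count_repetitions()`, `flag_known_genes()` —
  Bonferroni / Benjamini–Hochberg / fixed-cutoff policies, SNP and gene
  repetition counts across experiments, and known-vs-novel flags against
  user-supplied reference gene lists.
- `run_pipeline()` — YAML-config-driven orchestration of a whole
  GWAS-by-eQTL experiment grid with TSV outputs and a manifest. A thin
  CLI wrapper lives at `inst/cli/smrpipe.R`.
- `sim_scenario()`, `simulate_cohort()`, `cohort_to_gwas_summary()`,
  `cohort_to_eqtl_summary()`, `generate_experiment_grid()` — a seeded
  generator that simulates individual-level cohorts under known causal
  structure (causal, pleiotropy or null scenarios) and reduces them to
  summary statistics, so the whole pipeline is testable with a known
  true `b_xy`.

## Worked example

Simulate a cohort where the expression of one gene truly raises the trait
(`b_xy = 0.3`), reduce it to summary statistics, and fit:

```r
library(smrpipe)
sc   <- sim_scenario("causal", n_individuals = 5000, b_xy = 0.3, seed = 42)
coh  <- simulate_cohort(sc)
gwas <- cohort_to_gwas_summary(coh, "toy_gwas")
eqtl <- cohort_to_eqtl_summary(coh,
  data.frame(probe_id = c("pr1", "pr2"), gene_symbol = "GENE1",
             snp_id = "rs1"), "toy_eqtl")
fit <- smr(gwas, eqtl)
fit
```

```
Summary-data MR fit: toy_gwas x toy_eqtl
  probes tested: 2  skipped (no instrument): 0  pairs dropped in harmonization: 0
  top probes by p_smr:
 probe  gene SNP   b_xy    p_smr
   pr1 GENE1 rs1 0.2986 4.74e-11
   pr2 GENE1 rs1 0.2986 4.74e-11
```

Both probes tag the same gene and instrument, so they return the same
estimate: `b_xy = 0.2986`, within one standard error of the true 0.3.
The tiny `p_smr` reflects that both the eQTL and GWAS signals are strong.
Confidence intervals come from the delta-method SE:

```r
confint(fit)
#>         2.5 %   97.5 %
#> pr1 0.2096571 0.387583
#> pr2 0.2096571 0.387583
```

A full multi-dataset run goes through a YAML config:

```r
cfg <- generate_experiment_grid("fixtures", seed = 1)  # 2 GWAS x 5 eQTL
man <- run_pipeline(cfg)
man$repetitions   # SNP / gene repetition counts across the 10 experiments
```

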