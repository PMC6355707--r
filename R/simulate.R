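#' Define a simulation scenario for summary-data MR
#'
#' Specifies the linear mediation model under which cohorts are simulated:
#' genotype dosage g (Hardy-Weinberg, two independent allele draws per
#' individual, no LD between SNPs), expression
#' \deqn{x_i = \sum_j b_{zx,j} g_{ij} + \epsilon_x,\quad
#'       \epsilon_x \sim N(0, \sigma_x^2),}
#' and trait
#' \deqn{y_i = b_{xy} x_i + \sum_j b_{direct} g_{ij} + \epsilon_y,\quad
#'       \epsilon_y \sim N(0, \sigma_y^2).}
#' Three named scenarios constrain the parameters: \code{causal}
#' (\code{b_direct = 0}: the SNP affects the trait only through
#' expression), \code{pleiotropy} (\code{b_xy = 0}, \code{b_direct != 0}:
#' the SNP has a direct path to the trait, the estimator's failure mode),
#' and \code{null} (\code{b_xy = 0}, \code{b_direct = 0}: no SNP-trait
#' effect at all).
#'
#' @param scenario One of \code{"causal"}, \code{"pleiotropy"},
#'   \code{"null"}.
#' @param n_individuals Cohort size (>= 10; summary regressions degenerate
#'   below that).
#' @param snps Data frame with columns \code{snp_id}, \code{maf} in
#'   (0, 0.5], and \code{b_zx} (per-allele effect on expression, in
#'   expression SD units per allele).
#' @param b_xy Causal effect of expression on the trait (trait units per
#'   expression SD). Must be 0 unless \code{scenario = "causal"}.
#' @param b_direct Per-allele direct SNP-trait effect, applied to every
#'   SNP. Must be 0 except under \code{scenario = "pleiotropy"}, where it
#'   must be nonzero.
#' @param sigma_x,sigma_y Noise standard deviations (> 0).
#' @param seed Integer seed; fully determines the cohort.
#' @return An object of class \code{sim_scenario}.
#' @examples
#' sc <- sim_scenario("causal", b_xy = 0.3)
#' coh <- simulate_cohort(sc)
#' dim(coh$genotypes)
#' @export
sim_scenario <- function(scenario = c("causal", "pleiotropy", "null"),
                         n_individuals = 5000,
                         snps = data.frame(snp_id = "rs1", maf = 0.3,
                                           b_zx = 0.5),
                         b_xy = if (scenario == "causal") 0.3 else 0,
                         b_direct = if (scenario == "pleiotropy") 0.1 else 0,
                         sigma_x = 1, sigma_y = 1, seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(is.data.frame(snps),
            all(c("snp_id", "maf", "b_zx") %in% names(snps)))
  if (n_individuals < 10) stop("n_individuals must be at least 10")
  if (any(snps$maf <= 0 | snps$maf > 0.5)) {
    stop("maf must lie in (0, 0.5]")
  }
  if (sigma_x <= 0 || sigma_y <= 0) stop("noise SDs must be positive")
  if (anyDuplicated(snps$snp_id)) stop("duplicated snp_id in scenario")
  switch(scenario,
    causal = if (b_direct != 0)
      stop("causal scenario requires b_direct = 0"),
    pleiotropy = if (b_xy != 0 || b_direct == 0)
      stop("pleiotropy scenario requires b_xy = 0 and b_direct != 0"),
    null = if (b_xy != 0 || b_direct != 0)
      stop("null scenario requires b_xy = 0 and b_direct = 0")
  )
  structure(list(scenario = scenario,
                 n_individuals = as.integer(n_individuals),
                 snps = snps[, c("snp_id", "maf", "b_zx"), drop = FALSE],
                 b_xy = b_xy, b_direct = b_direct,
                 sigma_x = sigma_x, sigma_y = sigma_y,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("Simulation scenario:", x$scenario, "\n")
  cat("  individuals:", x$n_individuals, " SNPs:", nrow(x$snps), "\n")
  cat("  b_xy:", x$b_xy, " b_direct:", x$b_direct,
      " sigma_x:", x$sigma_x, " sigma_y:", x$sigma_y,
      " seed:", x$seed, "\n")
  invisible(x)
}

#' Simulate an individual-level cohort
#'
#' Draws genotypes, expression and trait under the scenario's generative
#' model. The same scenario (including seed) always yields a bit-identical
#' cohort.
#'
#' @param scenario A [sim_scenario()] object.
#' @return An object of class \code{cohort}: a list with
#'   \code{genotypes} (n x m integer matrix of dosages in 0/1/2, columns
#'   named by SNP), \code{expression}, \code{phenotype} (length-n numeric
#'   vectors) and the generating \code{scenario}.
#' @export
simulate_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  n <- scenario$n_individuals
  m <- nrow(scenario$snps)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old))
  set.seed(scenario$seed)
  g <- matrix(0L, n, m, dimnames = list(NULL, scenario$snps$snp_id))
  for (j in seq_len(m)) {
    # two independent allele draws per individual (Hardy-Weinberg)
    g[, j] <- stats::rbinom(n, 2L, scenario$snps$maf[j])
  }
  x <- drop(g %*% scenario$snps$b_zx) +
    stats::rnorm(n, 0, scenario$sigma_x)
  y <- scenario$b_xy * x + scenario$b_direct * rowSums(g) +
    stats::rnorm(n, 0, scenario$sigma_y)
  structure(list(genotypes = g, expression = x, phenotype = y,
                 scenario = scenario),
            class = "cohort")
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Reduce a cohort to GWAS summary statistics
#'
#' For every SNP, fits the simple linear regression of the trait on
#' genotype dosage and reports the slope, its standard error, and the
#' two-sided p-value from the large-sample normal approximation
#' \code{z = beta / se} (the convention under which public summary
#' statistics are produced). The effect allele is the counted allele; its
#' reported frequency is the sample frequency. SNPs that come out
#' monomorphic in the draw carry no regression information and are skipped
#' with a warning.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param name Dataset label.
#' @param a1,a2 Allele labels assigned to the counted and the alternative
#'   allele (recycled over SNPs).
#' @return A \code{gwas_sumstats} data frame.
#' @export
cohort_to_gwas_summary <- function(cohort, name = "sim_gwas",
                                   a1 = "A", a2 = "G") {
  stopifnot(inherits(cohort, "cohort"))
  s <- marginal_regressions(cohort$genotypes, cohort$phenotype)
  keep <- !s$monomorphic
  if (any(!keep)) {
    warning(sum(!keep), " monomorphic SNP(s) skipped: ",
            paste(colnames(cohort$genotypes)[!keep], collapse = ", "))
  }
  df <- data.frame(
    snp_id = colnames(cohort$genotypes)[keep],
    effect_allele = rep_len(toupper(a1), sum(keep)),
    other_allele = rep_len(toupper(a2), sum(keep)),
    eaf = s$eaf[keep], beta = s$beta[keep], se = s$se[keep],
    pvalue = s$pvalue[keep], n = nrow(cohort$genotypes),
    stringsAsFactors = FALSE
  )
  new_gwas_sumstats(df, name)
}

#' Reduce a cohort to eQTL summary statistics
#'
#' For every (probe, SNP) pair in \code{probe_map}, fits the simple linear
#' regression of expression on genotype dosage, exactly as
#' [cohort_to_gwas_summary()] does for the trait. Probes sharing a SNP
#' yield distinct records with identical estimates, mirroring microarray
#' designs where several probes annotate one gene.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param probe_map Data frame with columns \code{probe_id},
#'   \code{gene_symbol}, \code{snp_id}; one row per (probe, SNP) record to
#'   emit. Every \code{snp_id} must exist in the cohort.
#' @param name Dataset label.
#' @inheritParams cohort_to_gwas_summary
#' @return An \code{eqtl_sumstats} data frame.
#' @export
cohort_to_eqtl_summary <- function(cohort, probe_map, name = "sim_eqtl",
                                   a1 = "A", a2 = "G") {
  stopifnot(inherits(cohort, "cohort"), is.data.frame(probe_map),
            all(c("probe_id", "gene_symbol", "snp_id") %in% names(probe_map)))
  unknown <- setdiff(probe_map$snp_id, colnames(cohort$genotypes))
  if (length(unknown)) {
    stop("probe_map references SNP(s) absent from the cohort: ",
         paste(unknown, collapse = ", "))
  }
  if (nrow(probe_map) == 0L) {
    df <- data.frame(probe_id = character(), gene_symbol = character(),
                     snp_id = character(), effect_allele = character(),
                     other_allele = character(), eaf = numeric(),
                     beta = numeric(), se = numeric(), pvalue = numeric(),
                     n = numeric(), stringsAsFactors = FALSE)
    return(new_eqtl_sumstats(df, name))
  }
  s <- marginal_regressions(cohort$genotypes, cohort$expression)
  idx <- match(probe_map$snp_id, colnames(cohort$genotypes))
  keep <- !s$monomorphic[idx]
  if (any(!keep)) {
    warning(sum(!keep), " probe-SNP record(s) at monomorphic SNPs skipped")
  }
  df <- data.frame(
    probe_id = probe_map$probe_id[keep],
    gene_symbol = probe_map$gene_symbol[keep],
    snp_id = probe_map$snp_id[keep],
    effect_allele = rep_len(toupper(a1), sum(keep)),
    other_allele = rep_len(toupper(a2), sum(keep)),
    eaf = s$eaf[idx][keep], beta = s$beta[idx][keep],
    se = s$se[idx][keep], pvalue = s$pvalue[idx][keep],
    n = nrow(cohort$genotypes),
    stringsAsFactors = FALSE
  )
  new_eqtl_sumstats(df, name)
}

# Closed-form simple regression of outcome on each genotype column:
# beta = Sxy/Sxx, se^2 = (Syy - beta*Sxy)/((n-2)*Sxx). Equivalent to lm()
# per SNP, vectorized across SNPs.
marginal_regressions <- function(g, outcome) {
  n <- nrow(g)
  gc <- sweep(g, 2, colMeans(g))
  yc <- outcome - mean(outcome)
  sxx <- colSums(gc^2)
  sxy <- drop(crossprod(gc, yc))
  syy <- sum(yc^2)
  mono <- sxx == 0
  beta <- ifelse(mono, NA_real_, sxy / sxx)
  rss <- pmax(syy - beta * sxy, 0)
  se <- sqrt(rss / ((n - 2) * sxx))
  se[!mono & se == 0] <- .Machine$double.xmin  # constant outcome: keep se > 0
  z <- ifelse(se > 0, beta / se, 0)
  pvalue <- 2 * stats::pnorm(-abs(z))
  pvalue <- pmax(pvalue, .Machine$double.xmin)  # keep within (0, 1]
  list(beta = beta, se = se, pvalue = pvalue,
       eaf = colMeans(g) / 2, monomorphic = mono)
}

#' Write a self-contained synthetic fixture set
#'
#' Simulates a cohort, reduces it to one GWAS and one eQTL summary file in
#' the package's tab-delimited dialects, and records the generating
#' scenario (including the seed and the true \code{b_xy}) in a flat
#' \code{key=value} provenance file. The same scenario always produces
#' byte-identical files.
#'
#' @param scenario A [sim_scenario()] object.
#' @param probe_map Probe-to-SNP map, as in [cohort_to_eqtl_summary()].
#' @param out_dir Output directory (created if absent).
#' @param basename Stem for the three file names.
#' @return Character vector of the three written paths (gwas, eqtl,
#'   provenance), invisibly.
#' @export
generate_fixture_files <- function(scenario, probe_map, out_dir,
                                   basename = "sim") {
  stopifnot(inherits(scenario, "sim_scenario"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  coh <- simulate_cohort(scenario)
  gwas_path <- file.path(out_dir, paste0(basename, "_gwas.tsv"))
  eqtl_path <- file.path(out_dir, paste0(basename, "_eqtl.tsv"))
  prov_path <- file.path(out_dir, paste0(basename, "_provenance.txt"))
  write_gwas_summary(
    cohort_to_gwas_summary(coh, paste0(basename, "_gwas")), gwas_path)
  write_eqtl_summary(
    cohort_to_eqtl_summary(coh, probe_map, paste0(basename, "_eqtl")),
    eqtl_path)
  prov <- c(
    paste0("scenario=", scenario$scenario),
    paste0("n_individuals=", scenario$n_individuals),
    paste0("n_snps=", nrow(scenario$snps)),
    paste0("true_b_xy=", num_full(scenario$b_xy)),
    paste0("b_direct=", num_full(scenario$b_direct)),
    paste0("sigma_x=", num_full(scenario$sigma_x)),
    paste0("sigma_y=", num_full(scenario$sigma_y)),
    paste0("seed=", scenario$seed)
  )
  writeLines(prov, prov_path)
  invisible(c(gwas = gwas_path, eqtl = eqtl_path, provenance = prov_path))
}
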