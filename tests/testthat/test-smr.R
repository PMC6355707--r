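test_that("Wald ratio is the defining quotient with sign rule", {
  expect_equal(estimate_bxy(0.2, 0.5), 0.4)
  expect_equal(estimate_bxy(0, 0.5), 0)
  expect_equal(estimate_bxy(-0.2, 0.5), -0.4)
  expect_equal(estimate_bxy(c(0.2, -0.2), c(0.5, 0.5)), c(0.4, -0.4))
  expect_error(estimate_bxy(0.2, 0), "weak instrument")
})

test_that("delta-method SE matches its closed form and a parametric bootstrap", {
  se <- delta_se_bxy(0.2, 0.05, 0.5, 0.05)
  expect_equal(se, 0.4 * sqrt(0.0625 + 0.01), tolerance = 1e-12)
  # bootstrap oracle: SD of the ratio over sampling draws of both betas,
  # well-conditioned regime (|z_zx| = 10)
  withr::with_seed(123, {
    bzy <- rnorm(1e6, 0.2, 0.05)
    bzx <- rnorm(1e6, 0.5, 0.05)
  })
  expect_equal(se, sd(bzy / bzx), tolerance = 0.02)
})

test_that("delta-method SE is homogeneous and has the right limits", {
  base <- delta_se_bxy(0.2, 0.05, 0.5, 0.05)
  expect_equal(delta_se_bxy(0.6, 0.15, 0.5, 0.05), 3 * base)
  expect_equal(delta_se_bxy(0.2, 0.05, 0.5, 1e-12), 0.05 / 0.5,
               tolerance = 1e-6)
  expect_true(is.na(delta_se_bxy(0, 0.05, 0.5, 0.05)))
})

test_that("chi-square statistic is the harmonic z-score combination", {
  # z_zy = 4, z_zx = 10
  expect_equal(smr_statistic(0.2, 0.05, 0.5, 0.05), 1600 / 116,
               tolerance = 1e-12)
  expect_equal(smr_statistic(0, 0.05, 0.5, 0.05), 0)
  expect_equal(smr_statistic(0, 1, 0, 1), 0)
  # bounded by the weaker squared z-score
  for (zz in list(c(1, 2), c(5, 0.3), c(8, 8))) {
    t <- smr_statistic(zz[1], 1, zz[2], 1)
    expect_lte(t, min(zz^2) + 1e-12)
  }
})

test_that("p-value is the 1-df chi-square upper tail", {
  expect_equal(smr_pvalue(0), 1)
  ts <- c(0.5, 1, 3.841459, 13.7931)
  expect_equal(smr_pvalue(ts), 2 * (1 - pnorm(sqrt(ts))), tolerance = 1e-12)
  expect_equal(smr_pvalue(3.841459), 0.05, tolerance = 1e-5)
  # strictly decreasing in t
  expect_true(all(diff(smr_pvalue(seq(0, 30, 0.5))) < 0))
  expect_error(smr_pvalue(-1), "non-negative")
})

test_that("instrument selection takes the top eQTL SNP below threshold", {
  pairs <- data.frame(
    probe_id = "pr1", gene_symbol = "G", snp_id = c("rs1", "rs2", "rs3"),
    b_zy = 0.1, se_zy = 0.02, p_gwas = 1e-4,
    b_zx = c(0.5, 0.3, 0.5), se_zx = 0.05,
    p_eqtl = c(1e-9, 1e-6, 2e-9), stringsAsFactors = FALSE)
  expect_equal(select_instrument(pairs, 5e-8)$snp_id, "rs1")
  pairs$p_eqtl <- rep(1e-6, 3)
  expect_null(select_instrument(pairs, 5e-8))
  # tie on p: larger |z_zx| wins
  pairs$p_eqtl <- rep(1e-9, 3)
  expect_equal(select_instrument(pairs, 5e-8)$snp_id, "rs1")
  # full tie: lexicographically smallest snp_id
  pairs$b_zx <- 0.5
  expect_equal(select_instrument(pairs, 5e-8)$snp_id, "rs1")
  pairs2 <- pairs[c(3, 2, 1), ]
  pairs2$b_zx <- 0.5
  expect_equal(select_instrument(pairs2, 5e-8)$snp_id, "rs1")
  expect_error(select_instrument(rbind(pairs, within(pairs, probe_id <- "x"))),
               "single probe")
})

test_that("summary-level Wald ratio equals two-stage least squares", {
  coh <- causal_cohort(seed = 31, n = 2000)
  gwas <- cohort_to_gwas_summary(coh)
  eqtl <- cohort_to_eqtl_summary(coh, one_probe_map())
  fit <- smr(gwas, eqtl)
  # 2SLS with one instrument, individual-level oracle
  stage1 <- lm(coh$expression ~ coh$genotypes[, 1])
  stage2 <- lm(coh$phenotype ~ fitted(stage1))
  expect_equal(unname(coef(fit)), unname(coef(stage2)[2]),
               tolerance = 1e-10)
  expect_lt(abs(coef(fit) - 0.3), 3 * fit$results$se_xy)
})

test_that("the fit is invariant to trait rescaling and coherent in sign", {
  g <- make_gwas(gwas_df(c("rs1", "rs2"), beta = c(0.1, 0.02),
                         se = c(0.02, 0.02), pvalue = c(1e-6, 0.3)))
  e <- make_eqtl(eqtl_df(c("pr1", "pr1", "pr2"), c("G1", "G1", "G2"),
                         c("rs1", "rs2", "rs2"),
                         beta = c(0.5, 0.45, 0.4),
                         pvalue = c(1e-10, 2e-10, 1e-9)))
  fit <- smr(g, e)
  g_scaled <- g
  g_scaled$beta <- 3 * g$beta
  g_scaled$se <- 3 * g$se
  fit_s <- smr(g_scaled, e)
  expect_equal(fit_s$results$b_xy, 3 * fit$results$b_xy)
  expect_equal(fit_s$results$t_smr, fit$results$t_smr)
  expect_equal(fit_s$results$p_smr, fit$results$p_smr)
  g_neg <- g
  g_neg$beta <- -g$beta
  fit_n <- smr(g_neg, e)
  expect_equal(fit_n$results$b_xy, -fit$results$b_xy)
  expect_equal(fit_n$results$p_smr, fit$results$p_smr)
  expect_equal(sign(fit$results$b_xy),
               sign(fit$results$b_zy) * sign(fit$results$b_zx))
})

test_that("probes without a qualifying instrument are skipped, not errored", {
  g <- make_gwas(gwas_df("rs1"))
  e <- make_eqtl(eqtl_df("pr1", "G1", "rs1", pvalue = 1e-4))
  fit <- smr(g, e)
  expect_equal(nrow(fit$results), 0L)
  expect_equal(fit$skipped_probes, "pr1")
  expect_equal(fit$n_probes_tested, 0L)
})

test_that("results are ordered by p and expose all intermediates", {
  g <- make_gwas(gwas_df(c("rs1", "rs2"), beta = c(0.02, 0.1),
                         se = 0.02, pvalue = c(0.3, 1e-6)))
  e <- make_eqtl(eqtl_df(c("pr1", "pr2"), c("G1", "G2"), c("rs1", "rs2")))
  fit <- smr(g, e)
  expect_equal(fit$results$probe_id, c("pr2", "pr1"))
  expect_false(is.unsorted(fit$results$p_smr))
  expect_named(coef(fit), c("pr2", "pr1"))
  ci <- confint(fit)
  expect_equal(unname(ci[, 2] - ci[, 1]),
               2 * qnorm(0.975) * fit$results$se_xy)
  expect_equal(fit$results$b_xy,
               fit$results$b_zy / fit$results$b_zx)
  expect_output(print(fit), "probes tested: 2")
  expect_output(print(summary(fit)), "smallest p_smr")
})
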