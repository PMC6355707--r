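test_that("scenario invariants are enforced", {
  expect_error(sim_scenario("causal", b_direct = 0.1), "b_direct = 0")
  expect_error(sim_scenario("pleiotropy", b_direct = 0), "b_direct != 0")
  expect_error(sim_scenario("null", b_xy = 0.2), "b_xy = 0")
  expect_error(sim_scenario("causal", n_individuals = 5), "at least 10")
  expect_error(
    sim_scenario("causal",
                 snps = data.frame(snp_id = "rs1", maf = 0.6, b_zx = 0.5)),
    "maf")
  # pleiotropy scenario records true b_xy = 0
  sc <- sim_scenario("pleiotropy", b_direct = 0.1)
  expect_identical(sc$b_xy, 0)
})

test_that("seed fully determines the cohort", {
  sc <- sim_scenario("causal", n_individuals = 200, seed = 42)
  c1 <- simulate_cohort(sc)
  c2 <- simulate_cohort(sc)
  expect_identical(c1$genotypes, c2$genotypes)
  expect_identical(c1$expression, c2$expression)
  expect_identical(c1$phenotype, c2$phenotype)
  c3 <- simulate_cohort(sim_scenario("causal", n_individuals = 200,
                                     seed = 43))
  expect_false(identical(c1$phenotype, c3$phenotype))
})

test_that("genotypes are Hardy-Weinberg dosages in 0..2", {
  sc <- sim_scenario("null", n_individuals = 100000,
                     snps = data.frame(snp_id = "rs1", maf = 0.5,
                                       b_zx = 0.5), seed = 3)
  coh <- simulate_cohort(sc)
  expect_true(all(coh$genotypes %in% 0:2))
  # E(g) = 2*maf = 1, SE = sqrt(2*maf*(1-maf)/n)
  se <- sqrt(0.5 / 100000)
  expect_lt(abs(mean(coh$genotypes) - 1), 3 * se)
})

test_that("null scenario decouples trait from expression", {
  coh <- simulate_cohort(sim_scenario("null", n_individuals = 20000,
                                      b_xy = 0, seed = 11))
  expect_lt(abs(cor(coh$expression, coh$phenotype)), 3 / sqrt(20000))
})

test_that("per-SNP regression matches lm() to 1e-10", {
  sc <- sim_scenario("causal", n_individuals = 300,
                     snps = data.frame(snp_id = c("rs1", "rs2", "rs3"),
                                       maf = c(0.1, 0.3, 0.5),
                                       b_zx = c(0.2, 0.5, 0)),
                     b_xy = 0.3, seed = 5)
  coh <- simulate_cohort(sc)
  g <- cohort_to_gwas_summary(coh)
  for (j in 1:3) {
    fit <- lm(coh$phenotype ~ coh$genotypes[, j])
    co <- summary(fit)$coefficients
    expect_equal(g$beta[j], unname(co[2, 1]), tolerance = 1e-12)
    expect_equal(g$se[j], unname(co[2, 2]), tolerance = 1e-12)
    # p uses the normal, not t, approximation
    expect_equal(g$pvalue[j],
                 2 * pnorm(-abs(co[2, 1] / co[2, 2])), tolerance = 1e-12)
  }
  expect_equal(g$eaf, unname(colMeans(coh$genotypes) / 2))
})

test_that("trait slope on genotype recovers the path product b_zx * b_xy", {
  # mediation: E(slope of y on g) = b_zx * b_xy = 0.15
  reps <- 50
  betas <- ses <- numeric(reps)
  for (r in seq_len(reps)) {
    coh <- causal_cohort(seed = r, n = 5000)
    g <- cohort_to_gwas_summary(coh)
    betas[r] <- g$beta
    ses[r] <- g$se
  }
  se_mean <- sqrt(mean(ses^2) / reps)
  expect_lt(abs(mean(betas) - 0.15), 3 * se_mean)
})

test_that("doubling the trait doubles beta and se and fixes p", {
  coh <- causal_cohort(seed = 8, n = 500)
  g1 <- cohort_to_gwas_summary(coh)
  coh2 <- coh
  coh2$phenotype <- 2 * coh$phenotype
  g2 <- cohort_to_gwas_summary(coh2)
  expect_equal(g2$beta, 2 * g1$beta)
  expect_equal(g2$se, 2 * g1$se)
  expect_equal(g2$pvalue, g1$pvalue)
})

test_that("constant trait gives zero betas and p near 1", {
  coh <- causal_cohort(seed = 9, n = 100)
  coh$phenotype <- rep(1, 100)
  g <- cohort_to_gwas_summary(coh)
  expect_equal(g$beta, 0)
  expect_equal(g$pvalue, 1)
})

test_that("eQTL summaries: shared SNP probes duplicate the regression", {
  coh <- causal_cohort(seed = 10, n = 1000)
  pm <- rbind(one_probe_map(probe_id = "pr1"), one_probe_map(probe_id = "pr2"))
  e <- cohort_to_eqtl_summary(coh, pm)
  expect_equal(nrow(e), 2L)
  expect_equal(e$beta[1], e$beta[2])
  expect_equal(e$se[1], e$se[2])
  # estimated b_zx near the generative 0.5
  expect_lt(abs(e$beta[1] - 0.5), 3 * e$se[1])
})

test_that("eQTL summaries reject unknown SNPs and allow empty maps", {
  coh <- causal_cohort(seed = 10, n = 100)
  expect_error(cohort_to_eqtl_summary(coh, one_probe_map(snp_id = "rs99")),
               "absent from the cohort")
  e <- cohort_to_eqtl_summary(coh, one_probe_map()[0, ])
  expect_s3_class(e, "eqtl_sumstats")
  expect_equal(nrow(e), 0L)
})

test_that("null-scenario GWAS p-values are uniform", {
  # 1,000 independent null SNPs across replicate cohorts
  p <- numeric(0)
  for (r in 1:10) {
    sc <- sim_scenario("null", n_individuals = 500,
                       snps = data.frame(snp_id = sprintf("rs%d", 1:100),
                                         maf = rep(seq(0.1, 0.5, 0.1), 20),
                                         b_zx = 0),
                       seed = 100 + r)
    coh <- simulate_cohort(sc)
    p <- c(p, cohort_to_gwas_summary(coh)$pvalue)
  }
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("fixture files are deterministic and round-trip", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  sc <- sim_scenario("causal", n_individuals = 300, seed = 21)
  m1 <- generate_fixture_files(sc, one_probe_map(), dir1)
  m2 <- generate_fixture_files(sc, one_probe_map(), dir2)
  expect_length(m1, 3L)
  expect_true(all(file.exists(m1)))
  for (k in 1:3) {
    expect_identical(readLines(m1[k]), readLines(m2[k]))
  }
  coh <- simulate_cohort(sc)
  g_back <- read_gwas_summary(m1["gwas"])
  expect_equal(g_back$beta, cohort_to_gwas_summary(coh)$beta)
  e_back <- read_eqtl_summary(m1["eqtl"])
  expect_equal(e_back$beta, cohort_to_eqtl_summary(coh, one_probe_map())$beta)
  prov <- readLines(m1["provenance"])
  expect_true(any(grepl("^true_b_xy=0.2999", prov)))
  expect_true(any(prov == "seed=21"))
})
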