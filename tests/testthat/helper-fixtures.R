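# In-code fixture builders shared across test files.

gwas_df <- function(snp_id, effect_allele = "A", other_allele = "G",
                    eaf = 0.3, beta = 0.1, se = 0.02, pvalue = 1e-6,
                    n = 10000) {
  data.frame(snp_id = snp_id, effect_allele = effect_allele,
             other_allele = other_allele, eaf = eaf, beta = beta,
             se = se, pvalue = pvalue, n = n, stringsAsFactors = FALSE)
}

make_gwas <- function(df, name = "test_gwas") {
  new_gwas_sumstats(df, name)
}

eqtl_df <- function(probe_id, gene_symbol, snp_id, effect_allele = "A",
                    other_allele = "G", eaf = 0.3, beta = 0.5, se = 0.05,
                    pvalue = 1e-10, n = 5000) {
  data.frame(probe_id = probe_id, gene_symbol = gene_symbol,
             snp_id = snp_id, effect_allele = effect_allele,
             other_allele = other_allele, eaf = eaf, beta = beta,
             se = se, pvalue = pvalue, n = n, stringsAsFactors = FALSE)
}

make_eqtl <- function(df, name = "test_eqtl") {
  new_eqtl_sumstats(df, name)
}

write_gwas_text <- function(lines) {
  path <- tempfile("gwas", fileext = ".tsv")
  writeLines(lines, path)
  path
}

# single-SNP causal cohort used by several oracle tests
causal_cohort <- function(seed, n = 2000, maf = 0.3, b_zx = 0.5,
                          b_xy = 0.3) {
  simulate_cohort(sim_scenario(
    "causal", n_individuals = n,
    snps = data.frame(snp_id = "rs1", maf = maf, b_zx = b_zx),
    b_xy = b_xy, seed = seed))
}

one_probe_map <- function(snp_id = "rs1", probe_id = "pr1",
                          gene_symbol = "GENE1") {
  data.frame(probe_id = probe_id, gene_symbol = gene_symbol,
             snp_id = snp_id, stringsAsFactors = FALSE)
}
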