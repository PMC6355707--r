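#' Read a pipeline configuration file
#'
#' The configuration is a single declarative YAML file with sections
#' \code{experiments} (list of \code{gwas}, \code{eqtl}, \code{label}),
#' \code{smr} (\code{p_eqtl_instrument} and a \code{significance} block
#' with \code{method} and \code{alpha} or \code{cutoff}),
#' \code{harmonize}, optional \code{reference_lists} (name: path),
#' \code{output_dir}, \code{seed} and \code{log_level}.
#'
#' @param path Path to a YAML config file.
#' @return A validated config list of class \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  validate_pipeline_config(yaml::read_yaml(path))
}

validate_pipeline_config <- function(cfg) {
  stopifnot(is.list(cfg), length(cfg$experiments) > 0)
  labels <- vapply(cfg$experiments, function(e) {
    stopifnot(!is.null(e$gwas), !is.null(e$eqtl))
    e$label %||% paste0(tools::file_path_sans_ext(basename(e$gwas)), "_x_",
                        tools::file_path_sans_ext(basename(e$eqtl)))
  }, character(1))
  if (anyDuplicated(labels)) stop("experiment labels must be unique")
  for (i in seq_along(cfg$experiments)) cfg$experiments[[i]]$label <- labels[i]
  cfg$smr <- cfg$smr %||% list()
  cfg$smr$p_eqtl_instrument <- cfg$smr$p_eqtl_instrument %||% 5e-8
  sig <- cfg$smr$significance %||% list()
  sig$method <- sig$method %||% "bonferroni"
  sig$alpha <- sig$alpha %||% 0.05
  cfg$smr$significance <- sig
  hz <- cfg$harmonize %||% list()
  cfg$harmonize <- harmonize_options(
    drop_palindromic = hz$drop_palindromic %||% TRUE,
    freq_check = hz$freq_check %||% TRUE,
    max_freq_diff = hz$max_freq_diff %||% 0.2)
  cfg$output_dir <- cfg$output_dir %||% "smr_output"
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$log_level <- cfg$log_level %||% "info"
  class(cfg) <- "pipeline_config"
  cfg
}

pipe_log <- function(level, cfg_level, ...) {
  levels <- c(debug = 1, info = 2, warn = 3, quiet = 4)
  if (levels[[level %||% "info"]] >= levels[[cfg_level %||% "info"]]) {
    message("[", level, "] ", ...)
  }
}

#' Run the full SMR pipeline over a grid of experiments
#'
#' Runs every configured GWAS-by-eQTL experiment through harmonization,
#' SMR fitting and the significance policy, then aggregates the
#' significant results across experiments into a combined table (sorted
#' by p), per-experiment significant counts, a SNP repetition histogram,
#' and (when reference lists are configured) known/novel gene flags. All
#' outputs are TSV plus a plain-text manifest; reruns with the same
#' inputs and config are byte-identical. A failing experiment is logged
#' and skipped; the remaining experiments still run and the returned
#' manifest records the partial status.
#'
#' @param config A \code{pipeline_config} list, or the path to a YAML
#'   config file (see [read_pipeline_config()]).
#' @return An object of class \code{pipeline_manifest}: list with
#'   \code{files} (data frame: file, rows), \code{status} (data frame:
#'   label, status, n_tested, n_significant), \code{reports} (the
#'   per-experiment [apply_significance()] reports),
#'   \code{repetitions} (the [count_repetitions()] summary),
#'   \code{n_failed} and \code{output_dir}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- validate_pipeline_config(unclass(config))
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  add_file <- function(path, rows) {
    files[[length(files) + 1L]] <<- data.frame(
      file = path, rows = rows, stringsAsFactors = FALSE)
  }
  reports <- list()
  status <- list()
  for (ex in cfg$experiments) {
    lab <- ex$label
    res <- tryCatch({
      gwas <- read_gwas_summary(ex$gwas)
      eqtl <- read_eqtl_summary(ex$eqtl)
      fit <- smr(gwas, eqtl,
                 p_eqtl_instrument = cfg$smr$p_eqtl_instrument,
                 harmonize = cfg$harmonize, label = lab)
      sig <- cfg$smr$significance
      rep <- apply_significance(fit, method = sig$method,
                                alpha = sig$alpha, cutoff = sig$cutoff,
                                label = lab)
      pipe_log("info", cfg$log_level,
               lab, ": read ", nrow(gwas), " GWAS / ", nrow(eqtl),
               " eQTL rows; ", nrow(fit$results), " probes tested, ",
               nrow(fit$drops), " pairs dropped, ",
               nrow(rep$significant), " significant")
      list(fit = fit, report = rep)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      pipe_log("warn", cfg$log_level, lab, " FAILED: ",
               conditionMessage(res))
      status[[lab]] <- data.frame(label = lab, status = "failed",
                                  n_tested = NA_integer_,
                                  n_significant = NA_integer_,
                                  stringsAsFactors = FALSE)
      next
    }
    fit <- res$fit; rep <- res$report
    f_res <- file.path(out, paste0(lab, "_results.tsv"))
    f_sig <- file.path(out, paste0(lab, "_significant.tsv"))
    f_drop <- file.path(out, paste0(lab, "_drops.tsv"))
    write_results_table(fit$results, f_res)
    write_results_table(rep$significant, f_sig)
    write_tsv(stats::setNames(fit$drops, c("probe", "SNP", "reason")),
              f_drop)
    add_file(f_res, nrow(fit$results))
    add_file(f_sig, nrow(rep$significant))
    add_file(f_drop, nrow(fit$drops))
    reports[[lab]] <- rep
    status[[lab]] <- data.frame(label = lab, status = "ok",
                                n_tested = rep$n_tested,
                                n_significant = nrow(rep$significant),
                                stringsAsFactors = FALSE)
  }
  status_df <- do.call(rbind, unname(status))
  rownames(status_df) <- NULL

  # per-experiment counts (Table-1-style accounting)
  f_counts <- file.path(out, "experiment_counts.tsv")
  counts_df <- data.frame(
    experiment = status_df$label, status = status_df$status,
    n_tested = status_df$n_tested,
    n_significant = status_df$n_significant, stringsAsFactors = FALSE)
  write_tsv(counts_df, f_counts)
  add_file(f_counts, nrow(counts_df))

  # combined significant table across experiments, sorted by p
  combined <- do.call(rbind, c(lapply(names(reports), function(lab) {
    s <- reports[[lab]]$significant
    if (nrow(s) == 0L) return(NULL)
    cbind(data.frame(experiment = lab, stringsAsFactors = FALSE), s)
  }), list(make.row.names = FALSE)))
  if (is.null(combined)) {
    combined <- data.frame(experiment = character(), probe_id = character(),
                           gene_symbol = character(), snp_id = character(),
                           b_xy = numeric(), p_smr = numeric(),
                           stringsAsFactors = FALSE)
  }
  combined <- combined[order(combined$p_smr, combined$experiment,
                             combined$probe_id), , drop = FALSE]
  f_comb <- file.path(out, "combined_significant.tsv")
  comb_out <- combined
  for (cc in intersect(names(comb_out),
                       c("b_zx", "se_zx", "b_zy", "se_zy", "b_xy", "se_xy",
                         "t_smr"))) {
    comb_out[[cc]] <- num_full(comb_out[[cc]])
  }
  for (cc in intersect(names(comb_out), c("p_eqtl", "p_gwas", "p_smr"))) {
    comb_out[[cc]] <- num_sci(comb_out[[cc]])
  }
  write_tsv(comb_out, f_comb)
  add_file(f_comb, nrow(combined))

  # cross-experiment repetition bookkeeping
  reps <- count_repetitions(unname(reports))
  f_hist <- file.path(out, "repetition_histogram.tsv")
  hist_df <- data.frame(repetitions = as.integer(names(reps$histogram)),
                        n_snps = reps$histogram, stringsAsFactors = FALSE)
  rownames(hist_df) <- NULL
  write_tsv(hist_df, f_hist)
  add_file(f_hist, nrow(hist_df))
  f_genes <- file.path(out, "gene_counts.tsv")
  gene_df <- data.frame(gene = names(reps$gene_counts),
                        occurrences = reps$gene_counts,
                        stringsAsFactors = FALSE)
  rownames(gene_df) <- NULL
  write_tsv(gene_df, f_genes)
  add_file(f_genes, nrow(gene_df))

  if (!is.null(cfg$reference_lists)) {
    flags <- flag_known_genes(reps, unlist(cfg$reference_lists))
    f_flags <- file.path(out, "gene_flags.tsv")
    write_tsv(flags, f_flags)
    add_file(f_flags, nrow(flags))
  }

  files_df <- do.call(rbind, files)
  f_manifest <- file.path(out, "manifest.txt")
  writeLines(sprintf("%s\t%d", files_df$file, files_df$rows), f_manifest)
  n_failed <- sum(status_df$status == "failed")
  if (n_failed > 0) {
    pipe_log("warn", cfg$log_level, n_failed, " of ",
             nrow(status_df), " experiment(s) failed")
  }
  structure(list(files = files_df, status = status_df, reports = reports,
                 repetitions = reps, n_failed = n_failed,
                 output_dir = out, manifest_path = f_manifest),
            class = "pipeline_manifest")
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat("SMR pipeline run:", nrow(x$status), "experiment(s),",
      x$n_failed, "failed\n")
  print(x$status, row.names = FALSE)
  cat("outputs in", x$output_dir, "(", nrow(x$files), "files )\n")
  invisible(x)
}

#' Generate a seeded synthetic experiment grid
#'
#' Emulates the structure of a multi-consortium SMR study: several GWAS
#' summary datasets and several eQTL summary datasets over a shared SNP
#' panel, combined into every GWAS-by-eQTL experiment. Each dataset comes
#' from its own simulated cohort (independent draws, shared generative
#' effects), genes carry several probes each, and a subset of SNPs has no
#' expression effect so that some probes find no instrument. Writes the
#' fixture files plus a ready-to-run YAML config and returns the config
#' path.
#'
#' @param out_dir Directory for fixtures and config.
#' @param seed Master seed; every cohort seed derives from it.
#' @param n_gwas,n_eqtl Number of GWAS / eQTL datasets (default 2 and 5,
#'   a ten-experiment grid).
#' @param n_gwas_ind,n_eqtl_ind Cohort sizes per dataset.
#' @param b_xy True expression-to-trait effect under the causal scenario.
#' @param significance Significance block for the written config.
#' @return Path to the written YAML config, invisibly.
#' @export
generate_experiment_grid <- function(out_dir, seed = 1L, n_gwas = 2L,
                                     n_eqtl = 5L, n_gwas_ind = 4000L,
                                     n_eqtl_ind = 2000L, b_xy = 0.3,
                                     significance = list(
                                       method = "bonferroni",
                                       alpha = 0.05)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  genes <- sprintf("GENE%d", 1:6)
  # 12 SNPs over 6 genes; the last two genes' SNPs carry no expression
  # signal, so their probes never find an instrument
  snps <- data.frame(
    snp_id = sprintf("rs%03d", 1:12),
    maf = rep(c(0.15, 0.25, 0.35, 0.45), 3),
    b_zx = c(0.5, 0.6, 0.4, 0.5, 0.45, 0.55, 0.35, 0.5, 0, 0, 0, 0),
    gene = rep(genes, each = 2),
    stringsAsFactors = FALSE
  )
  scen <- function(s, n) {
    sim_scenario("causal", n_individuals = n,
                 snps = snps[, c("snp_id", "maf", "b_zx")],
                 b_xy = b_xy, seed = s)
  }
  experiments <- list()
  gwas_paths <- character(n_gwas)
  for (g in seq_len(n_gwas)) {
    coh <- simulate_cohort(scen(seed * 1000L + g, n_gwas_ind))
    nm <- sprintf("gwas%d", g)
    gwas_paths[g] <- file.path(out_dir, paste0(nm, ".tsv"))
    write_gwas_summary(cohort_to_gwas_summary(coh, nm), gwas_paths[g])
  }
  eqtl_paths <- character(n_eqtl)
  for (e in seq_len(n_eqtl)) {
    coh <- simulate_cohort(scen(seed * 1000L + 100L + e, n_eqtl_ind))
    # dataset-specific probe panel: 1 + (e mod 2) probes per gene
    pm <- do.call(rbind, lapply(seq_along(genes), function(k) {
      n_probes <- 1L + (e + k) %% 2L
      do.call(rbind, lapply(seq_len(n_probes), function(pr) {
        data.frame(probe_id = sprintf("e%d_%s_p%d", e, genes[k], pr),
                   gene_symbol = genes[k],
                   snp_id = snps$snp_id[snps$gene == genes[k]],
                   stringsAsFactors = FALSE)
      }))
    }))
    nm <- sprintf("eqtl%d", e)
    eqtl_paths[e] <- file.path(out_dir, paste0(nm, ".tsv"))
    write_eqtl_summary(cohort_to_eqtl_summary(coh, pm, nm), eqtl_paths[e])
  }
  for (g in seq_len(n_gwas)) {
    for (e in seq_len(n_eqtl)) {
      experiments[[length(experiments) + 1L]] <- list(
        gwas = gwas_paths[g], eqtl = eqtl_paths[e],
        label = sprintf("gwas%d_x_eqtl%d", g, e))
    }
  }
  cfg <- list(
    experiments = experiments,
    smr = list(p_eqtl_instrument = 5e-8, significance = significance),
    harmonize = list(drop_palindromic = TRUE, freq_check = TRUE,
                     max_freq_diff = 0.2),
    output_dir = file.path(out_dir, "results"),
    seed = seed,
    log_level = "quiet"
  )
  cfg_path <- file.path(out_dir, "pipeline.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}
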