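#' Apply a significance policy to an SMR fit
#'
#' Turns a fitted experiment into a report of significant probe-level
#' results under one of three policies: \code{bonferroni} (cutoff
#' \code{alpha / n_tested}), \code{fdr} (Benjamini-Hochberg step-up at
#' \code{alpha}, realized as the largest p passing the step-up rule), or
#' \code{fixed} (a user-supplied p cutoff). The comparison is inclusive
#' (\code{p_smr <= cutoff}).
#'
#' @param fit An [smr()] fit, or a results data frame with a
#'   \code{p_smr} column.
#' @param method \code{"bonferroni"}, \code{"fdr"} or \code{"fixed"}.
#' @param alpha Family-wise / false-discovery level for the first two
#'   policies (default 0.05).
#' @param cutoff Fixed p cutoff, required when \code{method = "fixed"}.
#' @param n_tested Number of probes tested; defaults to the fit's own
#'   count (must be >= the number of results).
#' @param label Experiment label; defaults to the fit's.
#' @return An object of class \code{experiment_report}: list with
#'   \code{label}, \code{significant} (results data frame),
#'   \code{n_tested}, \code{cutoff_used}, \code{method}.
#' @export
apply_significance <- function(fit, method = c("bonferroni", "fdr", "fixed"),
                               alpha = 0.05, cutoff = NULL,
                               n_tested = NULL, label = NULL) {
  method <- match.arg(method)
  if (inherits(fit, "smr")) {
    results <- fit$results
    n_tested <- n_tested %||% fit$n_probes_tested
    label <- label %||% fit$label
  } else {
    results <- fit
    n_tested <- n_tested %||% nrow(results)
    label <- label %||% "experiment"
  }
  if (n_tested < nrow(results)) {
    stop("n_tested (", n_tested, ") smaller than the number of results (",
         nrow(results), ")")
  }
  p <- results$p_smr
  cutoff_used <- switch(method,
    bonferroni = if (n_tested > 0) alpha / n_tested else alpha,
    fdr = {
      # BH step-up: largest p[i] <= i/m * alpha among sorted p
      if (length(p) == 0) 0 else {
        ps <- sort(p)
        ok <- ps <= seq_along(ps) / n_tested * alpha
        if (any(ok)) ps[max(which(ok))] else 0
      }
    },
    fixed = {
      if (is.null(cutoff)) stop("method 'fixed' requires a cutoff")
      cutoff
    }
  )
  stopifnot(alpha > 0, alpha < 1)
  sig <- results[!is.na(p) & p <= cutoff_used, , drop = FALSE]
  sig <- sig[order(sig$p_smr, sig$probe_id), , drop = FALSE]
  rownames(sig) <- NULL
  structure(list(label = label, significant = sig, n_tested = n_tested,
                 cutoff_used = cutoff_used, method = method, alpha = alpha),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Experiment:", x$label, "\n")
  cat("  policy:", x$method, " realized cutoff:", format(x$cutoff_used),
      "\n")
  cat("  significant:", nrow(x$significant), "of", x$n_tested,
      "probes tested\n")
  invisible(x)
}

#' Count SNP and gene repetitions across experiments
#'
#' A SNP close to a gene's expression signal is typically picked up by
#' several probes and in several GWAS-by-eQTL experiments; the number of
#' times it recurs among significant results is a crude reliability
#' signal. Each significant (SNP, probe, experiment) occurrence
#' contributes one count; the histogram groups SNPs by their total
#' occurrence count, and gene counts sum the occurrences of results
#' annotated to each gene symbol.
#'
#' @param reports A list of [apply_significance()] reports (order
#'   irrelevant).
#' @return An object of class \code{repetition_summary}: list with
#'   \code{snp_counts} and \code{gene_counts} (named integer vectors,
#'   decreasing), \code{histogram} (named integer vector: repetition
#'   count -> number of SNPs), \code{n_occurrences},
#'   \code{distinct_snps}, \code{distinct_genes}.
#' @export
count_repetitions <- function(reports) {
  if (inherits(reports, "experiment_report")) reports <- list(reports)
  stopifnot(all(vapply(reports, inherits, TRUE, "experiment_report")))
  sig <- lapply(reports, function(r) {
    if (nrow(r$significant) == 0L) return(NULL)
    data.frame(snp_id = r$significant$snp_id,
               gene_symbol = r$significant$gene_symbol,
               stringsAsFactors = FALSE)
  })
  sig <- do.call(rbind, sig[!vapply(sig, is.null, TRUE)])
  if (is.null(sig) || nrow(sig) == 0L) {
    return(structure(list(snp_counts = integer(0), gene_counts = integer(0),
                          histogram = integer(0), n_occurrences = 0L,
                          distinct_snps = 0L, distinct_genes = 0L),
                     class = "repetition_summary"))
  }
  snp_counts <- sort(table(sig$snp_id), decreasing = TRUE)
  gene_counts <- sort(table(sig$gene_symbol), decreasing = TRUE)
  hist_tab <- table(as.integer(snp_counts))
  structure(list(
    snp_counts = stats::setNames(as.integer(snp_counts), names(snp_counts)),
    gene_counts = stats::setNames(as.integer(gene_counts),
                                  names(gene_counts)),
    histogram = stats::setNames(as.integer(hist_tab), names(hist_tab)),
    n_occurrences = nrow(sig),
    distinct_snps = length(snp_counts),
    distinct_genes = length(gene_counts)
  ), class = "repetition_summary")
}

#' @export
print.repetition_summary <- function(x, ...) {
  cat("Repetition summary:", x$n_occurrences, "significant occurrences,",
      x$distinct_snps, "distinct SNPs,", x$distinct_genes,
      "distinct genes\n")
  if (length(x$histogram)) {
    cat("  repetitions -> SNPs:",
        paste(names(x$histogram), x$histogram, sep = "x", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Flag genes as known or novel against reference gene lists
#'
#' Compares each gene in a repetition summary against user-supplied
#' reference lists (plain text, one gene symbol per line; lines starting
#' with \code{#} ignored). Matching is case-insensitive. A gene absent
#' from a list is novel with respect to that list.
#'
#' @param summary A [count_repetitions()] summary, or a character vector
#'   of gene symbols.
#' @param reference_lists Named character vector of file paths, one per
#'   reference database.
#' @return Data frame with a \code{gene} column and one logical
#'   \code{known_<name>} column per reference list.
#' @export
flag_known_genes <- function(summary, reference_lists) {
  genes <- if (inherits(summary, "repetition_summary")) {
    names(summary$gene_counts)
  } else {
    as.character(summary)
  }
  stopifnot(length(reference_lists) > 0,
            !is.null(names(reference_lists)),
            all(nzchar(names(reference_lists))))
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (nm in names(reference_lists)) {
    path <- reference_lists[[nm]]
    if (!file.exists(path)) stop("reference list not found: ", path)
    ref <- readLines(path, warn = FALSE)
    ref <- trimws(ref)
    ref <- ref[nzchar(ref) & !startsWith(ref, "#")]
    out[[paste0("known_", nm)]] <- toupper(genes) %in% toupper(ref)
  }
  out
}
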