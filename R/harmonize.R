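#' Harmonization options
#'
#' Controls how GWAS and eQTL records for the same SNP are reconciled
#' before the SMR ratio is taken. Palindromic (A/T or C/G) SNPs are
#' dropped by default because their strand cannot be resolved from allele
#' labels in summary data; no strand-flipping is ever inferred from
#' frequencies. When both sources report an effect-allele frequency, a
#' sanity check drops SNPs whose aligned frequencies disagree by more than
#' \code{max_freq_diff}.
#'
#' @param drop_palindromic Drop A/T and C/G SNPs (default \code{TRUE}).
#' @param freq_check Compare aligned effect-allele frequencies (default
#'   \code{TRUE}; silently skipped when either frequency is \code{NA}).
#' @param max_freq_diff Maximum tolerated absolute frequency difference,
#'   in [0, 1] (default 0.2).
#' @return An object of class \code{harmonize_options}.
#' @export
harmonize_options <- function(drop_palindromic = TRUE, freq_check = TRUE,
                              max_freq_diff = 0.2) {
  stopifnot(is.logical(drop_palindromic), is.logical(freq_check),
            is.numeric(max_freq_diff),
            max_freq_diff >= 0, max_freq_diff <= 1)
  structure(list(drop_palindromic = drop_palindromic,
                 freq_check = freq_check,
                 max_freq_diff = max_freq_diff),
            class = "harmonize_options")
}

#' Is an allele pair palindromic?
#'
#' A SNP is palindromic when its two alleles are reverse complements of
#' each other ({A,T} or {C,G}), so the strand of a summary record cannot
#' be inferred from allele labels alone.
#'
#' @param a1,a2 Allele strings (vectorized).
#' @return Logical vector.
#' @examples
#' is_palindromic("A", "T")  # TRUE
#' is_palindromic("A", "G")  # FALSE
#' @export
is_palindromic <- function(a1, a2) {
  a1 <- toupper(a1); a2 <- toupper(a2)
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Align one eQTL record onto a GWAS record's effect allele
#'
#' The GWAS effect allele is adopted as the reference. If the eQTL record
#' reports the same allele pair the effect is copied; if its alleles are
#' swapped the eQTL effect is negated and its frequency complemented; any
#' other allele configuration is unresolvable and the pair is dropped.
#'
#' @param g One-row \code{gwas_sumstats} data frame (or a list with the
#'   same fields).
#' @param e One-row \code{eqtl_sumstats} data frame for the same SNP.
#' @param opts A [harmonize_options()] object.
#' @return A one-row data frame of the harmonized pair, or a
#'   \code{harmonize_drop} verdict whose \code{$reason} is one of
#'   \code{"allele_mismatch"}, \code{"palindromic"},
#'   \code{"freq_mismatch"}.
#' @export
align_alleles <- function(g, e, opts = harmonize_options()) {
  if (g$snp_id != e$snp_id) {
    stop("align_alleles called on different SNPs: ",
         g$snp_id, " vs ", e$snp_id)
  }
  drop <- function(reason) {
    structure(list(reason = reason), class = "harmonize_drop")
  }
  if (g$effect_allele == e$effect_allele &&
      g$other_allele == e$other_allele) {
    b_zx <- e$beta
    eaf_eqtl <- e$eaf
  } else if (g$effect_allele == e$other_allele &&
             g$other_allele == e$effect_allele) {
    b_zx <- -e$beta
    eaf_eqtl <- if (is.na(e$eaf)) NA_real_ else 1 - e$eaf
  } else {
    return(drop("allele_mismatch"))
  }
  if (opts$drop_palindromic &&
      is_palindromic(g$effect_allele, g$other_allele)) {
    return(drop("palindromic"))
  }
  if (opts$freq_check && !is.na(g$eaf) && !is.na(eaf_eqtl) &&
      abs(g$eaf - eaf_eqtl) > opts$max_freq_diff) {
    return(drop("freq_mismatch"))
  }
  data.frame(
    snp_id = g$snp_id, effect_allele = g$effect_allele,
    other_allele = g$other_allele,
    probe_id = e$probe_id, gene_symbol = e$gene_symbol,
    b_zy = g$beta, se_zy = g$se, p_gwas = g$pvalue,
    b_zx = b_zx, se_zx = e$se, p_eqtl = e$pvalue,
    eaf_gwas = g$eaf, eaf_eqtl = eaf_eqtl,
    n_gwas = g$n, n_eqtl = e$n,
    stringsAsFactors = FALSE
  )
}

#' Harmonize a GWAS and an eQTL summary dataset
#'
#' Inner-joins the two datasets on SNP id (once per probe) and aligns
#' every candidate (probe, SNP) pair onto the GWAS effect allele. Every
#' candidate is either emitted as a harmonized pair or recorded in the
#' drop ledger with exactly one reason, so that
#' \code{candidates = nrow(pairs) + nrow(drops)}. Output rows are ordered
#' by (probe_id, snp_id).
#'
#' @param gwas A \code{gwas_sumstats} data frame.
#' @param eqtl An \code{eqtl_sumstats} data frame.
#' @param opts A [harmonize_options()] object.
#' @return A list of class \code{harmonized} with components
#'   \code{pairs} (data frame of harmonized pairs), \code{drops}
#'   (data frame \code{probe_id, snp_id, reason}), and \code{n_candidates}.
#' @export
harmonize_datasets <- function(gwas, eqtl, opts = harmonize_options()) {
  stopifnot(inherits(gwas, "gwas_sumstats"), inherits(eqtl, "eqtl_sumstats"))
  e <- eqtl[eqtl$snp_id %in% gwas$snp_id, , drop = FALSE]
  e <- e[order(e$probe_id, e$snp_id), , drop = FALSE]
  gi <- match(e$snp_id, gwas$snp_id)
  pairs <- vector("list", nrow(e))
  drops <- vector("list", nrow(e))
  for (k in seq_len(nrow(e))) {
    res <- align_alleles(gwas[gi[k], ], e[k, ], opts)
    if (inherits(res, "harmonize_drop")) {
      drops[[k]] <- data.frame(probe_id = e$probe_id[k],
                               snp_id = e$snp_id[k],
                               reason = res$reason,
                               stringsAsFactors = FALSE)
    } else {
      pairs[[k]] <- res
    }
  }
  pairs_df <- if (any(lengths(pairs))) {
    do.call(rbind, pairs[lengths(pairs) > 0])
  } else {
    data.frame(snp_id = character(), effect_allele = character(),
               other_allele = character(), probe_id = character(),
               gene_symbol = character(), b_zy = numeric(),
               se_zy = numeric(), p_gwas = numeric(), b_zx = numeric(),
               se_zx = numeric(), p_eqtl = numeric(),
               eaf_gwas = numeric(), eaf_eqtl = numeric(),
               n_gwas = numeric(), n_eqtl = numeric(),
               stringsAsFactors = FALSE)
  }
  drops_df <- if (any(lengths(drops))) {
    do.call(rbind, drops[lengths(drops) > 0])
  } else {
    data.frame(probe_id = character(), snp_id = character(),
               reason = character(), stringsAsFactors = FALSE)
  }
  rownames(pairs_df) <- NULL
  rownames(drops_df) <- NULL
  structure(list(pairs = pairs_df, drops = drops_df,
                 n_candidates = nrow(e),
                 gwas_name = dataset_name(gwas),
                 eqtl_name = dataset_name(eqtl)),
            class = "harmonized")
}

#' @export
print.harmonized <- function(x, ...) {
  cat("Harmonized", x$gwas_name, "x", x$eqtl_name, "\n")
  cat("  candidates:", x$n_candidates,
      " pairs:", nrow(x$pairs), " dropped:", nrow(x$drops), "\n")
  if (nrow(x$drops)) {
    tab <- table(x$drops$reason)
    cat("  drop reasons:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
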