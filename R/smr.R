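#' Wald-ratio estimate of the expression-to-trait effect
#'
#' The single-instrument estimate of the effect of gene expression on the
#' trait: \eqn{b_{xy} = b_{zy} / b_{zx}}, where \eqn{b_{zy}} is the SNP's
#' effect on the trait (GWAS) and \eqn{b_{zx}} its effect on expression
#' (eQTL). Under the Mendelian-randomization assumptions (the SNP affects
#' the trait only through the gene's expression), this is the causal
#' effect free of non-genetic confounding, and it is algebraically
#' identical to single-instrument two-stage least squares on the
#' individual-level data.
#'
#' @param b_zy SNP effect on the trait.
#' @param b_zx SNP effect on expression; must be nonzero.
#' @return \code{b_zy / b_zx} (vectorized).
#' @export
estimate_bxy <- function(b_zy, b_zx) {
  if (any(b_zx == 0)) {
    stop("b_zx is zero: the SNP carries no expression signal ",
         "(weak instrument); the ratio is undefined")
  }
  b_zy / b_zx
}

#' Delta-method standard error of the Wald ratio
#'
#' First-order (delta-method) standard error of \eqn{b_{zy}/b_{zx}}:
#' \deqn{SE(b_{xy}) = |b_{zy}/b_{zx}|
#'   \sqrt{(se_{zy}/b_{zy})^2 + (se_{zx}/b_{zx})^2}.}
#' Valid when both z-scores are reasonably large; reported alongside the
#' estimate, while significance testing uses [smr_statistic()], which
#' remains well-behaved for weak instruments.
#'
#' @param b_zy,se_zy GWAS effect and its standard error.
#' @param b_zx,se_zx eQTL effect and its standard error.
#' @return Standard error (vectorized); \code{NA} where either beta is 0.
#' @export
delta_se_bxy <- function(b_zy, se_zy, b_zx, se_zx) {
  stopifnot(all(se_zy > 0), all(se_zx > 0))
  out <- ifelse(b_zy == 0 | b_zx == 0, NA_real_,
                abs(b_zy / b_zx) *
                  sqrt((se_zy / b_zy)^2 + (se_zx / b_zx)^2))
  out
}

#' SMR chi-square statistic
#'
#' Approximate chi-square statistic (1 df) for the null hypothesis
#' \eqn{b_{xy} = 0}, combining the two z-scores
#' \eqn{z_{zy} = b_{zy}/se_{zy}} and \eqn{z_{zx} = b_{zx}/se_{zx}}:
#' \deqn{T = \frac{z_{zy}^2\, z_{zx}^2}{z_{zy}^2 + z_{zx}^2}.}
#' This harmonic combination is bounded above by the smaller of the two
#' squared z-scores, so a weak instrument can never manufacture
#' significance. When both z-scores are zero the statistic is 0.
#'
#' @inheritParams delta_se_bxy
#' @return Chi-square statistic on 1 df (vectorized, >= 0).
#' @export
smr_statistic <- function(b_zy, se_zy, b_zx, se_zx) {
  stopifnot(all(se_zy > 0), all(se_zx > 0))
  z2y <- (b_zy / se_zy)^2
  z2x <- (b_zx / se_zx)^2
  ifelse(z2y + z2x == 0, 0, z2y * z2x / (z2y + z2x))
}

#' SMR p-value
#'
#' Upper-tail probability of the chi-square distribution with one degree
#' of freedom, equivalently \eqn{2(1 - \Phi(\sqrt{t}))}.
#'
#' @param t Chi-square statistic (>= 0).
#' @return p-value in (0, 1] (vectorized).
#' @export
smr_pvalue <- function(t) {
  if (any(t < 0)) stop("chi-square statistic must be non-negative")
  stats::pchisq(t, df = 1, lower.tail = FALSE)
}

#' Select a probe's instrument
#'
#' Picks the top cis-eQTL SNP as the probe's instrument: the harmonized
#' pair with the smallest eQTL p-value among those below the instrument
#' threshold. Ties on p are broken by larger \code{|b_zx/se_zx|}, then by
#' lexicographically smallest SNP id. Returns \code{NULL} when no SNP
#' qualifies.
#'
#' @param pairs_for_probe Data frame of harmonized pairs, all with the
#'   same \code{probe_id}.
#' @param p_threshold Instrument-selection p-value threshold (default
#'   5e-8, the conventional genome-wide level).
#' @return One-row data frame, or \code{NULL}.
#' @export
select_instrument <- function(pairs_for_probe, p_threshold = 5e-8) {
  if (nrow(pairs_for_probe) == 0L) return(NULL)
  if (length(unique(pairs_for_probe$probe_id)) != 1L) {
    stop("select_instrument requires pairs from a single probe")
  }
  cand <- pairs_for_probe[pairs_for_probe$p_eqtl < p_threshold, ,
                          drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  z <- abs(cand$b_zx / cand$se_zx)
  ord <- order(cand$p_eqtl, -z, cand$snp_id)
  cand[ord[1], , drop = FALSE]
}

#' Fit summary-data Mendelian randomization
#'
#' The package's central fit: harmonizes a GWAS and an eQTL summary
#' dataset, selects the top cis-eQTL SNP below the instrument threshold
#' for each probe, and computes per probe the Wald-ratio estimate
#' \eqn{b_{xy} = b_{zy}/b_{zx}} of the effect of that probe's expression
#' on the trait, its delta-method standard error, the chi-square SMR
#' statistic and its p-value.
#'
#' @param gwas A \code{gwas_sumstats} data frame
#'   (see [read_gwas_summary()]).
#' @param eqtl An \code{eqtl_sumstats} data frame
#'   (see [read_eqtl_summary()]).
#' @param p_eqtl_instrument Instrument-selection threshold on the eQTL
#'   p-value (default 5e-8). Probes with no SNP below it are skipped.
#' @param harmonize A [harmonize_options()] object.
#' @param label Optional experiment label; defaults to
#'   "<gwas name> x <eqtl name>".
#' @return An object of class \code{smr}: a list with
#'   \describe{
#'     \item{results}{data frame, one row per instrumented probe, with
#'       the instrument (\code{snp_id}), both source effects
#'       (\code{b_zx, se_zx, p_eqtl, b_zy, se_zy, p_gwas}), and the SMR
#'       quantities \code{b_xy, se_xy, t_smr, p_smr}, ordered by
#'       ascending \code{p_smr};}
#'     \item{drops}{harmonization drop ledger;}
#'     \item{skipped_probes}{probes with no qualifying instrument;}
#'     \item{n_probes_tested}{number of instrumented probes;}
#'     \item{label, config}{bookkeeping.}
#'   }
#' @examples
#' sc <- sim_scenario("causal", n_individuals = 2000, b_xy = 0.3, seed = 7)
#' coh <- simulate_cohort(sc)
#' gwas <- cohort_to_gwas_summary(coh)
#' eqtl <- cohort_to_eqtl_summary(coh,
#'   data.frame(probe_id = "pr1", gene_symbol = "GENE1", snp_id = "rs1"))
#' fit <- smr(gwas, eqtl)
#' coef(fit)
#' @export
smr <- function(gwas, eqtl, p_eqtl_instrument = 5e-8,
                harmonize = harmonize_options(), label = NULL) {
  stopifnot(p_eqtl_instrument > 0, p_eqtl_instrument < 1)
  h <- harmonize_datasets(gwas, eqtl, harmonize)
  probes <- unique(h$pairs$probe_id)
  rows <- vector("list", length(probes))
  skipped <- character(0)
  for (i in seq_along(probes)) {
    pp <- h$pairs[h$pairs$probe_id == probes[i], , drop = FALSE]
    inst <- select_instrument(pp, p_eqtl_instrument)
    if (is.null(inst)) {
      skipped <- c(skipped, probes[i])
      next
    }
    weak <- inst$b_zx == 0
    rows[[i]] <- data.frame(
      probe_id = inst$probe_id, gene_symbol = inst$gene_symbol,
      snp_id = inst$snp_id,
      b_zx = inst$b_zx, se_zx = inst$se_zx, p_eqtl = inst$p_eqtl,
      b_zy = inst$b_zy, se_zy = inst$se_zy, p_gwas = inst$p_gwas,
      b_xy = if (weak) NA_real_ else inst$b_zy / inst$b_zx,
      se_xy = delta_se_bxy(inst$b_zy, inst$se_zy, inst$b_zx, inst$se_zx),
      t_smr = smr_statistic(inst$b_zy, inst$se_zy, inst$b_zx, inst$se_zx),
      weak_instrument = weak,
      stringsAsFactors = FALSE
    )
  }
  results <- if (any(lengths(rows))) {
    do.call(rbind, rows[lengths(rows) > 0])
  } else {
    data.frame(probe_id = character(), gene_symbol = character(),
               snp_id = character(), b_zx = numeric(), se_zx = numeric(),
               p_eqtl = numeric(), b_zy = numeric(), se_zy = numeric(),
               p_gwas = numeric(), b_xy = numeric(), se_xy = numeric(),
               t_smr = numeric(), weak_instrument = logical(),
               stringsAsFactors = FALSE)
  }
  results$p_smr <- smr_pvalue(results$t_smr)
  results <- results[order(results$p_smr, results$probe_id), , drop = FALSE]
  rownames(results) <- NULL
  structure(list(
    results = results,
    drops = h$drops,
    skipped_probes = sort(skipped),
    n_probes_tested = nrow(results),
    label = label %||% paste(h$gwas_name, "x", h$eqtl_name),
    config = list(p_eqtl_instrument = p_eqtl_instrument,
                  harmonize = harmonize)
  ), class = "smr")
}

#' @export
print.smr <- function(x, ...) {
  cat("Summary-data MR fit:", x$label, "\n")
  cat("  probes tested:", x$n_probes_tested,
      " skipped (no instrument):", length(x$skipped_probes),
      " pairs dropped in harmonization:", nrow(x$drops), "\n")
  if (nrow(x$results)) {
    top <- utils::head(x$results, 5)
    cat("  top probes by p_smr:\n")
    print(data.frame(probe = top$probe_id, gene = top$gene_symbol,
                     SNP = top$snp_id,
                     b_xy = signif(top$b_xy, 4),
                     p_smr = signif(top$p_smr, 3)),
          row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.smr <- function(object, ...) {
  r <- object$results
  structure(list(
    label = object$label,
    n_probes_tested = object$n_probes_tested,
    n_skipped = length(object$skipped_probes),
    drops_by_reason = if (nrow(object$drops))
      table(object$drops$reason) else table(character(0)),
    results = r,
    min_p = if (nrow(r)) min(r$p_smr) else NA_real_
  ), class = "summary.smr")
}

#' @export
print.summary.smr <- function(x, ...) {
  cat("Summary-data MR:", x$label, "\n")
  cat("  probes tested:", x$n_probes_tested,
      "  skipped:", x$n_skipped, "\n")
  if (length(x$drops_by_reason)) {
    cat("  harmonization drops:",
        paste(names(x$drops_by_reason), x$drops_by_reason,
              sep = "=", collapse = ", "), "\n")
  }
  if (!is.na(x$min_p)) cat("  smallest p_smr:", format(x$min_p), "\n")
  if (nrow(x$results)) {
    cat("\n")
    print(x$results[, c("probe_id", "gene_symbol", "snp_id",
                        "b_xy", "se_xy", "p_smr")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Extract Wald-ratio estimates from an SMR fit
#'
#' @param object An [smr()] fit.
#' @param ... Unused.
#' @return Named numeric vector of \code{b_xy} estimates, one per probe.
#' @export
coef.smr <- function(object, ...) {
  stats::setNames(object$results$b_xy, object$results$probe_id)
}

#' Confidence intervals for Wald-ratio estimates
#'
#' Normal-theory intervals \code{b_xy +/- z * se_xy} using the
#' delta-method standard error.
#'
#' @param object An [smr()] fit.
#' @param parm Probe ids to include (default: all).
#' @param level Confidence level (default 0.95).
#' @param ... Unused.
#' @return Matrix with one row per probe and two columns of bounds.
#' @export
confint.smr <- function(object, parm, level = 0.95, ...) {
  r <- object$results
  if (!missing(parm)) r <- r[r$probe_id %in% parm, , drop = FALSE]
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(r$b_xy - z * r$se_xy, r$b_xy + z * r$se_xy)
  dimnames(out) <- list(r$probe_id,
                        sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                   1 - (1 - level) / 2)))
  out
}

#' Effect plot for an SMR fit
#'
#' Plots each instrumented probe's Wald-ratio estimate with its
#' delta-method confidence interval against the -log10 SMR p-value
#' (a volcano-style display).
#'
#' @param x An [smr()] fit.
#' @param level Confidence level for the error bars.
#' @param ... Passed to [plot()].
#' @return \code{x}, invisibly.
#' @export
plot.smr <- function(x, level = 0.95, ...) {
  r <- x$results
  if (!nrow(r)) {
    warning("nothing to plot: no instrumented probes")
    return(invisible(x))
  }
  graphics::plot(r$b_xy, -log10(r$p_smr),
                 xlab = expression(hat(b)[xy]),
                 ylab = expression(-log[10](p[SMR])),
                 main = x$label, pch = 19, ...)
  ci <- confint.smr(x, level = level)
  graphics::segments(ci[, 1], -log10(r$p_smr), ci[, 2], -log10(r$p_smr))
  invisible(x)
}
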