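#' Read a GWAS summary-statistics table
#'
#' Reads a tab-delimited GWAS summary file into a validated
#' \code{gwas_sumstats} data frame. The file must carry a header naming the
#' eight required columns \code{SNP, A1, A2, freq, b, se, p, n} in any
#' order; \code{A1} is the effect allele whose dosage \code{b} refers to.
#' Alleles are uppercased on read. The effect-allele frequency may be
#' \code{NA}, in which case downstream frequency checks are skipped for
#' that SNP.
#'
#' Row-level validation enforces \code{se > 0}, \code{p} in (0, 1],
#' \code{freq} in [0, 1] (when present), \code{n > 0} and
#' \code{A1 != A2}. In \code{strict} mode any offending row aborts the
#' read with its line number; in lenient mode offending rows are dropped
#' and a warning reports how many.
#'
#' @param path Path to a tab-delimited summary file.
#' @param name Dataset label; defaults to the file name without extension.
#' @param strict If \code{TRUE} (default), invalid rows are an error;
#'   otherwise they are dropped with a warning counting them.
#' @return A data frame of class \code{gwas_sumstats} with columns
#'   \code{snp_id, effect_allele, other_allele, eaf, beta, se, pvalue, n}
#'   and a \code{dataset_name} attribute.
#' @seealso [read_eqtl_summary()], [write_gwas_summary()]
#' @export
read_gwas_summary <- function(path, name = NULL, strict = TRUE) {
  raw <- read_sumstats_file(path, gwas_columns(), "GWAS")
  df <- data.frame(
    snp_id        = as.character(raw$SNP),
    effect_allele = toupper(as.character(raw$A1)),
    other_allele  = toupper(as.character(raw$A2)),
    eaf           = suppressWarnings(as.numeric(raw$freq)),
    beta          = suppressWarnings(as.numeric(raw$b)),
    se            = suppressWarnings(as.numeric(raw$se)),
    pvalue        = suppressWarnings(as.numeric(raw$p)),
    n             = suppressWarnings(as.numeric(raw$n)),
    stringsAsFactors = FALSE
  )
  df <- validate_sumstats_rows(df, raw, strict, freq_given = raw$freq)
  if (anyDuplicated(df$snp_id)) {
    stop("duplicated snp_id in GWAS dataset: ",
         paste(unique(df$snp_id[duplicated(df$snp_id)]), collapse = ", "))
  }
  if (nrow(df) == 0L) warning("GWAS file '", path, "' contains no data rows")
  new_gwas_sumstats(df, name %||% tools::file_path_sans_ext(basename(path)))
}

#' Read an eQTL summary-statistics table
#'
#' As [read_gwas_summary()], with two additional mandatory columns:
#' \code{probe} (expression probe identifier) and \code{gene} (annotated
#' gene symbol). Several probes may tag the same gene and the same SNP may
#' appear under different probes; only the (probe, SNP) pair must be
#' unique within a dataset.
#'
#' @inheritParams read_gwas_summary
#' @return A data frame of class \code{eqtl_sumstats} with columns
#'   \code{probe_id, gene_symbol, snp_id, effect_allele, other_allele,
#'   eaf, beta, se, pvalue, n} and a \code{dataset_name} attribute.
#' @export
read_eqtl_summary <- function(path, name = NULL, strict = TRUE) {
  raw <- read_sumstats_file(path, eqtl_columns(), "eQTL")
  df <- data.frame(
    probe_id      = as.character(raw$probe),
    gene_symbol   = as.character(raw$gene),
    snp_id        = as.character(raw$SNP),
    effect_allele = toupper(as.character(raw$A1)),
    other_allele  = toupper(as.character(raw$A2)),
    eaf           = suppressWarnings(as.numeric(raw$freq)),
    beta          = suppressWarnings(as.numeric(raw$b)),
    se            = suppressWarnings(as.numeric(raw$se)),
    pvalue        = suppressWarnings(as.numeric(raw$p)),
    n             = suppressWarnings(as.numeric(raw$n)),
    stringsAsFactors = FALSE
  )
  df <- validate_sumstats_rows(df, raw, strict, freq_given = raw$freq)
  key <- paste(df$probe_id, df$snp_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (probe_id, snp_id) in eQTL dataset: ",
         paste(unique(sub("\r", "/", key[duplicated(key)])), collapse = ", "))
  }
  if (nrow(df) == 0L) warning("eQTL file '", path, "' contains no data rows")
  new_eqtl_sumstats(df, name %||% tools::file_path_sans_ext(basename(path)))
}

#' Write a GWAS summary dataset to its tab-delimited dialect
#'
#' Numeric fields are written with full double precision so that
#' read-after-write reproduces the dataset field-for-field.
#'
#' @param x A \code{gwas_sumstats} data frame.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_gwas_summary <- function(x, path) {
  stopifnot(inherits(x, "gwas_sumstats"))
  out <- data.frame(
    SNP = x$snp_id, A1 = x$effect_allele, A2 = x$other_allele,
    freq = num_full(x$eaf), b = num_full(x$beta), se = num_full(x$se),
    p = num_full(x$pvalue), n = num_full(x$n),
    stringsAsFactors = FALSE
  )
  write_tsv(out, path)
  invisible(path)
}

#' Write an eQTL summary dataset to its tab-delimited dialect
#'
#' @param x An \code{eqtl_sumstats} data frame.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_eqtl_summary <- function(x, path) {
  stopifnot(inherits(x, "eqtl_sumstats"))
  out <- data.frame(
    probe = x$probe_id, gene = x$gene_symbol, SNP = x$snp_id,
    A1 = x$effect_allele, A2 = x$other_allele,
    freq = num_full(x$eaf), b = num_full(x$beta), se = num_full(x$se),
    p = num_full(x$pvalue), n = num_full(x$n),
    stringsAsFactors = FALSE
  )
  write_tsv(out, path)
  invisible(path)
}

#' Write an SMR results table
#'
#' Emits the per-probe results as a tab-delimited table with one row per
#' probe-level test, ordered by ascending \code{p_smr}. Effect sizes keep
#' full precision; p-values are rendered in scientific notation with four
#' significant digits.
#'
#' @param results A data frame of SMR results (as the \code{$results}
#'   component of an [smr()] fit), possibly empty.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_results_table <- function(results, path) {
  cols <- c("snp_id", "gene_symbol", "probe_id", "b_zx", "se_zx", "p_eqtl",
            "b_zy", "se_zy", "p_gwas", "b_xy", "se_xy", "t_smr", "p_smr")
  missing <- setdiff(cols, names(results))
  if (length(missing)) {
    stop("results table lacks columns: ", paste(missing, collapse = ", "))
  }
  results <- results[order(results$p_smr, results$probe_id, results$snp_id), ,
                     drop = FALSE]
  out <- data.frame(
    index = seq_len(nrow(results)),
    SNP = results$snp_id, GENE = results$gene_symbol,
    probe = results$probe_id,
    b_zx = num_full(results$b_zx), se_zx = num_full(results$se_zx),
    p_eqtl = num_sci(results$p_eqtl),
    b_zy = num_full(results$b_zy), se_zy = num_full(results$se_zy),
    p_gwas = num_sci(results$p_gwas),
    b_xy = num_full(results$b_xy), se_xy = num_full(results$se_xy),
    T_smr = num_full(results$t_smr),
    p_smr = num_sci(results$p_smr),
    stringsAsFactors = FALSE
  )
  if (nrow(results) == 0L) out <- out[0, , drop = FALSE]
  write_tsv(out, path)
  invisible(path)
}

## ---- internal helpers -----------------------------------------------------

gwas_columns <- function() c("SNP", "A1", "A2", "freq", "b", "se", "p", "n")
eqtl_columns <- function() c("probe", "gene", gwas_columns())

`%||%` <- function(a, b) if (is.null(a)) b else a

read_sumstats_file <- function(path, required, label) {
  if (!file.exists(path)) stop(label, " file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           comment.char = "", check.names = FALSE,
                           na.strings = character(0))
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop(label, " file '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  raw
}

# Row invariants shared by both record types. `freq_given` carries the raw
# freq strings so a literal "NA" can be told apart from an unparseable value.
validate_sumstats_rows <- function(df, raw, strict, freq_given) {
  n <- nrow(df)
  if (n == 0L) return(df)
  freq_na_ok <- toupper(trimws(freq_given)) %in% c("NA", "")
  bad <- character(n)
  flag <- function(cond, msg) {
    cond[is.na(cond)] <- FALSE
    bad[cond & !nzchar(bad)] <<- msg
  }
  flag(is.na(df$beta), "non-numeric beta")
  flag(is.na(df$se), "non-numeric se")
  flag(is.na(df$pvalue), "non-numeric p")
  flag(is.na(df$n), "non-numeric n")
  flag(is.na(df$eaf) & !freq_na_ok, "non-numeric freq")
  flag(df$se <= 0, "se <= 0")
  flag(df$pvalue <= 0 | df$pvalue > 1, "p outside (0, 1]")
  flag(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1), "freq outside [0, 1]")
  flag(df$n <= 0, "n <= 0")
  flag(df$effect_allele == df$other_allele, "effect allele equals other allele")
  idx <- which(nzchar(bad))
  if (length(idx)) {
    # +1 for the header line
    if (strict) {
      stop("invalid summary row at line ", idx[1] + 1L, ": ", bad[idx[1]])
    }
    warning("dropped ", length(idx), " invalid row(s)")
    df <- df[-idx, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

new_gwas_sumstats <- function(df, name) {
  stopifnot(nzchar(name))
  structure(df, dataset_name = name,
            class = c("gwas_sumstats", "data.frame"))
}

new_eqtl_sumstats <- function(df, name) {
  stopifnot(nzchar(name))
  structure(df, dataset_name = name,
            class = c("eqtl_sumstats", "data.frame"))
}

#' Dataset label of a summary-statistics object
#' @param x A \code{gwas_sumstats} or \code{eqtl_sumstats} object.
#' @return The dataset name as a single string.
#' @export
dataset_name <- function(x) attr(x, "dataset_name") %||% "unnamed"

# %.17g keeps doubles exactly round-trippable through text
num_full <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
num_sci <- function(x) ifelse(is.na(x), "NA", sprintf("%.3e", x))

write_tsv <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write '", path, "': ", conditionMessage(ok))
  invisible(path)
}
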