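# Female-vs-male expression bias from a TPM matrix: expression filter,
# fold change, Welch t-test with BH correction, and per-class summaries.

#' Remove genes below a mean-TPM expression floor
#'
#' @param expr an `expression_table`.
#' @param min_mean genes with mean TPM (across all samples) below this are
#'   dropped; default 1. A mean of exactly `min_mean` is kept.
#' @return The filtered `expression_table`.
#' @export
tpm_filter <- function(expr, min_mean = 1) {
  keep <- rowMeans(expr$tpm) >= min_mean
  expression_table(expr$tpm[keep, , drop = FALSE], expr$meta)
}

#' log2 fold change of female over male mean expression
#'
#' Computes `log2((mean_F + eps) / (mean_M + eps))` on raw TPM, with a
#' pseudocount `eps` (default 0.5, matching the log2(x + 0.5) transform
#' used throughout the package).
#'
#' @param expr an `expression_table`.
#' @param gene gene identifier (row of the TPM matrix).
#' @param eps pseudocount.
#' @return A single numeric log2 fold change.
#' @export
log2_fold_change <- function(expr, gene, eps = 0.5) {
  if (!gene %in% rownames(expr$tpm)) stop("unknown gene: ", gene)
  for (s in c("F", "M")) {
    if (!any(expr$meta$sex == s)) {
      stop("no samples of sex ", s, " in expression table")
    }
  }
  v <- expr$tpm[gene, ]
  mf <- mean(v[expr$meta$sex == "F"])
  mm <- mean(v[expr$meta$sex == "M"])
  log2((mf + eps) / (mm + eps))
}

#' Test every gene for sex-biased expression
#'
#' Welch two-sample t-test on log2(TPM + eps), female vs male samples,
#' with Benjamini-Hochberg correction across all tested genes. A gene is
#' flagged `biased` when its (uncorrected) p-value falls below `p_cut` and
#' its |log2FC| exceeds `fc_cut`; both cut-offs are configurable (the
#' defaults match the thymocyte landscape regime; see also
#' [xci_thresholds()]).
#'
#' @param expr an `expression_table` (usually after [tpm_filter()]).
#' @param p_cut significance cut-off, default 1e-5.
#' @param fc_cut absolute log2FC cut-off, default 0.2.
#' @param eps pseudocount, default 0.5.
#' @param use_q if TRUE the `biased` flag uses the BH-adjusted q-value
#'   instead of the raw p-value.
#' @return data.frame with one row per gene: `gene_id, log2fc, mean_tpm_f,
#'   mean_tpm_m, p_value, q_value, biased`. With fewer than two samples in
#'   either sex, p and q are `NA`, `biased` is FALSE, and a warning is
#'   raised.
#' @export
sex_bias_test <- function(expr, p_cut = 1e-5, fc_cut = 0.2, eps = 0.5,
                          use_q = FALSE) {
  isf <- expr$meta$sex == "F"
  ism <- expr$meta$sex == "M"
  mat <- expr$tpm
  mf <- rowMeans(mat[, isf, drop = FALSE])
  mm <- rowMeans(mat[, ism, drop = FALSE])
  out <- data.frame(gene_id = rownames(mat),
                    log2fc = log2((mf + eps) / (mm + eps)),
                    mean_tpm_f = mf, mean_tpm_m = mm,
                    stringsAsFactors = FALSE)
  if (sum(isf) < 2 || sum(ism) < 2) {
    warning("fewer than 2 samples in one sex; p-values unavailable")
    out$p_value <- NA_real_
    out$q_value <- NA_real_
    out$biased <- FALSE
    rownames(out) <- NULL
    return(out)
  }
  lmat <- log2(mat + eps)
  out$p_value <- vapply(seq_len(nrow(lmat)), function(i) {
    x <- lmat[i, isf]; y <- lmat[i, ism]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      return(if (mean(x) == mean(y)) 1 else 0)
    }
    stats::t.test(x, y)$p.value
  }, numeric(1))
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  crit <- if (use_q) out$q_value else out$p_value
  out$biased <- crit < p_cut & abs(out$log2fc) > fc_cut
  rownames(out) <- NULL
  out
}

#' Summarize sex bias per XCI gene class
#'
#' Median and IQR of log2FC for the PAR, escape and inactive classes
#' (classes taken from the annotation: region PAR1/PAR2, else
#' prior_status). An optional display cap truncates reported log2FC to
#' +/- `cap` *after* all statistics are computed on raw values; capped
#' genes are flagged and their raw values kept.
#'
#' @param results output of [sex_bias_test()].
#' @param annotation gene annotation data.frame.
#' @param cap optional absolute display cap (e.g. 1); NULL for none.
#' @return list with `per_class` (class, n, median_log2fc, iqr_log2fc) and
#'   `genes` (per-gene table with class and, if capped, `log2fc_display`,
#'   `capped`, raw `log2fc`). Classes with zero genes are omitted with a
#'   warning.
#' @export
group_bias_summary <- function(results, annotation, cap = NULL) {
  cls <- ifelse(annotation$region %in% c("PAR1", "PAR2"), "PAR",
                annotation$prior_status)
  map <- stats::setNames(cls, annotation$gene_id)
  genes <- results
  genes$class <- unname(map[genes$gene_id])
  genes <- genes[!is.na(genes$class) &
                   genes$class %in% c("PAR", "escape", "inactive"), ,
                 drop = FALSE]
  per <- lapply(c("PAR", "escape", "inactive"), function(cl) {
    v <- genes$log2fc[genes$class == cl]
    if (length(v) == 0) {
      warning("class with zero genes omitted: ", cl)
      return(NULL)
    }
    data.frame(class = cl, n = length(v),
               median_log2fc = stats::median(v),
               iqr_log2fc = stats::IQR(v), stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, per[!vapply(per, is.null, logical(1))])
  if (!is.null(cap)) {
    genes$log2fc_display <- pmin(pmax(genes$log2fc, -cap), cap)
    genes$capped <- abs(genes$log2fc) > cap
  }
  rownames(genes) <- NULL
  list(per_class = per_class, genes = genes)
}
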