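# The combined XCI status classifier: allele-specific expression when
# available, otherwise promoter methylation plus sex-biased expression.

.xci_statuses <- c("escape_ASE", "inactive_ASE", "escape_high",
                   "escape_low", "inactive", "unclassified")

#' Classify one gene's XCI status
#'
#' Decision rule (thresholds configurable, defaults shown):
#' \itemize{
#'   \item ASE evidence, when present, is decisive: mean deviation
#'     <= 0.4 -> `escape_ASE`; > 0.4 -> `inactive_ASE`.
#'   \item Otherwise, low promoter methylation (beta < 0.25) with
#'     log2FC > 0.2 -> `escape_high`; with 0 < log2FC <= 0.2 ->
#'     `escape_low`; with log2FC <= 0 -> `unclassified`.
#'   \item Non-low methylation (beta >= 0.25) with log2FC < 0.2 ->
#'     `inactive`; with log2FC >= 0.2 -> `unclassified`.
#'   \item No ASE and no methylation evidence -> `unclassified`
#'     (reason "no evidence").
#' }
#' The rule is exhaustive and mutually exclusive over every combination of
#' inputs. The log2FC criterion is directional (female-biased), not an
#' absolute value. When `gate_fc_on_p` is set, the methylation+bias branch
#' additionally requires `biased = TRUE` from the sex-bias test for its
#' fold-change comparisons (off by default).
#'
#' @param ase_dev mean ASE deviation of the gene, or `NA`/`NULL` when the
#'   gene has no ASE coverage.
#' @param meth_beta mean promoter methylation beta, or `NA`/`NULL` when no
#'   probe covers the promoter.
#' @param log2fc female-over-male log2 fold change (`NA` if untested).
#' @param biased logical sex-bias significance flag (used only with
#'   `gate_fc_on_p`).
#' @param thresholds list from [xci_thresholds()].
#' @return list with `status`, `reason`, and the evidence echoed.
#' @export
classify_gene <- function(ase_dev = NA, meth_beta = NA, log2fc = NA,
                          biased = NA, thresholds = xci_thresholds()) {
  thr <- thresholds
  if (is.null(ase_dev)) ase_dev <- NA_real_
  if (is.null(meth_beta)) meth_beta <- NA_real_
  if (is.null(log2fc)) log2fc <- NA_real_
  if (!is.na(ase_dev)) {
    status <- if (ase_dev <= thr$ase_dev) "escape_ASE" else "inactive_ASE"
    return(list(status = status, reason = "ASE",
                ase_dev = ase_dev, meth_beta = meth_beta, log2fc = log2fc))
  }
  if (is.na(meth_beta) || is.na(log2fc)) {
    return(list(status = "unclassified", reason = "no evidence",
                ase_dev = NA_real_, meth_beta = meth_beta, log2fc = log2fc))
  }
  fc <- log2fc
  fc_usable <- !isTRUE(thr$gate_fc_on_p) || isTRUE(biased)
  meth_is_low <- if (isTRUE(thr$meth_low_inclusive)) {
    meth_beta <= thr$meth_low
  } else {
    meth_beta < thr$meth_low
  }
  status <- if (meth_is_low) {
    if (fc_usable && fc > thr$fc_escape) "escape_high"
    else if (fc_usable && fc > 0) "escape_low"
    else "unclassified"
  } else {
    if (!fc_usable || fc < thr$fc_escape) "inactive" else "unclassified"
  }
  list(status = status, reason = "methylation+bias",
       ase_dev = NA_real_, meth_beta = meth_beta, log2fc = log2fc)
}

#' Classify all genes from ASE, methylation and sex-bias tables
#'
#' Joins the three evidence tables by gene and applies [classify_gene()]
#' to each gene present in any of them.
#'
#' @param ase output of [ase_score()] (may be NULL).
#' @param meth output of [promoter_mean_beta()] (may be NULL).
#' @param bias output of [sex_bias_test()] (may be NULL).
#' @param thresholds list from [xci_thresholds()].
#' @return data.frame with one row per gene: `gene_id, status, reason,
#'   ase_dev, meth_beta, meth_category, log2fc` plus the threshold columns
#'   `thr_ase_dev, thr_meth_low, thr_fc_escape` used, suitable for
#'   [write_status_table()].
#' @export
classify_genes <- function(ase = NULL, meth = NULL, bias = NULL,
                           thresholds = xci_thresholds()) {
  genes <- unique(c(if (!is.null(ase)) ase$gene_id,
                    if (!is.null(meth)) meth$gene_id,
                    if (!is.null(bias)) bias$gene_id))
  look <- function(df, col, g) {
    if (is.null(df)) return(NA)
    i <- match(g, df$gene_id)
    if (is.na(i)) NA else df[[col]][i]
  }
  rows <- lapply(genes, function(g) {
    dev <- look(ase, "mean_dev", g)
    mb <- look(meth, "mean_beta", g)
    mc <- look(meth, "category", g)
    fc <- look(bias, "log2fc", g)
    bs <- look(bias, "biased", g)
    cl <- classify_gene(dev, mb, fc, bs, thresholds)
    data.frame(gene_id = g, status = cl$status, reason = cl$reason,
               ase_dev = as.numeric(dev), meth_beta = as.numeric(mb),
               meth_category = if (is.na(mc)) NA_character_ else mc,
               log2fc = as.numeric(fc), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$thr_ase_dev <- thresholds$ase_dev
  out$thr_meth_low <- thresholds$meth_low
  out$thr_fc_escape <- thresholds$fc_escape
  rownames(out) <- NULL
  out
}

#' Compare XCI calls with a reference annotation
#'
#' Calls are collapsed to binary escape/inactive (ASE-based and high/low
#' confidence merged; unclassified excluded) and compared with the
#' annotation's `prior_status` over genes where both are informative
#' (prior escape or inactive).
#'
#' @param calls data.frame from [classify_genes()].
#' @param annotation gene annotation with `prior_status`.
#' @return list with `n_comparable`, `n_agree`, `agreement` (fraction, or
#'   `NA` with `agreement_defined = FALSE` when no gene is comparable),
#'   `confusion` (2x2 table call x prior), and `reclassified` (gene_id,
#'   prior_status, status).
#' @export
compare_with_reference <- function(calls, annotation) {
  bin <- ifelse(calls$status %in% c("escape_ASE", "escape_high",
                                    "escape_low"), "escape",
         ifelse(calls$status %in% c("inactive_ASE", "inactive"),
                "inactive", NA_character_))
  prior <- annotation$prior_status[match(calls$gene_id,
                                         annotation$gene_id)]
  ok <- !is.na(bin) & !is.na(prior) & prior %in% c("escape", "inactive")
  n_comp <- sum(ok)
  if (n_comp == 0) {
    return(list(n_comparable = 0L, n_agree = 0L, agreement = NA_real_,
                agreement_defined = FALSE,
                confusion = table(call = character(0),
                                  prior = character(0)),
                reclassified = data.frame(gene_id = character(0),
                                          prior_status = character(0),
                                          status = character(0),
                                          stringsAsFactors = FALSE)))
  }
  lv <- c("escape", "inactive")
  conf <- table(call = factor(bin[ok], lv), prior = factor(prior[ok], lv))
  agree <- bin[ok] == prior[ok]
  recl <- data.frame(gene_id = calls$gene_id[ok][!agree],
                     prior_status = prior[ok][!agree],
                     status = calls$status[ok][!agree],
                     stringsAsFactors = FALSE)
  rownames(recl) <- NULL
  list(n_comparable = as.integer(n_comp), n_agree = as.integer(sum(agree)),
       agreement = mean(agree), agreement_defined = TRUE,
       confusion = conf, reclassified = recl)
}

#' Run the full bulk classification pipeline on a cohort
#'
#' Convenience wrapper tying the modules together: strict ASE filtering and
#' per-gene site selection for the chosen donor (by default the donor
#' flagged as completely skewed by [detect_cxci()], since ASE in bulk
#' resolves XCI only under complete skewing), sex-bias testing on the
#' TPM matrix, promoter methylation categorisation, and the combined
#' classifier, restricted to chrX genes.
#'
#' @param cohort list with `annotation`, `expression`, `sites`,
#'   `methylation` (as from [simulate_cohort()] or assembled from the
#'   readers).
#' @param ase_individual donor whose allelic data feed the ASE arm; NULL
#'   to auto-select via [detect_cxci()] (NA ASE arm if none qualifies).
#' @param thresholds list from [xci_thresholds()].
#' @return list with `calls` (classification table), `ase`, `bias`,
#'   `meth`, and `ase_individual` used.
#' @export
classify_cohort <- function(cohort, ase_individual = NULL,
                            thresholds = xci_thresholds()) {
  ann <- cohort$annotation
  x_genes <- ann$gene_id[ann$chrom %in% c("chrX", "X")]

  expr <- tpm_filter(cohort$expression, thresholds$tpm_min)
  bias <- sex_bias_test(expr, p_cut = thresholds$sexbias_p,
                        fc_cut = thresholds$sexbias_fc,
                        eps = thresholds$eps)

  filtered <- filter_ase_sites(cohort$sites, "strict",
                               maf_source = thresholds$maf_source)
  if (is.null(ase_individual)) {
    for (ind in unique(sub("_[^_]+$", "", filtered$sample_id))) {
      s_ind <- filtered[startsWith(filtered$sample_id, paste0(ind, "_")), ,
                        drop = FALSE]
      cx <- detect_cxci(s_ind, ann,
                        min_snps = thresholds$min_informative_snps,
                        dev_threshold = thresholds$cxci_dev,
                        frac_threshold = thresholds$cxci_frac)
      if (isTRUE(cx$cxci_flag)) { ase_individual <- ind; break }
    }
  }
  ase <- NULL
  if (!is.null(ase_individual)) {
    s_ind <- filtered[startsWith(filtered$sample_id,
                                 paste0(ase_individual, "_")), ,
                      drop = FALSE]
    ase <- ase_score(select_sites(s_ind),
                     dev_threshold = thresholds$ase_dev)
  }

  meth <- NULL
  if (!is.null(cohort$methylation)) {
    meth <- promoter_mean_beta(cohort$methylation, ann,
                               low = thresholds$meth_low,
                               high = thresholds$meth_high,
                               low_inclusive = thresholds$meth_low_inclusive)
  }

  sub_x <- function(df) if (is.null(df)) NULL else
    df[df$gene_id %in% x_genes, , drop = FALSE]
  calls <- classify_genes(sub_x(ase), sub_x(meth), sub_x(bias), thresholds)
  list(calls = calls, ase = ase, bias = bias, meth = meth,
       ase_individual = ase_individual)
}
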