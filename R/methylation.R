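# Promoter methylation summaries: per-gene mean beta over a strand-aware
# TSS window and the low/intermediate/high categories the classifier uses.

#' Mean promoter methylation per gene
#'
#' Averages probe beta values inside a strand-aware promoter window
#' `[TSS - upstream_bp, TSS + downstream_bp]` on the transcribed strand
#' (for minus-strand genes the window is reflected in genome coordinates:
#' `[TSS - downstream_bp, TSS + upstream_bp]`). Probe values are averaged
#' within the window per sample, then over samples (and per cell type when
#' sample metadata is available).
#'
#' @param meth a `methylation_table`.
#' @param annotation gene annotation with `gene_id, chrom, tss, strand`.
#' @param upstream_bp,downstream_bp window size in bp; defaults 500 and 0
#'   (the classifier window). Use `downstream_bp = 1500` for the wider
#'   display window.
#' @return data.frame `gene_id, n_probes, mean_beta, category` with one
#'   row per annotated gene; genes with no probe in the window get
#'   `category = "no_probe"` and `mean_beta = NA`. Per-cell-type means (if
#'   metadata present) attached as attribute `"per_cell_type"`.
#' @param low,high,low_inclusive category boundaries, passed to
#'   [categorize_beta()].
#' @export
promoter_mean_beta <- function(meth, annotation, upstream_bp = 500,
                               downstream_bp = 0, low = 0.25, high = 0.75,
                               low_inclusive = FALSE) {
  pr <- meth$probes
  res <- data.frame(gene_id = annotation$gene_id,
                    n_probes = 0L, mean_beta = NA_real_,
                    stringsAsFactors = FALSE)
  per_ct <- NULL
  ct <- if (!is.null(meth$meta) && "cell_type" %in% names(meth$meta)) {
    meth$meta$cell_type[match(colnames(meth$beta), meth$meta$sample_id)]
  } else NULL
  ct_rows <- list()
  for (i in seq_len(nrow(annotation))) {
    tss <- annotation$tss[i]
    if (annotation$strand[i] == "-") {
      lo <- tss - downstream_bp; hi <- tss + upstream_bp
    } else {
      lo <- tss - upstream_bp; hi <- tss + downstream_bp
    }
    in_win <- pr$chrom == annotation$chrom[i] & pr$pos >= lo & pr$pos <= hi
    res$n_probes[i] <- sum(in_win)
    if (any(in_win)) {
      sub <- meth$beta[in_win, , drop = FALSE]
      res$mean_beta[i] <- mean(colMeans(sub))
      if (!is.null(ct)) {
        m <- tapply(colMeans(sub), ct, mean)
        ct_rows[[annotation$gene_id[i]]] <-
          data.frame(gene_id = annotation$gene_id[i],
                     cell_type = names(m), mean_beta = as.numeric(m),
                     stringsAsFactors = FALSE)
      }
    }
  }
  res$category <- ifelse(res$n_probes == 0, "no_probe",
                         categorize_beta(ifelse(is.na(res$mean_beta), 0,
                                                res$mean_beta),
                                         low, high, low_inclusive))
  res$category[res$n_probes == 0] <- "no_probe"
  if (length(ct_rows)) per_ct <- do.call(rbind, ct_rows)
  rownames(res) <- NULL
  attr(res, "per_cell_type") <- per_ct
  res
}

#' Categorize a mean beta value as low / intermediate / high
#'
#' Default boundaries follow the classifier convention: `low` strictly
#' below 0.25, `high` strictly above 0.75, `intermediate` in between.
#' Set `low_inclusive = TRUE` for the alternative reading in which
#' beta = 0.25 is still low. The function is total on \[0, 1\]: every beta
#' maps to exactly one category.
#'
#' @param beta numeric vector of mean beta values in \[0, 1\].
#' @param low,high boundaries, defaults 0.25 / 0.75.
#' @param low_inclusive whether beta == `low` counts as low.
#' @return Character vector over \{low, intermediate, high\}.
#' @export
categorize_beta <- function(beta, low = 0.25, high = 0.75,
                            low_inclusive = FALSE) {
  if (any(is.na(beta)) || any(beta < 0 | beta > 1)) {
    stop("beta values must lie in [0, 1]")
  }
  is_low <- if (low_inclusive) beta <= low else beta < low
  ifelse(is_low, "low", ifelse(beta > high, "high", "intermediate"))
}

#' Select the most variable probes
#'
#' Ranks probes by variance across samples and returns the top `n`;
#' deterministic tie-break by genomic coordinate (chrom, then position).
#' Intended for sample-level clustering of methylation profiles.
#'
#' @param meth a `methylation_table`.
#' @param n number of probes to keep, default 1000. If `n` exceeds the
#'   probe count, all probes are returned with a warning.
#' @return A `methylation_table` restricted to the selected probes.
#' @export
top_variable_probes <- function(meth, n = 1000) {
  total <- nrow(meth$beta)
  if (n > total) {
    warning("n (", n, ") exceeds probe count (", total, "); returning all")
    n <- total
  }
  v <- apply(meth$beta, 1, stats::var)
  o <- order(-v, meth$probes$chrom, meth$probes$pos)
  keep <- sort(o[seq_len(n)])
  methylation_table(meth$beta[keep, , drop = FALSE],
                    meth$probes[keep, , drop = FALSE], meth$meta)
}
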