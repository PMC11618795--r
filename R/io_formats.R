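# Readers/writers for the plain-TSV tables the pipeline consumes. All
# coordinates are 1-based (VCF convention); BED input is converted on read.

.bulk_count_cols <- c("sample_id", "cell_type", "gene_id", "chrom", "pos",
                      "ref_allele", "alt_allele",
                      "rna_ref", "rna_alt", "dna_ref", "dna_alt")
.sc_count_cols <- c("cell_id", "cell_type", "gene_id", "chrom", "pos",
                    "ref_allele", "alt_allele", "rna_ref", "rna_alt")

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

.write_tsv <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok))
  invisible(path)
}

.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, ": missing required column(s): ", paste(miss, collapse = ", "))
  }
}

.check_counts <- function(df, cols, what) {
  for (cc in cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad)) {
      stop(what, ": invalid count in column '", cc, "' at row ", bad[1],
           " (value '", df[[cc]][bad[1]], "')")
    }
    df[[cc]] <- as.integer(v)
  }
  df
}

#' Read a table of allelic counts at heterozygous SNPs
#'
#' Parses an ASEReadCounter-style TSV of per-site reference/alternative read
#' counts. The bulk schema carries matched RNA and DNA (WES) counts per
#' sample and cell type; the single-cell schema carries RNA counts per cell.
#'
#' @param path path to a tab-separated file with a header row.
#' @param schema `"bulk"` or `"singlecell"`.
#' @return A data.frame with one row per site; positions are 1-based
#'   integers. Columns for bulk:
#'   `sample_id, cell_type, gene_id, chrom, pos, ref_allele, alt_allele,
#'   rna_ref, rna_alt, dna_ref, dna_alt`; single-cell replaces `sample_id`
#'   with `cell_id` and drops the DNA columns.
#' @export
read_allelic_counts <- function(path, schema = c("bulk", "singlecell")) {
  schema <- match.arg(schema)
  cols <- if (schema == "bulk") .bulk_count_cols else .sc_count_cols
  df <- .read_tsv(path)
  .require_cols(df, cols, "allelic counts")
  df <- df[, cols, drop = FALSE]
  if (nrow(df) == 0) return(df)
  count_cols <- grep("^(rna|dna)_", cols, value = TRUE)
  df <- .check_counts(df, c("pos", count_cols), "allelic counts")
  if (any(df$pos < 1)) {
    stop("allelic counts: position < 1 at row ", which(df$pos < 1)[1])
  }
  same <- which(df$ref_allele == df$alt_allele)
  if (length(same)) {
    stop("allelic counts: ref_allele equals alt_allele at row ", same[1])
  }
  df
}

#' Write allelic counts to TSV
#'
#' Inverse of [read_allelic_counts()]; round-trips losslessly.
#'
#' @param sites data.frame of allelic sites.
#' @param path output path.
#' @export
write_allelic_counts <- function(sites, path) {
  .write_tsv(sites, path)
}

#' Classify a position into PAR1/PAR2/nonPAR/autosome
#'
#' @param chrom chromosome name(s).
#' @param pos 1-based position(s).
#' @param par_intervals PAR intervals as from [par_intervals_hg38()].
#' @return Character vector over \{PAR1, PAR2, nonPAR, autosome\}.
#' @export
classify_region <- function(chrom, pos, par_intervals = par_intervals_hg38()) {
  is_x <- chrom %in% c("chrX", "X")
  p1 <- par_intervals$PAR1
  p2 <- par_intervals$PAR2
  out <- ifelse(!is_x, "autosome",
         ifelse(pos >= p1[1] & pos <= p1[2], "PAR1",
         ifelse(pos >= p2[1] & pos <= p2[2], "PAR2", "nonPAR")))
  out
}

#' Read a gene annotation table
#'
#' Accepts either a headered TSV with 1-based TSS coordinates (`format =
#' "tsv"`) or a 6-column BED file (`format = "bed"`, 0-based half-open;
#' the strand-aware TSS is taken from the interval and converted to
#' 1-based). Optional columns `region`, `prior_status` and `immune_flag`
#' default to a PAR-interval derivation, `"unknown"` and `FALSE`.
#'
#' @param path input file.
#' @param format `"tsv"` or `"bed"`.
#' @param par_intervals PAR intervals used to derive `region` when absent.
#' @return data.frame with columns `gene_id, chrom, tss, strand, region,
#'   prior_status, immune_flag`.
#' @export
read_gene_annotation <- function(path, format = c("tsv", "bed"),
                                 par_intervals = par_intervals_hg38()) {
  format <- match.arg(format)
  if (format == "bed") {
    raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (ncol(raw) < 6) stop("BED annotation needs 6 columns (incl. strand)")
    names(raw)[1:6] <- c("chrom", "start", "end", "gene_id", "score", "strand")
    df <- data.frame(gene_id = raw$gene_id, chrom = raw$chrom,
                     tss = ifelse(raw$strand == "-", raw$end, raw$start + 1L),
                     strand = raw$strand, stringsAsFactors = FALSE)
  } else {
    df <- .read_tsv(path)
    .require_cols(df, c("gene_id", "chrom", "tss", "strand"), "annotation")
  }
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad)) {
    stop("annotation: unknown strand symbol '", df$strand[bad[1]],
         "' at row ", bad[1])
  }
  df$tss <- as.integer(df$tss)
  if (any(is.na(df$tss) | df$tss < 1)) stop("annotation: TSS must be >= 1")
  if (is.null(df$region) || all(is.na(df$region))) {
    df$region <- classify_region(df$chrom, df$tss, par_intervals)
  }
  par_off_x <- df$region %in% c("PAR1", "PAR2") & !df$chrom %in% c("chrX", "X")
  if (any(par_off_x)) {
    stop("annotation: PAR region on non-X chromosome at row ",
         which(par_off_x)[1])
  }
  if (is.null(df$prior_status)) df$prior_status <- "unknown"
  df$prior_status[is.na(df$prior_status) | df$prior_status == ""] <- "unknown"
  ok_prior <- df$prior_status %in% c("escape", "inactive", "variable", "unknown")
  if (!all(ok_prior)) {
    stop("annotation: invalid prior_status at row ", which(!ok_prior)[1])
  }
  if (is.null(df$immune_flag)) df$immune_flag <- FALSE
  df$immune_flag <- as.logical(df$immune_flag)
  df$immune_flag[is.na(df$immune_flag)] <- FALSE
  cols <- c("gene_id", "chrom", "tss", "strand", "region", "prior_status",
            "immune_flag")
  df[, cols, drop = FALSE]
}

#' @rdname read_gene_annotation
#' @param annotation annotation data.frame to write.
#' @export
write_gene_annotation <- function(annotation, path) {
  .write_tsv(annotation, path)
}

#' Read a TPM expression matrix with sample metadata
#'
#' @param tpm_path TSV whose first column is `gene_id`, remaining columns
#'   one per sample.
#' @param meta_path TSV with columns `sample_id, sex, karyotype, cell_type,
#'   individual`; every expression column must have a metadata row.
#' @return An `expression_table`: list with `tpm` (genes x samples numeric
#'   matrix) and `meta` (data.frame, ordered as the matrix columns).
#' @export
read_expression_table <- function(tpm_path, meta_path) {
  tpm <- .read_tsv(tpm_path)
  .require_cols(tpm, "gene_id", "TPM table")
  mat <- as.matrix(tpm[, setdiff(names(tpm), "gene_id"), drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- tpm$gene_id
  if (any(is.na(mat)) || any(mat < 0)) stop("TPM table: TPM must be >= 0")
  meta <- .read_tsv(meta_path)
  .require_cols(meta, c("sample_id", "sex", "karyotype", "cell_type",
                        "individual"), "sample metadata")
  miss <- setdiff(colnames(mat), meta$sample_id)
  if (length(miss)) {
    stop("sample metadata: no metadata for sample(s): ",
         paste(miss, collapse = ", "))
  }
  if (!all(meta$sex %in% c("F", "M"))) stop("sample metadata: sex must be F/M")
  if (!all(meta$karyotype %in% c("XX", "XY", "X0"))) {
    stop("sample metadata: karyotype must be XX/XY/X0")
  }
  meta <- meta[match(colnames(mat), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  expression_table(mat, meta)
}

#' Construct an expression table from a matrix and metadata
#'
#' @param tpm genes x samples numeric matrix of TPM.
#' @param meta data.frame with one row per column of `tpm`.
#' @return An object of class `expression_table`.
#' @export
expression_table <- function(tpm, meta) {
  stopifnot(is.matrix(tpm), ncol(tpm) == nrow(meta))
  structure(list(tpm = tpm, meta = meta), class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat("expression_table:", nrow(x$tpm), "genes x", ncol(x$tpm), "samples (",
      sum(x$meta$sex == "F"), "F /", sum(x$meta$sex == "M"), "M )\n")
  invisible(x)
}

#' Write an expression table to a pair of TSV files
#'
#' @param expr `expression_table`.
#' @param tpm_path,meta_path output paths.
#' @export
write_expression_table <- function(expr, tpm_path, meta_path) {
  df <- data.frame(gene_id = rownames(expr$tpm), expr$tpm,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, tpm_path)
  .write_tsv(expr$meta, meta_path)
}

#' Read a methylation beta-value matrix
#'
#' @param path TSV with columns `probe_id, chrom, pos` followed by one
#'   column per sample of beta values in \[0, 1\].
#' @param meta_path optional sample metadata TSV (as for expression).
#' @return A `methylation_table`: list with `beta` (probes x samples
#'   matrix), `probes` (data.frame `probe_id, chrom, pos`) and `meta`
#'   (data.frame or NULL).
#' @export
read_methylation_table <- function(path, meta_path = NULL) {
  df <- .read_tsv(path)
  .require_cols(df, c("probe_id", "chrom", "pos"), "methylation table")
  mat <- as.matrix(df[, setdiff(names(df), c("probe_id", "chrom", "pos")),
                      drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- df$probe_id
  if (any(is.na(mat)) || any(mat < 0) || any(mat > 1)) {
    stop("methylation table: beta values must lie in [0, 1]")
  }
  probes <- data.frame(probe_id = df$probe_id, chrom = df$chrom,
                       pos = as.integer(df$pos), stringsAsFactors = FALSE)
  meta <- if (!is.null(meta_path)) .read_tsv(meta_path) else NULL
  methylation_table(mat, probes, meta)
}

#' Construct a methylation table
#'
#' @param beta probes x samples matrix of beta values in \[0, 1\].
#' @param probes data.frame `probe_id, chrom, pos` (1-based).
#' @param meta optional sample metadata.
#' @return Object of class `methylation_table`.
#' @export
methylation_table <- function(beta, probes, meta = NULL) {
  stopifnot(is.matrix(beta), nrow(beta) == nrow(probes))
  if (any(beta < 0 | beta > 1)) stop("beta values must lie in [0, 1]")
  structure(list(beta = beta, probes = probes, meta = meta),
            class = "methylation_table")
}

#' @export
print.methylation_table <- function(x, ...) {
  cat("methylation_table:", nrow(x$beta), "probes x", ncol(x$beta),
      "samples\n")
  invisible(x)
}

#' Write a methylation table to TSV
#'
#' @param meth `methylation_table`.
#' @param path output path.
#' @export
write_methylation_table <- function(meth, path) {
  df <- data.frame(meth$probes, meth$beta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

.status_cols <- c("gene_id", "status", "ase_dev", "meth_beta",
                  "meth_category", "log2fc", "thr_ase_dev", "thr_meth_low",
                  "thr_fc_escape")

#' Write per-gene XCI status calls to TSV
#'
#' One row per gene with the final status, the evidence behind it and the
#' thresholds applied. Missing optional evidence is written as an empty
#' cell (never `0`) so the table round-trips losslessly through
#' [read_status_table()].
#'
#' @param calls non-empty data.frame of status calls (see
#'   [classify_genes()]).
#' @param path output path.
#' @export
write_status_table <- function(calls, path) {
  if (is.null(calls) || nrow(calls) == 0) stop("no status calls to write")
  .require_cols(calls, .status_cols, "status table")
  .write_tsv(calls[, .status_cols, drop = FALSE], path)
}

#' @rdname write_status_table
#' @export
read_status_table <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, .status_cols, "status table")
  for (cc in c("ase_dev", "meth_beta", "log2fc", "thr_ase_dev",
               "thr_meth_low", "thr_fc_escape")) {
    df[[cc]][df[[cc]] == ""] <- NA
    df[[cc]] <- as.numeric(df[[cc]])
  }
  df$meth_category[is.na(df$meth_category)] <- NA_character_
  df[, .status_cols, drop = FALSE]
}
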