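# Shared fixture builders: everything is generated in code, no data files.

# Build a bulk allelic-site table from parallel vectors.
make_sites <- function(rna_ref, rna_alt, dna_ref = 40, dna_alt = 40,
                       gene_id = "G1", pos = NULL, sample_id = "F1_ETP",
                       cell_type = "ETP", chrom = "chrX") {
  n <- length(rna_ref)
  data.frame(
    sample_id = rep_len(sample_id, n), cell_type = rep_len(cell_type, n),
    gene_id = rep_len(gene_id, n), chrom = rep_len(chrom, n),
    pos = if (is.null(pos)) seq(100L, by = 100L, length.out = n)
          else rep_len(pos, n),
    ref_allele = "A", alt_allele = "G",
    rna_ref = rna_ref, rna_alt = rna_alt,
    dna_ref = rep_len(dna_ref, n), dna_alt = rep_len(dna_alt, n),
    stringsAsFactors = FALSE)
}

# Single-cell allelic rows.
make_sc_counts <- function(cell_id, gene_id, rna_ref, rna_alt,
                           pos = NULL, cell_type = "DPearly") {
  n <- max(length(cell_id), length(gene_id), length(rna_ref))
  g <- rep_len(gene_id, n)
  data.frame(cell_id = rep_len(cell_id, n),
             cell_type = rep_len(cell_type, n),
             gene_id = g, chrom = "chrX",
             pos = if (is.null(pos)) 1000L + 17L * match(g, unique(g))
                   else rep_len(pos, n),
             ref_allele = "A", alt_allele = "G",
             rna_ref = rep_len(rna_ref, n), rna_alt = rep_len(rna_alt, n),
             stringsAsFactors = FALSE)
}

# Minimal gene annotation.
make_annotation <- function(gene_id, chrom = "chrX", tss = NULL,
                            strand = "+", prior_status = "unknown",
                            immune_flag = FALSE) {
  n <- length(gene_id)
  df <- data.frame(gene_id = gene_id, chrom = rep_len(chrom, n),
                   tss = if (is.null(tss)) seq(5e6, by = 1e6,
                                               length.out = n)
                         else rep_len(tss, n),
                   strand = rep_len(strand, n),
                   prior_status = rep_len(prior_status, n),
                   immune_flag = rep_len(immune_flag, n),
                   stringsAsFactors = FALSE)
  df$region <- classify_region(df$chrom, df$tss)
  df[, c("gene_id", "chrom", "tss", "strand", "region", "prior_status",
         "immune_flag")]
}

# Expression table from per-sex value matrices (genes x samples).
make_expression <- function(f_mat, m_mat, genes = NULL) {
  f_mat <- as.matrix(f_mat); m_mat <- as.matrix(m_mat)
  if (is.null(genes)) genes <- sprintf("G%d", seq_len(nrow(f_mat)))
  tpm <- cbind(f_mat, m_mat)
  rownames(tpm) <- genes
  colnames(tpm) <- c(sprintf("F%d_S", seq_len(ncol(f_mat))),
                     sprintf("M%d_S", seq_len(ncol(m_mat))))
  meta <- data.frame(
    sample_id = colnames(tpm),
    sex = c(rep("F", ncol(f_mat)), rep("M", ncol(m_mat))),
    karyotype = c(rep("XX", ncol(f_mat)), rep("XY", ncol(m_mat))),
    cell_type = "S",
    individual = sub("_S$", "", colnames(tpm)),
    stringsAsFactors = FALSE)
  expression_table(tpm, meta)
}

# Independent brute-force reimplementation of the printed site filters,
# deliberately written as a plain per-row rule walk.
brute_force_filter <- function(sites, mode, maf_source = "dna") {
  keep <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    r <- sites[i, ]
    rna_total <- r$rna_ref + r$rna_alt
    dna_total <- r$dna_ref + r$dna_alt
    if (mode == "minor_allele") {
      keep[i] <- rna_total >= 10 && dna_total > 20
    } else {
      depth_ok <- r$dna_ref >= 20 && r$dna_alt >= 20
      dna_maf_ok <- dna_total > 0 &&
        min(r$dna_ref, r$dna_alt) / dna_total >= 0.10
      maf_ok <- dna_maf_ok
      if (maf_source == "either") {
        rna_maf_ok <- rna_total > 0 &&
          min(r$rna_ref, r$rna_alt) / rna_total >= 0.10
        maf_ok <- dna_maf_ok || rna_maf_ok
      }
      keep[i] <- depth_ok && maf_ok && rna_total >= 10
    }
  }
  sites[keep, , drop = FALSE]
}

# Independent transcription of the status decision rules (defaults only).
expected_status <- function(ase_dev, meth_beta, log2fc) {
  if (!is.na(ase_dev)) {
    if (ase_dev <= 0.4) return("escape_ASE") else return("inactive_ASE")
  }
  if (is.na(meth_beta) || is.na(log2fc)) return("unclassified")
  if (meth_beta < 0.25) {
    if (log2fc > 0.2) return("escape_high")
    if (log2fc > 0) return("escape_low")
    return("unclassified")
  }
  if (log2fc < 0.2) return("inactive")
  "unclassified"
}
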