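# Filtering and scoring of allele-specific expression at heterozygous
# SNPs, and the ASE-based escape/inactive call per gene.

#' Filter heterozygous SNP sites for ASE analysis
#'
#' Two filter regimes are supported. `strict` (used for XCI status calls)
#' keeps sites with WES depth >= 20 reads *per allele*, a WES minor-allele
#' fraction >= 10%, and RNA total depth >= 10. `minor_allele` (used for
#' Xi leakiness read-counting, where more sites are wanted) keeps sites
#' with RNA total >= 10 and WES total > 20.
#'
#' @param sites data.frame of allelic sites (bulk schema, see
#'   [read_allelic_counts()]).
#' @param mode `"strict"` or `"minor_allele"`.
#' @param maf_source for strict mode, where the 10% minor-allele fraction
#'   is evaluated: `"dna"` (WES only, the default) or `"either"` (passes
#'   if RNA or WES reaches 10%).
#' @return The surviving subset of `sites`, input order preserved.
#'   Filtering is idempotent.
#' @export
filter_ase_sites <- function(sites, mode = c("strict", "minor_allele"),
                             maf_source = c("dna", "either")) {
  mode <- match.arg(mode)
  maf_source <- match.arg(maf_source)
  if (nrow(sites) == 0) return(sites)
  rna_tot <- sites$rna_ref + sites$rna_alt
  dna_tot <- sites$dna_ref + sites$dna_alt
  if (mode == "minor_allele") {
    keep <- rna_tot >= 10 & dna_tot > 20
  } else {
    dna_maf <- ifelse(dna_tot > 0,
                      pmin(sites$dna_ref, sites$dna_alt) / dna_tot, 0)
    maf_ok <- dna_maf >= 0.10
    if (maf_source == "either") {
      rna_maf <- ifelse(rna_tot > 0,
                        pmin(sites$rna_ref, sites$rna_alt) / rna_tot, 0)
      maf_ok <- maf_ok | rna_maf >= 0.10
    }
    keep <- sites$dna_ref >= 20 & sites$dna_alt >= 20 & maf_ok &
      rna_tot >= 10
  }
  sites[keep, , drop = FALSE]
}

#' Select the single reporting site per gene
#'
#' When a gene carries several surviving heterozygous SNPs in one sample
#' and cell type, only the site with the highest RNA read count is used;
#' ties break to the smallest genomic position.
#'
#' @param sites allelic sites of *one* gene in one sample/cell type.
#' @return The selected single-row data.frame, or `NULL` when `sites` is
#'   empty (no call possible).
#' @export
select_gene_site <- function(sites) {
  if (is.null(sites) || nrow(sites) == 0) return(NULL)
  tot <- sites$rna_ref + sites$rna_alt
  cand <- which(tot == max(tot))
  pick <- cand[which.min(sites$pos[cand])]
  sites[pick, , drop = FALSE]
}

#' Apply per-gene site selection across a whole site table
#'
#' Groups `sites` by (sample_id, cell_type, gene_id) and keeps the
#' highest-RNA-count site of each group (ties to smallest position).
#'
#' @param sites filtered allelic sites (bulk schema).
#' @return One row per (sample, cell type, gene), with columns `rr`
#'   (reference ratio) and `dev` (|rr - 0.5|) appended.
#' @export
select_sites <- function(sites) {
  if (nrow(sites) == 0) {
    sites$rr <- numeric(0); sites$dev <- numeric(0)
    return(sites)
  }
  key <- paste(sites$sample_id, sites$cell_type, sites$gene_id, sep = "\r")
  tot <- sites$rna_ref + sites$rna_alt
  # order so the preferred site comes first within each group
  o <- order(key, -tot, sites$pos)
  sel <- sites[o, , drop = FALSE][!duplicated(key[o]), , drop = FALSE]
  tot <- sel$rna_ref + sel$rna_alt
  sel$rr <- ifelse(tot > 0, sel$rna_ref / tot, NA_real_)
  sel$dev <- abs(sel$rr - 0.5)
  rownames(sel) <- NULL
  sel
}

#' Score per-gene allelic expression across cell types
#'
#' For each gene, the reference ratio RR = rna_ref / (rna_ref + rna_alt)
#' of its selected site is computed per cell type; the deviation
#' D = |RR - 0.5| is averaged over the cell types with a surviving site.
#' A gene is called `inactive` when its mean deviation exceeds
#' `dev_threshold` (consistent monoallelic expression) and `escape`
#' otherwise; genes with no surviving site are `no_call`.
#'
#' @param selected one-site-per-(sample, cell type, gene) table, as from
#'   [select_sites()]; normally restricted to a single donor.
#' @param dev_threshold mean-deviation boundary, default 0.4; a mean of
#'   exactly 0.4 is called escape.
#' @return data.frame with one row per gene: `gene_id, n_cell_types,
#'   mean_rr, mean_dev, ase_status`. The per-cell-type detail is attached
#'   as attribute `"detail"`.
#' @export
ase_score <- function(selected, dev_threshold = 0.4) {
  if (nrow(selected) == 0) {
    out <- data.frame(gene_id = character(0), n_cell_types = integer(0),
                      mean_rr = numeric(0), mean_dev = numeric(0),
                      ase_status = character(0), stringsAsFactors = FALSE)
    attr(out, "detail") <- selected
    return(out)
  }
  sp <- split(seq_len(nrow(selected)), selected$gene_id)
  out <- data.frame(
    gene_id = names(sp),
    n_cell_types = vapply(sp, length, integer(1)),
    mean_rr = vapply(sp, function(i) mean(selected$rr[i]), numeric(1)),
    mean_dev = vapply(sp, function(i) mean(selected$dev[i]), numeric(1)),
    stringsAsFactors = FALSE)
  out$ase_status <- ifelse(out$mean_dev > dev_threshold, "inactive",
                           "escape")
  rownames(out) <- NULL
  attr(out, "detail") <- selected
  out
}

#' Summarize minor-allele read counts over a gene set
#'
#' The minor allele of a site is the one with fewer reads. Totals are
#' aggregated per cell type over the chosen gene set (`inactive`: genes
#' with prior status inactive; `immune`: immune-flagged genes), giving the
#' Xi leakiness readout: total reads, minor reads and the minor fraction.
#'
#' @param sites allelic sites already filtered in `minor_allele` mode.
#' @param annotation gene annotation data.frame.
#' @param gene_set `"inactive"` or `"immune"`.
#' @return list with `per_cell_type` (cell_type, n_sites, total_reads,
#'   minor_reads, minor_fraction) and `per_gene` (gene_id, total_reads,
#'   minor_reads).
#' @export
minor_allele_summary <- function(sites, annotation,
                                 gene_set = c("inactive", "immune")) {
  gene_set <- match.arg(gene_set)
  keep_genes <- if (gene_set == "inactive") {
    annotation$gene_id[annotation$prior_status == "inactive"]
  } else {
    annotation$gene_id[annotation$immune_flag]
  }
  s <- sites[sites$gene_id %in% keep_genes, , drop = FALSE]
  if (nrow(s) == 0) {
    return(list(
      per_cell_type = data.frame(cell_type = character(0),
                                 n_sites = integer(0),
                                 total_reads = integer(0),
                                 minor_reads = integer(0),
                                 minor_fraction = numeric(0),
                                 stringsAsFactors = FALSE),
      per_gene = data.frame(gene_id = character(0), total_reads = integer(0),
                            minor_reads = integer(0),
                            stringsAsFactors = FALSE)))
  }
  s$total <- s$rna_ref + s$rna_alt
  s$minor <- pmin(s$rna_ref, s$rna_alt)
  agg <- function(by) {
    tot <- tapply(s$total, by, sum)
    mnr <- tapply(s$minor, by, sum)
    n <- tapply(s$total, by, length)
    data.frame(key = names(tot), n_sites = as.integer(n),
               total_reads = as.integer(tot), minor_reads = as.integer(mnr),
               stringsAsFactors = FALSE)
  }
  pct <- agg(s$cell_type)
  names(pct)[1] <- "cell_type"
  pct$minor_fraction <- ifelse(pct$total_reads > 0,
                               pct$minor_reads / pct$total_reads, NA_real_)
  pg <- agg(s$gene_id)[, c("key", "total_reads", "minor_reads")]
  names(pg)[1] <- "gene_id"
  list(per_cell_type = pct, per_gene = pg)
}
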