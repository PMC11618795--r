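# Inference of each cell's inactive-X haplotype from single-cell allelic
# counts: XIST seeding, anchor-gene discovery, propagation to XIST-negative
# cells, and per-SNP escape calls per cluster.

#' Filter cells on QC metrics
#'
#' Keeps cells with mitochondrial fraction <= 0.10, ribosomal fraction
#' <= 0.20 and total reads between 125,000 and 1,000,000.
#'
#' @param counts single-cell allelic counts (single-cell schema).
#' @param qc data.frame `cell_id, total_reads, mito_fraction,
#'   ribo_fraction`.
#' @param mito_max,ribo_max,reads_min,reads_max cut-offs.
#' @return list with `counts` and `qc` restricted to passing cells, and
#'   `removed` (cell ids that failed).
#' @export
qc_filter_cells <- function(counts, qc, mito_max = 0.10, ribo_max = 0.20,
                            reads_min = 125000, reads_max = 1e6) {
  pass <- qc$mito_fraction <= mito_max & qc$ribo_fraction <= ribo_max &
    qc$total_reads >= reads_min & qc$total_reads <= reads_max
  keep <- qc$cell_id[pass]
  list(counts = counts[counts$cell_id %in% keep, , drop = FALSE],
       qc = qc[pass, , drop = FALSE],
       removed = qc$cell_id[!pass])
}

#' Assign cells to Xi clusters from XIST allelic reads
#'
#' XIST is expressed only from the inactive X, so a cell's XIST allele
#' identifies its Xi haplotype. Cells whose XIST reads are exclusively the
#' reference allele form cluster 1; exclusively alternative, cluster 2
#' (the numbering convention is fixed here: cluster 1 = XIST reference
#' allele). Cells with both alleles detected are left unassigned with
#' basis `"conflict"` (doublets or index hopping are likelier than truly
#' biallelic XIST); cells without XIST reads are unassigned.
#'
#' @param counts single-cell allelic counts.
#' @param xist_gene gene identifier of XIST in the count table.
#' @param min_reads minimum reads to count an allele as detected,
#'   default 1.
#' @return data.frame `cell_id, cluster, basis` over all cells in
#'   `counts`; `cluster` in \{1, 2, NA\}. Warns when the XIST SNP is
#'   absent altogether.
#' @export
assign_by_xist <- function(counts, xist_gene = "XIST", min_reads = 1) {
  cells <- unique(counts$cell_id)
  out <- data.frame(cell_id = cells, cluster = NA_integer_,
                    basis = NA_character_, stringsAsFactors = FALSE)
  x <- counts[counts$gene_id == xist_gene, , drop = FALSE]
  if (nrow(x) == 0) {
    warning("no XIST allelic reads found; all cells unassigned")
    return(out)
  }
  ref <- tapply(x$rna_ref, x$cell_id, sum)
  alt <- tapply(x$rna_alt, x$cell_id, sum)
  for (cid in names(ref)) {
    i <- match(cid, out$cell_id)
    has_ref <- ref[[cid]] >= min_reads
    has_alt <- alt[[cid]] >= min_reads
    if (has_ref && has_alt) {
      out$basis[i] <- "conflict"
    } else if (has_ref) {
      out$cluster[i] <- 1L; out$basis[i] <- "XIST"
    } else if (has_alt) {
      out$cluster[i] <- 2L; out$basis[i] <- "XIST"
    }
  }
  out
}

#' Discover anchor genes from XIST-assigned cells
#'
#' An anchor is an inactive gene whose allelic expression separates the
#' two Xi clusters: within each cluster, every expressing XIST-assigned
#' cell shows the same single allele, the two clusters' alleles are
#' opposite, and each cluster has at least `min_cells` expressing cells.
#' Anchors let cells without XIST reads be assigned (see
#' [propagate_clusters()]).
#'
#' @param counts single-cell allelic counts.
#' @param assignment output of [assign_by_xist()].
#' @param candidates gene identifiers to consider (normally
#'   prior-inactive genes). A named preset of the seven anchors used in
#'   thymocytes is available as [anchor_gene_preset()].
#' @param min_cells minimum expressing XIST-assigned cells per cluster,
#'   default 3.
#' @param min_reads minimum reads to count an allele as detected.
#' @return data.frame `gene_id, allele_cluster1, allele_cluster2` (values
#'   `"ref"`/`"alt"`); zero rows when no gene qualifies.
#' @export
find_anchor_genes <- function(counts, assignment, candidates,
                              min_cells = 3, min_reads = 1) {
  res <- list()
  for (g in unique(candidates)) {
    sub <- counts[counts$gene_id == g, , drop = FALSE]
    sub_cl <- assignment$cluster[match(sub$cell_id, assignment$cell_id)]
    sub <- sub[!is.na(sub_cl), , drop = FALSE]
    sub_cl <- sub_cl[!is.na(sub_cl)]
    if (nrow(sub) == 0) next
    allele_of <- function(k) {
      s <- sub[sub_cl == k, , drop = FALSE]
      ref <- tapply(s$rna_ref, s$cell_id, sum)
      alt <- tapply(s$rna_alt, s$cell_id, sum)
      has_ref <- ref >= min_reads
      has_alt <- alt >= min_reads
      expressing <- has_ref | has_alt
      if (sum(expressing) < min_cells) return(NA_character_)
      if (any(has_ref & has_alt)) return(NA_character_)  # biallelic cell
      if (all(has_ref[expressing]) && !any(has_alt[expressing])) return("ref")
      if (all(has_alt[expressing]) && !any(has_ref[expressing])) return("alt")
      NA_character_  # mixed alleles across cells within the cluster
    }
    a1 <- allele_of(1L); a2 <- allele_of(2L)
    if (!is.na(a1) && !is.na(a2) && a1 != a2) {
      res[[g]] <- data.frame(gene_id = g, allele_cluster1 = a1,
                             allele_cluster2 = a2, stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(gene_id = character(0),
                      allele_cluster1 = character(0),
                      allele_cluster2 = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' The seven anchor genes used for thymocyte Xi clustering
#'
#' Inactive X-linked genes with consistent monoallelic expression per
#' cluster, usable to seed [propagate_clusters()] when anchor discovery is
#' not wanted.
#'
#' @return Character vector of gene symbols.
#' @export
anchor_gene_preset <- function() {
  c("ATRX", "BEX4", "ITM2A", "LAMP2", "MORF4L2", "PIN4", "TMSB4X")
}

#' Propagate cluster assignments to XIST-negative cells via anchors
#'
#' Each still-unassigned cell votes once per expressed anchor gene: the
#' allele it expresses maps to that anchor's cluster. A strict majority
#' assigns the cell (basis records the deciding anchors); ties or zero
#' votes leave it unassigned (`basis = "conflict"` on a tie).
#'
#' @param counts single-cell allelic counts.
#' @param assignment output of [assign_by_xist()].
#' @param anchors output of [find_anchor_genes()].
#' @param min_reads minimum reads to count an allele as detected.
#' @return Updated assignment data.frame.
#' @export
propagate_clusters <- function(counts, assignment, anchors, min_reads = 1) {
  if (nrow(anchors) == 0) return(assignment)
  out <- assignment
  todo <- out$cell_id[is.na(out$cluster) &
                        (is.na(out$basis) | out$basis != "conflict")]
  sub <- counts[counts$gene_id %in% anchors$gene_id &
                  counts$cell_id %in% todo, , drop = FALSE]
  if (nrow(sub) == 0) return(out)
  for (cid in unique(sub$cell_id)) {
    s <- sub[sub$cell_id == cid, , drop = FALSE]
    votes <- integer(0); used <- character(0)
    for (g in unique(s$gene_id)) {
      sg <- s[s$gene_id == g, , drop = FALSE]
      ref <- sum(sg$rna_ref); alt <- sum(sg$rna_alt)
      has_ref <- ref >= min_reads; has_alt <- alt >= min_reads
      if (has_ref == has_alt) next  # biallelic or undetected: no vote
      allele <- if (has_ref) "ref" else "alt"
      a <- anchors[anchors$gene_id == g, ]
      v <- if (allele == a$allele_cluster1) 1L
      else if (allele == a$allele_cluster2) 2L else NA_integer_
      if (!is.na(v)) { votes <- c(votes, v); used <- c(used, g) }
    }
    if (!length(votes)) next
    i <- match(cid, out$cell_id)
    n1 <- sum(votes == 1L); n2 <- sum(votes == 2L)
    if (n1 == n2) {
      out$basis[i] <- "conflict"
    } else {
      out$cluster[i] <- if (n1 > n2) 1L else 2L
      out$basis[i] <- paste0("anchor:",
                             paste(sort(unique(used[votes ==
                                                      out$cluster[i]])),
                                   collapse = "+"))
    }
  }
  out
}

#' Call per-SNP escape status within each Xi cluster
#'
#' For every heterozygous SNP and cluster, the mean per-cell reference
#' ratio (unweighted over cells with at least one read) is computed. SNPs
#' detected in at most one cell of a cluster get `no_call` there;
#' otherwise the SNP escapes XCI in that cluster when the mean RR lies in
#' `rr_window` (both alleles are seen, within cells or across cells of the
#' cluster) and is inactive otherwise. `concordant` compares the two
#' clusters' statuses (`NA` when either is no_call).
#'
#' @param counts single-cell allelic counts (XIST excluded automatically).
#' @param assignment cluster assignment data.frame.
#' @param rr_window escape window on mean RR, default `c(0.1, 0.9)`.
#' @param min_cells minimum detected cells per cluster for a call,
#'   default 2 ("more than one cell").
#' @param xist_gene gene to exclude from escape calling.
#' @return data.frame `gene_id, pos, mean_rr_1, n_cells_1, status_1,
#'   mean_rr_2, n_cells_2, status_2, concordant`.
#' @export
call_snp_escape <- function(counts, assignment, rr_window = c(0.1, 0.9),
                            min_cells = 2, xist_gene = "XIST") {
  cl <- assignment$cluster[match(counts$cell_id, assignment$cell_id)]
  sub <- counts[!is.na(cl) & counts$gene_id != xist_gene, , drop = FALSE]
  cl <- cl[!is.na(cl) & counts$gene_id != xist_gene]
  tot <- sub$rna_ref + sub$rna_alt
  sub <- sub[tot > 0, , drop = FALSE]
  cl <- cl[tot > 0]
  key <- paste(sub$gene_id, sub$pos, sep = "\r")
  snps <- unique(data.frame(gene_id = sub$gene_id, pos = sub$pos, key = key,
                            stringsAsFactors = FALSE))
  rr <- sub$rna_ref / (sub$rna_ref + sub$rna_alt)
  stat_one <- function(k, clu) {
    i <- key == k & cl == clu
    n <- sum(i)
    if (n < min_cells) {
      return(list(mean_rr = if (n > 0) mean(rr[i]) else NA_real_,
                  n = n, status = "no_call"))
    }
    m <- mean(rr[i])
    list(mean_rr = m, n = n,
         status = if (m >= rr_window[1] && m <= rr_window[2]) "escape"
                  else "inactive")
  }
  rows <- lapply(snps$key, function(k) {
    s1 <- stat_one(k, 1L); s2 <- stat_one(k, 2L)
    conc <- if (s1$status == "no_call" || s2$status == "no_call")
      NA else s1$status == s2$status
    data.frame(gene_id = snps$gene_id[snps$key == k][1],
               pos = snps$pos[snps$key == k][1],
               mean_rr_1 = s1$mean_rr, n_cells_1 = s1$n,
               status_1 = s1$status,
               mean_rr_2 = s2$mean_rr, n_cells_2 = s2$n,
               status_2 = s2$status, concordant = conc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Infer the Xi allele of every SNP per cluster
#'
#' For inactive genes, the expressed (majority) allele within a cluster is
#' the Xa allele, so the Xi allele is its opposite. Used when ground-truth
#' phase is unavailable.
#'
#' @param counts single-cell allelic counts.
#' @param assignment cluster assignment data.frame.
#' @param genes gene set to consider (normally inactive genes).
#' @return data.frame `gene_id, pos, cluster, xi_allele` ("ref"/"alt").
#' @export
infer_xi_alleles <- function(counts, assignment, genes) {
  cl <- assignment$cluster[match(counts$cell_id, assignment$cell_id)]
  sub <- counts[!is.na(cl) & counts$gene_id %in% genes, , drop = FALSE]
  cl <- cl[!is.na(cl) & counts$gene_id %in% genes]
  if (nrow(sub) == 0) {
    return(data.frame(gene_id = character(0), pos = integer(0),
                      cluster = integer(0), xi_allele = character(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(sub$gene_id, sub$pos, cl, sep = "\r")
  ref <- tapply(sub$rna_ref, key, sum)
  alt <- tapply(sub$rna_alt, key, sum)
  parts <- do.call(rbind, strsplit(names(ref), "\r", fixed = TRUE))
  data.frame(gene_id = parts[, 1], pos = as.integer(parts[, 2]),
             cluster = as.integer(parts[, 3]),
             xi_allele = ifelse(ref >= alt, "alt", "ref"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Histogram of Xi-origin reads per cell at inactive genes
#'
#' Sums, per assigned cell, the reads matching the inactive-X allele
#' across inactive-gene SNPs and buckets cells into 0 / 1 / >= 2 Xi
#' reads — the readout of XCI maintenance fidelity at single-cell level.
#'
#' @param counts single-cell allelic counts.
#' @param assignment cluster assignment data.frame.
#' @param xi_alleles per-SNP per-cluster Xi alleles, from
#'   [infer_xi_alleles()] or ground truth; columns `gene_id, pos, cluster,
#'   xi_allele`.
#' @return list with `histogram` (named counts for "0", "1", ">=2"),
#'   `per_cell` (cell_id, xi_reads) and `n_unassigned` (cells excluded).
#' @export
xi_read_histogram <- function(counts, assignment, xi_alleles) {
  cl <- assignment$cluster[match(counts$cell_id, assignment$cell_id)]
  assigned_cells <- assignment$cell_id[!is.na(assignment$cluster)]
  n_unassigned <- sum(is.na(assignment$cluster))
  sub <- counts[!is.na(cl), , drop = FALSE]
  clv <- cl[!is.na(cl)]
  key <- paste(sub$gene_id, sub$pos, clv, sep = "\r")
  akey <- paste(xi_alleles$gene_id, xi_alleles$pos, xi_alleles$cluster,
                sep = "\r")
  xa <- xi_alleles$xi_allele[match(key, akey)]
  known <- !is.na(xa)
  xi_reads <- ifelse(xa[known] == "ref", sub$rna_ref[known],
                     sub$rna_alt[known])
  per_cell_sum <- tapply(xi_reads, sub$cell_id[known], sum)
  per_cell <- data.frame(cell_id = assigned_cells,
                         xi_reads = 0, stringsAsFactors = FALSE)
  hit <- match(names(per_cell_sum), per_cell$cell_id)
  per_cell$xi_reads[hit[!is.na(hit)]] <-
    as.numeric(per_cell_sum)[!is.na(hit)]
  b <- cut(per_cell$xi_reads, c(-Inf, 0.5, 1.5, Inf),
           labels = c("0", "1", ">=2"))
  hist <- table(b)
  list(histogram = stats::setNames(as.integer(hist), names(hist)),
       per_cell = per_cell, n_unassigned = n_unassigned)
}
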