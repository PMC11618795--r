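# Synthetic cohort generator with known XCI ground truth. Emulates the
# study design: several female and male donors, six thymocyte subtypes,
# bulk RNA/WES allelic counts at heterozygous SNPs, a TPM matrix, promoter
# methylation beta values, and Smart-seq2-like single-cell allelic counts.

#' Build a simulation configuration
#'
#' Defaults describe the emulated study conditions: 4 female + 3 male
#' donors across six thymocyte subtypes; ~19% of X-linked genes escaping
#' XCI with an Xi/Xa expression ratio giving female-biased log2FC around
#' 0.4; the focal female completely skewed (cXCI) and the single-cell donor
#' unskewed. Allelic RNA counts are beta-binomial (intraclass correlation
#' `overdispersion`) with a per-read allele miscall rate `seq_error`; WES
#' counts are binomial 50:50 at fixed depth.
#'
#' @param n_genes named counts of simulated genes per class
#'   (`PAR`, `escape`, `inactive`, `autosome`).
#' @param n_females,n_males,n_x0 donor counts per karyotype (XX, XY, X0).
#' @param cell_types character vector of cell types (samples are donor x
#'   cell type).
#' @param skewing XCI skewing of the focal (first) female: fraction of her
#'   cells with parental haplotype 1 active, in \[0.5, 1\]; 1 = cXCI.
#'   Remaining females are unskewed (0.5).
#' @param sc_skewing skewing of the single-cell donor, in \[0.5, 1\].
#' @param xi_ratio Xi/Xa expression ratio of escape genes (>= 0).
#' @param leak_fraction fraction of cells reactivating a nominally inactive
#'   gene, in \[0, 1\].
#' @param leak_ratio Xi/Xa ratio within such leaky cells (>= 0).
#' @param rna_depth mean RNA read depth per heterozygous site.
#' @param dna_depth WES read depth per site (fixed).
#' @param overdispersion beta-binomial intraclass correlation of RNA
#'   allelic counts, in \[0, 1).
#' @param seq_error per-read probability that a read reports the wrong
#'   allele, in \[0, 0.5).
#' @param het_rate probability that a donor is heterozygous at a candidate
#'   site.
#' @param sites_per_gene candidate heterozygous SNPs per gene.
#' @param expr_meanlog,expr_sdlog log-normal distribution of per-gene base
#'   expression (TPM scale).
#' @param noise_sdlog log-scale biological + technical noise between
#'   samples.
#' @param meth_params named list of `c(shape1, shape2)` Beta parameters for
#'   promoter-probe beta values per gene class.
#' @param probes_per_gene promoter probes per gene, placed within 500 bp
#'   upstream of the TSS.
#' @param n_cells total single cells (split evenly over `cell_types`).
#' @param sc_depth mean reads per expressed site per cell.
#' @param sc_expr_rate probability a cell expresses a given site.
#' @param xist_detect_rate probability a cell yields XIST allelic reads.
#' @param qc_fail_fraction fraction of cells simulated to fail QC.
#' @param seed master seed; identical seed gives identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = c(PAR = 10, escape = 30, inactive = 120,
                                   autosome = 100),
                       n_females = 4, n_males = 3, n_x0 = 0,
                       cell_types = c("ETP", "T-C", "DPearly", "DPlate",
                                      "CD4SP", "CD8SP"),
                       skewing = 1, sc_skewing = 0.5,
                       xi_ratio = 0.33,
                       leak_fraction = 0, leak_ratio = 1,
                       rna_depth = 60, dna_depth = 80,
                       overdispersion = 0.01, seq_error = 0.002,
                       het_rate = 0.2, sites_per_gene = 2,
                       expr_meanlog = log(50), expr_sdlog = 1,
                       noise_sdlog = 0.25,
                       meth_params = list(PAR = c(2, 30),
                                          escape = c(2, 30),
                                          inactive = c(20, 20),
                                          autosome = c(2, 30)),
                       probes_per_gene = 3,
                       n_cells = 480, sc_depth = 5, sc_expr_rate = 0.5,
                       xist_detect_rate = 0.3, qc_fail_fraction = 0.1,
                       seed = 1L) {
  cfg <- as.list(environment())
  .validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

.validate_sim_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid sim_config: ", msg)
  chk(all(c("PAR", "escape", "inactive", "autosome") %in% names(cfg$n_genes)),
      "n_genes must name PAR, escape, inactive, autosome")
  chk(all(cfg$n_genes >= 0), "gene counts must be >= 0")
  chk(cfg$skewing >= 0.5 && cfg$skewing <= 1, "skewing must be in [0.5, 1]")
  chk(cfg$sc_skewing >= 0.5 && cfg$sc_skewing <= 1,
      "sc_skewing must be in [0.5, 1]")
  chk(cfg$xi_ratio >= 0, "xi_ratio must be >= 0")
  chk(cfg$leak_fraction >= 0 && cfg$leak_fraction <= 1,
      "leak_fraction must be in [0, 1]")
  chk(cfg$leak_ratio >= 0, "leak_ratio must be >= 0")
  chk(cfg$overdispersion >= 0 && cfg$overdispersion < 1,
      "overdispersion must be in [0, 1)")
  chk(cfg$seq_error >= 0 && cfg$seq_error < 0.5,
      "seq_error must be in [0, 0.5)")
  chk(cfg$het_rate >= 0 && cfg$het_rate <= 1, "het_rate must be in [0, 1]")
  chk(cfg$rna_depth > 0 && cfg$dna_depth > 0, "depths must be positive")
  chk(cfg$qc_fail_fraction >= 0 && cfg$qc_fail_fraction < 1,
      "qc_fail_fraction must be in [0, 1)")
  chk(cfg$n_cells >= 0, "n_cells must be >= 0")
  invisible(TRUE)
}

# Beta-binomial sampler: n trials, mean p, intraclass correlation rho.
.rbetabinom <- function(size, p, rho) {
  n <- length(size)
  p <- rep_len(p, n)
  q <- p
  vary <- rho > 0 & p > 0 & p < 1
  if (any(vary)) {
    conc <- (1 - rho) / rho
    q[vary] <- stats::rbeta(sum(vary), p[vary] * conc, (1 - p[vary]) * conc)
  }
  stats::rbinom(n, size, q)
}

# Expected reference-read fraction at a het site of a female donor.
# pi_a = fraction of cells in which the haplotype carrying REF is active;
# xi expression ratio r applies in all cells (escape) or, for inactive
# genes, as f * leak_ratio in expectation over leak cells.
.expected_ref_fraction <- function(pi_a, r) {
  (pi_a + (1 - pi_a) * r) / (1 + r)
}

.gene_table <- function(cfg) {
  par_iv <- par_intervals_hg38()
  classes <- rep(c("PAR", "escape", "inactive", "autosome"),
                 times = cfg$n_genes[c("PAR", "escape", "inactive",
                                       "autosome")])
  n <- length(classes)
  ids <- sprintf("G%03d_%s", seq_len(n), classes)
  chrom <- ifelse(classes == "autosome", "chr1", "chrX")
  tss <- integer(n)
  is_par <- classes == "PAR"
  tss[is_par] <- as.integer(round(seq(par_iv$PAR1[1] + 5e4,
                                      par_iv$PAR1[2] - 5e4,
                                      length.out = max(sum(is_par), 1))))[seq_len(sum(is_par))]
  is_npx <- classes %in% c("escape", "inactive")
  tss[is_npx] <- as.integer(round(seq(3e6, 1.55e8,
                                      length.out = max(sum(is_npx), 1))))[seq_len(sum(is_npx))]
  is_auto <- classes == "autosome"
  tss[is_auto] <- as.integer(round(seq(1e6, 2.4e8,
                                       length.out = max(sum(is_auto), 1))))[seq_len(sum(is_auto))]
  strand <- rep(c("+", "-"), length.out = n)
  prior <- ifelse(classes == "PAR", "escape",
           ifelse(classes == "autosome", "unknown", classes))
  data.frame(gene_id = ids, class = classes, chrom = chrom, tss = tss,
             strand = strand,
             region = classify_region(chrom, tss, par_iv),
             prior_status = prior,
             immune_flag = FALSE, stringsAsFactors = FALSE)
}

#' Simulate a full bulk cohort with known XCI ground truth
#'
#' Generates (i) a gene annotation, (ii) a TPM expression matrix over all
#' donors and cell types, (iii) bulk allelic counts (RNA + WES) at
#' heterozygous sites of diploid-X donors, (iv) promoter methylation beta
#' values for the female donors, and (v) the ground truth behind all of it.
#'
#' Expression dosage: X-linked non-PAR genes are expressed at one unit from
#' Xa in both sexes, escape genes add `xi_ratio` units from Xi in females,
#' so the expected female/male fold change of an escape gene is
#' `log2(1 + xi_ratio)`. PAR and autosomal genes are unbiased. XY and X0
#' donors carry no heterozygous non-PAR chrX sites; X0 donors carry no chrX
#' sites at all; PAR sites are diploid in XX and XY.
#'
#' @param config a [sim_config()].
#' @return A list of class `xci_cohort` with elements `annotation`,
#'   `expression`, `sites`, `methylation`, `truth`. `truth` carries the
#'   per-gene class/status and phase, per-donor karyotype and skewing, the
#'   simulated het-site table, and the global parameters.
#' @export
simulate_cohort <- function(config) {
  .validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed)

  genes <- .gene_table(cfg)
  annotation <- genes[, c("gene_id", "chrom", "tss", "strand", "region",
                          "prior_status", "immune_flag")]
  # a handful of immune genes among the inactive class (leakiness readout)
  inact_idx <- which(genes$class == "inactive")
  if (length(inact_idx) >= 5) {
    annotation$immune_flag[inact_idx[seq_len(min(20, length(inact_idx)))]] <- TRUE
  }

  # donors -------------------------------------------------------------
  n_ind <- cfg$n_females + cfg$n_males + cfg$n_x0
  individuals <- data.frame(
    individual = c(sprintf("F%d", seq_len(cfg$n_females)),
                   sprintf("M%d", seq_len(cfg$n_males)),
                   if (cfg$n_x0 > 0) sprintf("TS%d", seq_len(cfg$n_x0))),
    sex = c(rep("F", cfg$n_females), rep("M", cfg$n_males),
            rep("F", cfg$n_x0)),
    karyotype = c(rep("XX", cfg$n_females), rep("XY", cfg$n_males),
                  rep("X0", cfg$n_x0)),
    skewing = c(if (cfg$n_females > 0) c(cfg$skewing,
                                         rep(0.5, cfg$n_females - 1)),
                rep(NA_real_, cfg$n_males + cfg$n_x0)),
    stringsAsFactors = FALSE)

  # phase: per gene x diploid-X donor, is the REF allele on haplotype 1?
  diploid_x <- individuals$karyotype == "XX"
  phase <- expand.grid(gene_id = genes$gene_id,
                       individual = individuals$individual,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  phase$ref_on_h1 <- stats::rbinom(nrow(phase), 1, 0.5) == 1

  # expression ----------------------------------------------------------
  set.seed(cfg$seed + 11L)
  base_expr <- stats::rlnorm(nrow(genes), cfg$expr_meanlog, cfg$expr_sdlog)
  samples <- expand.grid(individual = individuals$individual,
                         cell_type = cfg$cell_types,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- samples[order(match(samples$individual,
                                 individuals$individual)), ]
  samples$sample_id <- paste(samples$individual, samples$cell_type, sep = "_")
  samples$sex <- individuals$sex[match(samples$individual,
                                       individuals$individual)]
  samples$karyotype <- individuals$karyotype[match(samples$individual,
                                                   individuals$individual)]
  dosage <- matrix(1, nrow(genes), n_ind,
                   dimnames = list(genes$gene_id, individuals$individual))
  for (j in seq_len(n_ind)) {
    k <- individuals$karyotype[j]
    if (k == "XX") {
      dosage[genes$class == "escape", j] <- 1 + cfg$xi_ratio
      dosage[genes$class == "inactive", j] <-
        1 + cfg$leak_fraction * cfg$leak_ratio
    } else if (k == "X0") {
      dosage[genes$class == "PAR", j] <- 0.5
    }
  }
  tpm <- matrix(0, nrow(genes), nrow(samples),
                dimnames = list(genes$gene_id, samples$sample_id))
  for (s in seq_len(nrow(samples))) {
    j <- match(samples$individual[s], individuals$individual)
    tpm[, s] <- base_expr * dosage[, j] *
      stats::rlnorm(nrow(genes), 0, cfg$noise_sdlog)
  }
  meta <- samples[, c("sample_id", "sex", "karyotype", "cell_type",
                      "individual")]
  rownames(meta) <- NULL
  expression <- expression_table(tpm, meta)

  # bulk allelic sites ---------------------------------------------------
  set.seed(cfg$seed + 23L)
  site_tpl <- data.frame(
    gene_id = rep(genes$gene_id, each = cfg$sites_per_gene),
    class = rep(genes$class, each = cfg$sites_per_gene),
    chrom = rep(genes$chrom, each = cfg$sites_per_gene),
    pos = rep(genes$tss, each = cfg$sites_per_gene) +
      200L * seq_len(cfg$sites_per_gene),
    stringsAsFactors = FALSE)
  site_tpl$ref_allele <- rep_len(c("A", "C", "G", "T"), nrow(site_tpl))
  site_tpl$alt_allele <- rep_len(c("G", "T", "A", "C"), nrow(site_tpl))

  site_rows <- list()
  truth_sites <- list()
  for (j in seq_len(n_ind)) {
    ind <- individuals$individual[j]
    k <- individuals$karyotype[j]
    if (k == "X0") {
      eligible <- site_tpl$class == "autosome"
    } else if (k == "XY") {
      eligible <- site_tpl$class %in% c("autosome", "PAR")
    } else {
      eligible <- rep(TRUE, nrow(site_tpl))
    }
    het <- eligible & stats::rbinom(nrow(site_tpl), 1, cfg$het_rate) == 1
    if (!any(het)) next
    st <- site_tpl[het, , drop = FALSE]
    st$individual <- ind
    ph <- phase$ref_on_h1[match(paste(st$gene_id, ind),
                                paste(phase$gene_id, phase$individual))]
    st$ref_on_h1 <- ph
    # expected REF fraction before sequencing error
    if (k == "XX") {
      pi_h1 <- individuals$skewing[j]
      pi_a <- ifelse(st$ref_on_h1, pi_h1, 1 - pi_h1)
      r <- ifelse(st$class == "escape", cfg$xi_ratio,
           ifelse(st$class == "inactive",
                  cfg$leak_fraction * cfg$leak_ratio, NA))
      p_ref <- ifelse(st$class %in% c("PAR", "autosome"), 0.5,
                      .expected_ref_fraction(pi_a, r))
    } else {
      p_ref <- rep(0.5, nrow(st))
    }
    st$p_ref <- p_ref * (1 - cfg$seq_error) + (1 - p_ref) * cfg$seq_error
    truth_sites[[ind]] <- st
    # WES once per donor; RNA per cell type
    dna_ref <- stats::rbinom(nrow(st), cfg$dna_depth, 0.5)
    for (ct in cfg$cell_types) {
      tot <- stats::rpois(nrow(st), cfg$rna_depth)
      rref <- .rbetabinom(tot, st$p_ref, cfg$overdispersion)
      site_rows[[paste(ind, ct)]] <- data.frame(
        sample_id = paste(ind, ct, sep = "_"), cell_type = ct,
        gene_id = st$gene_id, chrom = st$chrom, pos = st$pos,
        ref_allele = st$ref_allele, alt_allele = st$alt_allele,
        rna_ref = rref, rna_alt = tot - rref,
        dna_ref = dna_ref, dna_alt = cfg$dna_depth - dna_ref,
        stringsAsFactors = FALSE)
    }
  }
  sites <- if (length(site_rows)) do.call(rbind, site_rows) else
    stats::setNames(data.frame(matrix(ncol = 11, nrow = 0)),
                    .bulk_count_cols)
  rownames(sites) <- NULL
  truth_sites <- if (length(truth_sites)) do.call(rbind, truth_sites) else
    NULL
  if (!is.null(truth_sites)) rownames(truth_sites) <- NULL

  # methylation (female donors) -----------------------------------------
  set.seed(cfg$seed + 37L)
  fem <- individuals$individual[individuals$karyotype == "XX"]
  meth <- NULL
  if (length(fem) > 0 && cfg$probes_per_gene > 0) {
    offs <- matrix(sample(20:480, nrow(genes) * cfg$probes_per_gene,
                          replace = TRUE),
                   nrow(genes), cfg$probes_per_gene)
    probe_pos <- ifelse(rep(genes$strand, cfg$probes_per_gene) == "+",
                        rep(genes$tss, cfg$probes_per_gene) - as.vector(offs),
                        rep(genes$tss, cfg$probes_per_gene) + as.vector(offs))
    probes <- data.frame(
      probe_id = sprintf("cg_%s_%d", rep(genes$gene_id, cfg$probes_per_gene),
                         rep(seq_len(cfg$probes_per_gene),
                             each = nrow(genes))),
      chrom = rep(genes$chrom, cfg$probes_per_gene),
      pos = as.integer(probe_pos), stringsAsFactors = FALSE)
    probe_class <- rep(genes$class, cfg$probes_per_gene)
    msam <- expand.grid(individual = fem, cell_type = cfg$cell_types,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    msam$sample_id <- paste(msam$individual, msam$cell_type, sep = "_")
    beta <- matrix(NA_real_, nrow(probes), nrow(msam),
                   dimnames = list(probes$probe_id, msam$sample_id))
    for (cl in names(cfg$meth_params)) {
      idx <- probe_class == cl
      if (!any(idx)) next
      ab <- cfg$meth_params[[cl]]
      beta[idx, ] <- stats::rbeta(sum(idx) * ncol(beta), ab[1], ab[2])
    }
    meth <- methylation_table(beta, probes,
                              msam[, c("sample_id", "individual",
                                       "cell_type")])
  }

  truth <- list(
    genes = data.frame(
      gene_id = genes$gene_id, class = genes$class,
      true_status = ifelse(genes$class %in% c("PAR", "escape"), "escape",
                    ifelse(genes$class == "inactive", "inactive",
                           NA_character_)),
      stringsAsFactors = FALSE),
    phase = phase,
    sites = truth_sites,
    individuals = individuals,
    params = list(skewing = cfg$skewing, sc_skewing = cfg$sc_skewing,
                  xi_ratio = cfg$xi_ratio,
                  leak_fraction = cfg$leak_fraction,
                  leak_ratio = cfg$leak_ratio,
                  seq_error = cfg$seq_error),
    config = cfg)

  structure(list(annotation = annotation, expression = expression,
                 sites = sites, methylation = meth, truth = truth),
            class = "xci_cohort")
}

#' @export
print.xci_cohort <- function(x, ...) {
  cat("xci_cohort:", nrow(x$annotation), "genes,",
      ncol(x$expression$tpm), "samples,",
      nrow(x$sites), "bulk allelic rows\n")
  invisible(x)
}

# hg38 position of the simulated XIST SNP (within the XIST locus)
.XIST_POS <- 73829000L

#' Simulate single-cell allelic profiles sharing the bulk phase
#'
#' Cells are drawn from the focal female donor's genotype (phase shared
#' with the bulk truth) with their own skewing `sc_skewing`: each cell
#' inactivates parental haplotype 2 with probability `sc_skewing`. Reads at
#' inactive-gene sites come only from the cell's active haplotype unless
#' the cell is a leak cell for that gene; escape and PAR sites yield reads
#' from both haplotypes; XIST reads come only from the inactive haplotype.
#' Per-read allele miscalls occur at rate `seq_error`. A fraction
#' `qc_fail_fraction` of cells is given failing QC metrics (high
#' mitochondrial or ribosomal content, or out-of-range read counts).
#'
#' Cluster convention: cluster 1 is the set of cells whose XIST (Xi) allele
#' is the reference allele.
#'
#' @param config a [sim_config()].
#' @param truth the `truth` element of a [simulate_cohort()] result built
#'   from the same config.
#' @return A list of class `sc_profiles` with `counts` (per cell per SNP
#'   allelic reads, single-cell schema), `qc` (per-cell QC metrics), and
#'   `truth_cells` (cell_id, cell_type, xi_hap, true cluster, qc_fail,
#'   per-gene leak state attribute).
#' @export
simulate_single_cells <- function(config, truth) {
  .validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed + 101L)

  if (cfg$n_cells == 0) {
    empty <- stats::setNames(data.frame(matrix(ncol = 9, nrow = 0)),
                             .sc_count_cols)
    return(structure(list(counts = empty,
                          qc = data.frame(cell_id = character(0),
                                          total_reads = numeric(0),
                                          mito_fraction = numeric(0),
                                          ribo_fraction = numeric(0)),
                          truth_cells = NULL),
                     class = "sc_profiles"))
  }

  focal <- truth$individuals$individual[truth$individuals$karyotype == "XX"][1]
  if (is.na(focal)) stop("no diploid-X donor in truth; cannot simulate cells")
  tsites <- truth$sites[truth$sites$individual == focal &
                          truth$sites$class != "autosome", , drop = FALSE]
  if (nrow(tsites) == 0) stop("focal donor has no heterozygous chrX sites")

  # XIST het site, phase drawn once; reference-on-h1 decides cluster labels
  xist_ref_on_h1 <- stats::rbinom(1, 1, 0.5) == 1

  cells <- data.frame(
    cell_id = sprintf("cell%04d", seq_len(cfg$n_cells)),
    cell_type = rep_len(cfg$cell_types, cfg$n_cells),
    stringsAsFactors = FALSE)
  # active haplotype: h1 with probability sc_skewing; Xi is the other
  h1_active <- stats::rbinom(cfg$n_cells, 1, cfg$sc_skewing) == 1
  cells$xi_hap <- ifelse(h1_active, 2L, 1L)
  xist_ref_on_xi <- ifelse(cells$xi_hap == 1L, xist_ref_on_h1,
                           !xist_ref_on_h1)
  cells$true_cluster <- ifelse(xist_ref_on_xi, 1L, 2L)
  cells$qc_fail <- stats::rbinom(cfg$n_cells, 1, cfg$qc_fail_fraction) == 1

  err_flip <- function(n_from_a, total) {
    # reads truly from allele A; each read miscalled with prob seq_error
    kept <- stats::rbinom(length(total), n_from_a, 1 - cfg$seq_error)
    gained <- stats::rbinom(length(total), total - n_from_a, cfg$seq_error)
    kept + gained
  }

  rows <- vector("list", cfg$n_cells)
  leak_flags <- vector("list", cfg$n_cells)
  inact_genes <- unique(tsites$gene_id[tsites$class == "inactive"])
  p_xi_escape <- cfg$xi_ratio / (1 + cfg$xi_ratio)
  p_xi_leak <- if (cfg$leak_ratio > 0)
    cfg$leak_ratio / (1 + cfg$leak_ratio) else 0

  for (i in seq_len(cfg$n_cells)) {
    expressed <- stats::rbinom(nrow(tsites), 1, cfg$sc_expr_rate) == 1
    tot <- stats::rpois(nrow(tsites), cfg$sc_depth) * expressed
    keep <- tot > 0
    if (!any(keep)) { rows[[i]] <- NULL; next }
    st <- tsites[keep, , drop = FALSE]
    tot <- tot[keep]
    active_h1 <- h1_active[i]
    leak_gene <- inact_genes[stats::rbinom(length(inact_genes), 1,
                                           cfg$leak_fraction) == 1]
    leak_flags[[i]] <- leak_gene
    # probability a read originates from the Xi copy
    p_xi <- ifelse(st$class == "escape", p_xi_escape,
            ifelse(st$class == "PAR", 0.5,
            ifelse(st$gene_id %in% leak_gene, p_xi_leak, 0)))
    from_xi <- stats::rbinom(length(tot), tot, p_xi)
    # Xi haplotype carries REF iff (xi_hap==1) == ref_on_h1
    xi_is_ref <- (cells$xi_hap[i] == 1L) == st$ref_on_h1
    true_ref <- ifelse(xi_is_ref, from_xi, tot - from_xi)
    obs_ref <- err_flip(true_ref, tot)
    df <- data.frame(cell_id = cells$cell_id[i],
                     cell_type = cells$cell_type[i],
                     gene_id = st$gene_id, chrom = st$chrom, pos = st$pos,
                     ref_allele = st$ref_allele, alt_allele = st$alt_allele,
                     rna_ref = obs_ref, rna_alt = tot - obs_ref,
                     stringsAsFactors = FALSE)
    # XIST: Xi-only expression
    if (stats::rbinom(1, 1, cfg$xist_detect_rate) == 1) {
      xtot <- stats::rpois(1, cfg$sc_depth)
      if (xtot > 0) {
        xref_true <- if (xist_ref_on_xi[i]) xtot else 0L
        xref <- err_flip(xref_true, xtot)
        df <- rbind(df, data.frame(
          cell_id = cells$cell_id[i], cell_type = cells$cell_type[i],
          gene_id = "XIST", chrom = "chrX", pos = .XIST_POS,
          ref_allele = "A", alt_allele = "G",
          rna_ref = xref, rna_alt = xtot - xref,
          stringsAsFactors = FALSE))
      }
    }
    rows[[i]] <- df
  }
  counts <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(counts) <- NULL

  # QC metrics
  set.seed(cfg$seed + 211L)
  n <- cfg$n_cells
  qc <- data.frame(cell_id = cells$cell_id,
                   total_reads = round(stats::runif(n, 2e5, 8e5)),
                   mito_fraction = stats::runif(n, 0.01, 0.08),
                   ribo_fraction = stats::runif(n, 0.05, 0.15),
                   stringsAsFactors = FALSE)
  fail <- which(cells$qc_fail)
  if (length(fail)) {
    mode_pick <- sample(c("mito", "ribo", "low", "high"), length(fail),
                        replace = TRUE)
    qc$mito_fraction[fail[mode_pick == "mito"]] <-
      stats::runif(sum(mode_pick == "mito"), 0.12, 0.35)
    qc$ribo_fraction[fail[mode_pick == "ribo"]] <-
      stats::runif(sum(mode_pick == "ribo"), 0.22, 0.45)
    qc$total_reads[fail[mode_pick == "low"]] <-
      round(stats::runif(sum(mode_pick == "low"), 2e4, 1.2e5))
    qc$total_reads[fail[mode_pick == "high"]] <-
      round(stats::runif(sum(mode_pick == "high"), 1.05e6, 2.5e6))
  }

  truth_cells <- cells
  attr(truth_cells, "leak_genes") <- leak_flags
  attr(truth_cells, "xist_ref_on_h1") <- xist_ref_on_h1
  attr(truth_cells, "focal_individual") <- focal

  structure(list(counts = counts, qc = qc, truth_cells = truth_cells),
            class = "sc_profiles")
}

#' @export
print.sc_profiles <- function(x, ...) {
  cat("sc_profiles:", nrow(x$qc), "cells,", nrow(x$counts),
      "allelic rows\n")
  invisible(x)
}

#' Write a simulated cohort to a directory of TSV files
#'
#' Writes every table of a cohort (and optionally its single cells) through
#' the package readers' formats, plus `truth_genes.tsv` /
#' `truth_individuals.tsv` with the ground truth.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @param cells optional result of [simulate_single_cells()].
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, cells = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_annotation(cohort$annotation, file.path(dir, "annotation.tsv"))
  write_expression_table(cohort$expression, file.path(dir, "tpm.tsv"),
                         file.path(dir, "samples.tsv"))
  write_allelic_counts(cohort$sites, file.path(dir, "allelic_counts.tsv"))
  if (!is.null(cohort$methylation)) {
    write_methylation_table(cohort$methylation, file.path(dir, "beta.tsv"))
  }
  .write_tsv(cohort$truth$genes, file.path(dir, "truth_genes.tsv"))
  .write_tsv(cohort$truth$individuals,
             file.path(dir, "truth_individuals.tsv"))
  if (!is.null(cells)) {
    write_allelic_counts(cells$counts, file.path(dir, "sc_counts.tsv"))
    .write_tsv(cells$qc, file.path(dir, "sc_qc.tsv"))
  }
  invisible(dir)
}
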