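# XCI skewing detection/estimation from bulk allelic data, and an exact
# binomial upper bound on the fraction of cells with loss of XCI.

# Aggregate a donor's filtered sites over cell types to one row per SNP of
# the requested prior class, with pooled counts, RR and deviation.
.informative_snps <- function(sites, annotation,
                              prior = "inactive") {
  genes <- annotation$gene_id[annotation$prior_status %in% prior]
  s <- sites[sites$gene_id %in% genes, , drop = FALSE]
  if (nrow(s) == 0) {
    return(data.frame(gene_id = character(0), pos = integer(0),
                      rna_ref = integer(0), rna_alt = integer(0),
                      rr = numeric(0), dev = numeric(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(s$gene_id, s$pos, sep = "\r")
  ref <- tapply(s$rna_ref, key, sum)
  alt <- tapply(s$rna_alt, key, sum)
  parts <- do.call(rbind, strsplit(names(ref), "\r", fixed = TRUE))
  out <- data.frame(gene_id = parts[, 1], pos = as.integer(parts[, 2]),
                    rna_ref = as.integer(ref), rna_alt = as.integer(alt),
                    stringsAsFactors = FALSE, row.names = NULL)
  tot <- out$rna_ref + out$rna_alt
  out$rr <- ifelse(tot > 0, out$rna_ref / tot, NA_real_)
  out$dev <- abs(out$rr - 0.5)
  out[!is.na(out$rr), , drop = FALSE]
}

#' Detect complete XCI skewing from inactive-gene allelic ratios
#'
#' In a completely skewed (cXCI) female, every cell has silenced the same
#' parental X, so inactive genes appear monoallelic in bulk: their
#' heterozygous SNPs show an allelic deviation |RR - 0.5| above
#' `dev_threshold`. The donor is flagged cXCI when the fraction of
#' informative inactive-gene SNPs that are monoallelic exceeds
#' `frac_threshold`.
#'
#' @param sites one donor's filtered allelic sites (counts are pooled per
#'   SNP across cell types).
#' @param annotation gene annotation carrying `prior_status`.
#' @param min_snps minimum informative SNPs for a determinate result,
#'   default 10.
#' @param dev_threshold per-SNP monoallelic deviation cut, default 0.4.
#' @param frac_threshold fraction of monoallelic SNPs required,
#'   default 0.95.
#' @return list with `cxci_flag` (TRUE/FALSE, or NA when indeterminate),
#'   `determinate`, `n_informative_snps`, `frac_monoallelic`, and the
#'   per-SNP table.
#' @export
detect_cxci <- function(sites, annotation, min_snps = 10,
                        dev_threshold = 0.4, frac_threshold = 0.95) {
  snps <- .informative_snps(sites, annotation, "inactive")
  n <- nrow(snps)
  if (n < min_snps) {
    return(list(cxci_flag = NA, determinate = FALSE,
                n_informative_snps = n,
                frac_monoallelic = NA_real_, snps = snps))
  }
  frac <- mean(snps$dev > dev_threshold)
  list(cxci_flag = frac > frac_threshold, determinate = TRUE,
       n_informative_snps = n, frac_monoallelic = frac, snps = snps)
}

#' Estimate the XCI skewing parameter from inactive-gene SNPs
#'
#' For a gene fully silenced on Xi, the expected major-allele fraction of
#' its bulk allelic counts equals max(pi, 1 - pi), where pi is the
#' fraction of cells with the same parental X active. The estimate is the
#' median over informative SNPs of the folded fraction max(RR, 1 - RR),
#' clipped to \[0.5, 1\]; the median resists contamination by residual
#' escape genes in the prior-inactive set, and folding makes the estimate
#' invariant to ref/alt labelling.
#'
#' @inheritParams detect_cxci
#' @return list with `pi_hat` (NA when indeterminate), `determinate`,
#'   `n_informative_snps`, and per-SNP folded fractions in `snps$folded`.
#' @export
estimate_skewing <- function(sites, annotation, min_snps = 10) {
  snps <- .informative_snps(sites, annotation, "inactive")
  snps$folded <- pmax(snps$rr, 1 - snps$rr)
  n <- nrow(snps)
  if (n < min_snps) {
    return(list(pi_hat = NA_real_, determinate = FALSE,
                n_informative_snps = n, snps = snps))
  }
  pi_hat <- min(max(stats::median(snps$folded), 0.5), 1)
  list(pi_hat = pi_hat, determinate = TRUE, n_informative_snps = n,
       snps = snps)
}

#' Upper bound on the fraction of cells with loss of XCI
#'
#' In a completely skewed donor all minor-allele reads at inactive genes
#' are attributable to the inactive X. If a fraction `f` of cells
#' re-express the silenced allele at ratio `rho_leak` relative to the
#' active allele, the expected minor-read fraction is
#' `p = f * rho_leak / (1 + f * rho_leak)`. Observing `m` minor reads out
#' of `N`, the exact one-sided Clopper-Pearson upper bound `p_u` on `p`
#' (at level `conf`) converts to `f_upper = p_u / (rho_leak * (1 - p_u))`,
#' capped at 1. The exact bound (rather than a normal approximation) is
#' essential in the regime of interest, `m` near 0: at m = 0,
#' `p_u = 1 - (1 - conf)^(1/N)`.
#'
#' @param m observed minor-allele reads (>= 0).
#' @param N total reads (> 0).
#' @param rho_leak assumed Xi/Xa expression ratio within leaky cells;
#'   must be > 0 (the bound is unidentifiable at 0). Sensitivity over
#'   \{0.33, 0.5, 1\} is conventional.
#' @param conf one-sided confidence level, default 0.95.
#' @return list with `f_upper`, `p_upper`, `m`, `N`, `rho_leak`, `conf`.
#' @export
leak_upper_bound <- function(m, N, rho_leak = 1, conf = 0.95) {
  if (length(m) != 1 || length(N) != 1) stop("m and N must be scalars")
  if (N <= 0) stop("N must be positive")
  if (m < 0 || m > N) stop("m must satisfy 0 <= m <= N")
  if (rho_leak <= 0) stop("rho_leak must be > 0 (f is unidentifiable)")
  # Clopper-Pearson one-sided upper bound for a binomial proportion
  p_u <- if (m >= N) 1 else stats::qbeta(conf, m + 1, N - m)
  f_u <- if (p_u >= 1) Inf else p_u / (rho_leak * (1 - p_u))
  list(f_upper = min(f_u, 1), p_upper = p_u, m = m, N = N,
       rho_leak = rho_leak, conf = conf)
}

#' Leak-bound sensitivity over a grid of reactivation ratios
#'
#' @inheritParams leak_upper_bound
#' @param rho_grid reactivation ratios to evaluate, default
#'   `c(0.33, 0.5, 1)`.
#' @return data.frame `rho_leak, p_upper, f_upper`.
#' @export
leak_bound_grid <- function(m, N, rho_grid = c(0.33, 0.5, 1),
                            conf = 0.95) {
  rows <- lapply(rho_grid, function(r) {
    b <- leak_upper_bound(m, N, r, conf)
    data.frame(rho_leak = r, p_upper = b$p_upper, f_upper = b$f_upper)
  })
  do.call(rbind, rows)
}
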