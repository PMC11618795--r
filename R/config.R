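#' Default pseudoautosomal region (PAR) intervals, hg38
#'
#' 1-based inclusive chrX coordinates of PAR1 and PAR2 on the GRCh38
#' assembly. Genes whose TSS falls inside either interval are biallelic in
#' both sexes and escape X inactivation by construction.
#'
#' @return A named list with elements `PAR1` and `PAR2`, each a numeric
#'   vector `c(start, end)`.
#' @export
#' @examples
#' par_intervals_hg38()$PAR1
par_intervals_hg38 <- function() {
  list(PAR1 = c(start = 10001, end = 2781479),
       PAR2 = c(start = 155701383, end = 156030895))
}

#' Default thresholds for XCI status calling
#'
#' All tunable cut-offs used across the pipeline, overridable individually.
#' Defaults follow the classifier convention: a gene is monoallelic when its
#' mean ASE deviation exceeds `ase_dev`; promoter methylation is "low"
#' strictly below `meth_low` (set `meth_low_inclusive = TRUE` for the
#' alternative boundary reading) and "high" strictly above `meth_high`;
#' sex-biased expression requires p below `sexbias_p` and |log2FC| above
#' `sexbias_fc`.
#'
#' @param ... named overrides of any default listed below.
#' @return A named list of thresholds:
#' \describe{
#'   \item{ase_dev}{mean ASE deviation boundary, default 0.4.}
#'   \item{meth_low, meth_high}{beta-value category boundaries, 0.25 / 0.75.}
#'   \item{meth_low_inclusive}{if TRUE, beta = 0.25 is "low"; default FALSE.}
#'   \item{fc_escape}{log2FC above which methylation-based escape calls are
#'     high-confidence, default 0.2.}
#'   \item{sexbias_p, sexbias_fc}{significance / fold-change cut-offs for the
#'     sex-bias flag, defaults 1e-5 and 0.2.}
#'   \item{gate_fc_on_p}{whether the classifier requires the sex-bias test to
#'     be significant before using its log2FC; default FALSE.}
#'   \item{tpm_min}{mean-TPM expression filter, default 1.}
#'   \item{eps}{pseudocount added before log2, default 0.5.}
#'   \item{maf_source}{where the 10% minor-allele filter is evaluated:
#'     "dna" (default) or "either" (RNA or DNA).}
#'   \item{sc_rr_window}{single-cell escape window on mean reference ratio,
#'     c(0.1, 0.9).}
#'   \item{min_informative_snps}{minimum SNPs for skewing estimation, 10.}
#'   \item{cxci_dev, cxci_frac}{per-SNP deviation cut and fraction of
#'     monoallelic SNPs required to flag complete skewing, 0.4 / 0.95.}
#' }
#' @export
xci_thresholds <- function(...) {
  defaults <- list(
    ase_dev = 0.4,
    meth_low = 0.25,
    meth_high = 0.75,
    meth_low_inclusive = FALSE,
    fc_escape = 0.2,
    sexbias_p = 1e-5,
    sexbias_fc = 0.2,
    gate_fc_on_p = FALSE,
    tpm_min = 1,
    eps = 0.5,
    maf_source = "dna",
    sc_rr_window = c(0.1, 0.9),
    min_informative_snps = 10,
    cxci_dev = 0.4,
    cxci_frac = 0.95
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(defaults))
    if (length(bad)) {
      stop("unknown threshold(s): ", paste(bad, collapse = ", "))
    }
    defaults[names(dots)] <- dots
  }
  defaults
}

#' Read thresholds and PAR intervals from a YAML configuration file
#'
#' The file may contain a `thresholds:` mapping (any subset of the names in
#' [xci_thresholds()]) and a `par_intervals:` mapping with `PAR1`/`PAR2`
#' entries of the form `[start, end]`. Missing entries keep their defaults.
#'
#' @param path path to a YAML file.
#' @return A list with elements `thresholds` and `par_intervals`.
#' @export
read_xci_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  thr <- do.call(xci_thresholds, as.list(cfg$thresholds))
  par <- par_intervals_hg38()
  for (nm in intersect(names(cfg$par_intervals), names(par))) {
    v <- as.numeric(cfg$par_intervals[[nm]])
    if (length(v) != 2 || any(is.na(v)) || v[1] > v[2]) {
      stop("invalid interval for ", nm, " in ", path)
    }
    par[[nm]] <- c(start = v[1], end = v[2])
  }
  list(thresholds = thr, par_intervals = par)
}
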