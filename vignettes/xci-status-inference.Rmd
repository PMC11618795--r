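---
title: "Calling X-inactivation status from allelic expression, methylation and sex bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling X-inactivation status from allelic expression, methylation and sex bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xcistate)
```

## The inference problem

Female somatic cells silence one X chromosome, but silencing is not
uniform: pseudoautosomal (PAR) genes are diploid in both sexes and escape
by construction, a minority of non-PAR genes escape partially (the
inactive-X copy is expressed, typically at a fraction of the active-X
level), and the rest are inactivated. No single assay resolves this for
all genes:

* **ASE** is direct but only works at heterozygous SNPs, and in bulk
  tissue only for donors with completely skewed XCI (cXCI) — otherwise
  expression from oppositely skewed cells averages out to allelic balance.
* **Promoter methylation** covers all genes but is indirect: XCI-subject
  promoters carry intermediate β (one methylated, one unmethylated
  allele), escapee promoters low β.
* **Sex-biased expression** covers all genes but conflates escape with any
  other cause of female-biased expression.

The package combines them with a fixed precedence: ASE when present,
otherwise methylation corroborated by sex bias.

## The decision rule

With mean ASE deviation $D$ (mean over cell types of $|RR - 0.5|$ at the
gene's selected SNP), promoter methylation $\beta$ (mean over probes in
$[TSS-500, TSS]$ on the transcribed strand, then over samples) and
female/male fold change $FC = \log_2\frac{\bar x_F + 0.5}{\bar x_M + 0.5}$:

| evidence | condition | status |
|---|---|---|
| ASE | $D \le 0.4$ | escape (ASE) |
| ASE | $D > 0.4$ | inactive (ASE) |
| no ASE | $\beta < 0.25$, $FC > 0.2$ | escape, high confidence |
| no ASE | $\beta < 0.25$, $0 < FC \le 0.2$ | escape, low confidence |
| no ASE | $\beta \ge 0.25$, $FC < 0.2$ | inactive |
| no ASE | $\beta < 0.25$, $FC \le 0$; or $\beta \ge 0.25$, $FC \ge 0.2$ | unclassified |

Design choices that were genuinely open, and how they were fixed:

* **ASE precedence.** The escape/inactive criteria are disjunctive
  ("either ASE … or methylation+bias …"), so a gene could satisfy an
  escape clause and an inactive clause simultaneously (e.g. biallelic ASE
  but intermediate methylation). ASE is the direct measurement, so it
  wins; the methylation+bias branch is only consulted without ASE
  coverage.
* **Directional fold change.** The $FC$ criteria use the signed
  female-over-male value, not $|FC|$: the unclassified band explicitly
  distinguishes "below 0" from "above 0.2", which only makes sense
  directionally.
* **Boundaries.** $D = 0.4$ is escape ("≤ 0.4" beats "> 0.4");
  $\beta = 0.25$ is non-low by default (`meth_low_inclusive` switches to
  the inclusive reading, since published boundary wordings disagree);
  $FC = 0.2$ falls into the low-confidence band and $FC = 0$ is not an
  escape call (strict inequalities). All of these are configurable in
  `xci_thresholds()`.
* **Significance gating.** The classifier consumes the fold-change value
  only; requiring the sex-bias test to be significant first is available
  (`gate_fc_on_p`) but off by default, because the classification rule is
  stated in terms of the FC value alone and genes classified from
  methylation+bias often sit below genome-wide significance.

`classify_gene()` is total and mutually exclusive over its input space;
the test suite checks this on a grid containing every boundary value.

## Site filtering and scoring

Two filter regimes serve different purposes (`filter_ase_sites()`):

* `strict` — XCI status calling: WES depth ≥ 20 reads *per allele*, WES
  minor-allele fraction ≥ 10% (heterozygosity confirmation), RNA depth
  ≥ 10. The 10% rule is applied to DNA by default because its purpose is
  genotype confirmation; `maf_source = "either"` accepts RNA or DNA.
* `minor_allele` — leakiness read-counting: RNA ≥ 10 and WES total > 20,
  keeping more sites while still requiring confident heterozygosity.

Within a gene, sample and cell type, only the SNP with the highest RNA
count reports (`select_gene_site()`); ties break to the smallest position
for determinism. Cell types with no surviving site simply drop out of the
gene's mean deviation — averaging is over available cell types only.

## Skewing and the leak bound

For inactive genes in a donor with skewing $\pi$ (fraction of cells with
the same parental X active), the expected major-allele fraction at a
heterozygous SNP is $\max(\pi, 1-\pi)$. `estimate_skewing()` pools each
SNP's counts across cell types, folds ($\max(RR, 1-RR)$, making the
estimate invariant to ref/alt labels), and takes the median over SNPs —
the median resists contamination by mis-annotated escape genes. Near
$\pi = 0.5$ the folded fraction is upward-biased by sampling noise (the
fold maps noise of both signs upward); at 30 SNPs and depth ~500 the bias
is well under the 0.05 tolerance the recovery tests use. cXCI detection
(`detect_cxci()`) flags a donor when > 95% of informative inactive-gene
SNPs are monoallelic ($D > 0.4$); with fewer than 10 informative SNPs the
result is *indeterminate*, never a silent FALSE.

The leak bound (`leak_upper_bound()`) formalises the subpopulation
argument: in a cXCI donor, minor-allele reads at inactive genes are the
only trace of cells that lost XCI. If a fraction $f$ of cells re-express
the silenced allele at ratio $\rho$ of the active allele, the expected
minor-read fraction is $p = f\rho/(1+f\rho)$. A one-sided Clopper–Pearson
bound is used because the regime of interest is $m$ near zero, where
normal approximations fail; at $m = 0$, $p_u = 1 - 0.05^{1/N}$. Since
$\rho$ is not identifiable from bulk data, `leak_bound_grid()` reports the
bound over $\rho \in \{0.33, 0.5, 1\}$ by convention.

## Single-cell Xi haplotyping

XIST marks the inactive X, so allelic XIST reads assign a cell's Xi
haplotype directly; cluster 1 is *defined* as "XIST reference allele"
(the numbering is a package convention — relabelling clusters provably
leaves escape calls and concordance unchanged). Cells with biallelic XIST
or tied anchor votes stay unassigned as `conflict`: doublets and index
hopping are likelier explanations than true biallelic XIST. Anchor genes
are discovered automatically (consistent, opposite monoallelic expression
in ≥ 3 XIST-assigned cells per cluster) rather than hard-coded; the seven
genes conventionally used in thymocytes ship as `anchor_gene_preset()`.
Detection of an allele within a cell means ≥ 1 read (`min_reads`
config-exposed). Escape calls per SNP use the *unweighted* mean of
per-cell RRs over cells with any read (≥ 2 cells required), so deep cells
do not dominate; the 0.1–0.9 window admits both escape routes — biallelic
reads within one cell, or opposite monoallelic cells within one cluster.

## What the synthetic cohorts emulate

`simulate_cohort()` generates the full study structure: 4 XX + 3 XY
donors × 6 thymocyte subtypes (ETP, T-C, DPearly, DPlate, CD4SP, CD8SP),
160 X-linked + 100 autosomal genes, bulk RNA/WES allelic counts,
TPM, promoter methylation for female donors, plus optional X0 donors.
Defaults, chosen once as the emulated study conditions:

* **Escape share and effect size.** 30/160 X genes escape (19%, inside
  the canonical 15–20%); Xi/Xa expression ratio 0.33, so escape genes'
  expected female/male log2FC is $\log_2 1.33 \approx 0.41$, mid the
  reported 0.22–0.59 range for female-biased escapees. PAR genes are
  balanced in both sexes.
* **Skewing.** The focal female (F1) is completely skewed ($\pi = 1$),
  matching the natural cXCI donor that makes bulk ASE informative;
  remaining females are unskewed. The single-cell donor is unskewed
  ($\pi = 0.5$), as in the emulated design.
* **Counts.** RNA allelic counts are beta-binomial around the closed-form
  expected reference fraction
  $p = (\pi_A + (1-\pi_A)\rho_g)/(1+\rho_g)$ with intraclass correlation
  0.01 — the residual overdispersion typical of reference-bias-filtered
  allelic data; WES counts are binomial 50:50 at fixed depth 80 (DNA has
  no allelic imbalance). A per-read allele miscall rate of 0.002 emulates
  residual sequencing/alignment error, so "monoallelic" sites carry a
  realistic trickle of minor reads (~0.2% of reads at inactive genes,
  matching the sub-0.5% levels seen in practice). Set `seq_error = 0` for
  error-free constructions.
* **Methylation.** Promoter probes drawn per class: Beta(2, 30) for
  escape/PAR (mean 0.06), Beta(20, 20) for inactive (mean 0.5, almost
  surely within the intermediate band).
* **Linkage.** All SNPs of a gene share phase (ref alleles on one
  parental haplotype). This is a simplification — real SNPs phase
  independently — adopted so that gene-level anchor semantics ("the same
  single allele per cluster") are exact.
* **Determinism.** One master seed; each generation block re-seeds from a
  fixed offset of it, so identical configs give byte-identical cohorts
  regardless of which blocks run.

What the generator does **not** emulate: reference/mapping bias (assumed
removed upstream), linkage-independent phasing, copy-number variation,
cell-type-specific escape, probe-level EPIC artefacts, and ambient RNA or
doublets in single cells (QC failures are injected as metric outliers, not
as mixed transcriptomes). Recovery rates on synthetic data therefore
demonstrate correctness of the inference logic under the stated model, not
performance on raw real-world data.

## Numerical and scale choices

Welch's t-test runs on $\log_2(TPM + 0.5)$; the 0.5 pseudocount matches
the fold-change transform. Degenerate designs (< 2 samples in a sex)
yield `NA` p-values with a warning rather than errors. BH correction is
applied across tested genes; the `biased` flag uses the raw p-value by
default (threshold $10^{-5}$) with `use_q` available. Constant genes get
p = 1.

Test and acceptance problem sizes are desk-scale by design: cohorts of
~260 genes × 42 samples, 150–200 single cells, 50 replicates per point of
the skewing grid, 1000-replicate calibration of the leak bound — enough
for the binomial tolerances used, and fast enough to re-run wholesale.

## Known limitations

* Bulk ASE is uninformative without cXCI; the pipeline auto-selects a
  completely skewed donor and otherwise classifies from methylation+bias
  alone.
* The skewing estimator's small upward bias at $\pi \approx 0.5$ is
  inherent to folding; it matters only if sub-0.05 precision near perfect
  balance is needed.
* The leak bound depends linearly on the assumed reactivation ratio
  $\rho$ at small $f$; report the grid, not a single value.
* Variable-escape genes (escaping in some tissues or individuals) are
  represented in annotations as `prior_status = "variable"` but the
  classifier has no dedicated variable category — they resolve to
  whatever the evidence in the analysed tissue supports.
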