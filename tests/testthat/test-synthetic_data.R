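# The generator is first-class code: its distributional guarantees are what
# every downstream recovery test rests on.

small_cfg <- function(...) {
  sim_config(n_genes = c(PAR = 4, escape = 8, inactive = 20, autosome = 10),
             n_females = 2, n_males = 1,
             cell_types = c("ETP", "CD4SP"), n_cells = 40, ...)
}

test_that("identical seed gives identical output, different seed differs", {
  c1 <- simulate_cohort(small_cfg(seed = 42))
  c2 <- simulate_cohort(small_cfg(seed = 42))
  expect_identical(c1, c2)
  s1 <- simulate_single_cells(small_cfg(seed = 42), c1$truth)
  s2 <- simulate_single_cells(small_cfg(seed = 42), c2$truth)
  expect_identical(s1, s2)
  c3 <- simulate_cohort(small_cfg(seed = 43))
  expect_false(identical(c1$sites, c3$sites))
})

test_that("invalid rates are rejected before any sampling", {
  expect_error(sim_config(skewing = 0.4), "skewing")
  expect_error(sim_config(leak_fraction = 1.5), "leak_fraction")
  expect_error(sim_config(overdispersion = 1), "overdispersion")
  expect_error(sim_config(seq_error = 0.6), "seq_error")
})

test_that("karyotypes control which heterozygous chrX sites exist", {
  cfg <- sim_config(n_genes = c(PAR = 10, escape = 10, inactive = 30,
                                autosome = 20),
                    n_females = 1, n_males = 1, n_x0 = 1,
                    cell_types = "ETP", het_rate = 0.9, seed = 5)
  co <- simulate_cohort(cfg)
  st <- merge(co$sites, co$annotation[, c("gene_id", "region")],
              by = "gene_id")
  x0 <- st[startsWith(st$sample_id, "TS1_"), ]
  expect_true(all(x0$chrom != "chrX"))
  xy <- st[startsWith(st$sample_id, "M1_"), ]
  expect_true(all(xy$region[xy$chrom == "chrX"] %in% c("PAR1", "PAR2")))
  xx <- st[startsWith(st$sample_id, "F1_"), ]
  expect_true(any(xx$region == "nonPAR"))
})

test_that("allelic ratios follow the closed-form expectations", {
  # cXCI, no escape expression, no noise sources: inactive genes are
  # essentially purely monoallelic
  cfg <- sim_config(n_genes = c(PAR = 0, escape = 0, inactive = 40,
                                autosome = 0),
                    n_females = 1, n_males = 0, cell_types = "ETP",
                    skewing = 1, rna_depth = 1000, overdispersion = 0,
                    seq_error = 0, het_rate = 1, seed = 11)
  co <- simulate_cohort(cfg)
  minor_frac <- with(co$sites, pmin(rna_ref, rna_alt) /
                       (rna_ref + rna_alt))
  expect_lt(mean(minor_frac), 0.005)

  # escape gene at xi_ratio 0.5 under cXCI: expected fraction from the
  # always-active haplotype is 1 / 1.5
  cfg2 <- sim_config(n_genes = c(PAR = 0, escape = 60, inactive = 0,
                                 autosome = 0),
                     n_females = 1, n_males = 0, cell_types = "ETP",
                     skewing = 1, xi_ratio = 0.5, rna_depth = 1000,
                     overdispersion = 0, seq_error = 0, het_rate = 1,
                     seed = 12)
  co2 <- simulate_cohort(cfg2)
  tr <- co2$truth$sites
  st <- merge(co2$sites, tr[, c("gene_id", "pos", "ref_on_h1")],
              by = c("gene_id", "pos"))
  # fold onto the active-haplotype fraction using the true phase
  act_frac <- ifelse(st$ref_on_h1, st$rna_ref, st$rna_alt) /
    (st$rna_ref + st$rna_alt)
  p <- 1 / 1.5
  se <- stats::sd(act_frac) / sqrt(nrow(st))
  expect_lt(abs(mean(act_frac) - p), 3 * se + 1e-3)
})

test_that("counts are consistent and leakiness is monotone in f", {
  co <- simulate_cohort(small_cfg(seed = 2))
  expect_true(all(co$sites$rna_ref >= 0 & co$sites$rna_alt >= 0))
  expect_true(all(co$sites$dna_ref + co$sites$dna_alt == 80))

  minor_at_f <- function(f, seed) {
    cfg <- sim_config(n_genes = c(PAR = 0, escape = 0, inactive = 50,
                                  autosome = 0),
                      n_females = 1, n_males = 0, cell_types = "ETP",
                      skewing = 1, leak_fraction = f, leak_ratio = 1,
                      rna_depth = 500, seq_error = 0, het_rate = 1,
                      seed = seed)
    co <- simulate_cohort(cfg)
    sum(pmin(co$sites$rna_ref, co$sites$rna_alt))
  }
  seeds <- 101:105
  m0 <- vapply(seeds, function(s) minor_at_f(0, s), numeric(1))
  m05 <- vapply(seeds, function(s) minor_at_f(0.05, s), numeric(1))
  m20 <- vapply(seeds, function(s) minor_at_f(0.20, s), numeric(1))
  expect_true(all(mean(m0) < mean(m05), mean(m05) < mean(m20)))
})

test_that("sex-biased expression emerges for escape genes but not PAR", {
  co <- simulate_cohort(sim_config(seed = 8))
  bias <- sex_bias_test(tpm_filter(co$expression))
  cls <- co$truth$genes
  fc <- function(cl) bias$log2fc[match(
    cls$gene_id[cls$class == cl], bias$gene_id)]
  expect_gt(median(fc("escape"), na.rm = TRUE), 0.2)
  expect_lt(abs(median(fc("PAR"), na.rm = TRUE)), 0.1)
  expect_lt(abs(median(fc("inactive"), na.rm = TRUE)), 0.1)
})

test_that("single cells respect haplotype structure and XIST origin", {
  cfg <- sim_config(n_genes = c(PAR = 0, escape = 0, inactive = 30,
                                autosome = 0),
                    n_females = 1, n_males = 0, cell_types = "ETP",
                    n_cells = 60, leak_fraction = 0, seq_error = 0,
                    het_rate = 1, sc_skewing = 0.5, xist_detect_rate = 1,
                    seed = 21)
  co <- simulate_cohort(cfg)
  cells <- simulate_single_cells(cfg, co$truth)
  tc <- cells$truth_cells
  ph <- co$truth$sites[co$truth$sites$individual == "F1",
                       c("gene_id", "pos", "ref_on_h1")]
  cnt <- merge(cells$counts[cells$counts$gene_id != "XIST", ], ph,
               by = c("gene_id", "pos"))
  xi <- tc$xi_hap[match(cnt$cell_id, tc$cell_id)]
  # f = 0, no errors: every inactive-gene read comes from the active
  # haplotype of its cell
  active_is_ref <- (xi == 2L) == cnt$ref_on_h1  # active hap = the other one
  expect_true(all(cnt$rna_alt[active_is_ref] == 0))
  expect_true(all(cnt$rna_ref[!active_is_ref] == 0))

  # XIST reads come from the opposite haplotype (the Xi)
  xist <- cells$counts[cells$counts$gene_id == "XIST", ]
  xist_on_h1 <- attr(tc, "xist_ref_on_h1")
  xi_x <- tc$xi_hap[match(xist$cell_id, tc$cell_id)]
  xist_ref_expected <- (xi_x == 1L) == xist_on_h1
  expect_true(all(xist$rna_alt[xist_ref_expected] == 0))
  expect_true(all(xist$rna_ref[!xist_ref_expected] == 0))
})

test_that("unskewed single-cell donor yields balanced clusters", {
  cfg <- sim_config(n_cells = 200, sc_skewing = 0.5, seed = 31)
  co <- simulate_cohort(cfg)
  cells <- simulate_single_cells(cfg, co$truth)
  n1 <- sum(cells$truth_cells$true_cluster == 1L)
  expect_lt(abs(n1 - 100), 3 * sqrt(50))
  # n_cells = 0 -> empty result, not an error
  empty <- simulate_single_cells(sim_config(n_cells = 0, seed = 31),
                                 co$truth)
  expect_equal(nrow(empty$counts), 0)
})
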