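test_that("strict filter applies the per-allele depth and MAF rules", {
  # dna 25/25, rna 15 total, DNA minor 50% -> kept
  kept <- make_sites(10, 5, dna_ref = 25, dna_alt = 25)
  expect_equal(nrow(filter_ase_sites(kept, "strict")), 1)
  # dna 19/40 -> removed on per-allele depth even though MAF > 10%
  shallow <- make_sites(50, 50, dna_ref = 19, dna_alt = 40)
  expect_equal(nrow(filter_ase_sites(shallow, "strict")), 0)
  # DNA minor allele below 10% -> removed despite depth
  skewed <- make_sites(50, 50, dna_ref = 300, dna_alt = 20)
  expect_equal(nrow(filter_ase_sites(skewed, "strict")), 0)
  # RNA depth below 10 -> removed
  lowrna <- make_sites(4, 5, dna_ref = 40, dna_alt = 40)
  expect_equal(nrow(filter_ase_sites(lowrna, "strict")), 0)
  # minor_allele mode: RNA >= 10 and WES total strictly > 20
  ma <- make_sites(c(9, 10, 10), c(0, 0, 0), dna_ref = c(30, 10, 11),
                   dna_alt = c(30, 10, 10))
  keep_ma <- filter_ase_sites(ma, "minor_allele")
  expect_equal(nrow(keep_ma), 1)          # 9 RNA reads and WES = 20 fail
  expect_equal(keep_ma$dna_ref, 11)
})

test_that("filter matches the brute-force oracle on random tables", {
  set.seed(601)
  n <- 300
  sites <- make_sites(rpois(n, 12), rpois(n, 12),
                      dna_ref = rpois(n, 25), dna_alt = rpois(n, 25),
                      gene_id = sprintf("G%d", sample(1:40, n, TRUE)))
  for (mode in c("strict", "minor_allele")) {
    got <- filter_ase_sites(sites, mode)
    want <- brute_force_filter(sites, mode)
    expect_equal(got, want)
  }
  got_e <- filter_ase_sites(sites, "strict", maf_source = "either")
  expect_equal(got_e, brute_force_filter(sites, "strict", "either"))
})

test_that("filtering is idempotent and label-symmetric", {
  set.seed(602)
  n <- 200
  sites <- make_sites(rpois(n, 12), rpois(n, 12),
                      dna_ref = rpois(n, 25), dna_alt = rpois(n, 25))
  once <- filter_ase_sites(sites, "strict")
  expect_identical(filter_ase_sites(once, "strict"), once)

  # swapping ref/alt labels leaves deviations and minor counts unchanged
  swapped <- sites
  swapped[, c("rna_ref", "rna_alt")] <- sites[, c("rna_alt", "rna_ref")]
  swapped[, c("dna_ref", "dna_alt")] <- sites[, c("dna_alt", "dna_ref")]
  d1 <- select_sites(filter_ase_sites(sites, "strict"))
  d2 <- select_sites(filter_ase_sites(swapped, "strict"))
  expect_equal(d1$dev, d2$dev)
  expect_equal(pmin(sites$rna_ref, sites$rna_alt),
               pmin(swapped$rna_ref, swapped$rna_alt))
})

test_that("site selection keeps the highest RNA count, ties to position", {
  two <- make_sites(c(6, 30), c(6, 10), pos = c(100L, 200L))
  expect_equal(select_gene_site(two)$pos, 200L)
  one <- make_sites(5, 5)
  expect_equal(select_gene_site(one), one)
  tie <- make_sites(c(15, 20), c(15, 10), pos = c(200L, 100L))
  expect_equal(select_gene_site(tie)$pos, 100L)
  expect_null(select_gene_site(two[0, ]))

  # grouped selection agrees with per-group application
  set.seed(603)
  n <- 120
  sites <- make_sites(rpois(n, 20), rpois(n, 20),
                      gene_id = sprintf("G%d", sample(1:15, n, TRUE)),
                      pos = sample(1:5000, n),
                      cell_type = sample(c("ETP", "CD4SP"), n, TRUE))
  sites$sample_id <- paste0("F1_", sites$cell_type)
  sel <- select_sites(sites)
  for (k in sample(nrow(sel), 10)) {
    grp <- sites[sites$gene_id == sel$gene_id[k] &
                   sites$cell_type == sel$cell_type[k], ]
    expect_equal(select_gene_site(grp)$pos, sel$pos[k])
  }
})

test_that("ase_score averages deviations and applies the 0.4 rule", {
  mk <- function(rr, ct) {
    s <- make_sites(round(rr * 100), round((1 - rr) * 100),
                    cell_type = ct, sample_id = paste0("F1_", ct))
    s
  }
  sel <- select_sites(rbind(mk(0.95, "ETP"), mk(0.89, "CD4SP")))
  sc <- ase_score(sel)
  expect_equal(sc$mean_dev, mean(c(0.45, 0.39)))
  expect_equal(sc$ase_status, "inactive")   # 0.42 > 0.4

  expect_equal(ase_score(select_sites(mk(0.5, "ETP")))$ase_status,
               "escape")                    # D = 0
  expect_equal(ase_score(select_sites(mk(1.0, "ETP")))$ase_status,
               "inactive")                  # D = 0.5
  # boundary: mean deviation exactly 0.4 is escape
  expect_equal(ase_score(select_sites(mk(0.9, "ETP")))$ase_status,
               "escape")
  # no surviving site: empty score table, the no-call signal
  expect_equal(nrow(ase_score(select_sites(mk(0.5, "ETP")[0, ]))), 0)
})

test_that("ASE status recovers the simulated truth under cXCI", {
  cfg <- sim_config(n_genes = c(PAR = 0, escape = 40, inactive = 60,
                                autosome = 0),
                    n_females = 1, n_males = 0, skewing = 1,
                    xi_ratio = 0.5, het_rate = 1, seed = 77)
  co <- simulate_cohort(cfg)
  sc <- ase_score(select_sites(filter_ase_sites(co$sites, "strict")))
  m <- merge(sc, co$truth$genes, by = "gene_id")
  for (cl in c("escape", "inactive")) {
    acc <- mean(m$ase_status[m$class == cl] == cl)
    expect_gte(acc, 0.95)
  }
})

test_that("minor allele summary counts the rarer allele per site", {
  ann <- make_annotation(c("G1", "G2", "IMM"),
                         prior_status = c("inactive", "inactive",
                                          "unknown"),
                         immune_flag = c(FALSE, FALSE, TRUE))
  s <- rbind(make_sites(98, 2, gene_id = "G1"),
             make_sites(c(10, 50), c(0, 1), gene_id = "G2"))
  out <- minor_allele_summary(s, ann, "inactive")
  expect_equal(out$per_cell_type$minor_reads, 3L)
  expect_equal(out$per_cell_type$total_reads, 161L)
  g2 <- out$per_gene[out$per_gene$gene_id == "G2", ]
  expect_equal(g2$minor_reads, 1L)
  expect_equal(g2$total_reads, 61L)

  # no immune-flagged genes present in the data -> empty summary
  none <- minor_allele_summary(make_sites(5, 5, gene_id = "G1"),
                               make_annotation("G1"), "immune")
  expect_equal(nrow(none$per_cell_type), 0)
  expect_error(minor_allele_summary(s, ann, "nonsense"))
})
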