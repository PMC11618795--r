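mk_qc <- function(cell_id, reads = 5e5, mito = 0.05, ribo = 0.10) {
  data.frame(cell_id = cell_id, total_reads = rep_len(reads,
                                                      length(cell_id)),
             mito_fraction = rep_len(mito, length(cell_id)),
             ribo_fraction = rep_len(ribo, length(cell_id)),
             stringsAsFactors = FALSE)
}

test_that("cell QC applies the mito/ribo/read-count windows", {
  qc <- mk_qc(sprintf("c%d", 1:5),
              reads = c(5e5, 1e5, 5e5, 5e5, 1.2e6),
              mito = c(0.05, 0.05, 0.12, 0.05, 0.05),
              ribo = c(0.10, 0.10, 0.10, 0.25, 0.10))
  counts <- make_sc_counts(sprintf("c%d", 1:5), "G1", 3, 0)
  out <- qc_filter_cells(counts, qc)
  expect_equal(out$qc$cell_id, "c1")
  expect_setequal(out$removed, c("c2", "c3", "c4", "c5"))
  # boundaries are inclusive where the rule says "between"
  edge <- mk_qc("e1", reads = 125000, mito = 0.10, ribo = 0.20)
  expect_equal(nrow(qc_filter_cells(counts[0, ], edge)$qc), 1)
})

test_that("XIST seeding follows the allele rule table", {
  counts <- rbind(
    make_sc_counts("c1", "XIST", 3, 0),
    make_sc_counts("c2", "XIST", 0, 2),
    make_sc_counts("c3", "XIST", 1, 1),
    make_sc_counts("c4", "ATRX", 5, 0))
  asg <- assign_by_xist(counts)
  get <- function(cid, col) asg[[col]][asg$cell_id == cid]
  expect_equal(get("c1", "cluster"), 1L)
  expect_equal(get("c1", "basis"), "XIST")
  expect_equal(get("c2", "cluster"), 2L)
  expect_true(is.na(get("c3", "cluster")))
  expect_equal(get("c3", "basis"), "conflict")
  expect_true(is.na(get("c4", "cluster")))
  expect_warning(assign_by_xist(counts[counts$gene_id == "ATRX", ]),
                 "no XIST")
})

test_that("anchor discovery requires opposite consistent monoallelic use", {
  cl1 <- sprintf("a%d", 1:3); cl2 <- sprintf("b%d", 1:3)
  xist <- rbind(make_sc_counts(cl1, "XIST", 2, 0),
                make_sc_counts(cl2, "XIST", 0, 2))
  good <- rbind(make_sc_counts(cl1, "GOOD", 4, 0),
                make_sc_counts(cl2, "GOOD", 0, 4))
  biall <- rbind(make_sc_counts(cl1, "BIAL", c(4, 4, 2), c(0, 0, 2)),
                 make_sc_counts(cl2, "BIAL", 0, 4))
  same <- rbind(make_sc_counts(cl1, "SAME", 4, 0),
                make_sc_counts(cl2, "SAME", 4, 0))
  rare <- rbind(make_sc_counts(cl1[1:2], "RARE", 4, 0),
                make_sc_counts(cl2, "RARE", 0, 4))
  counts <- rbind(xist, good, biall, same, rare)
  asg <- assign_by_xist(counts)
  anc <- find_anchor_genes(counts, asg, c("GOOD", "BIAL", "SAME", "RARE"))
  expect_equal(anc$gene_id, "GOOD")         # the only qualifying gene
  expect_equal(anc$allele_cluster1, "ref")
  expect_equal(anc$allele_cluster2, "alt")
  # RARE fails only on the min_cells requirement
  anc2 <- find_anchor_genes(counts, asg, "RARE", min_cells = 2)
  expect_equal(anc2$gene_id, "RARE")
})

test_that("propagation votes per anchor; ties and silence stay unassigned", {
  anchors <- data.frame(gene_id = c("A1", "A2", "A3"),
                        allele_cluster1 = c("ref", "ref", "alt"),
                        allele_cluster2 = c("alt", "alt", "ref"),
                        stringsAsFactors = FALSE)
  counts <- rbind(
    make_sc_counts("n1", "A1", 0, 3),            # alt -> cluster 2
    make_sc_counts("n2", c("A1", "A2"), c(3, 0), c(0, 4)),  # 1 vs 2 tie
    make_sc_counts("n3", "OTHER", 5, 0),         # no anchor expressed
    make_sc_counts("n4", c("A1", "A2", "A3"), c(3, 4, 0), c(0, 0, 3)))
  asg <- data.frame(cell_id = c("n1", "n2", "n3", "n4"),
                    cluster = NA_integer_, basis = NA_character_,
                    stringsAsFactors = FALSE)
  out <- propagate_clusters(counts, asg, anchors)
  expect_equal(out$cluster[out$cell_id == "n1"], 2L)
  expect_equal(out$basis[out$cell_id == "n1"], "anchor:A1")
  expect_true(is.na(out$cluster[out$cell_id == "n2"]))
  expect_equal(out$basis[out$cell_id == "n2"], "conflict")
  expect_true(is.na(out$cluster[out$cell_id == "n3"]))
  # n4: A1 ref -> 1, A2 ref -> 1, A3 alt -> ... A3 alt is cluster-1 allele
  expect_equal(out$cluster[out$cell_id == "n4"], 1L)
  # empty anchor list leaves everything untouched
  expect_identical(propagate_clusters(counts, asg, anchors[0, ]), asg)
})

test_that("per-SNP escape calls use the mean RR window and cell minimum", {
  asg <- data.frame(cell_id = sprintf("c%d", 1:6),
                    cluster = rep(1:2, each = 3), basis = "XIST",
                    stringsAsFactors = FALSE)
  counts <- rbind(
    # cluster 1, gene E: per-cell RRs 1, 1, 0.6 -> mean 0.867 -> escape
    make_sc_counts(c("c1", "c2", "c3"), "E", c(5, 4, 6), c(0, 0, 4),
                   pos = 100L),
    # cluster 2, gene E: monoallelic everywhere -> mean 1 -> inactive
    make_sc_counts(c("c4", "c5", "c6"), "E", c(5, 5, 5), 0, pos = 100L),
    # gene S detected in exactly one cell of cluster 1 -> no_call there
    make_sc_counts("c1", "S", 3, 0, pos = 200L),
    make_sc_counts(c("c4", "c5"), "S", 3, 0, pos = 200L),
    # route b: every cell monoallelic but both alleles seen in cluster 1
    make_sc_counts(c("c1", "c2"), "RB", c(4, 0), c(0, 4), pos = 300L))
  esc <- call_snp_escape(counts, asg)
  e <- esc[esc$gene_id == "E", ]
  expect_equal(e$mean_rr_1, mean(c(1, 1, 0.6)))
  expect_equal(e$status_1, "escape")
  expect_equal(e$status_2, "inactive")
  expect_false(e$concordant)
  s <- esc[esc$gene_id == "S", ]
  expect_equal(s$status_1, "no_call")
  expect_equal(s$status_2, "inactive")
  expect_true(is.na(s$concordant))
  rb <- esc[esc$gene_id == "RB", ]
  expect_equal(rb$mean_rr_1, 0.5)
  expect_equal(rb$status_1, "escape")
})

test_that("relabelling clusters leaves statuses and concordance unchanged", {
  set.seed(91)
  cells <- sprintf("c%d", 1:20)
  counts <- rbind(
    make_sc_counts(cells, "INA", ifelse(seq_along(cells) <= 10, 5, 0),
                   ifelse(seq_along(cells) <= 10, 0, 5), pos = 10L),
    make_sc_counts(cells, "ESC", rbinom(20, 5, 0.5), rbinom(20, 5, 0.5),
                   pos = 20L))
  asg <- data.frame(cell_id = cells,
                    cluster = rep(1:2, each = 10), basis = "XIST",
                    stringsAsFactors = FALSE)
  flipped <- asg
  flipped$cluster <- 3L - asg$cluster
  a <- call_snp_escape(counts, asg)
  b <- call_snp_escape(counts, flipped)
  expect_equal(a$status_1, b$status_2)
  expect_equal(a$status_2, b$status_1)
  expect_equal(a$concordant, b$concordant)
})

test_that("Xi read histogram buckets cells by inactive-X reads", {
  asg <- data.frame(cell_id = c("c1", "c2", "c3", "c4"),
                    cluster = c(1L, 1L, 2L, NA), basis = "XIST",
                    stringsAsFactors = FALSE)
  # cluster 1 Xi allele is alt; cluster 2 Xi allele is ref
  xi <- data.frame(gene_id = "INA", pos = 10L, cluster = 1:2,
                   xi_allele = c("alt", "ref"), stringsAsFactors = FALSE)
  counts <- rbind(
    make_sc_counts("c1", "INA", 5, 0, pos = 10L),   # 0 Xi reads
    make_sc_counts("c2", "INA", 4, 1, pos = 10L),   # 1 Xi read
    make_sc_counts("c3", "INA", 2, 3, pos = 10L),   # ref = Xi -> 2 reads
    make_sc_counts("c4", "INA", 9, 9, pos = 10L))   # unassigned, excluded
  h <- xi_read_histogram(counts, asg, xi)
  expect_equal(h$histogram, c("0" = 1L, "1" = 1L, ">=2" = 1L))
  expect_equal(h$n_unassigned, 1L)
})

test_that("the full single-cell chain recovers simulated clusters", {
  cfg <- sim_config(n_cells = 150, sc_skewing = 0.5, seed = 92)
  co <- simulate_cohort(cfg)
  cells <- simulate_single_cells(cfg, co$truth)
  flt <- qc_filter_cells(cells$counts, cells$qc)
  # QC removes exactly the deliberately injected failing cells
  expect_setequal(flt$removed,
                  cells$truth_cells$cell_id[cells$truth_cells$qc_fail])
  asg <- assign_by_xist(flt$counts)
  inact <- co$annotation$gene_id[co$annotation$prior_status == "inactive"]
  anc <- find_anchor_genes(flt$counts, asg, inact)
  asg <- propagate_clusters(flt$counts, asg, anc)
  tc <- cells$truth_cells
  ok <- !is.na(asg$cluster)
  truecl <- tc$true_cluster[match(asg$cell_id, tc$cell_id)]
  expect_gte(mean(asg$cluster[ok] == truecl[ok]), 0.99)
  expect_gt(sum(ok), 0.5 * nrow(asg))

  # with f = 0 and no sequencing error every inactive read is Xa-origin
  cfg0 <- sim_config(n_cells = 60, sc_skewing = 0.5, seq_error = 0,
                     seed = 93)
  co0 <- simulate_cohort(cfg0)
  cells0 <- simulate_single_cells(cfg0, co0$truth)
  asg0 <- assign_by_xist(cells0$counts)
  inact0 <- co0$annotation$gene_id[co0$annotation$prior_status ==
                                     "inactive"]
  anc0 <- find_anchor_genes(cells0$counts, asg0, inact0)
  asg0 <- propagate_clusters(cells0$counts, asg0, anc0)
  xi0 <- infer_xi_alleles(cells0$counts, asg0, inact0)
  h0 <- xi_read_histogram(
    cells0$counts[cells0$counts$gene_id %in% inact0, ], asg0, xi0)
  expect_equal(unname(h0$histogram[c("1", ">=2")]), c(0L, 0L))
})
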