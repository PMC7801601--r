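ps_df <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  peak_set(rep("chr1", nrow(m)), m[, 1], m[, 2])
}

test_that("consensus is intersection at k = n and union at k = 1", {
  r1 <- ps_df(100, 200)
  r2 <- ps_df(150, 250)
  both <- consensus_peaks(list(r1, r2), 2)
  expect_equal(both$start, 150)
  expect_equal(both$end, 200)
  one <- consensus_peaks(list(r1, r2), 1)
  expect_equal(one$start, 100)
  expect_equal(one$end, 250)
  expect_error(consensus_peaks(list(r1, r2), 3), "exceeds")
})

test_that("overlapping peaks within one replicate count once toward support", {
  r1 <- ps_df(100, 300, 200, 400)  # overlapping pair in the same replicate
  r2 <- ps_df(500, 600)
  both <- consensus_peaks(list(r1, r2), 2)
  expect_equal(nrow(both), 0L)
})

test_that("merged coverage removes double counting", {
  expect_equal(merged_coverage_bp(ps_df(0, 100, 50, 150)), 150)
  expect_equal(merged_coverage_bp(ps_df(0, 10, 20, 30)), 20)
  expect_equal(merged_coverage_bp(peak_set(character(0), numeric(0), numeric(0))), 0)
})

test_that("consensus and coverage match the per-base oracle on random sets", {
  for (s in 1:8) {
    g <- gen_peak_replicates(seed = 100 + s, n_peaks = 120, n_rep = 3,
                             chrom_lengths = c(chr1 = 5e5, chr2 = 3e5),
                             jitter = 120, dropout = 0.25)
    for (k in 1:3) {
      cons <- consensus_peaks(g$replicates, k)
      oracle <- oracle_consensus(g$replicates, k)
      expect_equal(data.frame(cons), oracle)
    }
    cons2 <- consensus_peaks(g$replicates, 2)
    if (nrow(cons2) > 0)
      expect_equal(merged_coverage_bp(cons2), oracle_coverage_bp(cons2))
  }
})

test_that("consensus support is monotone decreasing in k", {
  g <- gen_peak_replicates(seed = 55, n_peaks = 150, n_rep = 4,
                           jitter = 200, dropout = 0.3)
  covs <- vapply(1:4, function(k)
    merged_coverage_bp(consensus_peaks(g$replicates, k)), numeric(1))
  expect_true(all(diff(covs) <= 0))
  # every base at support k+1 is at support k: containment as base sets
  for (k in 1:3) {
    hi <- consensus_peaks(g$replicates, k + 1)
    lo <- consensus_peaks(g$replicates, k)
    merged <- consensus_peaks(list(hi, lo), 1)
    expect_equal(merged_coverage_bp(merged), merged_coverage_bp(lo))
  }
})

test_that("zero jitter and dropout reproduce the planted truth at full support", {
  g <- gen_peak_replicates(seed = 7, n_peaks = 60, n_rep = 3)
  cons <- consensus_peaks(g$replicates, 3)
  expect_equal(data.frame(cons), data.frame(g$truth))
  g2 <- gen_peak_replicates(seed = 7, n_peaks = 60, n_rep = 3, dropout = 1)
  expect_equal(nrow(consensus_peaks(g2$replicates, 3)), 0L)
})

toy_genes <- function() {
  gene_annotation(gene_id = sprintf("g%02d", 1:5),
                  chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
                  strand = c("+", "-", "+", "+", "-"),
                  tss = c(1000, 25000, 40000, 5000, 90000),
                  body_start = c(1000, 20000, 40000, 5000, 80000),
                  body_end = c(8000, 25001, 47000, 9000, 90001))
}

test_that("peak annotation prefers promoter over genic over intergenic", {
  genes <- toy_genes()
  ps <- peak_set(c("chr1", "chr1", "chr1", "chr3"),
                 c(990, 5000, 300000, 10), c(1010, 5100, 300100, 20))
  expect_warning(ann <- annotate_peaks(ps, genes, promoter_window = 2000),
                 "absent")
  expect_equal(ann$labels, c("promoter", "genic", "intergenic", "intergenic"))
  expect_equal(unname(ann$counts), c(1L, 1L, 2L))
})

test_that("annotation labels match the exhaustive pairwise oracle", {
  set.seed(23)
  tss <- sort(sample(1e6, 50))
  genes <- gene_annotation(gene_id = sprintf("G%02d", 1:50),
                           chrom = sample(c("chr1", "chr2"), 50, TRUE),
                           strand = sample(c("+", "-"), 50, TRUE),
                           tss = tss,
                           body_start = tss,
                           body_end = tss + sample(2000:20000, 50))
  for (s in 1:4) {
    g <- gen_peak_replicates(seed = 200 + s, n_peaks = 150,
                             chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
                             n_rep = 1)
    ps <- g$replicates[[1]]
    ann <- annotate_peaks(ps, genes, promoter_window = 2000)
    expect_equal(ann$labels, oracle_annotate(ps, genes, 2000))
  }
})

test_that("binding matrix recovers planted bound-gene contrasts", {
  # 24 genes; peaks planted at 22 in one condition, 2 in the other
  genes <- gene_annotation(gene_id = sprintf("t%02d", 1:24),
                           chrom = "chr1", strand = "+",
                           tss = seq(1e4, by = 4e4, length.out = 24),
                           body_start = seq(1e4, by = 4e4, length.out = 24),
                           body_end = seq(2e4, by = 4e4, length.out = 24))
  plant <- function(idx) data.frame(chrom = "chr1",
                                    start = genes$body_start[idx] + 100,
                                    end = genes$body_start[idx] + 400)
  gx <- gen_peak_replicates(seed = 31, n_rep = 2, plant_at = plant(1:22))
  gy <- gen_peak_replicates(seed = 32, n_rep = 2, plant_at = plant(c(5, 17)))
  cons <- list(condX = consensus_peaks(gx$replicates, 2),
               condY = consensus_peaks(gy$replicates, 2))
  bm <- gene_binding_matrix(cons, genes, window = 5000)
  expect_equal(unname(bm$n_bound), c(22, 2))
  expect_equal(bm$bound, oracle_binding(cons, genes, 5000),
               ignore_attr = TRUE)
})

test_that("binding calls respect the window and flag missing genes", {
  genes <- gene_annotation("g1", "chr1", "+", 1000, 1000, 2000)
  inside <- list(c = peak_set("chr1", 1500, 1600))
  away <- list(c = peak_set("chr1", 7200, 7300))
  expect_true(gene_binding_matrix(inside, genes, window = 0)$bound["g1", "c"])
  expect_false(gene_binding_matrix(away, genes, window = 0)$bound["g1", "c"])
  expect_true(gene_binding_matrix(away, genes, window = 6000)$bound["g1", "c"])

  bm <- gene_binding_matrix(inside, genes, gene_ids = c("g1", "g9"))
  expect_equal(bm$missing, "g9")
  expect_true(is.na(bm$bound["g9", "c"]))

  empty <- list(c = peak_set(character(0), numeric(0), numeric(0)))
  expect_false(any(gene_binding_matrix(empty, genes)$bound))
})

test_that("interval validation enforces 0-based half-open invariants", {
  expect_error(peak_set("chr1", 10, 10), "start < end")
  expect_error(peak_set("chr1", -1, 10), "start < end")
  ps <- peak_set(c("chr2", "chr1"), c(5, 1), c(10, 4))
  expect_equal(ps$chrom, c("chr1", "chr2"))  # sorted on construction
})
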