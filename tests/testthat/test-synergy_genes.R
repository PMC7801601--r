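make_means <- function(dmso, a, b, combo, gene = "g1") {
  m <- cbind(DMSO = dmso, drugA = a, drugB = b, combo = combo)
  rownames(m) <- if (length(dmso) == length(gene)) gene else
    sprintf("g%03d", seq_along(dmso))
  m
}

test_that("condition means average replicates and report counts", {
  expr <- rbind(g1 = c(10, 12, 5, 7, 6, 8, 20, 22),
                g2 = c(1, 1, 2, 2, 3, 3, 4, 4))
  sheet <- data.frame(sample = paste0("s", 1:8),
                      condition = rep(c("DMSO", "drugA", "drugB", "combo"), each = 2),
                      replicate = rep(1:2, 4))
  colnames(expr) <- sheet$sample
  m <- summarize_conditions(expr, sheet)
  expect_equal(m["g1", ], c(DMSO = 11, drugA = 6, drugB = 7, combo = 21))
  expect_equal(unname(attr(m, "n_rep")), rep(2L, 4))
  expect_error(summarize_conditions(expr, sheet[sheet$condition != "combo", ]),
               "combo")
})

test_that("the synergy rule classifies by C/(A+B) with an inclusive 1.25 threshold", {
  rec <- call_synergy_genes(make_means(10, 12, 11, 14))
  expect_equal(rec$A, 2); expect_equal(rec$B, 1); expect_equal(rec$C, 4)
  expect_equal(rec$ratio, 4 / 3)
  expect_equal(rec$class, "up")

  rec2 <- call_synergy_genes(make_means(10, 9, 9, 7))
  expect_equal(rec2$ratio, 1.5)
  expect_equal(rec2$class, "down")

  # boundary: ratio exactly 1.25 with combo > DMSO is up
  rec3 <- call_synergy_genes(make_means(10, 11, 11, 12.5))
  expect_equal(rec3$ratio, 1.25)
  expect_equal(rec3$class, "up")
  # just below threshold is not
  rec4 <- call_synergy_genes(make_means(10, 11, 11, 12.49))
  expect_equal(rec4$class, "none")

  # A + B numerically zero: undefined, not a call
  rec5 <- call_synergy_genes(make_means(10, 12, 8, 15))
  expect_equal(rec5$class, "undefined")
  expect_true(is.na(rec5$ratio))
})

test_that("classification is invariant under joint positive rescaling of a gene", {
  set.seed(31)
  for (i in 1:25) {
    v <- runif(4, 1, 50)
    s <- 10^runif(1, -2, 2)
    r1 <- call_synergy_genes(make_means(v[1], v[2], v[3], v[4]))
    r2 <- call_synergy_genes(make_means(s * v[1], s * v[2], s * v[3], s * v[4]))
    expect_identical(r1$class, r2$class)
    expect_equal(r1$ratio, r2$ratio, tolerance = 1e-12)
  }
})

test_that("classes partition the gene universe", {
  g <- gen_expression_matrix(seed = 6, n_genes = 500, n_up = 30, n_down = 12,
                             noise_sd = 0.2)
  rec <- call_synergy_genes(summarize_conditions(g$expr, g$sheet))
  expect_true(all(rec$class %in% c("up", "down", "none", "undefined")))
  expect_equal(length(rec$class), 500L)
  expect_false(any(rec$class == "up" & rec$class == "down"))
})

test_that("noiseless planted tables are recovered exactly", {
  g <- gen_expression_matrix(seed = 2, n_genes = 10000, n_up = 252, n_down = 94,
                             noise_sd = 0)
  rec <- call_synergy_genes(summarize_conditions(g$expr, g$sheet))
  expect_setequal(rec$gene[rec$class == "up"], g$truth$up)
  expect_setequal(rec$gene[rec$class == "down"], g$truth$down)
  expect_true(all(rec$ratio[rec$class == "up"] >= 1.4))
})

test_that("a significance mask restricts calls without changing the rule", {
  g <- gen_expression_matrix(seed = 3, n_genes = 400, n_up = 40, n_down = 10,
                             noise_sd = 0)
  m <- summarize_conditions(g$expr, g$sheet)
  mask <- stats::setNames(rep(FALSE, 400), rownames(m))
  keep <- g$truth$up[1:10]
  mask[keep] <- TRUE
  rec <- call_synergy_genes(m, significance_mask = mask)
  expect_setequal(rec$gene[rec$class == "up"], keep)
})

test_that("the built-in Welch mask flags responsive genes at low noise", {
  g <- gen_expression_matrix(seed = 8, n_genes = 150, n_up = 20, n_down = 5,
                             noise_sd = 0.02, n_rep = 3)
  mask <- welch_significance_mask(g$expr, g$sheet)
  # every gene in this generator responds strongly to at least one drug
  expect_gt(mean(mask), 0.95)
})

test_that("gene-set overlap counts and hypergeometric tail match enumeration", {
  rec <- data.frame(gene = letters[1:10],
                    class = c("up", "up", "up", rep("none", 7)))
  ov <- intersect_gene_set(rec, c("b", "c", "d"))
  expect_equal(ov$overlap, 2L)
  expect_setequal(ov$overlap_genes, c("B", "C"))
  expect_equal(ov$p_value, oracle_hyper_upper(2, 10, 3, 3), tolerance = 1e-12)

  ov0 <- intersect_gene_set(rec, c("x", "y", "z"))
  expect_equal(ov0$overlap, 0L)
  expect_equal(ov0$p_value, 1)

  # brute-force agreement across configurations on a 20-gene universe
  set.seed(17)
  for (i in 1:20) {
    genes <- sprintf("G%02d", 1:20)
    n_call <- sample(1:10, 1)
    cls <- rep("none", 20); cls[sample(20, n_call)] <- "up"
    set <- sample(genes, sample(1:12, 1))
    rec <- data.frame(gene = genes, class = cls)
    ov <- intersect_gene_set(rec, set)
    expect_equal(ov$p_value,
                 oracle_hyper_upper(ov$overlap, 20, ov$n_set, ov$n_called),
                 tolerance = 1e-12)
  }
  expect_error(intersect_gene_set(rec, character(0)), "empty")
})

test_that("the dependence contrast partitions control calls by knockdown outcome", {
  ctrl <- data.frame(gene = c("a", "b", "c", "d"),
                     class = c("up", "up", "up", "none"))
  kd <- data.frame(gene = c("a", "b", "c", "d"),
                   class = c("none", "down", "up", "none"))
  dep <- p53_dependence(ctrl, kd, "up")
  expect_setequal(dep$dependent, c("A", "B"))
  expect_setequal(dep$independent, "C")

  same <- p53_dependence(ctrl, ctrl, "up")
  expect_length(same$dependent, 0)
  expect_equal(same$n_independent, 3L)

  kd_bad <- kd[1:3, ]
  expect_error(p53_dependence(ctrl, kd_bad), "universes differ")
})

test_that("reverted knockdown genes are exactly the dependent set", {
  g <- gen_expression_matrix(seed = 4, n_genes = 3000, n_up = 120, n_down = 40,
                             noise_sd = 0, knockdown = TRUE, revert_fraction = 0.9)
  rec_c <- call_synergy_genes(summarize_conditions(g$expr, g$sheet))
  rec_k <- call_synergy_genes(summarize_conditions(g$knockdown$expr, g$knockdown$sheet))
  dep <- c(p53_dependence(rec_c, rec_k, "up")$dependent,
           p53_dependence(rec_c, rec_k, "down")$dependent)
  expect_setequal(dep, toupper(g$knockdown$reverted))
  expect_equal(length(dep), round(0.9 * 160))
})
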