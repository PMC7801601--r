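test_that("generators are byte-identical under the same seed and diverge otherwise", {
  a <- gen_dose_response(seed = 42, noise_sd = 0.05)
  b <- gen_dose_response(seed = 42, noise_sd = 0.05)
  expect_identical(a, b)
  c <- gen_dose_response(seed = 43, noise_sd = 0.05)
  expect_false(identical(a$curve1$fa, c$curve1$fa))

  p1 <- gen_viability_plate(seed = 42, noise_sd = 0.1)
  p2 <- gen_viability_plate(seed = 42, noise_sd = 0.1)
  expect_identical(p1, p2)

  e1 <- gen_expression_matrix(seed = 42, n_genes = 100, n_up = 5, n_down = 5,
                              noise_sd = 0.2, knockdown = TRUE)
  e2 <- gen_expression_matrix(seed = 42, n_genes = 100, n_up = 5, n_down = 5,
                              noise_sd = 0.2, knockdown = TRUE)
  expect_identical(e1, e2)

  t1 <- gen_ct_timecourse(seed = 42, noise_sd = 0.1, n_rep = 2)
  t2 <- gen_ct_timecourse(seed = 42, noise_sd = 0.1, n_rep = 2)
  expect_identical(t1, t2)

  k1 <- gen_peak_replicates(seed = 42, jitter = 50, dropout = 0.2)
  k2 <- gen_peak_replicates(seed = 42, jitter = 50, dropout = 0.2)
  expect_identical(k1, k2)
})

test_that("sub-seed derivation separates generator streams", {
  labels <- c("dose_response", "viability_plate", "expression_matrix",
              "expression_replicates", "knockdown_selection",
              "knockdown_replicates", "ct_timecourse", "peak_replicates")
  subs <- vapply(labels, derive_seed, integer(1), seed = 7)
  expect_equal(anyDuplicated(subs), 0L)
  expect_true(all(subs >= 0 & subs < 2^31 - 1))
  expect_false(derive_seed(7, "dose_response") ==
               derive_seed(8, "dose_response"))
})

test_that("dose-response truth is honoured at zero noise", {
  g <- gen_dose_response(seed = 1, m1 = 1.5, Dm1 = 0.7, m2 = 0.8, Dm2 = 9,
                         noise_sd = 0)
  expect_equal(g$curve1$fa, effect_at_dose(list(m = 1.5, Dm = 0.7), g$curve1$doses))
  expect_equal(g$design$combo_fa, g$truth$combo_fa_true)
  # grid margins are the single-agent effects, origin is zero
  expect_equal(g$bliss_observed[1, 1], 0, ignore_attr = TRUE)
  expect_equal(unname(g$bliss_observed[-1, 1]), g$curve1$fa)
  expect_equal(unname(g$bliss_observed[1, -1]), g$curve2$fa)
})

test_that("plate generator obeys its truth and replication defaults", {
  g <- gen_viability_plate(seed = 3, A = 0.7, B = 0.4, noise_sd = 0)
  fr <- normalize_viability(g$plate)
  expect_equal(fr$fraction[fr$condition == "A"], rep(0.7, 3))
  expect_equal(fr$fraction[fr$condition == "AB"], rep(0.28, 3))
  expect_equal(sum(g$plate$condition == "vehicle"), 6L)  # 2 * n_rep
  expect_equal(g$truth$cdi, 1)
  g2 <- gen_viability_plate(seed = 3, A = 0.6, B = 0.5, AB = 0.15)
  expect_equal(g2$truth$cdi, 0.5)
})

test_that("expression truth: nulls are exactly additive, planted ratios >= 1.4", {
  g <- gen_expression_matrix(seed = 12, n_genes = 800, n_up = 40, n_down = 20)
  m <- g$truth$means
  dA <- m[, "drugA"] - m[, "DMSO"]
  dB <- m[, "drugB"] - m[, "DMSO"]
  dC <- m[, "combo"] - m[, "DMSO"]
  nulls <- g$truth$kind == "null"
  expect_equal(dC[nulls], (dA + dB)[nulls], tolerance = 1e-12)
  planted <- !nulls
  expect_true(all(dC[planted] / (dA + dB)[planted] >= 1.4))
  expect_true(all(m >= 0))
  expect_true(all(sign(dA[planted]) == sign(dB[planted])))
  expect_error(gen_expression_matrix(seed = 1, n_genes = 10, n_up = 8, n_down = 5),
               "exceed")
})

test_that("knockdown table reverts the requested fraction of planted genes", {
  g <- gen_expression_matrix(seed = 5, n_genes = 500, n_up = 30, n_down = 10,
                             knockdown = TRUE, revert_fraction = 0.5)
  expect_length(g$knockdown$reverted, 20L)
  expect_true(all(g$knockdown$reverted %in% c(g$truth$up, g$truth$down)))
  kd <- g$knockdown$means
  m <- g$truth$means
  rev_ratio <- (kd[g$knockdown$reverted, "combo"] - kd[g$knockdown$reverted, "DMSO"]) /
    (kd[g$knockdown$reverted, "drugA"] + kd[g$knockdown$reverted, "drugB"] -
       2 * kd[g$knockdown$reverted, "DMSO"])
  expect_equal(unname(rev_ratio), rep(1, 20), tolerance = 1e-12)
  untouched <- setdiff(rownames(m), g$knockdown$reverted)
  expect_equal(kd[untouched, ], m[untouched, ])
})

test_that("Ct generator encodes half-life as cycles per hour", {
  g <- gen_ct_timecourse(seed = 1, half_lives = 2, times = c(0, 2, 4, 6))
  expect_equal(g$ct_table$ct, c(20, 21, 22, 23))
  gInf <- gen_ct_timecourse(seed = 1, half_lives = Inf)
  expect_equal(gInf$ct_table$ct, rep(20, 4))
  hl <- data.frame(gene = c("a", "b"), condition = "vehicle",
                   half_life = c(1, 4))
  g2 <- gen_ct_timecourse(seed = 2, half_lives = hl, n_rep = 2)
  expect_equal(nrow(g2$ct_table), 2 * 2 * 4)
  expect_equal(g2$ct_table$ct[g2$ct_table$gene == "a" & g2$ct_table$time == 4],
               rep(24, 2))
})

test_that("peak generator honours jitter, dropout and planting", {
  g0 <- gen_peak_replicates(seed = 9, n_peaks = 50)
  for (r in g0$replicates) expect_equal(data.frame(r), data.frame(g0$truth))
  expect_true(all(g0$truth$end - g0$truth$start >= 200))
  expect_true(all(g0$truth$end - g0$truth$start <= 800))
  expect_true(all(diff(g0$truth$start) > 0))

  gj <- gen_peak_replicates(seed = 9, n_peaks = 50, jitter = 30)
  for (r in gj$replicates) {
    expect_true(all(abs(r$start - gj$truth$start) <= 30))
    expect_true(all(r$end > r$start))
  }

  gd <- gen_peak_replicates(seed = 9, n_peaks = 400, n_rep = 1, dropout = 0.5)
  n_kept <- nrow(gd$replicates[[1]])
  expect_gt(n_kept, 400 * 0.3)
  expect_lt(n_kept, 400 * 0.7)

  planted <- data.frame(chrom = "chrX", start = c(10, 500), end = c(100, 700))
  gp <- gen_peak_replicates(seed = 9, plant_at = planted)
  expect_equal(data.frame(gp$truth),
               data.frame(peak_set(planted$chrom, planted$start, planted$end)))
})
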