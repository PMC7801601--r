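#' Derive a deterministic sub-seed from a root seed
#'
#' Each generator seeds its own random stream from the root simulation
#' seed and a short label, so adding a new generator to a workflow never
#' perturbs the draws of existing ones. The derivation is a fixed
#' polynomial hash of the label folded into the root seed, reduced
#' modulo 2^31 - 1.
#'
#' @param seed Integer root seed.
#' @param label Character stream label.
#' @return Integer sub-seed in \[0, 2^31 - 2\].
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% (2^31 - 1))
}

# Loewe-additive combination response: given component doses (d1, d2) and
# the two median-effect fits, solve d1/Dx1(fa) + d2/Dx2(fa) = 1 for fa by
# bisection. The interaction sum is strictly decreasing in fa, positive as
# fa -> 0 and -> -1 as fa -> 1, so the root is bracketed for any valid fit.
loewe_fa <- function(d1, d2, fit1, fit2, tol = 1e-10) {
  if (d1 == 0 && d2 == 0) return(0)
  if (d2 == 0) return(effect_at_dose(fit1, d1))
  if (d1 == 0) return(effect_at_dose(fit2, d2))
  g <- function(fa) d1 / dose_for_effect(fit1, fa) +
    d2 / dose_for_effect(fit2, fa) - 1
  lo <- 1e-12; hi <- 1 - 1e-12
  if (g(lo) < 0 || g(hi) > 0)
    stop("internal error: Loewe bisection not bracketed")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# multiplicative lognormal noise on the survival scale, converted back to
# fraction affected and clipped into [0, 1]
noisy_fa <- function(fa, sd) {
  if (sd == 0) return(fa)
  v <- (1 - fa) * exp(stats::rnorm(length(fa), 0, sd))
  pmin(pmax(1 - v, 0), 1)
}

#' Simulate a constant-ratio dose-response experiment
#'
#' Generates two single-agent median-effect curves, a constant-ratio
#' combination series under a chosen interaction model, and a full
#' checkerboard grid scored on the inhibition scale, with the generating
#' parameters recorded as ground truth.
#'
#' Interaction models: `"loewe_additive"` solves the dose-equivalence
#' relation d1/Dx1(fa) + d2/Dx2(fa) = 1 by bisection (tolerance 1e-10),
#' so the fitted combination index is exactly 1; `"bliss_independent"`
#' combines the single-agent effects as E_A + E_B - E_A*E_B, so the
#' excess over Bliss is exactly 0; `"potency_synergy"` multiplies both
#' effective component doses by `alpha` before the Loewe solve, so the
#' combination index is 1/alpha at every effect level.
#'
#' @param seed Integer seed (only consumed when `noise_sd > 0`).
#' @param m1,Dm1,m2,Dm2 True median-effect parameters of the two drugs.
#' @param ratio Drug1:drug2 dose ratio (length-2 vector or `"a:b"`).
#' @param model Interaction model (see Details).
#' @param alpha Potency multiplier for `"potency_synergy"` (> 0).
#' @param n_doses Number of doses per series (geometric, 2-fold steps
#'   centred on each curve's median-effect dose).
#' @param noise_sd Lognormal noise sd applied on the survival scale.
#' @return List with `curve1`, `curve2` ([dose_response_curve()]s),
#'   `design` ([constant_ratio_design()]), `bliss_observed` (inhibition
#'   matrix with zero-dose margins) and `truth`.
#' @export
gen_dose_response <- function(seed = 1, m1 = 1, Dm1 = 1, m2 = 1, Dm2 = 10,
                              ratio = c(1, 12.5),
                              model = c("loewe_additive", "bliss_independent",
                                        "potency_synergy"),
                              alpha = 1, n_doses = 6, noise_sd = 0) {
  model <- match.arg(model)
  stopifnot(alpha > 0)
  set.seed(derive_seed(seed, "dose_response"))
  ratio <- parse_ratio(ratio)
  w <- ratio / sum(ratio)
  fit1 <- list(m = m1, Dm = Dm1)
  fit2 <- list(m = m2, Dm = Dm2)
  steps <- 2^seq(-2.5, 2.5, length.out = n_doses)

  doses1 <- Dm1 * steps
  doses2 <- Dm2 * steps
  fa1 <- noisy_fa(effect_at_dose(fit1, doses1), noise_sd)
  fa2 <- noisy_fa(effect_at_dose(fit2, doses2), noise_sd)
  curve1 <- dose_response_curve("drug1", doses1, fa1)
  curve2 <- dose_response_curve("drug2", doses2, fa2)

  # centre the combination series near its Loewe median-effect total dose
  Dm_combo <- 1 / (w[1] / Dm1 + w[2] / Dm2)
  totals <- Dm_combo * steps
  combo_true <- vapply(totals, function(D) {
    d1 <- D * w[1]; d2 <- D * w[2]
    switch(model,
           loewe_additive = loewe_fa(d1, d2, fit1, fit2),
           potency_synergy = loewe_fa(d1 * alpha, d2 * alpha, fit1, fit2),
           bliss_independent = {
             eA <- effect_at_dose(fit1, d1); eB <- effect_at_dose(fit2, d2)
             eA + eB - eA * eB
           })
  }, numeric(1))
  design <- constant_ratio_design(curve1, curve2, ratio, totals,
                                  noisy_fa(combo_true, noise_sd))

  # checkerboard inhibition grid with monotherapy margins
  g1 <- c(0, doses1); g2 <- c(0, doses2)
  grid_true <- outer(g1, g2, Vectorize(function(d1, d2) {
    if (d1 == 0 && d2 == 0) return(0)
    switch(model,
           loewe_additive = loewe_fa(d1, d2, fit1, fit2),
           potency_synergy = loewe_fa(d1 * alpha, d2 * alpha, fit1, fit2),
           bliss_independent = {
             eA <- if (d1 > 0) effect_at_dose(fit1, d1) else 0
             eB <- if (d2 > 0) effect_at_dose(fit2, d2) else 0
             eA + eB - eA * eB
           })
  }))
  grid_obs <- matrix(noisy_fa(as.vector(grid_true), noise_sd),
                     nrow = length(g1),
                     dimnames = list(g1, g2))
  list(curve1 = curve1, curve2 = curve2, design = design,
       bliss_observed = grid_obs,
       truth = list(m1 = m1, Dm1 = Dm1, m2 = m2, Dm2 = Dm2, ratio = ratio,
                    model = model, alpha = alpha, noise_sd = noise_sd,
                    combo_fa_true = combo_true, expected_ci =
                      if (model == "potency_synergy") 1 / alpha
                      else if (model == "loewe_additive") 1 else NA_real_))
}

#' Simulate a vehicle-referenced viability plate
#'
#' Raw well signals are `scale * fraction * exp(noise)` with the vehicle
#' truth at fraction 1. The default combination truth is Bliss
#' independence on survival, `AB = A * B`; supply `AB` directly to plant
#' synergy (`AB < A*B`) or antagonism. The vehicle arm gets twice the
#' treatment-arm replication by default, reflecting plate layouts in
#' which the normalization anchor is replicated more heavily than any
#' single treatment.
#'
#' @param seed Integer seed.
#' @param A,B True single-agent surviving fractions.
#' @param AB True combination surviving fraction (default `A * B`).
#' @param n_rep Wells per treatment arm.
#' @param n_vehicle Vehicle wells (default `2 * n_rep`).
#' @param noise_sd Lognormal noise sd on raw signals.
#' @param scale Raw-signal scale of the vehicle mean.
#' @return List with `plate` ([viability_plate()]) and `truth`.
#' @export
gen_viability_plate <- function(seed = 1, A = 0.6, B = 0.5, AB = NULL,
                                n_rep = 3, n_vehicle = 2 * n_rep,
                                noise_sd = 0, scale = 1000) {
  if (is.null(AB)) AB <- A * B
  set.seed(derive_seed(seed, "viability_plate"))
  conds <- c(rep("vehicle", n_vehicle), rep("A", n_rep),
             rep("B", n_rep), rep("AB", n_rep))
  reps <- c(seq_len(n_vehicle), seq_len(n_rep), seq_len(n_rep), seq_len(n_rep))
  truth_fr <- c(rep(1, n_vehicle), rep(A, n_rep), rep(B, n_rep), rep(AB, n_rep))
  noise <- if (noise_sd > 0) exp(stats::rnorm(length(truth_fr), 0, noise_sd)) else 1
  plate <- viability_plate(conds, reps, scale * truth_fr * noise)
  list(plate = plate,
       truth = list(A = A, B = B, AB = AB, cdi = AB / (A * B),
                    noise_sd = noise_sd, n_rep = n_rep, n_vehicle = n_vehicle))
}

#' Simulate a four-condition expression table with planted synergy genes
#'
#' Emulates the strongly drug-responsive gene universe of a two-drug
#' transcriptome experiment. Every gene gets a baseline (vehicle) mean
#' and single-drug deltas A and B of a common sign; null genes respond
#' exactly additively (C = A + B, synergy ratio 1), while planted genes
#' get C = r * (A + B) with r >= 1.4, above the 1.25 calling threshold,
#' in a direction consistent with the deltas. Effect sizes are
#' several-fold (induced genes 4-7x per drug, repressed genes 46-50% per
#' drug), as for significantly changed genes in such experiments: the
#' synergy-ratio rule is only statistically meaningful when the summed
#' single-drug response is well above measurement noise.
#' Down-regulated effects are bounded so all condition means stay
#' positive. Replicate values are the condition mean times lognormal
#' noise. Optionally a paired "knockdown" table is produced in which a
#' chosen fraction of the planted genes reverts to exact additivity,
#' emulating loss of the upstream regulator.
#'
#' @param seed Integer seed.
#' @param n_genes Total genes.
#' @param n_up,n_down Planted synergistically up-/down-regulated genes.
#' @param n_rep Replicates per condition.
#' @param noise_sd Lognormal sd of replicate noise.
#' @param knockdown If `TRUE`, also generate the paired reverted table.
#' @param revert_fraction Fraction of planted genes reverted to
#'   additivity in the knockdown table.
#' @param baseline_meanlog,baseline_sdlog Lognormal parameters of the
#'   vehicle means.
#' @return List with `expr` (genes x samples matrix), `sheet` (sample,
#'   condition, replicate), `truth` (planted `up`/`down` ids and per-gene
#'   true means), and if requested `knockdown` (`expr`, `sheet`,
#'   `reverted` ids).
#' @export
gen_expression_matrix <- function(seed = 1, n_genes = 6000, n_up = 252,
                                  n_down = 94, n_rep = 3, noise_sd = 0,
                                  knockdown = FALSE, revert_fraction = 0.9,
                                  baseline_meanlog = log(20),
                                  baseline_sdlog = 0.8) {
  if (n_up + n_down > n_genes)
    stop("planted gene counts exceed the number of genes")
  set.seed(derive_seed(seed, "expression_matrix"))
  genes <- sprintf("g%05d", seq_len(n_genes))
  ids <- sample(n_genes)
  up_idx <- ids[seq_len(n_up)]
  down_idx <- ids[n_up + seq_len(n_down)]
  kind <- rep("null", n_genes)
  kind[up_idx] <- "up"; kind[down_idx] <- "down"

  m0 <- stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
  A <- B <- C <- numeric(n_genes)
  for (i in seq_len(n_genes)) {
    if (kind[i] == "up") {
      a <- stats::runif(2, 3, 6)
      r <- stats::runif(1, 1.4, 2.5)
      A[i] <- a[1] * m0[i]; B[i] <- a[2] * m0[i]
      C[i] <- r * (A[i] + B[i])
    } else if (kind[i] == "down") {
      # magnitudes bounded so that combo mean = m0 + C stays positive:
      # r * (a1 + a2) must not exceed 1
      r <- stats::runif(1, 1.45, 1.5)
      a <- stats::runif(2, 0.30, 0.999 / (2 * r))
      A[i] <- -a[1] * m0[i]; B[i] <- -a[2] * m0[i]
      C[i] <- r * (A[i] + B[i])
    } else {
      s <- sample(c(1, -1), 1)
      a <- if (s > 0) stats::runif(2, 3, 6) else stats::runif(2, 0.46, 0.50)
      A[i] <- s * a[1] * m0[i]; B[i] <- s * a[2] * m0[i]
      C[i] <- A[i] + B[i]
    }
  }
  means <- cbind(DMSO = m0, drugA = m0 + A, drugB = m0 + B, combo = m0 + C)
  rownames(means) <- genes
  stopifnot(all(means >= 0))

  make_table <- function(mns, stream) {
    set.seed(derive_seed(seed, stream))
    conds <- colnames(mns)
    sheet <- data.frame(
      condition = rep(conds, each = n_rep),
      replicate = rep(seq_len(n_rep), times = length(conds)),
      stringsAsFactors = FALSE)
    sheet$sample <- paste0(sheet$condition, "_", sheet$replicate)
    sheet <- sheet[, c("sample", "condition", "replicate")]
    expr <- matrix(0, n_genes, nrow(sheet),
                   dimnames = list(genes, sheet$sample))
    for (j in seq_len(nrow(sheet))) {
      mu <- mns[, sheet$condition[j]]
      expr[, j] <- if (noise_sd > 0)
        mu * exp(stats::rnorm(n_genes, 0, noise_sd)) else mu
    }
    list(expr = expr, sheet = sheet)
  }

  ctrl <- make_table(means, "expression_replicates")
  out <- list(expr = ctrl$expr, sheet = ctrl$sheet,
              truth = list(up = genes[up_idx], down = genes[down_idx],
                           kind = stats::setNames(kind, genes),
                           means = means, noise_sd = noise_sd))
  if (knockdown) {
    set.seed(derive_seed(seed, "knockdown_selection"))
    planted <- c(up_idx, down_idx)
    n_rev <- round(revert_fraction * length(planted))
    reverted <- sort(sample(planted, n_rev))
    C_kd <- C
    C_kd[reverted] <- A[reverted] + B[reverted]
    means_kd <- cbind(DMSO = m0, drugA = m0 + A, drugB = m0 + B,
                      combo = m0 + C_kd)
    rownames(means_kd) <- genes
    kd <- make_table(means_kd, "knockdown_replicates")
    out$knockdown <- list(expr = kd$expr, sheet = kd$sheet,
                          reverted = genes[reverted], means = means_kd)
  }
  out
}

#' Simulate qPCR Ct timecourses under transcription shutoff
#'
#' Ct(t) = Ct0 + t / half_life + N(0, noise_sd): with perfect doubling
#' per cycle, one extra cycle per half-life corresponds to exponential
#' decay at rate ln(2)/half_life. An infinite half-life gives a flat
#' timecourse.
#'
#' @param seed Integer seed.
#' @param half_lives Data.frame with columns `gene`, `condition`,
#'   `half_life` (hours; `Inf` allowed), or a single number applied to a
#'   single gene/condition.
#' @param times Sampling times in hours (must start at 0).
#' @param ct0 Baseline Ct at time 0.
#' @param noise_sd Additive normal Ct noise (cycles).
#' @param n_rep Replicate measurements per time point.
#' @return List with `ct_table` (gene, condition, replicate, time, ct)
#'   and `truth` (the half-life table).
#' @export
gen_ct_timecourse <- function(seed = 1, half_lives = 2,
                              times = c(0, 2, 4, 6), ct0 = 20,
                              noise_sd = 0, n_rep = 1) {
  if (is.numeric(half_lives) && length(half_lives) == 1L)
    half_lives <- data.frame(gene = "gene1", condition = "vehicle",
                             half_life = half_lives)
  stopifnot(is.data.frame(half_lives),
            all(c("gene", "condition", "half_life") %in% names(half_lives)))
  set.seed(derive_seed(seed, "ct_timecourse"))
  rows <- lapply(seq_len(nrow(half_lives)), function(i) {
    hl <- half_lives$half_life[i]
    slope <- if (is.finite(hl)) 1 / hl else 0
    do.call(rbind, lapply(seq_len(n_rep), function(r) {
      ct <- ct0 + times * slope +
        if (noise_sd > 0) stats::rnorm(length(times), 0, noise_sd) else 0
      data.frame(gene = half_lives$gene[i],
                 condition = half_lives$condition[i],
                 replicate = r, time = times, ct = ct,
                 stringsAsFactors = FALSE)
    }))
  })
  list(ct_table = do.call(rbind, rows), truth = half_lives)
}

#' Simulate replicate ChIP peak sets on a toy genome
#'
#' True peaks are placed one per equal-width bin along each chromosome
#' (guaranteeing a sorted, non-overlapping truth set), or taken verbatim
#' from `plant_at`. Each replicate then derives from the truth by
#' dropping every peak independently with probability `dropout` and
#' jittering each boundary by an independent uniform integer in
#' \[-jitter, jitter\] (clamped to keep valid intervals).
#'
#' @param seed Integer seed.
#' @param n_peaks True peaks per chromosome (ignored when `plant_at` is
#'   given).
#' @param n_rep Number of replicate peak sets.
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param width_range Min/max true peak width in bp.
#' @param jitter Maximum boundary jitter in bp.
#' @param dropout Per-peak, per-replicate dropout probability.
#' @param plant_at Optional data.frame (chrom, start, end) of true peaks.
#' @return List with `replicates` (list of [peak_set()]s), `truth`
#'   (the true [peak_set()]) and `params`.
#' @export
gen_peak_replicates <- function(seed = 1, n_peaks = 200, n_rep = 3,
                                chrom_lengths = c(chr1 = 1e6),
                                width_range = c(200, 800),
                                jitter = 0, dropout = 0, plant_at = NULL) {
  set.seed(derive_seed(seed, "peak_replicates"))
  if (is.null(plant_at)) {
    truth <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
      L <- chrom_lengths[[ch]]
      bin <- floor(L / n_peaks)
      wmax <- min(width_range[2], max(floor(bin / 2), width_range[1]))
      w <- floor(stats::runif(n_peaks, width_range[1], wmax + 1))
      start <- (seq_len(n_peaks) - 1) * bin +
        floor(stats::runif(n_peaks, 0, bin - w + 1))
      data.frame(chrom = ch, start = start, end = start + w,
                 stringsAsFactors = FALSE)
    }))
  } else {
    truth <- plant_at[, c("chrom", "start", "end")]
  }
  truth_ps <- peak_set(truth$chrom, truth$start, truth$end)
  replicates <- lapply(seq_len(n_rep), function(r) {
    keep <- stats::runif(nrow(truth_ps)) >= dropout
    sub <- truth_ps[keep, , drop = FALSE]
    if (nrow(sub) == 0L)
      return(peak_set(character(0), numeric(0), numeric(0)))
    if (jitter > 0) {
      js <- sample(seq(-jitter, jitter), nrow(sub), replace = TRUE)
      je <- sample(seq(-jitter, jitter), nrow(sub), replace = TRUE)
      s <- pmax(sub$start + js, 0)
      e <- pmax(sub$end + je, s + 1)
      peak_set(sub$chrom, s, e, replicate = as.character(r))
    } else {
      peak_set(sub$chrom, sub$start, sub$end, replicate = as.character(r))
    }
  })
  list(replicates = replicates, truth = truth_ps,
       params = list(n_rep = n_rep, jitter = jitter, dropout = dropout,
                     chrom_lengths = chrom_lengths))
}
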