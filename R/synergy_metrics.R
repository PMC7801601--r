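#' Construct a viability plate
#'
#' A long-format table of raw viability signals (e.g. CellTiter-Glo
#' luminescence or resazurin fluorescence), one row per well, labelled by
#' condition and replicate. Condition labels are free-form but a
#' `"vehicle"` condition must be present for normalization; the CDI
#' pipeline expects conditions `"A"`, `"B"` and `"AB"` for the two single
#' agents and their combination.
#'
#' @param condition Character vector of condition labels.
#' @param replicate Integer vector of replicate indices.
#' @param signal Numeric vector of raw signals, all >= 0.
#' @return A `data.frame` of class `viability_plate`.
#' @export
viability_plate <- function(condition, replicate, signal) {
  condition <- as.character(condition)
  replicate <- as.integer(replicate)
  signal <- as.numeric(signal)
  n <- length(condition)
  if (length(replicate) != n || length(signal) != n)
    stop("condition, replicate and signal must have equal lengths")
  if (any(!is.finite(signal)) || any(signal < 0))
    stop("signals must be finite and >= 0")
  if (!any(condition == "vehicle"))
    stop("plate must contain at least one 'vehicle' well")
  structure(data.frame(condition = condition, replicate = replicate,
                       signal = signal, stringsAsFactors = FALSE),
            class = c("viability_plate", "data.frame"))
}

#' Vehicle-normalize a viability plate
#'
#' Converts raw well signals to surviving fractions by dividing every
#' well by the mean vehicle signal, so the vehicle mean defines the 1.0
#' reference. Fractions above 1 (apparent stimulation) are retained but
#' flagged.
#'
#' @param plate A [viability_plate()] (or a data.frame with `condition`,
#'   `replicate`, `signal` columns).
#' @return A `data.frame` of class `surviving_fractions` with columns
#'   `condition`, `replicate`, `fraction` and logical `flagged_gt1`;
#'   attribute `vehicle_mean` records the normalizer.
#' @export
normalize_viability <- function(plate) {
  stopifnot(is.data.frame(plate),
            all(c("condition", "replicate", "signal") %in% names(plate)))
  veh <- plate$signal[plate$condition == "vehicle"]
  if (length(veh) == 0L) stop("normalization error: no vehicle wells")
  vm <- mean(veh)
  if (!is.finite(vm) || vm <= 0)
    stop("normalization error: vehicle mean signal is not positive")
  out <- data.frame(condition = plate$condition,
                    replicate = plate$replicate,
                    fraction = plate$signal / vm,
                    stringsAsFactors = FALSE)
  out$flagged_gt1 <- out$fraction > 1
  attr(out, "vehicle_mean") <- vm
  class(out) <- c("surviving_fractions", "data.frame")
  out
}

#' Extract per-condition replicate fraction vectors
#'
#' @param fr A `surviving_fractions` data.frame.
#' @param conditions Conditions to extract (default A, B, AB).
#' @return Named list of numeric vectors ordered by replicate index.
#' @export
fraction_arrays <- function(fr, conditions = c("A", "B", "AB")) {
  stopifnot(is.data.frame(fr), all(c("condition", "fraction") %in% names(fr)))
  out <- lapply(conditions, function(cc) {
    sub <- fr[fr$condition == cc, , drop = FALSE]
    if (nrow(sub) == 0L) stop("condition '", cc, "' absent from fractions")
    sub$fraction[order(sub$replicate)]
  })
  names(out) <- conditions
  out
}

#' Coefficient of drug interaction (CDI)
#'
#' CDI = AB / (A x B) on mean surviving fractions, where A and B are the
#' single-agent arms and AB the combination arm, all vehicle-normalized.
#' CDI < 1 indicates synergy, = 1 additivity, > 1 antagonism. The
#' significance test compares the AB replicate fractions against the
#' replicate-index-paired products A_i x B_i with a two-tailed unpaired
#' Welch t-test (requires >= 2 replicates in each arm; with fewer the
#' point estimate is returned with `p_value = NA`).
#'
#' @param fr A `surviving_fractions` data.frame (from
#'   [normalize_viability()]) or a named list with numeric elements `A`,
#'   `B`, `AB` of replicate fractions.
#' @return A list of class `cdi_result`: `cdi`, `p_value`, `n_products`,
#'   `n_combo`, `call` (one of `"synergistic"`, `"additive"`,
#'   `"antagonistic"`) and the means of each arm.
#' @export
cdi <- function(fr) {
  arms <- if (is.data.frame(fr)) fraction_arrays(fr) else fr
  stopifnot(all(c("A", "B", "AB") %in% names(arms)))
  A <- arms$A; B <- arms$B; AB <- arms$AB
  mA <- mean(A); mB <- mean(B); mAB <- mean(AB)
  if (mA * mB == 0)
    stop("CDI undefined: mean(A) * mean(B) is zero")
  value <- mAB / (mA * mB)

  np <- min(length(A), length(B))
  if (length(A) != length(B))
    warning("unequal replicate counts in A and B; products formed over the first ",
            np, " replicates of each")
  products <- A[seq_len(np)] * B[seq_len(np)]
  p_value <- NA_real_
  if (np >= 2L && length(AB) >= 2L &&
      (stats::sd(AB) > 0 || stats::sd(products) > 0)) {
    p_value <- stats::t.test(AB, products, alternative = "two.sided")$p.value
  }
  call <- if (value < 1) "synergistic" else if (value > 1) "antagonistic" else "additive"
  structure(list(cdi = value, p_value = p_value,
                 n_products = np, n_combo = length(AB),
                 mean_A = mA, mean_B = mB, mean_AB = mAB, call = call),
            class = "cdi_result")
}

#' @export
print.cdi_result <- function(x, ...) {
  cat(sprintf("<cdi_result> CDI = %.4g (%s), p = %s [n_combo = %d, n_products = %d]\n",
              x$cdi, x$call,
              if (is.na(x$p_value)) "NA" else format.pval(x$p_value, digits = 3),
              x$n_combo, x$n_products))
  invisible(x)
}

#' Excess-over-Bliss scoring of a dose-response matrix
#'
#' Scores a two-drug checkerboard of observed fractional inhibition
#' E(d1, d2) in \[0, 1\] against the Bliss independence expectation
#' E_A + E_B - E_A * E_B, taken from the monotherapy margins (the d2 = 0
#' column and d1 = 0 row). The excess over Bliss is
#' eob = observed - expected per cell; positive values indicate synergy.
#' The summary score is 100 x mean(eob) over all cells where both doses
#' are nonzero.
#'
#' @param observed Numeric matrix of observed inhibition with rownames
#'   the drug-1 doses and colnames the drug-2 doses; both margins must
#'   include a zero dose. Values outside \[0, 1\] are clipped (flagged in
#'   the result).
#' @return A list of class `bliss_matrix`: `observed`, `expected`, `eob`
#'   (full matrices), `mean_score` (percent scale), `n_scored`,
#'   `clipped` (count of clipped cells).
#' @export
excess_over_bliss <- function(observed) {
  stopifnot(is.matrix(observed))
  d1 <- as.numeric(rownames(observed))
  d2 <- as.numeric(colnames(observed))
  if (any(is.na(d1)) || any(is.na(d2)))
    stop("dimnames of the matrix must be numeric doses")
  i0 <- which(d1 == 0)
  j0 <- which(d2 == 0)
  if (length(i0) != 1L || length(j0) != 1L)
    stop("monotherapy margins missing: the matrix needs exactly one zero dose per drug")
  clipped <- sum(observed < 0 | observed > 1)
  obs <- pmin(pmax(observed, 0), 1)
  EA <- obs[, j0]           # drug-1 alone, indexed by d1
  EB <- obs[i0, ]           # drug-2 alone, indexed by d2
  expected <- outer(EA, EB, function(a, b) a + b - a * b)
  eob <- obs - expected
  nz <- outer(d1 != 0, d2 != 0, `&`)
  structure(list(observed = obs, expected = expected, eob = eob,
                 mean_score = 100 * mean(eob[nz]), n_scored = sum(nz),
                 clipped = clipped),
            class = "bliss_matrix")
}

#' @export
print.bliss_matrix <- function(x, ...) {
  cat(sprintf("<bliss_matrix> %d x %d grid, mean excess-over-Bliss score = %.3f (x100 scale)\n",
              nrow(x$observed), ncol(x$observed), x$mean_score))
  invisible(x)
}

#' Convert surviving fractions to fractional inhibition
#'
#' E = clip(1 - fraction, 0, 1). Fractions above 1 therefore map to
#' inhibition 0.
#'
#' @param fraction Numeric vector or matrix of surviving fractions.
#' @return Inhibition values on \[0, 1\], same shape.
#' @export
inhibition_from_survival <- function(fraction) {
  pmin(pmax(1 - fraction, 0), 1)
}
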