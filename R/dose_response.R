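#' Construct a single-agent dose-response curve
#'
#' Bundles a drug label with its dose series and fraction-affected (fa)
#' values. The fraction affected is the complement of the surviving
#' fraction: fa = 1 - viability. Replicate measurements at the same dose
#' are allowed; they are averaged at fitting time.
#'
#' @param drug Character label for the agent.
#' @param doses Numeric vector of concentrations, all strictly positive,
#'   in a single consistent unit.
#' @param fa Numeric vector of fraction-affected values in \[0, 1\], one
#'   per dose.
#' @return An object of class `dose_response_curve`.
#' @export
dose_response_curve <- function(drug, doses, fa) {
  stopifnot(is.character(drug), length(drug) == 1L)
  doses <- as.numeric(doses)
  fa <- as.numeric(fa)
  if (length(doses) != length(fa))
    stop("`doses` and `fa` must have the same length")
  if (any(!is.finite(doses)) || any(doses <= 0))
    stop("all doses must be finite and strictly positive")
  if (any(!is.finite(fa)) || any(fa < 0) || any(fa > 1))
    stop("all fa values must be finite and in [0, 1]")
  if (length(unique(doses)) < 2L)
    stop("at least 2 distinct doses are required")
  structure(list(drug = drug, doses = doses, fa = fa),
            class = "dose_response_curve")
}

#' @export
print.dose_response_curve <- function(x, ...) {
  cat(sprintf("<dose_response_curve> %s: %d points, doses %g-%g\n",
              x$drug, length(x$doses), min(x$doses), max(x$doses)))
  invisible(x)
}

# Boundary guard for the log-odds transform: fa of exactly 0 or 1 has no
# finite log-odds, so observed values are pulled just inside the open
# interval before fitting and the affected points flagged.
.FA_EPS <- 1e-4

#' Fit the median-effect model to a dose-response curve
#'
#' Fits the median-effect equation fa/fu = (D/Dm)^m (fu = 1 - fa) by
#' ordinary least squares of log10(fa/(1-fa)) on log10(D). The slope is
#' the sigmoidicity m and the intercept is -m*log10(Dm), so
#' Dm = 10^(-intercept/m). Observed fa outside the open unit interval is
#' clipped to \[1e-4, 1 - 1e-4\] first; replicate fa values at tied doses
#' are averaged before the transform.
#'
#' @param curve A [dose_response_curve()], or a numeric dose vector when
#'   `fa` is supplied directly.
#' @param fa Optional numeric fa vector (used when `curve` is a dose
#'   vector).
#' @return An object of class `median_effect_fit` with elements `m`,
#'   `Dm`, `r` (Pearson correlation of the regression), `n_points`, and
#'   `clipped` (indices of boundary fa values that were clipped).
#' @export
fit_median_effect <- function(curve, fa = NULL) {
  if (!inherits(curve, "dose_response_curve")) {
    curve <- dose_response_curve("drug", curve, fa)
  }
  doses <- curve$doses
  fobs <- curve$fa
  clipped <- which(fobs <= 0 | fobs >= 1)
  fobs <- pmin(pmax(fobs, .FA_EPS), 1 - .FA_EPS)

  # average replicate fa at tied doses before the log transform
  d_avg <- sort(unique(doses))
  f_avg <- vapply(d_avg, function(d) mean(fobs[doses == d]), numeric(1))
  if (length(d_avg) < 2L)
    stop("fewer than 2 distinct doses usable for fitting")
  if (length(unique(f_avg)) < 2L)
    stop("degenerate fit: all fa values identical")

  x <- log10(d_avg)
  y <- log10(f_avg / (1 - f_avg))
  fit <- stats::lm.fit(cbind(1, x), y)
  b <- unname(fit$coefficients)
  m <- b[2L]
  if (!is.finite(m) || m <= 0)
    warning("non-positive median-effect slope; curve is not monotone increasing")
  Dm <- 10^(-b[1L] / m)
  r <- stats::cor(x, y)
  structure(list(m = m, Dm = Dm, r = r, n_points = length(d_avg),
                 clipped = clipped),
            class = "median_effect_fit")
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat(sprintf("<median_effect_fit> m = %.4g, Dm = %.4g, r = %.4f (n = %d)\n",
              x$m, x$Dm, x$r, x$n_points))
  invisible(x)
}

#' Predicted fraction affected at a dose
#'
#' Inverts the fitted median-effect line: fa = 1 / (1 + (Dm/D)^m).
#' Strictly increasing in D for m > 0.
#'
#' @param fit A `median_effect_fit` (or any list with `m` and `Dm`).
#' @param D Numeric vector of doses, all > 0.
#' @return Numeric vector of fraction-affected values in (0, 1).
#' @export
effect_at_dose <- function(fit, D) {
  if (any(!is.finite(D)) || any(D <= 0))
    stop("doses must be finite and strictly positive")
  1 / (1 + (fit$Dm / D)^fit$m)
}

#' Dose required for a given effect level
#'
#' The Dx term of the combination index:
#' Dx = Dm * (fa/(1-fa))^(1/m). Exact inverse of [effect_at_dose()].
#'
#' @param fit A `median_effect_fit`.
#' @param fa Numeric vector of effect levels, each strictly in (0, 1).
#' @return Numeric vector of doses.
#' @export
dose_for_effect <- function(fit, fa) {
  if (any(!is.finite(fa)) || any(fa <= 0) || any(fa >= 1))
    stop("fa must be strictly inside (0, 1)")
  fit$Dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Construct a constant-ratio two-drug combination design
#'
#' In a constant-ratio design the two drugs are co-diluted so that every
#' combination well keeps the same d1:d2 dose ratio (e.g. 1:12.5), and the
#' combination series is indexed by its total dose d1 + d2.
#'
#' @param curve1,curve2 Single-agent [dose_response_curve()]s.
#' @param ratio Length-2 positive numeric vector `c(w1, w2)` or a string
#'   `"w1:w2"` giving the drug1:drug2 dose ratio.
#' @param total_doses Numeric vector of combination total doses (> 0).
#' @param combo_fa Fraction-affected values of the combination series,
#'   aligned to `total_doses`.
#' @return An object of class `constant_ratio_design`.
#' @export
constant_ratio_design <- function(curve1, curve2, ratio, total_doses, combo_fa) {
  stopifnot(inherits(curve1, "dose_response_curve"),
            inherits(curve2, "dose_response_curve"))
  ratio <- parse_ratio(ratio)
  if (length(total_doses) != length(combo_fa))
    stop("`total_doses` and `combo_fa` must have the same length")
  if (any(total_doses <= 0)) stop("total doses must be > 0")
  if (any(combo_fa < 0 | combo_fa > 1)) stop("combo fa must lie in [0, 1]")
  w <- ratio / sum(ratio)
  structure(list(curve1 = curve1, curve2 = curve2, ratio = ratio,
                 weights = w, total_doses = as.numeric(total_doses),
                 combo_fa = as.numeric(combo_fa)),
            class = "constant_ratio_design")
}

#' Parse a drug-dose ratio
#'
#' @param ratio Length-2 positive numeric vector or a `"a:b"` string.
#' @return Length-2 numeric vector.
#' @export
parse_ratio <- function(ratio) {
  if (is.character(ratio)) {
    parts <- strsplit(ratio, ":", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("ratio string must look like 'a:b'")
    ratio <- as.numeric(parts)
  }
  ratio <- as.numeric(ratio)
  if (length(ratio) != 2L || any(!is.finite(ratio)) || any(ratio <= 0))
    stop("ratio must be two positive numbers")
  ratio
}

#' Combination-index profile for a constant-ratio design
#'
#' Fits the two single agents and the combination series (over total
#' dose) with the median-effect model, then computes the mutually
#' exclusive two-term combination index at each effect level:
#' CI(fa) = D1/Dx1(fa) + D2/Dx2(fa), where (D1, D2) split the total
#' combination dose producing fa by the design ratio and Dx_i is the
#' single-agent dose producing the same fa. CI < 1 indicates synergy,
#' CI = 1 additivity and CI > 1 antagonism. Entries are produced at each
#' experimental combination point's fitted fa and at ED50/ED75/ED90.
#'
#' @param design A [constant_ratio_design()].
#' @param ed_levels Effect levels for the summary CI (default 0.50, 0.75,
#'   0.90).
#' @return An object of class `ci_profile`: a list with `entries`
#'   (data.frame of fa, total_dose, D1, D2, Dx1, Dx2, CI), `summary_CI`
#'   (named CI at the ED levels), and the three fits.
#' @export
combination_index <- function(design, ed_levels = c(0.50, 0.75, 0.90)) {
  stopifnot(inherits(design, "constant_ratio_design"))
  fit1 <- tryCatch(fit_median_effect(design$curve1),
                   error = function(e) stop("single-agent series '", design$curve1$drug,
                                            "' failed to fit: ", conditionMessage(e)))
  fit2 <- tryCatch(fit_median_effect(design$curve2),
                   error = function(e) stop("single-agent series '", design$curve2$drug,
                                            "' failed to fit: ", conditionMessage(e)))
  combo_curve <- dose_response_curve("combination", design$total_doses, design$combo_fa)
  fitc <- tryCatch(fit_median_effect(combo_curve),
                   error = function(e) stop("combination series failed to fit: ",
                                            conditionMessage(e)))
  w <- design$weights

  ci_at <- function(fa) {
    total <- dose_for_effect(fitc, fa)
    D1 <- total * w[1L]
    D2 <- total * w[2L]
    Dx1 <- dose_for_effect(fit1, fa)
    Dx2 <- dose_for_effect(fit2, fa)
    data.frame(fa = fa, total_dose = total, D1 = D1, D2 = D2,
               Dx1 = Dx1, Dx2 = Dx2, CI = D1 / Dx1 + D2 / Dx2)
  }

  # fitted fa at the experimental combination points, then the ED levels
  fa_pts <- effect_at_dose(fitc, design$total_doses)
  fa_pts <- fa_pts[fa_pts > 0 & fa_pts < 1]
  entries <- do.call(rbind, lapply(c(fa_pts, ed_levels), ci_at))
  entries$at_ed <- c(rep(FALSE, length(fa_pts)), rep(TRUE, length(ed_levels)))
  summary_CI <- entries$CI[entries$at_ed]
  names(summary_CI) <- sprintf("ED%d", round(100 * ed_levels))
  structure(list(entries = entries, summary_CI = summary_CI,
                 fit1 = fit1, fit2 = fit2, fit_combo = fitc,
                 ratio = design$ratio),
            class = "ci_profile")
}

#' @export
print.ci_profile <- function(x, ...) {
  cat("<ci_profile>\n  summary CI: ",
      paste(sprintf("%s = %.3f", names(x$summary_CI), x$summary_CI),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
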