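#' Relative mRNA abundance from a Ct timecourse (delta-Ct)
#'
#' Converts qPCR cycle-threshold values measured over a
#' transcription-shutoff (actinomycin D) timecourse into abundances
#' relative to time 0: abundance(t) = efficiency^(Ct(0) - Ct(t)), so one
#' extra cycle at perfect doubling (efficiency 2) halves the abundance.
#' No housekeeping normalization is applied; only within-gene Ct
#' differences matter.
#'
#' @param times Numeric vector of hours, strictly increasing, including 0.
#' @param ct Numeric vector of Ct values (cycles), same length.
#' @param efficiency Per-cycle amplification factor (default 2, perfect
#'   doubling).
#' @return Numeric vector of relative abundances (1 at t = 0), with
#'   attribute `flagged_increase` marking time points whose abundance
#'   exceeds 1.
#' @export
relative_abundance <- function(times, ct, efficiency = 2) {
  times <- as.numeric(times); ct <- as.numeric(ct)
  if (length(times) != length(ct)) stop("times and ct must match in length")
  if (any(!is.finite(times)) || any(!is.finite(ct)))
    stop("times and ct must be finite")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (times[1L] != 0) stop("timecourse must include time 0 as its first point")
  ab <- efficiency^(ct[1L] - ct)
  attr(ab, "flagged_increase") <- which(ab > 1 & times > 0)
  ab
}

#' Fit a first-order decay to relative abundances
#'
#' Least squares of ln(abundance) on time with an unconstrained
#' intercept; the decay constant is k = -slope (per hour) and the
#' half-life is ln(2)/k. A non-positive k (no measurable decay) yields an
#' infinite half-life with a warning.
#'
#' @param times Numeric vector of hours (>= 3 points).
#' @param abundance Strictly positive relative abundances.
#' @return A list of class `decay_fit`: `k`, `half_life` (hours), `r2`,
#'   `intercept` (ln scale), `n_points`.
#' @export
fit_decay <- function(times, abundance) {
  times <- as.numeric(times); abundance <- as.numeric(abundance)
  if (length(times) != length(abundance))
    stop("times and abundance must match in length")
  if (length(times) < 3L) stop("need >= 3 time points to fit decay")
  if (any(abundance <= 0)) stop("abundances must be strictly positive")
  y <- log(abundance)
  fit <- stats::lm.fit(cbind(1, times), y)
  b <- unname(fit$coefficients)
  k <- -b[2L]
  if (k <= 0) {
    warning("non-positive decay constant; half-life reported as infinite")
    half_life <- Inf
  } else {
    half_life <- log(2) / k
  }
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(k = k, half_life = half_life, r2 = r2,
                 intercept = b[1L], n_points = length(times)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> k = %.4g /h, half-life = %.4g h, r2 = %.4f (n = %d)\n",
              x$k, x$half_life, x$r2, x$n_points))
  invisible(x)
}

#' Fit decay per gene and condition from a Ct table
#'
#' Replicate Ct values at the same (gene, condition, time) are averaged
#' before the delta-Ct transform, then [relative_abundance()] and
#' [fit_decay()] are applied per gene x condition series.
#'
#' @param ct_table Data.frame with columns `gene`, `condition`, `time`,
#'   `ct` (and optionally `replicate`).
#' @param efficiency Amplification efficiency passed through.
#' @return Data.frame with one row per gene x condition: `k`,
#'   `half_life`, `r2`, `n_points`.
#' @export
fit_decay_table <- function(ct_table, efficiency = 2) {
  stopifnot(is.data.frame(ct_table),
            all(c("gene", "condition", "time", "ct") %in% names(ct_table)))
  agg <- stats::aggregate(ct ~ gene + condition + time, data = ct_table, FUN = mean)
  keys <- unique(agg[, c("gene", "condition")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- agg[agg$gene == keys$gene[i] & agg$condition == keys$condition[i], ]
    sub <- sub[order(sub$time), ]
    ab <- relative_abundance(sub$time, sub$ct, efficiency = efficiency)
    f <- withCallingHandlers(fit_decay(sub$time, ab),
                             warning = function(w) invokeRestart("muffleWarning"))
    data.frame(gene = keys$gene[i], condition = keys$condition[i],
               k = f$k, half_life = f$half_life, r2 = f$r2,
               n_points = f$n_points, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Half-life ratios against a reference condition
#'
#' For each gene, divides every condition's half-life by the reference
#' condition's half-life. Infinite or undefined half-lives propagate as
#' `NA` ratios with a flag.
#'
#' @param fits Data.frame from [fit_decay_table()] (columns `gene`,
#'   `condition`, `half_life`).
#' @param reference Reference condition label.
#' @return `fits` with added columns `ratio_vs_reference` and
#'   `ratio_flagged` (TRUE where the ratio is not a finite number).
#' @export
compare_stability <- function(fits, reference) {
  stopifnot(is.data.frame(fits),
            all(c("gene", "condition", "half_life") %in% names(fits)))
  if (!reference %in% fits$condition)
    stop("reference condition '", reference, "' absent from fits")
  ref <- fits[fits$condition == reference, c("gene", "half_life")]
  names(ref)[2L] <- "hl_ref"
  out <- merge(fits, ref, by = "gene", all.x = TRUE, sort = FALSE)
  ratio <- out$half_life / out$hl_ref
  # a ratio involving an infinite (non-decaying) half-life is undefined,
  # including the finite/Inf case where division alone would give 0
  flagged <- !is.finite(ratio) | !is.finite(out$half_life) |
    !is.finite(out$hl_ref)
  ratio[flagged] <- NA_real_
  out$ratio_vs_reference <- ratio
  out$ratio_flagged <- flagged
  out$hl_ref <- NULL
  out
}
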