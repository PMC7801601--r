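#' Per-gene condition means of an expression table
#'
#' Averages replicate expression values (FPKM-like, non-negative) within
#' each condition. The four-condition layout of a two-drug transcriptome
#' experiment is expected: vehicle (`DMSO`), each single drug (`drugA`,
#' `drugB`) and the combination (`combo`), but any label set can be
#' supplied via `required`.
#'
#' @param expr Numeric matrix, genes x samples, rownames = gene ids,
#'   colnames = sample ids. No negative values; gene ids unique.
#' @param sheet Data.frame with columns `sample`, `condition`,
#'   `replicate` describing the columns of `expr`.
#' @param required Condition labels that must all be present (default
#'   the four-condition design).
#' @return Numeric matrix genes x conditions of means, with attribute
#'   `n_rep` (named replicate counts).
#' @export
summarize_conditions <- function(expr, sheet,
                                 required = c("DMSO", "drugA", "drugB", "combo")) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (any(expr < 0)) stop("expression values must be non-negative")
  if (anyDuplicated(rownames(expr))) stop("gene ids must be unique")
  stopifnot(is.data.frame(sheet),
            all(c("sample", "condition") %in% names(sheet)))
  if (!all(sheet$sample %in% colnames(expr)))
    stop("sample sheet lists samples absent from the expression matrix")
  missing_cond <- setdiff(required, sheet$condition)
  if (length(missing_cond))
    stop("missing condition(s): ", paste(missing_cond, collapse = ", "))
  conds <- unique(as.character(sheet$condition))
  means <- vapply(conds, function(cc) {
    cols <- sheet$sample[sheet$condition == cc]
    rowMeans(expr[, cols, drop = FALSE])
  }, numeric(nrow(expr)))
  rownames(means) <- rownames(expr)
  attr(means, "n_rep") <- vapply(conds, function(cc)
    sum(sheet$condition == cc), integer(1))
  means
}

#' Call synergistically regulated genes from four-condition means
#'
#' Per gene, the vehicle-referenced deltas are A = mean_A - mean_DMSO,
#' B = mean_B - mean_DMSO and C = mean_combo - mean_DMSO, and the synergy
#' ratio is C/(A + B). A gene is called synergistically up-regulated when
#' ratio >= 1.25 and the combination mean exceeds the vehicle mean, and
#' synergistically down-regulated when ratio >= 1.25 and the combination
#' mean is below the vehicle mean (the threshold is inclusive). When
#' |A + B| is numerically zero the ratio, and hence the class, is
#' undefined. If a significance mask is supplied (e.g. from an external
#' differential-expression analysis), unflagged genes are classed
#' `"none"` without evaluating the rule.
#'
#' @param means Genes x conditions matrix from [summarize_conditions()].
#' @param significance_mask Optional logical vector (named by gene, or in
#'   row order) restricting classification to flagged genes.
#' @param ratio_threshold Inclusive synergy-ratio threshold (default 1.25).
#' @param conditions Named character vector mapping the roles `vehicle`,
#'   `drug_a`, `drug_b`, `combo` to column names of `means`.
#' @param eps Denominators with |A + B| < `eps` give an undefined ratio.
#' @return Data.frame of class `gene_synergy_records`: one row per gene
#'   with the condition means, `A`, `B`, `C`, `ratio` and
#'   `class` in `{"up", "down", "none", "undefined"}`.
#' @export
call_synergy_genes <- function(means, significance_mask = NULL,
                               ratio_threshold = 1.25,
                               conditions = c(vehicle = "DMSO", drug_a = "drugA",
                                              drug_b = "drugB", combo = "combo"),
                               eps = 1e-9) {
  stopifnot(is.matrix(means))
  need <- unname(conditions[c("vehicle", "drug_a", "drug_b", "combo")])
  if (!all(need %in% colnames(means)))
    stop("missing condition column(s): ",
         paste(setdiff(need, colnames(means)), collapse = ", "))
  m0 <- means[, conditions[["vehicle"]]]
  mA <- means[, conditions[["drug_a"]]]
  mB <- means[, conditions[["drug_b"]]]
  mC <- means[, conditions[["combo"]]]
  A <- mA - m0
  B <- mB - m0
  C <- mC - m0
  denom <- A + B
  ratio <- ifelse(abs(denom) < eps, NA_real_, C / denom)

  cls <- rep("none", nrow(means))
  cls[abs(denom) < eps] <- "undefined"
  defined <- !is.na(ratio)
  up <- defined & ratio >= ratio_threshold & mC > m0
  dn <- defined & ratio >= ratio_threshold & mC < m0
  cls[up] <- "up"
  cls[dn] <- "down"

  if (!is.null(significance_mask)) {
    mask <- significance_mask
    if (!is.null(names(mask))) {
      if (!all(rownames(means) %in% names(mask)))
        stop("significance mask does not cover all genes")
      mask <- mask[rownames(means)]
    }
    stopifnot(is.logical(mask), length(mask) == nrow(means))
    cls[!mask & cls %in% c("up", "down")] <- "none"
  }

  out <- data.frame(gene = rownames(means), mean_DMSO = m0, mean_A = mA,
                    mean_B = mB, mean_combo = mC, A = A, B = B, C = C,
                    ratio = ratio, class = cls,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("gene_synergy_records", "data.frame")
  out
}

#' Per-gene Welch-test significance mask
#'
#' A built-in stand-in for an external differential-expression result:
#' each non-vehicle condition is compared against vehicle with a Welch
#' t-test per gene, the minimum p-value per gene is Benjamini-Hochberg
#' adjusted across genes, and genes passing `alpha` are flagged. This is
#' a convenience filter, not a replacement for a dedicated
#' differential-expression pipeline; it requires >= 2 replicates per
#' condition.
#'
#' @param expr,sheet As in [summarize_conditions()].
#' @param alpha Adjusted-p cutoff (default 0.005).
#' @param vehicle Vehicle condition label.
#' @return Named logical vector over genes.
#' @export
welch_significance_mask <- function(expr, sheet, alpha = 0.005,
                                    vehicle = "DMSO") {
  conds <- setdiff(unique(sheet$condition), vehicle)
  v_cols <- sheet$sample[sheet$condition == vehicle]
  if (length(v_cols) < 2L) stop("need >= 2 vehicle replicates")
  pmin_gene <- rep(1, nrow(expr))
  for (cc in conds) {
    cols <- sheet$sample[sheet$condition == cc]
    if (length(cols) < 2L) stop("need >= 2 replicates in condition '", cc, "'")
    p <- vapply(seq_len(nrow(expr)), function(i) {
      x <- expr[i, cols]; y <- expr[i, v_cols]
      if (stats::sd(x) == 0 && stats::sd(y) == 0) return(1)
      stats::t.test(x, y)$p.value
    }, numeric(1))
    pmin_gene <- pmin(pmin_gene, p)
  }
  q <- stats::p.adjust(pmin_gene, method = "BH")
  stats::setNames(q <= alpha, rownames(expr))
}

#' Overlap of called synergy genes with a gene set
#'
#' Intersects the genes called in the requested classes with a reference
#' gene set (ids case-normalized to upper case) and computes an
#' upper-tail hypergeometric enrichment p-value with the classified gene
#' universe as background.
#'
#' @param records A `gene_synergy_records` data.frame.
#' @param gene_set Character vector of gene ids (non-empty).
#' @param classes Classes counted as "called" (default `"up"`).
#' @return A list of class `gene_set_overlap`: `universe_size`,
#'   `n_called`, `n_set` (set members within the universe),
#'   `overlap`, `overlap_genes`, `p_value`.
#' @export
intersect_gene_set <- function(records, gene_set, classes = "up") {
  stopifnot(is.data.frame(records),
            all(c("gene", "class") %in% names(records)))
  if (length(gene_set) == 0L) stop("empty gene set")
  universe <- toupper(records$gene)
  called <- toupper(records$gene[records$class %in% classes])
  set_in <- intersect(toupper(gene_set), universe)
  hit <- intersect(called, set_in)
  N <- length(universe); K <- length(set_in); n <- length(called)
  k <- length(hit)
  # upper tail P(X >= k), X ~ Hypergeometric(N, K, n)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(list(universe_size = N, n_called = n, n_set = K,
                 overlap = k, overlap_genes = sort(hit), p_value = p),
            class = "gene_set_overlap")
}

#' @export
print.gene_set_overlap <- function(x, ...) {
  cat(sprintf("<gene_set_overlap> %d of %d set genes among %d called (universe %d), p = %s\n",
              x$overlap, x$n_set, x$n_called, x$universe_size,
              format.pval(x$p_value, digits = 3)))
  invisible(x)
}

#' Genetic-dependence contrast between two synergy-gene call sets
#'
#' Partitions the genes called in a given direction in the control
#' experiment by whether the call survives in a perturbed (e.g.
#' regulator-knockdown) experiment: `dependent` genes lose the call,
#' `independent` genes keep it. Both record sets must cover the same
#' gene universe.
#'
#' @param records_control,records_knockdown `gene_synergy_records` from
#'   the two experiments.
#' @param direction `"up"` or `"down"`.
#' @return A list of class `dependence_partition`: `dependent`,
#'   `independent` (gene id vectors), `n_control_called`, `n_dependent`,
#'   `n_independent`.
#' @export
p53_dependence <- function(records_control, records_knockdown,
                           direction = c("up", "down")) {
  direction <- match.arg(direction)
  gc <- toupper(records_control$gene)
  gk <- toupper(records_knockdown$gene)
  if (!setequal(gc, gk)) {
    miss <- c(setdiff(gc, gk), setdiff(gk, gc))
    stop("gene universes differ between experiments; e.g.: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  called_c <- gc[records_control$class == direction]
  called_k <- gk[records_knockdown$class == direction]
  dependent <- sort(setdiff(called_c, called_k))
  independent <- sort(intersect(called_c, called_k))
  structure(list(direction = direction, dependent = dependent,
                 independent = independent,
                 n_control_called = length(called_c),
                 n_dependent = length(dependent),
                 n_independent = length(independent)),
            class = "dependence_partition")
}

#' @export
print.dependence_partition <- function(x, ...) {
  cat(sprintf("<dependence_partition> %s: %d called in control; %d dependent, %d independent\n",
              x$direction, x$n_control_called, x$n_dependent, x$n_independent))
  invisible(x)
}
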