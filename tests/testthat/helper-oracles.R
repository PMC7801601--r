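# Independent brute-force oracles used to cross-check the package's
# interval and combinatorial machinery. These deliberately avoid the
# implementations under test: intervals are checked base by base on
# explicit per-base arrays, and the hypergeometric tail is summed term
# by term from binomial coefficients.

# per-base replicate support -> maximal runs with support >= k
# (0-based half-open coordinates throughout)
oracle_consensus <- function(peaksets, k) {
  chroms <- sort(unique(unlist(lapply(peaksets, function(p) p$chrom))))
  out <- list()
  for (ch in chroms) {
    L <- max(unlist(lapply(peaksets, function(p) {
      sub <- p$end[p$chrom == ch]
      if (length(sub)) max(sub) else 0
    })))
    support <- integer(L)
    for (p in peaksets) {
      sub <- p[p$chrom == ch, , drop = FALSE]
      mask <- logical(L)
      for (i in seq_len(nrow(sub)))
        mask[(sub$start[i] + 1):sub$end[i]] <- TRUE
      support <- support + mask
    }
    r <- rle(support >= k)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep))
      out[[ch]] <- data.frame(chrom = ch, start = starts[keep],
                              end = ends[keep], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# union length by counting marked bases
oracle_coverage_bp <- function(ps) {
  total <- 0
  for (ch in unique(ps$chrom)) {
    sub <- ps[ps$chrom == ch, , drop = FALSE]
    mask <- logical(max(sub$end))
    for (i in seq_len(nrow(sub)))
      mask[(sub$start[i] + 1):sub$end[i]] <- TRUE
    total <- total + sum(mask)
  }
  total
}

# half-open interval overlap
ivl_overlaps <- function(a1, a2, b1, b2) a1 < b2 && b1 < a2

# exhaustive pairwise peak-vs-gene annotation
oracle_annotate <- function(ps, genes, window) {
  vapply(seq_len(nrow(ps)), function(i) {
    lab <- "intergenic"
    for (j in seq_len(nrow(genes))) {
      if (ps$chrom[i] != genes$chrom[j]) next
      if (ivl_overlaps(ps$start[i], ps$end[i],
                       genes$body_start[j], genes$body_end[j]))
        lab <- if (lab == "promoter") lab else "genic"
      if (ivl_overlaps(ps$start[i], ps$end[i],
                       max(genes$tss[j] - window, 0), genes$tss[j] + window + 1))
        lab <- "promoter"
    }
    lab
  }, character(1))
}

# exhaustive pairwise bound/unbound per gene x condition
oracle_binding <- function(consensus_by_condition, genes, window) {
  sapply(consensus_by_condition, function(ps) {
    vapply(seq_len(nrow(genes)), function(j) {
      s <- max(genes$body_start[j] - window, 0)
      e <- genes$body_end[j] + window
      any(vapply(seq_len(nrow(ps)), function(i) {
        ps$chrom[i] == genes$chrom[j] &&
          ivl_overlaps(ps$start[i], ps$end[i], s, e)
      }, logical(1)))
    }, logical(1))
  })
}

# upper-tail hypergeometric P(X >= k) by direct summation
oracle_hyper_upper <- function(k, N, K, n) {
  js <- seq(k, min(K, n))
  if (!length(js) || k > min(K, n)) return(if (k <= 0) 1 else 0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# independent Loewe-additive combination response for two median-effect
# drugs, via stats::uniroot rather than the package's bisection
oracle_loewe_fa <- function(d1, d2, m1, Dm1, m2, Dm2) {
  dx <- function(m, Dm, fa) Dm * (fa / (1 - fa))^(1 / m)
  g <- function(fa) d1 / dx(m1, Dm1, fa) + d2 / dx(m2, Dm2, fa) - 1
  stats::uniroot(g, c(1e-10, 1 - 1e-10), tol = 1e-12)$root
}
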