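#' Peak sets and interval conventions
#'
#' All peak coordinates in this package are 0-based half-open
#' (BED convention): a peak `[start, end)` covers bases `start` to
#' `end - 1`. Peak-caller outputs vary in convention, so inputs are
#' normalized to this representation on construction and only converted
#' to the 1-based closed convention internally when handed to
#' GenomicRanges. Peaks are strandless; strand matters only for placing
#' a gene's TSS.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer-valued coordinates with 0 <= start < end.
#' @param replicate,condition Optional labels recorded as attributes.
#' @return A `data.frame` of class `peak_set`, sorted by (chrom, start).
#' @export
peak_set <- function(chrom, start, end, replicate = NA_character_,
                     condition = NA_character_) {
  chrom <- as.character(chrom)
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(chrom) != length(start) || length(start) != length(end))
    stop("chrom, start, end must have equal lengths")
  if (any(!is.finite(start)) || any(!is.finite(end)) ||
      any(start < 0) || any(start >= end))
    stop("intervals must satisfy 0 <= start < end")
  o <- order(chrom, start, end)
  out <- data.frame(chrom = chrom[o], start = start[o], end = end[o],
                    stringsAsFactors = FALSE)
  attr(out, "replicate") <- replicate
  attr(out, "condition") <- condition
  class(out) <- c("peak_set", "data.frame")
  out
}

# BED half-open [start, end) -> GRanges 1-based closed [start+1, end]
peaks_to_granges <- function(ps, seqlengths = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = ps$chrom,
    ranges = IRanges::IRanges(start = ps$start + 1L, end = ps$end))
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}

granges_to_peaks <- function(gr) {
  peak_set(chrom = as.character(GenomicRanges::seqnames(gr)),
           start = GenomicRanges::start(gr) - 1L,
           end = GenomicRanges::end(gr))
}

# common seqlengths across peak sets: max end per chromosome
common_seqlengths <- function(peaksets) {
  all <- do.call(rbind, lapply(peaksets, function(p) p[, c("chrom", "end")]))
  sl <- vapply(split(all$end, all$chrom), max, numeric(1))
  sl[sort(names(sl))]
}

#' Replicate-consensus peaks
#'
#' Returns the maximal intervals covered by at least `min_support` of the
#' supplied replicate peak sets, computed per chromosome by base-level
#' support: within each replicate, overlapping peaks are first merged so
#' a replicate contributes at most 1 to the support of any base, then
#' bases with summed support >= `min_support` are sliced into maximal
#' runs. With `min_support = 1` this is the union; with
#' `min_support = length(peaksets)` it equals the overlap-based
#' intersection of all replicates.
#'
#' @param peaksets List of [peak_set()]s (one per replicate).
#' @param min_support Minimum number of replicates that must cover a
#'   base (k of "present in k of n replicates").
#' @return A [peak_set()] of non-overlapping sorted consensus intervals.
#' @export
consensus_peaks <- function(peaksets, min_support) {
  stopifnot(is.list(peaksets), length(peaksets) >= 1L)
  min_support <- as.integer(min_support)
  if (min_support < 1L) stop("min_support must be >= 1")
  if (min_support > length(peaksets))
    stop("min_support (", min_support, ") exceeds the number of peak sets (",
         length(peaksets), ")")
  nonempty <- peaksets[vapply(peaksets, nrow, integer(1)) > 0L]
  if (length(nonempty) < min_support)
    return(peak_set(character(0), numeric(0), numeric(0)))
  sl <- common_seqlengths(nonempty)
  covs <- lapply(nonempty, function(p)
    GenomicRanges::coverage(GenomicRanges::reduce(peaks_to_granges(p, sl))))
  total <- Reduce(`+`, covs)
  hits <- IRanges::slice(total, lower = min_support, rangesOnly = TRUE)
  chrom <- rep(names(hits), lengths(hits))
  ir <- unlist(hits, use.names = FALSE)
  if (length(ir) == 0L)
    return(peak_set(character(0), numeric(0), numeric(0)))
  peak_set(chrom = chrom, start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Total base pairs covered by a peak set
#'
#' Length of the union of the intervals (overlaps counted once).
#'
#' @param ps A [peak_set()].
#' @return Single numeric base-pair count.
#' @export
merged_coverage_bp <- function(ps) {
  if (nrow(ps) == 0L) return(0)
  sum(as.numeric(GenomicRanges::width(
    GenomicRanges::reduce(peaks_to_granges(ps)))))
}

#' Construct a gene annotation table
#'
#' Minimal gene models for peak annotation: per gene a chromosome,
#' strand, TSS position and gene-body extent, all in the package's
#' 0-based coordinate system (the TSS is the 0-based position of the
#' first transcribed base; body `[body_start, body_end)` half-open).
#'
#' @param gene_id,chrom Character vectors.
#' @param strand `"+"` or `"-"` per gene.
#' @param tss,body_start,body_end Numeric coordinates with
#'   body_start < body_end.
#' @return A `data.frame` of class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id, chrom, strand, tss, body_start, body_end) {
  stopifnot(all(strand %in% c("+", "-")),
            all(body_start < body_end))
  if (anyDuplicated(gene_id)) stop("gene ids must be unique")
  out <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                    strand = as.character(strand), tss = as.numeric(tss),
                    body_start = as.numeric(body_start),
                    body_end = as.numeric(body_end),
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_annotation", "data.frame")
  out
}

#' Annotate peaks against gene models
#'
#' Labels each peak `"promoter"` if it overlaps any window of
#' +/- `promoter_window` bp around a TSS, otherwise `"genic"` if it
#' overlaps any gene body, otherwise `"intergenic"` (promoter takes
#' precedence over genic). Peaks on chromosomes absent from the
#' annotation are labelled intergenic with a warning.
#'
#' @param ps A [peak_set()].
#' @param genes A [gene_annotation()] table.
#' @param promoter_window Half-width of the TSS window in bp
#'   (default 2000).
#' @return A list of class `peak_annotation`: `labels` (per-peak
#'   character vector aligned to `ps`), `counts` and `fractions` (named
#'   by category).
#' @export
annotate_peaks <- function(ps, genes, promoter_window = 2000) {
  stopifnot(inherits(ps, "data.frame"), inherits(genes, "data.frame"))
  cats <- c("promoter", "genic", "intergenic")
  labels <- rep("intergenic", nrow(ps))
  if (nrow(ps) > 0L && nrow(genes) > 0L) {
    unknown <- !(ps$chrom %in% genes$chrom)
    if (any(unknown))
      warning(sum(unknown), " peak(s) on chromosomes absent from the annotation; ",
              "labelled intergenic")
    pk <- peaks_to_granges(ps)
    # promoter windows: TSS base +/- window, clamped at the chromosome start
    prom <- GenomicRanges::GRanges(
      seqnames = genes$chrom,
      ranges = IRanges::IRanges(start = pmax(genes$tss - promoter_window, 0) + 1L,
                                end = genes$tss + promoter_window + 1L))
    body <- GenomicRanges::GRanges(
      seqnames = genes$chrom,
      ranges = IRanges::IRanges(start = genes$body_start + 1L,
                                end = genes$body_end))
    # seqlevel mismatches are expected (peaks on unannotated chromosomes
    # were warned about above), so silence the GenomicRanges notice
    in_body <- suppressWarnings(IRanges::overlapsAny(pk, body))
    in_prom <- suppressWarnings(IRanges::overlapsAny(pk, prom))
    labels[in_body] <- "genic"
    labels[in_prom] <- "promoter"
  }
  counts <- vapply(cats, function(cc) sum(labels == cc), integer(1))
  fractions <- if (nrow(ps) > 0L) counts / nrow(ps) else counts * NA_real_
  structure(list(labels = labels, counts = counts, fractions = fractions,
                 promoter_window = promoter_window),
            class = "peak_annotation")
}

#' @export
print.peak_annotation <- function(x, ...) {
  cat("<peak_annotation> ",
      paste(sprintf("%s: %d (%.1f%%)", names(x$counts), x$counts,
                    100 * x$fractions), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Gene-level binding matrix across conditions
#'
#' For each gene and condition, the gene is called bound when any
#' consensus peak of that condition overlaps the gene body extended by
#' `window` bp on both sides. Genes requested but absent from the
#' annotation get an `NA` row and are listed in the `missing` element.
#'
#' @param consensus_by_condition Named list of [peak_set()]s, one
#'   consensus set per condition.
#' @param genes A [gene_annotation()] table.
#' @param gene_ids Genes of interest (default: all annotated genes).
#' @param window Flanking window in bp added to each gene body
#'   (default 5000).
#' @return A list of class `binding_matrix`: `bound` (logical genes x
#'   conditions matrix), `n_bound` (per-condition counts over
#'   non-missing genes), `window`, `missing`.
#' @export
gene_binding_matrix <- function(consensus_by_condition, genes,
                                gene_ids = NULL, window = 5000) {
  stopifnot(is.list(consensus_by_condition),
            !is.null(names(consensus_by_condition)))
  if (is.null(gene_ids)) gene_ids <- genes$gene_id
  missing <- setdiff(gene_ids, genes$gene_id)
  ann <- genes[match(gene_ids, genes$gene_id), , drop = FALSE]
  present <- !is.na(ann$gene_id)
  targets <- GenomicRanges::GRanges(
    seqnames = ann$chrom[present],
    ranges = IRanges::IRanges(
      start = pmax(ann$body_start[present] - window, 0) + 1L,
      end = ann$body_end[present] + window))
  bound <- matrix(NA, nrow = length(gene_ids),
                  ncol = length(consensus_by_condition),
                  dimnames = list(gene_ids, names(consensus_by_condition)))
  for (cc in names(consensus_by_condition)) {
    ps <- consensus_by_condition[[cc]]
    hit <- if (nrow(ps) == 0L) rep(FALSE, sum(present)) else
      IRanges::overlapsAny(targets, peaks_to_granges(ps))
    bound[present, cc] <- hit
  }
  n_bound <- colSums(bound[present, , drop = FALSE])
  structure(list(bound = bound, n_bound = n_bound, window = window,
                 missing = missing),
            class = "binding_matrix")
}

#' @export
print.binding_matrix <- function(x, ...) {
  cat("<binding_matrix> ", nrow(x$bound), " genes x ", ncol(x$bound),
      " conditions; bound per condition: ",
      paste(sprintf("%s = %d", names(x$n_bound), x$n_bound), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
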