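#' File input/output
#'
#' Readers for the plain-text formats the pipeline consumes (TSV tables,
#' newline-delimited gene sets, BED intervals) and matching writers.
#' BED files are read and written through rtracklayer, preserving the
#' 0-based half-open coordinates exactly.
#'
#' @name io
NULL

read_tsv_checked <- function(path, required) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("file '", path, "' lacks required column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Write a data.frame as TSV
#' @param df Data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read single-agent dose-response series
#'
#' Expects columns `drug`, `dose`, `response` (and optionally
#' `replicate`). The `response` column is either the fraction affected
#' directly or a surviving fraction/viability, declared via `response_is`;
#' viability is converted as fa = 1 - viability.
#'
#' @param path TSV path.
#' @param response_is `"fa"` or `"viability"`.
#' @return Named list of [dose_response_curve()]s, one per drug.
#' @export
read_dose_response_tsv <- function(path, response_is = c("fa", "viability")) {
  response_is <- match.arg(response_is)
  df <- read_tsv_checked(path, c("drug", "dose", "response"))
  fa <- if (response_is == "viability") 1 - df$response else df$response
  drugs <- unique(df$drug)
  out <- lapply(drugs, function(d) {
    sel <- df$drug == d
    dose_response_curve(d, df$dose[sel], fa[sel])
  })
  stats::setNames(out, drugs)
}

#' Read a long-format viability plate
#'
#' Expects columns `condition`, `replicate`, `signal`.
#'
#' @param path TSV path.
#' @return A [viability_plate()].
#' @export
read_plate_tsv <- function(path) {
  df <- read_tsv_checked(path, c("condition", "replicate", "signal"))
  viability_plate(df$condition, df$replicate, df$signal)
}

#' Read a dose-matrix TSV
#'
#' Rows are drug-1 doses (first column), remaining column names are
#' drug-2 doses; cells are observed inhibition (or survival, see
#' `values`).
#'
#' @param path TSV path.
#' @param values `"inhibition"` or `"survival"` (converted via
#'   [inhibition_from_survival()]).
#' @return Numeric matrix with numeric dimnames, suitable for
#'   [excess_over_bliss()].
#' @export
read_bliss_matrix_tsv <- function(path, values = c("inhibition", "survival")) {
  values <- match.arg(values)
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  if (values == "survival") m <- inhibition_from_survival(m)
  m
}

#' Read an expression matrix and its sample sheet
#'
#' The expression TSV has gene ids in its first column and one column
#' per sample; the sheet TSV has columns `sample`, `condition`,
#' `replicate`.
#'
#' @param expr_path,sheet_path TSV paths.
#' @return List with `expr` (numeric matrix) and `sheet`.
#' @export
read_expression_tsv <- function(expr_path, sheet_path) {
  expr <- as.matrix(utils::read.delim(expr_path, row.names = 1,
                                      check.names = FALSE))
  sheet <- read_tsv_checked(sheet_path, c("sample", "condition", "replicate"))
  list(expr = expr, sheet = sheet)
}

#' Read a newline-delimited gene set
#'
#' @param path Text file, one gene id per line; blank lines and lines
#'   starting with `#` are skipped.
#' @return Character vector of gene ids.
#' @export
read_gene_set <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read peaks from a BED file
#'
#' @param path BED3+ path.
#' @param replicate,condition Optional labels attached to the result.
#' @return A [peak_set()] (0-based half-open, as in the file).
#' @export
read_bed <- function(path, replicate = NA_character_, condition = NA_character_) {
  gr <- rtracklayer::import(path, format = "BED")
  peak_set(chrom = as.character(GenomicRanges::seqnames(gr)),
           start = GenomicRanges::start(gr) - 1L,
           end = GenomicRanges::end(gr),
           replicate = replicate, condition = condition)
}

#' Write a peak set to a BED file
#'
#' @param ps A [peak_set()].
#' @param path Output path.
#' @export
write_bed <- function(ps, path) {
  gr <- peaks_to_granges(ps)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a minimal gene-model TSV
#'
#' Expects columns `gene_id`, `chrom`, `strand`, `tss`, `start`, `end`
#' (0-based, body half-open).
#'
#' @param path TSV path.
#' @return A [gene_annotation()].
#' @export
read_gene_model_tsv <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "chrom", "strand", "tss",
                                 "start", "end"))
  gene_annotation(df$gene_id, df$chrom, df$strand, df$tss, df$start, df$end)
}

#' Read a Ct timecourse TSV
#'
#' Expects columns `gene`, `condition`, `time_h`, `ct` (and optionally
#' `replicate`); `time_h` is renamed `time`.
#'
#' @param path TSV path.
#' @return Data.frame usable by [fit_decay_table()].
#' @export
read_ct_tsv <- function(path) {
  df <- read_tsv_checked(path, c("gene", "condition", "time_h", "ct"))
  names(df)[names(df) == "time_h"] <- "time"
  df
}
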