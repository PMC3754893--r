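# Tabular I/O. One dialect throughout: TSV with a header row. All genomic
# intervals are 0-based, half-open. Writers are deterministic: stable sort,
# numbers at 6 significant digits.

format_num <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x == round(x) & abs(x) < 1e15,
                format(x, scientific = FALSE, trim = TRUE),
                formatC(signif(x, 6), format = "g", digits = 6)))
}

#' Write a data.frame as TSV (deterministic formatting)
#'
#' @param df data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- format_num(out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

read_tsv_checked <- function(path, required, numeric_cols = character(),
                             what = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  check_columns(df, required, what)
  for (cl in numeric_cols) df[[cl]] <- as.numeric(df[[cl]])
  df
}

# split off rows failing `ok`; valid rows returned with the rejected rows
# (and reasons) in attribute "rejected"
reject_rows <- function(df, ok, reason) {
  rej <- df[!ok, , drop = FALSE]
  if (nrow(rej)) rej$reason <- reason
  out <- df[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rej
  out
}

#' Read a per-scaffold coverage table
#'
#' Expects columns `scaffold_id`, `chrom`, `start`, `length`, `reads_f`,
#' `reads_m`. Rows with non-positive length or negative counts are not an
#' error: they are removed and reported in the `"rejected"` attribute.
#'
#' @param path TSV file.
#' @return data.frame of valid rows; attribute `rejected` lists bad rows
#'   with a reason.
#' @export
read_coverage_table <- function(path) {
  df <- read_tsv_checked(path, c("scaffold_id", "chrom", "start", "length",
                                 "reads_f", "reads_m"),
                         c("start", "length", "reads_f", "reads_m"),
                         "coverage table")
  ok <- !is.na(df$length) & df$length > 0 &
    !is.na(df$reads_f) & df$reads_f >= 0 &
    !is.na(df$reads_m) & df$reads_m >= 0
  reject_rows(df, ok, "non-positive length or negative count")
}

#' Read a per-gene expression table
#'
#' Expects columns `gene_id`, `chrom`, `pos`, `fpkm_f`, `fpkm_m`; rows
#' with negative FPKM are rejected into the `"rejected"` attribute.
#'
#' @param path TSV file.
#' @return data.frame of valid rows.
#' @export
read_expression_table <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "chrom", "pos", "fpkm_f",
                                 "fpkm_m"),
                         c("pos", "fpkm_f", "fpkm_m"), "expression table")
  ok <- !is.na(df$fpkm_f) & df$fpkm_f >= 0 & !is.na(df$fpkm_m) & df$fpkm_m >= 0
  reject_rows(df, ok, "negative or missing FPKM")
}

#' Read a homology-hit table
#'
#' Expects `query_gene_id`, `scaffold_id`, `reference_chromosome`,
#' `reference_position`, `reference_strand`, `score`; rows with negative
#' position or score are rejected into the `"rejected"` attribute.
#'
#' @param path TSV file.
#' @return data.frame of valid rows.
#' @export
read_hits_table <- function(path) {
  df <- read_tsv_checked(path, c("query_gene_id", "scaffold_id",
                                 "reference_chromosome", "reference_position",
                                 "reference_strand", "score"),
                         c("reference_position", "score"), "hits table")
  ok <- !is.na(df$reference_position) & df$reference_position >= 0 &
    !is.na(df$score) & df$score >= 0
  reject_rows(df, ok, "negative position or score")
}

#' Read a per-site pileup table
#'
#' Expects `gene_id`, `site`, `sex`, `A`, `C`, `G`, `T`.
#'
#' @param path TSV file.
#' @return data.frame of valid rows (negative counts rejected).
#' @export
read_pileup_table <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "site", "sex", "A", "C", "G", "T"),
                         c("site", "A", "C", "G", "T"), "pileup table")
  ok <- !is.na(df$A) & !is.na(df$C) & !is.na(df$G) & !is.na(df$T) &
    df$A >= 0 & df$C >= 0 & df$G >= 0 & df$T >= 0
  reject_rows(df, ok, "negative or missing base count")
}

#' Read an aligned FASTA file as a codon alignment
#'
#' @param path FASTA file of equal-length, in-frame aligned sequences.
#' @param gene_id,class passed to [codon_alignment()].
#' @return a [codon_alignment()].
#' @export
read_fasta_alignment <- function(path, gene_id = sub("\\.[^.]*$", "",
                                                     basename(path)),
                                 class = "autosome") {
  dna <- ape::read.FASTA(path)
  if (!length(dna)) stop("empty FASTA file", call. = FALSE)
  seqs <- vapply(as.character(dna), function(ch)
    paste(toupper(ch), collapse = ""), character(1))
  codon_alignment(seqs, gene_id = gene_id, class = class)
}

#' Write a codon alignment as FASTA
#'
#' @param alignment a [codon_alignment()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(alignment, path) {
  stopifnot(inherits(alignment, "codon_alignment"))
  dna <- ape::as.DNAbin(lapply(alignment$seqs, function(s)
    strsplit(tolower(s), "")[[1]]))
  ape::write.FASTA(dna, path)
  invisible(path)
}

#' Write intervals as a BED-like file
#'
#' 0-based half-open intervals, tab-separated without header, sorted by
#' (chrom, start). Requires `chrom`, `start`, `end`; any further columns
#' are carried through in order.
#'
#' @param records data.frame with at least `chrom`, `start`, `end`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed_like <- function(records, path) {
  check_columns(records, c("chrom", "start", "end"), "BED records")
  if (any(records$start >= records$end))
    stop("BED intervals require start < end", call. = FALSE)
  ord <- order(records$chrom, records$start, records$end)
  out <- records[ord, c("chrom", "start", "end",
                        setdiff(names(records), c("chrom", "start", "end"))),
                 drop = FALSE]
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- format_num(out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a BED-like file
#'
#' @param path file written by [write_bed_like()] (or any headerless BED).
#' @param extra_names names for columns beyond the first three.
#' @return data.frame with `chrom`, `start`, `end` and any extra columns.
#' @export
read_bed_like <- function(path, extra_names = NULL) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  base <- c("chrom", "start", "end")
  n_extra <- ncol(df) - 3L
  if (n_extra < 0) stop("BED-like file needs at least 3 columns", call. = FALSE)
  names(df) <- c(base, if (n_extra > 0) {
    if (!is.null(extra_names) && length(extra_names) == n_extra) extra_names
    else paste0("V", seq_len(n_extra) + 3L)
  })
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  df
}
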