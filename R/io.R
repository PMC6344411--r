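# Readers/writers for the documented external formats: protein FASTA
# (Biostrings), gene coordinate tables (GFF3 via rtracklayer), and plain
# TSV tables (annotations, metadata, homology hits).

#' Protein FASTA I/O
#'
#' @param proteins Named character vector of amino-acid sequences.
#' @param path File path.
#' @return `read_protein_fasta()`: a named character vector.
#' @export
write_protein_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(proteins)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' @rdname write_protein_fasta
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  out <- as.character(aa)
  # FASTA headers may carry descriptions after the identifier.
  names(out) <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L)
  out
}

#' Gene coordinate table I/O (GFF3)
#'
#' Gene tables hold one row per CDS with 1-based inclusive coordinates:
#' `genome_id`, `replicon_id`, `ordinal` (start order within replicon),
#' `start`, `end`, `strand`, `protein_id`, `is_codh`, `pseudo`.  On disk
#' they are GFF3 CDS features whose attributes carry `protein_id`,
#' `genome_id` and the flags.
#'
#' @param genes A gene table data frame.
#' @param path File path.
#' @return `read_gene_table()`: a gene table data frame sorted by replicon
#'   and start, with ordinals recomputed.
#' @export
write_gene_table <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$replicon_id,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "codhscan", type = "CDS", phase = 0L,
    ID = genes$protein_id,
    protein_id = genes$protein_id,
    genome_id = genes$genome_id,
    is_codh = tolower(as.character(genes$is_codh)),
    pseudo = tolower(as.character(genes$pseudo)))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gene_table
#' @export
read_gene_table <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(
    genome_id = as.character(S4Vectors::mcols(gr)$genome_id),
    replicon_id = as.character(GenomicRanges::seqnames(gr)),
    ordinal = NA_integer_,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    protein_id = as.character(S4Vectors::mcols(gr)$protein_id),
    is_codh = .parse_flag(S4Vectors::mcols(gr)$is_codh),
    pseudo = .parse_flag(S4Vectors::mcols(gr)$pseudo),
    stringsAsFactors = FALSE)
  df <- df[order(df$replicon_id, df$start), , drop = FALSE]
  df$ordinal <- stats::ave(df$start, df$replicon_id,
                           FUN = seq_along)
  df$ordinal <- as.integer(df$ordinal)
  rownames(df) <- NULL
  df
}

.parse_flag <- function(x) {
  if (is.null(x)) return(rep(FALSE, 0L))
  tolower(as.character(x)) %in% c("true", "1", "yes")
}

#' Plain TSV I/O
#'
#' @param df A data frame.
#' @param path File path.
#' @return `read_tsv()`: a data frame.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a homology-hit table
#'
#' Accepts BLAST outfmt-6-like TSVs; the columns holding the subject
#' identifier, bit score and subject length are configurable by name.
#'
#' @param path File path.
#' @param subject_col,score_col,length_col Column names.
#' @return A data frame with columns `subject_id`, `bit_score`,
#'   `subject_length`.
#' @export
read_hit_table <- function(path, subject_col = "subject_id",
                           score_col = "bit_score",
                           length_col = "subject_length") {
  df <- read_tsv(path)
  missing <- setdiff(c(subject_col, score_col, length_col), names(df))
  if (length(missing))
    stop("hit table lacks column(s): ", paste(missing, collapse = ", "))
  data.frame(subject_id = as.character(df[[subject_col]]),
             bit_score = as.numeric(df[[score_col]]),
             subject_length = as.integer(df[[length_col]]),
             stringsAsFactors = FALSE)
}
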