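# Dataset curation: hit-quality thresholds, non-redundancy, cluster-region
# completeness, and per-species representative-genome selection.

#' Filter homology hits by score and length
#'
#' Retains a hit iff `bit_score >= min_bit_score` and
#' `subject_length >= min_length` (the printed exclusions are strict
#' "<200" / "<550", so values exactly at a threshold are kept).  Duplicate
#' subject identifiers collapse to one.
#'
#' @param hits Data frame with columns `subject_id`, `bit_score`,
#'   `subject_length` (see [read_hit_table()]).
#' @param min_bit_score Bit-score floor; default 200.
#' @param min_length Subject-length floor in residues; default 550.
#' @return Sorted character vector of retained subject identifiers.
#' @export
filter_hits <- function(hits, min_bit_score = 200, min_length = 550) {
  stopifnot(min_bit_score > 0, min_length > 0)
  keep <- hits$bit_score >= min_bit_score & hits$subject_length >= min_length
  sort(unique(hits$subject_id[keep]))
}

#' Collapse a protein list to one record per identifier
#'
#' Redundancy follows the non-redundant-database model: it is defined by
#' identifier, so two identifiers with identical sequences are both kept,
#' while one identifier listed with conflicting sequences is a
#' data-integrity error.
#'
#' @param proteins Named character vector (id -> sequence); repeated names
#'   allowed.
#' @return Named character vector with unique names, ordered by identifier.
#' @export
deduplicate_proteins <- function(proteins) {
  ids <- names(proteins)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("proteins must carry identifiers")
  split_seq <- split(unname(proteins), ids)
  bad <- names(split_seq)[vapply(split_seq, function(s)
    length(unique(s)) > 1L, logical(1))]
  if (length(bad))
    stop("conflicting sequences under identifier(s): ",
         paste(bad, collapse = ", "))
  out <- vapply(split_seq, `[[`, character(1), 1L)
  out[order(names(out))]
}

#' Filter out queries with deletions at cluster positions
#'
#' A query is retained iff none of the anchor's D-cluster, B-cluster,
#' C-cluster or acid-base positions maps to a gap ("absent") in the query.
#' Substitutions at those positions (non-gap, different residue) are
#' retained -- variant residue states are part of the classification
#' scheme, not a curation failure.
#'
#' @param mapped_positions Named list of `codh_position_map` objects
#'   (from [map_anchor_positions()]), one per query.
#' @return Character vector of retained query names.
#' @export
filter_complete_sequences <- function(mapped_positions) {
  keep <- vapply(mapped_positions, function(pm) {
    !anyNA(c(pm$d_positions, pm$b_cluster, pm$c_cluster, pm$acid_base))
  }, logical(1))
  names(mapped_positions)[keep]
}

#' Select representative genomes per species
#'
#' Within each species, genomes are partitioned by their set of CODH
#' protein identifiers; one genome is kept per distinct set (genomes of
#' the same species are redundant unless they encode different CODH
#' accessions).  The survivor is chosen by assembly priority
#' reference > representative > complete level > any other level, with
#' ties broken by lexicographically smallest `genome_id`.
#'
#' @param metadata Data frame with columns `genome_id`, `species`,
#'   `assembly_category` (`reference`/`representative`/`na`),
#'   `assembly_level` (`complete`/`chromosome`/`scaffold`/`contig`), and a
#'   list-column or separator-delimited column `codh_protein_ids`.
#' @param codh_ids Optional named list genome_id -> character vector of
#'   CODH protein ids, overriding the metadata column.
#' @return Sorted character vector of retained genome ids.
#' @export
select_representative_genomes <- function(metadata, codh_ids = NULL) {
  if (is.null(codh_ids)) {
    raw <- metadata$codh_protein_ids
    codh_ids <- if (is.list(raw)) raw else strsplit(as.character(raw), ",", fixed = TRUE)
    names(codh_ids) <- metadata$genome_id
  }
  idset_key <- vapply(metadata$genome_id, function(g)
    paste(sort(unique(codh_ids[[g]])), collapse = ";"), character(1))
  priority <- ifelse(metadata$assembly_category == "reference", 1L,
              ifelse(metadata$assembly_category == "representative", 2L,
              ifelse(metadata$assembly_level == "complete", 3L, 4L)))
  keep <- character(0)
  for (sp in unique(metadata$species)) {
    rows <- which(metadata$species == sp)
    for (key in unique(idset_key[rows])) {
      cand <- rows[idset_key[rows] == key]
      cand <- cand[order(priority[cand], metadata$genome_id[cand])]
      keep <- c(keep, metadata$genome_id[cand[1L]])
    }
  }
  sort(keep)
}

#' Drop pseudogene rows from a gene table
#'
#' CODH genes annotated as pseudogenes are excluded before any downstream
#' step; only non-pseudo CDS rows enter directon construction.
#'
#' @param genes A gene table (see [read_gene_table()]).
#' @return The gene table without pseudo rows, ordinals recomputed.
#' @export
drop_pseudogenes <- function(genes) {
  out <- genes[!genes$pseudo, , drop = FALSE]
  out <- out[order(out$replicon_id, out$start), , drop = FALSE]
  out$ordinal <- as.integer(stats::ave(out$start, out$replicon_id,
                                       FUN = seq_along))
  rownames(out) <- NULL
  out
}
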