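# Directon extraction and curated genomic contexts.  A directon is a
# maximal run of adjacent same-strand genes whose intergenic gaps stay
# within a threshold; CODH-anchored directons are the genomic-context unit,
# later expanded with flanking genes carrying enriched COGs.

.intergenic_gap <- function(left_end, right_start) {
  # bp strictly between two genes; overlapping genes count as gap 0
  max(0L, as.integer(right_start) - as.integer(left_end) - 1L)
}

#' Build the directon anchored at a CODH gene
#'
#' Starting from the CODH gene, extends in both directions along the
#' replicon while the next gene lies on the same strand, the intergenic
#' gap (`next.start - current.end - 1`, overlaps counted as 0) is at most
#' `max_gap_bp`, and at most `max_side_genes` genes have been added on
#' that side.
#'
#' @param genes Gene table rows of one replicon, sorted by start
#'   (non-pseudo CDS rows).
#' @param codh_index Row index (into `genes`) of the anchoring CODH gene.
#' @param max_gap_bp Intergenic gap threshold in bp; default 300
#'   ("within 300 bp" read as <= 300).
#' @param max_side_genes Maximum genes added on each side; default 15.
#' @return A list of class `codh_directon`: `replicon_id`, `strand`,
#'   `indices` (row indices, ascending), `gene_ids`, `codh_ids`.
#' @export
build_directon <- function(genes, codh_index, max_gap_bp = 300L,
                           max_side_genes = 15L) {
  n <- nrow(genes)
  stopifnot(codh_index >= 1L, codh_index <= n)
  if (is.unsorted(genes$start)) stop("genes must be sorted by start")
  strand <- genes$strand[codh_index]
  repl <- genes$replicon_id[codh_index]

  lo <- codh_index
  while (lo > 1L && (codh_index - (lo - 1L)) <= max_side_genes &&
         genes$replicon_id[lo - 1L] == repl &&
         genes$strand[lo - 1L] == strand &&
         .intergenic_gap(genes$end[lo - 1L], genes$start[lo]) <= max_gap_bp)
    lo <- lo - 1L
  hi <- codh_index
  while (hi < n && ((hi + 1L) - codh_index) <= max_side_genes &&
         genes$replicon_id[hi + 1L] == repl &&
         genes$strand[hi + 1L] == strand &&
         .intergenic_gap(genes$end[hi], genes$start[hi + 1L]) <= max_gap_bp)
    hi <- hi + 1L

  idx <- lo:hi
  structure(list(replicon_id = repl, strand = strand, indices = idx,
                 gene_ids = genes$protein_id[idx],
                 codh_ids = genes$protein_id[idx][genes$is_codh[idx]]),
            class = "codh_directon")
}

#' Expand a directon into a curated genomic context
#'
#' Serially adds flanking genes annotated with at least one significantly
#' enriched COG to the directon, regardless of their strand and with no
#' gap limit; expansion stops on each side at the first flanking gene
#' without an enriched COG (or the replicon end).
#'
#' @param directon A `codh_directon`.
#' @param genes The same replicon gene table the directon was built from.
#' @param enriched_cogs Character vector of enriched COG ids.
#' @param annotations Annotation data frame (`protein_id`, `cog`).
#' @return A list of class `codh_context`: `directon_ids`,
#'   `expansion_ids`, `gene_ids` (all, in replicon order), `indices`.
#' @export
expand_context <- function(directon, genes, enriched_cogs, annotations) {
  cog_by_protein <- split(annotations$cog, annotations$protein_id)
  has_enriched <- function(i) {
    cogs <- cog_by_protein[[genes$protein_id[i]]]
    !is.null(cogs) && any(cogs %in% enriched_cogs)
  }
  n <- nrow(genes)
  repl <- directon$replicon_id
  lo <- min(directon$indices)
  hi <- max(directon$indices)
  while (lo > 1L && genes$replicon_id[lo - 1L] == repl && has_enriched(lo - 1L))
    lo <- lo - 1L
  while (hi < n && genes$replicon_id[hi + 1L] == repl && has_enriched(hi + 1L))
    hi <- hi + 1L
  idx <- lo:hi
  structure(list(directon_ids = directon$gene_ids,
                 expansion_ids = setdiff(genes$protein_id[idx],
                                         directon$gene_ids),
                 gene_ids = genes$protein_id[idx],
                 indices = idx),
            class = "codh_context")
}

#' Build all CODH-anchored directons of a gene table
#'
#' Pseudogene rows are dropped first; one directon is returned per CODH
#' gene (two CODH genes in one run yield two loci with equal gene sets).
#'
#' @param genes Full gene table (any number of replicons).
#' @param codh_proteins Character vector of CODH protein ids (defines
#'   `is_codh`); if `NULL` the table's `is_codh` column is used.
#' @inheritParams build_directon
#' @return Named list (by CODH protein id) of `codh_directon` objects.
#' @export
find_codh_directons <- function(genes, codh_proteins = NULL,
                                max_gap_bp = 300L, max_side_genes = 15L) {
  genes <- drop_pseudogenes(genes)
  if (!is.null(codh_proteins))
    genes$is_codh <- genes$protein_id %in% codh_proteins
  out <- list()
  for (repl in unique(genes$replicon_id)) {
    sub <- genes[genes$replicon_id == repl, , drop = FALSE]
    rownames(sub) <- NULL
    for (i in which(sub$is_codh)) {
      d <- build_directon(sub, i, max_gap_bp = max_gap_bp,
                          max_side_genes = max_side_genes)
      out[[sub$protein_id[i]]] <- d
    }
  }
  out
}

#' Build curated context loci for every CODH gene
#'
#' One locus per CODH gene: its directon plus the enriched-COG expansion,
#' with the locus feature set (COGs present, the CODH structural group,
#' and taxonomy labels) attached.
#'
#' @param directons From [find_codh_directons()].
#' @param genes Full gene table (non-pseudo rows are used).
#' @param annotations Annotation data frame (`protein_id`, `cog`).
#' @param enriched_cogs Character vector of enriched COG ids.
#' @param classifications Classification data frame
#'   ([classify_proteins()]); supplies each locus's `group_label`.
#' @param metadata Genome metadata (for `phylum`/`family` labels).
#' @return A data.frame with one row per locus: `codh_protein`,
#'   `genome_id`, `group_label`, `family`, `phylum`, `n_directon`,
#'   `n_expansion`, and `;`-separated `gene_ids` and `cogs` columns.
#' @export
build_context_loci <- function(directons, genes, annotations, enriched_cogs,
                               classifications, metadata) {
  genes <- drop_pseudogenes(genes)
  genome_of <- setNames(genes$genome_id, genes$protein_id)
  cog_by_protein <- split(annotations$cog, annotations$protein_id)
  group_of <- setNames(classifications$group_label,
                       classifications$protein_id)
  fam <- setNames(metadata$family, metadata$genome_id)
  phy <- setNames(metadata$phylum, metadata$genome_id)

  rows <- lapply(names(directons), function(codh_id) {
    d <- directons[[codh_id]]
    sub <- genes[genes$replicon_id == d$replicon_id, , drop = FALSE]
    rownames(sub) <- NULL
    ctx <- expand_context(d, sub, enriched_cogs, annotations)
    cogs <- sort(unique(unlist(cog_by_protein[ctx$gene_ids])))
    g <- genome_of[[codh_id]]
    data.frame(codh_protein = codh_id, genome_id = g,
               group_label = if (codh_id %in% names(group_of))
                 group_of[[codh_id]] else NA_character_,
               family = if (g %in% names(fam)) fam[[g]] else NA_character_,
               phylum = if (g %in% names(phy)) phy[[g]] else NA_character_,
               n_directon = length(ctx$directon_ids),
               n_expansion = length(ctx$expansion_ids),
               gene_ids = paste(ctx$gene_ids, collapse = ";"),
               cogs = paste(cogs, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
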