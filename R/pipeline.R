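# Pipeline orchestration: curate -> align/classify -> context -> enrich ->
# network, with one config object, seeded determinism and a machine-
# readable run report.

#' Pipeline configuration
#'
#' Every threshold defaults to the printed constant of the method it
#' implements: hit filters (bit score 200, length 550 aa), alignment
#' trimming gap threshold 0.9, directon rules (gap 300 bp, 15 genes per
#' side), enrichment (alpha 0.05, FDR 0.05, e-value 1e-6, Ni-CODH COGs
#' excluded) and network (Simpson 0.4, COG locus floor 25).
#'
#' @param fasta,gff,annotations,metadata,anchors Input file paths (see
#'   [read_protein_fasta()], [read_gene_table()], [read_tsv()],
#'   [read_anchor_sidecar()]); `anchors` is required.
#' @param hits Optional homology-hit table path (see [read_hit_table()]).
#' @param out_dir Output directory.
#' @param min_bit_score,min_length,gap_threshold,max_gap_bp,max_side_genes
#'   Curation/context thresholds.
#' @param alpha,fdr,tau,min_cog_loci,evalue_cutoff Enrichment/network
#'   thresholds.
#' @param ambiguity_delta Clade-assignment ambiguity margin.
#' @param excluded_cogs Ni-CODH COGs excluded from enrichment testing.
#' @param seed Integer seed (recorded in the report; the pipeline itself
#'   is deterministic given inputs).
#' @return A list of class `codh_config`.
#' @export
pipeline_config <- function(fasta, gff, annotations, metadata, anchors,
                            hits = NULL, out_dir = tempfile("codhscan_run_"),
                            min_bit_score = 200, min_length = 550,
                            gap_threshold = 0.9, max_gap_bp = 300L,
                            max_side_genes = 15L, alpha = 0.05, fdr = 0.05,
                            tau = 0.4, min_cog_loci = 25L,
                            evalue_cutoff = 1e-6, ambiguity_delta = 5,
                            excluded_cogs = c("COG1151", "COG1152"),
                            seed = 1L) {
  structure(list(fasta = fasta, gff = gff, annotations = annotations,
                 metadata = metadata, anchors = anchors, hits = hits,
                 out_dir = out_dir, min_bit_score = min_bit_score,
                 min_length = min_length, gap_threshold = gap_threshold,
                 max_gap_bp = as.integer(max_gap_bp),
                 max_side_genes = as.integer(max_side_genes),
                 alpha = alpha, fdr = fdr, tau = tau,
                 min_cog_loci = as.integer(min_cog_loci),
                 evalue_cutoff = evalue_cutoff,
                 ambiguity_delta = ambiguity_delta,
                 excluded_cogs = excluded_cogs, seed = as.integer(seed)),
            class = "codh_config")
}

#' Run the full analysis pipeline
#'
#' Executes curate -> classify -> context -> enrich -> network on the
#' configured inputs and writes every stage output plus a JSON run report
#' into `config$out_dir`: `classifications.tsv`, `directons.tsv`,
#' `contexts.tsv`, `enrichment.tsv`, `edges.tsv`, `network.graphml`,
#' `report.json`.  Identical config and inputs yield byte-identical
#' outputs.
#'
#' @param config A `codh_config` from [pipeline_config()].
#' @return Invisibly, the run report (a list of per-stage counts and
#'   tallies).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "codh_config"))
  if (is.null(config$anchors) || !file.exists(config$anchors))
    stop("anchor sidecar not found: generate anchors with ",
         "generate_reference_anchors()/write_anchor_sidecar() or supply ",
         "your own (config$anchors)")
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  proteins <- read_protein_fasta(config$fasta)
  if (length(proteins) == 0L) stop("input FASTA contains no sequences")
  genes <- read_gene_table(config$gff)
  annotations <- read_tsv(config$annotations)
  metadata <- read_tsv(config$metadata)
  anchors <- read_anchor_sidecar(config$anchors)

  # --- curation ------------------------------------------------------
  if (!is.null(config$hits)) {
    hits <- read_hit_table(config$hits)
    keep <- filter_hits(hits, config$min_bit_score, config$min_length)
    proteins <- proteins[names(proteins) %in% keep]
    if (length(proteins) == 0L) stop("no proteins survive the hit filters")
  }
  proteins <- deduplicate_proteins(proteins)
  genes <- drop_pseudogenes(genes)

  codh_ids_by_genome <- lapply(split(genes$protein_id[genes$protein_id %in%
    names(proteins)], genes$genome_id[genes$protein_id %in% names(proteins)]),
    unique)
  kept_genomes <- select_representative_genomes(
    metadata[metadata$genome_id %in% names(codh_ids_by_genome), , drop = FALSE],
    codh_ids = codh_ids_by_genome)
  genes <- genes[genes$genome_id %in% kept_genomes, , drop = FALSE]

  # --- classification ------------------------------------------------
  cls <- classify_proteins(proteins, anchors,
                           ambiguity_delta = config$ambiguity_delta)
  n_incomplete <- sum(!cls$complete)
  cls_used <- cls[cls$complete, , drop = FALSE]
  write_tsv(cls, file.path(config$out_dir, "classifications.tsv"))

  # --- genomic context ----------------------------------------------
  directons <- find_codh_directons(genes, codh_proteins = cls_used$protein_id,
                                   max_gap_bp = config$max_gap_bp,
                                   max_side_genes = config$max_side_genes)
  if (length(directons) == 0L) stop("no CODH gene found in the gene table")
  dir_df <- data.frame(codh_protein = names(directons),
                       replicon_id = vapply(directons, `[[`, "", "replicon_id"),
                       strand = vapply(directons, `[[`, "", "strand"),
                       n_genes = vapply(directons, function(d)
                         length(d$gene_ids), integer(1)),
                       gene_ids = vapply(directons, function(d)
                         paste(d$gene_ids, collapse = ";"), character(1)),
                       stringsAsFactors = FALSE)
  write_tsv(dir_df, file.path(config$out_dir, "directons.tsv"))

  # --- enrichment ----------------------------------------------------
  enr <- find_enriched_cogs(directons, genes, annotations,
                            alpha = config$alpha, fdr = config$fdr,
                            excluded_cogs = config$excluded_cogs,
                            evalue_cutoff = config$evalue_cutoff)
  write_tsv(enr$results, file.path(config$out_dir, "enrichment.tsv"))

  # --- contexts + network -------------------------------------------
  loci <- build_context_loci(directons, genes, annotations, enr$enriched,
                             cls_used, metadata)
  write_tsv(loci, file.path(config$out_dir, "contexts.tsv"))
  fm <- build_feature_matrix(loci, enr$enriched)
  edges <- build_network(fm, tau = config$tau,
                         min_cog_loci = config$min_cog_loci)
  write_tsv(edges, file.path(config$out_dir, "edges.tsv"))
  if (nrow(edges) > 0L)
    write_graphml(edges, file.path(config$out_dir, "network.graphml"))

  report <- list(
    seed = config$seed,
    n_proteins = length(proteins),
    n_genomes = length(kept_genomes),
    n_incomplete = n_incomplete,
    clade_tally = as.list(table(cls_used$clade)),
    group_tally = as.list(table(cls_used$group_label)),
    n_ambiguous = sum(cls_used$ambiguous),
    n_directons = length(directons),
    n_loci = nrow(loci),
    n_cogs_tested = nrow(enr$results),
    n_enriched = length(enr$enriched),
    enriched_cogs = enr$enriched,
    n_edges = nrow(edges))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
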