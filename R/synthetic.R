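# Synthetic-data generator: clade anchors, group templates, planted protein
# sequences, and whole genome fixtures with controlled genomic context, so
# every downstream stage can be tested against known ground truth.

#' Generate one reference anchor per clade
#'
#' Draws, for each clade A-G, a background scaffold (i.i.d. residues from
#' the 18-letter alphabet excluding Cys and His, so planted Cys/His motifs
#' are unambiguous) and plants the clade's representative structural-group
#' signature on it.  E-/F-cluster positions are carried by the Cdh-type
#' clade A anchor only.
#'
#' @param seed Integer RNG seed; fixes the anchors completely.
#' @param scaffold_length Scaffold length in residues (default 650; the
#'   curation length floor is 550 aa, and full-length Ni-CODH subunits run
#'   a few hundred residues above it).
#' @return Named list of 7 `codh_anchor` profiles, names `"A"`..`"G"`.
#' @export
#' @examples
#' anchors <- generate_reference_anchors(seed = 1)
#' names(anchors)
generate_reference_anchors <- function(seed = 1, scaffold_length = 650L) {
  set.seed(seed)
  layout <- .codh_layout(scaffold_length)
  tab <- codh_group_table()
  anchors <- lapply(codh_clades(), function(cl) {
    scaffold <- paste(sample(AA_BACKGROUND, layout$scaffold_length,
                             replace = TRUE), collapse = "")
    rep_group <- .clade_representative[[cl]]
    plan <- .group_residue_plan(rep_group, layout)
    ch <- strsplit(scaffold, "", fixed = TRUE)[[1]]
    ch[as.integer(names(plan))] <- plan
    d_type <- tab[rep_group, "d_type"]
    anchor_profile(
      clade = cl, sequence = paste(ch, collapse = ""),
      d_region = layout$d_region,
      d_positions = layout$d_offsets[[d_type]],
      b_cluster = layout$b_cluster, c_cluster = layout$c_cluster,
      acid_base = layout$acid_base,
      e_cluster = if (cl == "A") layout$e_cluster else NULL,
      f_cluster = if (cl == "A") layout$f_cluster else NULL,
      core_start = layout$core_start, core_end = layout$core_end,
      scaffold = scaffold)
  })
  names(anchors) <- codh_clades()
  anchors
}

#' Build the 24 structural-group templates
#'
#' Each template pairs a clade's background scaffold (taken from the
#' reference anchors) with the residue plan realizing one Table-of-groups
#' row, so that two templates of the same clade differ only at signature
#' positions.
#'
#' @param anchors Anchors from [generate_reference_anchors()].
#' @return Named list of 24 `codh_template` objects.
#' @export
group_templates <- function(anchors = generate_reference_anchors()) {
  layout <- .codh_layout(nchar(anchors[[1]]$sequence))
  tab <- codh_group_table()
  tpl <- lapply(tab$group, function(g) {
    cl <- tab[g, "clade"]
    plan <- .group_residue_plan(g, layout)
    stopifnot(all(as.integer(names(plan)) >= 1L),
              all(as.integer(names(plan)) <= layout$scaffold_length))
    structure(list(group_label = g, clade = cl,
                   scaffold_length = layout$scaffold_length,
                   scaffold = anchors[[cl]]$scaffold,
                   motif_plan = plan),
              class = "codh_template")
  })
  names(tpl) <- tab$group
  tpl
}

#' Realize a template without noise
#'
#' @param template A `codh_template`.
#' @return The template's exact sequence realization (character scalar).
#' @export
realize_template <- function(template) {
  ch <- strsplit(template$scaffold, "", fixed = TRUE)[[1]]
  ch[as.integer(names(template$motif_plan))] <- template$motif_plan
  paste(ch, collapse = "")
}

#' Generate a protein sequence for a structural group
#'
#' Realizes the template and applies i.i.d. substitutions at the per-site
#' `mutation_rate`; with `protect_motifs = TRUE` (default) substitutions
#' are restricted to non-motif positions, so the planted signature is
#' preserved exactly.  Substituted residues are drawn uniformly from the
#' 19 other standard residues.
#'
#' @param template A `codh_template` from [group_templates()].
#' @param mutation_rate Per-site substitution probability in `[0, 1]`.
#' @param protect_motifs Restrict substitutions to non-motif positions.
#' @param seed Optional integer seed (set for reproducible draws).
#' @param id Protein identifier; defaults to `"SYNP_<group>"`.
#' @return A list with `id`, `seq`, `group_label`, `clade`.
#' @export
generate_protein_for_group <- function(template, mutation_rate = 0,
                                       protect_motifs = TRUE, seed = NULL,
                                       id = NULL) {
  stopifnot(inherits(template, "codh_template"),
            mutation_rate >= 0, mutation_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  ch <- strsplit(realize_template(template), "", fixed = TRUE)[[1]]
  if (mutation_rate > 0) {
    eligible <- seq_along(ch)
    if (protect_motifs)
      eligible <- setdiff(eligible, as.integer(names(template$motif_plan)))
    hit <- eligible[runif(length(eligible)) < mutation_rate]
    for (p in hit) ch[p] <- sample(setdiff(AA20, ch[p]), 1L)
  }
  list(id = if (is.null(id)) paste0("SYNP_", template$group_label) else id,
       seq = paste(ch, collapse = ""),
       group_label = template$group_label, clade = template$clade)
}

#' Describe a synthetic genomic-context scenario
#'
#' The scenario fixes every knob of the genome generator: genome and gene
#' counts, which structural groups anchor the planted CODH genes, which
#' COGs co-occur with CODH directons and at what probability, the uniform
#' background COG frequencies, gene-length and intergenic-gap laws, the
#' strand-flip rate that breaks directons, and the RNG seed.
#'
#' @param n_genomes Number of genomes (one replicon each).
#' @param genes_per_replicon Protein-coding genes per replicon.
#' @param codh_groups Structural-group labels planted round-robin across
#'   genomes (one CODH gene per genome).
#' @param enriched_cogs Data frame with columns `cog`, `prob`: each genome
#'   receives a gene annotated with `cog` inside its CODH directon with
#'   probability `prob`.
#' @param background_cogs Data frame with columns `cog`, `freq`: per-gene
#'   Bernoulli annotation probability over all genes.
#' @param gap_range Bounded uniform law (bp) for intergenic gaps.
#' @param gene_length_range Bounded uniform law (bp) for gene lengths.
#' @param strand_flip_rate Probability of a strand flip between adjacent
#'   genes outside the planted block (exercises directon breaking).
#' @param codh_mutation_rate Background mutation rate applied to planted
#'   CODH protein sequences (motifs protected).
#' @param max_gap_bp Directon gap threshold the planting respects.
#' @param seed Integer RNG seed; fixes the whole bundle.
#' @return A list of class `codh_scenario`.
#' @export
context_scenario <- function(n_genomes = 50L, genes_per_replicon = 60L,
                             codh_groups = c("F-1", "E-1", "A-1"),
                             enriched_cogs = data.frame(
                               cog = c("COG0437", "COG1142", "COG3640"),
                               prob = 0.9),
                             background_cogs = data.frame(
                               cog = sprintf("COG%04d", 5000:5199),
                               freq = 0.02),
                             gap_range = c(5L, 250L),
                             gene_length_range = c(300L, 1500L),
                             strand_flip_rate = 0.2,
                             codh_mutation_rate = 0.02,
                             max_gap_bp = 300L, seed = 1L) {
  sc <- structure(list(n_genomes = as.integer(n_genomes),
                       genes_per_replicon = as.integer(genes_per_replicon),
                       codh_groups = codh_groups,
                       enriched_cogs = enriched_cogs,
                       background_cogs = background_cogs,
                       gap_range = as.integer(gap_range),
                       gene_length_range = as.integer(gene_length_range),
                       strand_flip_rate = strand_flip_rate,
                       codh_mutation_rate = codh_mutation_rate,
                       max_gap_bp = as.integer(max_gap_bp),
                       seed = as.integer(seed)),
                  class = "codh_scenario")
  validate_scenario(sc)
  sc
}

validate_scenario <- function(sc) {
  if (sc$n_genomes < 1L || sc$genes_per_replicon < 1L)
    stop("scenario counts must be positive")
  if (any(sc$enriched_cogs$prob < 0 | sc$enriched_cogs$prob > 1) ||
      any(sc$background_cogs$freq < 0 | sc$background_cogs$freq > 1) ||
      sc$strand_flip_rate < 0 || sc$strand_flip_rate > 1 ||
      sc$codh_mutation_rate < 0 || sc$codh_mutation_rate > 1)
    stop("scenario probabilities must lie in [0, 1]")
  if (!all(sc$codh_groups %in% structural_groups()))
    stop("unknown structural group in codh_groups")
  n_planted <- 1L + nrow(sc$enriched_cogs)
  if (n_planted > sc$genes_per_replicon)
    stop("planted genes (", n_planted, ") exceed genes_per_replicon (",
         sc$genes_per_replicon, ")")
  if (nrow(sc$enriched_cogs) > 30L)
    stop("at most 30 enriched COGs can be planted (15 genes per side)")
  invisible(sc)
}

#' Generate genomes with planted CODH genomic contexts
#'
#' For each genome, one replicon of `genes_per_replicon` non-overlapping
#' CDS genes is laid out with uniform gene lengths and intergenic gaps and
#' a Markov strand chain (flip rate `strand_flip_rate` per adjacent pair).
#' One CODH gene per genome (structural groups recycled from
#' `codh_groups`) anchors a planted block: for each enriched COG, with its
#' stated probability, a neighboring gene annotated with that COG is placed
#' inside the CODH directon (same strand, gap capped at `max_gap_bp`,
#' alternating sides).  Background COGs are scattered per-gene at their
#' genome-wide frequency.  CODH proteins themselves are annotated with the
#' Ni-CODH COGs (COG1152 for clade A, COG1151 otherwise), which the
#' enrichment stage must exclude.
#'
#' @param scenario A `codh_scenario` from [context_scenario()].
#' @param anchors Optional anchors; default freshly generated from
#'   `scenario$seed` so bundles are self-consistent.
#' @return A list of class `codh_bundle`: `genes` (gene table),
#'   `annotations`, `metadata`, `proteins` (named character vector of CODH
#'   protein sequences), `anchors`, and `manifest` (planted ground truth).
#' @export
generate_context_genomes <- function(scenario = context_scenario(),
                                     anchors = NULL) {
  validate_scenario(scenario)
  if (is.null(anchors)) anchors <- generate_reference_anchors(scenario$seed)
  templates <- group_templates(anchors)
  set.seed(scenario$seed)

  phyla <- c("Firmicutes", "Proteobacteria", "Euryarchaeota", "Chloroflexi")
  fam_pool <- sprintf("%s_fam%02d", rep(phyla, each = 2L), 1:2)
  cats <- c("reference", "representative", "na")
  levels <- c("complete", "chromosome", "scaffold", "contig")

  genes <- list(); annots <- list(); meta <- list(); prots <- character(0)
  truth <- list()
  n <- scenario$genes_per_replicon
  n_enr <- nrow(scenario$enriched_cogs)

  for (g in seq_len(scenario$n_genomes)) {
    genome_id <- sprintf("SYN_G%03d", g)
    replicon <- paste0(genome_id, "_r1")
    group <- scenario$codh_groups[((g - 1L) %% length(scenario$codh_groups)) + 1L]

    lens <- sample(seq(scenario$gene_length_range[1],
                       scenario$gene_length_range[2]), n, replace = TRUE)
    gaps <- sample(seq(scenario$gap_range[1], scenario$gap_range[2]),
                   n, replace = TRUE)  # gaps[i] precedes gene i (gaps[1] = offset)
    flips <- runif(n - 1L) < scenario$strand_flip_rate
    strand <- character(n)
    strand[1] <- sample(c("+", "-"), 1L)
    for (i in 2:n) strand[i] <- if (flips[i - 1L])
      setdiff(c("+", "-"), strand[i - 1L]) else strand[i - 1L]

    # CODH slot placed so that 15-gene windows fit on both sides if possible.
    lo <- min(16L, max(1L, n %/% 2L)); hi <- max(lo, n - 15L)
    codh_slot <- if (hi > lo) sample(seq(lo, hi), 1L) else lo

    # Plant enriched COG successes on alternating neighbor slots.
    success <- runif(n_enr) < scenario$enriched_cogs$prob
    offsets <- integer(0)
    if (any(success)) {
      k <- sum(success)
      side <- rep(c(1L, -1L), length.out = k)
      stepn <- (seq_len(k) + 1L) %/% 2L
      offsets <- side * stepn
      offsets <- offsets[codh_slot + offsets >= 1L & codh_slot + offsets <= n]
    }
    planted_slots <- codh_slot + offsets
    block <- seq(min(c(codh_slot, planted_slots)),
                 max(c(codh_slot, planted_slots)))
    strand[block] <- strand[codh_slot]
    # Cap gaps inside the block at the directon threshold.
    if (length(block) > 1L) {
      inside <- setdiff(block, block[1])  # gaps[i] separates gene i-1 and i
      gaps[inside] <- pmin(gaps[inside], scenario$max_gap_bp)
    }

    starts <- cumsum(gaps + c(0L, lens[-n])) + 1L
    ends <- starts + lens - 1L
    pid <- sprintf("%s_%04d", genome_id, seq_len(n))
    is_codh <- seq_len(n) == codh_slot

    genes[[g]] <- data.frame(genome_id = genome_id, replicon_id = replicon,
                             ordinal = seq_len(n), start = starts, end = ends,
                             strand = strand, protein_id = pid,
                             is_codh = is_codh, pseudo = FALSE,
                             stringsAsFactors = FALSE)

    # CODH protein sequence.
    codh_pid <- pid[codh_slot]
    prot <- generate_protein_for_group(templates[[group]],
                                       mutation_rate = scenario$codh_mutation_rate,
                                       protect_motifs = TRUE, id = codh_pid)
    prots[[codh_pid]] <- prot$seq

    # Annotations: Ni-CODH COG on the CODH gene, planted enriched COGs,
    # scattered background COGs.
    an <- list(data.frame(protein_id = codh_pid,
                          cog = if (substr(group, 1, 1) == "A") "COG1152" else "COG1151",
                          evalue = 1e-30, stringsAsFactors = FALSE))
    planted_cogs <- scenario$enriched_cogs$cog[success][seq_along(offsets)]
    if (length(offsets))
      an[[length(an) + 1L]] <- data.frame(protein_id = pid[planted_slots],
                                          cog = planted_cogs,
                                          evalue = signif(10^-runif(length(offsets), 8, 30), 3),
                                          stringsAsFactors = FALSE)
    for (bi in seq_len(nrow(scenario$background_cogs))) {
      hit <- which(runif(n) < scenario$background_cogs$freq[bi])
      if (length(hit))
        an[[length(an) + 1L]] <- data.frame(protein_id = pid[hit],
                                            cog = scenario$background_cogs$cog[bi],
                                            evalue = signif(10^-runif(length(hit), 8, 30), 3),
                                            stringsAsFactors = FALSE)
    }
    annots[[g]] <- do.call(rbind, an)

    meta[[g]] <- data.frame(genome_id = genome_id,
                            species = sprintf("SYN_sp_%03d", g),
                            assembly_category = cats[((g - 1L) %% 3L) + 1L],
                            assembly_level = levels[((g - 1L) %% 4L) + 1L],
                            phylum = phyla[((g - 1L) %% 4L) + 1L],
                            family = fam_pool[((g - 1L) %% 8L) + 1L],
                            stringsAsFactors = FALSE)

    truth[[genome_id]] <- list(genome_id = genome_id, codh_protein = codh_pid,
                               group_label = group,
                               planted_cogs = as.list(planted_cogs),
                               planted_proteins = as.list(pid[planted_slots]))
  }

  manifest <- list(seed = scenario$seed,
                   n_genomes = scenario$n_genomes,
                   codh_groups = scenario$codh_groups,
                   enriched_cogs = scenario$enriched_cogs,
                   group_tally = as.list(table(vapply(truth, `[[`, "", "group_label"))),
                   genomes = truth)

  structure(list(genes = do.call(rbind, genes),
                 annotations = do.call(rbind, annots),
                 metadata = do.call(rbind, meta),
                 proteins = prots, anchors = anchors,
                 scenario = scenario, manifest = manifest),
            class = "codh_bundle")
}

#' Write a fixture bundle to disk
#'
#' Writes `proteins.faa` (FASTA), `genes.gff3`, `annotations.tsv`,
#' `metadata.tsv`, `anchors.json` and `manifest.json` into `directory`.
#'
#' @param bundle A `codh_bundle` from [generate_context_genomes()].
#' @param directory Output directory (created if missing).
#' @return Invisibly, the manifest augmented with the file paths.
#' @export
write_fixture_bundle <- function(bundle, directory) {
  stopifnot(inherits(bundle, "codh_bundle"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- list(proteins = file.path(directory, "proteins.faa"),
                genes = file.path(directory, "genes.gff3"),
                annotations = file.path(directory, "annotations.tsv"),
                metadata = file.path(directory, "metadata.tsv"),
                anchors = file.path(directory, "anchors.json"),
                manifest = file.path(directory, "manifest.json"))
  write_protein_fasta(bundle$proteins, paths$proteins)
  write_gene_table(bundle$genes, paths$genes)
  write_tsv(bundle$annotations, paths$annotations)
  write_tsv(bundle$metadata, paths$metadata)
  write_anchor_sidecar(bundle$anchors, paths$anchors)
  manifest <- c(bundle$manifest, list(files = lapply(paths, basename)))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a fixture bundle back from disk
#'
#' @param directory Directory written by [write_fixture_bundle()].
#' @return A list with `genes`, `annotations`, `metadata`, `proteins`,
#'   `anchors`, `manifest`.
#' @export
read_fixture_bundle <- function(directory) {
  list(genes = read_gene_table(file.path(directory, "genes.gff3")),
       annotations = read_tsv(file.path(directory, "annotations.tsv")),
       metadata = read_tsv(file.path(directory, "metadata.tsv")),
       proteins = read_protein_fasta(file.path(directory, "proteins.faa")),
       anchors = read_anchor_sidecar(file.path(directory, "anchors.json")),
       manifest = jsonlite::read_json(file.path(directory, "manifest.json"),
                                      simplifyVector = TRUE,
                                      simplifyDataFrame = TRUE))
}
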