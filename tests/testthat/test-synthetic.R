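# Synthetic-data generator: anchors, templates, planted proteins, genomes.

test_that("reference anchors cover all clades deterministically", {
  a1 <- generate_reference_anchors(seed = 1)
  a2 <- generate_reference_anchors(seed = 1)
  expect_identical(vapply(a1, `[[`, "", "clade"), setNames(LETTERS[1:7], LETTERS[1:7]))
  expect_identical(a1, a2)
  # E-/F-cluster positions only on the Cdh-type clade A anchor
  expect_false(is.null(a1$A$e_cluster))
  expect_false(is.null(a1$A$f_cluster))
  for (cl in LETTERS[2:7]) {
    expect_null(a1[[cl]]$e_cluster)
    expect_null(a1[[cl]]$f_cluster)
  }
  # different seed gives different scaffolds
  expect_false(identical(generate_reference_anchors(seed = 2)$A$sequence,
                         a1$A$sequence))
  for (a in a1) expect_silent(validate_anchor_profile(a))
})

test_that("zero-noise proteins equal their template realization and carry motifs", {
  tpl <- ref_templates[["A-1"]]
  p <- generate_protein_for_group(tpl, mutation_rate = 0)
  expect_identical(p$seq, realize_template(tpl))
  # type I D-cluster pattern Cys-X-X-Cys-Cys at the D positions
  d_start <- 50L
  expect_identical(substr(p$seq, d_start, d_start + 4L),
                   paste0("C", substr(p$seq, d_start + 1, d_start + 2), "CC"))
  expect_identical(substr(p$seq, d_start + 3L, d_start + 4L), "CC")
  # scaffold background carries no stray Cys/His
  bg <- strsplit(tpl$scaffold, "")[[1]]
  expect_false(any(bg %in% c("C", "H")))
})

test_that("protected mutation leaves motif positions untouched at the stated rate", {
  tpl <- ref_templates[["F-2"]]
  motif_pos <- as.integer(names(tpl$motif_plan))
  p <- generate_protein_for_group(tpl, mutation_rate = 0.3,
                                  protect_motifs = TRUE, seed = 11)
  ref <- realize_template(tpl)
  ch_p <- strsplit(p$seq, "")[[1]]
  ch_r <- strsplit(ref, "")[[1]]
  expect_identical(ch_p[motif_pos], ch_r[motif_pos])
  n_mut <- sum(ch_p != ch_r)
  n_free <- nchar(ref) - length(motif_pos)
  # ~Binomial(n_free, 0.3); a generous window around the mean
  expect_gt(n_mut, 0.15 * n_free)
  expect_lt(n_mut, 0.45 * n_free)
  # determinism under a fixed seed
  expect_identical(p$seq,
                   generate_protein_for_group(tpl, 0.3, TRUE, seed = 11)$seq)
})

test_that("context genomes plant enriched COGs inside CODH directons", {
  # probability-1 planting: the COG sits in every CODH directon
  sc1 <- context_scenario(n_genomes = 20, genes_per_replicon = 40,
                          enriched_cogs = data.frame(cog = "COG9001", prob = 1.0),
                          background_cogs = data.frame(cog = "COG8001", freq = 0.05),
                          seed = 3)
  b1 <- generate_context_genomes(sc1)
  d1 <- find_codh_directons(b1$genes)
  expect_length(d1, 20L)
  carriers <- b1$annotations$protein_id[b1$annotations$cog == "COG9001"]
  hit <- vapply(d1, function(d) any(d$gene_ids %in% carriers), logical(1))
  expect_true(all(hit))

  # probability-0: the COG never appears at all (planting is its only source)
  sc0 <- context_scenario(n_genomes = 10, genes_per_replicon = 40,
                          enriched_cogs = data.frame(cog = "COG9001", prob = 0.0),
                          background_cogs = data.frame(cog = "COG8001", freq = 0.05),
                          seed = 3)
  b0 <- generate_context_genomes(sc0)
  expect_false("COG9001" %in% b0$annotations$cog)
})

test_that("a fixed 100 bp gap law keeps every planted neighbor in the directon", {
  sc <- context_scenario(n_genomes = 12, genes_per_replicon = 40,
                         gap_range = c(100L, 100L),
                         enriched_cogs = data.frame(
                           cog = c("COG9001", "COG9002", "COG9003"), prob = 1.0),
                         background_cogs = data.frame(cog = "COG8001", freq = 0.02),
                         seed = 5)
  b <- generate_context_genomes(sc)
  genes <- b$genes
  for (g in b$manifest$genomes) {
    sub <- genes[genes$genome_id == g$genome_id, ]
    rownames(sub) <- NULL
    idx <- oracle_directon(sub, which(sub$is_codh))
    expect_true(all(unlist(g$planted_proteins) %in% sub$protein_id[idx]),
                info = g$genome_id)
  }
})

test_that("planted enrichment is detectable on the raw tables", {
  sc <- context_scenario(n_genomes = 20, genes_per_replicon = 50,
                         enriched_cogs = data.frame(
                           cog = c("COG9001", "COG9002"), prob = 0.9),
                         background_cogs = data.frame(
                           cog = sprintf("COG80%02d", 1:10), freq = 0.02),
                         seed = 9)
  b <- generate_context_genomes(sc)
  d <- find_codh_directons(b$genes)
  dir_genes <- unique(unlist(lapply(d, `[[`, "gene_ids")))
  all_genes <- b$genes$protein_id
  freq_in <- function(cog, set) {
    carriers <- unique(b$annotations$protein_id[b$annotations$cog == cog])
    length(intersect(carriers, set)) / length(set)
  }
  for (cog in c("COG9001", "COG9002"))
    expect_gt(freq_in(cog, dir_genes), freq_in(cog, setdiff(all_genes, dir_genes)))
})

test_that("invalid scenarios are rejected", {
  expect_error(context_scenario(genes_per_replicon = 2,
                                enriched_cogs = data.frame(
                                  cog = c("COG1", "COG2"), prob = 1)),
               "exceed genes_per_replicon")
  expect_error(context_scenario(enriched_cogs = data.frame(cog = "COG1", prob = 1.2)),
               "probabilities")
  expect_error(context_scenario(codh_groups = "Z-9"), "unknown structural group")
  expect_error(context_scenario(n_genomes = 0), "positive")
})

test_that("fixture bundles round-trip and are seed-deterministic", {
  sc <- context_scenario(n_genomes = 4, genes_per_replicon = 30, seed = 13)
  b <- generate_context_genomes(sc)
  dir1 <- withr::local_tempdir()
  manifest <- write_fixture_bundle(b, dir1)
  expect_true(all(c("proteins.faa", "genes.gff3", "annotations.tsv",
                    "metadata.tsv", "anchors.json", "manifest.json") %in%
                    list.files(dir1)))
  rb <- read_fixture_bundle(dir1)
  # identical in-memory objects after the round trip
  g0 <- b$genes[order(b$genes$replicon_id, b$genes$start), ]
  rownames(g0) <- NULL
  expect_identical(rb$genes, g0)
  expect_identical(rb$proteins[names(b$proteins)], b$proteins)
  expect_identical(rb$metadata, b$metadata)
  expect_identical(rb$anchors, b$anchors)
  expect_setequal(names(rb$annotations), names(b$annotations))
  # manifest lists every planted CODH protein id
  planted <- vapply(b$manifest$genomes, `[[`, "", "codh_protein")
  expect_setequal(vapply(rb$manifest$genomes, `[[`, "", "codh_protein"),
                  unname(planted))
  # same scenario + seed => byte-identical files
  dir2 <- withr::local_tempdir()
  write_fixture_bundle(generate_context_genomes(sc), dir2)
  for (f in list.files(dir1)) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))), info = f)
  }
})
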