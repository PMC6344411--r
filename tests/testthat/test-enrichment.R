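# Enrichment testing, FDR control, Simpson similarity, network building.

test_that("one-sided Fisher matches hand-derived and enumerated values", {
  # margins (5,5;5): P(a=5) = C(5,5)C(5,0)/C(10,5) = 1/252
  expect_equal(fisher_exact_greater(5, 0, 0, 5), 1 / 252, tolerance = 1e-14)
  # upper tail from 0 covers everything
  expect_identical(fisher_exact_greater(0, 7, 3, 11), 1)
  # zero margins
  expect_identical(fisher_exact_greater(0, 0, 4, 6), 1)
  expect_identical(fisher_exact_greater(0, 5, 0, 5), 1)
  # random tables vs the enumeration oracle and fisher.test
  set.seed(19)
  for (i in 1:50) {
    t <- as.integer(rmultinom(1, sample(5:40, 1), rep(0.25, 4)))
    p <- fisher_exact_greater(t[1], t[2], t[3], t[4])
    expect_lt(abs(p - oracle_fisher_greater(t[1], t[2], t[3], t[4])), 1e-12)
    ft <- stats::fisher.test(matrix(t, 2, byrow = TRUE),
                             alternative = "greater")$p.value
    expect_equal(p, ft, tolerance = 1e-9)
  }
})

test_that("BH adjustment reproduces the step-up construction", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(bh_adjust(0.2), 0.2)
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  set.seed(23)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, stats::p.adjust(p, method = "BH"))
    expect_true(all(q >= p - 1e-15 & q <= 1))
    # permutation equivariance
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), q[perm])
    # sorted inputs give non-decreasing q
    expect_true(!is.unsorted(bh_adjust(sort(p))))
  }
})

test_that("Simpson coefficient follows its set formula", {
  expect_identical(simpson_coefficient(c("a", "b"), c("a", "b")), 1)
  expect_identical(simpson_coefficient(c("a", "b"), c("a", "b", "c", "d")), 1)
  expect_identical(simpson_coefficient(letters[1:4], c(letters[1:2], LETTERS[1:8])), 0.5)
  expect_identical(simpson_coefficient(c("a"), c("b")), 0)
  expect_true(is.na(simpson_coefficient(character(0), "a")))
  set.seed(3)
  for (i in 1:10) {
    u <- sample(letters, 8); v <- sample(letters, 12)
    expect_identical(simpson_coefficient(u, v), simpson_coefficient(v, u))
  }
})

test_that("enrichment flags planted COGs and never the Ni-CODH COGs", {
  # 20 directons of 2 genes each; COGP in every directon, nowhere else;
  # COG1151 maximally enriched but excluded; COGB scattered everywhere.
  genes <- do.call(rbind, lapply(1:20, function(i) {
    g <- make_replicon(100, rep("+", 100), c(0L, rep(1000L, 98), 50L),
                       replicon = sprintf("r%02d", i),
                       genome = sprintf("g%02d", i), codh = 100)
    g
  }))
  # gene 99-100 gap is 50 -> directon {99,100}; all other gaps 1000
  d <- find_codh_directons(genes)
  expect_true(all(vapply(d, function(x) length(x$gene_ids), 1L) == 2L))
  ann <- rbind(
    data.frame(protein_id = genes$protein_id[genes$ordinal == 99],
               cog = "COGP"),
    data.frame(protein_id = genes$protein_id[genes$ordinal == 100],
               cog = "COG1151"),
    data.frame(protein_id = genes$protein_id[genes$ordinal %in% seq(5, 95, 5)],
               cog = "COGB"))
  res <- find_enriched_cogs(d, genes, ann)
  expect_identical(res$enriched, "COGP")
  expect_false("COG1151" %in% res$results$cog)
  row_p <- res$results[res$results$cog == "COGP", ]
  expect_identical(c(row_p$a, row_p$b), c(20L, 20L))
  expect_lt(row_p$p, 1e-20)
  row_b <- res$results[res$results$cog == "COGB", ]
  expect_false(row_b$enriched)
})

test_that("the annotation e-value cut is honored on ingest", {
  g <- make_replicon(4, rep("+", 4), rep(50L, 4), codh = 2)
  d <- find_codh_directons(g)
  ann <- data.frame(protein_id = c("g1_p001", "g1_p003"),
                    cog = "COGX", evalue = c(1e-10, 1e-3))
  res <- find_enriched_cogs(d, g, ann)
  expect_identical(res$results$a[res$results$cog == "COGX"], 1L)
})

test_that("the feature matrix namespaces features and keeps rows non-empty", {
  loci <- data.frame(codh_protein = c("p1", "p2", "p3"),
                     genome_id = c("g1", "g2", "g3"),
                     group_label = c("F-1", "F-1", "A-1"),
                     family = c("famA", "famB", "famA"),
                     phylum = "ph",
                     cogs = c("COG1;COG2", "COG1", ""),
                     stringsAsFactors = FALSE)
  m <- build_feature_matrix(loci, c("COG1", "COG2"))
  expect_setequal(colnames(m), c("cog:COG1", "cog:COG2", "group:A-1",
                                 "group:F-1", "family:famA", "family:famB"))
  expect_true(all(rowSums(m) >= 1))
  expect_identical(attr(m, "kind"),
                   sub(":.*$", "", colnames(m)))
  expect_identical(unname(colSums(m)[c("cog:COG1", "cog:COG2")]), c(2, 1))
})

test_that("network edges respect the Simpson threshold and COG locus floor", {
  # 200 loci; both COGs cover 100 loci, overlapping in 39 vs 40:
  # simpson 0.39 emits no edge, 0.40 does
  loci_ids <- sprintf("L%03d", 1:200)
  mk_pair <- function(overlap) {
    m <- matrix(FALSE, 200, 2, dimnames = list(loci_ids, c("cog:A", "cog:B")))
    m[1:100, "cog:A"] <- TRUE
    m[(101 - overlap):(200 - overlap), "cog:B"] <- TRUE
    attr(m, "kind") <- c("cog", "cog")
    m
  }
  expect_identical(nrow(build_network(mk_pair(39), tau = 0.4)), 0L)
  e40 <- build_network(mk_pair(40), tau = 0.4)
  expect_identical(nrow(e40), 1L)
  expect_identical(e40$simpson, 0.4)
  expect_identical(c(e40$u_count, e40$v_count), c(100, 100))

  # a subset pair scores 1 regardless of sizes
  m3 <- matrix(FALSE, 100, 2,
               dimnames = list(loci_ids[1:100], c("cog:A", "group:G")))
  m3[1:100, "cog:A"] <- TRUE
  m3[1:40, "group:G"] <- TRUE
  attr(m3, "kind") <- c("cog", "group")
  e3 <- build_network(m3, tau = 0.4)
  expect_identical(nrow(e3), 1L)
  expect_identical(e3$simpson, 1)

  # COG present in 24 loci is dropped as a node; 25 is kept;
  # group/taxonomy columns are exempt from the floor
  m4 <- matrix(FALSE, 30, 3,
               dimnames = list(sprintf("L%02d", 1:30),
                               c("cog:C24", "cog:C25", "group:G3")))
  m4[1:24, "cog:C24"] <- TRUE
  m4[1:25, "cog:C25"] <- TRUE
  m4[1:3, "group:G3"] <- TRUE
  attr(m4, "kind") <- c("cog", "cog", "group")
  e4 <- build_network(m4, tau = 0.4, min_cog_loci = 25)
  nodes <- unique(c(e4$u, e4$v))
  expect_false("cog:C24" %in% nodes)
  expect_true("cog:C25" %in% nodes)
  expect_true("group:G3" %in% nodes)  # simpson(C25, G3) = 3/3 = 1
})

test_that("GraphML export round-trips nodes and weights", {
  edges <- data.frame(u = c("cog:A", "cog:A"), v = c("group:G", "family:F"),
                      simpson = c(0.8, 0.5),
                      u_kind = "cog", v_kind = c("group", "family"),
                      u_count = c(30L, 30L), v_count = c(10L, 12L))
  path <- withr::local_tempfile(fileext = ".graphml")
  g <- write_graphml(edges, path)
  expect_true(file.exists(path))
  g2 <- igraph::read_graph(path, format = "graphml")
  expect_equal(as.integer(igraph::vcount(g2)), 3L)
  expect_equal(as.integer(igraph::ecount(g2)), 2L)
  expect_equal(sort(igraph::E(g2)$weight), c(0.5, 0.8))
})
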