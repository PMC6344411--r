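# COG enrichment inside CODH directons (exact one-sided test + step-up FDR
# control), the locus x feature boolean matrix, Simpson-coefficient
# similarities, and the co-occurrence network.

#' One-sided Fisher exact test for enrichment
#'
#' Exact upper-tail hypergeometric probability `P(X >= a)` with the table
#' margins fixed, computed via log-factorial (lchoose) sums.  This is the
#' one-sided (greater / enrichment) Fisher exact p-value for the 2x2 table
#' `(a, b; c, d)` with `a` = genes inside CODH directons carrying the COG,
#' `b` = directon genes without it, `c` = genes outside directons with it,
#' `d` = the rest.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @return The exact p-value; a zero margin (`a+b == 0` or `a+c == 0`)
#'   returns 1.
#' @export
#' @examples
#' fisher_exact_greater(5, 0, 0, 5)  # 1 / choose(10, 5) = 1/252
fisher_exact_greater <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  k <- a + b        # directon genes
  K <- a + c        # genes carrying the COG
  n <- a + b + c + d
  if (k == 0L || K == 0L) return(1)
  if (a == 0) return(1)  # the upper tail from 0 covers every outcome
  amax <- min(k, K)
  avals <- a:amax
  lp <- lchoose(K, avals) + lchoose(n - K, k - avals) - lchoose(n, k)
  mx <- max(lp)
  p <- exp(mx) * sum(exp(lp - mx))
  min(p, 1)
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up FDR control: on ascending-sorted p-values,
#' `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1, with the original
#' order restored.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (m == 0L) return(numeric(0))
  ord <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(m / seq(m, 1) * p[ord]))
  q[order(ord)]
}

#' Find COGs enriched inside CODH directons
#'
#' Builds, for every COG over all CODH-encoding genomes, the gene-level
#' contingency table directon-vs-rest, tests with
#' [fisher_exact_greater()], adjusts across all tested COGs with
#' [bh_adjust()], and flags a COG enriched iff `p < alpha` and
#' `q < fdr`.  The Ni-CODH COGs themselves (default COG1151 and COG1152)
#' are excluded from testing and can never be flagged.  A gene may carry
#' several COGs; each COG counts a gene once.  When the annotation table
#' has an `evalue` column, hits with `evalue >= evalue_cutoff` are dropped
#' on ingest.
#'
#' @param directons From [find_codh_directons()].
#' @param genes Full gene table; the contingency universe is every
#'   non-pseudo gene of genomes containing at least one CODH directon.
#' @param annotations Data frame `protein_id`, `cog` (optional `evalue`).
#' @param alpha,fdr Significance thresholds; default 0.05 each.
#' @param excluded_cogs COGs never tested; default `COG1151`, `COG1152`.
#' @param evalue_cutoff Annotation e-value cut; default 1e-6.
#' @return A list: `enriched` (character vector) and `results` (data.frame
#'   `cog`, `a`, `b`, `c`, `d`, `p`, `q`, `enriched`, sorted by `p`).
#' @export
find_enriched_cogs <- function(directons, genes, annotations,
                               alpha = 0.05, fdr = 0.05,
                               excluded_cogs = c("COG1151", "COG1152"),
                               evalue_cutoff = 1e-6) {
  genes <- drop_pseudogenes(genes)
  if ("evalue" %in% names(annotations))
    annotations <- annotations[annotations$evalue < evalue_cutoff, , drop = FALSE]

  codh_genomes <- unique(genes$genome_id[genes$protein_id %in%
    unlist(lapply(directons, `[[`, "codh_ids"))])
  universe <- genes$protein_id[genes$genome_id %in% codh_genomes]
  directon_genes <- intersect(unique(unlist(lapply(directons, `[[`,
                                                   "gene_ids"))), universe)
  annotations <- annotations[annotations$protein_id %in% universe, , drop = FALSE]
  annotations <- unique(annotations[, c("protein_id", "cog")])
  annotations <- annotations[!annotations$cog %in% excluded_cogs, , drop = FALSE]

  n_total <- length(unique(universe))
  n_dir <- length(directon_genes)
  if (nrow(annotations) == 0L)
    return(list(enriched = character(0),
                results = data.frame(cog = character(0), a = integer(0),
                                     b = integer(0), c = integer(0),
                                     d = integer(0), p = numeric(0),
                                     q = numeric(0), enriched = logical(0))))

  in_dir <- annotations$protein_id %in% directon_genes
  a <- tapply(in_dir, annotations$cog, sum)
  tot <- tapply(in_dir, annotations$cog, length)
  cogs <- names(a)
  a <- as.integer(a); tot <- as.integer(tot)
  b <- n_dir - a
  cc <- tot - a
  d <- n_total - a - b - cc
  p <- mapply(fisher_exact_greater, a, b, cc, d)
  q <- bh_adjust(p)
  res <- data.frame(cog = cogs, a = a, b = b, c = cc, d = d, p = p, q = q,
                    enriched = p < alpha & q < fdr,
                    stringsAsFactors = FALSE)
  res <- res[order(res$p, res$cog), , drop = FALSE]
  rownames(res) <- NULL
  list(enriched = res$cog[res$enriched], results = res)
}

#' Simpson overlap coefficient
#'
#' `|u intersect v| / min(|u|, |v|)` between the locus sets of two
#' features; symmetric, in `[0, 1]`, equal to 1 whenever one set contains
#' the other.
#'
#' @param loci_u,loci_v Character vectors of locus ids (non-empty).
#' @return The coefficient, or `NA_real_` (pair skipped) if either set is
#'   empty.
#' @export
simpson_coefficient <- function(loci_u, loci_v) {
  u <- unique(loci_u); v <- unique(loci_v)
  if (length(u) == 0L || length(v) == 0L) return(NA_real_)
  length(intersect(u, v)) / min(length(u), length(v))
}

#' Build the locus x feature boolean matrix
#'
#' Rows are context loci; columns are namespaced features: the enriched
#' COGs present in each locus (`cog:`), the locus's structural group
#' (`group:`) and its family-level taxonomy (`family:`).
#'
#' @param loci Data frame from [build_context_loci()].
#' @param enriched_cogs Character vector of enriched COG ids.
#' @return A logical matrix with a `kind` attribute (character vector per
#'   column: `"cog"`, `"group"`, `"family"`).
#' @export
build_feature_matrix <- function(loci, enriched_cogs) {
  stopifnot(nrow(loci) >= 1L)
  cog_sets <- strsplit(loci$cogs, ";", fixed = TRUE)
  cog_sets <- lapply(cog_sets, function(x) intersect(x, enriched_cogs))
  cog_cols <- sort(unique(unlist(cog_sets)))
  grp_cols <- sort(unique(loci$group_label[!is.na(loci$group_label)]))
  fam_cols <- sort(unique(loci$family[!is.na(loci$family)]))
  cols <- c(paste0("cog:", cog_cols), paste0("group:", grp_cols),
            paste0("family:", fam_cols))
  m <- matrix(FALSE, nrow = nrow(loci), ncol = length(cols),
              dimnames = list(loci$codh_protein, cols))
  for (i in seq_len(nrow(loci))) {
    feats <- c(if (length(cog_sets[[i]])) paste0("cog:", cog_sets[[i]]),
               if (!is.na(loci$group_label[i])) paste0("group:", loci$group_label[i]),
               if (!is.na(loci$family[i])) paste0("family:", loci$family[i]))
    m[i, feats] <- TRUE
  }
  attr(m, "kind") <- sub(":.*$", "", cols)
  m
}

#' Build the Simpson co-occurrence network
#'
#' COG columns present in fewer than `min_cog_loci` loci are dropped (the
#' locus floor is scoped to COGs only; structural-group and taxonomy
#' columns always stay).  All remaining feature pairs are scored with
#' [simpson_coefficient()] on their locus sets and an undirected edge is
#' emitted iff the coefficient is at least `tau`.
#'
#' @param matrix Feature matrix from [build_feature_matrix()].
#' @param tau Simpson edge threshold; default 0.4.
#' @param min_cog_loci COG locus floor; default 25.
#' @return A data.frame of edges: `u`, `v` (sorted within pair),
#'   `simpson`, `u_kind`, `v_kind`, `u_count`, `v_count`.
#' @export
build_network <- function(matrix, tau = 0.4, min_cog_loci = 25L) {
  kind <- attr(matrix, "kind")
  counts <- colSums(matrix)
  keep <- kind != "cog" | counts >= min_cog_loci
  m <- matrix[, keep, drop = FALSE]
  kind <- kind[keep]
  counts <- counts[keep]
  cols <- colnames(m)
  edges <- list()
  if (length(cols) >= 2L) {
    loci_sets <- lapply(seq_along(cols), function(j) rownames(m)[m[, j]])
    for (i in seq_len(length(cols) - 1L)) {
      for (j in seq(i + 1L, length(cols))) {
        s <- simpson_coefficient(loci_sets[[i]], loci_sets[[j]])
        if (!is.na(s) && s >= tau) {
          pair <- sort(c(cols[i], cols[j]))
          swap <- !identical(pair, c(cols[i], cols[j]))
          edges[[length(edges) + 1L]] <- data.frame(
            u = pair[1], v = pair[2], simpson = s,
            u_kind = if (swap) kind[j] else kind[i],
            v_kind = if (swap) kind[i] else kind[j],
            u_count = unname(if (swap) counts[j] else counts[i]),
            v_count = unname(if (swap) counts[i] else counts[j]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(edges)) do.call(rbind, edges) else
    data.frame(u = character(0), v = character(0), simpson = numeric(0),
               u_kind = character(0), v_kind = character(0),
               u_count = integer(0), v_count = integer(0))
  out <- out[order(out$u, out$v), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export the network as GraphML
#'
#' Nodes carry `kind` and `locus_count` attributes; edges carry the
#' Simpson coefficient as `weight`.
#'
#' @param edges Edge data frame from [build_network()].
#' @param path Output file.
#' @return Invisibly, the igraph object.
#' @export
write_graphml <- function(edges, path) {
  nodes <- unique(data.frame(
    name = c(edges$u, edges$v),
    kind = c(edges$u_kind, edges$v_kind),
    locus_count = c(edges$u_count, edges$v_count),
    stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(
    edges[, c("u", "v", "simpson")], directed = FALSE, vertices = nodes)
  igraph::E(g)$weight <- edges$simpson
  igraph::write_graph(g, path, format = "graphml")
  invisible(g)
}
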