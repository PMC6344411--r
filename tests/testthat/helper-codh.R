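# Shared fixtures and independent oracles for the test suite.

# Anchors/templates are deterministic in the seed; build once per run.
ref_anchors <- generate_reference_anchors(seed = 1)
ref_templates <- group_templates(ref_anchors)

random_protein <- function(n, alphabet = c("A", "C", "D", "E", "F", "G", "H",
                                           "I", "K", "L", "M", "N", "P", "Q",
                                           "R", "S", "T", "V", "W", "Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Independent brute-force affine-gap DP (score only), written as a plain
# three-state dynamic program over score matrices; no traceback, no C++.
oracle_align_score <- function(a, b, sub, gap_open = 11, gap_extend = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  A[!A %in% rownames(sub)] <- "X"; B[!B %in% rownames(sub)] <- "X"
  n <- length(A); m <- length(B)
  NEG <- -Inf
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (n > 0) X[2:(n + 1), 1] <- -(gap_open + gap_extend * (0:(n - 1)))
  if (m > 0) Y[1, 2:(m + 1)] <- -(gap_open + gap_extend * (0:(m - 1)))
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- sub[A[i], B[j]]
      M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open,
                             X[i, j + 1] - gap_extend,
                             Y[i, j + 1] - gap_open)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open,
                             X[i + 1, j] - gap_open,
                             Y[i + 1, j] - gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Exhaustive hypergeometric enumeration for the one-sided Fisher test.
oracle_fisher_greater <- function(a, b, c, d) {
  k <- a + b; K <- a + c; n <- a + b + c + d
  if (k == 0 || K == 0) return(1)
  avals <- max(0, k - (n - K)):min(k, K)
  probs <- stats::dhyper(avals, K, n - K, k)
  sum(probs[avals >= a])
}

# Direct rule simulation of the directon definition.
oracle_directon <- function(genes, codh_index, max_gap_bp = 300,
                            max_side_genes = 15) {
  gap <- function(l, r) max(0, genes$start[r] - genes$end[l] - 1)
  strand <- genes$strand[codh_index]
  repl <- genes$replicon_id[codh_index]
  lo <- codh_index
  added <- 0
  while (lo > 1 && added < max_side_genes &&
         genes$replicon_id[lo - 1] == repl &&
         genes$strand[lo - 1] == strand && gap(lo - 1, lo) <= max_gap_bp) {
    lo <- lo - 1; added <- added + 1
  }
  hi <- codh_index
  added <- 0
  while (hi < nrow(genes) && added < max_side_genes &&
         genes$replicon_id[hi + 1] == repl &&
         genes$strand[hi + 1] == strand && gap(hi, hi + 1) <= max_gap_bp) {
    hi <- hi + 1; added <- added + 1
  }
  lo:hi
}

# Brute-force D-region scanner: explicit position loops, no regex.
oracle_d_region <- function(region) {
  ch <- strsplit(region, "")[[1]]
  n <- length(ch)
  is_c <- ch == "C"
  type1 <- FALSE; type2 <- FALSE; type3 <- FALSE
  for (p in seq_len(n)) {
    if (!is_c[p]) next
    if (p + 4 <= n && is_c[p + 3] && is_c[p + 4]) type1 <- TRUE
    if (p + 9 <= n && is_c[p + 3] && is_c[p + 9]) type3 <- TRUE
    for (k in 7:13)
      if (p + k + 2 <= n && is_c[p + k + 1] && is_c[p + k + 2]) type2 <- TRUE
  }
  if (type1) return("I")
  if (type3) return("III")
  if (type2) return("II")
  "none"
}

# A small synthetic replicon table for directon tests.
make_replicon <- function(n, strands, gaps, lens = NULL, replicon = "r1",
                          genome = "g1", codh = integer(0)) {
  if (is.null(lens)) lens <- rep(900L, n)
  starts <- integer(n); ends <- integer(n)
  pos <- 1L
  for (i in seq_len(n)) {
    pos <- pos + gaps[i]
    starts[i] <- pos + 1L
    ends[i] <- starts[i] + lens[i] - 1L
    pos <- ends[i]
  }
  data.frame(genome_id = genome, replicon_id = replicon,
             ordinal = seq_len(n), start = starts, end = ends,
             strand = strands, protein_id = sprintf("%s_p%03d", genome, seq_len(n)),
             is_codh = seq_len(n) %in% codh, pseudo = FALSE,
             stringsAsFactors = FALSE)
}
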