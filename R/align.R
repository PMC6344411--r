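# Implemented stand-ins for the external alignment toolchain: affine-gap
# global pairwise alignment, anchor-position mapping, gap-threshold column
# trimming, and nearest-anchor clade assignment.

#' BLOSUM62 substitution table with neutral X
#'
#' The BLOSUM62 matrix (as shipped by Biostrings) restricted to the 20
#' standard residues plus `X`, with `X` scored 0 against every residue.
#'
#' @return A 21 x 21 numeric matrix with dimnames.
#' @export
blosum62_x0 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62[c(AA20, "X"), c(AA20, "X")]
  m["X", ] <- 0
  m[, "X"] <- 0
  storage.mode(m) <- "double"
  m
}

.encode_aa <- function(seq, alphabet) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  idx <- match(ch, alphabet)
  idx[is.na(idx)] <- match("X", alphabet)
  idx - 1L
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh alignment of two amino-acid sequences.  A gap run
#' of length L costs `gap_open + gap_extend * (L - 1)`: the opening residue
#' carries the full `gap_open` penalty, so a length-1 gap costs 11 under the
#' defaults.  Traceback is deterministic with operation precedence
#' diagonal > vertical (a residue of `seq_a` over a gap) > horizontal.
#' Unknown residues are treated as `X` and score 0 against everything.
#' An empty sequence yields the all-gap alignment with score
#' `-(gap_open + gap_extend * (len - 1))` against the other.
#'
#' @param seq_a,seq_b Character scalars (amino-acid sequences; `X` allowed).
#' @param substitution Substitution matrix with residue dimnames containing
#'   an `X` row/column; default [blosum62_x0()].
#' @param gap_open,gap_extend Affine gap parameters (positive costs).
#' @return A list with `score`, `aligned_a`, `aligned_b` (equal-length
#'   gapped strings, gap character `-`).
#' @export
#' @examples
#' global_align("ACDE", "ACDE")$score
#' global_align("A", "")$score  # -11
global_align <- function(seq_a, seq_b, substitution = blosum62_x0(),
                         gap_open = 11, gap_extend = 1) {
  stopifnot(is.character(seq_a), is.character(seq_b),
            length(seq_a) == 1L, length(seq_b) == 1L,
            gap_open >= 0, gap_extend >= 0)
  alphabet <- rownames(substitution)
  ai <- .encode_aa(seq_a, alphabet)
  bi <- .encode_aa(seq_b, alphabet)
  res <- .nw_affine(ai, bi, substitution, gap_open, gap_extend)
  a_ch <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1]]
  b_ch <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1]]
  ops <- res$ops
  out_a <- character(length(ops))
  out_b <- character(length(ops))
  i <- 0L; j <- 0L
  for (k in seq_along(ops)) {
    if (ops[k] == 0L) {
      i <- i + 1L; j <- j + 1L
      out_a[k] <- a_ch[i]; out_b[k] <- b_ch[j]
    } else if (ops[k] == 1L) {
      i <- i + 1L
      out_a[k] <- a_ch[i]; out_b[k] <- "-"
    } else {
      j <- j + 1L
      out_a[k] <- "-"; out_b[k] <- b_ch[j]
    }
  }
  list(score = res$score,
       aligned_a = paste(out_a, collapse = ""),
       aligned_b = paste(out_b, collapse = ""))
}

#' Map named anchor positions onto a query
#'
#' Globally aligns the query against the anchor sequence and maps every
#' named anchor position (cluster residues, catalytic residues, region
#' boundaries) onto 1-based query coordinates; positions aligned to a gap
#' in the query map to `NA` ("absent").
#'
#' @param query A character scalar (sequence) or a list with `id` and `seq`.
#' @param anchor An anchor profile from [anchor_profile()] /
#'   [generate_reference_anchors()].
#' @param ... Passed on to [global_align()].
#' @return A list of class `codh_position_map`: `query_id`, and for each
#'   named position slot an integer vector of query coordinates (`NA` =
#'   absent), plus `query_length`.
#' @export
map_anchor_positions <- function(query, anchor, ...) {
  qseq <- if (is.list(query)) query$seq else query
  qid <- if (is.list(query) && !is.null(query$id)) query$id else NA_character_
  aln <- global_align(qseq, anchor$sequence, ...)
  q_ch <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  a_ch <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  # For each anchor coordinate, the aligned column and the query coordinate.
  a_pos <- cumsum(a_ch != "-")
  q_pos <- cumsum(q_ch != "-")
  col_of_anchor <- match(seq_len(nchar(anchor$sequence)), a_pos)
  map1 <- function(p) {
    cols <- col_of_anchor[p]
    out <- ifelse(q_ch[cols] == "-", NA_integer_, q_pos[cols])
    as.integer(out)
  }
  slots <- c("d_positions", "b_cluster", "c_cluster", "acid_base",
             "e_cluster", "f_cluster")
  out <- list(query_id = qid, query_length = nchar(qseq))
  for (s in slots) {
    out[[s]] <- if (is.null(anchor[[s]])) NULL else map1(anchor[[s]])
  }
  out$d_region <- map1(anchor$d_region)
  out$core_start <- map1(anchor$core_start)
  out$core_end <- map1(anchor$core_end)
  structure(out, class = "codh_position_map")
}

#' Trim alignment columns by gap fraction
#'
#' Reproduces gap-threshold column trimming: a column is retained iff the
#' fraction of non-gap characters is at least `gap_threshold` (a column
#' sitting exactly at the threshold is kept).
#'
#' @param msa Character vector of equal-length aligned sequences.
#' @param gap_threshold Minimum non-gap fraction in `[0, 1]`; default 0.9.
#' @return Integer vector of retained (1-based) column indices.
#' @export
trim_alignment_columns <- function(msa, gap_threshold = 0.9) {
  stopifnot(length(msa) >= 1L, gap_threshold >= 0, gap_threshold <= 1)
  w <- unique(nchar(msa))
  if (length(w) != 1L) stop("all aligned sequences must have equal length")
  mat <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  nongap <- colMeans(mat != "-")
  which(nongap >= gap_threshold)
}

#' Assign a clade by nearest-anchor scoring
#'
#' Scores the query against every reference anchor with [global_align()]
#' and returns the clade of the best-scoring anchor.  This is a declared
#' stand-in for reading clades off a phylogenetic tree: assignments whose
#' top-two score margin falls below `ambiguity_delta` are flagged
#' ambiguous (ties resolve to the alphabetically first clade, flagged).
#'
#' @param query Character scalar sequence or list with `seq`.
#' @param anchors List of anchor profiles (one per clade).
#' @param ambiguity_delta Minimum top-two score margin; default 5.
#' @param ... Passed on to [global_align()].
#' @return A list: `clade`, `score`, `margin`, `ambiguous`, and the full
#'   named `scores` vector.
#' @export
assign_clade <- function(query, anchors, ambiguity_delta = 5, ...) {
  stopifnot(length(anchors) >= 1L)
  qseq <- if (is.list(query)) query$seq else query
  clades <- vapply(anchors, function(a) a$clade, character(1))
  scores <- vapply(anchors, function(a) global_align(qseq, a$sequence, ...)$score,
                   numeric(1))
  names(scores) <- clades
  ord <- order(-scores, clades)  # ties broken by clade alphabetical order
  best <- ord[1L]
  margin <- if (length(scores) > 1L) scores[best] - max(scores[-best]) else Inf
  list(clade = unname(clades[best]),
       score = unname(scores[best]),
       margin = unname(margin),
       ambiguous = margin < ambiguity_delta,
       scores = scores)
}
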