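# Structural classifier: reads the metal-cluster/catalyst signature of a
# query at anchor-mapped positions and assigns one of the 24 structural
# groups (or "others") by the per-clade decision table.

#' Classify a D-cluster region into motif types
#'
#' Scans the (already extracted) D-region string for the three D-cluster
#' Cys-spacing motifs: type I `Cys-X-X-Cys-Cys`, type II
#' `Cys-(X)7-13-Cys-Cys`, type III `Cys-X-X-Cys-(X)5-Cys` (X = any
#' residue).  Precedence when several match is I > III > II
#' (most-specific first).  Regions matching no pattern -- including
#' regions with one or no Cys at all -- return `"none"`.
#'
#' @param region Character scalar: the query subsequence mapped from the
#'   anchor's D-region span, widened by a small slack on each side.
#' @return One of `"I"`, `"II"`, `"III"`, `"none"`.
#' @export
#' @examples
#' classify_d_region("AACWSCCAA")          # type I
#' classify_d_region(paste0("C", strrep("A", 7), "CC"))  # type II
classify_d_region <- function(region) {
  if (is.na(region) || !nzchar(region)) return("none")
  if (grepl("C..CC", region)) return("I")
  if (grepl("C..C.{5}C", region)) return("III")
  if (grepl("C.{7,13}CC", region)) return("II")
  "none"
}

.res_at <- function(chars, pos) {
  if (is.null(pos)) return(NULL)
  out <- rep("absent", length(pos))
  ok <- !is.na(pos)
  out[ok] <- chars[pos[ok]]
  out
}

#' Extract the core residue signature at mapped cluster positions
#'
#' Reads the query residue at every mapped D-/B-/C-cluster and acid-base
#' position (`"absent"` where the query has a gap), sets the completeness
#' flags, and types the D-region with [classify_d_region()].
#'
#' @param query Character scalar sequence or list with `seq`.
#' @param position_map From [map_anchor_positions()].
#' @param anchor The anchor profile used for the mapping.
#' @param d_slack Residues of slack added on each side of the mapped
#'   D-region before motif scanning; default 5.
#' @return A list with `d_type`, `c_cluster` (6 states), `acid_base`
#'   (2 states), `b_complete`, `e_complete`, `f_complete` (`NA` for
#'   clades without E/F positions).
#' @export
extract_site_signature <- function(query, position_map, anchor, d_slack = 5L) {
  qseq <- if (is.list(query)) query$seq else query
  chars <- strsplit(qseq, "", fixed = TRUE)[[1]]
  b <- .res_at(chars, position_map$b_cluster)
  cc <- .res_at(chars, position_map$c_cluster)
  ab <- .res_at(chars, position_map$acid_base)
  e <- .res_at(chars, position_map$e_cluster)
  f <- .res_at(chars, position_map$f_cluster)

  span <- position_map$d_region
  if (anyNA(span)) {
    fallback <- range(c(span, position_map$d_positions), na.rm = TRUE)
    span <- if (all(is.finite(fallback))) as.integer(fallback) else NA_integer_
  }
  region <- if (anyNA(span)) "" else
    substr(qseq, max(1L, span[1] - d_slack),
           min(length(chars), span[2] + d_slack))

  list(d_type = classify_d_region(region),
       c_cluster = cc, acid_base = ab,
       b_complete = all(b == "C"),
       e_complete = if (is.null(e)) NA else all(e == "C"),
       f_complete = if (is.null(f)) NA else all(f == "C"))
}

.max_cys_window <- function(region, window = 20L) {
  chars <- strsplit(region, "", fixed = TRUE)[[1]]
  pos <- which(chars == "C")
  if (length(pos) == 0L) return(0L)
  best <- max(vapply(pos, function(p)
    sum(pos >= p & pos < p + window), integer(1)))
  best
}

.his_rich <- function(region) {
  chars <- strsplit(region, "", fixed = TRUE)[[1]]
  n_his <- sum(chars == "H")
  if (n_his < 4L) return(FALSE)
  starts <- which(chars == "H")
  starts <- starts[starts + 2L <= length(chars) & chars[starts + 2L] == "H"]
  length(starts) >= 2L && any(diff(sort(starts)) <= 2L)
}

#' Detect N-/C-terminal accessory motifs
#'
#' The N-terminal region is the query sequence before the mapped core
#' start; the C-terminal region follows the mapped core end.  The terminal
#' Cys motif count is the maximal number of Cys inside any 20-residue
#' window of the region, reported when at least 2 (capped at 4, matching
#' the observed "two to four Cys" motifs).  A region is His-rich iff it
#' holds at least 4 His and at least two overlapping `His-X-His` repeats.
#'
#' @inheritParams extract_site_signature
#' @param window Window width for Cys counting; default 20 residues.
#' @return A list: `nterm_cys_count`, `cterm_cys_count`,
#'   `nterm_his_rich`, `cterm_his_rich`.
#' @export
detect_terminal_motifs <- function(query, position_map, window = 20L) {
  qseq <- if (is.list(query)) query$seq else query
  len <- nchar(qseq)
  cs <- position_map$core_start
  ce <- position_map$core_end
  nterm <- if (is.na(cs) || cs <= 1L) "" else substr(qseq, 1L, cs - 1L)
  cterm <- if (is.na(ce) || ce >= len) "" else substr(qseq, ce + 1L, len)
  count <- function(region) {
    k <- if (nzchar(region)) .max_cys_window(region, window) else 0L
    if (k < 2L) 0L else min(k, 4L)
  }
  list(nterm_cys_count = count(nterm),
       cterm_cys_count = count(cterm),
       nterm_his_rich = nzchar(nterm) && .his_rich(nterm),
       cterm_his_rich = nzchar(cterm) && .his_rich(cterm))
}

#' Detect Cys x 4 insertions and protein fusions
#'
#' `c_insertion_cys4` is true iff at least 4 Cys occur strictly between
#' the mapped acid-base His-site column and the mapped C-cluster His
#' column (the C-4 signature).  `extra_ef_cys4_count` counts disjoint
#' windows of at most `ef_window` residues holding >= 4 Cys strictly
#' between the E- and F-cluster spans (the tandem A-5 signatures), scanned
#' greedily left to right; clades without E/F positions report 0.
#' `fusion` flags queries longer than the anchor by more than
#' `fusion_slack` residues.
#'
#' @inheritParams extract_site_signature
#' @param ef_window Maximum window width for an E/F insertion; default 30.
#' @param fusion_slack Length excess marking a fusion; default 200.
#' @return A list: `c_insertion_cys4`, `extra_ef_cys4_count`, `fusion`.
#' @export
detect_insertions <- function(query, position_map, anchor, ef_window = 30L,
                              fusion_slack = 200L) {
  qseq <- if (is.list(query)) query$seq else query
  chars <- strsplit(qseq, "", fixed = TRUE)[[1]]
  cys <- which(chars == "C")

  span_count <- function(lo, hi) {
    if (is.na(lo) || is.na(hi) || hi - lo < 2L) return(integer(0))
    cys[cys > lo & cys < hi]
  }
  ins <- span_count(position_map$acid_base[1], position_map$c_cluster[1])
  c_insertion <- length(ins) >= 4L

  ef_count <- 0L
  if (!is.null(position_map$e_cluster) && !is.null(position_map$f_cluster)) {
    lo <- suppressWarnings(max(position_map$e_cluster, na.rm = TRUE))
    hi <- suppressWarnings(min(position_map$f_cluster, na.rm = TRUE))
    pool <- if (is.finite(lo) && is.finite(hi)) span_count(lo, hi) else integer(0)
    while (length(pool) >= 4L) {
      inwin <- pool[pool <= pool[1] + ef_window - 1L]
      if (length(inwin) >= 4L) {
        ef_count <- ef_count + 1L
        pool <- pool[pool > max(inwin)]
      } else {
        pool <- pool[-1L]
      }
    }
  }

  list(c_insertion_cys4 = c_insertion,
       extra_ef_cys4_count = ef_count,
       fusion = nchar(qseq) > nchar(anchor$sequence) + fusion_slack)
}

#' Assemble the full structural signature of a query
#'
#' Convenience wrapper running [extract_site_signature()],
#' [detect_terminal_motifs()] and [detect_insertions()] on one position
#' map.
#'
#' @inheritParams extract_site_signature
#' @return A list of class `codh_signature` with all signature fields.
#' @export
structural_signature <- function(query, position_map, anchor) {
  sig <- c(extract_site_signature(query, position_map, anchor),
           detect_terminal_motifs(query, position_map),
           detect_insertions(query, position_map, anchor))
  class(sig) <- "codh_signature"
  sig
}

# All decision rows matching a (clade, signature) pair.  Used by
# assign_structural_group() and directly testable for mutual exclusivity.
.match_rows <- function(clade, sig) {
  cc <- sig$c_cluster
  ab <- sig$acid_base
  cc_eq <- function(...) identical(unname(cc), c(...))
  ab_eq <- function(...) identical(unname(ab), c(...))
  d <- sig$d_type
  ntc <- sig$nterm_cys_count >= 2L
  nhr <- isTRUE(sig$nterm_his_rich)
  chr <- isTRUE(sig$cterm_his_rich)
  cins <- isTRUE(sig$c_insertion_cys4)
  ef <- sig$extra_ef_cys4_count
  if (!isTRUE(sig$b_complete)) return(character(0))

  hits <- character(0)
  add <- function(cond, label) if (isTRUE(cond)) hits <<- c(hits, label)

  if (clade == "A") {
    e <- isTRUE(sig$e_complete); f <- isTRUE(sig$f_complete)
    add(d == "I"    & e & f  & cc_eq("H","C","C","C","C","C") & ab_eq("H","K") & ef == 0L, "A-1")
    add(d == "none" & e & f  & cc_eq("H","C","C","C","C","C") & ab_eq("H","K") & ef == 0L, "A-2")
    add(d == "none" & !e & !f & cc_eq("H","C","C","C","C","C") & ab_eq("H","K"),           "A-3")
    add(d == "none" & e & f  & cc_eq("D","P","C","C","C","C") & ab_eq("Q","R"),            "A-4")
    add(d == "none" & e & f  & cc_eq("H","C","C","C","C","C") & ab_eq("H","K") & ef == 2L, "A-5")
    add(d == "none" & e & !f & cc_eq("N","S","C","C","C","C") & ab_eq("H","L"),            "A-6")
  } else if (clade == "B") {
    base <- d == "II" & ab_eq("H","K") & cc[1] == "H" & cc[2] == "C" &
      all(cc[4:6] == "C")
    add(base & cc[3] %in% c("D", "E") & nhr,         "B-1")
    add(base & cc[3] == "D" & !nhr & !chr,           "B-2")
    add(base & cc[3] == "D" & !nhr & chr,            "B-3")
    add(base & cc[3] == "C" & !nhr & !chr,           "B-4")
  } else if (clade == "C") {
    base <- cc_eq("H","C","C","C","C","C") & ab_eq("Y","Q")
    add(base & d == "II" & ntc & !cins,   "C-1")
    add(base & d == "II" & !ntc & !cins,  "C-2")
    add(base & d == "none",               "C-3")
    add(base & d == "II" & !ntc & cins,   "C-4")
  } else if (clade == "D") {
    base <- cc[1] == "H" & all(cc[3:6] == "C")
    add(base & d == "III" & cc[2] == "E" & ab_eq("Y","K"),         "D-1")
    add(base & d == "III" & cc[2] == "C" & ab_eq("N","K"),         "D-2")
    add(base & d == "II"  & cc[2] == "C" & ab_eq("Y","K") & ntc,   "D-3")
    add(base & d == "II"  & cc[2] == "C" & ab_eq("Y","K") & !ntc,  "D-4")
  } else if (clade == "E") {
    base <- cc_eq("H","C","C","C","C","C") & ab_eq("H","K")
    add(base & d == "II" & !ntc,  "E-1")
    add(base & d == "III",        "E-2")
    add(base & d == "II" & ntc,   "E-3")
  } else if (clade == "F") {
    base <- cc_eq("H","C","C","C","C","C") & ab_eq("H","K")
    add(base & d == "II" & !ntc,  "F-1")
    add(base & d == "II" & ntc,   "F-2")
  } else if (clade == "G") {
    add(d == "III" & cc[1] == "H" & cc[2] == "T" & all(cc[3:6] == "C") &
          ab_eq("Y","K"), "G-1")
  }
  hits
}

#' Assign a structural group from clade and signature
#'
#' Applies the per-clade decision rows of the group table; any signature
#' matched by no row falls into `"others"`.  The function is total: every
#' (clade, signature) pair yields exactly one label.
#'
#' @param clade Clade label `"A"`..`"G"`.
#' @param signature A `codh_signature` (see [structural_signature()]).
#' @return A list: `group_label`, `clade`, `signature`, `notes`.
#' @export
assign_structural_group <- function(clade, signature) {
  hits <- .match_rows(clade, signature)
  label <- if (length(hits) >= 1L) hits[1L] else "others"
  notes <- character(0)
  if (length(hits) > 1L)
    notes <- paste("multiple decision rows matched:", paste(hits, collapse = ","))
  if (isTRUE(signature$fusion)) notes <- c(notes, "fusion-length query")
  list(group_label = label, clade = clade, signature = signature,
       notes = paste(notes, collapse = "; "))
}

#' Classify proteins end to end
#'
#' For each query: nearest-anchor clade assignment, anchor-position
#' mapping, signature extraction, completeness check (no deletions at
#' D-/B-/C-cluster or catalyst positions) and group assignment.
#'
#' @param proteins Named character vector of sequences.
#' @param anchors Anchors (named list of `codh_anchor`).
#' @param ambiguity_delta Passed to [assign_clade()].
#' @param ... Passed to [global_align()].
#' @return A data.frame with one row per protein: identifiers, clade
#'   assignment (score, margin, ambiguity), the full signature columns,
#'   `complete` (cluster-region completeness) and `group_label`.
#' @export
classify_proteins <- function(proteins, anchors, ambiguity_delta = 5, ...) {
  stopifnot(length(proteins) >= 1L, !is.null(names(proteins)))
  rows <- lapply(names(proteins), function(id) {
    qseq <- proteins[[id]]
    cl <- assign_clade(qseq, anchors, ambiguity_delta = ambiguity_delta, ...)
    anchor <- anchors[[cl$clade]]
    pm <- map_anchor_positions(list(id = id, seq = qseq), anchor, ...)
    sig <- structural_signature(qseq, pm, anchor)
    complete <- !anyNA(c(pm$d_positions, pm$b_cluster, pm$c_cluster,
                         pm$acid_base))
    grp <- assign_structural_group(cl$clade, sig)
    data.frame(protein_id = id, clade = cl$clade,
               clade_score = cl$score, clade_margin = cl$margin,
               ambiguous = cl$ambiguous, complete = complete,
               group_label = grp$group_label,
               d_type = sig$d_type,
               c_cluster = paste(sig$c_cluster, collapse = ""),
               acid_base = paste(sig$acid_base, collapse = ""),
               b_complete = sig$b_complete,
               e_complete = sig$e_complete, f_complete = sig$f_complete,
               nterm_cys_count = sig$nterm_cys_count,
               cterm_cys_count = sig$cterm_cys_count,
               nterm_his_rich = sig$nterm_his_rich,
               cterm_his_rich = sig$cterm_his_rich,
               c_insertion_cys4 = sig$c_insertion_cys4,
               extra_ef_cys4_count = sig$extra_ef_cys4_count,
               fusion = sig$fusion, notes = grp$notes,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
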