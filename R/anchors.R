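# Anchor profiles: clade-labeled reference sequences with a ledger of named
# cluster/catalyst positions.  Anchors stand in for the representative
# sequences of each clade; users may supply their own via the JSON sidecar.

#' Construct an anchor profile
#'
#' @param clade Clade label, one of `"A"`..`"G"`.
#' @param sequence Amino-acid sequence (character scalar).
#' @param d_region Length-2 integer span (start, end) of the D-cluster
#'   region.
#' @param d_positions Integer positions of the anchor's own D-cluster Cys
#'   residues (used by the completeness filter).
#' @param b_cluster Four B-cluster Cys positions.
#' @param c_cluster Six C-cluster positions, strictly increasing
#'   (His site, Cys1..Cys5).
#' @param acid_base Two catalytic positions (His site, Lys site).
#' @param e_cluster,f_cluster Four positions each; `NULL` for clades other
#'   than the Cdh-type clade A.
#' @param core_start,core_end First/last core column; residues before
#'   `core_start` / after `core_end` form the N-/C-terminal extension
#'   regions scanned for accessory motifs.
#' @param scaffold Optional unplanted background sequence (kept by the
#'   synthetic generator; not used by the classifier).
#' @return A list of class `codh_anchor`.
#' @export
anchor_profile <- function(clade, sequence, d_region, d_positions, b_cluster,
                           c_cluster, acid_base, e_cluster = NULL,
                           f_cluster = NULL, core_start, core_end,
                           scaffold = NULL) {
  p <- structure(list(
    clade = as.character(clade), sequence = toupper(sequence),
    d_region = as.integer(d_region), d_positions = as.integer(d_positions),
    b_cluster = as.integer(b_cluster), c_cluster = as.integer(c_cluster),
    acid_base = as.integer(acid_base),
    e_cluster = if (is.null(e_cluster)) NULL else as.integer(e_cluster),
    f_cluster = if (is.null(f_cluster)) NULL else as.integer(f_cluster),
    core_start = as.integer(core_start), core_end = as.integer(core_end),
    scaffold = scaffold), class = "codh_anchor")
  validate_anchor_profile(p)
  p
}

#' @rdname anchor_profile
#' @param x A `codh_anchor` object.
#' @export
validate_anchor_profile <- function(x) {
  len <- nchar(x$sequence)
  pos <- c(x$d_region, x$d_positions, x$b_cluster, x$c_cluster, x$acid_base,
           x$e_cluster, x$f_cluster, x$core_start, x$core_end)
  if (any(pos < 1L | pos > len))
    stop("anchor position outside [1, ", len, "]")
  if (any(diff(x$c_cluster) <= 0))
    stop("c_cluster positions must be strictly increasing")
  if (x$core_start > min(c(x$d_region, x$b_cluster, x$c_cluster, x$acid_base)))
    stop("core_start must not exceed the first cluster position")
  if (!x$clade %in% LETTERS[1:7]) stop("clade must be one of A-G")
  if (length(x$b_cluster) != 4L || length(x$c_cluster) != 6L ||
      length(x$acid_base) != 2L || length(x$d_region) != 2L)
    stop("malformed anchor position ledger")
  invisible(x)
}

#' @export
print.codh_anchor <- function(x, ...) {
  cat(sprintf("<codh_anchor> clade %s, %d aa; C-cluster at %s; E/F clusters: %s\n",
              x$clade, nchar(x$sequence),
              paste(x$c_cluster, collapse = ","),
              if (is.null(x$e_cluster)) "none" else "present"))
  invisible(x)
}

#' Read and write anchor profile sidecars
#'
#' Anchor profiles are serialized as a JSON array (clade, sequence, and the
#' named 1-based position slots).
#'
#' @param anchors List of `codh_anchor` objects.
#' @param path File path.
#' @return `read_anchor_sidecar()`: a named list of `codh_anchor` objects.
#' @export
write_anchor_sidecar <- function(anchors, path) {
  payload <- lapply(unname(anchors), function(a) {
    a[!vapply(a, is.null, logical(1))]
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_anchor_sidecar
#' @export
read_anchor_sidecar <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  anchors <- lapply(raw, function(a) {
    anchor_profile(clade = a$clade, sequence = a$sequence,
                   d_region = a$d_region, d_positions = a$d_positions,
                   b_cluster = a$b_cluster, c_cluster = a$c_cluster,
                   acid_base = a$acid_base, e_cluster = a$e_cluster,
                   f_cluster = a$f_cluster, core_start = a$core_start,
                   core_end = a$core_end, scaffold = a$scaffold)
  })
  names(anchors) <- vapply(anchors, function(a) a$clade, character(1))
  anchors[order(names(anchors))]
}
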