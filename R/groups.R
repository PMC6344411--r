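# Group-definition table and canonical scaffold layout.
#
# The 24 structural groups are defined by discrete residue states at the
# metal-cluster and catalytic positions: the D-cluster motif type, the six
# C-cluster states (His site then Cys1..Cys5), the acid-base catalyst pair
# (His site, Lys site), E-/F-cluster completeness (Cdh-type clade A only),
# and accessory motifs (N-terminal Cys motifs, terminal His-rich regions,
# Cys x 4 insertions).  Both the classifier and the synthetic generator are
# driven by this table; the classifier additionally applies precedence rules
# so that every signature maps to exactly one label.

#' The structural-group definition table
#'
#' One row per structural group: the clade, the D-cluster motif type
#' (`"I"`, `"II"`, `"III"` or `"none"`), the six C-cluster residue states
#' (His site, Cys1..Cys5), the acid-base catalyst pair, E-/F-cluster
#' completeness flags (meaningful for clade A only), and accessory-motif
#' requirements (`nterm_cys` = number of Cys planted in the N-terminal
#' extension motif, 0 if none; His-rich terminal flags; the Cys x 4
#' C-cluster insertion; the count of extra Cys x 4 motifs between the E-
#' and F-clusters).
#'
#' @return A data.frame with 24 rows.
#' @export
#' @examples
#' tab <- codh_group_table()
#' table(tab$clade)
codh_group_table <- function() {
  # columns: group clade d c1..c6 (His,Cys1..Cys5) ab1 ab2 e f
  #          nterm_cys nterm_his_rich cterm_his_rich c_insertion ef_cys4
  rows <- list(
    #       grp    cl  d      His C1  C2  C3  C4  C5  ab1 ab2 e     f     nC nHR    cHR    cIns   ef
    list("A-1", "A", "I",    "H","C","C","C","C","C","H","K", TRUE, TRUE, 0L, FALSE, FALSE, FALSE, 0L),
    list("A-2", "A", "none", "H","C","C","C","C","C","H","K", TRUE, TRUE, 0L, FALSE, FALSE, FALSE, 0L),
    list("A-3", "A", "none", "H","C","C","C","C","C","H","K", FALSE,FALSE,0L, FALSE, FALSE, FALSE, 0L),
    list("A-4", "A", "none", "D","P","C","C","C","C","Q","R", TRUE, TRUE, 0L, FALSE, FALSE, FALSE, 0L),
    list("A-5", "A", "none", "H","C","C","C","C","C","H","K", TRUE, TRUE, 0L, FALSE, FALSE, FALSE, 2L),
    list("A-6", "A", "none", "N","S","C","C","C","C","H","L", TRUE, FALSE,0L, FALSE, FALSE, FALSE, 0L),
    list("B-1", "B", "II",   "H","C","D","C","C","C","H","K", NA,   NA,   0L, TRUE,  FALSE, FALSE, 0L),
    list("B-2", "B", "II",   "H","C","D","C","C","C","H","K", NA,   NA,   0L, FALSE, FALSE, FALSE, 0L),
    list("B-3", "B", "II",   "H","C","D","C","C","C","H","K", NA,   NA,   0L, FALSE, TRUE,  FALSE, 0L),
    list("B-4", "B", "II",   "H","C","C","C","C","C","H","K", NA,   NA,   0L, FALSE, FALSE, FALSE, 0L),
    list("C-1", "C", "II",   "H","C","C","C","C","C","Y","Q", NA,   NA,   3L, FALSE, FALSE, FALSE, 0L),
    list("C-2", "C", "II",   "H","C","C","C","C","C","Y","Q", NA,   NA,   0L, FALSE, FALSE, FALSE, 0L),
    list("C-3", "C", "none", "H","C","C","C","C","C","Y","Q", NA,   NA,   0L, FALSE, FALSE, FALSE, 0L),
    list("C-4", "C", "II",   "H","C","C","C","C","C","Y","Q", NA,   NA,   0L, FALSE, FALSE, TRUE,  0L),
    list("D-1", "D", "III",  "H","E","C","C","C","C","Y","K", NA,   NA,   0L, FALSE, FALSE, FALSE, 0L),
    list("D-2", "D", "III",  "H","C","C","C","C","C","N","K", NA,   NA,   0L, FALSE, FALSE, FALSE, 0L),
    list("D-3", "D", "II",   "H","C","C","C","C","C","Y","K", NA,   NA,   3L, FALSE, FALSE, FALSE, 0L),
    list("D-4", "D", "II",   "H","C","C","C","C","C","Y","K", NA,   NA,   0L, FALSE, FALSE, FALSE, 0L),
    list("E-1", "E", "II",   "H","C","C","C","C","C","H","K", NA,   NA,   0L, FALSE, FALSE, FALSE, 0L),
    list("E-2", "E", "III",  "H","C","C","C","C","C","H","K", NA,   NA,   0L, FALSE, FALSE, FALSE, 0L),
    list("E-3", "E", "II",   "H","C","C","C","C","C","H","K", NA,   NA,   2L, FALSE, FALSE, FALSE, 0L),
    list("F-1", "F", "II",   "H","C","C","C","C","C","H","K", NA,   NA,   0L, FALSE, FALSE, FALSE, 0L),
    list("F-2", "F", "II",   "H","C","C","C","C","C","H","K", NA,   NA,   2L, FALSE, FALSE, FALSE, 0L),
    list("G-1", "G", "III",  "H","T","C","C","C","C","Y","K", NA,   NA,   0L, FALSE, FALSE, FALSE, 0L)
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(group = r[[1]], clade = r[[2]], d_type = r[[3]],
               c_his = r[[4]], c_cys1 = r[[5]], c_cys2 = r[[6]],
               c_cys3 = r[[7]], c_cys4 = r[[8]], c_cys5 = r[[9]],
               ab_his = r[[10]], ab_lys = r[[11]],
               e_complete = r[[12]], f_complete = r[[13]],
               nterm_cys = r[[14]], nterm_his_rich = r[[15]],
               cterm_his_rich = r[[16]], c_insertion = r[[17]],
               ef_cys4 = r[[18]], stringsAsFactors = FALSE)
  }))
  rownames(out) <- out$group
  out
}

#' Enumerate the classification scheme
#'
#' @return `structural_groups()`: the 24 group labels; `codh_clades()`: the
#'   seven clade labels A-G; `d_cluster_types()`: the three D-cluster motif
#'   types.
#' @export
structural_groups <- function() codh_group_table()$group

#' @rdname structural_groups
#' @export
codh_clades <- function() sort(unique(codh_group_table()$clade))

#' @rdname structural_groups
#' @export
d_cluster_types <- function() c("I", "II", "III")

# Representative group realized by each clade's reference anchor.
.clade_representative <- c(A = "A-1", B = "B-4", C = "C-2", D = "D-4",
                           E = "E-1", F = "F-1", G = "G-1")

# Canonical scaffold layout (1-based positions on a 650-residue scaffold).
# The layout is shared by all synthetic clades; real anchors supplied by a
# user carry their own position ledger.  Positions:
#   N-terminal extension  1 .. core_start-1      (accessory Cys / His-rich)
#   D-cluster region      d_region[1] .. [2]     (motif types planted at
#                                                 fixed offsets inside it)
#   E-/F-clusters         clade A only; the span between them hosts the
#                         tandem Cys x 4 insertions of group A-5
#   B-cluster             four Cys positions
#   acid-base catalysts   His site (upstream of the C-cluster His, so the
#                         C-4 insertion span lies between them) + Lys site
#   C-cluster             His site then Cys1..Cys5, strictly increasing
#   C-terminal extension  core_end+1 .. scaffold_length
.codh_layout <- function(scaffold_length = 650L) {
  stopifnot(scaffold_length >= 650L)
  list(
    scaffold_length = as.integer(scaffold_length),
    core_start = 41L,
    core_end   = 620L,
    d_region   = c(45L, 75L),
    d_offsets  = list(I = c(50L, 53L, 54L), II = c(50L, 60L, 61L),
                      III = c(50L, 53L, 59L), single = 50L),
    e_cluster  = c(90L, 95L, 100L, 105L),
    f_cluster  = c(230L, 235L, 240L, 245L),
    ef_insert  = list(c(130L, 133L, 136L, 139L), c(180L, 183L, 186L, 189L)),
    b_cluster  = c(280L, 285L, 290L, 295L),
    acid_base  = c(380L, 600L),
    c_insert   = c(400L, 405L, 410L, 415L),
    c_cluster  = c(450L, 460L, 470L, 520L, 526L, 555L),
    nterm_cys  = c(10L, 13L, 16L, 19L),
    nterm_his  = c(20L, 22L, 24L, 26L, 28L, 30L),
    cterm_his  = c(630L, 632L, 634L, 636L, 638L, 640L)
  )
}

# Residue plan for one group on the canonical layout: a named character
# vector position -> residue.  Every position that any group's motif can
# occupy is assigned explicitly (motif residue or 'A' filler) so that two
# groups of the same clade differ only at signature positions.
.group_residue_plan <- function(group, layout = .codh_layout()) {
  tab <- codh_group_table()
  if (!group %in% tab$group) stop("unknown structural group: ", group)
  row <- tab[group, ]
  plan <- character(0)
  put <- function(pos, res) {
    p <- setNames(rep_len(res, length(pos)), as.character(pos))
    plan[names(p)] <<- p
    invisible(NULL)
  }

  # D-cluster region: clear all plantable offsets, then set the type's Cys.
  put(unique(unlist(layout$d_offsets)), "A")
  if (row$d_type %in% names(layout$d_offsets)) put(layout$d_offsets[[row$d_type]], "C")
  if (group == "C-3") put(layout$d_offsets$single, "C")  # one lone Cys, type "none"

  # B-cluster: complete in all 24 groups.
  put(layout$b_cluster, "C")

  # C-cluster and acid-base catalysts.
  put(layout$c_cluster,
      c(row$c_his, row$c_cys1, row$c_cys2, row$c_cys3, row$c_cys4, row$c_cys5))
  put(layout$acid_base, c(row$ab_his, row$ab_lys))

  # E-/F-clusters (clade A only; others keep background there).
  if (row$clade == "A") {
    put(layout$e_cluster, "A")
    put(layout$f_cluster, "A")
    if (isTRUE(row$e_complete)) put(layout$e_cluster, "C")
    if (isTRUE(row$f_complete)) put(layout$f_cluster, "C")
    if (group == "A-6") put(layout$f_cluster[1:2], "C")  # incomplete F-cluster
  }

  # Tandem Cys x 4 motifs between the E- and F-clusters (A-5).
  put(unlist(layout$ef_insert), "A")
  if (row$ef_cys4 > 0L) put(unlist(layout$ef_insert[seq_len(row$ef_cys4)]), "C")

  # Cys x 4 insertion between the acid-base His site and the C-cluster His (C-4).
  put(layout$c_insert, "A")
  if (isTRUE(row$c_insertion)) put(layout$c_insert, "C")

  # N-terminal extension motifs.
  put(layout$nterm_cys, "A")
  if (row$nterm_cys > 0L) put(layout$nterm_cys[seq_len(row$nterm_cys)], "C")
  put(layout$nterm_his, "A")
  if (isTRUE(row$nterm_his_rich)) put(layout$nterm_his, "H")
  put(layout$cterm_his, "A")
  if (isTRUE(row$cterm_his_rich)) put(layout$cterm_his, "H")

  plan
}
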