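# Structural classifier: D-region typing, signature extraction, terminal
# motifs, insertions, and the group decision table.

test_that("D-region motif types match their printed patterns", {
  expect_identical(classify_d_region("AACWSCCAA"), "I")
  expect_identical(classify_d_region(paste0("C", strrep("A", 7), "CC")), "II")
  expect_identical(classify_d_region(paste0("C", strrep("A", 13), "CC")), "II")
  expect_identical(classify_d_region(paste0("CWSC", strrep("A", 5), "C")), "III")
  expect_identical(classify_d_region("AWSAA"), "none")   # no Cys
  expect_identical(classify_d_region("AWCAA"), "none")   # one lone Cys
  expect_identical(classify_d_region(""), "none")
  # spacer bounds: k = 6 and k = 14 match no type
  expect_identical(classify_d_region(paste0("C", strrep("A", 6), "CC")), "none")
  expect_identical(classify_d_region(paste0("C", strrep("A", 14), "CC")), "none")
})

test_that("D-region precedence is I > III > II", {
  # contains both III (1,4,10) and II (1,(X)8,10,11): III wins
  both23 <- "CAACAAAAACC"
  expect_identical(classify_d_region(both23), "III")
  # adding an adjacent CC triple makes type I win
  expect_identical(classify_d_region("CAACCAAAACC"), "I")
})

test_that("D-region typing agrees with the brute-force scanner", {
  # exhaustive over {C,A} strings up to length 12
  for (len in 1:12) {
    grids <- expand.grid(rep(list(c("C", "A")), len), stringsAsFactors = FALSE)
    strings <- do.call(paste0, grids)
    got <- vapply(strings, classify_d_region, "", USE.NAMES = FALSE)
    want <- vapply(strings, oracle_d_region, "", USE.NAMES = FALSE)
    expect_identical(got, want, info = paste("len", len))
  }
  # seeded random sample of longer strings (13-18)
  set.seed(33)
  for (i in 1:300) {
    s <- paste(sample(c("C", "A"), sample(13:18, 1), TRUE,
                      prob = c(0.35, 0.65)), collapse = "")
    expect_identical(classify_d_region(s), oracle_d_region(s), info = s)
  }
})

sig_of <- function(group, mutation_rate = 0, seed = NULL) {
  p <- generate_protein_for_group(ref_templates[[group]], mutation_rate,
                                  protect_motifs = TRUE, seed = seed)
  anchor <- ref_anchors[[ref_templates[[group]]$clade]]
  pm <- map_anchor_positions(p$seq, anchor)
  structural_signature(p$seq, pm, anchor)
}

test_that("site signatures read the planted residue states", {
  s_f1 <- sig_of("F-1")
  expect_identical(s_f1$c_cluster, c("H", "C", "C", "C", "C", "C"))
  expect_identical(s_f1$acid_base, c("H", "K"))
  expect_true(s_f1$b_complete)
  expect_identical(s_f1$d_type, "II")
  expect_true(is.na(s_f1$e_complete))

  s_b2 <- sig_of("B-2")
  expect_identical(s_b2$c_cluster, c("H", "C", "D", "C", "C", "C"))

  s_a4 <- sig_of("A-4")
  expect_identical(s_a4$c_cluster, c("D", "P", "C", "C", "C", "C"))
  expect_identical(s_a4$acid_base, c("Q", "R"))
  expect_true(s_a4$e_complete)

  # a gap at a B-cluster position reads "absent" and clears b_complete
  anchor <- ref_anchors$F
  del_at <- anchor$b_cluster[2]
  q <- paste0(substr(anchor$sequence, 1, del_at - 1),
              substr(anchor$sequence, del_at + 1, nchar(anchor$sequence)))
  pm <- map_anchor_positions(q, anchor)
  s <- extract_site_signature(q, pm, anchor)
  expect_false(s$b_complete)
})

test_that("terminal motifs are detected in the extension regions", {
  anchor <- ref_anchors$F
  pm <- map_anchor_positions(anchor$sequence, anchor)
  # plant 2 Cys near the N-terminus of a plain anchor sequence
  q <- anchor$sequence
  substr(q, 4, 4) <- "C"; substr(q, 7, 7) <- "C"
  tm <- detect_terminal_motifs(q, map_anchor_positions(q, anchor))
  expect_identical(tm$nterm_cys_count, 2L)
  expect_identical(tm$cterm_cys_count, 0L)

  # single Cys stays below the >=2 floor
  q1 <- anchor$sequence
  substr(q1, 4, 4) <- "C"
  expect_identical(detect_terminal_motifs(
    q1, map_anchor_positions(q1, anchor))$nterm_cys_count, 0L)

  # His-rich C-terminus: >=4 His in overlapping H-X-H repeats
  s_b3 <- sig_of("B-3")
  expect_true(s_b3$cterm_his_rich)
  expect_false(s_b3$nterm_his_rich)
  s_b1 <- sig_of("B-1")
  expect_true(s_b1$nterm_his_rich)
  expect_false(s_b1$cterm_his_rich)

  # 3 His only -> not His-rich
  q3 <- anchor$sequence
  for (p in c(625L, 627L, 629L)) substr(q3, p, p) <- "H"
  stopifnot(nchar(q3) == nchar(anchor$sequence))
  tm3 <- detect_terminal_motifs(q3, map_anchor_positions(q3, anchor))
  expect_false(tm3$cterm_his_rich)
})

test_that("insertion motifs and fusions are detected", {
  s_c4 <- sig_of("C-4")
  expect_true(s_c4$c_insertion_cys4)
  expect_identical(s_c4$extra_ef_cys4_count, 0L)

  s_a5 <- sig_of("A-5")
  expect_identical(s_a5$extra_ef_cys4_count, 2L)
  expect_false(s_a5$c_insertion_cys4)

  s_f1 <- sig_of("F-1")
  expect_false(s_f1$c_insertion_cys4)
  expect_identical(s_f1$extra_ef_cys4_count, 0L)
  expect_false(s_f1$fusion)

  # a query longer than the anchor by >200 residues flags as fusion
  anchor <- ref_anchors$F
  fused <- paste0(ref_templates[["F-1"]]$scaffold,
                  paste(rep("G", 230), collapse = ""))
  pm <- map_anchor_positions(fused, anchor)
  expect_true(detect_insertions(fused, pm, anchor)$fusion)
})

test_that("the decision table reproduces its printed rows", {
  mk_sig <- function(d_type = "II", cc = c("H", "C", "C", "C", "C", "C"),
                     ab = c("H", "K"), b = TRUE, e = NA, f = NA,
                     ntc = 0L, nhr = FALSE, chr = FALSE, cins = FALSE,
                     ef = 0L) {
    structure(list(d_type = d_type, c_cluster = cc, acid_base = ab,
                   b_complete = b, e_complete = e, f_complete = f,
                   nterm_cys_count = ntc, cterm_cys_count = 0L,
                   nterm_his_rich = nhr, cterm_his_rich = chr,
                   c_insertion_cys4 = cins, extra_ef_cys4_count = ef,
                   fusion = FALSE), class = "codh_signature")
  }
  lab <- function(clade, sig) assign_structural_group(clade, sig)$group_label
  expect_identical(lab("F", mk_sig()), "F-1")
  expect_identical(lab("F", mk_sig(ntc = 2L)), "F-2")
  expect_identical(lab("B", mk_sig(cc = c("H","C","D","C","C","C"), chr = TRUE)), "B-3")
  expect_identical(lab("B", mk_sig(cc = c("H","C","E","C","C","C"), nhr = TRUE)), "B-1")
  expect_identical(lab("A", mk_sig(d_type = "I", e = TRUE, f = TRUE)), "A-1")
  expect_identical(lab("A", mk_sig(d_type = "none", e = TRUE, f = TRUE, ef = 2L)), "A-5")
  expect_identical(lab("E", mk_sig(d_type = "III")), "E-2")
  expect_identical(lab("G", mk_sig(d_type = "III", cc = c("H","T","C","C","C","C"),
                                   ab = c("Y","K"))), "G-1")
  expect_identical(lab("C", mk_sig(d_type = "none", ab = c("Y","Q"))), "C-3")
  expect_identical(lab("C", mk_sig(cins = TRUE, ab = c("Y","Q"))), "C-4")
  # no clade-C row permits (H,K) catalysts
  expect_identical(lab("C", mk_sig()), "others")
  # incomplete B-cluster falls outside every row
  expect_identical(lab("F", mk_sig(b = FALSE)), "others")
})

test_that("decision rows are mutually exclusive and the table is total", {
  cc_variants <- list(c("H","C","C","C","C","C"), c("H","C","D","C","C","C"),
                      c("H","C","E","C","C","C"), c("D","P","C","C","C","C"),
                      c("N","S","C","C","C","C"), c("H","E","C","C","C","C"),
                      c("H","T","C","C","C","C"), c("H","C","C","absent","C","C"))
  ab_variants <- list(c("H","K"), c("Y","Q"), c("Y","K"), c("N","K"),
                      c("Q","R"), c("H","L"), c("A","A"))
  n_checked <- 0L
  violations <- character(0)
  for (clade in codh_clades()) {
    ef_grid <- if (clade == "A")
      list(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, FALSE)) else list(c(NA, NA))
    for (d in c("I", "II", "III", "none")) for (cc in cc_variants)
      for (ab in ab_variants) for (ef in ef_grid)
        for (ntc in c(0L, 3L)) for (nhr in c(FALSE, TRUE)) for (efc in c(0L, 2L))
          for (flags in list(c(FALSE, FALSE), c(TRUE, FALSE), c(FALSE, TRUE))) {
            sig <- structure(list(
              d_type = d, c_cluster = cc, acid_base = ab, b_complete = TRUE,
              e_complete = ef[1], f_complete = ef[2],
              nterm_cys_count = ntc, cterm_cys_count = 0L,
              nterm_his_rich = nhr, cterm_his_rich = flags[1],
              c_insertion_cys4 = flags[2],
              extra_ef_cys4_count = efc,
              fusion = FALSE), class = "codh_signature")
            hits <- codhscan:::.match_rows(clade, sig)
            if (length(hits) > 1L)
              violations <- c(violations, paste(clade, paste(hits, collapse = "+")))
            if (length(assign_structural_group(clade, sig)$group_label) != 1L)
              violations <- c(violations, paste(clade, "non-total"))
            n_checked <- n_checked + 1L
          }
  }
  expect_gt(n_checked, 10000L)
  expect_identical(unique(violations), character(0))
})
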