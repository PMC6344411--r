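---
title: "Classifying anaerobic Ni-CODHs and mining their genomic contexts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying anaerobic Ni-CODHs and mining their genomic contexts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codhscan)
```

## The biological problem

Anaerobic Ni-containing carbon-monoxide dehydrogenases (Ni-CODHs) catalyze
CO + H2O <-> CO2 + 2H+ + 2e-, the entry reaction of the carbonyl branch of
the Wood-Ljungdahl pathway and the energy source of carboxydotrophs.  They
belong to the hybrid-cluster protein (HCP) family and fall into two
lineages: the bacterial CooS type and the archaeal Cdh type.  Almost
everything that distinguishes one Ni-CODH from another is encoded in a
handful of residue positions:

* the **C-cluster** (the catalytic Ni-Fe-S center): one His plus five Cys;
* the **B-cluster** ([4Fe-4S], intramolecular electron transfer): four Cys;
* the **D-cluster** (subunit-interface [4Fe-4S]): a short Cys motif whose
  spacing defines three types -- type I `C-X-X-C-C`, type II
  `C-(X)7-13-C-C`, type III `C-X-X-C-(X)5-C`;
* the **acid-base catalyst pair** (canonically His/Lys, replaced by
  Tyr/Gln, Tyr/Lys, Asn/Lys, Gln/Arg or His/Leu in some groups);
* the **E- and F-clusters**, two extra [4Fe-4S] cubanes found only in the
  Cdh-type lineage (clade A here);
* accessory motifs: N-terminal Cys motifs (2-4 Cys), terminal His-rich
  regions built from overlapping `H-X-H` repeats, and Cys x 4 insertions
  (between the acid-base Tyr and the C-cluster His, or tandem pairs
  between the E- and F-clusters).

codhscan classifies a protein in two steps: a **clade** (A-G) by
nearest-anchor alignment, then a **structural group** (24 labels,
`A-1`..`G-1`, plus `others`) by a decision table over those residue
states.  Downstream, it asks which gene neighborhoods the CODH genes live
in: **directons** (maximal same-strand gene runs with intergenic gaps of
at most 300 bp, up to 15 genes on each side of the CODH gene), which COG
annotations are statistically enriched inside those directons, and how
COGs, structural groups and taxonomies co-occur across loci
(Simpson-coefficient network).

## Clade assignment is a declared stand-in

The original clades come from an approximate-ML phylogeny of ~2000
sequences.  Re-deriving trees is out of scope here; instead each clade is
represented by an **anchor profile** (a reference sequence plus a ledger
of its cluster positions) and a query is assigned the clade of its
best-scoring anchor under global affine-gap alignment
(BLOSUM62-equivalent scores, gap open 11 covering the first gapped
residue, extend 1; `X` is neutral).  Near clade boundaries nearest-anchor
assignment can disagree with a tree; assignments whose top-two score
margin is below `ambiguity_delta` (default 5 score units) are therefore
flagged `ambiguous` and never silently forced.  Ties resolve to the
alphabetically first clade, flagged.

The aligner itself pins conventions that differ between implementations,
because tests depend on them: a length-1 gap costs the full opening
penalty (11), traceback precedence is diagonal > vertical > horizontal,
and an empty sequence aligns as all gaps at cost
`open + extend * (len - 1)`.

## Reading the signature

Anchor positions are mapped onto the query through the pairwise
alignment; a position aligned to a query gap reads `absent`.  Decisions
taken where the source material is silent, fixed here once:

* **D-region**: the mapped D-region span is widened by 5 residues on each
  side before motif scanning; when several motif types match, precedence
  is I > III > II (most specific first).  Regions with one or no Cys, and
  regions matching no pattern, are all `none` -- the table prints a dash
  for both.
* **Terminal regions** are everything before/after the anchor's mapped
  core span.  The terminal Cys motif is the maximal Cys count in any
  20-residue window, reported at >= 2 and capped at 4 ("two to four Cys"
  is the observed range; no window is printed anywhere, so one is fixed
  here).  His-rich means >= 4 His (the observed lower bound) *and* at
  least two overlapping `H-X-H` repeats.
* **Insertions**: the C-cluster insertion is >= 4 Cys strictly between
  the acid-base His-site column and the C-cluster His column; E/F
  insertions are disjoint windows of <= 30 residues with >= 4 Cys,
  scanned greedily left to right between the two cluster spans.
* **Fusions** (found manually in the source study) are flagged
  mechanically: query longer than its anchor by more than 200 residues.
* **Completeness** (curation): a query with a deletion (gap) at any
  D-/B-/C-cluster or acid-base position is excluded from the dataset;
  substitutions are kept, since variant residue states are exactly what
  the classification reads.

The decision table requires an intact B-cluster (four Cys) for every
labeled row; any unmatched combination is `others`, making the classifier
total.  The single-member clade G keeps its own label `G-1` rather than
falling into `others`.

## Genomic context

Directons are built from non-pseudo CDS rows sorted by start.  The
intergenic gap is `next.start - current.end - 1`; overlapping genes count
as gap 0; "within 300 bp" is read inclusively (a 300 bp gap extends, 301
breaks).  The context of a CODH gene is its directon plus a serial
expansion: flanking genes carrying at least one *enriched* COG are added
regardless of strand and distance, stopping at the first flank without
one.  One context locus is produced per CODH gene, so two CODH genes in
one directon yield two loci with equal directon sets.

Enrichment uses gene counts over all CODH-encoding genomes: for each COG,
a 2x2 table of directon membership against COG membership, a one-sided
(enrichment) Fisher exact test computed from log-factorials, and
Benjamini-Hochberg step-up control across all tested COGs; a COG is
enriched iff `p < 0.05` and `q < 0.05`.  The sidedness is not stated in
the source; one-sided is chosen because the question is enrichment.  The
Ni-CODH COGs themselves (COG1151, COG1152) are excluded from testing.
Annotations with e-value >= 1e-6 are dropped on ingest when an e-value
column is present.

The locus x feature matrix holds the enriched COGs present in each
context, the locus's structural group, and its family-level taxonomy
(namespaced `cog:`/`group:`/`family:`).  All feature pairs are scored
with the Simpson coefficient `|A n B| / min(|A|, |B|)`; edges require
>= 0.4, and COG features (only; the parenthetical in the source scopes
the floor to COGs) need >= 25 loci to enter the network.  Pairs with an
empty locus set are skipped, not scored 0.

## The synthetic world

The generator exists so that every stage can be tested against planted
truth; its defaults are a stated world, not tuning knobs:

* **Scaffolds**: 650 residues (no empirical length distribution is
  printed beyond the >= 550 aa curation floor; 650 leaves realistic
  N-/C-terminal extensions), drawn i.i.d. from the 18 residues excluding
  Cys and His so planted motifs are unambiguous.  Each clade has one
  scaffold; its anchor realizes the clade's representative group, and the
  24 group templates differ from their clade scaffold only at signature
  positions -- so a noise-free template must classify to its own label
  (the round-trip property), and recovery under 5% protected mutation
  measures classifier robustness, not generator drift.
* **Genomes**: one replicon each, 60 genes by default, gene lengths
  U[300, 1500] bp and intergenic gaps U[5, 250] bp (bounded uniform laws
  give exact control of directon membership); strand flips at 0.2 per
  adjacent pair exercise directon breaking.  One CODH gene per genome;
  each enriched COG is planted on a directon neighbor (same strand, gap
  capped at 300 bp) with its stated probability; background COGs scatter
  per-gene at frequency 0.02.  CODH proteins are annotated COG1151/1152
  so the exclusion rule is exercised.  The default experiment is 50
  genomes, 3 enriched COGs at co-occurrence 0.9, 200 background COGs.

What a green test does **not** establish: the generator does not emulate
realistic substitution processes, homologous non-CODH family members
(HCPs enter only via the bit-score/length hit filters), overlapping gene
annotations, multi-replicon genomes, or real NCBI-scale redundancy.  The
headline dataset figures of the source study (1942 proteins, 1375
genomes, 36 phyla) depend on a 2018 database snapshot and are not
reproducible at desk scale; they are outside this package's test surface.

## Numerical and degenerate-input choices

* Fisher p-values: upper-tail sums of `exp(lchoose ...)` with max-shift;
  `a = 0` or a zero margin returns exactly 1.  Agreement with exhaustive
  enumeration is < 1e-12 for every table with total <= 40.
* BH: step-up cumulative-minimum construction, capped at 1,
  permutation-equivariant.
* Alignment determinism: fixed operation and state precedence makes
  tracebacks reproducible across platforms.
* Genome selection priority is reference > representative > complete
  assembly level > everything else ("draft"); ties break on the
  lexicographically smallest genome id (no tie rule is printed).
  Same-species genomes survive only with distinct CODH id *sets* -- our
  reading of "different accession numbers".

## A worked example

```{r example, eval = FALSE}
anchors <- generate_reference_anchors(seed = 1)
bundle <- generate_context_genomes(context_scenario(seed = 1), anchors)
write_fixture_bundle(bundle, "fixtures")

cfg <- pipeline_config(
  fasta = "fixtures/proteins.faa", gff = "fixtures/genes.gff3",
  annotations = "fixtures/annotations.tsv",
  metadata = "fixtures/metadata.tsv", anchors = "fixtures/anchors.json",
  out_dir = "run")
report <- run_pipeline(cfg)
str(report$group_tally)   # matches bundle$manifest$group_tally
report$enriched_cogs      # the three planted COGs
```

## Known limitations

* Nearest-anchor clade assignment can disagree with a tree near clade
  boundaries; ambiguous calls are flagged, not resolved.
* Context loci are keyed by CODH protein id; a protein shared verbatim
  between genomes would need genome-qualified ids from the caller.
* The classifier reads residue states only through the pairwise
  alignment to one anchor; a badly misaligned query degrades to
  `others` rather than failing loudly.
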