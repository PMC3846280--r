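# plescout

Structural annotation of *Penelope*-like retroelement (PLE) loci, with a
seeded synthetic-locus generator for end-to-end validation.

## The problem

PLEs are an ancient class of retroelements related to telomerase reverse
transcriptases. Unlike LTR retrotransposons, their terminal repeats
("pseudo-LTRs", pLTRs) occur in flexible direct and/or inverted
arrangements, can overlap the start of the single ORF, and optionally carry
a short 3′ "tail" extension. Annotating a PLE insertion therefore means
resolving a small geometric puzzle at every locus:

- which repeat units are present, in which orientation, with what overlap
  and truncation between the 5′ inverted unit and its direct neighbour;
- whether a tail extends one unit, and whether identical target-site
  duplications (TSDs) flank the whole insert;
- whether the pLTR interior carries terminal palindromes and TATA/initiator
  core-promoter motifs (possibly bidirectional);
- whether the ORF is intact or defective (frameshifts, premature stops,
  truncations, microhomology-mediated deletions), and whether it carries a
  several-hundred-residue in-frame insert with 25–30 % asparagine;
- whether a pLTR-framed interval is actually a *captured host gene
  cassette* — element-free between the repeats, TSD-flanked, and provably a
  transposition because the allelic "empty site" carries the target motif
  exactly once;
- how copies group into subfamilies/families/groups by pairwise identity,
  and how small-RNA coverage splits into sense and antisense along the
  element (the silencing signature).

`plescout` implements each of these steps as a separate, tested operation
and ties them together in `annotate_locus()`. A companion generator
(`forge_locus()`, `forge_orf()`, `forge_capture_pair()`,
`forge_smallrna_library()`) produces synthetic loci with machine-readable
ground truth, so every detector is validated against sequences whose true
structure is known exactly.

## Core methods

- **Repeat detection** (`find_terminal_repeats`): exact k-mer seeding
  (k = 12) with ungapped bidirectional extension under a +1/−2
  match/mismatch score and an X-drop stop; reported boundaries are the
  score-maximal endpoints, so every reported repeat is exactly maximal.
  Inverted self-matches that span their own anti-diagonal centre are
  palindromes and are split into arms.
- **Arrangement resolution** (`resolve_arrangement`): pair hits are merged
  into units; orientations propagate from the unit holding the ORF start;
  the overlap and truncation of the 5′ inverted unit are read off the
  coordinates.
- **Junctions** (`detect_tsd`, `detect_microhomology`, `find_palindromes`,
  `scan_promoter`): longest suffix–prefix match between the flanks for the
  TSD; maximal centre-expanded (near-)palindromes with a spacer; TATA →
  initiator spacing on both strands (`TCACT` forward, `ACATT` on the
  opposite orientation).
- **ORFs** (`find_orfs`, `classify_defects`, `detect_n_rich`,
  `scan_giy_yig`, `scan_cys_motif`, `detect_aay_bias`): six-frame ORF
  discovery; copy-versus-reference tiling by exact 8-aa words with frame
  switches → frameshifts, unchanged gaps with stops → premature stops,
  shortened gaps → deletions whose breakpoint microhomology is measured on
  the DNA; sliding-window asparagine-rich segment detection; GIY-YIG and
  Cys/His-X(1–3)-Cys-X(10)-Cys-X(2)-Cys motif scans.
- **Gene capture** (`detect_capture`, `verify_empty_site`): co-oriented
  pLTR hit pairs frame a cassette; element-freeness is absence of any
  shared 20-mer with the element ORF library; empty-site verification
  anchors both flanks in the candidate allele and requires adjacency with
  exactly one copy of the TSD motif at the junction.
- **Classification** (`pairwise_distances`, `cluster_families`,
  `neighbor_joining`, `inclusion_filter`): anchored p-distances,
  single-linkage cuts at 0.10/0.25/0.45 giving nested
  subfamily/family/group partitions, an NJ summary tree, and the ≥ 1/3
  coding-sequence coverage inclusion rule.
- **Small RNAs** (`map_reads`, `windowed_polarity`,
  `detect_polarity_switch`, `expression_density`): both-strand read
  placement with fractional multi-mapper weights, per-window polarity index
  (sense − antisense)/(sense + antisense), run-length polarity-switch
  calls, and counts-per-kb summaries.

## Worked example

Forge the canonical single-copy element — an 842-aa ORF bounded by two
218-bp direct pLTRs plus a truncated 5′ inverted unit, a 31-bp tail and a
9-bp TSD — and annotate it back:

```r
library(plescout)
fl  <- forge_locus(locus_spec(seed = 1))
ann <- annotate_locus(fl$sequence, id = "pen2a_synthetic")
ann
#> PLE annotation 'pen2a_synthetic' (3744 bp)
#>   arrangement: DD_plus_inverted5p (3 unit(s)), overlap_5p=15, truncation_5p=37, tail=31 bp
#>   TSD: GGTACAATT (9 bp)
#>   main ORF: 842 aa (+ strand)
head(ann$features)
#>   type start  end strand      name
#> 1 pltr   340  521      -  inverted
#> 2 pltr   506  724      +    direct
#> 3 pltr  3217 3435      +    direct
#> 4 tail   309  340      -      <NA>
#> 5  tsd   300  309      + GGTACAATT
#> 6  tsd  3435 3444      + GGTACAATT
```

Reading the output: the locus holds three pLTR units — a 181-bp inverted
unit (340–521) overlapping the first 218-bp direct unit (506–724) by 15 bp
and 37 bp shorter than it — a 31-bp tail extending the inverted unit, and
identical 9-bp TSD copies outside the whole insert. The direct unit covers
the first 36 bases of the ORF: `pltr_orf_codon_coverage()` reports 12
codons from the unit alone and 22 once the tail is credited.
`write_gff3(ann, "locus.gff3")` and `write_report(ann, "locus.json")`
export the feature table.

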