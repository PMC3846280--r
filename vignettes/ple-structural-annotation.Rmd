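---
title: "Structural annotation of Penelope-like retroelement loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural annotation of Penelope-like retroelement loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plescout)
```

## The model element

Penelope-like elements (PLEs) are retroelements whose single ORF (usually
800–900 aa, up to ~1,300–1,500 aa with inserts) encodes a reverse
transcriptase and, in the endonuclease-bearing lineages, a GIY-YIG
endonuclease. The element is bounded by "pseudo-LTRs" (pLTRs): terminal
repeats of roughly 180–220 bp that occur in flexible arrangements. The
canonical single-copy form modelled here has, 5′ to 3′:

* a truncated **inverted** pLTR that *overlaps* the adjacent direct unit by
  a short stretch (15 bp by default) and is shorter than the full unit
  (37 bp by default, i.e. 181 of 218 bp);
* a full **direct** pLTR whose 3′ end contains the first 12 codons of the
  ORF;
* the ORF body and a second full direct pLTR (again ending in the ORF
  head), optionally separated from the ORF by a unique spacer;
* an optional 31-bp **tail** extending the inverted unit's 3′ end with
  further ORF-derived sequence (12 → 22 encoded codons);
* identical **TSD** copies (8–10 bp) flanking the entire insert.

pLTR interiors may carry an even-length terminal palindrome (18 bp in one
family, a nearly perfect 38 bp in another) and a core promoter: a TATA box
(`TATATATA`, itself reverse-complement symmetric) separated by ~20 bp from
an initiator-like `TCACT`, with an opposite-orientation initiator `ACATT`
suggesting bidirectional transcription. Some ORFs carry an in-frame insert
of 460–554 aa with 25–30 % asparagine between catalytic domains. Elements
can also mobilize host sequence: an intron-containing gene cassette framed
by two direct plus one inverted pLTR, flanked by a TSD whose motif occurs
exactly once at the junction of the allelic empty site.

## What the generator emulates — and what it does not

`forge_locus()` draws background sequence i.i.d. over A/C/G/T (an AT-rich
mode is available via `at_fraction`, reflecting the preference of these
elements for simple AT-rich targets). Allelic divergence is substitutions
only — the quantity reported for real allelic pairs is a single divergence
percentage, and indel-free pairs keep the empty-site diagnostic crisp.
Insert asparagine codons are split evenly between AAT and AAC; non-Asn
insert residues are drawn from the 59 remaining sense codons so the
realized Asn fraction is an unbiased estimate of the target.

Two constructive choices matter for exactness:

1. **The overlap region is a near-palindrome.** The same genomic bases must
   read as the end of the inverted unit and the start of the direct unit.
   That is only possible if the shared block is reverse-complement
   symmetric; an odd-length block (15 bp) necessarily carries one central
   self-mismatch. This mirrors the palindromic pLTR termini of real
   elements and yields a detected inverted unit of full planted length with
   a single interior mismatch.

2. **Boundary hardening.** A detector that reports *maximal* repeats will
   extend a planted repeat by one base whenever the next base happens to
   match (probability 1/4 per side). The generator therefore forces up to
   three mismatching bases immediately outside every planted repeat copy
   (re-deriving dependent segments, keeping codons stop-free, and leaving
   fixed motifs untouched). Planted truth and maximal-repeat semantics then
   coincide, and structural parameters are recovered identically for every
   seed. A three-frame stop block (`TAATAATAA`) just upstream of the
   embedded ORF head likewise makes the element ORF start the unique
   read-through ATG inside the pLTR.

Consequently, passing the round-trip tests demonstrates that the detectors
implement their stated semantics exactly — it does not show that real,
decayed loci (whose boundaries are fuzzy and expert-curated) would be
recovered to the base pair. The configuration knob `boundary_slack`
(default 2 bp) exists for that situation: the end-to-end pipeline flags,
rather than suppresses, units whose called edges differ slightly from a
supplied expectation.

## Repeat semantics and numerical choices

`find_terminal_repeats()` seeds with exact 12-mers and extends ungapped
under a +1 match / −2 mismatch score, stopping when the running score falls
10 below its maximum (five consecutive mismatches trigger this exactly) and
reporting the score-argmax endpoints. Mismatch-tolerant extension is needed
because family copies diverge (≈ 90 % identity within subfamilies); the
argmax trim makes boundaries deterministic. Defaults: `min_unit` 50 bp
(units of interest are ~180–220 bp; the 31-bp tail deliberately falls below
this and is handled by `detect_tail()`), `min_identity` 0.80.

An inverted self-match whose two copies overlap *is* a palindrome; such
anti-diagonal segments are split at their centre and reported as arm pairs.
Without the split, the inverted-unit-plus-direct-unit region of the
canonical arrangement would merge into a single ~350-bp pseudo-unit.

Other numerical choices, each tested against a brute-force oracle:

* `detect_tsd`: longest suffix–prefix match, length 4–25 bp, exact by
  default (real TSDs here are 8–10 bp exact; a mismatch budget exists for
  diverged insertions). Flanks shorter than `max_len` restrict the search
  and set a flag.
* `find_palindromes`: centre expansion over spacers 0–4, mismatch budget 2
  (admits the "nearly perfect" 38-bp case), outermost pair must match,
  trailing mismatches trimmed; intervals reachable from several spacers are
  reported once with the fewest mismatches. A palindrome starting within
  5 bp of the sequence start is flagged terminal.
* `detect_tail`: score-maximal common extension beyond two units' 3′ ends;
  extensions shorter than 5 bp are not called tails (a 1-bp "extension"
  matches by chance in a quarter of tail-free loci).
* `classify_defects`: exact 8-aa seed words extended ungapped; gapped
  protein alignment is deliberately avoided at this scale. Breakpoint
  microhomology is measured on the DNA with extensions anchored a few
  codons *inside* each block, because synonymous codons can extend an
  amino-acid block past the true DNA junction and otherwise inflate the
  overlap.
* `detect_n_rich`: 50-aa windows at threshold 0.25, merged; a
  below-threshold dip shorter than one window does not split a segment when
  both neighbours are at least a window long. Because edge windows are
  binomial (at a true composition of 30 %, a boundary window falls below
  0.25 with roughly 10 % probability), recovered boundaries are
  window-limited: every seed lands within two windows of the planted edge
  and the average deviation stays within one window.
* `neighbor_joining`: canonical agglomeration via \pkg{ape}; negative
  branch lengths are clamped to zero and counted. Family cuts 0.10 / 0.25 /
  0.45 under single linkage give nested partitions by construction; labels
  are canonicalized by each cluster's lexicographically smallest member so
  assignments are order-invariant.
* `map_reads`: with one mismatch allowed, a placed read must match exactly
  on its first or last 12 bases (pigeonhole), so candidates come from a
  k-mer index and are verified base by base; multi-mappers get weight
  1/n_hits — repeats are the object of study, and discarding multi-mappers
  would zero out young copies. A read's window is its 5′ position; "sense"
  is the element ORF strand.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `repeats$min_unit` | 50 | bp | below the shortest unit of interest, above seed noise |
| `repeats$min_identity` | 0.80 | fraction | within-family copy divergence |
| `tsd$min_len`–`max_len` | 4–25 | bp | brackets the observed 8–10 bp |
| `palindrome$max_mismatch` | 2 | pairs | admits near-perfect long palindromes |
| `promoter$max_spacing` | 50 | bp | generous bound around the ~20 bp arrangement |
| `orf$min_aa` | 300 | aa | element ORFs run ~830–1,300 aa |
| `n_rich$window/threshold/min_len` | 50 / 0.25 / 100 | aa | inserts are 460–554 aa at 25–30 % |
| `capture$element_free_k` | 20 | bp | "no internal sequence in common" as exact long-word absence |
| `capture$min_anchor` | 200 | bp | flanks anchor despite 2–5 % allelic divergence |
| `classify` cuts | 0.10/0.25/0.45 | p-distance | 90 %-identity copies share a subfamily |

All defaults live in `default_config()` and in the shipped
`inst/extdata/default-config.yaml`.

## Problem sizes

The test-suite and acceptance computations use: single loci of ~3.7 kb
(842-aa ORF), 10-kb allelic backbones, ~4.8-kb capture scenes, 10 proteins
of 1,309 aa for composition recovery, small-RNA libraries of 10^3–10^4
reads on 3-kb elements, oracle-equivalence sweeps of 200 seeds on inputs of
50–450 bp, and 50-locus end-to-end round trips. These sizes keep each
check well inside a minute on one core while leaving the binomial
tolerances meaningful.

## Known limitations

* Detection is ungapped throughout; indel-diverged copies fragment into
  several blocks rather than one gapped alignment (the defect classifier
  interprets the fragments, but unit boundaries can shorten).
* RT-domain identification is a placeholder motif; intactness rests on
  length, absence of stops/frameshifts, and the GIY-YIG hit — there is no
  profile search.
* The empty-site verifier assumes collinear, indel-free flanks; a true
  empty site behind a rearranged allele would fail verification rather
  than be recovered.
* Family classification is a deterministic identity-based analogue of the
  phylogenetic grouping it stands in for; no likelihood model, no
  bootstrap.
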