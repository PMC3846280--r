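# Shared fixture builders (everything is generated in code at test time).

pen2a_spec <- function(seed = 1L) locus_spec(seed = seed)

# the canonical single-copy element scene: locus + its annotation
pen2a_scene <- function(seed = 1L) {
  fl <- forge_locus(pen2a_spec(seed))
  list(locus = fl, ann = annotate_locus(fl$sequence))
}

# capture/empty-site allelic scene used by the gene-capture tests
capture_scene <- function(seed = 1L, divergence = 0.02,
                          tsd_motif = "GAATTAAT") {
  pltr <- withr::with_seed(seed + 1000L, random_dna(190))
  exons <- withr::with_seed(seed + 2000L,
                            c(random_dna(700), random_dna(500), random_dna(400)))
  pair <- forge_capture_pair(pltr, exons, intron_lens = c(80L, 90L),
                             tsd_motif = tsd_motif, divergence = divergence,
                             seed = seed)
  orf_lib <- forge_orf(600L, seed = seed + 3000L)$dna
  list(pair = pair, pltr = pltr, orf_lib = orf_lib)
}
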