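test_that("an intron-containing cassette between pLTRs is detected with its TSD", {
  sc <- capture_scene(seed = 1)
  ev <- detect_capture(sc$pair$allele_A, list(sc$pltr), list(sc$orf_lib))
  expect_equal(length(ev), 1L)
  e <- ev[[1]]
  expect_true(e$cassette_is_element_free)
  expect_equal(e$tsd$length, 8L)
  expect_equal(e$tsd$motif, "GAATTAAT")
  expect_equal(nrow(e$framing), 3L)   # inverted + two direct copies
})

test_that("a cassette made of element ORF sequence is not element-free", {
  pltr <- withr::with_seed(5, random_dna(190))
  orf <- forge_orf(600, seed = 6)$dna
  cl <- forge_capture_locus(cassette_exons = substr(orf, 200, 1500),
                            pltr = pltr, tsd_len = 8, seed = 7)
  ev <- detect_capture(cl$sequence, list(pltr), list(orf))
  expect_equal(length(ev), 1L)
  expect_false(ev[[1]]$cassette_is_element_free)
})

test_that("loci without pLTR hits yield no events", {
  pltr <- withr::with_seed(8, random_dna(190))
  locus <- withr::with_seed(9, random_dna(3000))
  expect_equal(length(detect_capture(locus, list(pltr),
                                     list(forge_orf(300, seed = 1)$dna))), 0L)
})

test_that("empty-site verification passes on the allelic pair and counts one motif", {
  sc <- capture_scene(seed = 2)
  ev <- detect_capture(sc$pair$allele_A, list(sc$pltr), list(sc$orf_lib))[[1]]
  ver <- verify_empty_site(sc$pair$allele_A, ev, sc$pair$allele_B)
  expect_true(ver$pass)
  expect_equal(ver$motif_occurrences, 1L)
  expect_gte(ver$flank_identity, 0.9)
})

test_that("verification fails when the candidate allele also carries the insertion", {
  sc <- capture_scene(seed = 3)
  ev <- detect_capture(sc$pair$allele_A, list(sc$pltr), list(sc$orf_lib))[[1]]
  ver <- verify_empty_site(sc$pair$allele_A, ev, sc$pair$allele_A)
  expect_false(ver$pass)
  expect_false(ver$adjacent)
})

test_that("verification fails when the motif is deleted at the junction", {
  sc <- capture_scene(seed = 4)
  ev <- detect_capture(sc$pair$allele_A, list(sc$pltr), list(sc$orf_lib))[[1]]
  bv <- dna_chars(sc$pair$allele_B)
  at <- sc$pair$truth$junction
  bv[(at + 1):(at + 8)] <- rep("C", 8)   # destroy the single motif copy
  ver <- verify_empty_site(sc$pair$allele_A, ev, paste(bv, collapse = ""))
  expect_false(ver$pass)
  expect_equal(ver$motif_occurrences, 0L)
})

test_that("shuffled alleles never verify (no false passes)", {
  for (s in 1:15) {
    sc <- capture_scene(seed = 100 + s)
    ev <- detect_capture(sc$pair$allele_A, list(sc$pltr), list(sc$orf_lib))[[1]]
    shuffled <- withr::with_seed(s, paste(sample(dna_chars(sc$pair$allele_B)),
                                          collapse = ""))
    expect_false(verify_empty_site(sc$pair$allele_A, ev, shuffled)$pass,
                 info = paste("seed", s))
  }
})

test_that("element-free calls exclude cassettes overlapping ORF hits", {
  # a cassette that IS an ORF fragment: hits overlap it, so it must not be
  # called element-free
  pltr <- withr::with_seed(15, random_dna(190))
  orf <- forge_orf(600, seed = 16)$dna
  cl <- forge_capture_locus(cassette_exons = substr(orf, 200, 1500),
                            pltr = pltr, tsd_len = 8, seed = 17)
  evs <- detect_capture(cl$sequence, list(pltr), list(orf))
  hits <- plescout:::ungapped_hits(cl$sequence, orf, min_len = 50)
  expect_gt(nrow(hits), 0)
  for (e in evs) {
    overlaps <- any(vapply(seq_len(nrow(hits)), function(r)
      plescout:::interval_overlap(e$cassette[1], e$cassette[2],
                                  hits$start[r], hits$end[r]) > 0, logical(1)))
    expect_false(e$cassette_is_element_free && overlaps)
  }
  # and a genuinely foreign cassette is element-free with zero hit overlap
  sc <- capture_scene(seed = 5)
  evs2 <- detect_capture(sc$pair$allele_A, list(sc$pltr), list(sc$orf_lib))
  hits2 <- plescout:::ungapped_hits(sc$pair$allele_A, sc$orf_lib, min_len = 50)
  expect_true(all(vapply(evs2, `[[`, logical(1), "cassette_is_element_free")))
  expect_equal(nrow(hits2), 0L)
})

test_that("solo pLTR units are labeled by their context", {
  sc <- capture_scene(seed = 6)
  ev <- detect_capture(sc$pair$allele_A, list(sc$pltr), list(sc$orf_lib))
  units <- plescout:::units_from_hits(ev[[1]]$framing)
  labels <- classify_solo_pltrs(sc$pair$allele_A, units, ev)
  expect_equal(labels, rep("capture_framing", 3))
  # isolated unit, no TSD -> bare; with a planted duplication -> with TSD
  pltr <- withr::with_seed(7, random_dna(200))
  bare <- forge_locus(locus_spec(seed = 8, arrangement = "solo", tsd_len = 0))
  bu <- bare$truth$features[bare$truth$features$type == "pltr", ]
  units_b <- data.frame(start = bu$start, end = bu$end, unit_len = bu$end - bu$start,
                        orientation = "direct")
  expect_equal(classify_solo_pltrs(bare$sequence, units_b), "solo_bare")
  withtsd <- forge_locus(locus_spec(seed = 9, arrangement = "solo", tsd_len = 8))
  wu <- withtsd$truth$features[withtsd$truth$features$type == "pltr", ]
  units_w <- data.frame(start = wu$start, end = wu$end, unit_len = wu$end - wu$start,
                        orientation = "direct")
  expect_equal(classify_solo_pltrs(withtsd$sequence, units_w), "solo_with_tsd")
})

test_that("anchored divergence recovers planted rates and is symmetric", {
  backbone <- withr::with_seed(12, random_dna(20000))
  p2 <- forge_allelic_pair(backbone, 0.02, seed = 13)
  expect_lt(abs(allelic_divergence(p2$allele_A, p2$allele_B) - 0.02), 0.004)
  p5 <- forge_allelic_pair(backbone, 0.05, seed = 14)
  expect_lt(abs(allelic_divergence(p5$allele_A, p5$allele_B) - 0.05), 0.004)
  expect_equal(allelic_divergence(backbone, backbone), 0)
  expect_lt(abs(allelic_divergence(p5$allele_A, p5$allele_B) -
                allelic_divergence(p5$allele_B, p5$allele_A)), 1e-9)
})
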