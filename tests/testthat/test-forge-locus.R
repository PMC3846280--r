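test_that("the default locus carries the canonical structure in its truth", {
  fl <- forge_locus(pen2a_spec(seed = 7))
  tf <- fl$truth$features
  pltr <- tf[tf$type == "pltr", ]
  expect_equal(sort(pltr$end - pltr$start), c(181L, 218L, 218L))
  expect_equal(sum(pltr$name == "inverted"), 1L)
  tail <- tf[tf$type == "tail", ]
  expect_equal(tail$end - tail$start, 31L)
  tsd <- tf[tf$type == "tsd", ]
  expect_equal(nrow(tsd), 2L)
  expect_equal(tsd$end - tsd$start, c(9L, 9L))
  # TSD copies are byte-identical and flank the outermost structures
  s <- fl$sequence
  expect_identical(substr(s, tsd$start[1] + 1, tsd$end[1]),
                   substr(s, tsd$start[2] + 1, tsd$end[2]))
  expect_lt(tsd$end[1], min(pltr$start) + 1)
  expect_gt(tsd$start[2] + 1, max(pltr$end))
  # geometry of the 5' module: overlap and truncation as specified
  inv <- pltr[pltr$name == "inverted", ]
  d5 <- pltr[pltr$name == "direct", ][1, ]
  expect_equal(inv$end - d5$start, 15L)
  expect_equal(218L - (inv$end - inv$start), 37L)
  # ORF: planted length, starts 36 bp before the 5' direct unit end
  orf <- tf[tf$type == "orf", ]
  expect_equal(orf$end - orf$start, 3L * 842L + 3L)
  expect_equal(d5$end - orf$start, 36L)
  prot <- translate_dna(subseq0(s, orf$start, orf$end))
  expect_equal(nchar(prot), 843L)           # 842 aa + terminal stop
  expect_false(grepl("*", substr(prot, 1, 842), fixed = TRUE))
})

test_that("identical seeds give byte-identical sequence and truth", {
  a <- forge_locus(pen2a_spec(seed = 123))
  b <- forge_locus(pen2a_spec(seed = 123))
  expect_identical(a, b)
  c <- forge_locus(pen2a_spec(seed = 124))
  expect_false(identical(a$sequence, c$sequence))
})

test_that("solo arrangement without TSD has one unit and no TSD truth", {
  fl <- forge_locus(locus_spec(seed = 3, arrangement = "solo", tsd_len = 0))
  tf <- fl$truth$features
  expect_equal(sum(tf$type == "pltr"), 1L)
  expect_equal(sum(tf$type == "tsd"), 0L)
})

test_that("inconsistent specs fail validation naming the offending field", {
  expect_error(locus_spec(overlap_5p = 300), "overlap_5p")
  expect_error(locus_spec(tsd_len = 30), "tsd_len")
  expect_error(locus_spec(tsd_len = 8, tsd_motif = "GAATTAATX"), "tsd_motif")
  expect_error(locus_spec(tail_len = 218), "tail_len")
  expect_error(locus_spec(orf_aa = 0), "orf_aa")
})

test_that("allelic pairs realize the requested divergence", {
  backbone <- withr::with_seed(5, random_dna(10000))
  pair <- forge_allelic_pair(backbone, 0.02, seed = 9)
  d <- mean(strsplit(pair$allele_A, "")[[1]] != strsplit(pair$allele_B, "")[[1]])
  expect_lt(abs(d - 0.02), 0.004)   # binomial standard error margin
  same <- forge_allelic_pair(backbone, 0, seed = 9)
  expect_identical(same$allele_A, same$allele_B)
})

test_that("insertion alleles duplicate the motif; empty alleles keep one copy", {
  backbone <- withr::with_seed(6, random_dna(4000))
  ins <- withr::with_seed(7, random_dna(1500))
  pair <- forge_allelic_pair(backbone, 0.02,
                             insertion = list(sequence = ins, position = 2000L,
                                              tsd_motif = "GAATTAAT"),
                             seed = 11)
  near_junction <- substr(pair$allele_B, 2000 - 50, 2000 + 58)
  expect_equal(length(gregexpr("GAATTAAT", near_junction)[[1]]), 1L)
  expect_equal(length(gregexpr("GAATTAAT", pair$allele_A, fixed = TRUE)[[1]]), 2L)
})

test_that("small-RNA libraries match their composition spec", {
  el <- withr::with_seed(21, random_dna(3000))
  lib <- forge_smallrna_library(el, smallrna_spec(n_reads = 10000,
                                                  antisense_fraction = 0.9,
                                                  u5_bias = 0.8, seed = 3))
  expect_lt(abs(mean(lib$strand == "-") - 0.9), 0.01)
  expect_gte(mean(substr(lib$seq, 1, 1) == "T"), 0.78)
  expect_true(all(nchar(lib$seq) >= 25 & nchar(lib$seq) <= 32))
  sense <- forge_smallrna_library(el, smallrna_spec(500, antisense_fraction = 0,
                                                    seed = 4))
  expect_true(all(sense$strand == "+"))
  none <- forge_smallrna_library(el, smallrna_spec(0, seed = 5))
  expect_equal(nrow(none), 0L)
  restricted <- forge_smallrna_library(el,
    smallrna_spec(300, source_interval = c(1000L, 2000L), seed = 6))
  expect_true(all(restricted$start >= 1000 & restricted$start + restricted$length <= 2000))
})

test_that("insert composition converges to the target asparagine fraction", {
  fr <- vapply(1:20, function(s) {
    o <- forge_orf(100, insert = insert_spec(500, 0.30), seed = s)
    ins <- substr(o$protein, o$truth$insert[1] + 1, o$truth$insert[2])
    mean(strsplit(ins, "")[[1]] == "N")
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.30), 0.03)
  big <- forge_orf(100, insert = insert_spec(5000, 0.28), seed = 1)
  ins <- substr(big$protein, big$truth$insert[1] + 1, big$truth$insert[2])
  expect_lt(abs(mean(strsplit(ins, "")[[1]] == "N") - 0.28), 0.01)
})
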