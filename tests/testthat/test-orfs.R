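test_that("ORF discovery equals the six-frame brute force", {
  for (s in 1:25) {
    seqn <- withr::with_seed(700 + s, random_dna(1500))
    got <- find_orfs(seqn, min_aa = 20)
    orc <- oracle_orfs(seqn, min_aa = 20)
    expect_equal(nrow(got), nrow(orc), info = paste("seed", s))
    if (nrow(got)) {
      expect_equal(got$start, as.integer(orc[, 1]))
      expect_equal(got$end, as.integer(orc[, 2]))
      expect_equal(got$aa_len, as.integer(orc[, 3]))
    }
  }
})

test_that("a minimal hand-translatable ORF is reported", {
  got <- find_orfs("ATGAAATAA", min_aa = 1)
  expect_equal(nrow(got), 1L)
  expect_equal(got$aa_len, 2L)
  expect_equal(got$protein, "MK")
  expect_equal(c(got$start, got$end), c(0L, 9L))
})

test_that("the forged intact element yields its planted ORF", {
  fl <- forge_locus(locus_spec(seed = 31, orf_aa = 838))
  orfs <- find_orfs(fl$sequence, min_aa = 300)
  o_start <- fl$truth$params$orf_start
  hit <- orfs[orfs$start == o_start & orfs$strand == "+", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$aa_len, 838L)
})

test_that("planted defects are classified with their kinds and positions", {
  ref <- forge_orf(600, seed = 41)
  stopd <- forge_orf(600, defects = list(defect_spec("stop", 400)), seed = 41)
  d <- classify_defects(stopd$dna, ref$protein)
  expect_equal(d$kind, "premature_stop")
  expect_lt(abs(d$position - 399), 10)
  fs <- forge_orf(600, defects = list(defect_spec("frameshift", 200)), seed = 41)
  d2 <- classify_defects(fs$dna, ref$protein)
  expect_equal(d2$kind, "frameshift")
  expect_lt(abs(d2$position - 199), 10)
  clean <- classify_defects(ref$dna, ref$protein, ref$intact_dna)
  expect_equal(nrow(clean), 0L)
})

test_that("microhomology deletions report the planted breakpoint overlap", {
  for (s in 1:20) {
    o <- forge_orf(500, defects = list(
      defect_spec("microhomology_deletion", position = 450, size = 300,
                  microhomology_len = 3)), seed = s)
    ref_prot <- translate_dna(substr(o$intact_dna, 1, nchar(o$intact_dna) - 3))
    d <- classify_defects(o$dna, ref_prot, reference_dna = o$intact_dna)
    expect_equal(d$kind, "microhomology_deletion", info = paste("seed", s))
    expect_equal(d$microhomology_len, 3L, info = paste("seed", s))
  }
})

test_that("unrecognizable copies are flagged as doubly truncated", {
  junk <- withr::with_seed(3, random_dna(900))
  ref <- forge_orf(300, seed = 9)
  d <- classify_defects(junk, ref$protein)
  expect_setequal(d$kind, c("trunc5", "trunc3"))
})

test_that("the GIY-YIG scan finds embedded and constructed motifs", {
  o <- forge_orf(500, seed = 13)
  expect_false(is.null(scan_giy_yig(o$protein)))
  built <- paste0("AAAA", "GIY", strrep("Q", 10), "YIG", "AAAA")
  hit <- scan_giy_yig(built)
  expect_equal(hit$gap, 10L)
  expect_equal(hit$giy_pos, 4L)
  expect_null(scan_giy_yig(strrep("A", 100)))
})

test_that("the cysteine motif scan equals positional enumeration", {
  expect_equal(scan_cys_motif("HAACAAAAAAAAAACAAC"), 0L)
  expect_equal(length(scan_cys_motif(strrep("A", 50))), 0L)
  aas <- c("A", "C", "H", "G", "L", "S")
  for (s in 1:30) {
    prot <- withr::with_seed(40 + s,
      paste(sample(aas, 400, replace = TRUE, prob = c(.3, .25, .15, .1, .1, .1)),
            collapse = ""))
    expect_equal(scan_cys_motif(prot), oracle_cys(prot), info = paste("seed", s))
  }
})

test_that("N-rich segments recover planted insert boundaries", {
  dev <- numeric(0)
  for (s in 1:10) {
    o <- forge_orf(842, insert = insert_spec(467, 0.30), seed = 60 + s)
    seg <- detect_n_rich(o$protein, window = 50, threshold = 0.25, min_len = 100)
    expect_equal(nrow(seg), 1L, info = paste("seed", s))
    # edge windows are stochastic, so per-seed recovery is window-limited
    expect_lt(abs(seg$start - o$truth$insert[1]), 100)
    expect_lt(abs(seg$end - o$truth$insert[2]), 100)
    expect_lt(abs(seg$asn_fraction - 0.30), 0.05)
    dev <- c(dev, abs(seg$start - o$truth$insert[1]),
             abs(seg$end - o$truth$insert[2]))
  }
  expect_lt(mean(dev), 50)
  poly <- detect_n_rich(strrep("N", 200), window = 50, threshold = 0.25,
                        min_len = 100)
  expect_equal(poly$asn_fraction, 1.0)
  expect_equal(poly$length_aa, 200L)
  flat <- withr::with_seed(4, paste(sample(c("N", "A"), 2000, TRUE,
                                           prob = c(.05, .95)), collapse = ""))
  expect_equal(nrow(detect_n_rich(flat)), 0L)
})

test_that("AAY codon density reflects composition", {
  expect_equal(detect_aay_bias(strrep("AAT", 10), window = 10)$profile$fraction, 1)
  # uniform sense codons approach the 2/61 baseline
  o <- forge_orf(3000, seed = 77)
  prof <- detect_aay_bias(o$dna, window = 1000)
  expect_lt(abs(mean(prof$profile$fraction) - 2 / 61), 0.01)
  # a planted (AAY)n stretch is the density peak
  planted <- paste0(o$dna, strrep("AAC", 25), substr(o$dna, 1, 900))
  pk <- detect_aay_bias(planted, window = 25)
  expect_lt(abs(pk$peak - nchar(o$dna) / 3), 26)
})
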