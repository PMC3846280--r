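test_that("a planted exact direct repeat is recovered and matches the oracle", {
  seqn <- withr::with_seed(11, {
    unit <- random_dna(60)
    paste0(random_dna(40), unit, random_dna(90), unit, random_dna(50))
  })
  got <- find_terminal_repeats(seqn, min_unit = 50)
  orc <- oracle_repeats(seqn, min_unit = 50)
  expect_equal(pairs_key(got), pairs_key(orc))
  expect_true(any(got$length == 60 & got$orientation == "direct"))
})

test_that("uniform random sequence yields no repeat pairs", {
  seqn <- withr::with_seed(5, random_dna(2000))
  expect_equal(nrow(find_terminal_repeats(seqn, min_unit = 50)), 0L)
})

test_that("the canonical forged locus resolves to its printed geometry", {
  sc <- pen2a_scene(seed = 2)
  pairs <- sc$ann$pairs
  expect_true(any(pairs$length == 218 & pairs$orientation == "direct"))
  expect_true(any(pairs$length == 181 & pairs$orientation == "inverted"))
  ann <- sc$ann$pltr
  expect_equal(ann$arrangement, "DD_plus_inverted5p")
  expect_equal(ann$overlap_5p, 15L)
  expect_equal(ann$truncation_5p, 37L)
  expect_equal(sort(ann$units$unit_len), c(181L, 218L, 218L))
})

test_that("repeat finding is symmetric under reverse complement", {
  for (s in 1:10) {
    seqn <- withr::with_seed(s, {
      unit <- random_dna(70)
      paste0(random_dna(30), unit, random_dna(60), revcomp(unit),
             random_dna(20), unit, random_dna(40))
    })
    n <- nchar(seqn)
    fw <- find_terminal_repeats(seqn, min_unit = 50)
    rv <- find_terminal_repeats(revcomp(seqn), min_unit = 50)
    mirror <- function(p) {
      if (!nrow(p)) return(p)
      s1 <- n - p$end2; e1 <- n - p$start2
      s2 <- n - p$end1; e2 <- n - p$start1
      out <- data.frame(start1 = pmin(s1, s2), end1 = pmin(e1, e2),
                        start2 = pmax(s1, s2), end2 = pmax(e1, e2),
                        length = p$length, orientation = p$orientation,
                        identity = p$identity)
      out
    }
    expect_equal(pairs_key(mirror(rv)), pairs_key(fw))
  }
})

test_that("detector equals the exhaustive per-diagonal oracle on small inputs", {
  for (s in 1:40) {
    seqn <- withr::with_seed(100 + s, {
      unit <- random_dna(60)
      noisy <- chars_dna(plescout:::mutate_chars(dna_chars(unit), 0.05))
      paste0(random_dna(30), unit, random_dna(50),
             if (s %% 2) noisy else revcomp(noisy), random_dna(30))
    })
    expect_equal(pairs_key(find_terminal_repeats(seqn, min_unit = 40)),
                 pairs_key(oracle_repeats(seqn, min_unit = 40)),
                 info = paste("seed", s))
  }
})

test_that("tail measurement equals longest common extension on planted cases", {
  # two units (given by coordinates) whose downstream sequences share
  # exactly 12 bp beyond their 3' ends
  seqn <- withr::with_seed(9, {
    shared <- random_dna(12)
    paste0(random_dna(100), shared, "C", random_dna(60),
           shared, "G", random_dna(40))
  })
  units <- data.frame(start = c(20L, 153L), end = c(100L, 173L),
                      unit_len = c(80L, 20L),
                      orientation = c("direct", "direct"))
  tl <- detect_tail(units[1, ], seqn, units[2, , drop = FALSE])
  v <- dna_chars(seqn)
  lce <- 0L
  while (v[units$end[1] + lce + 1] == v[units$end[2] + lce + 1]) lce <- lce + 1L
  expect_equal(tl, lce)
  expect_equal(tl, 12L)
})

test_that("tail is absent when not planted and recovered when planted", {
  fl0 <- forge_locus(locus_spec(seed = 4, tail_len = 0))
  a0 <- annotate_locus(fl0$sequence)
  expect_equal(a0$tail_len, 0L)
  fl1 <- forge_locus(locus_spec(seed = 4))
  a1 <- annotate_locus(fl1$sequence)
  expect_equal(a1$tail_len, 31L)
})

test_that("pLTR codon coverage credits the unit and its tail", {
  unit <- list(start = 0L, end = 218L)
  orf <- list(start = 182L, end = 2700L)   # 36 ORF bases inside the unit
  expect_equal(pltr_orf_codon_coverage(unit, 31L, orf), 22L)
  expect_equal(pltr_orf_codon_coverage(unit, 0L, orf), 12L)
  expect_equal(pltr_orf_codon_coverage(unit, 31L, list(start = 300L, end = 400L)), 0L)
})
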