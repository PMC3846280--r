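test_that("read placement equals the naive sliding-window mapper", {
  el <- withr::with_seed(71, random_dna(400))
  lib <- forge_smallrna_library(el, smallrna_spec(30, antisense_fraction = 0.5,
                                                  seed = 72))
  al <- map_reads(lib, el, max_mismatch = 1)
  for (i in seq_len(nrow(lib))) {
    got_p <- sort(al$pos[al$read == i & al$strand == "+"])
    got_m <- sort(al$pos[al$read == i & al$strand == "-"])
    expect_equal(got_p, oracle_map_positions(lib$seq[i], el),
                 ignore_attr = TRUE, info = paste("read", i))
    expect_equal(got_m, oracle_map_positions(revcomp(lib$seq[i]), el),
                 ignore_attr = TRUE, info = paste("read", i))
  }
  # sense reads from unique loci are recovered on the plus strand
  expect_true(all(al$strand[al$read %in% which(lib$strand == "+")] %in% c("+", "-")))
})

test_that("absent reads yield no alignment; multi-mappers split their weight", {
  el <- withr::with_seed(73, paste0(random_dna(200), substr(random_dna(0), 1, 0)))
  absent <- strrep("ACGT", 8)
  expect_equal(nrow(map_reads(absent, el, max_mismatch = 0)), 0L)
  dup <- withr::with_seed(74, random_dna(30))
  el2 <- paste0(dup, withr::with_seed(75, random_dna(100)), dup)
  al <- map_reads(dup, el2, max_mismatch = 0)
  expect_equal(nrow(al), 2L)
  expect_equal(al$weight, c(0.5, 0.5))
  expect_equal(sum(al$weight), 1)
})

test_that("polarity reflects the forged antisense fraction", {
  el <- withr::with_seed(76, random_dna(3000))
  lib <- forge_smallrna_library(el, smallrna_spec(8000, antisense_fraction = 0.9,
                                                  seed = 77))
  prof <- windowed_polarity(map_reads(lib, el), nchar(el), window = 100)
  overall <- (1 - prof$antisense_fraction) - prof$antisense_fraction
  expect_lt(abs(overall - (-0.8)), 0.02)
  sense <- forge_smallrna_library(el, smallrna_spec(2000, antisense_fraction = 0,
                                                    u5_bias = 0, seed = 78))
  ps <- windowed_polarity(map_reads(sense, el), nchar(el), window = 100)
  covered <- !is.na(ps$polarity)
  expect_true(all(ps$polarity[covered] == 1))
  empty <- windowed_polarity(map_reads(character(0), el), nchar(el), 100)
  expect_true(all(is.na(empty$polarity)))
})

test_that("polarity switches are found at the forged midpoint only", {
  el <- withr::with_seed(79, random_dna(3000))
  l5 <- forge_smallrna_library(el, smallrna_spec(1500, antisense_fraction = 0.05,
                                                 source_interval = c(0L, 1500L),
                                                 seed = 80))
  l3 <- forge_smallrna_library(el, smallrna_spec(1500, antisense_fraction = 0.95,
                                                 source_interval = c(1500L, 3000L),
                                                 seed = 81))
  prof <- windowed_polarity(map_reads(rbind(l5, l3), el), nchar(el), 100)
  sw <- detect_polarity_switch(prof, min_run = 3)
  expect_equal(length(sw), 1L)
  expect_lt(abs(sw - 1500), 100)
  uni <- windowed_polarity(map_reads(l3, el), nchar(el), 100)
  expect_equal(length(detect_polarity_switch(uni, 3)), 0L)
  # alternating single-window noise never satisfies the run requirement
  fake <- structure(list(window = 100L, window_start = seq(0L, 900L, 100L),
                         sense = rep(c(1, 0), 5), antisense = rep(c(0, 1), 5),
                         polarity = rep(c(1, -1), 5),
                         antisense_fraction = 0.5),
                    class = "ple_smallrna_profile")
  expect_equal(length(detect_polarity_switch(fake, 3)), 0L)
})

test_that("expression density is counts per kb and recovers forged ratios", {
  expect_equal(expression_density(100, 1000), 100)
  expect_equal(expression_density(50, 2000), 25)
  expect_error(expression_density(10, 0), "positive")
  el <- withr::with_seed(82, random_dna(2000))
  hi <- forge_smallrna_library(el, smallrna_spec(4000, antisense_fraction = 0.5,
                                                 seed = 83))
  lo <- forge_smallrna_library(el, smallrna_spec(200, antisense_fraction = 0.5,
                                                 seed = 84))
  dh <- expression_density(sum(map_reads(hi, el)$weight), nchar(el))
  dl <- expression_density(sum(map_reads(lo, el)$weight), nchar(el))
  expect_lt(abs(dh / dl - 20), 2)
})
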