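test_that("the coverage inclusion rule uses a closed one-third threshold", {
  ref_len <- 2400L
  copies <- data.frame(label = c("a", "b", "c"),
                       start = c(0L, 0L, 0L),
                       end = c(960L, 480L, 800L))   # 40%, 20%, exactly 1/3
  kept <- inclusion_filter(copies, ref_len)
  expect_setequal(kept$label, c("a", "c"))
  expect_equal(attr(kept, "included"), c(TRUE, FALSE, TRUE))
})

test_that("pairwise distances recover planted substitution rates", {
  base <- withr::with_seed(21, random_dna(3000))
  seqs <- c(x = base,
            y = withr::with_seed(22, chars_dna(plescout:::mutate_chars(dna_chars(base), 0.10))),
            z = base)
  dm <- pairwise_distances(seqs)
  expect_equal(diag(dm), c(x = 0, y = 0, z = 0))
  expect_equal(dm, t(dm))
  expect_equal(dm["x", "z"], 0)
  expect_lt(abs(dm["x", "y"] - 0.10), 0.01)
})

test_that("single-linkage cuts yield nested, order-invariant partitions", {
  base1 <- withr::with_seed(31, random_dna(2500))
  base2 <- withr::with_seed(32, random_dna(2500))
  mut <- function(s, r, sd) withr::with_seed(sd,
    chars_dna(plescout:::mutate_chars(dna_chars(s), r)))
  seqs <- c(a1 = base1, a2 = mut(base1, 0.05, 41), a3 = mut(base1, 0.18, 42),
            b1 = base2, b2 = mut(base2, 0.05, 43))
  dm <- pairwise_distances(seqs)
  fam <- cluster_families(dm)
  # two groups, a3 a separate subfamily within the a family
  expect_equal(fam$group[fam$label == "a1"], fam$group[fam$label == "a3"])
  expect_false(fam$group[fam$label == "a1"] == fam$group[fam$label == "b1"])
  expect_equal(fam$subfamily[fam$label == "a1"], fam$subfamily[fam$label == "a2"])
  expect_false(fam$subfamily[fam$label == "a1"] == fam$subfamily[fam$label == "a3"])
  # nesting: same subfamily implies same family implies same group
  for (i in seq_len(nrow(fam))) for (j in seq_len(nrow(fam))) {
    if (fam$subfamily[i] == fam$subfamily[j])
      expect_equal(fam$family[i], fam$family[j])
    if (fam$family[i] == fam$family[j])
      expect_equal(fam$group[i], fam$group[j])
  }
  # invariance to input order
  perm <- c(4, 2, 5, 1, 3)
  fam2 <- cluster_families(pairwise_distances(seqs[perm]))
  fam2 <- fam2[match(fam$label, fam2$label), ]
  expect_equal(fam$group, fam2$group)
  expect_equal(fam$family, fam2$family)
  expect_equal(fam$subfamily, fam2$subfamily)
})

test_that("copies 90% identical share a subfamily at the 0.10 cut", {
  base <- withr::with_seed(51, random_dna(2500))
  seqs <- c(p = base, q = withr::with_seed(52,
    chars_dna(plescout:::mutate_chars(dna_chars(base), 0.095))))
  fam <- cluster_families(pairwise_distances(seqs))
  expect_equal(fam$subfamily[1], fam$subfamily[2])
})

test_that("one sequence forms a trivial singleton assignment", {
  fam <- cluster_families(matrix(0, 1, 1, dimnames = list("only", "only")))
  expect_equal(fam$group, 1L)
  expect_equal(fam$subfamily, 1L)
})

test_that("neighbor joining reconstructs additive four-taxon distances", {
  # tree: ((A:2,B:3):1,(C:2,D:4)); additive distances computed by hand
  dm <- matrix(c(0, 5, 5, 7,
                 5, 0, 6, 8,
                 5, 6, 0, 6,
                 7, 8, 6, 0), 4, 4,
               dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  nj <- neighbor_joining(dm)
  expect_equal(nj$clamped, 0L)
  # the reconstructed tree reproduces the input distances exactly
  cd <- cophenetic(nj$tree)[rownames(dm), colnames(dm)]
  expect_equal(unname(cd), unname(dm), tolerance = 1e-9)
  expect_error(neighbor_joining(dm[1:2, 1:2]), "3 taxa")
})

test_that("neighbor joining is consistent on random additive matrices", {
  for (s in 1:20) {
    tr <- withr::with_seed(800 + s, ape::rtree(sample(4:8, 1)))
    dm <- cophenetic(tr)
    nj <- neighbor_joining(dm)
    expect_equal(ape::dist.topo(ape::unroot(tr), nj$tree), structure(0, names = "PH85"),
                 ignore_attr = TRUE)
    cd <- cophenetic(nj$tree)[rownames(dm), colnames(dm)]
    expect_equal(unname(cd), unname(dm), tolerance = 1e-8)
  }
})

test_that("a forged two-clade population keeps its clades apart in the tree", {
  base1 <- withr::with_seed(61, random_dna(2000))
  base2 <- withr::with_seed(62, random_dna(2000))
  mut <- function(s, r, sd) withr::with_seed(sd,
    chars_dna(plescout:::mutate_chars(dna_chars(s), r)))
  seqs <- c(a1 = mut(base1, 0.05, 1), a2 = mut(base1, 0.05, 2),
            b1 = mut(base2, 0.05, 3), b2 = mut(base2, 0.05, 4))
  nj <- neighbor_joining(pairwise_distances(seqs))
  # the a/b split must be a bipartition of the unrooted tree
  cd <- cophenetic(nj$tree)
  within <- c(cd["a1", "a2"], cd["b1", "b2"])
  across <- c(cd["a1", "b1"], cd["a1", "b2"], cd["a2", "b1"], cd["a2", "b2"])
  expect_true(max(within) < min(across))
})
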