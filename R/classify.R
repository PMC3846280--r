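# Identity-based family classification: the coverage inclusion rule,
# anchored pairwise distances, nested single-linkage partitions, and a
# neighbor-joining summary tree.

#' Apply the coding-sequence coverage inclusion rule
#'
#' Keeps copies whose mapped interval covers at least one-third of the
#' family reference ORF (closed threshold: exactly one-third is included).
#'
#' @param copies data frame with `start`,`end` intervals on the reference
#'   (0-based half-open, bp).
#' @param reference_orf_len reference ORF length, bp.
#' @return `copies` restricted to the included rows, with a logical
#'   `included` attribute covering all input rows.
#' @export
inclusion_filter <- function(copies, reference_orf_len) {
  cov <- (copies$end - copies$start) / reference_orf_len
  included <- cov >= 1 / 3
  out <- copies[included, , drop = FALSE]
  attr(out, "included") <- included
  out
}

#' Anchored pairwise p-distance matrix
#'
#' Distance is the anchored per-column mismatch fraction (as in
#' [allelic_divergence()]); pairs without a shared anchor get distance 1
#' and are flagged.
#'
#' @param seqs named character vector of DNA sequences (>= 2).
#' @param k anchor word size.
#' @return symmetric matrix with zero diagonal; attribute `unanchored`
#'   lists label pairs without anchors.
#' @export
pairwise_distances <- function(seqs, k = 12L) {
  n <- length(seqs)
  if (n < 2L) stop("need at least two sequences")
  labels <- names(seqs) %||% paste0("seq", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  unanch <- character()
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    d <- suppressWarnings(allelic_divergence(seqs[[i]], seqs[[j]], anchor_k = k))
    if (is.na(d)) { d <- 1; unanch <- c(unanch, paste(labels[i], labels[j], sep = "|")) }
    m[i, j] <- m[j, i] <- d
  }
  attr(m, "unanchored") <- unanch
  m
}

#' Nested subfamily/family/group partitions by single linkage
#'
#' Single-linkage clustering cut at three increasing distance thresholds
#' yields nested partitions.  Cluster labels are canonical (numbered by the
#' lexicographically smallest member), so the assignment is invariant to
#' input order.
#'
#' @param dm symmetric distance matrix with labels.
#' @param subfamily_cut,family_cut,group_cut increasing distance cuts.
#' @return data frame: `label,group,family,subfamily`.
#' @export
cluster_families <- function(dm, subfamily_cut = 0.10, family_cut = 0.25,
                             group_cut = 0.45) {
  if (!(subfamily_cut < family_cut && family_cut < group_cut))
    stop("cuts must satisfy subfamily_cut < family_cut < group_cut")
  labels <- rownames(dm)
  if (length(labels) == 1L) {
    return(data.frame(label = labels, group = 1L, family = 1L,
                      subfamily = 1L, stringsAsFactors = FALSE))
  }
  hc <- stats::hclust(stats::as.dist(dm), method = "single")
  canon <- function(cl) {
    reps <- vapply(split(labels, cl), min, character(1))
    rank_of <- stats::setNames(rank(reps, ties.method = "first"), names(reps))
    as.integer(rank_of[as.character(cl)])
  }
  data.frame(label = labels,
             group = canon(stats::cutree(hc, h = group_cut)),
             family = canon(stats::cutree(hc, h = family_cut)),
             subfamily = canon(stats::cutree(hc, h = subfamily_cut)),
             stringsAsFactors = FALSE)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical NJ agglomeration (via \pkg{ape}); negative branch lengths are
#' clamped to zero and flagged.
#'
#' @param dm symmetric distance matrix (>= 3 taxa).
#' @return list: `tree` (an \pkg{ape} `phylo`), `newick` (string),
#'   `clamped` (number of negative branch lengths clamped).
#' @export
neighbor_joining <- function(dm) {
  if (nrow(dm) < 3L) stop("neighbor joining needs at least 3 taxa")
  tree <- ape::nj(stats::as.dist(dm))
  neg <- tree$edge.length < 0
  tree$edge.length[neg] <- 0
  list(tree = tree, newick = ape::write.tree(tree),
       clamped = sum(neg))
}
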