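# Terminal-repeat (pLTR) detection and arrangement resolution.
#
# Repeat semantics: ungapped matches found by exact k-mer seeding followed
# by bidirectional extension under a +1/-2 match/mismatch score with an
# X-drop stop; reported boundaries are the score-maximal endpoints, so a
# reported repeat is exactly maximal (cannot be extended without dropping
# below its best score).  Inverted self-matches that span their own
# anti-diagonal centre are palindromes; they are split into their two arms
# so that palindromic termini do not swallow adjacent units.

# maximal TRUE runs of length >= k in a logical vector
true_runs <- function(m, k) {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= k
  cbind(start = starts[keep], end = ends[keep])
}

# extend a seed run [s0, s1] on match vector m; +1/-2 scoring, stop when
# score < best - xdrop; returns score-argmax endpoints (closest on ties)
extend_run <- function(m, s0, s1, xdrop = 10L) {
  n <- length(m)
  best <- 0; bi <- s1; sc <- 0; i <- s1
  while (i < n) {
    i <- i + 1L
    sc <- sc + if (m[i]) 1L else -2L
    if (sc > best) { best <- sc; bi <- i }
    if (sc < best - xdrop) break
  }
  right <- bi
  best <- 0; bi <- s0; sc <- 0; i <- s0
  while (i > 1L) {
    i <- i - 1L
    sc <- sc + if (m[i]) 1L else -2L
    if (sc > best) { best <- sc; bi <- i }
    if (sc < best - xdrop) break
  }
  c(bi, right)
}

# positions (1-based) of each k-mer, keyed by k-mer string
kmer_index <- function(seqstr, k) {
  n <- nchar(seqstr)
  if (n < k) return(list())
  words <- substring(seqstr, 1:(n - k + 1L), k:n)
  split(seq_len(n - k + 1L), words)
}

#' Find terminal-repeat pairs in a locus
#'
#' Reports all maximal ungapped repeat pairs of the locus against itself
#' (direct) and against its reverse complement (inverted) with unit length
#' `>= min_unit` and identity `>= min_identity`, sorted by unit length
#' descending.  Coordinates are 0-based half-open with `start1 <= start2`.
#'
#' @param locus DNA string.
#' @param min_unit minimum unit length, bp.
#' @param min_identity minimum matched fraction within the unit.
#' @param k seed word size.
#' @param xdrop extension stop (score drop below the running maximum).
#' @return data frame: `start1,end1,start2,end2,length,orientation,identity`.
#' @export
find_terminal_repeats <- function(locus, min_unit = 50L, min_identity = 0.8,
                                  k = 12L, xdrop = 10L) {
  locus <- toupper(locus)
  n <- nchar(locus)
  out <- empty_pairs()
  if (n < 2L * min_unit) return(out)
  v <- dna_chars(locus)
  idx <- kmer_index(locus, k)

  # ---- direct: diagonals d = j - i > 0
  diags <- integer(0)
  for (pos in idx) {
    if (length(pos) < 2L) next
    cmb <- utils::combn(pos, 2L)
    diags <- c(diags, cmb[2L, ] - cmb[1L, ])
  }
  for (d in sort(unique(diags))) {
    m <- v[seq_len(n - d)] == v[(d + 1L):n]
    runs <- true_runs(m, k)
    segs <- unique(t(apply(runs, 1L, function(r) extend_run(m, r[1], r[2], xdrop))))
    for (ri in seq_len(nrow(segs))) {
      x1 <- segs[ri, 1]; x2 <- segs[ri, 2]
      len <- x2 - x1 + 1L
      if (len < min_unit) next
      ident <- sum(m[x1:x2]) / len
      if (ident < min_identity) next
      out <- rbind(out, data.frame(
        start1 = x1 - 1L, end1 = x2, start2 = x1 - 1L + d, end2 = x2 + d,
        length = len, orientation = "direct", identity = ident,
        stringsAsFactors = FALSE))
    }
  }

  # ---- inverted: anti-diagonals c = x + y (1-based), x restricted to the
  # lower half so palindromic matches are reported as arms
  rc <- revcomp(locus)
  ridx <- kmer_index(rc, k)
  cs <- integer(0)
  for (w in intersect(names(idx), names(ridx))) {
    for (i in idx[[w]]) for (r in ridx[[w]]) cs <- c(cs, i - r + n + 1L)
  }
  cv <- comp_chars(v)
  for (cc in sort(unique(cs))) {
    xs <- max(1L, cc - n)
    xe <- min(n, cc - 1L, (cc - 1L) %/% 2L)   # x < c - x
    if (xe - xs + 1L < k) next
    xr <- xs:xe
    m <- v[xr] == cv[cc - xr]
    runs <- true_runs(m, k)
    if (!nrow(runs)) next
    segs <- unique(t(apply(runs, 1L, function(r) extend_run(m, r[1], r[2], xdrop))))
    for (ri in seq_len(nrow(segs))) {
      x1 <- xs + segs[ri, 1] - 1L; x2 <- xs + segs[ri, 2] - 1L
      len <- x2 - x1 + 1L
      if (len < min_unit) next
      ident <- sum(m[(x1 - xs + 1L):(x2 - xs + 1L)]) / len
      if (ident < min_identity) next
      out <- rbind(out, data.frame(
        start1 = x1 - 1L, end1 = x2, start2 = cc - x2 - 1L, end2 = cc - x1,
        length = len, orientation = "inverted", identity = ident,
        stringsAsFactors = FALSE))
    }
  }
  out <- unique(out)
  out[order(-out$length, out$start1, out$start2), , drop = FALSE]
}

empty_pairs <- function() {
  data.frame(start1 = integer(), end1 = integer(), start2 = integer(),
             end2 = integer(), length = integer(), orientation = character(),
             identity = numeric(), stringsAsFactors = FALSE)
}

#' Resolve repeat pairs into a pLTR arrangement
#'
#' Merges pairwise hits into units (reciprocal overlap of at least half the
#' shorter interval), assigns orientations relative to the ORF strand by
#' propagating pair relations from an anchor unit (the unit covering the
#' ORF start, else the longest), computes the 5' overlap and truncation,
#' and labels the arrangement.
#'
#' @param pairs data frame from [find_terminal_repeats()] (or library hits
#'   with the same columns).
#' @param orf_strand strand of the element ORF (`"+"` or `"-"`).
#' @param orf_interval optional 0-based half-open ORF interval used to
#'   anchor orientation.
#' @return list of class `ple_pltr_annotation`: `units` (data frame
#'   start/end/unit_len/orientation), `arrangement`, `overlap_5p`,
#'   `truncation_5p`, `warnings`.
#' @export
resolve_arrangement <- function(pairs, orf_strand = "+", orf_interval = NULL) {
  warnings <- character()
  if (is.null(pairs) || !nrow(pairs)) {
    return(structure(list(units = data.frame(), arrangement = "none",
                          overlap_5p = 0L, truncation_5p = 0L,
                          warnings = warnings),
                     class = "ple_pltr_annotation"))
  }
  ivs <- rbind(data.frame(start = pairs$start1, end = pairs$end1),
               data.frame(start = pairs$start2, end = pairs$end2))
  # merge intervals into units
  unit_of <- integer(nrow(ivs))
  units <- list()
  for (i in seq_len(nrow(ivs))) {
    placed <- FALSE
    for (u in seq_along(units)) {
      ov <- interval_overlap(ivs$start[i], ivs$end[i],
                             units[[u]]$start, units[[u]]$end)
      shorter <- min(ivs$end[i] - ivs$start[i],
                     units[[u]]$end - units[[u]]$start)
      if (shorter > 0 && ov >= 0.5 * shorter) {
        units[[u]]$start <- min(units[[u]]$start, ivs$start[i])
        units[[u]]$end <- max(units[[u]]$end, ivs$end[i])
        unit_of[i] <- u
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      units[[length(units) + 1L]] <- list(start = ivs$start[i], end = ivs$end[i])
      unit_of[i] <- length(units)
    }
  }
  nu <- length(units)
  ud <- data.frame(start = vapply(units, `[[`, integer(1), "start"),
                   end = vapply(units, `[[`, integer(1), "end"))
  ud$unit_len <- ud$end - ud$start
  # relation edges: same orientation (direct pair) / opposite (inverted)
  np <- nrow(pairs)
  rel <- data.frame(a = unit_of[seq_len(np)], b = unit_of[np + seq_len(np)],
                    same = pairs$orientation == "direct")
  rel <- rel[rel$a != rel$b, , drop = FALSE]
  # anchor: unit covering the ORF start on the ORF strand, else longest
  anchor <- NA_integer_
  if (!is.null(orf_interval)) {
    orf_anchor_pos <- if (identical(orf_strand, "-")) orf_interval[2] - 1L else orf_interval[1]
    cand <- which(ud$start <= orf_anchor_pos & ud$end > orf_anchor_pos)
    if (length(cand)) anchor <- cand[which.max(ud$unit_len[cand])]
  }
  if (is.na(anchor)) anchor <- order(-ud$unit_len, -ud$start)[1]
  orient <- rep(NA, nu)
  orient[anchor] <- TRUE   # TRUE = direct
  repeat {
    moved <- FALSE
    for (e in seq_len(nrow(rel))) {
      a <- rel$a[e]; b <- rel$b[e]; same <- rel$same[e]
      for (pr in list(c(a, b), c(b, a))) {
        if (!is.na(orient[pr[1]]) && is.na(orient[pr[2]])) {
          orient[pr[2]] <- if (same) orient[pr[1]] else !orient[pr[1]]
          moved <- TRUE
        }
      }
      if (!is.na(orient[a]) && !is.na(orient[b])) {
        want <- if (same) orient[a] else !orient[a]
        if (orient[b] != want)
          warnings <- c(warnings, "contradictory orientation relation between units")
      }
    }
    if (!moved) break
  }
  orient[is.na(orient)] <- TRUE
  ud$orientation <- ifelse(orient, "direct", "inverted")
  # containment (nested units) is contradictory
  nested <- FALSE
  for (i in seq_len(nu)) for (j in seq_len(nu)) {
    if (i != j && ud$start[i] >= ud$start[j] && ud$end[i] <= ud$end[j] &&
        ud$unit_len[i] < ud$unit_len[j]) nested <- TRUE
  }
  ud <- ud[order(ud$start), , drop = FALSE]
  rownames(ud) <- NULL
  ndir <- sum(ud$orientation == "direct")
  ninv <- sum(ud$orientation == "inverted")
  overlap_5p <- 0L; truncation_5p <- 0L
  arrangement <- if (nested) {
    warnings <- c(warnings, "nested units; arrangement not resolved")
    "none"
  } else if (nu == 1L) "solo"
  else if (ninv == 0L) { if (nu == 2L) "DD_only" else "tandem_partial" }
  else if (ndir >= 2L && ninv >= 1L) "DD_plus_inverted5p"
  else if (nu == 2L) "inverted_pair"
  else "none"
  if (arrangement == "DD_plus_inverted5p") {
    inv <- which(ud$orientation == "inverted")[1]
    dirs <- which(ud$orientation == "direct")
    ovl <- vapply(dirs, function(d) interval_overlap(ud$start[inv], ud$end[inv],
                                                     ud$start[d], ud$end[d]),
                  integer(1))
    overlap_5p <- max(ovl)
    truncation_5p <- max(ud$unit_len[dirs]) - ud$unit_len[inv]
  }
  structure(list(units = ud, arrangement = arrangement,
                 overlap_5p = as.integer(overlap_5p),
                 truncation_5p = as.integer(truncation_5p),
                 warnings = warnings),
            class = "ple_pltr_annotation")
}

# the sequence stream beyond a unit's 3' end, in element orientation
beyond_3p <- function(v, unit_start0, unit_end0, orientation, max_len) {
  n <- length(v)
  if (orientation == "direct") {
    if (unit_end0 >= n) return(character(0))
    v[(unit_end0 + 1L):min(n, unit_end0 + max_len)]
  } else {
    if (unit_start0 <= 0L) return(character(0))
    comp_chars(rev(v[max(1L, unit_start0 - max_len + 1L):unit_start0]))
  }
}

#' Measure the shared 3' tail extension of a pLTR unit
#'
#' The tail is the maximal extension beyond the unit's 3' end that matches
#' the sequence beyond another unit's 3' end (score-maximal extension under
#' the same +1/-2 scoring as repeat detection, reported only when the
#' matched fraction reaches `min_identity`).
#'
#' @param unit one row of the `units` table of a
#'   [resolve_arrangement()] result (or any list with `start`, `end`,
#'   `orientation`).
#' @param locus locus DNA string.
#' @param other_units data frame of the remaining units.
#' @param max_len maximum extension examined, bp.
#' @param min_identity minimum matched fraction of the reported extension.
#' @param min_len shortest extension reported as a tail (chance matches of
#'   a few bases are not tails), bp.
#' @return tail length in bp (0 when absent).
#' @export
detect_tail <- function(unit, locus, other_units, max_len = 200L,
                        min_identity = 0.9, min_len = 5L) {
  v <- dna_chars(locus)
  a <- beyond_3p(v, unit$start, unit$end, unit$orientation, max_len)
  if (!length(a) || is.null(other_units) || !nrow(other_units)) return(0L)
  best <- 0L
  for (i in seq_len(nrow(other_units))) {
    b <- beyond_3p(v, other_units$start[i], other_units$end[i],
                   other_units$orientation[i], max_len)
    l <- min(length(a), length(b))
    if (l == 0L) next
    m <- a[seq_len(l)] == b[seq_len(l)]
    if (!m[1]) next
    sc <- cumsum(ifelse(m, 1L, -2L))
    len <- which.max(sc)
    if (len >= min_len && sum(m[seq_len(len)]) / len >= min_identity)
      best <- max(best, len)
  }
  as.integer(best)
}

#' ORF codons covered by a pLTR unit plus its tail
#'
#' @param pltr_unit list/row with `start`, `end` (0-based half-open).
#' @param tail_len tail extension credited to the unit, bp.
#' @param orf list/row with `start`, `end` of the ORF.
#' @return number of complete codons covered: `floor((covered + tail)/3)`.
#' @export
pltr_orf_codon_coverage <- function(pltr_unit, tail_len, orf) {
  covered <- interval_overlap(pltr_unit$start, pltr_unit$end,
                              orf$start, orf$end)
  if (covered == 0L) return(0L)   # ORF outside the unit: the tail alone counts nothing
  as.integer((covered + tail_len) %/% 3L)
}
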