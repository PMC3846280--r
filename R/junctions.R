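# Insertion-boundary characterization: target-site duplications,
# junction microhomology, palindromes, and pLTR-internal promoter motifs.

#' Detect a target-site duplication between two flanks
#'
#' Returns the longest suffix of `left_flank` that matches a prefix of
#' `right_flank` with at most `max_mismatch` mismatches and length within
#' `[min_len, max_len]`; `NULL` when no qualifying match exists.  When a
#' flank is shorter than `max_len` the search is limited to the available
#' length and the result is flagged (`truncated_search = TRUE`).
#'
#' @param left_flank,right_flank DNA strings immediately outside the
#'   element boundaries (left flank ends at the 5' junction, right flank
#'   starts at the 3' junction).
#' @param min_len,max_len length bounds, bp.
#' @param max_mismatch mismatch budget.
#' @return `NULL`, or list with `motif` (left-flank copy), `length`,
#'   `mismatches`, `truncated_search`.
#' @export
detect_tsd <- function(left_flank, right_flank, min_len = 4L, max_len = 25L,
                       max_mismatch = 0L) {
  lv <- dna_chars(left_flank)
  rv <- dna_chars(right_flank)
  lim <- min(max_len, length(lv), length(rv))
  truncated <- lim < max_len
  if (lim < min_len) return(NULL)
  for (k in lim:min_len) {
    a <- lv[(length(lv) - k + 1L):length(lv)]
    b <- rv[seq_len(k)]
    mm <- sum(a != b)
    if (mm <= max_mismatch) {
      return(list(motif = chars_dna(a), length = as.integer(k),
                  mismatches = as.integer(mm),
                  truncated_search = truncated))
    }
  }
  NULL
}

#' Measure microhomology across a junction
#'
#' Longest exact overlap between the element's terminal bases and the
#' adjacent target bases: the largest `h` such that the last `h` bases of
#' `element_end` equal the first `h` bases of `target_flank`.  Values below
#' `min_len` are reported as 0.
#'
#' @param element_end terminal element sequence (junction at its right end).
#' @param target_flank target sequence (junction at its left end).
#' @param min_len minimum reportable overlap.
#' @return overlap length in bp.
#' @export
detect_microhomology <- function(element_end, target_flank, min_len = 2L) {
  ev <- dna_chars(element_end)
  tv <- dna_chars(target_flank)
  best <- 0L
  for (h in seq_len(min(length(ev), length(tv)))) {
    if (identical(ev[(length(ev) - h + 1L):length(ev)], tv[seq_len(h)]))
      best <- h
  }
  if (best >= min_len) as.integer(best) else 0L
}

#' Find (near-)palindromes in a sequence
#'
#' A palindrome is an interval whose left arm equals the reverse complement
#' of its right arm up to `max_mismatch` mismatched pairs, with an optional
#' central spacer of at most `max_spacer` bases.  Arms are expanded from
#' every centre/spacer combination; reported intervals are maximal (the
#' outermost pair always matches, and no further expansion stays within the
#' mismatch budget) and at least `min_len` long.  Intervals reachable from
#' several spacer widths are reported once with the smallest mismatch
#' count.  A palindrome starting within 5 bp of the sequence start is
#' flagged `terminal`.
#'
#' @param seq DNA string.
#' @param min_len minimum total length (arms + spacer), bp.
#' @param max_mismatch arm mismatch budget.
#' @param max_spacer maximum central spacer, bp.
#' @return data frame sorted by position: `start,end,length,mismatches,
#'   spacer,terminal` (0-based half-open).
#' @export
find_palindromes <- function(seq, min_len = 10L, max_mismatch = 2L,
                             max_spacer = 4L) {
  v <- dna_chars(seq)
  n <- length(v)
  cv <- comp_chars(v)
  hits <- list()
  for (c0 in 0:n) {               # spacer starts after position c0 (0-based)
    for (s in 0:max_spacer) {
      if (c0 + s > n) next
      l <- c0; r <- c0 + s + 1L   # 1-based arm cursors
      mm <- 0L; arm <- 0L
      best_arm <- 0L; best_mm <- 0L
      while (l >= 1L && r <= n) {
        if (v[l] == cv[r]) {
          arm <- arm + 1L
          best_arm <- arm; best_mm <- mm
        } else {
          if (mm + 1L > max_mismatch) break
          mm <- mm + 1L
          arm <- arm + 1L
        }
        l <- l - 1L; r <- r + 1L
      }
      if (best_arm == 0L) next
      len <- 2L * best_arm + s
      if (len < min_len) next
      start0 <- c0 - best_arm
      hits[[length(hits) + 1L]] <-
        data.frame(start = start0, end = start0 + len, length = len,
                   mismatches = best_mm, spacer = s)
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(), end = integer(), length = integer(),
                      mismatches = integer(), spacer = integer(),
                      terminal = logical()))
  }
  out <- do.call(rbind, hits)
  # drop non-maximal duplicates: same interval from several spacers -> best;
  # intervals strictly contained in a reported interval with the same centre
  # are already excluded by maximal expansion
  out <- out[order(out$start, out$end, out$mismatches, out$spacer), , drop = FALSE]
  out <- out[!duplicated(out[, c("start", "end")]), , drop = FALSE]
  out$terminal <- out$start <= 5L
  rownames(out) <- NULL
  out
}

#' Scan a pLTR for TATA/initiator promoter arrangements on both strands
#'
#' For each strand, reports every occurrence of the TATA motif followed
#' within `max_spacing` bases by an initiator-like motif (`TCACT` on the
#' forward strand, `ACATT` on the reverse-orientation scan by default).
#' Minus-strand positions refer to the reverse-complemented sequence.
#'
#' @param pltr_seq pLTR DNA string.
#' @param promoter a [promoter_spec()] providing the motifs.
#' @param max_spacing maximum TATA-to-initiator gap, bp.
#' @return data frame: `strand,tata_pos,inr_pos,spacing,inr_motif`
#'   (0-based positions on the scanned strand).
#' @export
scan_promoter <- function(pltr_seq, promoter = promoter_spec(),
                          max_spacing = 50L) {
  scan_one <- function(s, strand, inr) {
    tata <- promoter$tata_motif
    tpos <- find_all(s, tata)
    ipos <- find_all(s, inr)
    rows <- list()
    for (t in tpos) {
      for (i in ipos) {
        spacing <- i - (t + nchar(tata))
        if (spacing >= 0L && spacing <= max_spacing) {
          rows[[length(rows) + 1L]] <-
            data.frame(strand = strand, tata_pos = t, inr_pos = i,
                       spacing = spacing, inr_motif = inr,
                       stringsAsFactors = FALSE)
        }
      }
    }
    rows
  }
  fwd <- scan_one(toupper(pltr_seq), "+", promoter$inr_motif)
  rev <- scan_one(revcomp(pltr_seq), "-", "ACATT")
  rows <- c(fwd, rev)
  if (!length(rows)) {
    return(data.frame(strand = character(), tata_pos = integer(),
                      inr_pos = integer(), spacing = integer(),
                      inr_motif = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# all 0-based occurrence positions of a fixed DNA motif (A-Z only),
# overlapping occurrences included
find_all <- function(s, motif) {
  hits <- gregexpr(paste0("(?=", motif, ")"), s, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L
}
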