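# pLTR-framed gene-capture detection, allelic empty-site verification,
# solo-pLTR classification, and anchored divergence estimation.

# cross-sequence ungapped hits (same seeding/extension semantics as
# find_terminal_repeats): intervals of `a` matching intervals of `b`
ungapped_hits <- function(a, b, k = 12L, xdrop = 10L, min_len = 50L,
                          min_identity = 0.8) {
  av <- dna_chars(a); bv <- dna_chars(b)
  na <- length(av); nb <- length(bv)
  out <- data.frame(start = integer(), end = integer(),
                    q_start = integer(), q_end = integer(),
                    length = integer(), identity = numeric())
  if (na < k || nb < k) return(out)
  ia <- kmer_index(a, k); ib <- kmer_index(b, k)
  diags <- integer(0)
  for (w in intersect(names(ia), names(ib)))
    for (i in ia[[w]]) diags <- c(diags, ib[[w]] - i)
  for (d in sort(unique(diags))) {
    i0 <- max(1L, 1L - d); i1 <- min(na, nb - d)
    if (i1 - i0 + 1L < k) next
    ir <- i0:i1
    m <- av[ir] == bv[ir + d]
    runs <- true_runs(m, k)
    if (!nrow(runs)) next
    segs <- unique(t(apply(runs, 1L, function(r) extend_run(m, r[1], r[2], xdrop))))
    for (ri in seq_len(nrow(segs))) {
      x1 <- i0 + segs[ri, 1] - 1L; x2 <- i0 + segs[ri, 2] - 1L
      len <- x2 - x1 + 1L
      if (len < min_len) next
      ident <- sum(m[(x1 - i0 + 1L):(x2 - i0 + 1L)]) / len
      if (ident < min_identity) next
      out <- rbind(out, data.frame(start = x1 - 1L, end = x2,
                                   q_start = x1 + d - 1L, q_end = x2 + d,
                                   length = len, identity = ident))
    }
  }
  unique(out)
}

#' Locate pLTR-library hits in a locus (both strands)
#'
#' @param locus locus DNA string.
#' @param pltr_library character vector of pLTR sequences.
#' @param min_identity minimum hit identity.
#' @param min_cov minimum hit length as a fraction of the library unit.
#' @return data frame: `start,end,strand,lib,length,identity`, sorted by
#'   position (0-based half-open, locus coordinates).
#' @export
find_pltr_hits <- function(locus, pltr_library, min_identity = 0.8,
                           min_cov = 0.5) {
  rows <- list()
  for (qi in seq_along(pltr_library)) {
    q <- toupper(pltr_library[[qi]])
    ml <- max(30L, as.integer(min_cov * nchar(q)))
    for (strand in c("+", "-")) {
      qq <- if (strand == "+") q else revcomp(q)
      h <- ungapped_hits(locus, qq, min_len = ml, min_identity = min_identity)
      if (nrow(h)) {
        h$strand <- strand; h$lib <- qi
        rows[[length(rows) + 1L]] <- h[, c("start", "end", "strand", "lib",
                                           "length", "identity")]
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(), strand = character(),
                      lib = integer(), length = integer(),
                      identity = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# do two sequences share any exact k-mer (either strand of `a`)?
shares_kmer <- function(a, b, k = 20L) {
  if (nchar(a) < k || nchar(b) < k) return(FALSE)
  ka <- unique(names(kmer_index(a, k)))
  kar <- unique(names(kmer_index(revcomp(a), k)))
  kb <- unique(names(kmer_index(b, k)))
  length(intersect(c(ka, kar), kb)) > 0L
}

#' Detect pLTR-framed capture events
#'
#' Locates pLTR-library hits, pairs adjacent co-oriented hits, extracts the
#' intervening cassette, tests the cassette for element-derived sequence
#' (shared 20-mers with the element ORF library), and infers the TSD from
#' the flanks outside the outermost hits of the event.
#'
#' @param locus locus DNA string.
#' @param pltr_library character vector of pLTR sequences (non-empty).
#' @param element_orf_library character vector of element ORF DNA sequences
#'   (non-empty).
#' @param min_identity minimum pLTR hit identity.
#' @param flank_probe flank length examined for the TSD, bp.
#' @param join_gap maximum gap for attaching additional pLTR hits (for
#'   example the 5' inverted companion) to an event, bp.
#' @return list of capture events, each a list with `cassette` (0-based
#'   interval), `framing` (hit rows), `outer_span`, `tsd` (as
#'   [detect_tsd()]), `cassette_is_element_free`; sorted by position.
#' @export
detect_capture <- function(locus, pltr_library, element_orf_library,
                           min_identity = 0.8, flank_probe = 60L,
                           join_gap = 10L) {
  if (!length(pltr_library) || !length(element_orf_library))
    stop("pLTR and element ORF libraries must be non-empty")
  locus <- toupper(locus)
  hits <- find_pltr_hits(locus, pltr_library, min_identity)
  events <- list()
  if (nrow(hits) < 2L) return(events)
  for (i in seq_len(nrow(hits) - 1L)) {
    j <- i + 1L
    if (hits$strand[i] != hits$strand[j]) next
    cass <- c(hits$end[i], hits$start[j])
    if (cass[2] - cass[1] < 50L) next
    members <- c(i, j)
    # absorb adjacent hits on either side (e.g. the inverted companion)
    k <- i - 1L
    while (k >= 1L && hits$start[members[1]] - hits$end[k] <= join_gap) {
      members <- c(k, members); k <- k - 1L
    }
    k <- j + 1L
    while (k <= nrow(hits) && hits$start[k] - hits$end[utils::tail(members, 1)] <= join_gap) {
      members <- c(members, k); k <- k + 1L
    }
    span <- c(min(hits$start[members]), max(hits$end[members]))
    cass_seq <- subseq0(locus, cass[1], cass[2])
    free <- !any(vapply(element_orf_library,
                        function(o) shares_kmer(cass_seq, toupper(o)),
                        logical(1)))
    lf <- subseq0(locus, max(0L, span[1] - flank_probe), span[1])
    rf <- subseq0(locus, span[2], min(nchar(locus), span[2] + flank_probe))
    tsd <- detect_tsd(lf, rf)
    events[[length(events) + 1L]] <-
      list(cassette = cass, framing = hits[members, , drop = FALSE],
           outer_span = span, tsd = tsd, cassette_is_element_free = free)
  }
  events[order(vapply(events, function(e) e$cassette[1], integer(1)))]
}

# dominant-diagonal anchoring of `query` inside `subject`; NULL when no
# shared k-mer exists
anchor_align <- function(query, subject, k = 16L) {
  qi <- kmer_index(query, k); si <- kmer_index(subject, k)
  shared <- intersect(names(qi), names(si))
  if (!length(shared)) return(NULL)
  diags <- integer(0)
  for (w in shared) for (i in qi[[w]]) diags <- c(diags, si[[w]] - i)
  tab <- table(diags)
  d <- as.integer(names(tab)[which.max(tab)])
  qv <- dna_chars(query); sv <- dna_chars(subject)
  i0 <- max(1L, 1L - d); i1 <- min(length(qv), length(sv) - d)
  if (i1 < i0) return(NULL)
  m <- qv[i0:i1] == sv[(i0:i1) + d]
  list(offset = d, columns = i1 - i0 + 1L, identity = mean(m),
       mismatches = sum(!m))
}

#' Verify an insertion against a candidate empty-site allele
#'
#' Anchors the insertion's left and right flanks in the candidate allele,
#' checks that they are adjacent there up to one copy of the TSD motif, and
#' counts motif occurrences around the junction.  Verification passes when
#' the flanks anchor with identity at or above `identity_min`, sit adjacent
#' at the junction, and the motif occurs exactly once there.
#'
#' @param insertion_locus locus carrying the insertion.
#' @param event a capture event from [detect_capture()].
#' @param candidate_allele candidate empty-site allele DNA.
#' @param min_anchor anchored flank length, bp.
#' @param identity_min minimum flank identity.
#' @param window motif counting half-window around the junction, bp.
#' @return list: `junction_pos`, `motif_occurrences`, `flank_identity`,
#'   `adjacent`, `pass`.
#' @export
verify_empty_site <- function(insertion_locus, event, candidate_allele,
                              min_anchor = 200L, identity_min = 0.90,
                              window = 50L) {
  locus <- toupper(insertion_locus); allele <- toupper(candidate_allele)
  span <- event$outer_span
  motif <- if (!is.null(event$tsd)) event$tsd$motif else ""
  m <- nchar(motif)
  fail <- function(id) list(junction_pos = NA_integer_, motif_occurrences = 0L,
                            flank_identity = id, adjacent = FALSE, pass = FALSE)
  if (span[1] - min_anchor < 0L || span[2] + min_anchor > nchar(locus))
    return(fail(0))
  left <- subseq0(locus, span[1] - min_anchor, span[1])
  right <- subseq0(locus, span[2], span[2] + min_anchor)
  aL <- anchor_align(left, allele)
  aR <- anchor_align(right, allele)
  if (is.null(aL) || is.null(aR)) return(fail(0))
  eL <- aL$offset + min_anchor    # 0-based end of the left flank in the allele
  sR <- aR$offset                 # 0-based start of the right flank
  adjacent <- abs(sR - (eL - m)) <= 2L
  junction <- eL - m
  occ <- 0L
  if (m > 0) {
    lo <- max(0L, junction - window)
    hi <- min(nchar(allele), junction + m + window)
    occ <- length(find_all(subseq0(allele, lo, hi), motif))
  }
  idn <- min(aL$identity, aR$identity)
  list(junction_pos = as.integer(junction), motif_occurrences = occ,
       flank_identity = idn, adjacent = adjacent,
       pass = adjacent && idn >= identity_min && (m == 0L || occ == 1L))
}

#' Classify pLTR units as element-terminal, capture-framing or solo
#'
#' @param locus locus DNA string.
#' @param units data frame of units (`start,end,orientation`).
#' @param events list of capture events from [detect_capture()].
#' @param element_hits data frame of element ORF similarity intervals
#'   (`start,end`), possibly empty.
#' @param near_gap distance (bp) within which a unit counts as attached to
#'   an element body.
#' @return character vector: one of `element_terminal`, `capture_framing`,
#'   `solo_with_tsd`, `solo_bare` per unit.
#' @export
classify_solo_pltrs <- function(locus, units, events = list(),
                                element_hits = NULL, near_gap = 20L) {
  n <- nrow(units)
  labels <- character(n)
  for (i in seq_len(n)) {
    u <- units[i, ]
    in_event <- FALSE
    for (e in events) {
      fr <- e$framing
      for (r in seq_len(nrow(fr))) {
        if (interval_overlap(u$start, u$end, fr$start[r], fr$end[r]) >=
            0.5 * (u$end - u$start)) in_event <- TRUE
      }
    }
    if (in_event) { labels[i] <- "capture_framing"; next }
    near_elem <- FALSE
    if (!is.null(element_hits) && nrow(element_hits)) {
      for (r in seq_len(nrow(element_hits))) {
        gap <- max(element_hits$start[r] - u$end, u$start - element_hits$end[r], 0L)
        if (interval_overlap(u$start, u$end, element_hits$start[r],
                             element_hits$end[r]) > 0L || gap <= near_gap)
          near_elem <- TRUE
      }
    }
    if (near_elem) { labels[i] <- "element_terminal"; next }
    lf <- subseq0(locus, max(0L, u$start - 60L), u$start)
    rf <- subseq0(locus, u$end, min(nchar(locus), u$end + 60L))
    tsd <- detect_tsd(lf, rf)
    labels[i] <- if (!is.null(tsd)) "solo_with_tsd" else "solo_bare"
  }
  labels
}

#' Anchored p-distance between two collinear sequences
#'
#' Shared k-mers define the dominant alignment diagonal; the p-distance is
#' the per-column mismatch fraction over the aligned span.  `NA` (with a
#' warning) when the sequences share no anchor.
#'
#' @param a,b DNA strings.
#' @param anchor_k anchor word size.
#' @return mismatch fraction in `[0, 1]`, or `NA_real_`.
#' @export
allelic_divergence <- function(a, b, anchor_k = 14L) {
  al <- anchor_align(toupper(a), toupper(b), k = anchor_k)
  if (is.null(al)) {
    warning("sequences share no anchor; divergence undefined")
    return(NA_real_)
  }
  al$mismatches / al$columns
}
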