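# Small-RNA mapping and sense/antisense polarity profiling along an
# element.  "Sense" is defined relative to the element ORF strand; a
# read's window is determined by its 5' position; multi-mappers contribute
# a fractional 1/n_hits weight at every position.

#' Map small-RNA reads to an element (both strands)
#'
#' Exact/near-exact ungapped placement of every read on the element and
#' its reverse complement, with at most `max_mismatch` mismatches.
#' Multi-mapping reads are reported at every hit with weight `1/n_hits`.
#'
#' @param reads character vector of read sequences, or a data frame with a
#'   `seq` column (such as from [forge_smallrna_library()]).
#' @param element element DNA string (ORF strand).
#' @param max_mismatch mismatch budget per alignment.
#' @return data frame: `read` (index), `pos` (0-based start on the
#'   element), `strand`, `length`, `weight`.
#' @export
map_reads <- function(reads, element, max_mismatch = 1L) {
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  element <- toupper(element)
  empty <- data.frame(read = integer(), pos = integer(), strand = character(),
                      length = integer(), weight = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(seqs)) return(empty)
  k <- 12L
  ev <- dna_chars(element)
  ne <- length(ev)
  idx <- kmer_index(element, k)
  # pigeonhole seeding: with <= 1 mismatch, the first or last k bases of a
  # placed read are exact; candidate offsets come from the k-mer index and
  # are verified base by base
  place <- function(s) {
    L <- nchar(s)
    cand <- integer(0)
    pre <- idx[[substr(s, 1L, k)]]
    if (!is.null(pre)) cand <- c(cand, pre)
    suf <- idx[[substr(s, L - k + 1L, L)]]
    if (!is.null(suf)) cand <- c(cand, suf - (L - k))
    cand <- unique(cand[cand >= 1L & cand + L - 1L <= ne])
    sv <- dna_chars(s)
    cand[vapply(cand, function(p)
      sum(sv != ev[p:(p + L - 1L)]) <= max_mismatch, logical(1))]
  }
  if (max_mismatch > 1L || any(nchar(seqs) < 2L * k)) {
    # exhaustive fallback for permissive budgets or very short reads
    place <- function(s) {
      L <- nchar(s)
      if (L > ne) return(integer(0))
      sv <- dna_chars(s)
      which(vapply(seq_len(ne - L + 1L), function(p)
        sum(sv != ev[p:(p + L - 1L)]) <= max_mismatch, logical(1)))
    }
  }
  uniq <- unique(seqs)
  rcs <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(uniq)))
  cache <- vector("list", length(uniq))
  names(cache) <- uniq
  for (ui in seq_along(uniq)) {
    pp <- place(uniq[ui])
    pm <- place(rcs[ui])
    cache[[ui]] <- if (length(pp) + length(pm))
      data.frame(pos = c(pp, pm) - 1L,
                 strand = c(rep("+", length(pp)), rep("-", length(pm))),
                 stringsAsFactors = FALSE) else NULL
  }
  hit_of <- cache[match(seqs, uniq)]
  nh <- vapply(hit_of, function(h) if (is.null(h)) 0L else nrow(h), integer(1))
  if (!sum(nh)) return(empty)
  keep <- which(nh > 0L)
  data.frame(
    read = rep(keep, nh[keep]),
    pos = unlist(lapply(hit_of[keep], `[[`, "pos"), use.names = FALSE),
    strand = unlist(lapply(hit_of[keep], `[[`, "strand"), use.names = FALSE),
    length = rep(nchar(seqs[keep]), nh[keep]),
    weight = rep(1 / nh[keep], nh[keep]),
    stringsAsFactors = FALSE)
}

#' Windowed sense/antisense polarity profile
#'
#' Weighted read counts are binned by 5' position (plus strand: alignment
#' start; minus strand: alignment end) into windows of `window` bp; the
#' polarity index per window is `(sense - antisense)/(sense + antisense)`,
#' undefined (`NA`) where a window holds no signal.
#'
#' @param alignments data frame from [map_reads()].
#' @param element_len element length, bp.
#' @param window window width, bp.
#' @return object of class `ple_smallrna_profile`: list with `window`,
#'   `window_start` (0-based), `sense`, `antisense`, `polarity`,
#'   `antisense_fraction` (overall, weighted).
#' @export
windowed_polarity <- function(alignments, element_len, window = 100L) {
  stopifnot(window >= 1L)
  nb <- max(1L, as.integer(ceiling(element_len / window)))
  sense <- numeric(nb); anti <- numeric(nb)
  if (nrow(alignments)) {
    p5 <- ifelse(alignments$strand == "+", alignments$pos,
                 alignments$pos + alignments$length - 1L)
    bin <- pmin(nb - 1L, p5 %/% window) + 1L
    for (i in seq_len(nrow(alignments))) {
      if (alignments$strand[i] == "+") sense[bin[i]] <- sense[bin[i]] + alignments$weight[i]
      else anti[bin[i]] <- anti[bin[i]] + alignments$weight[i]
    }
  }
  tot <- sense + anti
  pol <- ifelse(tot > 0, (sense - anti) / tot, NA_real_)
  structure(list(window = as.integer(window),
                 window_start = as.integer((seq_len(nb) - 1L) * window),
                 sense = sense, antisense = anti, polarity = pol,
                 antisense_fraction = if (sum(tot) > 0) sum(anti) / sum(tot) else NA_real_),
            class = "ple_smallrna_profile")
}

#' Detect polarity switches along a profile
#'
#' A switch is a boundary between two runs of opposite polarity sign, each
#' sustained for at least `min_run` defined windows.  Windows without
#' signal (or with polarity exactly 0) do not contribute to runs.
#'
#' @param profile a `ple_smallrna_profile`.
#' @param min_run minimum run length (windows) on each side.
#' @return integer vector of switch positions (bp: start of the first
#'   window of the new run).
#' @export
detect_polarity_switch <- function(profile, min_run = 3L) {
  def <- which(!is.na(profile$polarity) & profile$polarity != 0)
  if (length(def) < 2L * min_run) return(integer(0))
  sgn <- sign(profile$polarity[def])
  r <- rle(sgn)
  if (length(r$lengths) < 2L) return(integer(0))
  ends <- cumsum(r$lengths)
  switches <- integer(0)
  for (i in 1:(length(r$lengths) - 1L)) {
    if (r$lengths[i] >= min_run && r$lengths[i + 1L] >= min_run) {
      w <- def[ends[i] + 1L]          # first defined window of the new run
      switches <- c(switches, profile$window_start[w])
    }
  }
  switches
}

#' Read density in counts per kb
#'
#' @param read_count (weighted) read count.
#' @param element_len element length, bp (> 0).
#' @return `1000 * read_count / element_len`.
#' @export
expression_density <- function(read_count, element_len) {
  if (element_len <= 0) stop("element length must be positive")
  1000 * read_count / element_len
}
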