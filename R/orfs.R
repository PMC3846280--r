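# ORF discovery, defect classification against a family reference,
# catalytic-motif scans, and asparagine-rich insert detection.

#' Find ORFs in all six frames
#'
#' Reports every ATG-initiated, stop-terminated ORF of at least `min_aa`
#' residues on both strands.  `aa_len` excludes the stop; coordinates are
#' 0-based half-open on the input sequence and include the stop codon.
#'
#' @param seq DNA string.
#' @param min_aa minimum ORF length in residues.
#' @return data frame: `start,end,strand,frame,aa_len,protein`.
#' @export
find_orfs <- function(seq, min_aa = 300L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  rows <- list()
  for (strand in c("+", "-")) {
    w <- if (strand == "+") seq else revcomp(seq)
    for (f in 0:2) {
      sub <- substr(w, f + 1L, n)
      prot <- translate_dna(sub)
      pv <- strsplit(prot, "")[[1]]
      stops <- which(pv == "*")
      ms <- which(pv == "M")
      if (!length(stops) || !length(ms)) next
      for (m in ms) {
        nx <- stops[stops > m]
        if (!length(nx)) next
        stp <- nx[1]
        aa_len <- stp - m
        if (aa_len < min_aa) next
        a1 <- f + 3L * (m - 1L) + 1L      # 1-based nt on working strand
        b1 <- f + 3L * stp                 # last nt of stop codon
        if (strand == "+") {
          s0 <- a1 - 1L; e0 <- b1
        } else {
          s0 <- n - b1; e0 <- n - a1 + 1L
        }
        rows[[length(rows) + 1L]] <- data.frame(
          start = s0, end = e0, strand = strand, frame = f,
          aa_len = aa_len,
          protein = paste(pv[m:(stp - 1L)], collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(), strand = character(),
                      frame = integer(), aa_len = integer(),
                      protein = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---- defect classification ---------------------------------------------

# exact 8-aa word matches between a frame translation and the reference,
# extended ungapped to maximal exact blocks
match_blocks <- function(prot, ref, word = 8L) {
  np <- nchar(prot); nr <- nchar(ref)
  if (np < word || nr < word) return(NULL)
  ref_words <- substring(ref, 1:(nr - word + 1L), word:nr)
  idx <- split(seq_len(nr - word + 1L), ref_words)
  pw <- substring(prot, 1:(np - word + 1L), word:np)
  hit <- which(pw %in% names(idx))
  if (!length(hit)) return(NULL)
  pv <- strsplit(prot, "")[[1]]
  rv <- strsplit(ref, "")[[1]]
  blocks <- list()
  seen <- character()
  for (i in hit) {
    for (r in idx[[pw[i]]]) {
      d <- r - i
      # extend
      a <- i; b <- i + word - 1L
      while (a > 1L && a + d > 1L && pv[a - 1L] == rv[a + d - 1L]) a <- a - 1L
      while (b < np && b + d < nr && pv[b + 1L] == rv[b + d + 1L]) b <- b + 1L
      key <- paste(a, d, sep = ":")
      if (key %in% seen) next
      seen <- c(seen, key)
      blocks[[length(blocks) + 1L]] <-
        data.frame(prot_start = a, prot_end = b, ref_start = a + d,
                   ref_end = b + d, len = b - a + 1L)
    }
  }
  do.call(rbind, blocks)
}

#' Classify ORF defects of an element copy against a family reference
#'
#' The copy is translated in three plus-strand frames and tiled against the
#' reference protein by exact 8-aa seed words extended ungapped.  Chained
#' blocks are interpreted as: a frame switch between adjacent blocks is a
#' frameshift; a same-frame gap of unchanged length containing a stop is a
#' premature stop; a shortened gap is a deletion, called
#' microhomology-mediated (with its length) when `reference_dna` is
#' supplied and the maximal exact cross-junction extensions overlap by at
#' least 2 bp; a lengthened gap is an insertion; a missing reference prefix
#' or suffix of at least 30 aa is a 5'/3' truncation.
#'
#' @param copy element copy DNA.
#' @param reference_protein full-length family reference protein.
#' @param reference_dna optional reference coding DNA (frame 0 of
#'   `reference_protein`); enables microhomology measurement.
#' @param word seed word size in aa.
#' @param trunc_min minimum missing terminal stretch called a truncation, aa.
#' @return data frame: `kind,position,evidence` (position on the reference,
#'   0-based aa).
#' @export
classify_defects <- function(copy, reference_protein, reference_dna = NULL,
                             word = 8L, trunc_min = 30L) {
  copy <- toupper(copy)
  nref <- nchar(reference_protein)
  all_blocks <- list()
  prots <- character(3)
  for (f in 0:2) {
    prots[f + 1L] <- translate_dna(substr(copy, f + 1L, nchar(copy)))
    b <- match_blocks(prots[f + 1L], reference_protein, word)
    if (!is.null(b) && nrow(b)) { b$frame <- f; all_blocks[[length(all_blocks) + 1L]] <- b }
  }
  def <- function(kind, pos, evidence, mh = NA_integer_) data.frame(kind = kind,
    position = as.integer(pos), evidence = evidence,
    microhomology_len = as.integer(mh), stringsAsFactors = FALSE)
  if (!length(all_blocks)) {
    return(rbind(def("trunc5", 0L, "no part of the reference recognized"),
                 def("trunc3", nref - 1L, "no part of the reference recognized")))
  }
  bl <- do.call(rbind, all_blocks)
  # greedy chain: longest blocks first, drop heavy reference overlaps
  bl <- bl[order(-bl$len, bl$ref_start), , drop = FALSE]
  keep <- list()
  for (i in seq_len(nrow(bl))) {
    ok <- TRUE
    for (k in keep) {
      ov <- interval_overlap(bl$ref_start[i], bl$ref_end[i] + 1L,
                             k$ref_start, k$ref_end + 1L)
      if (ov > 0.5 * min(bl$len[i], k$len)) { ok <- FALSE; break }
    }
    if (ok) keep[[length(keep) + 1L]] <- bl[i, ]
  }
  ch <- do.call(rbind, keep)
  ch <- ch[order(ch$ref_start), , drop = FALSE]
  out <- list()
  if (ch$ref_start[1] - 1L >= trunc_min)
    out[[length(out) + 1L]] <- def("trunc5", 0L,
      sprintf("first %d reference aa unmatched", ch$ref_start[1] - 1L))
  if (nref - ch$ref_end[nrow(ch)] >= trunc_min)
    out[[length(out) + 1L]] <- def("trunc3", nref - 1L,
      sprintf("last %d reference aa unmatched", nref - ch$ref_end[nrow(ch)]))
  if (nrow(ch) > 1L) {
    for (i in 1:(nrow(ch) - 1L)) {
      L <- ch[i, ]; R <- ch[i + 1L, ]
      ref_gap <- R$ref_start - L$ref_end - 1L
      prot_gap <- R$prot_start - L$prot_end - 1L
      at <- L$ref_end   # 0-based aa position right after the left block
      if (L$frame != R$frame) {
        out[[length(out) + 1L]] <- def("frameshift", at,
          sprintf("reading frame switches %d->%d", L$frame, R$frame))
        next
      }
      if (ref_gap == prot_gap) {
        gapseq <- if (prot_gap > 0)
          substr(prots[L$frame + 1L], L$prot_end + 1L, R$prot_start - 1L) else ""
        if (grepl("*", gapseq, fixed = TRUE))
          out[[length(out) + 1L]] <- def("premature_stop", at,
            "in-frame stop within a matched frame")
        next
      }
      if (prot_gap < ref_gap) {
        mh <- 0L
        if (!is.null(reference_dna)) {
          mh <- junction_microhomology(copy, toupper(reference_dna),
                                       L, R)
        }
        if (mh >= 2L) {
          out[[length(out) + 1L]] <- def("microhomology_deletion", at,
            sprintf("deletion of %d aa with %d-bp breakpoint microhomology",
                    ref_gap - prot_gap, mh), mh = mh)
        } else {
          out[[length(out) + 1L]] <- def("indel", at,
            sprintf("deletion of %d aa", ref_gap - prot_gap))
        }
      } else {
        out[[length(out) + 1L]] <- def("indel", at,
          sprintf("insertion of %d aa", prot_gap - ref_gap))
      }
    }
  }
  if (!length(out)) {
    return(data.frame(kind = character(), position = integer(),
                      evidence = character(),
                      microhomology_len = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Overlap (bp) of the maximal exact cross-junction extensions around a
# deletion between two chained blocks; >= 2 is diagnostic of
# microhomology-mediated annealing.  Extensions are anchored a few codons
# inside each block (amino-acid blocks can overrun the DNA junction through
# synonymous codons) and measured base by base on the DNA.
junction_microhomology <- function(copy, refdna, L, R, inset = 5L) {
  cv <- dna_chars(copy); rv <- dna_chars(refdna)
  ins_l <- min(inset, L$prot_end - L$prot_start)
  ce <- L$frame + 3L * (L$prot_end - ins_l)        # 0-based, inside left block
  re <- 3L * (L$ref_end - ins_l)
  fwd <- 0L
  while (ce + fwd < length(cv) && re + fwd < length(rv) &&
         cv[ce + fwd + 1L] == rv[re + fwd + 1L]) fwd <- fwd + 1L
  p1 <- ce + fwd                                   # exclusive end of left match
  ins_r <- min(inset, R$prot_end - R$prot_start)
  cs <- R$frame + 3L * (R$prot_start - 1L + ins_r) # 0-based, inside right block
  rs <- 3L * (R$ref_start - 1L + ins_r)
  bwd <- 0L
  while (cs - bwd > 0L && rs - bwd > 0L &&
         cv[cs - bwd] == rv[rs - bwd]) bwd <- bwd + 1L
  p2 <- cs - bwd                                   # inclusive start of right match
  max(0L, p1 - p2)
}

## ---- motif scans --------------------------------------------------------

#' Locate the GIY-YIG endonuclease motif pair
#'
#' First occurrence of literal `GIY` followed by `YIG` at an 8-12 aa gap.
#'
#' @param protein amino-acid string.
#' @return `NULL`, or list with `giy_pos`, `yig_pos`, `gap` (0-based aa).
#' @export
scan_giy_yig <- function(protein) {
  m <- regexpr("GIY.{8,12}?YIG", protein, perl = TRUE)
  if (m == -1L) return(NULL)
  giy <- as.integer(m) - 1L
  yig <- giy + attr(m, "match.length") - 3L
  list(giy_pos = giy, yig_pos = yig, gap = yig - giy - 3L)
}

#' Scan for the PLE cysteine-rich insert motif
#'
#' All matches of `[Cys/His]-X(1,3)-Cys-X(10)-Cys-X(2)-Cys`, overlapping
#' occurrences included.
#'
#' @param protein amino-acid string.
#' @return integer vector of 0-based match start positions.
#' @export
scan_cys_motif <- function(protein) {
  hits <- gregexpr("(?=[CH].{1,3}C.{10}C.{2}C)", protein, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L
}

## ---- compositional scans ------------------------------------------------

#' Detect asparagine-rich segments in a protein
#'
#' Sliding windows with Asn fraction at or above `threshold` are merged
#' into maximal covered segments; segments of at least `min_len` residues
#' are reported with their exact Asn fraction.
#'
#' @param protein amino-acid string.
#' @param window window width, aa.
#' @param threshold minimum per-window Asn fraction.
#' @param min_len minimum reported segment length, aa.
#' @return data frame: `start,end,length_aa,asn_fraction` (0-based aa).
#' @export
detect_n_rich <- function(protein, window = 50L, threshold = 0.25,
                          min_len = 100L) {
  v <- strsplit(protein, "")[[1]]
  n <- length(v)
  emptyres <- data.frame(start = integer(), end = integer(),
                         length_aa = integer(), asn_fraction = numeric())
  if (n < window) return(emptyres)
  asn <- as.integer(v == "N")
  cs <- cumsum(c(0L, asn))
  frac <- (cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]) / window
  qual <- frac >= threshold
  if (!any(qual)) return(emptyres)
  covered <- logical(n)
  for (i in which(qual)) covered[i:(i + window - 1L)] <- TRUE
  # bridge sub-window dips: a gap shorter than the window does not split a
  # segment, provided both of its neighbours are at least a window long
  # (so short chance windows outside a segment are not annexed)
  r0 <- rle(covered)
  e0 <- cumsum(r0$lengths); s0 <- e0 - r0$lengths + 1L
  for (g in which(!r0$values & r0$lengths < window)) {
    if (g > 1L && g < length(r0$lengths) &&
        r0$lengths[g - 1L] >= window && r0$lengths[g + 1L] >= window)
      covered[s0[g]:e0[g]] <- TRUE
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  segs <- which(r$values & r$lengths >= min_len)
  if (!length(segs)) return(emptyres)
  out <- data.frame(start = starts[segs] - 1L, end = ends[segs],
                    length_aa = r$lengths[segs],
                    asn_fraction = vapply(segs, function(k) {
                      (cs[ends[k] + 1L] - cs[starts[k]]) / r$lengths[k]
                    }, numeric(1)))
  rownames(out) <- NULL
  out
}

#' Codon-frame (AAY)n density along an ORF
#'
#' Fraction of codons in `{AAT, AAC}` per sliding window of `window`
#' codons, in the reading frame of the input.  Trailing bases that do not
#' fill a codon are ignored and flagged.
#'
#' @param dna in-frame ORF DNA.
#' @param window window width in codons.
#' @return list with `profile` (data frame `codon_start` 0-based,
#'   `fraction`), `peak` (0-based codon index of the maximum),
#'   `trailing_ignored` (bases dropped).
#' @export
detect_aay_bias <- function(dna, window = 20L) {
  dna <- toupper(dna)
  nc <- nchar(dna) %/% 3L
  trailing <- nchar(dna) - 3L * nc
  codons <- substring(dna, 3L * (seq_len(nc) - 1L) + 1L, 3L * seq_len(nc))
  ind <- as.integer(codons %in% c("AAT", "AAC"))
  if (nc < window) {
    return(list(profile = data.frame(codon_start = integer(),
                                     fraction = numeric()),
                peak = NA_integer_, trailing_ignored = trailing))
  }
  cs <- cumsum(c(0L, ind))
  frac <- (cs[(window + 1L):(nc + 1L)] - cs[1:(nc - window + 1L)]) / window
  prof <- data.frame(codon_start = 0:(nc - window), fraction = frac)
  list(profile = prof, peak = prof$codon_start[which.max(frac)],
       trailing_ignored = trailing)
}
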