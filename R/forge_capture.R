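# Synthetic gene-capture loci and allelic locus pairs.
#
# A capture locus models trans-mobilization of a host gene cassette: the
# cassette (exons with GT..AG introns) sits between two direct pLTR copies,
# an inverted pLTR completes the 5' end, and the whole structure is flanked
# by identical TSD copies.  The paired "empty site" allele carries the TSD
# motif exactly once at the junction.

#' Forge a pLTR-framed gene-capture locus
#'
#' @param cassette_exons character vector of exon DNA strings (>= 1).
#' @param intron_lens integer vector of intron lengths; must be one shorter
#'   than `cassette_exons`.  Introns are random with canonical `GT`..`AG`
#'   termini.
#' @param pltr pLTR DNA string used for all three framing copies.
#' @param tsd_len TSD length, bp (0 = none).
#' @param tsd_motif optional explicit TSD string (length `tsd_len`).
#' @param flank_len host flank length on each side.
#' @param seed integer seed.
#' @return list with `sequence` and `truth` (features + params, 0-based).
#' @export
forge_capture_locus <- function(cassette_exons, intron_lens = integer(),
                                pltr, tsd_len = 8L, tsd_motif = NULL,
                                flank_len = 300L, seed = 1L) {
  if (!length(cassette_exons) || any(!nzchar(cassette_exons)))
    stop("empty cassette: at least one non-empty exon is required")
  if (length(intron_lens) != length(cassette_exons) - 1L)
    stop("intron count must be exon count - 1")
  if (!is.null(tsd_motif) && nchar(tsd_motif) != tsd_len)
    stop("tsd_motif length must equal tsd_len")
  with_seed(seed, {
    built <- build_capture_unit(cassette_exons, intron_lens, pltr)
    tsd <- if (tsd_len > 0) {
      if (!is.null(tsd_motif)) toupper(tsd_motif) else random_dna(tsd_len)
    } else ""
    flankL <- random_dna(flank_len)
    flankR <- random_dna(flank_len)
    seqn <- paste0(flankL, tsd, built$unit, tsd, flankR)
    off <- nchar(flankL) + nchar(tsd)
    feats <- built$features
    feats$start <- feats$start + off
    feats$end <- feats$end + off
    if (tsd_len > 0) {
      feats <- rbind(feats,
        feature_row("tsd", nchar(flankL), nchar(flankL) + tsd_len, name = tsd),
        feature_row("tsd", off + nchar(built$unit),
                    off + nchar(built$unit) + tsd_len, name = tsd))
    }
    params <- list(tsd_len = tsd_len, tsd_motif = if (tsd_len > 0) tsd else NULL,
                   pltr_len = nchar(pltr), pltr_seq = toupper(pltr),
                   unit_interval = c(off, off + nchar(built$unit)),
                   cassette_interval = built$cassette + off)
    list(sequence = seqn, truth = list(features = feats, params = params))
  })
}

# [inverted pLTR][direct pLTR][cassette][direct pLTR]; coordinates relative
# to the unit start
build_capture_unit <- function(cassette_exons, intron_lens, pltr) {
  pltr <- toupper(pltr)
  L <- nchar(pltr)
  pieces <- character(0)
  feats <- empty_features()
  pos <- 0L
  cass <- character(0)
  for (i in seq_along(cassette_exons)) {
    cass <- c(cass, toupper(cassette_exons[i]))
    if (i <= length(intron_lens)) {
      il <- intron_lens[i]
      if (il < 4L) stop("introns need at least 4 bp (GT..AG)")
      cass <- c(cass, paste0("GT", random_dna(il - 4L), "AG"))
    }
  }
  cassette <- paste(cass, collapse = "")
  unit <- paste0(revcomp(pltr), pltr, cassette, pltr)
  feats <- rbind(feats,
    feature_row("pltr", 0L, L, "-", "inverted"),
    feature_row("pltr", L, 2L * L, "+", "direct"),
    feature_row("cassette", 2L * L, 2L * L + nchar(cassette)),
    feature_row("pltr", 2L * L + nchar(cassette), 3L * L + nchar(cassette),
                "+", "direct"))
  # exon/intron sub-features
  at <- 2L * L
  for (i in seq_along(cass)) {
    type <- if (i %% 2L == 1L) "exon" else "intron"
    feats <- rbind(feats, feature_row(type, at, at + nchar(cass[i])))
    at <- at + nchar(cass[i])
  }
  list(unit = unit, features = feats,
       cassette = c(2L * L, 2L * L + nchar(cassette)))
}

#' Forge an allelic pair (insertion allele and diverged partner)
#'
#' `allele_B` is derived from the backbone by per-site substitution at rate
#' `divergence` (no indels).  When `insertion` is supplied, `allele_A`
#' carries `insertion$sequence` at `insertion$position` with the target
#' motif duplicated on both sides, while `allele_B` keeps exactly one copy
#' of the motif at the junction; the motif site itself is exempt from
#' substitution so the empty-site diagnostic stays well defined.
#'
#' @param sequence backbone DNA (the empty locus).
#' @param divergence per-site substitution rate in `[0, 0.25]`.
#' @param insertion optional list with `sequence`, `position` (0-based
#'   offset into the backbone) and `tsd_motif`.
#' @param seed integer seed.
#' @return list with `allele_A`, `allele_B`, and `truth` (junction position,
#'   realized divergence, substituted sites).
#' @export
forge_allelic_pair <- function(sequence, divergence, insertion = NULL,
                               seed = 1L) {
  if (divergence < 0 || divergence > 0.25)
    stop("divergence must lie in [0, 0.25]")
  sequence <- toupper(sequence)
  with_seed(seed, {
    v <- dna_chars(sequence)
    protect <- integer()
    allele_A <- sequence
    junction <- NULL
    if (!is.null(insertion)) {
      pos <- insertion$position
      motif <- toupper(insertion$tsd_motif %||% "")
      m <- nchar(motif)
      if (pos < 0 || pos + m > length(v)) stop("insertion position outside backbone")
      if (m > 0) {
        v <- replace0(v, pos, dna_chars(motif))   # backbone carries the site once
        protect <- (pos + 1L):(pos + m)
      }
      allele_A <- paste0(chars_dna(v[seq_len(pos + m)]),
                         toupper(insertion$sequence),
                         motif,
                         if (pos + m < length(v)) chars_dna(v[(pos + m + 1L):length(v)]) else "")
      junction <- pos
    }
    b <- mutate_chars(v, divergence, protect = protect)
    nsub <- sum(b != v)
    list(allele_A = allele_A, allele_B = chars_dna(b),
         truth = list(junction = junction,
                      tsd_motif = if (!is.null(insertion)) toupper(insertion$tsd_motif) else NULL,
                      divergence_target = divergence,
                      divergence_realized = nsub / length(v),
                      n_substitutions = nsub))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Forge a complete capture/empty-site allelic scene
#'
#' Builds an empty backbone with two host gene placeholders and a single
#' copy of the target motif at the junction, then produces the insertion
#' allele (inverted + direct + cassette + direct pLTR unit, motif duplicated)
#' and the diverged empty-site allele.
#'
#' @param pltr pLTR string for the framing copies.
#' @param cassette_exons,intron_lens cassette description as in
#'   [forge_capture_locus()].
#' @param tsd_motif target motif duplicated on insertion.
#' @param divergence allelic divergence rate.
#' @param flank_len backbone length on each side of the junction.
#' @param seed integer seed.
#' @return list with `allele_A` (insertion), `allele_B` (empty site) and
#'   `truth`.
#' @export
forge_capture_pair <- function(pltr, cassette_exons, intron_lens = integer(),
                               tsd_motif = "GAATTAAT", divergence = 0.02,
                               flank_len = 1200L, seed = 1L) {
  with_seed(seed, {
    backbone <- paste0(random_dna(flank_len), tsd_motif, random_dna(flank_len))
    unit <- build_capture_unit(cassette_exons, intron_lens, pltr)$unit
    pair <- forge_allelic_pair(backbone, divergence,
                               insertion = list(sequence = unit,
                                                position = flank_len,
                                                tsd_motif = tsd_motif),
                               seed = seed + 7919L)
    pair$truth$pltr_seq <- toupper(pltr)
    pair$truth$unit_len <- nchar(unit)
    pair
  })
}
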