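# Blueprint objects consumed by the synthetic-locus generator.  Defaults
# follow the canonical Pen2a-style single-copy element: a 218-bp pLTR in a
# direct/direct + 5'-inverted arrangement, a 15-bp overlap between the 5'
# inverted unit and the adjacent direct unit, a 37-bp truncation of the
# inverted unit, an optional 31-bp tail, a 9-bp TSD and an 842-aa ORF whose
# first 12 codons lie inside the pLTR.

ARRANGEMENTS <- c("DD_plus_inverted5p", "DD_only", "inverted_pair",
                  "solo", "tandem_partial")
DEFECT_KINDS <- c("frameshift", "stop", "trunc5", "trunc3", "indel",
                  "microhomology_deletion")
INSERT_POSITIONS <- c("RT_EN_linker", "RT_thumb_linker")

#' Blueprint for a synthetic PLE insertion locus
#'
#' @param seed integer seed driving every random draw for this locus.
#' @param flank_len host flank length on each side, bp.
#' @param pltr_len full pseudo-LTR unit length, bp.
#' @param pltr_identity identity of the 3' pLTR copy to the 5' copy; values
#'   below 1 apply random substitutions to the 3' copy.
#' @param arrangement one of `"DD_plus_inverted5p"`, `"DD_only"`,
#'   `"inverted_pair"`, `"solo"`, `"tandem_partial"`.
#' @param overlap_5p overlap (bp) between the 5' inverted unit and the
#'   adjacent direct unit (DD_plus_inverted5p only).
#' @param trunc_5p_inverted truncation (bp) of the 5' inverted unit relative
#'   to the full pLTR.
#' @param tail_len optional 3' tail extension of the inverted unit, bp
#'   (0 = absent).
#' @param tsd_len target-site-duplication length, bp (0 = none).
#' @param tsd_motif optional explicit TSD string; length must equal
#'   `tsd_len`.
#' @param orf_aa core ORF length in amino acids (start codon included,
#'   stop excluded).
#' @param insert optional [insert_spec()] describing an in-frame N-rich
#'   insert.
#' @param defects list of [defect_spec()] applied to the ORF.
#' @param palindrome_len planted terminal palindrome length for arrangements
#'   without a 5' overlap (the overlap region itself is a near-palindromic
#'   terminus when present).
#' @param palindrome_mismatches internal arm mismatches planted into the
#'   terminal palindrome.
#' @param promoter optional [promoter_spec()] planted inside the pLTR.
#' @param spacer_len unique spacer (bp) between the ORF end and the 3' pLTR
#'   (Pen1-style, typically 900-1500; 0 = none).
#' @param at_fraction A+T fraction of background sequence (0.5 = uniform).
#' @return an object of class `ple_locus_spec`.
#' @export
locus_spec <- function(seed = 1L,
                       flank_len = 300L,
                       pltr_len = 218L,
                       pltr_identity = 1.0,
                       arrangement = "DD_plus_inverted5p",
                       overlap_5p = 15L,
                       trunc_5p_inverted = 37L,
                       tail_len = 31L,
                       tsd_len = 9L,
                       tsd_motif = NULL,
                       orf_aa = 842L,
                       insert = NULL,
                       defects = list(),
                       palindrome_len = 0L,
                       palindrome_mismatches = 0L,
                       promoter = NULL,
                       spacer_len = 0L,
                       at_fraction = 0.5) {
  arrangement <- match.arg(arrangement, ARRANGEMENTS)
  spec <- list(seed = as.integer(seed), flank_len = as.integer(flank_len),
               pltr_len = as.integer(pltr_len), pltr_identity = pltr_identity,
               arrangement = arrangement, overlap_5p = as.integer(overlap_5p),
               trunc_5p_inverted = as.integer(trunc_5p_inverted),
               tail_len = as.integer(tail_len), tsd_len = as.integer(tsd_len),
               tsd_motif = if (is.null(tsd_motif)) NULL else toupper(tsd_motif),
               orf_aa = as.integer(orf_aa), insert = insert, defects = defects,
               palindrome_len = as.integer(palindrome_len),
               palindrome_mismatches = as.integer(palindrome_mismatches),
               promoter = promoter, spacer_len = as.integer(spacer_len),
               at_fraction = at_fraction)
  class(spec) <- "ple_locus_spec"
  validate_locus_spec(spec)
  spec
}

validate_locus_spec <- function(spec) {
  fail <- function(field, msg) {
    stop(sprintf("invalid locus spec: field '%s' %s", field, msg), call. = FALSE)
  }
  if (spec$pltr_len <= spec$tail_len || spec$tail_len < 0)
    fail("tail_len", "must satisfy pltr_len > tail_len >= 0")
  if (spec$overlap_5p >= spec$pltr_len)
    fail("overlap_5p", "must be smaller than pltr_len")
  if (spec$tsd_len < 0 || spec$tsd_len > 25)
    fail("tsd_len", "must lie in [0, 25]")
  if (!is.null(spec$tsd_motif) && nchar(spec$tsd_motif) != spec$tsd_len)
    fail("tsd_motif", "length must equal tsd_len")
  if (spec$orf_aa < 1)
    fail("orf_aa", "must be >= 1")
  if (spec$trunc_5p_inverted < 0 || spec$trunc_5p_inverted >= spec$pltr_len)
    fail("trunc_5p_inverted", "must lie in [0, pltr_len)")
  if (spec$spacer_len < 0)
    fail("spacer_len", "must be >= 0")
  if (!is.null(spec$insert) && !inherits(spec$insert, "ple_insert_spec"))
    fail("insert", "must be an insert_spec()")
  for (d in spec$defects)
    if (!inherits(d, "ple_defect_spec")) fail("defects", "entries must be defect_spec()")
  invisible(spec)
}

#' Blueprint for an in-frame asparagine-rich ORF insert
#'
#' @param aa_len insert length in amino acids (paper-scale inserts are
#'   460-554 aa, or 467 aa for the N1 type).
#' @param asn_fraction target asparagine fraction (typically 0.25-0.30).
#' @param position `"RT_EN_linker"` or `"RT_thumb_linker"`.
#' @param in_frame if `FALSE` one extra base is inserted, breaking the frame.
#' @return object of class `ple_insert_spec`.
#' @export
insert_spec <- function(aa_len = 467L, asn_fraction = 0.30,
                        position = "RT_EN_linker", in_frame = TRUE) {
  position <- match.arg(position, INSERT_POSITIONS)
  if (aa_len < 1) stop("invalid insert spec: field 'aa_len' must be >= 1")
  if (asn_fraction < 0 || asn_fraction > 1)
    stop("invalid insert spec: field 'asn_fraction' must lie in [0, 1]")
  structure(list(aa_len = as.integer(aa_len), asn_fraction = asn_fraction,
                 position = position, in_frame = isTRUE(in_frame)),
            class = "ple_insert_spec")
}

#' Blueprint for an ORF defect
#'
#' Positions are interpreted per kind: `stop` and `frameshift` take a 1-based
#' codon index; `indel` and `microhomology_deletion` take a 0-based bp offset
#' into the ORF DNA (codon-aligned offsets recommended); `trunc5`/`trunc3`
#' remove `size` bp from the respective end.
#'
#' @param kind defect kind.
#' @param position codon index or bp offset (see above).
#' @param size bp removed/inserted for indel/deletion/truncation kinds;
#'   negative `size` for `indel` means a deletion.
#' @param microhomology_len planted breakpoint microhomology (>= 2) for
#'   `microhomology_deletion`.
#' @return object of class `ple_defect_spec`.
#' @export
defect_spec <- function(kind, position = 0L, size = 0L, microhomology_len = 0L) {
  kind <- match.arg(kind, DEFECT_KINDS)
  if (kind == "microhomology_deletion" && microhomology_len < 2)
    stop("invalid defect spec: field 'microhomology_len' must be >= 2")
  structure(list(kind = kind, position = as.integer(position),
                 size = as.integer(size),
                 microhomology_len = as.integer(microhomology_len)),
            class = "ple_defect_spec")
}

#' Blueprint for a pLTR-internal core promoter
#'
#' The default motifs follow the bidirectional pLTR promoter arrangement:
#' a TATA box (`TATATATA`, itself reverse-complement symmetric) separated by
#' `spacing` bp from a forward initiator-like `TCACT`; when `bidirectional`,
#' an opposite-strand initiator `ACATT` is additionally planted downstream of
#' the TATA box in minus-strand orientation.
#'
#' @param tata_motif TATA-box string.
#' @param inr_motif forward-strand initiator string.
#' @param spacing bp between TATA end and initiator start.
#' @param bidirectional also plant the opposite-strand initiator `ACATT`.
#' @return object of class `ple_promoter_spec`.
#' @export
promoter_spec <- function(tata_motif = "TATATATA", inr_motif = "TCACT",
                          spacing = 20L, bidirectional = FALSE) {
  if (spacing < 0) stop("invalid promoter spec: field 'spacing' must be >= 0")
  if (!nzchar(tata_motif) || !nzchar(inr_motif))
    stop("invalid promoter spec: motifs must be non-empty")
  structure(list(tata_motif = toupper(tata_motif),
                 inr_motif = toupper(inr_motif),
                 spacing = as.integer(spacing),
                 bidirectional = isTRUE(bidirectional)),
            class = "ple_promoter_spec")
}

#' Blueprint for a synthetic small-RNA library
#'
#' Defaults emulate an Argonaute/Piwi-bound piRNA-like fraction: 25-32 nt
#' reads with a strong 5'-uridine bias.
#'
#' @param n_reads number of reads.
#' @param len_range integer vector `c(min, max)` read length, nt; must lie
#'   within `[15, 50]`.
#' @param antisense_fraction fraction of reads drawn from the reverse
#'   complement of the element.
#' @param u5_bias fraction of reads whose 5' base is forced to U (T in DNA
#'   space).
#' @param source_interval optional 0-based half-open interval restricting
#'   read origins (segment-restricted transcription).
#' @param seed integer seed.
#' @return object of class `ple_smallrna_spec`.
#' @export
smallrna_spec <- function(n_reads = 10000L, len_range = c(25L, 32L),
                          antisense_fraction = 0.9, u5_bias = 0.8,
                          source_interval = NULL, seed = 1L) {
  if (antisense_fraction < 0 || antisense_fraction > 1)
    stop("invalid small-RNA spec: field 'antisense_fraction' must lie in [0, 1]")
  if (u5_bias < 0 || u5_bias > 1)
    stop("invalid small-RNA spec: field 'u5_bias' must lie in [0, 1]")
  if (len_range[1] < 15 || len_range[2] > 50 || len_range[1] > len_range[2])
    stop("invalid small-RNA spec: field 'len_range' must lie within [15, 50]")
  structure(list(n_reads = as.integer(n_reads),
                 len_range = as.integer(len_range),
                 antisense_fraction = antisense_fraction,
                 u5_bias = u5_bias, source_interval = source_interval,
                 seed = as.integer(seed)),
            class = "ple_smallrna_spec")
}
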