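# End-to-end per-locus annotation: repeats -> arrangement -> tail ->
# element span -> TSD -> ORFs -> compositional and motif scans ->
# capture events.

# build a unit table directly from library hits (used when a locus holds a
# single unit that self-comparison cannot reveal, e.g. a solo pLTR)
units_from_hits <- function(hits) {
  if (!nrow(hits)) return(data.frame())
  ud <- data.frame(start = hits$start, end = hits$end,
                   unit_len = hits$end - hits$start,
                   orientation = ifelse(hits$strand == "+", "direct", "inverted"),
                   stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(ud))
  for (i in seq_len(nrow(ud))) for (j in seq_len(nrow(ud))) {
    if (i != j && keep[i] && keep[j] &&
        interval_overlap(ud$start[i], ud$end[i], ud$start[j], ud$end[j]) >=
          0.5 * min(ud$unit_len[i], ud$unit_len[j]) &&
        ud$unit_len[i] <= ud$unit_len[j] && i > j) keep[i] <- FALSE
  }
  ud <- ud[keep, , drop = FALSE]
  ud[order(ud$start), , drop = FALSE]
}

#' Annotate a PLE locus end to end
#'
#' Runs the full structural annotation: terminal-repeat detection and
#' arrangement resolution (self-comparison, supplemented by pLTR library
#' hits when a library is given), tail measurement, TSD inference from the
#' flanks outside the element span, ORF discovery with motif and
#' N-rich-segment scans, palindrome and promoter scans inside the resolved
#' units, and capture-event detection when both libraries are supplied.
#'
#' @param locus locus DNA string.
#' @param pltr_library optional character vector of pLTR sequences.
#' @param orf_library optional character vector of element ORF DNA.
#' @param config configuration list, see [default_config()].
#' @param id locus identifier used in reports.
#' @return object of class `ple_annotation`: a list with `pltr`
#'   (arrangement annotation), `tail_len`, `element_span`, `tsd`, `orfs`,
#'   `n_rich`, `palindromes`, `promoters`, `capture`, and a GFF3-ready
#'   `features` table.
#' @export
annotate_locus <- function(locus, pltr_library = NULL, orf_library = NULL,
                           config = default_config(), id = "locus") {
  locus <- toupper(locus)
  n <- nchar(locus)
  cfg <- config
  pairs <- find_terminal_repeats(locus, min_unit = cfg$repeats$min_unit,
                                 min_identity = cfg$repeats$min_identity,
                                 k = cfg$repeats$k, xdrop = cfg$repeats$xdrop)
  orfs <- find_orfs(locus, min_aa = cfg$orf$min_aa)
  main_orf <- if (nrow(orfs)) orfs[which.max(orfs$aa_len), ] else NULL
  ann <- resolve_arrangement(pairs,
                             orf_strand = if (!is.null(main_orf)) main_orf$strand else "+",
                             orf_interval = if (!is.null(main_orf)) c(main_orf$start, main_orf$end))
  hits <- NULL
  if (!is.null(pltr_library)) {
    hits <- find_pltr_hits(locus, pltr_library,
                           min_identity = cfg$capture$min_identity)
    if (!nrow(ann$units) && nrow(hits)) {
      ud <- units_from_hits(hits)
      ann$units <- ud
      ann$arrangement <- if (nrow(ud) == 1L) "solo" else ann$arrangement
    }
  }

  tail_len <- 0L
  if (nrow(ann$units) > 1L) {
    inv <- which(ann$units$orientation == "inverted")
    for (i in inv) {
      tl <- detect_tail(ann$units[i, ], locus, ann$units[-i, , drop = FALSE])
      tail_len <- max(tail_len, tl)
    }
  }

  span <- NULL; tsd <- NULL
  if (nrow(ann$units)) {
    span <- c(min(ann$units$start), max(ann$units$end))
    if (tail_len > 0L) {
      # the tail extends the element span on the side of the inverted unit
      inv <- ann$units[ann$units$orientation == "inverted", , drop = FALSE]
      if (nrow(inv) && inv$start[1] == span[1]) span[1] <- span[1] - tail_len
      else span[2] <- span[2] + tail_len
    }
    fp <- cfg$tsd$flank_probe
    lf <- subseq0(locus, max(0L, span[1] - fp), span[1])
    rf <- subseq0(locus, span[2], min(n, span[2] + fp))
    tsd <- detect_tsd(lf, rf, min_len = cfg$tsd$min_len,
                      max_len = cfg$tsd$max_len,
                      max_mismatch = cfg$tsd$max_mismatch)
  }

  pal <- list(); prom <- list()
  if (nrow(ann$units)) {
    for (i in seq_len(nrow(ann$units))) {
      u <- ann$units[i, ]
      us <- subseq0(locus, u$start, u$end)
      if (u$orientation == "inverted") us <- revcomp(us)
      pal[[i]] <- find_palindromes(us, min_len = cfg$palindrome$min_len,
                                   max_mismatch = cfg$palindrome$max_mismatch,
                                   max_spacer = cfg$palindrome$max_spacer)
      prom[[i]] <- scan_promoter(us,
                                 promoter_spec(tata_motif = cfg$promoter$tata_motif,
                                               inr_motif = cfg$promoter$inr_motif),
                                 max_spacing = cfg$promoter$max_spacing)
    }
  }

  n_rich <- NULL
  motifs <- NULL
  if (!is.null(main_orf)) {
    n_rich <- detect_n_rich(main_orf$protein, window = cfg$n_rich$window,
                            threshold = cfg$n_rich$threshold,
                            min_len = cfg$n_rich$min_len)
    motifs <- list(giy_yig = scan_giy_yig(main_orf$protein),
                   cys = scan_cys_motif(main_orf$protein))
  }

  capture <- list()
  if (!is.null(pltr_library) && !is.null(orf_library)) {
    capture <- detect_capture(locus, pltr_library, orf_library,
                              min_identity = cfg$capture$min_identity)
  }

  feats <- empty_features()
  if (nrow(ann$units)) {
    for (i in seq_len(nrow(ann$units))) {
      u <- ann$units[i, ]
      feats <- rbind(feats, feature_row("pltr", u$start, u$end,
        strand = if (u$orientation == "inverted") "-" else "+",
        name = u$orientation))
    }
  }
  if (tail_len > 0L && !is.null(span))
    feats <- rbind(feats, feature_row("tail", span[1], span[1] + tail_len, "-"))
  if (!is.null(tsd) && !is.null(span)) {
    feats <- rbind(feats,
      feature_row("tsd", span[1] - tsd$length, span[1], name = tsd$motif),
      feature_row("tsd", span[2], span[2] + tsd$length, name = tsd$motif))
  }
  if (!is.null(main_orf))
    feats <- rbind(feats, feature_row("orf", main_orf$start, main_orf$end,
                                      main_orf$strand))
  if (!is.null(n_rich) && nrow(n_rich) && !is.null(main_orf)) {
    for (i in seq_len(nrow(n_rich))) {
      feats <- rbind(feats, feature_row("n_rich_insert",
        main_orf$start + 3L * n_rich$start[i],
        main_orf$start + 3L * n_rich$end[i]))
    }
  }
  for (e in capture)
    feats <- rbind(feats, feature_row("cassette", e$cassette[1], e$cassette[2]))

  structure(list(id = id, length = n, pltr = ann, pairs = pairs,
                 hits = hits, tail_len = tail_len, element_span = span,
                 tsd = tsd, orfs = orfs, main_orf = main_orf,
                 n_rich = n_rich, motifs = motifs,
                 palindromes = pal, promoters = prom,
                 capture = capture, features = feats,
                 config = cfg),
            class = "ple_annotation")
}

#' @export
print.ple_annotation <- function(x, ...) {
  cat(sprintf("PLE annotation '%s' (%d bp)\n", x$id, x$length))
  cat(sprintf("  arrangement: %s (%d unit(s)), overlap_5p=%d, truncation_5p=%d, tail=%d bp\n",
              x$pltr$arrangement, nrow(x$pltr$units), x$pltr$overlap_5p,
              x$pltr$truncation_5p, x$tail_len))
  if (!is.null(x$tsd))
    cat(sprintf("  TSD: %s (%d bp)\n", x$tsd$motif, x$tsd$length))
  if (!is.null(x$main_orf))
    cat(sprintf("  main ORF: %d aa (%s strand)\n", x$main_orf$aa_len,
                x$main_orf$strand))
  if (length(x$capture))
    cat(sprintf("  capture events: %d\n", length(x$capture)))
  invisible(x)
}
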