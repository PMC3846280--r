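# Synthetic PLE insertion loci.
#
# The generator assembles a locus from parts (flanks, TSD copies, pLTR
# copies, the optional tail, the ORF, an optional spacer) and emits a truth
# table of every planted feature in 0-based half-open coordinates.
#
# Two constructive details matter for exact recovery of printed structural
# parameters:
#
# * In the direct/direct + 5'-inverted arrangement the inverted unit and the
#   adjacent direct unit share `overlap_5p` genomic bases.  The shared block
#   is built reverse-complement-symmetric (up to the unavoidable centre base
#   of an odd-length block), so the same bases read as the end of the
#   inverted unit and as the start of the direct unit, exactly as a
#   palindromic pLTR terminus behaves.
#
# * Every planted repeat is "hardened": the three bases immediately outside
#   each copy are forced to mismatch their would-be partners, so each
#   planted repeat is exactly maximal and boundary coordinates are
#   deterministic rather than subject to chance single-base extensions.

#' Forge a synthetic PLE locus
#'
#' @param spec a [locus_spec()].
#' @return list with `sequence` (DNA string) and `truth`, itself a list of
#'   `features` (data frame: type/start/end/strand/name, 0-based half-open)
#'   and `params` (planted structural parameters, including the pLTR
#'   consensus and the ORF DNA).
#' @export
forge_locus <- function(spec) {
  validate_locus_spec(spec)
  with_seed(spec$seed, {
    arr <- spec$arrangement
    L <- spec$pltr_len; ov <- spec$overlap_5p; tr <- spec$trunc_5p_inverted
    TL <- spec$tail_len; Tn <- spec$tsd_len; FL <- spec$flank_len
    IL <- L - tr
    embed <- arr %in% c("DD_plus_inverted5p", "DD_only", "tandem_partial")
    if (arr != "DD_plus_inverted5p") TL <- 0L

    orf <- NULL; O <- character()
    if (arr != "solo") {
      orf <- forge_orf(spec$orf_aa, spec$insert, spec$defects,
                       seed = spec$seed + 104729L)
      O <- dna_chars(orf$dna)
      if (embed && length(O) < 36L + TL + 9L)
        stop("invalid locus spec: field 'orf_aa' too short for an embedded ORF start")
    }
    head_len <- if (embed) 36L else 0L

    tsd <- if (Tn > 0) {
      if (!is.null(spec$tsd_motif)) dna_chars(spec$tsd_motif)
      else dna_chars(random_dna(Tn, spec$at_fraction))
    } else character()
    tsd_fixed <- !is.null(spec$tsd_motif)
    flankL <- dna_chars(random_dna(FL, spec$at_fraction))
    flankR <- dna_chars(random_dna(FL, spec$at_fraction))
    spacer <- dna_chars(random_dna(spec$spacer_len, spec$at_fraction))

    pb <- build_pltr_chars(spec, O, head_len)
    p <- pb$p

    # immutable ORF indices (1-based): embedded head, tail source is derived
    # (hence editable), catalytic motifs, microhomology windows, the stop
    o_immutable <- integer()
    if (length(O)) {
      o_immutable <- c(if (head_len) seq_len(head_len),
                       (length(O) - 2L):length(O))
      tr_aa <- orf$truth
      for (iv in list(tr_aa$rt, tr_aa$en))
        if (!is.null(iv)) o_immutable <- c(o_immutable, (3L * iv[1] + 1L):(3L * iv[2]))
      for (d in spec$defects)
        if (d$kind == "microhomology_deletion")
          o_immutable <- c(o_immutable,
                           max(1L, d$position - d$microhomology_len - 2L):
                             min(length(O), d$position + 4L))
    }

    p2 <- p
    if (spec$pltr_identity < 1)
      p2 <- mutate_chars(p, 1 - spec$pltr_identity)

    tail_chars <- function() if (TL > 0) rev(comp_chars(O[(head_len + 1L):(head_len + TL)])) else character()
    icore_chars <- function() if (arr == "DD_plus_inverted5p") rev(comp_chars(p[(ov + 1L):IL])) else character()

    segments <- function() {
      o_rest <- if (length(O)) O[(head_len + 1L):length(O)] else character()
      switch(arr,
        DD_plus_inverted5p = list(
          flankL = flankL, tsd1 = tsd, tail = tail_chars(),
          icore = icore_chars(), pltr1 = p, orfrest = o_rest,
          spacer = spacer, pltr2 = p2, tsd2 = tsd, flankR = flankR),
        DD_only = list(
          flankL = flankL, tsd1 = tsd, pltr1 = p, orfrest = o_rest,
          spacer = spacer, pltr2 = p2, tsd2 = tsd, flankR = flankR),
        inverted_pair = list(
          flankL = flankL, tsd1 = tsd, ipltr = rev(comp_chars(p)),
          orfrest = o_rest, spacer = spacer, pltr2 = p2, tsd2 = tsd,
          flankR = flankR),
        solo = list(flankL = flankL, tsd1 = tsd, pltr1 = p, tsd2 = tsd,
                    flankR = flankR),
        tandem_partial = {
          unit <- c(p, o_rest)
          part <- unit[(length(unit) - (length(unit) %/% 2L) + 1L):length(unit)]
          list(flankL = flankL, tsd1 = tsd, pltr1 = p, orfrest = o_rest,
               pltr2 = p2, partial = part, tsd2 = tsd, flankR = flankR)
        })
    }

    seg_offsets <- function(segs) {
      lens <- vapply(segs, length, integer(1))
      starts <- cumsum(c(0L, lens))[seq_along(lens)]
      names(starts) <- names(segs)
      list(starts = starts, lens = lens)
    }

    # planted repeat pairs: list(x0, xend, y0, yend, inverted) 0-based
    planted_pairs <- function(off) {
      st <- off$starts
      switch(arr,
        DD_plus_inverted5p = {
          s <- st[["icore"]]; d1 <- st[["pltr1"]]; d2 <- st[["pltr2"]]
          # NB: the I~D1 match is palindromic (the copies overlap); its
          # boundaries coincide with the I~D2 constraints, so it is not a
          # hardening target itself
          pr <- list(
            list(x0 = d1, xe = d1 + L, y0 = d2, ye = d2 + L, inv = FALSE),
            list(x0 = s, xe = s + IL, y0 = d2, ye = d2 + IL, inv = TRUE))
          if (TL > 0) {
            a1 <- st[["tail"]]
            pr <- c(pr, list(list(x0 = a1, xe = a1 + TL,
                                  y0 = d1 + L, ye = d1 + L + TL, inv = TRUE)))
          }
          pr
        },
        DD_only = {
          d1 <- st[["pltr1"]]; d2 <- st[["pltr2"]]
          list(list(x0 = d1, xe = d1 + L, y0 = d2, ye = d2 + L, inv = FALSE))
        },
        inverted_pair = {
          i1 <- st[["ipltr"]]; d2 <- st[["pltr2"]]
          list(list(x0 = i1, xe = i1 + L, y0 = d2, ye = d2 + L, inv = TRUE))
        },
        solo = list(),
        tandem_partial = {
          d1 <- st[["pltr1"]]; d2 <- st[["pltr2"]]
          list(list(x0 = d1, xe = d1 + L, y0 = d2, ye = d2 + L, inv = FALSE))
        })
    }

    locate <- function(pos0, off) {
      k <- max(which(off$starts <= pos0))
      list(seg = names(off$starts)[k], at = pos0 - off$starts[[k]] + 1L)  # 1-based offset
    }

    # try to force a mismatch at genome position pos0 against base `bad`
    # (the base it must not equal after the edit); returns TRUE on success
    try_fix <- function(pos0, bad, off) {
      loc <- locate(pos0, off); seg <- loc$seg; at <- loc$at
      pick <- function(cur) other_base(unique(c(bad, cur)))
      switch(seg,
        flankL = { flankL[at] <<- pick(flankL[at]); TRUE },
        flankR = { flankR[at] <<- pick(flankR[at]); TRUE },
        spacer = { spacer[at] <<- pick(spacer[at]); TRUE },
        tsd1 = , tsd2 = {
          if (tsd_fixed) return(FALSE)
          tsd[at] <<- pick(tsd[at]); TRUE
        },
        tail = {  # derived: tail[at] = comp(O[head_len + TL + 1 - at])
          oi <- head_len + TL + 1L - at
          fix_orf_index(oi, comp = TRUE, bad = bad)
        },
        orfrest = fix_orf_index(head_len + at, comp = FALSE, bad = bad),
        icore = {  # icore[at] = comp(p[IL + 1 - at])
          pi <- IL + 1L - at
          fix_pltr_index(pi, comp = TRUE, bad = bad)
        },
        ipltr = fix_pltr_index(L + 1L - at, comp = TRUE, bad = bad),
        pltr1 = , pltr2 = , partial = fix_pltr_index(at, comp = FALSE, bad = bad),
        FALSE)
    }

    fix_orf_index <- function(oi, comp, bad) {
      if (oi < 1L || oi > length(O) || oi %in% o_immutable) return(FALSE)
      avoid <- if (comp) comp_chars(bad) else bad
      b <- safe_base(O, oi, avoid = c(avoid, O[oi]))
      if (is.na(b)) return(FALSE)
      O[oi] <<- b
      TRUE
    }

    fix_pltr_index <- function(pi, comp, bad) {
      if (pi < 1L || pi > L || pi %in% pb$immutable) return(FALSE)
      if (pi > L - head_len) {  # embedded ORF head
        return(fix_orf_index(pi - (L - head_len), comp = comp, bad = bad))
      }
      avoid <- if (comp) comp_chars(bad) else bad
      p[pi] <<- other_base(unique(c(avoid, p[pi])))
      if (spec$pltr_identity >= 1) p2[pi] <<- p[pi]
      TRUE
    }

    # hardening loop: force the 3 bases outside every planted repeat copy to
    # mismatch their partners
    unfixable <- character()
    for (iter in 1:60) {
      segs <- segments(); off <- seg_offsets(segs)
      g <- unlist(segs, use.names = FALSE)
      n <- length(g)
      viol <- NULL
      for (pr in planted_pairs(off)) {
        for (t in 0:2) {
          cand <- if (!pr$inv) list(
            c(pr$x0 - 1L - t, pr$y0 - 1L - t),   # left extension
            c(pr$xe + t, pr$ye + t))             # right extension
          else list(
            c(pr$x0 - 1L - t, pr$ye + t),        # left of x vs right of y
            c(pr$xe + t, pr$y0 - 1L - t))        # right of x vs left of y
          for (cp in cand) {
            i <- cp[1]; j <- cp[2]
            if (i < 0L || j < 0L || i >= n || j >= n) next
            if (paste(i, j) %in% unfixable) next
            gi <- g[i + 1L]; gj <- if (pr$inv) comp_chars(g[j + 1L]) else g[j + 1L]
            if (gi == gj) { viol <- list(i = i, j = j, inv = pr$inv); break }
          }
          if (!is.null(viol)) break
        }
        if (!is.null(viol)) break
      }
      if (is.null(viol)) break
      # prefer editing the side living in freer sequence
      fixed <- FALSE
      ord <- order_fix_sides(locate(viol$i, off)$seg, locate(viol$j, off)$seg)
      for (side in ord) {
        pos <- if (side == 1L) viol$i else viol$j
        partner <- if (side == 1L) viol$j else viol$i
        pg <- g[partner + 1L]
        bad <- if (viol$inv) comp_chars(pg) else pg
        if (try_fix(pos, bad, off)) { fixed <- TRUE; break }
      }
      if (!fixed) unfixable <- c(unfixable, paste(viol$i, viol$j))
    }

    segs <- segments(); off <- seg_offsets(segs)
    g <- unlist(segs, use.names = FALSE)
    st <- off$starts
    feats <- empty_features()
    add <- function(type, seg, len = NULL, strand = "+", name = NA, start0 = NULL) {
      s0 <- if (is.null(start0)) st[[seg]] else start0
      l <- if (is.null(len)) off$lens[[seg]] else len
      feats <<- rbind(feats, feature_row(type, s0, s0 + l, strand, name))
    }
    if (Tn > 0) { add("tsd", "tsd1", name = chars_dna(tsd)); add("tsd", "tsd2", name = chars_dna(tsd)) }
    if (TL > 0) add("tail", "tail", strand = "-")
    orf_start <- NA_integer_
    if (arr == "DD_plus_inverted5p") {
      add("pltr", "icore", len = IL, strand = "-", name = "inverted")
      add("pltr", "pltr1", name = "direct")
      add("pltr", "pltr2", name = "direct")
      orf_start <- st[["pltr1"]] + L - head_len
    } else if (arr %in% c("DD_only", "tandem_partial")) {
      add("pltr", "pltr1", name = "direct")
      add("pltr", "pltr2", name = "direct")
      orf_start <- st[["pltr1"]] + L - head_len
    } else if (arr == "inverted_pair") {
      add("pltr", "ipltr", strand = "-", name = "inverted")
      add("pltr", "pltr2", name = "direct")
      orf_start <- st[["orfrest"]]
    } else if (arr == "solo") {
      add("pltr", "pltr1", name = "direct")
    }
    if (length(O) && !is.na(orf_start)) {
      feats <- rbind(feats, feature_row("orf", orf_start, orf_start + length(O)))
      it <- orf$truth$insert
      if (!is.null(it))
        feats <- rbind(feats, feature_row("n_rich_insert",
                                          orf_start + 3L * it[1],
                                          orf_start + 3L * it[2]))
      for (dt in orf$truth$defects)
        feats <- rbind(feats, feature_row("defect",
                                          orf_start + 3L * dt$aa_pos,
                                          orf_start + 3L * dt$aa_pos + max(3L, dt$size),
                                          name = dt$kind))
    }
    params <- list(arrangement = arr,
                   overlap_5p = if (arr == "DD_plus_inverted5p") ov else 0L,
                   truncation_5p = if (arr == "DD_plus_inverted5p") tr else 0L,
                   tail_len = TL, tsd_len = Tn,
                   tsd_motif = if (Tn > 0) chars_dna(tsd) else NULL,
                   pltr_len = L, pltr_seq = chars_dna(p),
                   orf_strand = "+", orf_start = orf_start,
                   orf_dna = if (length(O)) chars_dna(O) else NULL,
                   orf_head_in_pltr = head_len,
                   promoter = pb$promoter)
    list(sequence = chars_dna(g),
         truth = list(features = feats, params = params))
  })
}

# editing priority: freer sequence first
order_fix_sides <- function(seg_i, seg_j) {
  rank <- function(s) switch(s, flankL = , flankR = , spacer = 1,
                             orfrest = 2, tail = 2, pltr1 = , pltr2 = ,
                             partial = , icore = , ipltr = 3,
                             tsd1 = , tsd2 = 4, 5)
  if (rank(seg_i) <= rank(seg_j)) c(1L, 2L) else c(2L, 1L)
}

# Build the pLTR consensus: random sequence; a reverse-complement-symmetric
# terminus covering the 5' overlap (DD_plus_inverted5p) or a planted
# terminal palindrome; an optional promoter block; the embedded ORF head.
build_pltr_chars <- function(spec, O, head_len) {
  L <- spec$pltr_len
  p <- dna_chars(random_dna(L, spec$at_fraction))
  immutable <- integer()
  if (spec$arrangement == "DD_plus_inverted5p" && spec$overlap_5p > 1) {
    ov <- spec$overlap_5p
    half <- ov %/% 2L
    for (k in seq_len(half)) p[ov + 1L - k] <- comp_chars(p[k])
    immutable <- c(immutable, seq_len(ov))
  } else if (spec$palindrome_len >= 4) {
    pal <- plant_palindrome(p, spec$palindrome_len, spec$palindrome_mismatches)
    p <- pal
    immutable <- c(immutable, seq_len(spec$palindrome_len))
  }
  promoter <- NULL
  if (!is.null(spec$promoter)) {
    pp <- plant_promoter(p, spec$promoter, offset = max(spec$overlap_5p,
                                                        spec$palindrome_len) + 20L)
    p <- pp$p
    promoter <- pp$truth
    immutable <- c(immutable, pp$span)
  }
  if (head_len > 0) {
    p[(L - head_len + 1L):L] <- O[seq_len(head_len)]
    immutable <- c(immutable, (L - head_len + 1L):L)
    # a stop in every plus-strand frame shortly before the ORF head, so the
    # embedded ATG is the unique ORF start within the unit (no chance
    # upstream ATG can read through into the element ORF)
    blk <- (L - head_len - 11L):(L - head_len - 3L)
    if (blk[1] > max(spec$overlap_5p, spec$palindrome_len) + 1L) {
      p[blk] <- dna_chars("TAATAATAA")
      immutable <- c(immutable, blk)
      pos0 <- L - head_len - 2L   # only remaining upstream ATG start slot
      if (p[pos0] == "A") p[pos0] <- "C"
    }
  }
  list(p = p, immutable = immutable, promoter = promoter)
}

# plant an exact-arm palindrome at the start of a char vector; mismatches
# are introduced at interior arm pairs only (never the outermost pair)
plant_palindrome <- function(p, pal_len, mismatches = 0L) {
  if (pal_len %% 2L != 0L)
    stop("planted palindrome length must be even")
  arm <- pal_len %/% 2L
  for (k in seq_len(arm)) p[pal_len + 1L - k] <- comp_chars(p[k])
  if (mismatches > 0) {
    if (arm < mismatches + 1L) stop("palindrome too short for planted mismatches")
    at <- (2:arm)[sample.int(arm - 1L, mismatches)]   # pair index from the outside, >1
    for (k in at) p[pal_len + 1L - k] <- other_base(c(comp_chars(p[k])))
  }
  p
}

# plant [AATGT gap] TATA [spacing] INR inside the unit
plant_promoter <- function(p, prom, offset = 40L) {
  tata <- dna_chars(prom$tata_motif)
  inr <- dna_chars(prom$inr_motif)
  rev_inr <- dna_chars(revcomp("ACATT"))
  gap_rev <- 15L
  truth <- list()
  idx <- offset
  if (prom$bidirectional) {
    p[(idx + 1L):(idx + 5L)] <- rev_inr
    truth$rev_inr_start <- idx
    idx <- idx + 5L + gap_rev
  }
  p[(idx + 1L):(idx + length(tata))] <- tata
  truth$tata_start <- idx
  idx <- idx + length(tata) + prom$spacing
  p[(idx + 1L):(idx + length(inr))] <- inr
  truth$inr_start <- idx
  truth$spacing <- prom$spacing
  span <- (offset + 1L):(idx + length(inr))
  if (max(span) > length(p)) stop("promoter block does not fit inside the pLTR")
  # scrub chance extra occurrences of the scanned motifs so the planted
  # arrangement is the unique promoter call
  planted <- c(truth$tata_start + seq_along(tata),
               truth$inr_start + seq_along(inr),
               if (prom$bidirectional) truth$rev_inr_start + 1:5)
  motifs <- unique(c(prom$tata_motif, prom$inr_motif, "AATGT",
                     revcomp(prom$tata_motif)))
  for (pass in 1:10) {
    dirty <- FALSE
    s <- chars_dna(p)
    for (mo in motifs) {
      for (at in find_all(s, mo)) {      # 0-based
        occ <- (at + 1L):(at + nchar(mo))
        if (all(occ %in% planted)) next
        free <- setdiff(occ, planted)
        if (!length(free)) next
        i <- free[(length(free) + 1L) %/% 2L]
        p[i] <- other_base(p[i])
        dirty <- TRUE
      }
    }
    if (!dirty) break
  }
  list(p = p, truth = truth, span = span)
}

#' Forge a standalone pLTR unit
#'
#' Convenience generator for promoter- and palindrome-scan experiments: a
#' random unit of length `len` with an optional exact or near-exact terminal
#' palindrome and an optional planted promoter block.
#'
#' @param len unit length, bp.
#' @param palindrome_len planted terminal palindrome length (even; 0 = none).
#' @param palindrome_mismatches internal arm mismatches planted into the
#'   palindrome.
#' @param promoter optional [promoter_spec()].
#' @param seed integer seed.
#' @return list with `sequence` and `truth` (palindrome interval, promoter
#'   positions; 0-based).
#' @export
forge_pltr <- function(len = 193L, palindrome_len = 18L,
                       palindrome_mismatches = 0L, promoter = NULL,
                       seed = 1L) {
  with_seed(seed, {
    p <- dna_chars(random_dna(len))
    truth <- list()
    if (palindrome_len >= 4) {
      p <- plant_palindrome(p, palindrome_len, palindrome_mismatches)
      truth$palindrome <- c(0L, palindrome_len)
      truth$palindrome_mismatches <- palindrome_mismatches
    }
    if (!is.null(promoter)) {
      pp <- plant_promoter(p, promoter, offset = palindrome_len + 20L)
      p <- pp$p
      truth$promoter <- pp$truth
    }
    list(sequence = chars_dna(p), truth = truth)
  })
}

# per-site substitution at `rate`; protected positions are left untouched
mutate_chars <- function(v, rate, protect = integer()) {
  hit <- which(stats::runif(length(v)) < rate)
  hit <- setdiff(hit, protect)
  for (i in hit) v[i] <- other_base(v[i])
  v
}
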