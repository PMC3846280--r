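# Synthetic PLE open reading frames.  The ORF is a single ATG-initiated,
# stop-terminated frame carrying placeholder catalytic motifs (an RT core
# word and a GIY-X10-YIG endonuclease word) at fixed relative positions,
# optionally an in-frame N-rich insert, and optionally planted defects.

RT_MOTIF <- "LVFADDLT"

# uniform draw over the 61 sense codons
sample_codons <- function(n) sample(nonstop_codons(), n, replace = TRUE)

# random synonymous codon per residue
aa_to_codons <- function(aa) {
  vapply(strsplit(aa, "")[[1]], function(a) {
    cs <- codons_for(a)
    if (!length(cs)) stop("no codon for residue ", a)
    if (length(cs) == 1L) cs else sample(cs, 1L)
  }, character(1))
}

# insert codons: Asn with probability `asn_fraction` (AAT/AAC split evenly),
# otherwise uniform over the sense codons that do not encode Asn, so the
# realized Asn fraction is an unbiased estimate of the target.
insert_codons <- function(aa_len, asn_fraction) {
  is_asn <- stats::runif(aa_len) < asn_fraction
  out <- character(aa_len)
  out[is_asn] <- sample(c("AAT", "AAC"), sum(is_asn), replace = TRUE)
  pool <- setdiff(nonstop_codons(), c("AAT", "AAC"))
  out[!is_asn] <- sample(pool, sum(!is_asn), replace = TRUE)
  out
}

# relative anchor positions (1-based aa indices within the core ORF)
orf_layout <- function(orf_aa) {
  list(rt = max(2L, as.integer(floor(0.35 * orf_aa))),
       en = as.integer(floor(0.75 * orf_aa)),
       ins_rt_en = as.integer(floor(0.55 * orf_aa)),
       ins_rt_thumb = as.integer(floor(0.62 * orf_aa)))
}

#' Forge a synthetic PLE ORF
#'
#' Builds the DNA of a single ORF (`ATG` ... single terminal stop) of
#' `orf_aa` residues, embeds placeholder RT and GIY-YIG endonuclease motifs
#' when the frame is long enough, optionally splices in an in-frame
#' asparagine-rich insert, and finally applies the requested defects.
#'
#' Microhomology-mediated deletions are planted so that the breakpoints
#' share exactly `microhomology_len` identical bases and the flanking bases
#' are forced to differ, making the planted length recoverable by maximal
#' cross-junction extension.
#'
#' @param orf_aa core ORF length in residues (ATG included, stop excluded).
#' @param insert optional [insert_spec()].
#' @param defects list of [defect_spec()].
#' @param seed integer seed.
#' @return list with `dna` (defective copy), `intact_dna`, `protein`
#'   (translation of `intact_dna` without the stop), `truth` (aa-coordinate
#'   features: insert interval, motif positions, defect records, all
#'   0-based half-open).
#' @export
forge_orf <- function(orf_aa, insert = NULL, defects = list(), seed = 1L) {
  orf_aa <- as.integer(orf_aa)
  if (orf_aa < 1) stop("invalid ORF spec: field 'orf_aa' must be >= 1")
  lay <- orf_layout(orf_aa)
  embed <- orf_aa >= 60L

  with_seed(seed, {
    for (attempt in 1:25) {
      core <- sample_codons(orf_aa)
      core[1] <- "ATG"
      en_final <- NULL
      rt_final <- NULL
      if (embed) {
        rt_cod <- aa_to_codons(RT_MOTIF)
        core[lay$rt:(lay$rt + length(rt_cod) - 1L)] <- rt_cod
        en_aa <- paste0("GIY", paste(sample(setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z")), 10, TRUE), collapse = ""), "YIG")
        en_cod <- aa_to_codons(en_aa)
        core[lay$en:(lay$en + length(en_cod) - 1L)] <- en_cod
        rt_final <- c(lay$rt - 1L, lay$rt - 1L + nchar(RT_MOTIF))
        en_final <- c(lay$en - 1L, lay$en - 1L + nchar(en_aa))
      }

      ins_interval <- NULL
      if (!is.null(insert)) {
        ipos <- if (insert$position == "RT_EN_linker") lay$ins_rt_en else lay$ins_rt_thumb
        ipos <- max(1L, min(ipos, orf_aa - 1L))
        icod <- insert_codons(insert$aa_len, insert$asn_fraction)
        codons <- c(core[1:ipos], icod, core[(ipos + 1L):orf_aa])
        ins_interval <- c(ipos, ipos + insert$aa_len)
        if (!is.null(en_final) && en_final[1] >= ipos)
          en_final <- en_final + insert$aa_len
      } else {
        codons <- core
      }

      dna <- c(unlist(strsplit(codons, "")), c("T", "A", "A"))
      if (!is.null(insert) && !insert$in_frame)
        dna <- append(dna, sample(DNA_BASES, 1L), after = 3L * ins_interval[2])

      # plant microhomology context into the intact sequence before copying
      ok <- TRUE
      for (d in defects) {
        if (d$kind == "microhomology_deletion") {
          res <- plant_microhomology(dna, d)
          if (is.null(res)) { ok <- FALSE; break }
          dna <- res
        }
      }
      if (!ok) next
      intact <- chars_dna(dna)
      prot <- translate_dna(intact)
      body <- substr(prot, 1, nchar(prot) - 1L)
      if (grepl("*", body, fixed = TRUE)) next   # rare planting side effect
      copy <- apply_defects(dna, defects)
      truth <- list(aa_len = nchar(body),
                    insert = ins_interval, rt = rt_final, en = en_final,
                    defects = lapply(defects, defect_truth, dna = dna))
      return(list(dna = chars_dna(copy), intact_dna = intact,
                  protein = body, truth = truth))
    }
    stop("could not forge a stop-free ORF under the requested constraints")
  })
}

# Force dna[b-h, b) == dna[a-h, a) (0-based; deletion interval is [a, b)),
# and force the bases just outside the shared word to differ so the planted
# microhomology is exactly maximal.  Returns NULL when the codons spanning
# the edits cannot be kept stop-free.
plant_microhomology <- function(dna, d) {
  a <- d$position; b <- a + d$size; h <- d$microhomology_len
  n <- length(dna)
  if (a - h - 1L < 0L || b >= n - 3L) stop("defect position outside ORF")
  # 0-based [b-h, b) == 1-based positions (b-h+1)..b
  dna[(b - h + 1L):b] <- dna[(a - h + 1L):a]
  # hardening: first retained base after junction differs across breakpoints
  if (dna[b + 1L] == dna[a + 1L])
    dna[b + 1L] <- safe_base(dna, b + 1L, avoid = dna[a + 1L])
  if (dna[b - h] == dna[a - h])
    dna[b - h] <- safe_base(dna, b - h, avoid = dna[a - h])
  if (is.na(dna[b + 1L]) || is.na(dna[b - h])) return(NULL)
  dna
}

# change position `i` (1-based) to a base not in `avoid` while keeping the
# covering codon stop-free; NA when impossible
safe_base <- function(dna, i, avoid) {
  ci <- ((i - 1L) %/% 3L) * 3L + 1L
  for (b in sample(setdiff(DNA_BASES, avoid))) {
    cod <- dna[ci:(ci + 2L)]
    cod[i - ci + 1L] <- b
    if (!(chars_dna(cod) %in% stop_codons())) return(b)
  }
  NA_character_
}

# aa-level description of a planted defect (for the truth sidecar)
defect_truth <- function(d, dna) {
  pos_aa <- switch(d$kind,
    stop = , frameshift = d$position - 1L,
    indel = , microhomology_deletion = d$position %/% 3L,
    trunc5 = 0L,
    trunc3 = (length(dna) - d$size) %/% 3L)
  list(kind = d$kind, aa_pos = pos_aa, size = d$size,
       microhomology_len = d$microhomology_len)
}

# apply defects to a char vector, right-to-left so stored positions stay valid
apply_defects <- function(dna, defects) {
  if (!length(defects)) return(dna)
  bp_pos <- vapply(defects, function(d) switch(d$kind,
    stop = , frameshift = 3L * (d$position - 1L),
    indel = , microhomology_deletion = d$position,
    trunc5 = 0L, trunc3 = length(dna)), integer(1))
  for (d in defects[order(bp_pos, decreasing = TRUE)]) {
    n <- length(dna)
    dna <- switch(d$kind,
      stop = {
        i <- 3L * (d$position - 1L)
        if (i + 3L > n) stop("defect position outside ORF")
        replace0(dna, i, c("T", "A", "A"))
      },
      frameshift = {
        i <- 3L * (d$position - 1L) + 1L
        if (i > n) stop("defect position outside ORF")
        dna[-i]
      },
      indel = {
        if (d$position > n) stop("defect position outside ORF")
        if (d$size >= 0) append(dna, sample(DNA_BASES, d$size, TRUE), after = d$position)
        else dna[-((d$position + 1L):(d$position - d$size))]
      },
      trunc5 = dna[-seq_len(min(d$size, n))],
      trunc3 = dna[seq_len(max(0L, n - d$size))],
      microhomology_deletion = {
        if (d$position + d$size > n) stop("defect position outside ORF")
        dna[-((d$position + 1L):(d$position + d$size))]
      })
  }
  dna
}
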