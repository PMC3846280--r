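# Brute-force reference implementations used to validate the detectors on
# small inputs.  These recompute the same quantities by exhaustive
# enumeration, independent of the seeded/hashed production code paths.

# -- maximal ungapped repeats, full per-diagonal scan ----------------------
oracle_repeats <- function(locus, min_unit = 50L, min_identity = 0.8,
                           k = 12L, xdrop = 10L) {
  v <- strsplit(toupper(locus), "")[[1]]
  cv <- unname(c(A = "T", C = "G", G = "C", T = "A")[v])
  n <- length(v)
  out <- list()
  argmax_ext <- function(m, from, dir) {
    # walk from `from` (exclusive) in direction dir over match vector m,
    # +1/-2 scoring, return index of the score maximum (0 steps if none)
    best <- 0; sc <- 0; at <- from
    i <- from
    repeat {
      i <- i + dir
      if (i < 1L || i > length(m)) break
      sc <- sc + if (m[i]) 1 else -2
      if (sc > best) { best <- sc; at <- i }
      if (sc < best - xdrop) break
    }
    at
  }
  seg_from_runs <- function(m) {
    r <- rle(m); ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    runs <- cbind(starts[r$values & r$lengths >= k], ends[r$values & r$lengths >= k])
    if (!nrow(runs)) return(NULL)
    segs <- unique(t(apply(runs, 1L, function(rr)
      c(argmax_ext(m, rr[1], -1L), argmax_ext(m, rr[2], +1L)))))
    segs
  }
  for (d in 1:(n - 1)) {
    if (n - d < k) next
    m <- v[1:(n - d)] == v[(1 + d):n]
    segs <- seg_from_runs(m)
    if (is.null(segs)) next
    for (ri in seq_len(nrow(segs))) {
      x1 <- segs[ri, 1]; x2 <- segs[ri, 2]; len <- x2 - x1 + 1L
      if (len < min_unit || sum(m[x1:x2]) / len < min_identity) next
      out[[length(out) + 1L]] <- data.frame(
        start1 = x1 - 1L, end1 = x2, start2 = x1 + d - 1L, end2 = x2 + d,
        length = len, orientation = "direct",
        identity = sum(m[x1:x2]) / len, stringsAsFactors = FALSE)
    }
  }
  for (cc in 3:(2 * n - 1)) {
    xs <- max(1L, cc - n); xe <- min(n, (cc - 1L) %/% 2L)
    if (xe - xs + 1L < k) next
    xr <- xs:xe
    m <- v[xr] == cv[cc - xr]
    segs <- seg_from_runs(m)
    if (is.null(segs)) next
    for (ri in seq_len(nrow(segs))) {
      x1 <- xs + segs[ri, 1] - 1L; x2 <- xs + segs[ri, 2] - 1L
      len <- x2 - x1 + 1L
      mm <- m[(x1 - xs + 1L):(x2 - xs + 1L)]
      if (len < min_unit || sum(mm) / len < min_identity) next
      out[[length(out) + 1L]] <- data.frame(
        start1 = x1 - 1L, end1 = x2, start2 = cc - x2 - 1L, end2 = cc - x1,
        length = len, orientation = "inverted",
        identity = sum(mm) / len, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(plescout:::empty_pairs())
  res <- unique(do.call(rbind, out))
  res[order(-res$length, res$start1, res$start2), , drop = FALSE]
}

pairs_key <- function(p) {
  if (!nrow(p)) return(character(0))
  sort(sprintf("%d:%d:%d:%d:%s", p$start1, p$end1, p$start2, p$end2,
               p$orientation))
}

# -- exhaustive palindrome enumeration ------------------------------------
oracle_palindromes <- function(seq, min_len = 10L, max_mismatch = 2L,
                               max_spacer = 4L) {
  v <- strsplit(toupper(seq), "")[[1]]
  cv <- unname(c(A = "T", C = "G", G = "C", T = "A")[v])
  n <- length(v)
  valid <- function(i, j, s) {
    # interval [i, j) 0-based, spacer s; TRUE if arms complementary within
    # budget and the outermost pair matches
    len <- j - i
    a <- (len - s) / 2
    if (a < 1 || a != floor(a)) return(NA)
    lt <- v[(i + 1):(i + a)]
    rt <- cv[j:(j - a + 1)]
    mm <- sum(lt != rt)
    if (lt[1] != rt[1]) return(NA)
    if (mm > max_mismatch) return(NA)
    mm
  }
  rows <- list()
  for (i in 0:(n - 1)) for (j in (i + 2):n) {
    if (j > n) next
    for (s in 0:max_spacer) {
      mm <- valid(i, j, s)
      if (is.na(mm)) next
      if (j - i < min_len) next
      # maximal: no larger valid palindrome shares this centre and spacer
      larger <- FALSE
      t <- 1L
      while (i - t >= 0 && j + t <= n) {
        if (!is.na(valid(i - t, j + t, s))) { larger <- TRUE; break }
        t <- t + 1L
      }
      if (larger) next
      rows[[length(rows) + 1L]] <- data.frame(start = i, end = j,
                                              length = j - i,
                                              mismatches = mm, spacer = s)
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(), length = integer(),
                      mismatches = integer(), spacer = integer()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end, out$mismatches, out$spacer), , drop = FALSE]
  out <- out[!duplicated(out[, c("start", "end")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# -- TSD by full (suffix, prefix, k) enumeration --------------------------
oracle_tsd <- function(left, right, min_len = 4L, max_len = 25L,
                       max_mismatch = 0L) {
  lv <- strsplit(left, "")[[1]]; rv <- strsplit(right, "")[[1]]
  best <- NULL
  for (kk in min_len:min(max_len, length(lv), length(rv))) {
    a <- lv[(length(lv) - kk + 1):length(lv)]; b <- rv[1:kk]
    if (sum(a != b) <= max_mismatch) best <- kk
  }
  best
}

# -- six-frame ORF scan by explicit codon walking -------------------------
oracle_orfs <- function(seq, min_aa) {
  seq <- toupper(seq)
  n <- nchar(seq)
  gc <- as.character(Biostrings::GENETIC_CODE)
  names(gc) <- names(Biostrings::GENETIC_CODE)
  res <- list()
  for (strand in c("+", "-")) {
    w <- if (strand == "+") seq else plescout::revcomp(seq)
    for (f in 0:2) {
      i <- f + 1L
      starts <- integer(0)
      while (i + 2L <= n) {
        cod <- substr(w, i, i + 2L)
        if (cod == "ATG") starts <- c(starts, i)
        if (cod %in% c("TAA", "TAG", "TGA")) {
          for (s in starts) {
            aa <- (i - s) / 3
            if (aa >= min_aa) {
              if (strand == "+") iv <- c(s - 1L, i + 2L)
              else iv <- c(n - (i + 2L), n - s + 1L)
              res[[length(res) + 1L]] <- c(iv, aa)
            }
          }
          starts <- integer(0)
        }
        i <- i + 3L
      }
    }
  }
  if (!length(res)) return(matrix(numeric(0), ncol = 3))
  m <- do.call(rbind, res)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# -- cysteine motif by explicit gap enumeration ---------------------------
oracle_cys <- function(protein) {
  v <- strsplit(protein, "")[[1]]
  n <- length(v)
  hits <- integer(0)
  for (i in seq_len(n)) {
    if (!(v[i] %in% c("C", "H"))) next
    for (g in 1:3) {
      j <- i + 1L + g            # first C
      k2 <- j + 11L              # second C
      k3 <- k2 + 3L              # third C
      if (k3 > n) next
      if (v[j] == "C" && v[k2] == "C" && v[k3] == "C") {
        hits <- c(hits, i - 1L)
        break
      }
    }
  }
  hits
}

# -- naive read placement -------------------------------------------------
oracle_map_positions <- function(read, element, max_mismatch = 1L) {
  ev <- strsplit(toupper(element), "")[[1]]
  rv <- strsplit(toupper(read), "")[[1]]
  L <- length(rv)
  if (L > length(ev)) return(integer(0))
  which(vapply(seq_len(length(ev) - L + 1L), function(p)
    sum(rv != ev[p:(p + L - 1L)]) <= max_mismatch, logical(1))) - 1L
}
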