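# Low-level sequence helpers shared by the generator and the annotators.
# All public coordinates in this package are 0-based half-open; these helpers
# do the +1 bookkeeping against R's 1-based strings in exactly one place.

DNA_BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

dna_chars <- function(x) {
  if (length(x) != 1L) stop("expected a single DNA string")
  strsplit(toupper(x), "", fixed = TRUE)[[1]]
}

chars_dna <- function(v) paste(v, collapse = "")

comp_chars <- function(v) unname(.COMP[v])

#' Reverse complement of a DNA string
#'
#' @param x single DNA string (A/C/G/T/N, any case).
#' @return The reverse complement, upper case.
#' @export
revcomp <- function(x) chars_dna(rev(comp_chars(dna_chars(x))))

#' Extract a 0-based half-open subsequence
#'
#' @param x DNA string.
#' @param start0,end0 0-based half-open bounds.
#' @return substring `x[start0, end0)`.
#' @export
subseq0 <- function(x, start0, end0) {
  stopifnot(start0 >= 0, end0 >= start0, end0 <= nchar(x))
  substr(x, start0 + 1L, end0)
}

# In-place replacement on a char vector, 0-based half-open target.
replace0 <- function(v, start0, value_chars) {
  idx <- seq_along(value_chars) + start0
  stopifnot(max(idx) <= length(v))
  v[idx] <- value_chars
  v
}

#' Random DNA with configurable AT content
#'
#' Background sequence is i.i.d. over A/C/G/T.  `at` is the total A+T
#' fraction (0.5 = uniform); AT-rich backgrounds emulate preferred PLE
#' integration targets.
#'
#' @param n length in bp.
#' @param at A+T fraction in `[0, 1]`.
#' @return DNA string of length `n`.
#' @export
random_dna <- function(n, at = 0.5) {
  if (n <= 0) return("")
  p <- c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# pick a base different from all bases in `avoid`
other_base <- function(avoid) {
  pool <- setdiff(DNA_BASES, avoid)
  if (!length(pool)) stop("no base available outside the avoid set")
  sample(pool, 1L)
}

## ---- genetic code -------------------------------------------------------

.GC <- NULL
genetic_code <- function() {
  if (is.null(.GC)) {
    gc <- as.character(Biostrings::GENETIC_CODE)
    names(gc) <- names(Biostrings::GENETIC_CODE)
    utils::assignInMyNamespace(".GC", gc)
  }
  .GC
}

stop_codons <- function() c("TAA", "TAG", "TGA")

nonstop_codons <- function() setdiff(names(genetic_code()), stop_codons())

# codons for one amino-acid letter
codons_for <- function(aa) {
  gc <- genetic_code()
  names(gc)[gc == aa]
}

#' Translate DNA in frame 0
#'
#' Trailing bases that do not fill a codon are ignored.  Stops translate
#' to `*`.
#'
#' @param dna DNA string.
#' @return amino-acid string.
#' @export
translate_dna <- function(dna) {
  n <- nchar(dna) %/% 3L
  if (n == 0L) return("")
  codons <- substring(dna, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
  paste(unname(genetic_code()[codons]), collapse = "")
}

## ---- seeding ------------------------------------------------------------

# Every generator takes an explicit integer seed; nothing touches global
# RNG state outside withr::with_seed.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, code)
}

## ---- intervals ----------------------------------------------------------

feature_row <- function(type, start0, end0, strand = "+", name = NA_character_) {
  data.frame(type = type, start = as.integer(start0), end = as.integer(end0),
             strand = strand, name = name, stringsAsFactors = FALSE)
}

empty_features <- function() {
  data.frame(type = character(), start = integer(), end = integer(),
             strand = character(), name = character(), stringsAsFactors = FALSE)
}

interval_overlap <- function(s1, e1, s2, e2) {
  max(0L, min(e1, e2) - max(s1, s2))
}
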