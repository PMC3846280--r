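# Synthetic small-RNA libraries emulating a piRNA-like size class
# (25-32 nt, strong 5'-U bias) sampled from an element sequence.

#' Forge a small-RNA read library from an element
#'
#' Reads are drawn uniformly along the element (restricted to
#' `source_interval` when given); a fraction `antisense_fraction` is taken
#' from the reverse complement, and a fraction `u5_bias` has its 5' base
#' forced to U (T in DNA space), mirroring the 5'-uridine preference of
#' Piwi-bound small RNAs.
#'
#' @param element element DNA string (ORF/sense strand).
#' @param spec a [smallrna_spec()].
#' @return data frame with one row per read: `name`, `seq`, `strand`
#'   (truth), `start` (truth 5'-independent element offset, 0-based),
#'   `length`.
#' @export
forge_smallrna_library <- function(element, spec) {
  stopifnot(inherits(spec, "ple_smallrna_spec"))
  element <- toupper(element)
  n <- spec$n_reads
  if (n == 0L) {
    return(data.frame(name = character(), seq = character(),
                      strand = character(), start = integer(),
                      length = integer(), stringsAsFactors = FALSE))
  }
  lo <- spec$len_range[1]; hi <- spec$len_range[2]
  if (nchar(element) < hi) stop("element shorter than the maximum read length")
  iv <- spec$source_interval %||% c(0L, nchar(element))
  if (iv[2] - iv[1] < hi) stop("source interval shorter than the maximum read length")
  with_seed(spec$seed, {
    len <- sample(lo:hi, n, replace = TRUE)
    start <- iv[1] + floor(stats::runif(n) * (iv[2] - iv[1] - len + 1L))
    anti <- stats::runif(n) < spec$antisense_fraction
    force_u <- stats::runif(n) < spec$u5_bias
    seqs <- substring(element, start + 1L, start + len)
    seqs[anti] <- vapply(seqs[anti], revcomp, character(1), USE.NAMES = FALSE)
    if (any(force_u))
      seqs[force_u] <- paste0("T", substring(seqs[force_u], 2L))
    data.frame(name = sprintf("read_%06d", seq_len(n)),
               seq = seqs,
               strand = ifelse(anti, "-", "+"),
               start = as.integer(start),
               length = as.integer(len),
               stringsAsFactors = FALSE)
  })
}

#' Write a read library to FASTA or FASTQ
#'
#' FASTQ records carry a constant dummy quality of `I`.
#'
#' @param reads data frame from [forge_smallrna_library()].
#' @param path output file path; format chosen from the extension
#'   (`.fastq`/`.fq` = FASTQ, anything else FASTA).
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$name
  if (grepl("\\.(fastq|fq)$", path)) {
    qual <- Biostrings::BStringSet(strrep("I", nchar(reads$seq)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  } else {
    Biostrings::writeXStringSet(x, path, format = "fasta")
  }
  invisible(path)
}
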