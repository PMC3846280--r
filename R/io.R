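# File formats and configuration.  FASTA through Biostrings, GFF3 through
# rtracklayer (internal coordinates are 0-based half-open and converted at
# the boundary), reports as TSV/JSON, configuration as YAML.

#' Read a FASTA file of loci
#'
#' Wrapped lines and mixed case are tolerated; sequences are upper-cased
#' (with a message when lower case was present).  Records containing
#' characters outside `A/C/G/T/N` raise an error naming the record.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  seqs <- as.character(x)
  if (any(grepl("[acgtn]", seqs))) message("lower-case FASTA input upcased")
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("malformed FASTA record: ", paste(names(seqs)[bad], collapse = ", "))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) names(x) <- paste0("seq", seq_along(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# feature table (0-based half-open) -> GRanges (1-based inclusive)
features_to_granges <- function(features, seqid = "locus") {
  if (any(features$end < features$start))
    stop("malformed feature interval (end < start)")
  gr <- GenomicRanges::GRanges(
    seqnames = seqid,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = ifelse(features$strand %in% c("+", "-"), features$strand, "*"))
  S4Vectors::mcols(gr)$type <- features$type
  S4Vectors::mcols(gr)$Name <- features$name
  gr
}

#' Write an annotation feature table as GFF3
#'
#' Feature types follow the package vocabulary (`pltr`, `tail`, `tsd`,
#' `orf`, `n_rich_insert`, `cassette`, `defect`, ...); coordinates are
#' emitted 1-based inclusive.
#'
#' @param features feature data frame (`type,start,end,strand,name`,
#'   0-based half-open) or an annotation bundle from [annotate_locus()].
#' @param path output path.
#' @param seqid sequence identifier for column 1.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path, seqid = NULL) {
  if (inherits(features, "ple_annotation")) {
    seqid <- seqid %||% features$id
    features <- features$features
  }
  seqid <- seqid %||% "locus"
  rtracklayer::export(features_to_granges(features, seqid), path,
                      format = "gff3")
  invisible(path)
}

#' Read a GFF3 feature file back into a feature table
#'
#' @param path GFF3 file.
#' @return feature data frame (0-based half-open).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  nm <- S4Vectors::mcols(gr)$Name
  if (is.null(nm)) nm <- rep(NA_character_, length(gr))
  out <- data.frame(type = as.character(S4Vectors::mcols(gr)$type),
                    start = BiocGenerics::start(gr) - 1L,
                    end = BiocGenerics::end(gr),
                    strand = as.character(BiocGenerics::strand(gr)),
                    name = as.character(nm),
                    stringsAsFactors = FALSE)
  out$strand[out$strand == "*"] <- "+"
  if (any(out$end < out$start)) stop("malformed GFF interval (end < start)")
  out
}

#' Write an annotation report
#'
#' @param bundle an annotation bundle from [annotate_locus()].
#' @param path output path.
#' @param format `"json"` or `"tsv"` (TSV writes the feature table with
#'   stable columns `type,start,end,strand,name`).
#' @return `path`, invisibly.
#' @export
write_report <- function(bundle, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(bundle$features, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    out <- list(id = bundle$id, length = bundle$length,
                arrangement = bundle$pltr$arrangement,
                overlap_5p = bundle$pltr$overlap_5p,
                truncation_5p = bundle$pltr$truncation_5p,
                tail_len = bundle$tail_len,
                tsd = bundle$tsd, features = bundle$features)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(path)
}

#' Default analysis configuration
#'
#' All detector thresholds in one nested list, overridable per call and
#' serializable to YAML; the shipped example file
#' `system.file("extdata", "default-config.yaml", package = "plescout")`
#' mirrors these values.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    repeats = list(min_unit = 50L, min_identity = 0.8, k = 12L, xdrop = 10L),
    tsd = list(min_len = 4L, max_len = 25L, max_mismatch = 0L,
               flank_probe = 60L),
    palindrome = list(min_len = 10L, max_mismatch = 2L, max_spacer = 4L),
    promoter = list(tata_motif = "TATATATA", inr_motif = "TCACT",
                    max_spacing = 50L),
    orf = list(min_aa = 300L),
    n_rich = list(window = 50L, threshold = 0.25, min_len = 100L),
    capture = list(min_identity = 0.8, element_free_k = 20L,
                   min_anchor = 200L, flank_identity = 0.90,
                   motif_window = 50L),
    classify = list(subfamily_cut = 0.10, family_cut = 0.25,
                    group_cut = 0.45, anchor_k = 12L),
    smallrna = list(max_mismatch = 1L, window = 100L, min_run = 3L),
    boundary_slack = 2L)
}

#' Read a YAML configuration, filling defaults
#'
#' @param path YAML file with any subset of the [default_config()] keys.
#' @return complete configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_cfg <- function(def, usr) {
    for (k in names(usr)) {
      def[[k]] <- if (is.list(def[[k]]) && is.list(usr[[k]]))
        merge_cfg(def[[k]], usr[[k]]) else usr[[k]]
    }
    def
  }
  merge_cfg(default_config(), user)
}
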