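#' @useDynLib senmiR, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
#' @importFrom stats median rbinom rnbinom rnorm runif setNames rmultinom
#' @importFrom utils head read.table write.table
#' @keywords internal
"_PACKAGE"

# Sequences are handled as plain character vectors in the DNA alphabet
# (T, not U); Biostrings does the file-format work.

#' Reverse complement of DNA sequences
#'
#' @param x character vector of DNA sequences (ACGTN).
#' @return character vector of reverse complements.
#' @export
dna_revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read a FASTA file as a named character vector
#'
#' Names are truncated at the first whitespace; the full header is kept in
#' the `"description"` attribute.
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  desc <- names(out)
  names(out) <- sub("\\s.*$", "", desc)
  attr(out, "description") <- desc
  out
}

#' Write a named character vector of sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a FASTQ file into a data.frame
#'
#' @param path file path.
#' @return data.frame with columns `id`, `seq`, `qual` (Phred+33 strings).
#' @export
read_fastq <- function(path) {
  # Biostrings warns that it drops its own metadata columns here; the
  # quality strings we need are retained
  qs <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  data.frame(
    id   = names(qs),
    seq  = as.character(qs),
    qual = as.character(Biostrings::quality(qs)),
    stringsAsFactors = FALSE
  )
}

#' Write reads to a FASTQ file
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)),
            all(nchar(reads$seq) == nchar(reads$qual)))
  ss <- Biostrings::DNAStringSet(reads$seq)
  names(ss) <- reads$id
  Biostrings::writeXStringSet(ss, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

# mean Phred score per quality string (Phred+33)
qual_means <- function(qual) {
  vapply(qual, function(q) mean(utf8ToInt(q)) - 33, numeric(1),
         USE.NAMES = FALSE)
}

# random Phred+33 quality strings of the given lengths, scores drawn from
# `scores`
random_quals <- function(lens, scores) {
  n <- length(lens)
  if (n == 0L) return(character(0))
  maxlen <- max(lens)
  draws <- matrix(sample(scores + 33L, n * maxlen, replace = TRUE),
                  nrow = n)
  vapply(seq_len(n), function(i) intToUtf8(draws[i, seq_len(lens[i])]),
         character(1))
}

# all substrings of `x` of width `w` (vectorized over start positions)
substr_windows <- function(x, w) {
  L <- nchar(x)
  if (w > L) return(character(0))
  starts <- seq_len(L - w + 1L)
  substring(x, starts, starts + w - 1L)
}

stop_if_negative <- function(x, what) {
  if (any(x < 0, na.rm = TRUE)) {
    stop(what, " must be nonnegative", call. = FALSE)
  }
  invisible(x)
}
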