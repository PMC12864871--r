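#' @import data.table
#' @importFrom stats cor cov.wt median pt quantile rbinom rnorm runif setNames var sd
#' @importFrom utils head tail
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Validate a nucleotide sequence
#'
#' Checks that `x` is a single upper-case string over the alphabet
#' `{A, C, G, T, N}`. All scanning operations additionally require a
#' non-empty sequence.
#'
#' @param x Character scalar.
#' @param allow_n Logical; permit ambiguous `N` bases (default `TRUE`).
#' @param allow_empty Logical; permit the empty string (default `FALSE`).
#' @param what Label used in error messages.
#' @return `x`, invisibly, after validation.
#' @export
check_dna <- function(x, allow_n = TRUE, allow_empty = FALSE, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  if (!allow_empty && nchar(x) == 0L) {
    stop(what, " must be non-empty", call. = FALSE)
  }
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  if (!grepl(pat, x)) {
    stop(what, " contains characters outside the ",
         if (allow_n) "{A,C,G,T,N}" else "{A,C,G,T}", " alphabet", call. = FALSE)
  }
  invisible(x)
}

#' Reverse complement
#'
#' Watson-Crick complement, reversed. `N` maps to `N`. Vectorised over `x`.
#'
#' @param x Character vector of sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("AGCA")  # "TGCT"
#' revcomp("AGCT")  # palindromic
#' @export
revcomp <- function(x) {
  if (!is.character(x)) stop("x must be character", call. = FALSE)
  bad <- !grepl("^[ACGTN]*$", x)
  if (any(bad)) {
    stop("non-nucleotide character in sequence(s): ",
         paste(head(which(bad), 3L), collapse = ", "), call. = FALSE)
  }
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(comp, function(s) {
    if (nchar(s) == 0L) return("")
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# split a sequence into a character vector of single bases
seq_chars <- function(x) {
  if (nchar(x) == 0L) return(character(0L))
  strsplit(x, "", fixed = TRUE)[[1L]]
}

#' Read sequences from a FASTA file
#'
#' @param path Path to a (plain-text) FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read paired FASTQ mates
#'
#' Reads a Phred+33 FASTQ file into a read set: a list with character
#' vector `id`, character vector `bases` and a list `quals` of integer
#' Phred scores per read.
#'
#' @param path FASTQ path (optionally gzip-compressed).
#' @param phred_offset Quality encoding offset, default 33.
#' @return A list of class `shm_reads` with elements `id`, `bases`, `quals`.
#' @export
read_fastq <- function(path, phred_offset = 33L) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  q <- S4Vectors::mcols(x)$qualities
  quals <- lapply(as.character(q), function(s) utf8ToInt(s) - phred_offset)
  reads <- list(id = names(x), bases = unname(toupper(as.character(x))),
                quals = unname(quals))
  class(reads) <- "shm_reads"
  reads
}

#' Write paired FASTQ mates
#'
#' @param reads An `shm_reads` list (`id`, `bases`, `quals`).
#' @param path Output FASTQ path.
#' @param phred_offset Quality encoding offset, default 33.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, phred_offset = 33L) {
  qual <- vapply(reads$quals, function(q) intToUtf8(q + phred_offset), character(1L))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$bases, "\n+\n", qual), con)
  invisible(path)
}
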