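# WRCH motif grammar: enumeration, two-strand scanning, orientation
# classification, C-centred context windows and PyPy dimer counting.
#
# Coordinates are 1-based inclusive throughout the user-facing API;
# bottom-strand hits are detected as top-strand DGYW occurrences and
# reported in top-strand coordinates.

IUPAC_CLASSES <- list(
  W = c("A", "T"), R = c("A", "G"), C = "C", H = c("A", "C", "T"),
  D = c("A", "G", "T"), G = "G", Y = c("C", "T")
)

#' Enumerate the twelve concrete WRCH motifs
#'
#' Expands the degenerate AID hotspot pattern WRCH (W = A/T, R = A/G,
#' H = A/C/T) into its 2 x 2 x 1 x 3 = 12 concrete 4-mers,
#' lexicographically ordered. The third base of every member is the
#' target cytosine.
#'
#' @return Character vector of 12 motifs.
#' @examples
#' wrch_motifs()
#' @export
wrch_motifs <- function() {
  g <- expand.grid(h = IUPAC_CLASSES$H, c = "C", r = IUPAC_CLASSES$R,
                   w = IUPAC_CLASSES$W, stringsAsFactors = FALSE)
  sort(unique(paste0(g$w, g$r, g$c, g$h)))
}

#' Enumerate the twelve concrete DGYW motifs
#'
#' DGYW (D = A/G/T, Y = C/T) is the reverse complement of WRCH: a
#' top-strand DGYW occurrence marks a bottom-strand WRCH whose target C
#' pairs with the top-strand G at the second motif position.
#'
#' @return Character vector of 12 motifs, lexicographically ordered.
#' @export
dgyw_motifs <- function() sort(revcomp(wrch_motifs()))

#' Classify the strand orientation of a WRCH motif
#'
#' A motif is `palindromic` when it equals its own reverse complement
#' (both strands carry a target C at juxtaposed positions, producing the
#' paired G/C mutation peaks seen for AGCT); `bidirectional` when its
#' reverse complement is a different WRCH motif (AGCA/TGCT); otherwise
#' `unidirectional`.
#'
#' @param motif Character vector of concrete WRCH 4-mers.
#' @return Character vector with values in
#'   `c("palindromic", "bidirectional", "unidirectional")`.
#' @examples
#' classify_orientation(c("AGCT", "AGCA", "AACT"))
#' @export
classify_orientation <- function(motif) {
  wrch <- wrch_motifs()
  if (any(!motif %in% wrch)) {
    stop("not a WRCH motif: ",
         paste(unique(motif[!motif %in% wrch]), collapse = ", "), call. = FALSE)
  }
  rc <- revcomp(motif)
  ifelse(rc == motif, "palindromic",
         ifelse(rc %in% wrch, "bidirectional", "unidirectional"))
}

#' Scan a sequence for WRCH motifs on both strands
#'
#' Reports every top-strand WRCH occurrence and every bottom-strand
#' occurrence (detected as a top-strand DGYW match). All coordinates are
#' 1-based top-strand positions. `start` is the first base of the motif
#' span on the top strand; `target_c` is the top-strand coordinate of the
#' deaminated base: the C at `start + 2` for top-strand hits and the G at
#' `start + 1` (paired with the bottom-strand C) for bottom-strand hits.
#' `motif` is always given 5'->3' on its own strand. Positions containing
#' `N` never produce hits; overlapping hits are all reported.
#'
#' @param seq Sequence string over `{A,C,G,T,N}`.
#' @param name Sequence identifier recorded in the output.
#' @return `data.table` with columns `seq_name`, `motif`, `strand`
#'   (`"top"`/`"bottom"`), `start`, `target_c`, `orientation`, sorted by
#'   `start` then strand (top first).
#' @export
scan_wrch <- function(seq, name = "seq") {
  check_dna(seq, allow_n = TRUE, allow_empty = TRUE)
  n <- nchar(seq)
  empty <- data.table(seq_name = character(), motif = character(),
                      strand = character(), start = integer(),
                      target_c = integer(), orientation = character())
  if (n < 4L) return(empty)
  starts <- seq_len(n - 3L)
  kmers <- substring(seq, starts, starts + 3L)
  wrch <- wrch_motifs()
  dgyw <- dgyw_motifs()
  top_i <- which(kmers %in% wrch)
  bot_i <- which(kmers %in% dgyw)
  hits <- rbindlist(list(
    data.table(seq_name = name, motif = kmers[top_i], strand = "top",
               start = starts[top_i], target_c = starts[top_i] + 2L),
    data.table(seq_name = name, motif = revcomp(kmers[bot_i]), strand = "bottom",
               start = starts[bot_i], target_c = starts[bot_i] + 1L)
  ))
  if (nrow(hits) == 0L) return(empty)
  hits[, orientation := classify_orientation(motif)]
  hits[order(start, strand == "bottom")]
}

#' Extract the k-mer context window centred on a cytosine
#'
#' Returns the `k`-mer (default 15) whose central base is the C at
#' `c_pos`, together with the central WRCH motif when present (window
#' positions 6-9 for k = 15, i.e. 5' flank of 5 nt + motif + 3' flank).
#' Windows that would run off either sequence end, or that contain a
#' non-ACGT base, are dropped (`NULL`), mirroring the exclusion of
#' sequences with unknown bases.
#'
#' @param seq Sequence string.
#' @param c_pos 1-based position of a C in `seq`.
#' @param k Odd window size, default 15.
#' @return A list of class `context_window` with elements `kmer`,
#'   `central_c_pos`, `motif` (`NA` if the central 4-mer is not WRCH),
#'   or `NULL` when the window is ineligible.
#' @export
extract_context <- function(seq, c_pos, k = 15L) {
  check_dna(seq)
  stopifnot(k %% 2L == 1L, k >= 5L)
  if (c_pos < 1L || c_pos > nchar(seq) || substr(seq, c_pos, c_pos) != "C") {
    stop("base at c_pos is not C", call. = FALSE)
  }
  half <- (k - 1L) %/% 2L
  lo <- c_pos - half
  hi <- c_pos + half
  if (lo < 1L || hi > nchar(seq)) return(NULL)
  kmer <- substr(seq, lo, hi)
  if (grepl("N", kmer, fixed = TRUE)) return(NULL)
  motif <- substr(kmer, half - 1L, half + 2L)  # WRC*H* with C central
  structure(list(kmer = kmer, central_c_pos = c_pos,
                 motif = if (motif %in% wrch_motifs()) motif else NA_character_),
            class = "context_window")
}

#' Count pyrimidine dimers in a segment
#'
#' Number of positions i such that bases i and i+1 are both pyrimidines
#' (C or T); overlapping occurrences are all counted.
#'
#' @param segment Sequence string over `{A,C,G,T}` (may be empty).
#' @return Non-negative integer.
#' @examples
#' count_pypy("CCTACATGC")  # 2 (CC and CT overlap)
#' count_pypy("TACGGTAGT")  # 0
#' @export
count_pypy <- function(segment) {
  if (!is.character(segment) || length(segment) != 1L || is.na(segment)) {
    stop("segment must be a single string", call. = FALSE)
  }
  if (!grepl("^[ACGT]*$", segment)) {
    stop("segment contains characters outside {A,C,G,T}", call. = FALSE)
  }
  if (nchar(segment) < 2L) return(0L)
  py <- seq_chars(segment) %in% c("C", "T")
  sum(py[-length(py)] & py[-1L])
}

#' PyPy content of a context window
#'
#' Applies [count_pypy()] to the configured slice of a 15-mer context
#' window. The default segment, `"wrch5"`, is the motif plus 5 nt on
#' either side (window positions 1-14 of a 15-mer); `"full15"` uses the
#' whole window. With `include_motif = FALSE`, dimers lying entirely
#' inside the central motif (window positions 6-9) are excluded.
#'
#' @param window A `context_window` from [extract_context()], or a bare
#'   15-mer string.
#' @param mode `"wrch5"` (default) or `"full15"`.
#' @param include_motif Count motif-internal dimers (default `TRUE`).
#' @return Non-negative integer.
#' @export
pypy_content <- function(window, mode = c("wrch5", "full15"),
                         include_motif = TRUE) {
  mode <- match.arg(mode)
  kmer <- if (inherits(window, "context_window")) window$kmer else window
  check_dna(kmer, allow_n = FALSE, what = "window")
  k <- nchar(kmer)
  stopifnot(k %% 2L == 1L, k >= 9L)
  half <- (k - 1L) %/% 2L
  motif_lo <- half - 1L                 # first base of WRCH within window
  lo <- max(1L, motif_lo - 5L)
  hi <- if (mode == "wrch5") min(k, motif_lo + 3L + 5L) else k
  if (mode == "full15") lo <- 1L
  seg <- substr(kmer, lo, hi)
  n <- count_pypy(seg)
  if (!include_motif) {
    inner <- substr(kmer, motif_lo, motif_lo + 3L)
    n <- n - count_pypy(inner)
  }
  as.integer(n)
}

#' Span of a symmetric context swap
#'
#' Exchanging the `flank` bases on each side of a 4-nt motif replaces a
#' contiguous stretch of `2 * flank + 4` nucleotides: 22 nt for +/-9 bp,
#' 16 nt for +/-6 bp, 10 nt for +/-3 bp.
#'
#' @param flank Non-negative integer flank length in bp.
#' @return Integer span in nt.
#' @export
context_swap_span <- function(flank) {
  stopifnot(all(flank >= 0L))
  as.integer(2L * flank + 4L)
}

#' Pair palindromic hits into G/C coordinate doublets
#'
#' For palindromic motifs (AGCT, TGCA) each motif instance produces a
#' top-strand hit (target C) and a bottom-strand hit (target G) one base
#' apart. This helper collapses a hit table to one row per motif
#' instance with the G and C coordinates, the presentation used for
#' double-peak mutation profiles (e.g. "311G/312C").
#'
#' @param hits A hit table from [scan_wrch()].
#' @return `data.table` with columns `seq_name`, `motif`, `start`,
#'   `g_pos`, `c_pos`.
#' @export
palindromic_pairs <- function(hits) {
  h <- as.data.table(hits)[orientation == "palindromic"]
  if (nrow(h) == 0L) {
    return(data.table(seq_name = character(), motif = character(),
                      start = integer(), g_pos = integer(), c_pos = integer()))
  }
  h[, .(g_pos = target_c[strand == "bottom"],
        c_pos = target_c[strand == "top"]),
    by = .(seq_name, motif, start)]
}

#' Write a motif hit table to TSV
#'
#' @param hits Hit table from [scan_wrch()]; coordinates stay 1-based.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  fwrite(as.data.table(hits), path, sep = "\t")
  invisible(path)
}
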