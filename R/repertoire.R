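# Repertoire statistics over germline-aligned V-region sequences:
# context grouping by C-centred 15-mer, coverage filtering, mutability
# and mutation-frequency estimates versus PyPy content, and per-region
# mutation loads.

REGION_LABELS <- c("FWR1", "CDR1", "FWR2", "CDR2", "FWR3", "CDR3")

#' Build a validated repertoire of germline-aligned records
#'
#' A repertoire is a table of clonally independent observations, each an
#' observed V-region sequence paired with its germline of identical
#' length (substitution-only alignment; indel- or N-containing records
#' are rejected, with a message reporting how many were dropped). The
#' region map labels FWR1..CDR3 intervals in germline coordinates and is
#' shared by all records (records from different germline genes may
#' still be pooled when their coordinate systems agree).
#'
#' @param record_id Character vector of unique record identifiers.
#' @param germline,observed Character vectors of equal-length sequences.
#' @param region_map Optional `data.frame` with columns `region`,
#'   `start`, `end` (1-based inclusive, disjoint, ordered).
#' @return A `data.table` of class `shm_repertoire` with columns
#'   `record_id`, `germline`, `observed` and a `region_map` attribute.
#' @export
repertoire <- function(record_id, germline, observed, region_map = NULL) {
  stopifnot(length(record_id) == length(germline),
            length(germline) == length(observed))
  germline <- toupper(germline)
  observed <- toupper(observed)
  ok_alpha <- grepl("^[ACGT]+$", germline) & grepl("^[ACGT]+$", observed)
  ok_len <- nchar(germline) == nchar(observed)
  keep <- ok_alpha & ok_len
  if (any(!keep)) {
    message(sum(!keep), " record(s) rejected (N bases, empty, or length mismatch)")
  }
  rec <- data.table(record_id = as.character(record_id)[keep],
                    germline = germline[keep], observed = observed[keep])
  if (anyDuplicated(rec$record_id)) stop("duplicate record_id", call. = FALSE)
  if (!is.null(region_map)) {
    region_map <- validate_region_map(region_map, max(c(0L, nchar(rec$germline))))
  }
  setattr(rec, "region_map", region_map)
  setattr(rec, "class", c("shm_repertoire", class(rec)))
  rec
}

validate_region_map <- function(region_map, seq_len) {
  rm <- as.data.table(region_map)
  stopifnot(all(c("region", "start", "end") %in% names(rm)))
  rm <- rm[, .(region = as.character(region), start = as.integer(start),
               end = as.integer(end))]
  setorder(rm, start)
  if (any(rm$start > rm$end)) stop("region with start > end", call. = FALSE)
  if (nrow(rm) > 1L && any(rm$start[-1L] <= rm$end[-nrow(rm)])) {
    stop("region intervals overlap", call. = FALSE)
  }
  if (seq_len > 0L && any(rm$end > seq_len)) {
    stop("region interval exceeds sequence length", call. = FALSE)
  }
  rm
}

#' Read a repertoire from a TSV file
#'
#' Expects columns `record_id`, `germline`, `observed`;
#' AIRR-rearrangement style aliases (`sequence_id`,
#' `germline_alignment`, `sequence_alignment`) are accepted. Regions may
#' be supplied as a sidecar TSV (`region`, `start`, `end`).
#'
#' @param path Repertoire TSV path.
#' @param region_path Optional region-map TSV path.
#' @return An `shm_repertoire`.
#' @export
read_repertoire_tsv <- function(path, region_path = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  x <- fread(path, sep = "\t")
  aliases <- c(sequence_id = "record_id", germline_alignment = "germline",
               sequence_alignment = "observed")
  for (a in names(aliases)) {
    if (a %in% names(x) && !aliases[[a]] %in% names(x)) {
      setnames(x, a, aliases[[a]])
    }
  }
  stopifnot(all(c("record_id", "germline", "observed") %in% names(x)))
  rmap <- if (!is.null(region_path)) fread(region_path, sep = "\t") else NULL
  repertoire(x$record_id, x$germline, x$observed, region_map = rmap)
}

#' Call substitution mutations in one record
#'
#' One call per position where the observed base differs from the
#' germline base. Indels are outside the data model (records containing
#' them are rejected at load).
#'
#' @param germline,observed Equal-length sequence strings.
#' @return `data.table` with columns `position`, `from`, `to`.
#' @export
call_mutations <- function(germline, observed) {
  check_dna(germline, allow_n = FALSE)
  check_dna(observed, allow_n = FALSE)
  if (nchar(germline) != nchar(observed)) {
    stop("germline/observed length mismatch (", nchar(germline), " vs ",
         nchar(observed), ")", call. = FALSE)
  }
  g <- seq_chars(germline)
  o <- seq_chars(observed)
  i <- which(g != o)
  data.table(position = i, from = g[i], to = o[i])
}

# all eligible C-centred windows of one germline, as a data.table
germline_windows <- function(germline, k = 15L) {
  half <- (k - 1L) %/% 2L
  g <- seq_chars(germline)
  cpos <- which(g == "C")
  cpos <- cpos[cpos > half & cpos <= length(g) - half]
  if (length(cpos) == 0L) {
    return(data.table(central_c_pos = integer(), kmer = character(),
                      motif = character()))
  }
  kmer <- substring(germline, cpos - half, cpos + half)
  keep <- !grepl("N", kmer, fixed = TRUE)
  cpos <- cpos[keep]; kmer <- kmer[keep]
  motif <- substring(kmer, half - 1L, half + 2L)
  motif[!motif %in% wrch_motifs()] <- NA_character_
  data.table(central_c_pos = cpos, kmer = kmer, motif = motif)
}

#' Group a repertoire into C-centred context groups
#'
#' Windows are taken from the GERMLINE sequence (grouping by mutated
#' windows would destroy the key the mutation itself changed) around
#' every eligible C, keyed by the exact k-mer string: identical 15-mers
#' from different germline genes or positions pool into one group.
#' Coverage counts every observation of the window; `central_mutated`
#' counts observations whose base at the central position differs from
#' C.
#'
#' @param records An `shm_repertoire`.
#' @param k Window size, default 15.
#' @param wrch_only Keep only groups whose central 4-mer is a WRCH motif.
#' @param pypy_mode Segment for PyPy counting, see [pypy_content()].
#' @return `data.table` of class `shm_context_groups` with columns
#'   `kmer`, `motif`, `coverage`, `central_mutated`,
#'   `central_mutation_frequency`, `pypy`.
#' @export
build_context_groups <- function(records, k = 15L, wrch_only = FALSE,
                                 pypy_mode = c("wrch5", "full15")) {
  pypy_mode <- match.arg(pypy_mode)
  stopifnot(inherits(records, "shm_repertoire"))
  pieces <- list()
  for (germ in unique(records$germline)) {
    win <- germline_windows(germ, k)
    if (nrow(win) == 0L) next
    obs <- records$observed[records$germline == germ]
    m <- do.call(rbind, strsplit(obs, "", fixed = TRUE))
    mut <- vapply(win$central_c_pos, function(p) sum(m[, p] != "C"), integer(1L))
    win[, `:=`(coverage = length(obs), central_mutated = mut)]
    pieces[[length(pieces) + 1L]] <- win
  }
  if (length(pieces) == 0L) {
    out <- data.table(kmer = character(), motif = character(),
                      coverage = integer(), central_mutated = integer())
  } else {
    out <- rbindlist(pieces)[, .(coverage = sum(coverage),
                                 central_mutated = sum(central_mutated),
                                 motif = motif[1L]),
                             by = kmer]
  }
  if (wrch_only) out <- out[!is.na(motif)]
  out[, central_mutation_frequency := ifelse(coverage > 0L,
                                             central_mutated / coverage, NA_real_)]
  out[, pypy := vapply(kmer, pypy_content, integer(1L), mode = pypy_mode,
                       USE.NAMES = FALSE)]
  setcolorder(out, c("kmer", "motif", "coverage", "central_mutated",
                     "central_mutation_frequency", "pypy"))
  setattr(out, "class", c("shm_context_groups", class(out)))
  out[]
}

#' Filter context groups by coverage
#'
#' Groups observed fewer than `min_coverage` times are excluded
#' (default 30, the repertoire-analysis threshold). Idempotent and
#' monotone in `min_coverage`.
#'
#' @param groups An `shm_context_groups` table.
#' @param min_coverage Minimum retained coverage (inclusive).
#' @return Filtered table of the same class.
#' @export
filter_coverage <- function(groups, min_coverage = 30L) {
  out <- as.data.table(groups)[coverage >= min_coverage]
  setattr(out, "class", c("shm_context_groups", class(out)))
  out[]
}

weighted_pearson <- function(x, y, w) {
  if (length(x) < 2L || var(x) == 0 || var(y) == 0) return(NA_real_)
  cv <- cov.wt(cbind(x, y), wt = w / sum(w), cor = TRUE)
  unname(cv$cor[1L, 2L])
}

#' Motif mutability versus PyPy content
#'
#' For the context groups of one motif: at each PyPy level, the fraction
#' of unique 15-mers with any mutation at the central C ("mutability"),
#' plus the Pearson correlation between PyPy level and that fraction.
#' The default correlates over levels with weights equal to the number
#' of 15-mers per level (mirroring dot-size-weighted level plots);
#' `weighted = FALSE` gives the unweighted level correlation and
#' `by_level = FALSE` correlates PyPy content with the per-15-mer
#' mutated indicator instead.
#'
#' @param groups Context groups sharing one central motif.
#' @param weighted Weight levels by group counts (default `TRUE`).
#' @param by_level Correlate on levels (default) or individual 15-mers.
#' @return List of class `shm_correlation`: `motif`, `levels` (table of
#'   `pypy`, `n_kmers`, `fraction_mutated`), `r`, `r_squared`,
#'   `n_points`, `flag` (`NA` unless the correlation is undefined).
#' @export
mutability_by_pypy <- function(groups, weighted = TRUE, by_level = TRUE) {
  g <- as.data.table(groups)
  motif <- unique(g$motif)
  if (length(motif) > 1L) stop("groups span several motifs", call. = FALSE)
  lev <- g[, .(n_kmers = .N, fraction_mutated = mean(central_mutated > 0L)),
           by = pypy][order(pypy)]
  flag <- NA_character_
  if (by_level) {
    r <- weighted_pearson(lev$pypy, lev$fraction_mutated,
                          if (weighted) lev$n_kmers else rep(1, nrow(lev)))
    n_points <- nrow(lev)
  } else {
    r <- if (nrow(g) >= 2L && var(g$pypy) > 0 && var(g$central_mutated > 0) > 0) {
      cor(g$pypy, as.numeric(g$central_mutated > 0L))
    } else NA_real_
    n_points <- nrow(g)
  }
  if (is.na(r)) flag <- "correlation undefined (fewer than 2 levels or zero variance)"
  structure(list(motif = motif, levels = lev[], r = r,
                 r_squared = if (is.na(r)) NA_real_ else r^2,
                 n_points = n_points, flag = flag),
            class = "shm_correlation")
}

#' Central-C mutation frequency distributions per PyPy level
#'
#' Box-plot style summaries of `central_mutation_frequency` per PyPy
#' level, by default restricted to groups with at least one central
#' mutation (the mutated-15-mer presentation). Whiskers follow the Tukey
#' convention (most extreme values within 1.5 IQR of the quartiles).
#'
#' @param groups Context groups for one motif.
#' @param mutated_only Keep only groups with `central_mutated > 0`.
#' @return `data.table` with `pypy`, `n`, `median`, `q1`, `q3`,
#'   `whisker_lo`, `whisker_hi`; empty levels are omitted.
#' @export
frequency_by_pypy <- function(groups, mutated_only = TRUE) {
  g <- as.data.table(groups)
  if (mutated_only) g <- g[central_mutated > 0L]
  g[, {
    v <- central_mutation_frequency
    q <- quantile(v, c(.25, .5, .75), names = FALSE, type = 7)
    iqr <- q[3L] - q[1L]
    .(n = .N, median = q[2L], q1 = q[1L], q3 = q[3L],
      whisker_lo = min(v[v >= q[1L] - 1.5 * iqr]),
      whisker_hi = max(v[v <= q[3L] + 1.5 * iqr]))
  }, by = pypy][order(pypy)]
}

#' Per-subregion mutation load
#'
#' Mutation load of target cytosines per V-region subregion
#' (FWR1..CDR3): number of target C positions, observation counts and
#' aggregate mutation frequency (mutated observations over total
#' observations at those positions). With `wrch_only = TRUE` the targets
#' are the central Cs of WRCH motifs and the table is split by motif
#' with explicit zero rows for motifs absent from a region; otherwise
#' all germline Cs count. Positions outside the region map are reported
#' under `"unassigned"` with a warning.
#'
#' @param records An `shm_repertoire` whose `region_map` attribute is set.
#' @param wrch_only Restrict to WRCH-central cytosines and split by motif.
#' @return `data.table` with `region`, `motif`, `n_sites`,
#'   `n_observations`, `n_mutated`, `mutation_frequency`.
#' @export
subregion_summary <- function(records, wrch_only = FALSE) {
  stopifnot(inherits(records, "shm_repertoire"))
  rmap <- attr(records, "region_map")
  if (is.null(rmap)) stop("records carry no region_map", call. = FALSE)
  pieces <- list()
  for (germ in unique(records$germline)) {
    g <- seq_chars(germ)
    obs <- records$observed[records$germline == germ]
    m <- do.call(rbind, strsplit(obs, "", fixed = TRUE))
    if (wrch_only) {
      hits <- scan_wrch(germ)
      hits <- hits[strand == "top"]
      sites <- hits$target_c
      motifs <- hits$motif
    } else {
      sites <- which(g == "C")
      motifs <- rep("all", length(sites))
    }
    if (length(sites) == 0L) next
    reg <- rep("unassigned", length(sites))
    for (j in seq_len(nrow(rmap))) {
      inside <- sites >= rmap$start[j] & sites <= rmap$end[j]
      reg[inside] <- rmap$region[j]
    }
    mut <- vapply(sites, function(p) sum(m[, p] != g[p]), integer(1L))
    pieces[[length(pieces) + 1L]] <- data.table(
      region = reg, motif = motifs, n_sites = 1L,
      n_observations = length(obs), n_mutated = mut)
  }
  tab <- if (length(pieces)) {
    rbindlist(pieces)[, .(n_sites = sum(n_sites),
                          n_observations = sum(n_observations),
                          n_mutated = sum(n_mutated)),
                      by = .(region, motif)]
  } else {
    data.table(region = character(), motif = character(), n_sites = integer(),
               n_observations = integer(), n_mutated = integer())
  }
  if (any(tab$region == "unassigned")) {
    warning("target positions outside the region map counted as 'unassigned'")
  }
  # explicit zero rows: every region x every motif seen anywhere
  grid <- CJ(region = unique(c(rmap$region,
                               tab$region[tab$region == "unassigned"])),
             motif = unique(c(tab$motif, if (wrch_only) character() else "all")),
             unique = TRUE)
  tab <- tab[grid, on = c("region", "motif")]
  for (col in c("n_sites", "n_observations", "n_mutated")) {
    set(tab, which(is.na(tab[[col]])), col, 0L)
  }
  tab[, mutation_frequency := ifelse(n_observations > 0L,
                                     n_mutated / n_observations, 0)]
  tab[, region := factor(region, levels = c(rmap$region, "unassigned"))]
  setorder(tab, region, motif)
  tab[, region := as.character(region)]
  tab[]
}
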