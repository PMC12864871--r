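# Forward simulator of context-dependent cytosine deamination.
#
# The simulator is mechanistic-phenomenological: per-site independent
# Bernoulli deamination with a probability built from three axes --
# motif identity (base rate per WRCH motif and strand), local context
# (a multiplier keyed by the PyPy count of the motif +/-5 bp segment or
# by exact k-mer) and motif position (a multiplier per coordinate
# interval). It models no transcription, repair or processivity; those
# are not needed to exercise per-site frequency estimators.

#' Germline layout specification
#'
#' Describes a synthetic V-region germline: total length, motifs
#' planted at fixed 1-based starts, a FWR/CDR region map, background
#' base-composition weights, and whether accidental WRCH motifs are
#' allowed in the filler (by default the filler is WRCH-free on both
#' strands, by rejection sampling).
#'
#' @param length Total sequence length (nt).
#' @param motifs `data.frame` with columns `motif` (4-mer) and `start`
#'   (1-based); spans must not overlap.
#' @param region_map `data.frame` with `region`, `start`, `end`.
#' @param background Named composition weights for filler bases
#'   (default slightly GC-rich, as for Ig V exons).
#' @param allow_incidental Allow accidental WRCH/DGYW in filler.
#' @return List of class `germline_layout`.
#' @export
germline_layout <- function(length, motifs, region_map = NULL,
                            background = c(A = 0.25, C = 0.27, G = 0.27, T = 0.21),
                            allow_incidental = FALSE) {
  motifs <- as.data.table(motifs)
  stopifnot(all(c("motif", "start") %in% names(motifs)))
  motifs[, start := as.integer(start)]
  if (nrow(motifs) > 0L) {
    stopifnot(all(nchar(motifs$motif) == 4L),
              all(motifs$start >= 1L),
              all(motifs$start + 3L <= length))
    o <- order(motifs$start)
    s <- motifs$start[o]
    if (any(s[-1L] <= s[-length(s)] + 3L)) {
      stop("planted motifs overlap", call. = FALSE)
    }
  }
  if (!is.null(region_map)) region_map <- validate_region_map(region_map, length)
  structure(list(length = as.integer(length), motifs = motifs[],
                 region_map = region_map, background = background,
                 allow_incidental = allow_incidental),
            class = "germline_layout")
}

#' Default B1-8hi-like layout (synthetic)
#'
#' A synthetic stand-in for the murine B1-8hi V region (whose sequence
#' is not reproduced here): 336 nt with five palindromic AGCT motifs
#' planted so that their G/C target pairs fall at the characteristic
#' coordinates 27G/28C, 54G/55C, 89G/90C, 243G/244C and 311G/312C
#' (FWR3 -> CDR3 spacing 311 - 243 = 68 bp), plus an AGCA in CDR2 with
#' its G/C at 194/195. The region map is IMGT-like and chosen so the
#' planted motifs fall in the named subregions.
#'
#' @param with_agca Also plant the CDR2 AGCA motif (default `TRUE`).
#' @return A `germline_layout`.
#' @export
b18_layout <- function(with_agca = TRUE) {
  motifs <- data.table(motif = "AGCT", start = c(26L, 53L, 88L, 242L, 310L))
  if (with_agca) {
    motifs <- rbind(motifs, data.table(motif = "AGCA", start = 193L))
  }
  region_map <- data.frame(
    region = c("FWR1", "CDR1", "FWR2", "CDR2", "FWR3", "CDR3"),
    start = c(1L, 76L, 109L, 163L, 196L, 307L),
    end = c(75L, 108L, 162L, 195L, 306L, 336L))
  germline_layout(336L, motifs, region_map)
}

#' Build a germline sequence from a layout
#'
#' Deterministic for a fixed seed. Filler bases are drawn from the
#' background composition; unless `allow_incidental`, any accidental
#' WRCH occurrence (either strand) outside the planted spans is
#' resampled until the scan of the result reports planted motifs only.
#'
#' @param layout A `germline_layout`.
#' @param seed Integer seed.
#' @return List `sequence` (string), `region_map`, `layout`, `seed`.
#' @export
make_germline <- function(layout, seed = 1L) {
  stopifnot(inherits(layout, "germline_layout"))
  set.seed(seed)
  n <- layout$length
  bases <- sample(names(layout$background), n, replace = TRUE,
                  prob = layout$background)
  planted <- integer(0L)
  for (j in seq_len(nrow(layout$motifs))) {
    s <- layout$motifs$start[j]
    bases[s:(s + 3L)] <- seq_chars(layout$motifs$motif[j])
    planted <- c(planted, s:(s + 3L))
  }
  if (!layout$allow_incidental) {
    for (iter in 1:200) {
      seqstr <- paste(bases, collapse = "")
      hits <- scan_wrch(seqstr)
      extra <- unique(unlist(lapply(hits$start, function(s) s:(s + 3L))))
      extra <- setdiff(extra, planted)
      # resample only filler positions participating in unplanted hits
      bad <- integer(0L)
      for (s in hits$start) {
        span <- s:(s + 3L)
        if (!all(span %in% planted)) bad <- c(bad, setdiff(span, planted))
      }
      bad <- unique(bad)
      if (length(bad) == 0L) break
      bases[bad] <- sample(names(layout$background), length(bad),
                           replace = TRUE, prob = layout$background)
    }
    if (length(bad) > 0L) {
      stop("could not build WRCH-free filler; relax allow_incidental",
           call. = FALSE)
    }
  }
  list(sequence = paste(bases, collapse = ""),
       region_map = layout$region_map, layout = layout, seed = seed)
}

#' Mutation model for the deamination simulator
#'
#' Per-site deamination probability for a motif hit is
#' `base_rate[motif] * strand_factor * context_multiplier * position_multiplier`,
#' clipped to `[0, 1]`; non-target cytosines mutate at `background_rate`.
#' The context multiplier is keyed by the PyPy count of the motif
#' +/-5 bp segment (`pypy_multiplier`, a function or a numeric vector
#' indexed by `pypy + 1`) or overridden for exact k-mers
#' (`kmer_multiplier`, a named vector). The position multiplier is a
#' step function over coordinate intervals. Deaminated Cs resolve by
#' the substitution spectrum (C->T replication over uracil dominates;
#' C->G/C->A stand in for UNG/MSH2 processing, which is not modelled
#' mechanistically).
#'
#' @param base_rate Named per-motif deamination rates; motifs absent
#'   from the vector fall back to `default_rate`.
#' @param default_rate Rate for unlisted motifs.
#' @param bottom_strand_factor Multiplier applied to bottom-strand hits.
#' @param pypy_multiplier Function of the PyPy count, or numeric vector
#'   indexed by count + 1 (recycled at the top), or `NULL` for 1.
#' @param kmer_multiplier Named multipliers for exact 15-mers.
#' @param position_multiplier `data.frame` with `start`, `end`,
#'   `factor`, or `NULL` for 1 everywhere.
#' @param spectrum Named weights for `C->T`, `C->G`, `C->A`; must sum
#'   to 1.
#' @param background_rate Per-site rate at non-WRCH cytosines.
#' @return List of class `mutation_model`.
#' @export
mutation_model <- function(base_rate = c(AGCT = 0.08), default_rate = 0.02,
                           bottom_strand_factor = 1,
                           pypy_multiplier = NULL, kmer_multiplier = NULL,
                           position_multiplier = NULL,
                           spectrum = c(T = 0.8, G = 0.12, A = 0.08),
                           background_rate = 5e-4) {
  stopifnot(all(base_rate >= 0), default_rate >= 0, background_rate >= 0,
            abs(sum(spectrum) - 1) < 1e-9,
            all(names(spectrum) %in% c("T", "G", "A")))
  if (!is.null(position_multiplier)) {
    position_multiplier <- as.data.table(position_multiplier)
    stopifnot(all(c("start", "end", "factor") %in% names(position_multiplier)),
              all(position_multiplier$factor >= 0))
  }
  structure(list(base_rate = base_rate, default_rate = default_rate,
                 bottom_strand_factor = bottom_strand_factor,
                 pypy_multiplier = pypy_multiplier,
                 kmer_multiplier = kmer_multiplier,
                 position_multiplier = position_multiplier,
                 spectrum = spectrum, background_rate = background_rate),
            class = "mutation_model")
}

context_factor <- function(model, kmer, pypy) {
  if (!is.null(model$kmer_multiplier) && !is.na(kmer) &&
      kmer %in% names(model$kmer_multiplier)) {
    return(unname(model$kmer_multiplier[[kmer]]))
  }
  pm <- model$pypy_multiplier
  if (is.null(pm)) return(1)
  if (is.function(pm)) return(pm(pypy))
  unname(pm[[min(pypy + 1L, length(pm))]])
}

position_factor <- function(model, pos) {
  pm <- model$position_multiplier
  if (is.null(pm)) return(1)
  hit <- pm[pos >= start & pos <= end]
  if (nrow(hit) == 0L) 1 else hit$factor[1L]
}

#' Per-site deamination probabilities for a germline
#'
#' Applies the mutation-model rate algebra to every WRCH hit of the
#' germline (both strands) and to every remaining top-strand C
#' (background rate). For bottom-strand hits the mutated base in
#' top-strand coordinates is the G paired with the deaminated C.
#'
#' @param germline Germline sequence string.
#' @param model A `mutation_model`.
#' @param k Context window size used for the context multiplier.
#' @return `data.table` with `position`, `strand`, `motif`, `kmer`,
#'   `pypy`, `rate` (clipped to `[0, 1]`).
#' @export
site_rates <- function(germline, model, k = 15L) {
  stopifnot(inherits(model, "mutation_model"))
  hits <- scan_wrch(germline)
  rows <- list()
  if (nrow(hits) > 0L) {
    for (i in seq_len(nrow(hits))) {
      strand <- hits$strand[i]
      pos <- hits$target_c[i]
      # context window around the target C, on the strand carrying it
      if (strand == "top") {
        ctx <- tryCatch(extract_context(germline, pos, k), error = function(e) NULL)
      } else {
        rcseq <- revcomp(germline)
        rcpos <- nchar(germline) - pos + 1L
        ctx <- tryCatch(extract_context(rcseq, rcpos, k), error = function(e) NULL)
      }
      kmer <- if (is.null(ctx)) NA_character_ else ctx$kmer
      pypy <- if (is.null(ctx)) 0L else pypy_content(ctx)
      base <- if (hits$motif[i] %in% names(model$base_rate)) {
        model$base_rate[[hits$motif[i]]]
      } else model$default_rate
      rate <- base *
        (if (strand == "bottom") model$bottom_strand_factor else 1) *
        context_factor(model, kmer, pypy) *
        position_factor(model, pos)
      rows[[length(rows) + 1L]] <- data.table(
        position = pos, strand = strand, motif = hits$motif[i],
        kmer = kmer, pypy = pypy, rate = min(1, max(0, rate)))
    }
  }
  tab <- rbindlist(rows)
  g <- seq_chars(germline)
  other_c <- setdiff(which(g == "C"),
                     if (nrow(tab)) tab[strand == "top", position] else integer())
  bg <- data.table(position = other_c, strand = "top", motif = NA_character_,
                   kmer = NA_character_, pypy = NA_integer_,
                   rate = model$background_rate)
  out <- rbindlist(list(tab, bg))
  if (nrow(out) == 0L) return(out)
  # several motifs can target one site: combine as independent chances
  out <- out[, .(motif = motif[1L], kmer = kmer[1L], pypy = pypy[1L],
                 rate = if (.N == 1L) rate else 1 - prod(1 - rate)),
             by = .(position, strand)]
  setorder(out, position, strand)
  out[]
}

#' Simulate a mutated repertoire
#'
#' Draws `n_sequences` clonally independent records: each site mutates
#' by an independent Bernoulli trial at its model rate; a deaminated
#' top-strand C is replaced per the substitution spectrum, and a
#' bottom-strand deamination is written as the complementary change at
#' the paired top-strand G. Substitution-only output (no indels, no N).
#'
#' @param germ Output of [make_germline()] (or a list with `sequence`
#'   and `region_map`).
#' @param model A `mutation_model`.
#' @param n_sequences Number of records.
#' @param seed Integer seed.
#' @return An `shm_repertoire`; the `site_rates` table used is attached
#'   as attribute `truth`.
#' @export
simulate_repertoire <- function(germ, model, n_sequences, seed = 1L) {
  stopifnot(n_sequences >= 1L)
  set.seed(seed)
  rates <- site_rates(germ$sequence, model)
  g <- seq_chars(germ$sequence)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  spec <- model$spectrum
  obs <- rep(germ$sequence, n_sequences)
  nsite <- nrow(rates)
  if (nsite > 0L) {
    # records x sites Bernoulli field, drawn record-major for determinism
    hit <- matrix(runif(n_sequences * nsite), nrow = n_sequences,
                  byrow = TRUE) < rep(rates$rate, each = n_sequences)
    hit <- matrix(hit, nrow = n_sequences)
    mutated <- which(rowSums(hit) > 0L)
    for (i in mutated) {
      j <- which(hit[i, ])
      to <- sample(names(spec), length(j), replace = TRUE, prob = spec)
      s <- g
      s[rates$position[j]] <- ifelse(rates$strand[j] == "top", to,
                                     unname(comp[to]))
      obs[i] <- paste(s, collapse = "")
    }
  }
  rec <- repertoire(sprintf("rec%06d", seq_len(n_sequences)),
                    rep(germ$sequence, n_sequences), obs,
                    region_map = germ$region_map)
  setattr(rec, "truth", rates)
  rec
}

#' Configuration for the paired-end read simulator
#'
#' @param read_len_r1,read_len_r2 Mate lengths; `R1 + R2` must cover
#'   the amplicon plus `min_overlap` so the mates overlap.
#' @param error_rate Independent per-base error probability.
#' @param qual_mean,qual_sd Gaussian quality model, rounded and capped
#'   to `[2, 40]`.
#' @param depth Number of read pairs.
#' @param seed Integer seed.
#' @return List of class `read_sim_config`.
#' @export
read_sim_config <- function(read_len_r1 = 250L, read_len_r2 = 180L,
                            error_rate = 0.001, qual_mean = 37,
                            qual_sd = 3, depth = 1000L, seed = 1L) {
  stopifnot(error_rate >= 0, error_rate < 1, depth >= 1L)
  structure(list(read_len_r1 = as.integer(read_len_r1),
                 read_len_r2 = as.integer(read_len_r2),
                 error_rate = error_rate, qual_mean = qual_mean,
                 qual_sd = qual_sd, depth = as.integer(depth),
                 seed = as.integer(seed)),
            class = "read_sim_config")
}

add_seq_errors <- function(chars, error_rate) {
  n <- length(chars)
  err <- which(runif(n) < error_rate)
  if (length(err)) {
    alt <- vapply(chars[err], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1L), USE.NAMES = FALSE)
    chars[err] <- alt
  }
  chars
}

sim_quals <- function(n, cfg) {
  as.integer(pmin(40, pmax(2, round(rnorm(n, cfg$qual_mean, cfg$qual_sd)))))
}

#' Simulate overlapping paired-end reads over template sequences
#'
#' Each pair is drawn from one template (an amplicon molecule): read 1
#' is the 5' prefix, read 2 the reverse complement of the 3' suffix,
#' with independent per-base errors and Gaussian qualities. Templates
#' are cycled through uniformly at random when several are given.
#'
#' @param templates Character vector of template sequences (equal
#'   lengths), e.g. a simulated clone pool.
#' @param cfg A `read_sim_config`; mate geometry must cover the
#'   template with at least 1 nt of overlap.
#' @return List with `r1`, `r2` (`shm_reads`) and `template_index`
#'   (which template each pair came from).
#' @export
simulate_read_pairs <- function(templates, cfg = read_sim_config()) {
  stopifnot(inherits(cfg, "read_sim_config"), length(templates) >= 1L)
  len <- unique(nchar(templates))
  stopifnot(length(len) == 1L)
  if (cfg$read_len_r1 > len || cfg$read_len_r2 > len ||
      cfg$read_len_r1 + cfg$read_len_r2 < len + 1L) {
    stop("read geometry impossible: mates must each fit the amplicon and ",
         "overlap it fully", call. = FALSE)
  }
  set.seed(cfg$seed)
  idx <- sample.int(length(templates), cfg$depth, replace = TRUE)
  r1b <- character(cfg$depth); r2b <- character(cfg$depth)
  r1q <- vector("list", cfg$depth); r2q <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {
    tchars <- seq_chars(templates[idx[i]])
    f1 <- add_seq_errors(tchars[seq_len(cfg$read_len_r1)], cfg$error_rate)
    f2 <- add_seq_errors(tchars[(len - cfg$read_len_r2 + 1L):len], cfg$error_rate)
    r1b[i] <- paste(f1, collapse = "")
    r2b[i] <- revcomp(paste(f2, collapse = ""))
    r1q[[i]] <- sim_quals(cfg$read_len_r1, cfg)
    r2q[[i]] <- sim_quals(cfg$read_len_r2, cfg)
  }
  ids <- sprintf("sim_pair_%06d", seq_len(cfg$depth))
  r1 <- structure(list(id = ids, bases = r1b, quals = r1q), class = "shm_reads")
  r2 <- structure(list(id = ids, bases = r2b, quals = r2q), class = "shm_reads")
  list(r1 = r1, r2 = r2, template_index = idx)
}

#' Swap the context flanking a motif between two sites
#'
#' Replaces the `flank` bases on each side of the motif at `start`
#' (1-based first motif base) with the corresponding flanks from
#' around `donor_start`, emulating the +/-3, +/-6 and +/-9 bp
#' context-exchange constructs. The exchanged stretch spans
#' `2 * flank + 4` nt (see [context_swap_span()]).
#'
#' @param sequence Sequence string.
#' @param start Motif start at the acceptor site.
#' @param donor_start Motif start at the donor site.
#' @param flank Flank length in bp.
#' @return Modified sequence string.
#' @export
swap_motif_context <- function(sequence, start, donor_start, flank) {
  n <- nchar(sequence)
  stopifnot(start - flank >= 1L, start + 3L + flank <= n,
            donor_start - flank >= 1L, donor_start + 3L + flank <= n)
  ch <- seq_chars(sequence)
  acc <- c((start - flank):(start - 1L), (start + 4L):(start + 3L + flank))
  don <- c((donor_start - flank):(donor_start - 1L),
           (donor_start + 4L):(donor_start + 3L + flank))
  if (flank == 0L) return(sequence)
  ch[acc] <- ch[don]
  paste(ch, collapse = "")
}
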