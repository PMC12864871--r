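# Amplicon deep-sequencing (MutPE-seq style) quantification.
#
# The published processing chain (cutadapt / trimmomatic / FLASH /
# Bowtie2 / samtools) is re-specified here as simplified native
# operations implementing the same stated thresholds: sliding-window
# quality trimming (Q25, 5 nt), mate length filtering (200/100 nt),
# overlap merging (>=10 nt, <=10% mismatch), a +/-30 nt merged-length
# gate, gapless best-offset alignment to a single short amplicon
# reference, and a Q30 pileup. Gapless alignment is justified by the
# fixed short reference; reads failing placement are dropped and
# counted in the run log.

#' Rejection sentinel for pipeline stages
#'
#' Stages that can drop a read ([merge_pair()], [align_to_reference()])
#' return an `shm_reject` object carrying the reason instead of a
#' result; `is_rejected()` tests for it.
#'
#' @param x Object returned by a pipeline stage.
#' @return Logical scalar.
#' @export
is_rejected <- function(x) inherits(x, "shm_reject")

reject <- function(reason) structure(list(reason = reason), class = "shm_reject")

#' Sliding-window 3' quality trimming
#'
#' Scans 5' to 3' with a window of `window` bases; at the first window
#' whose mean quality drops below `min_mean_q` the read is cut there,
#' keeping any leading bases of the failing window whose individual
#' quality still meets the threshold (the trimmomatic SLIDINGWINDOW
#' convention). Reads shorter than the window are kept untouched.
#'
#' @param bases Read sequence string.
#' @param quals Integer vector of per-base Phred scores.
#' @param window Window width, default 5.
#' @param min_mean_q Mean-quality threshold, default 25.
#' @return List `bases`, `quals` of the trimmed read (possibly empty).
#' @export
sliding_window_trim <- function(bases, quals, window = 5L, min_mean_q = 25) {
  stopifnot(nchar(bases) == length(quals), window >= 1L)
  n <- length(quals)
  if (n < window) return(list(bases = bases, quals = quals))
  cs <- cumsum(c(0, quals))
  means <- (cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]) / window
  fail <- which(means < min_mean_q)
  if (length(fail) == 0L) return(list(bases = bases, quals = quals))
  cut <- fail[1L]                      # first failing window starts here
  keep <- cut - 1L
  while (keep < n && quals[keep + 1L] >= min_mean_q) keep <- keep + 1L
  list(bases = substr(bases, 1L, keep), quals = quals[seq_len(keep)])
}

#' Mate-pair minimum-length filter
#'
#' @param len1,len2 Post-trim lengths of read 1 and read 2.
#' @param min_r1,min_r2 Inclusive minima (defaults 200 and 100 nt).
#' @return Logical: keep the pair?
#' @export
length_filter <- function(len1, len2, min_r1 = 200L, min_r2 = 100L) {
  len1 >= min_r1 & len2 >= min_r2
}

#' Merge a mate pair into a combined single-end read
#'
#' Read 2 is reverse-complemented, then slid along read 1; the offset
#' maximising the number of matching bases over all overlaps of at
#' least `min_overlap` is chosen (ties broken toward the longer
#' overlap). The merge is accepted when the mismatch fraction within
#' the overlap is at most `max_mismatch_fraction`; in the overlap each
#' output base is the mate base with the higher quality (ties take read
#' 1) and its quality is the maximum of the two.
#'
#' @param r1,r2 Lists with `bases` (string) and `quals` (integer vector).
#' @param max_mismatch_fraction Maximum overlap mismatch fraction (0.10).
#' @param min_overlap Minimum overlap length (10 nt).
#' @return On success, a list `bases`, `quals`, `overlap_length`,
#'   `mismatch_fraction`; on failure an `shm_reject` carrying the
#'   reason (see [is_rejected()]).
#' @export
merge_pair <- function(r1, r2, max_mismatch_fraction = 0.10, min_overlap = 10L) {
  b1 <- utf8ToInt(r1$bases); q1 <- as.numeric(r1$quals)
  b2 <- utf8ToInt(revcomp(r2$bases)); q2 <- rev(as.numeric(r2$quals))
  n1 <- length(b1); n2 <- length(b2)
  if (n1 < min_overlap || n2 < min_overlap) {
    return(reject("reads shorter than min_overlap"))
  }
  best <- NULL
  for (d in 0L:(n1 - min_overlap)) {      # rc(r2) starts at r1 position d+1
    o <- min(n1 - d, n2)
    matches <- sum(b1[(d + 1L):(d + o)] == b2[1L:o])
    if (is.null(best) || matches > best$matches) {
      best <- list(d = d, o = o, matches = matches)
    }
  }
  mmf <- (best$o - best$matches) / best$o
  if (mmf > max_mismatch_fraction) {
    return(reject("no acceptable overlap"))
  }
  d <- best$d; o <- best$o
  ov1 <- (d + 1L):(d + o)
  take1 <- q1[ov1] >= q2[1L:o]
  ov_bases <- ifelse(take1, b1[ov1], b2[1L:o])
  ov_quals <- pmax(q1[ov1], q2[1L:o])
  bases <- c(b1[seq_len(d)], ov_bases, if (o < n2) b2[(o + 1L):n2] else integer())
  quals <- c(q1[seq_len(d)], ov_quals, if (o < n2) q2[(o + 1L):n2] else numeric())
  list(bases = intToUtf8(bases), quals = as.integer(round(quals)),
       overlap_length = o, mismatch_fraction = mmf)
}

#' Merged-read length gate
#'
#' Removes obviously erroneous mergers: keep iff the merged length is
#' within `tolerance` nt of the expected amplicon length.
#'
#' @param merged_length Length of the merged read.
#' @param expected_length Amplicon length.
#' @param tolerance Allowed absolute deviation (default 30 nt).
#' @return Logical.
#' @export
length_gate <- function(merged_length, expected_length, tolerance = 30L) {
  abs(merged_length - expected_length) <= tolerance
}

#' Gapless alignment of a merged read to the amplicon reference
#'
#' Places the read at the reference offset minimising mismatches
#' (leftmost offset on ties); rejects when the best mismatch rate
#' exceeds `max_mismatch_rate` or the read is longer than the
#' reference.
#'
#' @param bases Merged read sequence string.
#' @param ref Reference sequence string.
#' @param max_mismatch_rate Post-alignment mismatch ceiling (0.15).
#' @return On success a list `offset` (0-based), `mismatches`
#'   (1-based reference coordinates); on failure an `shm_reject`
#'   carrying the reason (see [is_rejected()]).
#' @export
align_to_reference <- function(bases, ref, max_mismatch_rate = 0.15) {
  b <- utf8ToInt(bases); r <- utf8ToInt(ref)
  n <- length(b); nr <- length(r)
  if (n == 0L) return(reject("empty read"))
  if (n > nr) return(reject("read longer than reference"))
  best_off <- 0L; best_mm <- n + 1L
  for (d in 0L:(nr - n)) {
    mm <- sum(b != r[(d + 1L):(d + n)])
    if (mm < best_mm) { best_mm <- mm; best_off <- d }
  }
  if (best_mm / n > max_mismatch_rate) {
    return(reject("mismatch rate above ceiling"))
  }
  mism <- best_off + which(b != r[(best_off + 1L):(best_off + n)])
  list(offset = best_off, mismatches = mism)
}

#' Quality-filtered pileup over the reference
#'
#' Counts A/C/G/T observations per reference position among aligned
#' read bases with quality at least `min_base_q` (default 30).
#'
#' @param alignments List of lists, each with `offset` (0-based),
#'   `bases` (string) and `quals` (integer vector) of an aligned read.
#' @param ref Reference sequence string.
#' @param min_base_q Per-base quality threshold.
#' @return `data.table` with `position`, `ref_base`, `A`, `C`, `G`,
#'   `T`, `depth`.
#' @export
build_pileup <- function(alignments, ref, min_base_q = 30) {
  nr <- nchar(ref)
  pos_all <- integer(0L); base_all <- integer(0L)
  base_code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  for (al in alignments) {
    keep <- al$quals >= min_base_q
    if (!any(keep)) next
    b <- utf8ToInt(al$bases)[keep]
    p <- al$offset + which(keep)
    code <- integer(length(b))
    code[b == 65L] <- 1L; code[b == 67L] <- 2L
    code[b == 71L] <- 3L; code[b == 84L] <- 4L
    ok <- code > 0L & p >= 1L & p <= nr
    pos_all <- c(pos_all, p[ok]); base_all <- c(base_all, code[ok])
  }
  counts <- matrix(tabulate((pos_all - 1L) * 4L + base_all, nbins = 4L * nr),
                   nrow = 4L)
  out <- data.table(position = seq_len(nr), ref_base = seq_chars(ref),
                    A = counts[1L, ], C = counts[2L, ],
                    G = counts[3L, ], T = counts[4L, ])
  out[, depth := A + C + G + T]
  out[]
}

#' Per-position mutation frequencies from a pileup
#'
#' Total mutation frequency is the fraction of mutated bases over all
#' bases covering the position; per-substitution frequencies give the
#' spectrum. Zero-depth positions get `NA` (never 0/0).
#'
#' @param pileup A pileup table from [build_pileup()].
#' @param sample_id Sample label stored in the result.
#' @return `data.table` of class `shm_profile` with `position`,
#'   `ref_base`, `depth`, `frequency` and `to_A`, `to_C`, `to_G`,
#'   `to_T` substitution frequencies.
#' @export
mutation_frequency <- function(pileup, sample_id = "sample") {
  p <- as.data.table(pileup)
  cnt <- as.matrix(p[, .(A, C, G, T)])
  ref_idx <- match(p$ref_base, c("A", "C", "G", "T"))
  ref_cnt <- cnt[cbind(seq_len(nrow(cnt)), ref_idx)]
  freq <- ifelse(p$depth > 0L, (p$depth - ref_cnt) / p$depth, NA_real_)
  sub <- sweep(cnt, 1L, pmax(p$depth, 1L), "/")
  sub[p$depth == 0L, ] <- NA_real_
  sub[cbind(seq_len(nrow(sub)), ref_idx)] <- 0
  out <- data.table(position = p$position, ref_base = p$ref_base,
                    depth = p$depth, frequency = freq,
                    to_A = sub[, 1L], to_C = sub[, 2L],
                    to_G = sub[, 3L], to_T = sub[, 4L])
  setattr(out, "sample_id", sample_id)
  setattr(out, "class", c("shm_profile", class(out)))
  out[]
}

#' Normalized mutation frequency
#'
#' Each position's frequency divided by the sum of frequencies over the
#' entire profiled region, removing between-sample differences in
#' overall mutation load; values sum to 1. An all-zero profile is an
#' error (the quantity is undefined), never silently zero.
#'
#' @param profile An `shm_profile` (or numeric vector of frequencies).
#' @return The profile with a `normalized` column added (or the
#'   normalized numeric vector).
#' @export
normalize_profile <- function(profile) {
  if (is.numeric(profile)) {
    tot <- sum(profile, na.rm = TRUE)
    if (!is.finite(tot) || tot <= 0) {
      stop("normalized frequency undefined: profile has no mutated position",
           call. = FALSE)
    }
    return(profile / tot)
  }
  p <- as.data.table(profile)
  tot <- sum(p$frequency, na.rm = TRUE)
  if (!is.finite(tot) || tot <= 0) {
    stop("normalized frequency undefined: profile has no mutated position",
         call. = FALSE)
  }
  p[, normalized := frequency / tot]
  setattr(p, "class", c("shm_profile", class(p)))
  p[]
}

#' Two-sample comparison of one position between sample groups
#'
#' Unpaired two-tailed Student's t-test with pooled variance (the
#' classical test; Welch's unequal-variance form via
#' `var_equal = FALSE`). When both groups are constant and equal the
#' statistic is undefined and `p = 1` by convention, flagged.
#'
#' @param values_a,values_b Numeric vectors (each length >= 2), e.g.
#'   normalized frequencies of one position across replicate samples.
#' @param var_equal Pooled-variance Student form (default `TRUE`).
#' @param alpha Significance threshold for the `significant` label.
#' @return List of class `shm_position_test`: `t_statistic`, `df`,
#'   `p_value`, `significant`, `flag`.
#' @export
compare_position <- function(values_a, values_b, var_equal = TRUE,
                             alpha = 0.05) {
  stopifnot(length(values_a) >= 2L, length(values_b) >= 2L)
  flag <- NA_character_
  if (var(values_a) == 0 && var(values_b) == 0) {
    if (mean(values_a) == mean(values_b)) {
      return(structure(list(t_statistic = 0, df = NA_real_, p_value = 1,
                            significant = FALSE,
                            flag = "zero variance in both groups; p = 1 by convention"),
                       class = "shm_position_test"))
    }
    return(structure(list(t_statistic = Inf * sign(mean(values_a) - mean(values_b)),
                          df = NA_real_, p_value = 0, significant = TRUE,
                          flag = "zero variance in both groups, unequal means"),
                     class = "shm_position_test"))
  }
  ht <- stats::t.test(values_a, values_b, var.equal = var_equal)
  structure(list(t_statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, significant = ht$p.value < alpha,
                 flag = flag),
            class = "shm_position_test")
}

#' Run the full amplicon quantification pipeline on mate pairs
#'
#' trim -> length filter -> merge -> length gate -> align -> pileup ->
#' per-position (normalized) mutation frequencies. Every input pair is
#' accounted for exactly once in the returned tally.
#'
#' @param r1,r2 `shm_reads` mate sets of equal length (see
#'   [read_fastq()]).
#' @param ref Amplicon reference sequence string.
#' @param config Threshold list, see [mutpe_config()].
#' @return List of class `shm_mutpe_run`: `profile` (an `shm_profile`
#'   with `normalized` when defined), `pileup`, `tally` (named integer
#'   vector over input / rejection / aligned classes).
#' @export
mutpe_run <- function(r1, r2, ref, config = mutpe_config()) {
  stopifnot(length(r1$bases) == length(r2$bases))
  check_dna(ref, allow_n = FALSE, what = "reference")
  n <- length(r1$bases)
  tally <- c(input_pairs = n, rejected_length = 0L, rejected_merge = 0L,
             rejected_gate = 0L, rejected_align = 0L, aligned = 0L)
  clip <- config$primer_clip_5p
  alignments <- vector("list", n)
  for (i in seq_len(n)) {
    a <- list(bases = r1$bases[i], quals = r1$quals[[i]])
    b <- list(bases = r2$bases[i], quals = r2$quals[[i]])
    if (clip > 0L) {
      a <- list(bases = substr(a$bases, clip + 1L, nchar(a$bases)),
                quals = a$quals[-seq_len(clip)])
      b <- list(bases = substr(b$bases, clip + 1L, nchar(b$bases)),
                quals = b$quals[-seq_len(clip)])
    }
    a <- sliding_window_trim(a$bases, a$quals, config$trim_window, config$trim_min_q)
    b <- sliding_window_trim(b$bases, b$quals, config$trim_window, config$trim_min_q)
    if (!length_filter(nchar(a$bases), nchar(b$bases),
                       config$min_len_r1, config$min_len_r2)) {
      tally["rejected_length"] <- tally["rejected_length"] + 1L
      next
    }
    m <- merge_pair(a, b, config$max_mismatch_fraction, config$min_overlap)
    if (is_rejected(m)) {
      tally["rejected_merge"] <- tally["rejected_merge"] + 1L
      next
    }
    if (!length_gate(nchar(m$bases), nchar(ref), config$length_tolerance)) {
      tally["rejected_gate"] <- tally["rejected_gate"] + 1L
      next
    }
    al <- align_to_reference(m$bases, ref, config$max_mismatch_rate)
    if (is_rejected(al)) {
      tally["rejected_align"] <- tally["rejected_align"] + 1L
      next
    }
    tally["aligned"] <- tally["aligned"] + 1L
    alignments[[i]] <- list(offset = al$offset, bases = m$bases, quals = m$quals)
  }
  alignments <- alignments[!vapply(alignments, is.null, logical(1L))]
  pileup <- build_pileup(alignments, ref, config$min_base_q)
  profile <- mutation_frequency(pileup, sample_id = config$sample_id)
  profile <- tryCatch(normalize_profile(profile), error = function(e) profile)
  structure(list(profile = profile, pileup = pileup, tally = tally),
            class = "shm_mutpe_run")
}

#' Default amplicon-quantification thresholds
#'
#' Every default is the published processing value: Q25 mean over a
#' 5-nt window for trimming, 200/100 nt mate length minima, 10% overlap
#' mismatch with a 10-nt minimum overlap, a +/-30 nt merged-length
#' gate, a Q30 pileup threshold, and a package-default post-alignment
#' mismatch ceiling of 0.15 (not stated in the published chain).
#'
#' @param ... Named overrides of any threshold.
#' @return Named list of thresholds.
#' @export
mutpe_config <- function(...) {
  cfg <- list(trim_window = 5L, trim_min_q = 25, min_len_r1 = 200L,
              min_len_r2 = 100L, max_mismatch_fraction = 0.10,
              min_overlap = 10L, length_tolerance = 30L,
              max_mismatch_rate = 0.15, min_base_q = 30,
              primer_clip_5p = 0L, sample_id = "sample")
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown mutpe config key: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  cfg
}

#' Write a mutation profile to TSV
#'
#' @param profile An `shm_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  fwrite(as.data.table(profile), path, sep = "\t")
  invisible(path)
}
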