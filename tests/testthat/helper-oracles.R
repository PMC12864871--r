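# Independent oracles and small generators shared across the suite.

rand_dna <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Brute-force two-strand WRCH matcher: tests every offset of the
# sequence (top) and of its reverse complement (bottom, mapped back to
# top-strand coordinates) against the 12 concrete motifs. Independent
# of the DGYW route used by scan_wrch().
oracle_scan <- function(seq) {
  motifs <- c("AACA", "AACC", "AACT", "AGCA", "AGCC", "AGCT",
              "TACA", "TACC", "TACT", "TGCA", "TGCC", "TGCT")
  n <- nchar(seq)
  out <- list()
  if (n >= 4L) {
    for (i in seq_len(n - 3L)) {
      k <- substr(seq, i, i + 3L)
      if (k %in% motifs) {
        out[[length(out) + 1L]] <- data.frame(
          motif = k, strand = "top", start = i, target_c = i + 2L)
      }
    }
    rc <- shmgrammar::revcomp(seq)
    for (j in seq_len(n - 3L)) {
      k <- substr(rc, j, j + 3L)
      if (k %in% motifs) {
        start_top <- n - (j + 3L) + 1L   # first motif base in top coords
        out[[length(out) + 1L]] <- data.frame(
          motif = k, strand = "bottom", start = start_top,
          target_c = start_top + 1L)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(motif = character(), strand = character(),
                      start = integer(), target_c = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$strand == "bottom"), , drop = FALSE]
}

# textbook two-pass Pearson correlation (optionally weighted)
oracle_pearson <- function(x, y, w = rep(1, length(x))) {
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  sxy <- sum(w * (x - mx) * (y - my))
  sxy / sqrt(sum(w * (x - mx)^2) * sum(w * (y - my)^2))
}

# brute-force regrouping of repertoire windows by 15-mer string
oracle_context_groups <- function(records, k = 15L) {
  half <- (k - 1L) %/% 2L
  rows <- list()
  for (i in seq_len(nrow(records))) {
    g <- strsplit(records$germline[i], "")[[1L]]
    o <- strsplit(records$observed[i], "")[[1L]]
    for (p in seq_along(g)) {
      if (g[p] != "C" || p <= half || p > length(g) - half) next
      kmer <- paste(g[(p - half):(p + half)], collapse = "")
      if (grepl("N", kmer)) next
      rows[[length(rows) + 1L]] <- data.frame(
        kmer = kmer, mutated = o[p] != "C")
    }
  }
  df <- do.call(rbind, rows)
  agg <- aggregate(mutated ~ kmer, df, function(v) c(n = length(v), m = sum(v)))
  data.frame(kmer = agg$kmer, coverage = agg$mutated[, "n"],
             central_mutated = agg$mutated[, "m"])
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# five-motif layout with well-separated planted rates (10-fold range),
# used by the parameter-recovery checks
recovery_world <- function() {
  motifs <- data.frame(motif = c("AGCT", "TGCT", "AGCA", "TACT", "AACC"),
                       start = c(30L, 80L, 130L, 180L, 230L))
  layout <- shmgrammar::germline_layout(300L, motifs)
  rates <- c(AGCT = 0.20, TGCT = 0.112, AGCA = 0.063, TACT = 0.035,
             AACC = 0.02)
  model <- shmgrammar::mutation_model(base_rate = rates, default_rate = 0.01,
                                      background_rate = 0)
  list(layout = layout, rates = rates, model = model, motifs = motifs)
}
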