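# Amplicon quantification: trimming, filtering, merging, alignment,
# pileup, frequencies, normalization and position tests.

mk_read <- function(bases, q = 40) {
  list(bases = bases, quals = rep(as.integer(q), nchar(bases)))
}

test_that("sliding-window trimming follows the windowed Q25 rule", {
  r <- sliding_window_trim("ACGTACGTAC", rep(40L, 10L))
  expect_identical(nchar(r$bases), 10L)                  # untouched
  # first failing 5-window at base 4 (mean 22); bases 4,5 stay (q >= 25)
  r <- sliding_window_trim("ACGTACGTAC", c(rep(40L, 5L), rep(10L, 5L)))
  expect_identical(r$bases, "ACGTA")
  expect_identical(r$quals, rep(40L, 5L))
  r <- sliding_window_trim("ACGTACGTAC", rep(10L, 10L))
  expect_identical(nchar(r$bases), 0L)                   # all poor -> empty
  # independent window-scan oracle on random quality strings
  set.seed(13)
  for (i in 1:50) {
    n <- sample(5:40, 1L)
    q <- sample(2:40, n, replace = TRUE)
    got <- length(sliding_window_trim(strrep("A", n), q)$quals)
    fail <- which(vapply(seq_len(n - 4L), function(j) {
      mean(q[j:(j + 4L)]) < 25
    }, logical(1L)))
    want <- if (length(fail) == 0L) n else {
      keep <- fail[1L] - 1L
      while (keep < n && q[keep + 1L] >= 25) keep <- keep + 1L
      keep
    }
    expect_identical(got, want)
  }
})

test_that("mate length filter uses inclusive 200/100 minima", {
  expect_true(length_filter(250L, 150L))
  expect_true(length_filter(200L, 100L))
  expect_false(length_filter(199L, 150L))
  expect_false(length_filter(250L, 99L))
})

test_that("merge_pair reconstructs fragments and enforces 10% mismatch", {
  set.seed(17)
  frag <- rand_dna(60)
  r1 <- mk_read(substr(frag, 1L, 40L))
  r2 <- mk_read(revcomp(substr(frag, 21L, 60L)))
  m <- merge_pair(r1, r2)
  expect_identical(m$bases, frag)
  expect_identical(m$overlap_length, 20L)
  expect_identical(m$mismatch_fraction, 0)
  # 2 mismatches in a 20-base overlap (10%) accepted, 3 (15%) rejected
  flip <- function(s, i) { substr(s, i, i) <- chartr("ACGT", "TGCA", substr(s, i, i)); s }
  # r2 positions 21-40 are the overlapped 20 bases (fragment 21-40)
  r2b <- r2
  for (i in c(25L, 30L)) r2b$bases <- flip(r2b$bases, i)
  m2 <- merge_pair(r1, r2b)
  expect_false(is_rejected(m2))
  expect_equal(m2$mismatch_fraction, 0.10)
  r2c <- r2b
  r2c$bases <- flip(r2c$bases, 35L)
  expect_true(is_rejected(merge_pair(r1, r2c)))
  # the higher-quality mate wins disagreements in the overlap
  r1q <- mk_read(substr(frag, 1L, 40L), q = 20)
  m3 <- merge_pair(r1q, r2b)
  expect_identical(m3$bases, paste0(substr(frag, 1L, 20L),
                                    revcomp(r2b$bases)))
  expect_true(is_rejected(merge_pair(mk_read("ACGTA"), mk_read("ACGTA"))))
})

test_that("length gate is inclusive at +/-30 nt", {
  expect_true(length_gate(300L, 300L))
  expect_true(length_gate(270L, 300L))
  expect_true(length_gate(330L, 300L))
  expect_false(length_gate(331L, 300L))
  expect_false(length_gate(269L, 300L))
})

test_that("gapless alignment finds the minimal-mismatch offset", {
  set.seed(19)
  ref <- rand_dna(120)
  expect_identical(align_to_reference(ref, ref)$offset, 0L)
  read <- substr(ref, 31L, 90L)
  al <- align_to_reference(read, ref)
  expect_identical(al$offset, 30L)
  expect_length(al$mismatches, 0L)
  mut <- read
  substr(mut, 10L, 10L) <- setdiff(c("A", "C", "G", "T"),
                                   substr(mut, 10L, 10L))[1L]
  al2 <- align_to_reference(mut, ref)
  expect_identical(al2$offset, 30L)
  expect_identical(al2$mismatches, 40L)   # reference coordinate 30 + 10
  # unrelated random read: expected mismatch rate ~0.75 >> ceiling
  expect_true(is_rejected(align_to_reference(rand_dna(60), ref)))
})

test_that("pileup respects the Q30 threshold and counts by base", {
  ref <- "ACGTACGT"
  als <- c(
    replicate(3L, list(offset = 0L, bases = ref, quals = rep(40L, 8L)),
              simplify = FALSE),
    list(list(offset = 2L, bases = "GTAC", quals = c(40L, 29L, 40L, 40L))))
  p <- build_pileup(als, ref)
  expect_identical(p$depth, c(3L, 3L, 4L, 3L, 4L, 4L, 3L, 3L))  # q29 excluded
  expect_identical(p$G[3L], 4L)
  expect_true(all(p$depth <= 4L))
})

test_that("mutation frequencies are per-position ratios with spectrum", {
  p <- data.table::data.table(position = 1:3, ref_base = c("C", "C", "C"),
                              A = c(0L, 0L, 0L), C = c(98L, 100L, 90L),
                              G = c(0L, 0L, 4L), T = c(2L, 0L, 6L))
  p$depth <- p$A + p$C + p$G + p$T
  prof <- mutation_frequency(p)
  expect_equal(prof$frequency, c(0.02, 0, 0.10))
  expect_equal(prof$to_T, c(0.02, 0, 0.06))
  expect_equal(prof$to_G, c(0, 0, 0.04))
  zero <- data.table::data.table(position = 1L, ref_base = "A", A = 0L,
                                 C = 0L, G = 0L, T = 0L, depth = 0L)
  expect_true(is.na(mutation_frequency(zero)$frequency))
})

test_that("normalization sums to one and is scale invariant", {
  expect_equal(normalize_profile(c(0.02, 0.03, 0.05)), c(0.2, 0.3, 0.5))
  expect_equal(normalize_profile(c(0, 0, 0.07)), c(0, 0, 1))
  set.seed(23)
  f <- runif(50)
  for (k in c(1e-6, 0.5, 3, 1e4)) {
    expect_equal(normalize_profile(k * f), normalize_profile(f),
                 tolerance = 1e-12)
  }
  expect_error(normalize_profile(rep(0, 10)), "undefined")
})

test_that("position comparison is a pooled-variance two-tailed t-test", {
  a <- c(1, 2, 3, 4)
  res <- compare_position(a, a)
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_value, 1)
  b <- c(1.01, 1.02, 0.99, 1.00)
  z <- c(0.001, -0.002, 0.002, -0.001)
  sep <- compare_position(z, b)
  expect_lt(sep$p_value, 1e-6)
  # swapping groups negates t and preserves p
  s1 <- compare_position(a, b)
  s2 <- compare_position(b, a)
  expect_equal(s1$t_statistic, -s2$t_statistic)
  expect_equal(s1$p_value, s2$p_value)
  # agrees with stats::t.test pooled form
  ht <- t.test(a, b, var.equal = TRUE)
  expect_equal(s1$t_statistic, unname(ht$statistic))
  expect_equal(s1$p_value, ht$p.value)
  const <- compare_position(c(1, 1), c(1, 1))
  expect_equal(const$p_value, 1)
  expect_match(const$flag, "zero variance")
})

test_that("mutpe_run conserves every input pair in the tally", {
  set.seed(29)
  germ <- make_germline(b18_layout(), seed = 31L)
  rep <- simulate_repertoire(germ, mutation_model(), 20L, seed = 32L)
  reads <- simulate_read_pairs(unique(rep$observed),
                               read_sim_config(depth = 120L, seed = 33L,
                                               error_rate = 0.002))
  # corrupt a few pairs so several rejection classes are exercised
  reads$r1$quals[[1L]] <- rep(5L, length(reads$r1$quals[[1L]]))   # trim -> short
  reads$r2$bases[2L] <- rand_dna(nchar(reads$r2$bases[2L]))       # merge fail
  run <- mutpe_run(reads$r1, reads$r2, germ$sequence)
  expect_identical(unname(run$tally["input_pairs"]), 120L)
  expect_identical(sum(run$tally[c("rejected_length", "rejected_merge",
                                   "rejected_gate", "rejected_align",
                                   "aligned")]),
                   120L)
  expect_gte(run$tally[["rejected_length"]], 1L)
  expect_gte(run$tally[["rejected_merge"]], 1L)
  # pileup depth never exceeds the number of aligned reads
  expect_true(all(run$pileup$depth <= run$tally[["aligned"]]))
  expect_true("normalized" %in% names(run$profile))
  expect_equal(sum(run$profile$normalized, na.rm = TRUE), 1)
})

test_that("palindromic AGCT planted on both strands gives matched G/C peaks", {
  set.seed(37)
  layout <- germline_layout(240L, data.frame(motif = "AGCT", start = 120L))
  germ <- make_germline(layout, seed = 41L)
  model <- mutation_model(base_rate = c(AGCT = 0.15), background_rate = 0,
                          bottom_strand_factor = 1)
  rep <- simulate_repertoire(germ, model, 4000L, seed = 42L)
  groups <- build_context_groups(rep)
  # C peak at 122 (top strand), G peak at 121 (bottom strand)
  cfreq <- groups$central_mutation_frequency[
    groups$kmer == extract_context(germ$sequence, 122L)$kmer]
  gchars <- do.call(rbind, strsplit(rep$observed, ""))
  gfreq <- mean(gchars[, 121L] != "G")
  se <- sqrt(0.15 * 0.85 / 4000L)
  expect_lt(abs(cfreq - 0.15), 3 * se)
  expect_lt(abs(gfreq - 0.15), 3 * se)
  expect_lt(abs(cfreq - gfreq), 4 * se)
})

test_that("FASTQ round trip preserves bases and qualities", {
  set.seed(43)
  reads <- structure(list(id = c("a", "b"),
                          bases = c(rand_dna(30), rand_dna(30)),
                          quals = list(sample(2:40, 30L, TRUE),
                                       sample(2:40, 30L, TRUE))),
                     class = "shm_reads")
  tmp <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, tmp)
  back <- read_fastq(tmp)
  expect_identical(back$id, reads$id)
  expect_identical(back$bases, reads$bases)
  expect_identical(back$quals, reads$quals)
})
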