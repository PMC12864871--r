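# Synthetic-data generators: germlines, site-rate algebra, repertoire
# and read simulation.

test_that("the default layout reproduces the characteristic coordinates", {
  germ <- make_germline(b18_layout(), seed = 1L)
  hits <- scan_wrch(germ$sequence)
  agct <- palindromic_pairs(hits)
  expect_identical(nrow(agct), 5L)
  expect_identical(agct$g_pos, c(27L, 54L, 89L, 243L, 311L))
  expect_identical(agct$c_pos, c(28L, 55L, 90L, 244L, 312L))
  expect_identical(agct$c_pos[5L] - agct$c_pos[4L], 68L)
  # the CDR2 AGCA lands at 194G/195C
  agca <- hits[hits$motif == "AGCA" & hits$strand == "top", ]
  expect_identical(agca$target_c, 195L)
  # region map places the motifs in the named subregions
  rmap <- germ$region_map
  region_of <- function(p) rmap$region[p >= rmap$start & p <= rmap$end]
  expect_identical(region_of(28L), "FWR1")
  expect_identical(region_of(90L), "CDR1")
  expect_identical(region_of(195L), "CDR2")
  expect_identical(region_of(244L), "FWR3")
  expect_identical(region_of(312L), "CDR3")
})

test_that("germline construction is deterministic and WRCH-free outside plants", {
  g1 <- make_germline(b18_layout(), seed = 5L)
  g2 <- make_germline(b18_layout(), seed = 5L)
  g3 <- make_germline(b18_layout(), seed = 6L)
  expect_identical(g1$sequence, g2$sequence)
  expect_false(g1$sequence == g3$sequence)
  # no motifs planted + WRCH-free filler -> empty scan
  empty <- germline_layout(150L, data.frame(motif = character(),
                                            start = integer()))
  expect_identical(nrow(scan_wrch(make_germline(empty, seed = 2L)$sequence)), 0L)
  # overlapping plants are a construction error
  expect_error(germline_layout(100L, data.frame(motif = c("AGCT", "TGCA"),
                                                start = c(10L, 12L))),
               "overlap")
})

test_that("site rates follow the base x context x position product", {
  layout <- germline_layout(200L, data.frame(motif = c("AGCT", "AGCT"),
                                             start = c(50L, 150L)))
  germ <- make_germline(layout, seed = 3L)
  flat <- mutation_model(base_rate = c(AGCT = 0.1), background_rate = 1e-3)
  r <- site_rates(germ$sequence, flat)
  expect_equal(r$rate[r$position == 52L & r$strand == "top"], 0.1)
  expect_equal(r$rate[r$position == 152L & r$strand == "top"], 0.1)
  expect_true(all(r$rate[is.na(r$motif)] == 1e-3))
  # zero position multiplier silences an interval
  zoned <- mutation_model(base_rate = c(AGCT = 0.1),
                          position_multiplier = data.frame(
                            start = 100L, end = 200L, factor = 0))
  rz <- site_rates(germ$sequence, zoned)
  expect_equal(rz$rate[rz$position == 52L & rz$strand == "top"], 0.1)
  expect_equal(rz$rate[rz$position == 152L & rz$strand == "top"], 0)
  # a 1 vs 0.25 position multiplier gives a 4-fold rate ratio
  quarter <- mutation_model(base_rate = c(AGCT = 0.1),
                            position_multiplier = data.frame(
                              start = 100L, end = 200L, factor = 0.25))
  rq <- site_rates(germ$sequence, quarter)
  expect_equal(rq$rate[rq$position == 52L & rq$strand == "top"] /
                 rq$rate[rq$position == 152L & rq$strand == "top"], 4)
  # context multiplier keyed by PyPy count
  ctx <- mutation_model(base_rate = c(AGCT = 0.1),
                        pypy_multiplier = function(p) 1 + p)
  rc <- site_rates(germ$sequence, ctx)
  w <- extract_context(germ$sequence, 52L)
  expect_equal(rc$rate[rc$position == 52L & rc$strand == "top"],
               0.1 * (1 + pypy_content(w)))
  # probabilities are clipped to [0, 1]
  hot <- mutation_model(base_rate = c(AGCT = 0.9),
                        pypy_multiplier = function(p) 100)
  expect_true(all(site_rates(germ$sequence, hot)$rate <= 1))
})

test_that("repertoire simulation is Bernoulli per site with the spectrum", {
  layout <- germline_layout(120L, data.frame(motif = "AGCT", start = 60L))
  germ <- make_germline(layout, seed = 8L)
  # all-zero model reproduces the germline exactly
  null_model <- mutation_model(base_rate = c(AGCT = 0), default_rate = 0,
                               background_rate = 0)
  rep0 <- simulate_repertoire(germ, null_model, 25L, seed = 9L)
  expect_true(all(rep0$observed == germ$sequence))
  # planted rate recovered within 3 binomial SE at n = 10000
  p <- 0.07
  model <- mutation_model(base_rate = c(AGCT = p), background_rate = 0,
                          bottom_strand_factor = 0)
  n <- 10000L
  rep1 <- simulate_repertoire(germ, model, n, seed = 10L)
  hitc <- sum(substr(rep1$observed, 62L, 62L) != "C")
  expect_lt(abs(hitc - n * p), 3 * sqrt(n * p * (1 - p)))
  # substitutions only, drawn from the spectrum (no C kept among mutated)
  mutated <- substr(rep1$observed, 62L, 62L)
  expect_true(all(mutated %in% c("C", "T", "G", "A")))
  expect_gt(sum(mutated == "T"), sum(mutated == "G"))
  # determinism
  rep2 <- simulate_repertoire(germ, model, 50L, seed = 11L)
  rep3 <- simulate_repertoire(germ, model, 50L, seed = 11L)
  expect_identical(rep2$observed, rep3$observed)
})

test_that("bottom-strand deamination writes the complementary change at G", {
  layout <- germline_layout(120L, data.frame(motif = "AGCT", start = 60L))
  germ <- make_germline(layout, seed = 12L)
  model <- mutation_model(base_rate = c(AGCT = 0.5), background_rate = 0,
                          spectrum = c(T = 1, G = 0, A = 0))
  rep <- simulate_repertoire(germ, model, 400L, seed = 13L)
  gbase <- substr(rep$observed, 61L, 61L)   # paired G of the bottom-strand C
  expect_true(all(gbase %in% c("G", "A")))  # C->T on bottom = G->A on top
  expect_gt(sum(gbase == "A"), 0L)
})

test_that("read simulation round-trips and respects the error model", {
  set.seed(51)
  template <- rand_dna(300)
  cfg0 <- read_sim_config(read_len_r1 = 200L, read_len_r2 = 150L,
                          error_rate = 0, depth = 5L, seed = 3L)
  reads <- simulate_read_pairs(template, cfg0)
  for (i in 1:5) {
    m <- merge_pair(list(bases = reads$r1$bases[i], quals = reads$r1$quals[[i]]),
                    list(bases = reads$r2$bases[i], quals = reads$r2$quals[[i]]))
    expect_identical(m$bases, template)
  }
  # byte-identical FASTQ for a fixed seed
  t1 <- withr::local_tempfile(fileext = ".fastq")
  t2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(simulate_read_pairs(template, cfg0)$r1, t1)
  write_fastq(simulate_read_pairs(template, cfg0)$r1, t2)
  expect_identical(readLines(t1), readLines(t2))
  # error rate within 3 SE of its binomial expectation
  cfg1 <- read_sim_config(read_len_r1 = 200L, read_len_r2 = 150L,
                          error_rate = 0.01, depth = 40L, seed = 4L)
  sim <- simulate_read_pairs(template, cfg1)
  nbases <- 40L * 200L
  errs <- sum(vapply(seq_len(40L), function(i) {
    sum(strsplit(sim$r1$bases[i], "")[[1L]] !=
          strsplit(substr(template, 1L, 200L), "")[[1L]])
  }, numeric(1L)))
  expect_lt(abs(errs - nbases * 0.01), 3 * sqrt(nbases * 0.01 * 0.99))
  # impossible geometry is a configuration error
  expect_error(simulate_read_pairs(template,
                                   read_sim_config(read_len_r1 = 100L,
                                                   read_len_r2 = 100L)),
               "geometry")
})

test_that("context swaps exchange exactly the configured flanks", {
  set.seed(53)
  layout <- germline_layout(240L, data.frame(motif = c("AGCT", "AGCT"),
                                             start = c(60L, 160L)))
  germ <- make_germline(layout, seed = 14L)$sequence
  for (flank in c(3L, 6L, 9L)) {
    swapped <- swap_motif_context(germ, 160L, 60L, flank)
    expect_identical(nchar(swapped), nchar(germ))
    # acceptor stretch now equals the donor stretch (motif included)
    expect_identical(substr(swapped, 160L - flank, 163L + flank),
                     substr(germ, 60L - flank, 63L + flank))
    # nothing outside the swapped stretch changed
    expect_identical(substr(swapped, 1L, 160L - flank - 1L),
                     substr(germ, 1L, 160L - flank - 1L))
    expect_identical(substr(swapped, 164L + flank, 240L),
                     substr(germ, 164L + flank, 240L))
    expect_identical(nchar(substr(swapped, 160L - flank, 163L + flank)),
                     context_swap_span(flank))
  }
})

test_that("position multipliers drive measurable frequency ratios", {
  # identical 22-nt contexts at two positions, multipliers 1 vs 0.25
  set.seed(55)
  layout <- germline_layout(260L, data.frame(motif = c("AGCT", "AGCT"),
                                             start = c(60L, 180L)))
  germ <- make_germline(layout, seed = 15L)
  germ$sequence <- swap_motif_context(germ$sequence, 180L, 60L, 9L)
  model <- mutation_model(base_rate = c(AGCT = 0.2), background_rate = 0,
                          bottom_strand_factor = 0,
                          position_multiplier = data.frame(
                            start = 100L, end = 260L, factor = 0.25))
  rep <- simulate_repertoire(germ, model, 8000L, seed = 16L)
  f1 <- mean(substr(rep$observed, 62L, 62L) != "C")
  f2 <- mean(substr(rep$observed, 182L, 182L) != "C")
  expect_gt(f1 / f2, 3)
  expect_lt(f1 / f2, 5.5)
})
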