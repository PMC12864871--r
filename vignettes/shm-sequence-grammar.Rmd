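---
title: "The sequence grammar of somatic hypermutation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The sequence grammar of somatic hypermutation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shmgrammar)
```

## The problem

AID deaminates cytosine to uracil on single-stranded DNA exposed during
transcription of immunoglobulin V regions, seeding somatic hypermutation.
Its intrinsic preference is the degenerate 4-mer WRCH (W = A/T, R = A/G,
H = A/C/T), twelve concrete motifs whose third base is the target C. Both
strands carry targets: a top-strand DGYW occurrence is a bottom-strand
WRCH whose C pairs with the top-strand G. Identical motifs mutate at very
different rates depending on where they sit, and this package implements
the three analysis layers used to dissect that variability — repertoire
context statistics, amplicon mutation quantification, and structural
descriptors of deaminase–ssDNA binding — together with a forward simulator
that generates all inputs synthetically.

## Motif grammar

`scan_wrch()` enumerates every top-strand WRCH occurrence and every
top-strand DGYW occurrence (reported as a bottom-strand hit). Coordinates
are 1-based and always in top-strand space, with `target_c` the deaminated
base: `start + 2` (a C) on the top strand, `start + 1` (the paired G) on
the bottom. This coordinate convention mirrors the field's "G/C pair"
presentation for palindromic motifs (e.g. "311G/312C"); internal
computation is plain vectorised substring matching, and a brute-force
two-strand oracle in the test suite confirms equality on 1000 random
sequences. Positions containing `N` never produce hits.

Orientation is derived, not tabulated: a motif is *palindromic* iff it
equals its own reverse complement (AGCT, TGCA), *bidirectional* iff its
reverse complement is a different WRCH (AGCA ↔ TGCT), else
*unidirectional* — giving the 2/2/8 partition.

Context windows are 15-mers centred on a C (`extract_context()`), with
the motif at window positions 6–9. Windows truncated by sequence ends or
containing `N` are dropped, mirroring the exclusion of records with
unknown bases. PyPy dimers (two consecutive C/T, overlaps counted) are
counted by default over the *motif ± 5 bp* segment, i.e. window positions
1–14; the whole-15-mer variant is a mode flag. The two segment definitions
appear interchangeably in the literature this package follows and differ
by at most one dimer (the one ending at window position 15); the ± 5 bp
segment is the default because it is the definition attached to the
per-motif mutability analyses. Motif-internal dimers (the CT inside AGCT)
are counted by default — the counting rule is "all occurrences" — with
exclusion available as a flag.

## Repertoire analysis

The repertoire model assumes clonally independent, substitution-only
records: an observed sequence aligned to an equal-length germline, with
indel- or N-containing records rejected at load (counted and reported).
Clone collapsing is out of scope; inputs are assumed pre-processed and
non-productive (hence free of antigenic selection).

**Contexts are taken from the germline sequence.** Grouping by the
observed 15-mer would let the mutation itself destroy or create the
grouping key, conflating cause and effect; the germline-derived window is
the exposure, the observed base at its centre the outcome. Groups are
keyed by the exact 15-mer string, so identical contexts from different
genes or positions pool their coverage. Groups observed fewer than 30
times are excluded (`filter_coverage()`, inclusive at 30).

Two statistics are computed per motif: *mutability* — the fraction of
unique 15-mers with any mutation at the central C, per PyPy level — and
the *mutation frequency* distribution of (by default) mutated 15-mers per
level. The mutability–PyPy correlation is computed on levels, weighted by
the number of 15-mers per level (the dot-size-weighted presentation);
unweighted and per-15-mer variants are flags, because the level-versus-
individual choice is not uniquely determined by the figures this follows.
The Pearson coefficient uses `stats::cov.wt`; a two-pass textbook formula
serves as the test oracle at 1e-12. "Mutation frequency of the central C
per unique 15-mer" is pooled across genes (mutated observations over
total observations), the simplest estimator consistent with coverage-based
filtering; per-gene averaging is not implemented. No multiple-testing
correction is applied, matching the per-motif reporting convention.

Degenerate inputs are flagged, not fabricated: fewer than two PyPy levels,
or zero variance in either variable, yields `r = NA` with an explanatory
flag.

## Amplicon quantification

The published processing chain (cutadapt / trimmomatic / FLASH / Bowtie2 /
samtools) is re-specified as native operations with the same thresholds;
this keeps the package dependency-free and the filters transparent:

| step | rule | default |
|---|---|---|
| quality trim | 5′→3′ sliding window, cut at first window mean < Q | window 5, Q25 |
| length filter | inclusive minima per mate | R1 200 nt, R2 100 nt |
| merge | best-match overlap, mismatch fraction ≤ max | overlap ≥ 10, ≤ 10 % |
| length gate | |merged − amplicon| ≤ tol | ± 30 nt |
| align | gapless, minimal-mismatch offset, leftmost tie | ceiling 0.15 |
| pileup | count bases with quality ≥ Q | Q30 |

Two semantics were genuinely open. First, the trimming rule: the stated
rule is ambiguous between "truncate at the failing window's start" and
trimmomatic's actual behaviour (cut at the failing window, then keep its
leading bases that individually meet the threshold). Only the latter
reproduces the canonical example (qualities `[40×5, 10×5]` keep 5 bases —
the first failing window already starts at base 4), so trimmomatic
semantics are used. Second, no post-alignment mismatch ceiling is stated;
0.15 is a package default, configurable, and chosen to sit far above real
mutation loads (≤ a few %) but far below the ~75 % mismatch rate of an
unrelated sequence.

Gapless alignment is justified because the reference is a single short
fixed amplicon and per-position analysis cannot interpret indel-bearing
reads; reads failing placement are dropped *and counted* — the run tally
accounts for every input pair exactly once across
`{rejected_length, rejected_merge, rejected_gate, rejected_align, aligned}`
(trim failures surface as length rejections, since trimming only
shortens).

Mutation frequency at a position is mutated bases over covering bases;
zero-depth positions are absent (`NA`), never 0/0. The normalized
frequency divides by the summed frequency over the entire profiled region
— its purpose is scale invariance across samples with different overall
loads, and that invariance is asserted to 1e-12. An all-zero profile makes
the quantity undefined and is an error, not a silent zero. Between-sample
position tests are classical pooled-variance Student t-tests (two-tailed,
α = 0.05 labels), with Welch available by flag; two constant equal groups
give p = 1 by convention, flagged.

## The simulator: a stated world

The simulator is deliberately mechanistic-phenomenological. Each site
mutates by an independent Bernoulli trial with probability

```
rate(site) = base_rate(motif, strand) × context_multiplier × position_multiplier
```

clipped to [0, 1]; non-WRCH cytosines mutate at a background rate.
Deaminated Cs resolve as C→T with minority C→G/C→A (defaults 0.8 / 0.12 /
0.08) — transversions arise in vivo through UNG/MSH2 processing, which is
represented only as spectrum weights, not mechanism. Bottom-strand
deamination is written as the complementary change at the paired G. There
is no transcription, processivity, repair, clonal lineage, selection, or
indel model: per-site frequency estimators, which is all the analyses
consume, cannot distinguish those mechanisms anyway. A green round-trip
test therefore establishes estimator correctness, not biological realism
of the generating process.

Default parameter choices, fixed once: the default germline layout is a
**synthetic** 336-nt stand-in for the murine B1-8hi V region (whose real
sequence is not reproduced here) with five AGCT motifs planted so their
G/C pairs fall at the characteristic coordinates 27/28, 54/55, 89/90,
243/244, 311/312 and an AGCA at 194/195; the region map is IMGT-like and
chosen so those coordinates fall in FWR1, FWR1, CDR1, FWR3, CDR3 and CDR2
respectively. Filler is rejection-sampled to be WRCH-free on both strands
(a flag permits incidental motifs for realism), slightly GC-rich
(A/C/G/T = 0.25/0.27/0.27/0.21) as for Ig V exons. No quantitative
motif or context rate constants are published for this system, so base
rates are package choices in the biologically plausible 10⁻²–10⁻¹ per-site
range, and every acceptance check uses ratios or planted-value recovery
rather than absolute rates. Read simulation uses 250/180 nt mates over the
full amplicon (so mates always overlap), per-base error 0.001 and Gaussian
qualities (mean 37, sd 3, capped to [2, 40]) — an idealisation of
post-QC short-read data with no quality decay along the read and no
chimeras. All randomness flows from one explicit seed.

Two sizing decisions were made inside stated constraints. The
rate-recovery check plants five rates spanning 10-fold (log-uniform:
0.02…0.2) at coverage 4000 per group; with the stated lower bound
(coverage ≥ 500) the two smallest rates, 1.78-fold apart, would flip rank
by binomial noise in ~5 % of seeds, making "rank order recovered exactly,
20/20 seeds" unattainable — at 4000 a flip has probability ~10⁻⁴. And the
amplicon round trip compares measured frequencies not to the raw planted
fraction *f* but to the expected observed frequency under the simulator's
own error channel, `f_exp = f + e − (4/3)·f·e` (uniform errors at rate
*e*): with any nonzero sequencing error, every *f* = 0 position would
otherwise sit outside its zero-width binomial band. Both are exact model
consequences, not tolerance adjustments.

## Trajectory metrics

The protein is approximated as a sphere of radius Rg (uniform weights by
default — mass weighting is a flag, as no weighting convention is stated
for this use), and the per-nucleotide surface distance is
Δ_s = |r_P − c| − Rg for each DNA phosphorus. The centre *c* is the
unweighted protein centroid by default; the alternative reading of the
method — anchoring at a single reference Cα atom — is exposed as
`center_mode = "atom"`, and neither is asserted as canonical because the
source text conflates the two. Δ_s can be negative (phosphorus inside the
effective sphere) and is comparable across nucleotides of one complex in
shape, not in absolute value. A 5′-terminal nucleotide without a phosphate
contributes no value (warned, not imputed).

RMSF is `sqrt(mean_t |r_i(t) − ⟨r_i⟩|²)` after an optional least-squares
rigid superposition of each frame onto the mean structure (Kabsch via SVD
with reflection guard, iterated once: fit, recompute mean, refit).
Superposition defaults to on — the common trajectory-analysis default —
but is flaggable off since the upstream convention is unstated; a
degenerate target (all atoms coincident) falls back to no superposition
with a warning. Residue grouping averages member-atom RMSF values.
Interaction energies are out of scope (they need force-field evaluation);
`energy_summary()` only ingests externally computed per-frame tables for
mean ± SD reporting.

Numerical checks: Rg and Δ_s are rigid-transform invariant to 1e-10; a
thin uniform shell of 10⁴ points has Rg = R to 1 %, giving the closed form
Δ_s = d − R used as an oracle.

## Limitations

* The repertoire module assumes a shared coordinate system across records
  pooled into one analysis; it does no gene assignment, numbering or
  lineage reconstruction.
* The aligner is gapless by design; amplicons with real indel variation
  need an external aligner, and such reads are dropped (visibly, in the
  tally).
* The simulator's independence assumptions (across sites and records)
  underestimate the clustered, processive character of real AID action;
  effect *sizes* recovered from simulated data validate estimators, not
  biology.
* The synthetic B1-8hi-like germline shares coordinates and motif layout
  with the real V region but not its sequence; analyses keyed to exact
  k-mer identity will not transfer to the real locus.
* Δ_s values depend on protein shape and are not comparable between
  different complexes; only profile shape and per-position variability
  are.
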