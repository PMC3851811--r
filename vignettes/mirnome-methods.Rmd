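---
title: "Profiling a composite miRNA transcriptome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling a composite miRNA transcriptome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Deep sequencing of the small RNA fraction of a cell does not return a tidy
list of mature miRNAs. It returns tens of millions of short reads drawn from
miRNAs and their length variants (isomiRs), fragments of sn/snoRNAs,
lincRNAs, tRNAs, rRNAs, degraded mRNAs, unannotated genomic transcripts and
sequencing artefacts. Summarising such a library only by the canonical
(miRBase-deposited) mature sequences misses a large part of the picture: for
most miRNAs the most abundant sequenced form is *not* the canonical one, and
miRNAs whose canonical form was never read at all are invisible to an
exact-match profile. `mirnome` implements the full composite ("miRnome")
analysis as a set of testable, deterministic stages:

1. **Length filtering and diagnostics** — reads shorter than 14 nt are
   removed; the count-weighted length histogram is the standard library
   quality readout (intact libraries peak at 22 nt, the average mature miRNA
   length; degraded libraries shift towards 17 nt with a heavy short tail).
2. **Elimination annotation** — each read is assigned to the *first* RNA
   class it matches (miRNA, sn/snoRNA, lincRNA, tRNA, rRNA, mRNA, misc, in
   that priority order) with up to 2 substitutions, and is then removed from
   the pool. Survivors are matched exactly against intergenic/intronic
   genomic regions; the remainder is unmatched.
3. **Reference profile** — per-miRNA raw counts of reads exactly equal to
   the canonical mature sequence, normalised as
   `TPM = count / library_total * 1e6`.
4. **IsomiR families** — reads are aligned (ungapped, at most 2
   substitutions, sense strand) to the pre-miRNA hairpins; each alignment is
   assigned to the mature locus it overlaps most; the member with the
   highest count is the *dominant isomiR*, the operational "active form" of
   the miRNA. The dominant counts form the abundant-isomiR profile.
5. **YES/NO comparison** — per sample, a miRNA is YES when its dominant
   isomiR *is* the canonical sequence; a group of samples gets a YES/NO
   label only when the miRNA is expressed in every sample and the calls are
   unanimous. Mixed calls are `non_uniform`; missing expression is
   `low_expression`.
6. **Novel discovery** — unannotated reads with counts of at least 5 are
   matched exactly to intergenic/intronic regions, extended by 70 nt on both
   sides (roughly precursor length), folded, and kept when the window folds
   as a single-loop hairpin with the read inside one stem arm. Candidates
   from a common locus are pooled across samples, deduplicated and named
   `jnu-pat-hsa-1..N` by descending total count.

## Matching model

All read-versus-database and read-versus-hairpin matching is ungapped,
end-to-end of the read, substitutions only. This matches short-read practice
for 17–30 nt queries (indels in such reads are overwhelmingly artefactual)
and, importantly, makes the matcher *exactly* checkable against a
brute-force sliding-window Hamming scan — a property the test suite
exercises on hundreds of random fixtures. An ambiguous base (N) never
matches anything, not even another N. Class databases are scanned in their
transcript sense; the read is tried in both orientations. Genomic region
matching for the novel track is exact (0 substitutions) on both strands.

Ties in best-hit matching are resolved deterministically: fewest
mismatches, then database record name, then offset, then forward
orientation. Elimination order dominates mismatch count by construction: a
2-mismatch hit in an early class beats an exact hit in a later one, which is
the defining property of elimination annotation (and is pinned by a test).

## Expression, profiles and clustering

TPM normalisation is the plain ratio `count / library_total * 1e6`, with the
post-length-filter library total. The reference profile lists only miRNAs
with at least one exact read; the abundant-isomiR profile lists every miRNA
with at least one family member, so it is always a row superset of the
reference profile and its counts dominate row-wise (the canonical sequence,
when read, is itself a family member). Two mature names sharing one
sequence each receive the full count; the profile records such groups in a
`duplicated_sequences` attribute rather than silently halving either.

"Highly expressed" uses a strict threshold (count > 10,000 by default) and
singletons are rows with count exactly 1. Expression spans several orders of
magnitude, so sample clustering operates on `log2(TPM + 1)` with distance
`1 - Spearman correlation` and average linkage — rank-based correlation and
the log transform keep a handful of very abundant miRNAs from dominating
the distance. Both choices are configurable; the group-recovery behaviour
(planted sample groups merge first) is what the tests assert, not any
particular height values.

## Hairpin folding and novel-candidate filters

The folding engine is pluggable. The built-in engine maximises base pairing
(Watson–Crick plus G·U) over nested structures with a minimum hairpin loop
of 3 nt, via the classic cubic dynamic programme with a deterministic
traceback that prefers closing a pair on ties — so equal-score structures
resolve to stacked stems rather than gratuitous multiloops. The traceback's
pair count is verified against an independent brute-force enumeration of all
nested structures for short sequences. External predictors can be swapped in
as any function returning a pairing vector; their scores are recorded
verbatim, never re-implemented.

A fold window is accepted as a putative precursor when its optimal structure
has a single terminal loop, a 5' stem arm spanning at least 16 positions and
a stem pairing fraction of at least 0.6. These three thresholds are package
defaults, chosen so that every stem-loop the synthetic generator plants is
accepted while composition-preserving shuffles and low-complexity loci are
rejected; all are configurable. Windows shorter than 40 nt are rejected
before folding (a clipped window near a chromosome end cannot be a
precursor).

Of the three structural features of a genuine miRNA locus — the read lies in
one stem arm; at least one other read is within ±3 nt of both its ends (an
isomiR); at least one read lies in the other arm (the counterpart) — only
the first is a hard gate by default, because the latter two are reported
attributes of real candidate tables rather than universal requirements;
`strict_filters = TRUE` gates on all three. Candidate windows over one locus
are merged strand-agnostically: the two arms of a hairpin are near-reverse
complements, so a read from one arm also places on the minus strand of the
other, and both windows describe the same precursor.

## The synthetic data generator

The generator exists so that every downstream stage can be tested against
planted ground truth without any external download. It emulates the
*statistical structure* of PBMC-like small RNA libraries:

* **Class proportions** default to miRNA 74%, sn/sno 2%, lincRNA 3%, tRNA
  3%, rRNA 1%, mRNA 4%, misc 2%, unannotated-genomic 5%, unmatched 6%.
* **Read lengths** peak at 22 nt. The degraded mode 3'-truncates 65% of
  reads down to a length drawn geometrically at or below 17 nt, reproducing
  the shifted mode and heavy short tail of degraded patient libraries with
  two parameters.
* **Expression** per miRNA is log-normal (sdlog 1.5), spanning roughly four
  orders of magnitude at desk scale, including singletons.
* **IsomiR families**: offsets are uniform over `[-2, 2]` at both ends (the
  only constraint the underlying biology imposes is "a few nucleotides");
  one planted dominant member holds at least a two-fold count margin over
  every other member, making dominant recovery deterministic; the dominant
  is the canonical form with probability 0.32, so roughly 68% of planted
  miRNAs are dominated by a non-reference isomiR. Family size grows with
  expression (log2 of the count, capped at 7 members), reflecting that
  deeper families reveal more isomiRs.
* **Guaranteed separability**: contaminant, genomic and unmatched read
  species are rejection-sampled so they never hit an earlier elimination
  class within the mismatch tolerance, which is what makes the planted
  confusion matrix exactly diagonal. This is a deliberate idealisation —
  real libraries contain genuinely ambiguous reads — so a diagonal result
  shows the elimination machinery is correct, not that real data are
  unambiguous.
* **Planted novel loci** use a 30 bp C/G-only stem with poly-A loop and
  flanks. Since the fold window then contains no T, adenines cannot pair
  and the planted stem is provably the unique optimal structure; decoy loci
  are A/C-only and cannot pair at all. Every planted window is additionally
  verified against the pipeline's own fold-and-filter path at generation
  time and redrawn on failure. Again an idealisation: real novel loci sit
  in sequence that folds imperfectly, so recovery rates on real data will
  be lower than the planted 100%.
* The miRNA *annotation* database is the hairpin set (not the matures), so
  5'/3'-extended isomiRs still annotate as miRNA during elimination.

Counts are multinomial by default; `fixture_mode = TRUE` switches to
largest-remainder apportionment for exactly reproducible unit fixtures.
Every generator function consumes an explicit seed and restores the
caller's RNG state, so identical spec + seed gives byte-identical outputs.

Degradation truncates 3' ends and can merge two planted isomiRs into one
sequence, so per-family dominant truth is only guaranteed in the intact
length mode; cohort truth labels for degraded groups are `NA`, and the
dominant-recovery and YES/NO acceptance checks run on intact-mode groups.

## Numerical and contract choices

* Coordinates are 0-based half-open everywhere internally (BED native);
  FASTA headers never carry coordinates.
* RNA alphabet (U) is normalised to DNA (T) on ingestion; all outputs are
  DNA.
* The length cutoff retains reads of length ≥ 14 nt (the boundary is
  inclusive).
* 5p/3p arm assignment uses the `-5p`/`-3p` name suffix when present; the
  positional fallback (first half / second half / midpoint) only serves
  synthetic or unnamed data.
* FASTQ ingestion uses a strict 4-line parser so that malformed records can
  be reported with their line numbers, which the error contract requires;
  multi-line FASTQ is out of scope.
* The modal read length resolves ties towards the smaller length.
* Dominant-isomiR ties resolve towards smaller |5' offset|, then smaller
  |3' offset| (so the canonical form wins a tie), then lexicographically.
* Unlocated matures (no exact substring on any name-matched hairpin) stay in
  the reference domain — reads can still exact-match them — but cannot found
  isomiR families, which need hairpin coordinates.
* Multi-mapped reads contribute their full count to every family they
  enter; the family-conservation invariant is therefore asserted on
  uniquely-mapping fixtures.
* The "expressed" detection threshold for the group comparison is a dominant
  count of at least 1 in every sample; it is configurable, and the
  low-versus-non-uniform split depends on it.

## Problem sizes

The test suite and the acceptance script run synthetic libraries of 10^4 to
10^5 reads over 40 hairpins (80 mature miRNAs), 2 chromosomes of 12 kb and
6 records per contaminant class — small enough to run in seconds, large
enough that multinomial sampling noise is far below every asserted margin
(for example, the miRNA mass fraction at 10^5 reads has a standard error of
about 0.14 percentage points against an asserted tolerance of 1 point).

## Known limitations

* The matcher models substitutions only; an isomiR created by an internal
  indel would be missed, as would a class hit requiring a gapped alignment.
* The built-in folding engine maximises pair count, not free energy; it is
  a structural gate, not a thermodynamic predictor, and the acceptance
  thresholds are calibrated against the generator's planted hairpins, not
  against miRBase-wide statistics.
* Non-templated 3' additions (A/U tailing) are not modelled as a separate
  isomiR class; a tailed read simply fails to align once it exceeds the
  mismatch budget.
* The generator's separability guarantees (diagonal confusion, 100% planted
  recovery) quantify the pipeline's correctness, not its expected accuracy
  on real libraries, where ambiguous reads, imperfect folds and
  cross-mapping families all occur.
* Differential expression across conditions is intentionally out of scope;
  the package stops at per-sample profiles, group comparisons and
  clustering.
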