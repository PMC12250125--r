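---
title: "Methods: homology-based plant miRNA discovery with mirquest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homology-based plant miRNA discovery with mirquest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records the model behind each pipeline stage, every
threshold, and the numerical conventions the implementation commits to —
including the places where a convention had to be chosen among defensible
alternatives.

## 1. Coordinates and alphabets

All spans are 0-based half-open (`start` inclusive, `end` exclusive) in
every tibble; the GFF3 writer converts to that format's 1-based inclusive
columns on output. Sequences are normalized on input to uppercase RNA
(T → U). IUPAC ambiguity codes are tolerated in transcripts but any window
containing one is excluded from scoring; mature miRNA references must be
unambiguous.

## 2. Homology scan

Known plant mature miRNAs are first deduplicated by exact sequence
(first-seen record kept, input order preserved). Each remaining query is
expanded into a fragment set: the full-length sequence plus every gap-free
prefix and suffix down to `min_len = 18` nt. Every fragment is compared,
ungapped, at every offset of every transcript on both strands (the minus
strand via the reverse complement of the fragment), and positions with at
most `max_mismatch = 2` Hamming mismatches are recorded.

Overlapping raw matches of the same (transcript, miRNA) pair are collapsed
greedily after sorting by **match length descending, then mismatches
ascending, then start ascending**. This combined key reconciles two
requirements that can conflict — "prefer full-length matches" and "prefer
fewest mismatches, ties leftmost" — by making length dominant: a
full-length match with 2 mismatches beats an 18-nt fragment with 0. The
brute-force oracle in the test suite implements the same rule
independently.

## 3. Coding filter

A transcript is heuristically coding if any of its six frames contains an
AUG-initiated, stop-terminated open reading frame of at least
`min_orf_aa = 100` codons. An external evidence table (e.g. from a protein
database search run elsewhere) overrides the heuristic per transcript;
evidence rows naming unknown transcripts warn and are ignored, and
conflicting duplicate verdicts are an error at read time. Hits on coding
transcripts are dropped; the transcripts themselves are retained in the
verdict table so stage counts reconcile.

## 4. Precursor windows

Candidate precursor windows of `window = 100` nt are slid in steps of
`step = 20` nt. Start positions run from `max(0, hit_start − flank)` to
`min(L − window, hit_end + flank − window)` with `flank = 80`, windows are
clipped at the transcript end, and only windows that fully contain the
mature span are kept. A transcript shorter than the window yields the
whole transcript as the single window. The "starts from the formula, then
containment filter" order is the commitment here: the filter can remove
windows the raw formula emits (a start 20 nt before an early mature can
end before the mature does), and for hits too close to a transcript end it
can legitimately remove all of them, in which case the hit yields no
candidate.

For minus-strand hits the window sequence is reverse-complemented before
folding, so precursors are always reported in the duplex (5'→3' mature)
orientation, with the mature span re-mapped accordingly
(`mature_start = window_end − hit_end`).

## 5. Folding providers

Two interchangeable providers sit behind `fold_rna()`:

* **vienna** — ViennaRNA's `RNAfold` at 37 °C, batch over stdin, used
  automatically when on `PATH`. This is the thermodynamic provider; MFE is
  in kcal/mol. Constrained folding (`-C --enforceConstraint`) backs the
  site-accessibility energy (section 7 below).
* **nussinov** — a built-in base-pair-maximization dynamic program:
  Watson-Crick and G:U pairs, minimum loop of 3 unpaired nt, "MFE"
  defined as minus the pair count so that the ≤ −20 criterion reads "at
  least 20 pairs in 100 nt". Traceback is deterministic: at each
  subproblem the split is scanned in ascending position and the **most
  distant admissible partner** is preferred on score ties, which biases
  toward long-range stems (hairpin-like structures) instead of scattered
  local helices. The pair counts (though not the particular structures)
  are pinned to an exhaustive memoized recursion in the tests.

Sequences shorter than 15 nt are rejected: nothing that short can form a
hairpin with a 3-nt loop and a meaningful stem.

## 6. Hairpin criteria and statistics

Each folded window is screened against five criteria, each reported as its
own flag so failures are attributable:

1. ≤ 3 mismatches between the predicted mature and the known miRNA
   (inclusive). For truncated hits the comparison is over the better of
   the prefix/suffix alignment and the unaligned overhang of the known
   miRNA counts as mismatched.
2. The mature lies entirely within one arm of a stem-loop: its paired
   partners must all sit on one side, it must not pair with itself, and it
   must not reach into the terminal loop of its own hairpin (the region
   strictly inside the innermost enclosing pair).
3. AU content in [30, 70] % inclusive. GC% is defined as 100 − AU%, so the
   two always sum to exactly 100.
4. Fewer than 6 mature positions unpaired opposite the star strand
   (strict inequality; G:U wobbles count as paired). The star span is read
   off the reported structure, extended by the 2-nt 3' overhang of Dicer
   products and clipped at the precursor end.
5. MFE ≤ −20 (kcal/mol for vienna; −pairs for nussinov), inclusive.

Statistics: AMFE = 100·MFE/length (reported to 3 decimals in the candidate
report), MFEI = |AMFE|/GC% (2 decimals, positive by convention, undefined
at GC 0). Among passing windows of one hit the minimal-MFEI window is
selected, ties broken by lower MFE, then leftmost start.

One bundled-data caveat, stated once here: in the packaged table of 17
published precursor statistics, one EST row's printed AMFE cell does not
recompute from its own printed MFE and length (−106.000 printed vs
−106.452 recomputed), and the TSA rows' printed MFEI cells do not
recompute from their printed AMFE and GC% (deviations 0.03–0.18). The
tests pin every internally consistent cell at print precision and assert
the inconsistency of the rest rather than papering over it.

## 7. Target-site scoring

Scoring follows the psRNATarget/miRU expectation convention over the
ungapped antiparallel duplex: miRNA position *k* (1-based from its 5' end)
faces mRNA window position *L − k + 1*. Penalties: Watson-Crick 0, G:U
0.5, mismatch 1, (gap 2, unused in ungapped mode), doubled at seed
positions 2–13. Windows with expectation ≤ 3.0 are reported; overlapping
windows of one miRNA:mRNA pair collapse to the best-scoring one (ties
leftmost). Any non-Watson-Crick position among miRNA positions 9–11 calls
translational inhibition; full central complementarity calls cleavage.

Site accessibility (UPE) is the energy to hold the site single-stranded:
the constrained-minus-free MFE difference of the local context (17 nt
upstream, 13 nt downstream), floored at 0. It needs the thermodynamic
provider (NA otherwise) and is advisory — sites above 25 kcal/mol are
flagged, not removed.

## 8. Expression analysis

Stem-loop qRT-PCR Ct values are converted per reaction as
2^−(Ct_gene − Ct_reference), normalizing against the mean reference-gene
Ct of the same sample and molecular class (a U6 snRNA for miRNAs, a
ubiquitin mRNA for targets). Technical replicates are averaged within each
biological sample first; the reported mean and SEM (sd/√n, NA at n = 1)
are across biological samples. Stress/control ratios at or beyond
1.5-fold (inclusive) are called up/down; a gene undetected in either
condition is flat and can never support an inverse call. A miRNA:target
pair is flagged inverse only for strictly opposite calls in the same
group × tissue cell. Two-way ANOVA (condition × group) with Tukey's HSD is
provided as a routine companion via `stats::aov`/`TukeyHSD`.

## 9. Synthetic generators

Every generator is a pure function of a mandatory seed, and their defaults
mirror the study conditions (22-nt-scale matures, 300-nt transcripts,
3 biological × 3 technical replicates, reference Ct 18, baseline Ct 24).

* `make_hairpin()` builds mature + loop + reverse complement. The loop is
  drawn from {A, C} only so it cannot pair internally. Star knockouts
  substitute the base that can pair with **neither** Watson-Crick nor G:U
  against the facing mature base (facing A/U → C, facing G/C → A), and the
  returned designed structure marks both duplex positions unpaired —
  criteria checks against designed imperfect duplexes use this structure,
  since a refold may legally re-pair a knocked position elsewhere.
* `make_decoy()` rejection-samples an A/C-dominated alphabet
  (A 0.49, C 0.49, G 0.01, U 0.01) until the chosen folder reports
  MFE > −20: a sequence too weakly self-complementary to pass criterion
  (v) by construction. The tiny G/U admixture keeps the alphabet honest
  without letting abundant C capture every G into a stem.
* `make_target_mrna()` plants a site whose expectation is computed
  analytically from the scoring weights — the round trip against
  `score_site()` is therefore a real two-implementation check, not a
  tautology.
* `make_ct_table()` encodes fold change *F* as a stress-condition Ct shift
  of −log2 F, adds Gaussian noise to both conditions, and emits the
  reference genes noise-free so σ = 0 recovery is exact.
* `make_discovery_corpus()` mixes planted, criteria-conforming hairpins
  (miRNAs assigned round-robin) with decoys; per-item seeds are derived
  arithmetically from the corpus seed so the corpus is one deterministic
  object. A perfect planted hairpin legitimately yields a second hit on
  its star arm (the reverse complement of the mature), which also
  validates; the pipeline reports both rather than guessing which arm is
  "the" mature.

Limits worth stating: planted hairpins are perfect or near-perfect duplex
caricatures, not bulged natural precursors; decoys are compositionally
extreme; i.i.d. backgrounds have no isochore or repeat structure. The
generators are for correctness testing with known ground truth, not for
benchmarking sensitivity on realistic genomes.

## 10. Problem sizes and determinism

The built-in folder is O(n³) in plain R: ~0.06 s at 100 nt (the window
size, so discovery cost is per-window) and ~0.9 s at 300 nt. Test and
example corpora are sized accordingly (tens of 300-nt transcripts);
dataset-scale EST/TSA pools are out of scope and would use the vienna
provider. Identical inputs, configuration and seed produce byte-identical
report files; every run writes a resolved JSON copy of its configuration
next to its outputs.
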