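# mirquest

Homology-based discovery of conserved plant microRNAs in transcript
sequences, with hairpin validation, target prediction and qRT-PCR
expression analysis — the classic EST/TSA miRNA-mining workflow as a single
tidyverse-native R package.

## What it does

Plant miRNAs are deeply conserved, so new family members can be found by
scanning expressed sequences against known mature miRNAs and then asking
whether the surrounding sequence folds into a credible pre-miRNA hairpin.
`mirquest` implements that workflow end to end:

1. **Homology scan** — an exhaustive, ungapped, mismatch-limited scan of
   both strands of every transcript against a non-redundant set of known
   mature miRNAs (≤ 2 mismatches; full-length matches preferred, gap-free
   fragments down to 18 nt accepted).
2. **Coding filter** — transcripts with a long open reading frame
   (≥ 100 codons, six frames) or external coding evidence are removed;
   miRNA precursors are non-coding.
3. **Precursor extraction and hairpin validation** — 100-nt windows
   (step 20, flank 80) around each hit are folded and screened against the
   five conventional criteria: (i) ≤ 3 mismatches to the known mature,
   (ii) the mature sits in one arm of the stem-loop, (iii) AU content in
   30–70 %, (iv) fewer than 6 mature positions unpaired opposite the star
   strand, (v) MFE ≤ −20 kcal/mol. Each candidate is annotated with
   AMFE = 100·MFE/length and MFEI = |AMFE|/GC% — the index that separates
   miRNA precursors (≈ ≥ 0.85) from other structured RNAs.
4. **Target prediction** — psRNATarget-style expectation scoring of the
   antiparallel miRNA:mRNA duplex (WC 0, G:U 0.5, mismatch 1, doubled in
   seed positions 2–13; sites reported at expectation ≤ 3.0), with
   cleavage/translational-inhibition calls from the central positions 9–11
   and an optional site-accessibility energy (UPE).
5. **Expression analysis** — 2^−ΔCt relative expression against
   class-specific reference genes, technical-then-biological replicate
   summaries, 1.5-fold direction calls, miRNA/target inverse-expression
   flags, heatmaps, and routine ANOVA/Tukey companions.

Two folding providers are supported: ViennaRNA's `RNAfold` (thermodynamic,
used automatically when on `PATH`) and a built-in, dependency-free
Nussinov base-pair-maximization folder (its "MFE" is minus the pair count,
on the same ≤ −20 criterion scale). Every stage is a plain function from
tibbles to tibbles; pipeline results support `tidy()`, `glance()`,
`autoplot()` and `print()`.

The package also ships seeded generators for every input it consumes —
designed hairpins, planted discovery corpora, low-structure decoys, target
mRNAs with analytically known expectation, and Ct tables with known fold
changes — so the whole pipeline is testable against ground truth.

## Worked example

Plant a perfect miR528 hairpin in a random 300-nt transcript and
rediscover it:

```r
library(mirquest)

mir <- read_mature_mirnas(system.file("extdata", "musa_mature_mirnas.fasta",
                                      package = "mirquest"))
mi  <- mir[mir$name == "miR528-5p", ]

hp  <- make_hairpin(mi$seq, star_mismatches = 0, loop_len = 8, seed = 42)
emb <- embed_precursors(hp$precursor, 120, 300, seed = 43, id = "tx1")

res <- run_discovery(emb$transcript, mi,
                     config = mir_config(provider = "nussinov"))
res
#> <mir_discovery>
#>   2 passing precursor(s) from 2 homology hit(s), 1 family
#> # A tibble: 4 × 3
#>   stage               n_in n_out
#> 1 dedup_mirnas           1     1
#> 2 scan_transcripts       1     2
#> 3 coding_filter          2     2
#> 4 predict_precursors     2     2
```

Two hits because a perfect hairpin contains the mature *and* its reverse
complement (the star arm), and each validates. The best window for the
mature hit:

```r
tidy(res)[1, c("window_start", "window_end", "au_pct", "gc_pct",
               "mfe", "amfe", "mfei", "arm", "passed")]
#>   window_start window_end au_pct gc_pct mfe amfe  mfei arm passed
#> 1           80        180     47     53 -37  -37 0.698  5p TRUE
```

The precursor statistics reproduce published values from printed inputs;
for example, a 65-nt precursor with MFE −88.40 kcal/mol and GC 61.88 %:

```r
compute_amfe(-88.40, 65)                      # -136.000 kcal/mol per 100 nt
compute_mfei(compute_amfe(-88.40, 65), 61.88) # 2.20
```

Target prediction with a designed central-mismatch site:

```r
m <- "UGGAAGGGGCAUGCAGAGGAG"
t <- make_target_mrna(m, mismatch_positions = 10, length = 300,
                      position = 150, seed = 7)
find_sites(tibble::tibble(name = "miR528-5p", seq = m), t$mrna)
#>   mirna_name mrna_id start end expectation  inhibition
#> 1  miR528-5p  mrna_1   150 171           2 translation
#> UGGAAGGGGCAUGCAGAGGAG
#> ||||||||| |||||||||||
#> ACCUUCCCCAUACGUCUCCUC
```

Expression: a miRNA up 3-fold under stress and its target down to 0.4-fold
(Ct noise σ = 0.15) come back with an inverse-expression flag:

```r
g   <- tibble::tibble(gene = c("miR397a", "LAC17"),
                      class = c("miRNA", "mRNA"),
                      fold_change = c(3, 0.4))
sim <- make_ct_table(g, seed = 11, noise_sd = 0.15)
d   <- expression_directions(
         summarize_expression(rel_expression_table(sim$ct_table)))
d[, c("gene", "ratio", "log2_ratio", "direction")]
#>      gene ratio log2_ratio direction
#> 1 miR397a 3.103       1.63        up
#> 2   LAC17 0.416      -1.27      down
flag_inverse(d, tibble::tibble(mirna = "miR397a", target = "LAC17"))$inverse
#> TRUE
```

## Command line

A thin CLI over the same functions is installed at
`system.file("exec", "mirquest", package = "mirquest")`:

```
mirquest scan          --transcripts tx.fasta --mirnas mature.fasta --out hits.tsv
mirquest filter-coding --transcripts tx.fasta --out coding.tsv
mirquest predict       --transcripts tx.fasta --mirnas mature.fasta --hits hits.tsv
mirquest targets       --mirnas mature.fasta --mrnas cds.fasta
mirquest expression    --ct ct.tsv
mirquest synth         --seed 1 --out-dir synth/
mirquest run           --transcripts tx.fasta --mirnas mature.fasta --out-dir out/
```

`run` writes the candidate report, hit tables (TSV + GFF3), per-stage
counts and a resolved JSON copy of the configuration; identical inputs and
seed give byte-identical outputs.

## Reproduction

The published per-precursor statistics (MFE, length, AU/GC content, AMFE,
MFEI of 17 *Musa* precursors) are bundled as
`inst/extdata/musa_precursor_stats.tsv`, and the 17 mature query sequences
as `inst/extdata/musa_mature_mirnas.fasta`. To recompute the derived
statistics from their printed inputs and write them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

The script also runs a seeded planted-corpus discovery as a smoke check.
The full test suite — including brute-force oracle comparisons for the
scanner, folder, ORF finder and target scorer, planted-hairpin recovery,
and exact/noisy expression recovery — runs with:

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "mirquest",
                               load_package = "installed")'
```

Two caveats found while assembling the bundled table: one printed AMFE
cell (row FL667486) is internally inconsistent with its own printed MFE
and length, and the TSA rows' printed MFEI cells do not recompute from
their printed AMFE and GC%; the tests pin the consistent cells and
document the exceptions. The headline dataset-scale results (survivor
counts from the full EST/TSA pools, 59 predicted targets, field qRT-PCR
fold changes) require external sequence databases and unpublished Ct
measurements and are out of scope; the synthetic generators stand in for
them with known ground truth.

See the methods vignette (`vignettes/mirquest-methods.Rmd`) for the model,
every threshold, and the numerical conventions.
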