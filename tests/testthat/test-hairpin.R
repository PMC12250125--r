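test_that("window extraction follows the documented sliding geometry", {
  seq <- withr::with_seed(71, random_seq(300))
  w <- extract_windows(seq, 100, 122)
  # starts run from hit_start - flank in steps of 20; windows that do not
  # fully contain the mature span are dropped
  expect_equal(w$window_start, c(40L, 60L, 80L, 100L))
  expect_equal(w$window_end, w$window_start + 100L)
  expect_true(all(w$window_start <= 100 & w$window_end >= 122))
  expect_equal(w$seq, substring(seq, w$window_start + 1, w$window_end))

  # near the 5' end the start list is clipped at zero
  s2 <- withr::with_seed(72, random_seq(120))
  w2 <- extract_windows(s2, 10, 32)
  expect_equal(w2$window_start, 0L)
  expect_equal(w2$window_end, 100L)

  # a transcript shorter than the window yields one whole-transcript window
  s3 <- withr::with_seed(73, random_seq(80))
  w3 <- extract_windows(s3, 30, 52)
  expect_equal(nrow(w3), 1L)
  expect_equal(w3$window_start, 0L)
  expect_equal(w3$window_end, 80L)
  expect_equal(w3$seq, s3)

  # a span that does not fit yields no windows
  expect_equal(nrow(extract_windows("ACGUACGU", 2, 20)), 0L)
})

test_that("AU and GC percentages are complementary and correct", {
  x <- compute_au_gc("AAUUGGCC")
  expect_equal(x$au_pct, 50)
  expect_equal(x$gc_pct, 50)
  expect_equal(compute_au_gc("AUAUAU")$au_pct, 100)
  withr::with_seed(74, {
    for (i in 1:10) {
      s <- random_seq(60)
      x <- compute_au_gc(s)
      expect_equal(x$au_pct + x$gc_pct, 100)
      expect_equal(x$au_pct,
                   100 * sum(chars(s) %in% c("A", "U")) / 60)
    }
  })
})

test_that("AMFE and MFEI reproduce the worked example and are scale invariant", {
  expect_equal(round(compute_amfe(-88.40, 65), 3), -136.000)
  expect_equal(round(compute_mfei(compute_amfe(-88.40, 65), 61.88), 2), 2.20)
  # AMFE(k*mfe, k*lp) == AMFE(mfe, lp)
  expect_equal(compute_amfe(-30 * 3, 90 * 3), compute_amfe(-30, 90))
  expect_error(compute_amfe(-50, 0), "positive")
  expect_true(is.na(compute_mfei(-100, 0)))
  # MFEI is reported positive
  expect_gt(compute_mfei(-136, 61.88), 0)
})

test_that("published precursor statistics are internally consistent", {
  tab <- readr::read_tsv(system.file("extdata", "musa_precursor_stats.tsv",
                                     package = "mirquest"),
                         show_col_types = FALSE)
  expect_equal(nrow(tab), 17L)
  expect_true(all(abs(tab$au_pct + tab$gc_pct - 100) < 0.015))
  expect_true(all(tab$n_a + tab$n_c + tab$n_g + tab$n_u >= tab$precursor_length))
  # AMFE recomputes from MFE and length at print precision for every entry
  # except one EST whose printed AMFE cell is internally inconsistent
  amfe <- round(compute_amfe(tab$mfe, tab$precursor_length), 3)
  cons <- tab$est_id != "FL667486"
  expect_true(all(abs(amfe[cons] - tab$amfe[cons]) <= 0.01))
  expect_gt(abs(amfe[!cons] - tab$amfe[!cons]), 0.01)
  # MFEI recomputes from the printed AMFE and GC% for every EST entry
  est <- tab$source == "EST"
  mfei <- round(compute_mfei(tab$amfe, tab$gc_pct), 2)
  expect_true(all(abs(mfei[est] - tab$mfei[est]) <= 0.005))
})

test_that("arm location classifies constructed stem-loops", {
  s <- "((((....))))"
  expect_equal(locate_arm(s, 0, 4), "5p")
  expect_equal(locate_arm(s, 8, 12), "3p")
  # fully unpaired mature
  expect_true(is.na(locate_arm(s, 4, 8)))
  # spans both arms (pairs with itself across the loop)
  expect_true(is.na(locate_arm(s, 2, 10)))
  # overlaps the terminal loop of its own hairpin
  expect_true(is.na(locate_arm("((((....))))....", 1, 7)))
  expect_error(locate_arm(s, 5, 20), "outside")
})

test_that("arm location agrees with the designed orientation of synthetic hairpins", {
  mir <- ref_mirnas()
  for (i in 1:5) {
    m <- mir$seq[i]
    hp <- make_hairpin(m, star_mismatches = 0, loop_len = 8, seed = 80 + i)
    expect_equal(locate_arm(hp$structure, hp$mature_start, hp$mature_end), "5p")
    # the mirror-image construct places the mature on the 3p arm
    L <- nchar(m)
    n <- nchar(hp$precursor)
    expect_equal(locate_arm(hp$structure, n - L, n), "3p")
  }
})

test_that("star derivation reads mismatches off the designed structure", {
  m <- "UGCAUUUGCACCUGCACCUA" # 20 nt
  for (mm in c(0L, 3L, 6L)) {
    hp <- make_hairpin(m, star_mismatches = mm, loop_len = 8, seed = 90 + mm)
    st <- derive_star(hp$precursor, hp$structure, 0, 20)
    expect_equal(st$star_mismatches, mm)
  }
  hp0 <- make_hairpin(m, star_mismatches = 0, loop_len = 8, seed = 91)
  st0 <- derive_star(hp0$precursor, hp0$structure, 0, 20)
  # perfect duplex: the star is the 3' arm plus no extension past the end
  expect_equal(st0$star_start, 28L)
  expect_equal(st0$star_end, 48L)
  expect_equal(st0$star_seq, substr(hp0$precursor, 29, 48))
  # fully unpaired mature: no star, all positions count as mismatched
  un <- derive_star("AAAAAAAAAAUUUU", strrep(".", 14), 0, 10)
  expect_true(is.na(un$star_seq))
  expect_equal(un$star_mismatches, 10L)
})

test_that("candidate validation applies the five criteria independently", {
  m <- "UGCAUUUGCACCUGCACCUA"
  hp <- make_hairpin(m, star_mismatches = 0, loop_len = 8, seed = 101)
  base <- function(mfe = -30, mature = m, known = m, ...) {
    validate_candidate(hp$precursor, hp$structure, mfe, 0, 20,
                       mature, known, ...)
  }
  good <- base()
  expect_true(good$passed)
  expect_true(all(c(good$crit_homology, good$crit_hairpin, good$crit_au,
                    good$crit_star, good$crit_mfe)))
  expect_equal(good$precursor_length, 48L)
  expect_equal(good$n_a + good$n_c + good$n_g + good$n_u, 48L)
  expect_equal(good$amfe, compute_amfe(-30, 48))
  expect_equal(good$arm, "5p")

  # (v) an energy above the threshold fails only the energy criterion
  weak <- base(mfe = -15)
  expect_false(weak$crit_mfe)
  expect_false(weak$passed)
  expect_true(weak$crit_hairpin && weak$crit_au && weak$crit_star)
  # boundary: exactly -20 passes (inclusive)
  expect_true(base(mfe = -20)$crit_mfe)

  # (i) four mature mismatches fail homology, three pass (inclusive bound)
  mut <- function(k) {
    v <- chars(m); v[1:k] <- ifelse(v[1:k] == "A", "C", "A")
    paste(v, collapse = "")
  }
  expect_true(base(mature = mut(3))$crit_homology)
  expect_false(base(mature = mut(4))$crit_homology)
  # truncated mature: unaligned overhang of the known counts as mismatched
  known22 <- paste0(m, "GG")
  expect_equal(base(known = known22)$mature_mismatches, 2)
  expect_true(base(known = known22)$crit_homology)

  # (iii) an AU-rich precursor fails the composition window
  mau <- "UAUAUUAAUUAAUAUUAAUU"
  hau <- make_hairpin(mau, star_mismatches = 0, loop_len = 8, seed = 102)
  rau <- validate_candidate(hau$precursor, hau$structure, -30, 0, 20, mau, mau)
  expect_gt(rau$au_pct, 70)
  expect_false(rau$crit_au)
  expect_false(rau$passed)
  expect_true(rau$crit_hairpin)

  # (iv) six unpaired mature positions fail (strict), five pass
  h6 <- make_hairpin(m, star_mismatches = 6, loop_len = 8, seed = 103)
  r6 <- validate_candidate(h6$precursor, h6$structure, -30, 0, 20, m, m)
  expect_equal(r6$star_mismatches, 6L)
  expect_false(r6$crit_star)
  h5 <- make_hairpin(m, star_mismatches = 5, loop_len = 8, seed = 104)
  r5 <- validate_candidate(h5$precursor, h5$structure, -30, 0, 20, m, m)
  expect_true(r5$crit_star)

  # (ii) an unstructured context fails the hairpin requirement
  run <- validate_candidate(hp$precursor, strrep(".", 48), -30, 0, 20, m, m)
  expect_false(run$crit_hairpin)
  expect_false(run$passed)
})

test_that("best-window selection minimizes MFEI with documented tie-breaks", {
  w <- tibble::tibble(
    passed = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    mfei = c(0.9, 0.7, 0.1, 0.7, 0.7),
    mfe = c(-40, -35, -90, -42, -42),
    window_start = c(0L, 20L, 40L, 60L, 80L)
  )
  best <- select_best_window(w)
  expect_equal(nrow(best), 1L)
  expect_equal(best$window_start, 60L) # min mfei among passed, then min mfe,
                                       # then leftmost
  # permutation invariance (sort oracle)
  withr::with_seed(111, {
    for (i in 1:5) {
      expect_equal(select_best_window(w[sample(nrow(w)), ]), best)
    }
  })
  expect_equal(nrow(select_best_window(w[w$mfei > 1, ])), 0L)
})

test_that("a planted hairpin is recovered as a passing precursor end to end", {
  mir <- ref_mirnas()[3, c("name", "seq", "family")]
  hp <- make_hairpin(mir$seq, star_mismatches = 0, loop_len = 8, seed = 121)
  emb <- embed_precursors(hp$precursor, 120, 300, seed = 122, id = "tx1")
  hits <- scan_transcripts(emb$transcript, mir)
  hits <- hits[hits$strand == "+" & hits$start == 120, ]
  expect_equal(nrow(hits), 1L)
  cand <- predict_precursors(emb$transcript, hits, mir, provider = "nussinov")
  expect_equal(nrow(cand), 1L)
  expect_true(cand$passed)
  expect_equal(cand$family, mir$family)
  # the planted precursor lies inside the selected window
  expect_lte(cand$window_start, 120L)
  expect_gte(cand$window_end, 120L + nchar(hp$precursor))
  expect_equal(substr(cand$precursor_seq,
                      cand$mature_start + 1, cand$mature_end),
               mir$seq)
})

test_that("minus-strand hits yield precursors in duplex orientation", {
  mir <- ref_mirnas()[5, c("name", "seq", "family")]
  hp <- make_hairpin(mir$seq, star_mismatches = 0, loop_len = 8, seed = 131)
  emb <- embed_precursors(reverse_complement(hp$precursor), 120, 300,
                          seed = 132, id = "tx1")
  hits <- scan_transcripts(emb$transcript, mir)
  hits <- hits[hits$strand == "-", ]
  expect_gte(nrow(hits), 1L)
  cand <- predict_precursors(emb$transcript, hits, mir, provider = "nussinov")
  expect_true(any(cand$passed))
  best <- cand[cand$passed, ][1, ]
  expect_equal(substr(best$precursor_seq,
                      best$mature_start + 1, best$mature_end),
               mir$seq)
})
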