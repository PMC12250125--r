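test_that("generators are pure functions of their seed", {
  m <- "UGCAUUUGCACCUGCACCUA"
  expect_identical(make_hairpin(m, 2, seed = 401), make_hairpin(m, 2, seed = 401))
  expect_false(identical(make_hairpin(m, 2, seed = 401)$precursor,
                         make_hairpin(m, 2, seed = 402)$precursor))
  expect_identical(make_decoy(120, seed = 403, provider = "nussinov"),
                   make_decoy(120, seed = 403, provider = "nussinov"))
  t1 <- make_target_mrna(m, c(3, 10), seed = 404)
  expect_identical(t1, make_target_mrna(m, c(3, 10), seed = 404))
  g <- tibble::tibble(gene = "g", class = "miRNA", fold_change = 2)
  expect_identical(make_ct_table(g, seed = 405), make_ct_table(g, seed = 405))
})

test_that("designed hairpins have the documented geometry and fold as designed", {
  m <- "UGCAUUUGCACCUGCACCUA" # 20 nt
  hp <- make_hairpin(m, star_mismatches = 0, loop_len = 8, seed = 406)
  expect_equal(nchar(hp$precursor), 48L) # 20 + 8 + 20
  expect_equal(substr(hp$precursor, 1, 20), m)
  expect_equal(substr(hp$precursor, 29, 48), reverse_complement(m))
  expect_true(grepl("^[AC]+$", substr(hp$precursor, 21, 28))) # inert loop
  expect_equal(hp$structure,
               paste0(strrep("(", 20), strrep(".", 8), strrep(")", 20)))
  # the built-in folder pairs every mature position of the perfect duplex
  f <- nussinov_fold(hp$precursor)
  pt <- dot_bracket_pairs(f$structure)
  expect_true(all(!is.na(pt[1:20])))
  expect_equal(locate_arm(f$structure, 0, 20), "5p")
  expect_error(make_hairpin(m, loop_len = 2, seed = 1), "loop_len")
  expect_error(make_hairpin(m, star_mismatches = 9, seed = 1), "between")
})

test_that("knocked-out star positions cannot pair with their facing base", {
  m <- "UGCAUUUGCACCUGCACCUA"
  hp <- make_hairpin(m, star_mismatches = 7, loop_len = 8, seed = 407)
  # the designed structure reports exactly 7 unpaired duplex positions
  v <- validate_candidate(hp$precursor, hp$structure, -30, 0, 20, m, m)
  expect_equal(v$star_mismatches, 7L)
  expect_false(v$crit_star)
  expect_false(v$passed)
  # every substituted pair is neither Watson-Crick nor G:U
  pre <- chars(hp$precursor)
  des <- chars(hp$structure)
  knocked <- which(des[1:20] == ".")
  expect_length(knocked, 7L)
  for (i in knocked) {
    pair <- paste0(pre[i], pre[48 - i + 1])
    expect_false(pair %in% c("AU", "UA", "GC", "CG", "GU", "UG"), info = pair)
  }
})

test_that("embedding plants precursors verbatim at the requested positions", {
  hp <- make_hairpin("UGGAAGGGGCAUGCAGAGGAG", 0, seed = 408)$precursor
  emb <- embed_precursors(hp, 100, 400, seed = 409, id = "t")
  expect_equal(nchar(emb$transcript$seq), 400L)
  expect_equal(substr(emb$transcript$seq, 101, 100 + nchar(hp)), hp)
  expect_equal(emb$truth$precursor_start, 100L)
  expect_equal(emb$truth$precursor_end, 100L + nchar(hp))
  # at position 0 the precursor is a prefix
  e0 <- embed_precursors(hp, 0, 200, seed = 410)
  expect_equal(substr(e0$transcript$seq, 1, nchar(hp)), hp)
  # two non-overlapping plants both land; overlap and overflow are errors
  e2 <- embed_precursors(c(hp, hp), c(0, 500), 1000, seed = 411)
  expect_equal(substr(e2$transcript$seq, 501, 500 + nchar(hp)), hp)
  expect_error(embed_precursors(c(hp, hp), c(0, 10), 1000, seed = 1),
               "overlap")
  expect_error(embed_precursors(hp, 980, 1000, seed = 1), "fit")
})

test_that("background composition follows the requested GC bias", {
  emb <- embed_precursors(character(0), integer(0), 4000, seed = 412,
                          gc_bias = 0.7)
  v <- chars(emb$transcript$seq)
  expect_lt(abs(mean(v %in% c("G", "C")) - 0.7), 0.05)
})

test_that("decoys fold above the energetic threshold by construction", {
  for (i in 1:5) {
    d <- make_decoy(300, seed = 420 + i, provider = "nussinov")
    expect_equal(nchar(d), 300L)
    expect_gt(fold_rna(d, provider = "nussinov")$mfe, -20)
  }
})

test_that("designed target mRNAs carry the site at the designed span", {
  m <- "UCUUUCCAAUUCCUCCCAUGCC"
  t <- make_target_mrna(m, c(2, 10), length = 300, position = 40, seed = 430)
  expect_equal(nchar(t$mrna$seq), 300L)
  expect_equal(t$truth$site_start, 40L)
  expect_equal(t$truth$site_end, 40L + nchar(m))
  # expectation: position 2 (seed) 1*2 + position 10 (seed) 1*2 = 4
  expect_equal(t$truth$designed_expectation, 4)
  expect_equal(t$truth$designed_inhibition, "translation")
  t2 <- make_target_mrna(m, c(2, 15), length = 300, seed = 431)
  # position 15 lies outside the seed: 1*2 + 1 = 3
  expect_equal(t2$truth$designed_expectation, 3)
  expect_equal(t2$truth$designed_inhibition, "cleavage")
  expect_error(make_target_mrna(m, 30, seed = 1), "outside")
  expect_error(make_target_mrna(m, length = 10, seed = 1), "shorter")
})

test_that("Ct tables encode fold changes in the stress condition only", {
  g <- tibble::tibble(gene = c("a", "b"), class = c("miRNA", "mRNA"),
                      fold_change = c(8, 0.25))
  sim <- make_ct_table(g, seed = 440, n_bio = 2, n_tech = 2)
  ct <- sim$ct_table
  expect_setequal(unique(ct$gene), c("a", "b", "MaU6", "MaUBQ2"))
  a <- ct[ct$gene == "a", ]
  expect_equal(unique(a$ct[a$condition == "control"]), 24)
  expect_equal(unique(a$ct[a$condition == "stress"]), 24 - 3) # log2(8)
  b <- ct[ct$gene == "b", ]
  expect_equal(unique(b$ct[b$condition == "stress"]), 24 + 2) # -log2(0.25)
  expect_equal(unique(ct$ct[ct$gene == "MaU6"]), 18)
  # replicate structure: 2 bio x 2 tech per condition per gene
  expect_equal(nrow(a), 2 * 2 * 2)
  expect_error(make_ct_table(tibble::tibble(gene = "x", class = "miRNA",
                                            fold_change = 0), seed = 1),
               "> 0")
})

test_that("the discovery corpus mixes criteria-conforming plants with decoys", {
  mir <- ref_mirnas()[1:4, c("name", "seq")]
  corp <- make_discovery_corpus(mir, n_planted = 4, n_decoys = 2,
                                transcript_len = 300, seed = 450,
                                provider = "nussinov")
  expect_equal(nrow(corp$transcripts), 6L)
  expect_equal(nrow(corp$truth), 4L)
  expect_length(corp$decoy_ids, 2L)
  # miRNAs are assigned round-robin
  expect_equal(corp$truth$mirna_name, mir$name)
  # every planted mature is present verbatim at its recorded span
  for (i in 1:4) {
    tr <- corp$truth[i, ]
    seq <- corp$transcripts$seq[corp$transcripts$id == tr$id]
    expect_equal(substr(seq, tr$mature_start + 1, tr$mature_end),
                 mir$seq[i])
  }
})
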