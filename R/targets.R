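# miRNA:mRNA target-site scoring in the psRNATarget/miRU tradition: a
# positionwise expectation penalty over the antiparallel duplex (Watson-Crick
# pair 0, G:U wobble 0.5, mismatch 1; penalties doubled in the seed region,
# miRNA positions 2-13), a maximum-expectation reporting cutoff, and a
# central-window (positions 9-11) rule separating cleavage from
# translational inhibition.

#' Default target-scoring weights
#'
#' @param wc,gu,mismatch,gap Per-position penalties.
#' @param seed_start,seed_end Seed region (1-based, inclusive, from the
#'   miRNA 5' end) in which penalties are doubled.
#' @param seed_multiplier Penalty multiplier inside the seed.
#' @return Named list of weights.
#' @export
target_weights <- function(wc = 0, gu = 0.5, mismatch = 1, gap = 2,
                           seed_start = 2, seed_end = 13,
                           seed_multiplier = 2) {
  list(wc = wc, gu = gu, mismatch = mismatch, gap = gap,
       seed_start = seed_start, seed_end = seed_end,
       seed_multiplier = seed_multiplier)
}

# Per-position penalties for a miRNA against one mRNA window, antiparallel:
# miRNA position k (1-based from its 5' end) faces mRNA window position
# L - k + 1 (window given 5'->3').
site_penalties <- function(mirna_seq, mrna_window, weights = target_weights()) {
  L <- nchar(mirna_seq)
  if (nchar(mrna_window) != L) {
    abort("score_site: mRNA window length must equal miRNA length (ungapped mode)")
  }
  assert_unambiguous(c(mirna_seq, mrna_window))
  mi <- seq_chars(mirna_seq)
  mr <- rev(seq_chars(mrna_window)) # antiparallel
  wc <- (mi == "A" & mr == "U") | (mi == "U" & mr == "A") |
    (mi == "G" & mr == "C") | (mi == "C" & mr == "G")
  gu <- (mi == "G" & mr == "U") | (mi == "U" & mr == "G")
  pen <- ifelse(wc, weights$wc, ifelse(gu, weights$gu, weights$mismatch))
  k <- seq_len(L)
  seed <- k >= weights$seed_start & k <= weights$seed_end
  pen[seed] <- pen[seed] * weights$seed_multiplier
  list(penalty = pen, wc = wc, gu = gu)
}

#' Expectation score of a miRNA against one mRNA window
#'
#' Lower is better; 0 means full Watson-Crick complementarity.
#'
#' @param mirna_seq Mature miRNA, 5'->3'.
#' @param mrna_window mRNA window of the same length, 5'->3'.
#' @param weights Scoring weights (see [target_weights()]).
#' @return Numeric expectation (penalty sum).
#' @export
#' @examples
#' score_site("UGGAAGGGGCAUGCAGAGGAG",
#'            reverse_complement("UGGAAGGGGCAUGCAGAGGAG")) # 0
score_site <- function(mirna_seq, mrna_window, weights = target_weights()) {
  sum(site_penalties(mirna_seq, mrna_window, weights)$penalty)
}

#' Classify the predicted inhibition mode of a site
#'
#' Translational inhibition is called when any non-Watson-Crick position
#' (mismatch or G:U wobble) falls in the central window, miRNA positions
#' `central_start`-`central_end` (default 9-11, 1-based from the 5' end);
#' full central complementarity predicts cleavage.
#'
#' @inheritParams score_site
#' @param central_start,central_end Central window bounds.
#' @return `"cleavage"` or `"translation"`.
#' @export
classify_inhibition <- function(mirna_seq, mrna_window,
                                weights = target_weights(),
                                central_start = 9, central_end = 11) {
  p <- site_penalties(mirna_seq, mrna_window, weights)
  k <- seq_len(nchar(mirna_seq))
  central <- k >= central_start & k <= central_end
  if (any(!p$wc[central])) "translation" else "cleavage"
}

#' Find target sites of miRNAs in mRNAs
#'
#' Scores every window of each mRNA against each miRNA and reports windows
#' with expectation at or below `max_expectation`. Overlapping windows of
#' one miRNA:mRNA pair are collapsed to the best-scoring one (ties ->
#' leftmost). Each site carries flanking context (17 nt upstream, 13 nt
#' downstream by default) for reporting and accessibility analysis.
#'
#' @param mirnas Tibble with `name`, `seq` columns.
#' @param mrnas Tibble with `id`, `seq` columns.
#' @param max_expectation Reporting cutoff (default 3.0).
#' @param weights Scoring weights (see [target_weights()]).
#' @param flank_up,flank_down Reported flanking context in nt.
#' @return Tibble with columns `mirna_name`, `mrna_id`, `start`, `end`
#'   (0-based half-open on the mRNA), `expectation`, `inhibition`,
#'   `aln_mirna`, `aln_match`, `aln_mrna` (alignment triple: miRNA 5'->3',
#'   match line with `|` for Watson-Crick and `o` for G:U, mRNA 3'->5'),
#'   `flank_up`, `flank_down`.
#' @export
find_sites <- function(mirnas, mrnas, max_expectation = 3.0,
                       weights = target_weights(),
                       flank_up = 17, flank_down = 13) {
  out <- list()
  for (i in seq_len(nrow(mirnas))) {
    m <- mirnas$seq[i]
    L <- nchar(m)
    for (j in seq_len(nrow(mrnas))) {
      s <- mrnas$seq[j]
      n <- nchar(s)
      if (n < L) next
      starts <- 0:(n - L)
      windows <- substring(s, starts + 1L, starts + L)
      scores <- vapply(windows, score_site, numeric(1), mirna_seq = m,
                       weights = weights, USE.NAMES = FALSE)
      ok <- which(scores <= max_expectation)
      if (length(ok) == 0) next
      sites <- tibble(start = starts[ok], expectation = scores[ok]) |>
        collapse_sites(L)
      rows <- pmap(sites, function(start, expectation) {
        win <- substr(s, start + 1L, start + L)
        p <- site_penalties(m, win, weights)
        match_line <- paste(ifelse(p$wc, "|", ifelse(p$gu, "o", " ")),
                            collapse = "")
        tibble(
          mirna_name = mirnas$name[i], mrna_id = mrnas$id[j],
          start = start, end = start + L,
          expectation = expectation,
          inhibition = classify_inhibition(m, win, weights),
          aln_mirna = m, aln_match = match_line,
          aln_mrna = paste(rev(seq_chars(win)), collapse = ""),
          flank_up = substr(s, max(1L, start + 1L - flank_up), start),
          flank_down = substr(s, start + L + 1L,
                              min(n, start + L + flank_down))
        )
      })
      out[[length(out) + 1L]] <- bind_rows(rows)
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(mirna_name = character(), mrna_id = character(),
                  start = integer(), end = integer(),
                  expectation = numeric(), inhibition = character(),
                  aln_mirna = character(), aln_match = character(),
                  aln_mrna = character(), flank_up = character(),
                  flank_down = character()))
  }
  arrange(res, .data$mirna_name, .data$mrna_id, .data$start)
}

# best-scoring representative of each run of mutually overlapping windows
collapse_sites <- function(sites, L) {
  sites <- arrange(sites, .data$expectation, .data$start)
  kept <- integer(0); ks <- integer(0)
  for (i in seq_len(nrow(sites))) {
    s <- sites$start[i]
    if (all(abs(s - ks) >= L)) {
      kept <- c(kept, i); ks <- c(ks, s)
    }
  }
  sites[sort(kept), ]
}

#' Energy to unpair a target site (UPE)
#'
#' Accessibility of a site: the difference between the minimum free energy
#' of the local mRNA context folded with the site forced single-stranded and
#' folded without constraint. Always non-negative. Requires the
#' thermodynamic (vienna) provider; NA is returned when it is unavailable.
#' Sites with UPE above the conventional 25 kcal/mol threshold are flagged
#' as poorly accessible, not removed.
#'
#' @param mrna_seq The mRNA sequence.
#' @param start,end Site span, 0-based half-open.
#' @param flank_up,flank_down Context taken around the site, nt.
#' @return Numeric UPE in kcal/mol, or NA.
#' @export
compute_upe <- function(mrna_seq, start, end, flank_up = 17, flank_down = 13) {
  if (!vienna_available()) return(NA_real_)
  n <- nchar(mrna_seq)
  c1 <- max(0L, start - flank_up)
  c2 <- min(n, end + flank_down)
  ctx <- substr(mrna_seq, c1 + 1L, c2)
  constraint <- strrep(".", c2 - c1)
  site_idx <- (start - c1 + 1L):(end - c1)
  constraint <- seq_chars(constraint)
  constraint[site_idx] <- "x"
  constraint <- paste(constraint, collapse = "")
  free <- vienna_fold(ctx)
  open <- vienna_fold(ctx, constraints = constraint)
  max(0, open$mfe - free$mfe)
}
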