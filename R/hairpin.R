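# Precursor extraction and hairpin validation. Candidate windows around each
# homology hit are folded and screened against five criteria:
#   (i)   <= 3 mismatches between the predicted mature and the known miRNA,
#   (ii)  the mature sits in one arm of a hairpin stem-loop,
#   (iii) precursor AU% between 30 and 70 (inclusive),
#   (iv)  fewer than 6 mature positions unpaired opposite the star strand,
#   (v)   MFE at or below -20 kcal/mol.
# Alongside the verdicts the standard precursor statistics are computed:
# AMFE = 100 * MFE / length and MFEI = |AMFE| / GC%.

#' Candidate precursor windows around a homology hit
#'
#' Slides a window of `window` nt in steps of `step` nt across the region
#' from `flank` nt upstream of the mature to `flank` nt downstream, keeping
#' every window that fully contains the mature span. Windows are clipped at
#' transcript ends; a transcript shorter than `window` yields a single
#' whole-transcript window.
#'
#' @param seq Transcript sequence.
#' @param hit_start,hit_end Mature span on the transcript, 0-based half-open.
#' @param window,step,flank Window geometry in nt (defaults 100/20/80).
#' @return Tibble with `window_start`, `window_end` (0-based half-open) and
#'   `seq`; empty if the mature span does not fit on the transcript.
#' @export
extract_windows <- function(seq, hit_start, hit_end, window = 100, step = 20,
                            flank = 80) {
  L <- nchar(seq)
  span <- hit_end - hit_start
  if (span > L || hit_start < 0 || hit_end > L) {
    return(tibble(window_start = integer(), window_end = integer(),
                  seq = character()))
  }
  if (L <= window) {
    starts <- 0L
  } else {
    lo <- max(0L, hit_start - flank)
    hi <- min(L - window, hit_end + flank - window)
    starts <- if (hi < lo) lo else seq(lo, hi, by = step)
  }
  ends <- pmin(starts + window, L)
  keep <- starts <= hit_start & ends >= hit_end
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts) == 0) {
    return(tibble(window_start = integer(), window_end = integer(),
                  seq = character()))
  }
  tibble(window_start = as.integer(starts), window_end = as.integer(ends),
         seq = substring(seq, starts + 1L, ends))
}

#' AU and GC percentage of a precursor
#'
#' @param seq RNA string over {A,C,G,U}.
#' @return Named list with `au_pct` and `gc_pct` (they sum to 100).
#' @export
compute_au_gc <- function(seq) {
  assert_unambiguous(seq)
  v <- seq_chars(seq)
  n <- length(v)
  au <- 100 * sum(v %in% c("A", "U")) / n
  list(au_pct = au, gc_pct = 100 - au)
}

#' Adjusted minimal folding free energy (AMFE)
#'
#' MFE normalized to a 100-nt precursor: `100 * mfe / lp`, in kcal/mol per
#' 100 nt.
#'
#' @param mfe Minimal folding free energy, kcal/mol.
#' @param lp Precursor length, nt (> 0).
#' @return Numeric AMFE.
#' @export
#' @examples
#' compute_amfe(-88.40, 65) # -136
compute_amfe <- function(mfe, lp) {
  if (any(lp <= 0)) abort("precursor length must be positive")
  100 * mfe / lp
}

#' Minimal folding free energy index (MFEI)
#'
#' `|AMFE| / GC%`, reported as a positive, dimensionless number. Values
#' above ~0.85 distinguish miRNA precursors from other structured RNAs.
#' Undefined (NA) when GC% is zero.
#'
#' @param amfe AMFE value (see [compute_amfe()]).
#' @param gc_pct GC percentage of the precursor.
#' @return Numeric MFEI, or NA when `gc_pct` is 0.
#' @export
#' @examples
#' compute_mfei(compute_amfe(-88.40, 65), 61.88) # ~2.20
compute_mfei <- function(amfe, gc_pct) {
  ifelse(gc_pct == 0, NA_real_, abs(amfe) / gc_pct)
}

#' Locate the hairpin arm holding the mature miRNA
#'
#' Identifies the hairpin whose stem pairs with the mature and classifies
#' the mature as 5p (entirely 5' of that hairpin's terminal loop) or 3p
#' (entirely 3' of it). Rejected (NA) when the mature is fully unpaired,
#' pairs with itself, spans both arms, or overlaps the terminal loop.
#'
#' @param structure Dot-bracket string.
#' @param mature_start,mature_end Mature span within the precursor, 0-based
#'   half-open.
#' @return `"5p"`, `"3p"`, or `NA_character_` when rejected.
#' @export
locate_arm <- function(structure, mature_start, mature_end) {
  if (mature_end > nchar(structure) || mature_start < 0) {
    abort("mature span outside structure")
  }
  pt <- dot_bracket_pairs(structure)
  mp <- (mature_start + 1L):mature_end
  paired <- mp[!is.na(pt[mp])]
  if (length(paired) == 0) return(NA_character_)
  q <- pt[paired]
  if (any(q %in% mp)) return(NA_character_) # pairs with itself across the loop
  if (all(q > max(mp))) {
    side <- "5p"
    b_in <- min(q); a_in <- pt[b_in]
  } else if (all(q < min(mp))) {
    side <- "3p"
    a_in <- max(q); b_in <- pt[a_in]
  } else {
    return(NA_character_) # partners on both sides: spans both arms
  }
  # terminal loop of the enclosing helix = strictly inside its innermost pair
  if (any(mp > a_in & mp < b_in)) return(NA_character_)
  side
}

#' Derive the star strand opposite the mature
#'
#' The star is read off the reported structure: the positions pairing with
#' the mature, extended by the 2-nt 3' overhang characteristic of Dicer
#' products. The star mismatch count is the number of mature positions left
#' unpaired within the mature-star duplex (G:U wobbles count as paired).
#'
#' @param seq Precursor sequence.
#' @param structure Dot-bracket string for `seq`.
#' @param mature_start,mature_end Mature span, 0-based half-open.
#' @return List with `star_seq`, `star_start`, `star_end` (0-based
#'   half-open) and `star_mismatches`; `star_seq` is NA and
#'   `star_mismatches` is the full mature length when the mature is fully
#'   unpaired.
#' @export
derive_star <- function(seq, structure, mature_start, mature_end) {
  pt <- dot_bracket_pairs(structure)
  mp <- (mature_start + 1L):mature_end
  paired <- mp[!is.na(pt[mp])]
  unpaired <- length(mp) - length(paired)
  if (length(paired) == 0) {
    return(list(star_seq = NA_character_, star_start = NA_integer_,
                star_end = NA_integer_, star_mismatches = length(mp)))
  }
  q <- pt[paired]
  s1 <- min(q)
  s2 <- min(max(q) + 2L, nchar(seq)) # 2-nt 3' overhang
  list(star_seq = substr(seq, s1, s2),
       star_start = s1 - 1L, star_end = s2,
       star_mismatches = unpaired)
}

#' Validate one precursor candidate against the five criteria
#'
#' @param seq Precursor (window) sequence.
#' @param structure Dot-bracket structure for `seq`.
#' @param mfe Folding energy of `seq` (kcal/mol for a thermodynamic
#'   provider; minus the pair count for the built-in folder).
#' @param mature_start,mature_end Mature span within the precursor, 0-based
#'   half-open.
#' @param mature_seq The predicted mature sequence (duplex orientation).
#' @param known_seq The known plant miRNA it was matched to.
#' @param max_mature_mismatch Criterion (i) bound (default 3, inclusive).
#' @param au_min,au_max Criterion (iii) bounds (default 30-70, inclusive).
#' @param max_star_mismatch Criterion (iv) bound (default 6, strict: fewer
#'   than 6 unpaired mature positions pass).
#' @param max_mfe Criterion (v) bound (default -20, inclusive).
#' @return One-row tibble with the composition and energy statistics, the
#'   arm/star calls, five criterion flags (`crit_homology`, `crit_hairpin`,
#'   `crit_au`, `crit_star`, `crit_mfe`) and `passed`.
#' @export
validate_candidate <- function(seq, structure, mfe, mature_start, mature_end,
                               mature_seq, known_seq,
                               max_mature_mismatch = 3,
                               au_min = 30, au_max = 70,
                               max_star_mismatch = 6,
                               max_mfe = -20) {
  comp <- compute_au_gc(seq)
  lp <- nchar(seq)
  amfe <- compute_amfe(mfe, lp)
  mfei <- compute_mfei(amfe, comp$gc_pct)
  arm <- locate_arm(structure, mature_start, mature_end)
  star <- derive_star(seq, structure, mature_start, mature_end)
  n_mm <- if (nchar(mature_seq) == nchar(known_seq)) {
    hamming_mismatches(mature_seq, known_seq)
  } else {
    # truncated homology hit: compare over the aligned fragment and count
    # the unaligned overhang of the known miRNA as mismatched
    k <- nchar(mature_seq)
    best <- min(hamming_mismatches(mature_seq, substr(known_seq, 1, k)),
                hamming_mismatches(mature_seq,
                                   substr(known_seq,
                                          nchar(known_seq) - k + 1,
                                          nchar(known_seq))))
    best + (nchar(known_seq) - k)
  }
  v <- seq_chars(seq)
  tibble(
    precursor_length = lp,
    au_pct = comp$au_pct, gc_pct = comp$gc_pct,
    n_a = sum(v == "A"), n_c = sum(v == "C"),
    n_g = sum(v == "G"), n_u = sum(v == "U"),
    mfe = mfe, amfe = amfe, mfei = mfei,
    arm = arm,
    star_seq = star$star_seq, star_mismatches = star$star_mismatches,
    mature_mismatches = n_mm,
    crit_homology = n_mm <= max_mature_mismatch,
    crit_hairpin = !is.na(arm),
    crit_au = comp$au_pct >= au_min & comp$au_pct <= au_max,
    crit_star = star$star_mismatches < max_star_mismatch,
    crit_mfe = mfe <= max_mfe
  ) |>
    mutate(passed = .data$crit_homology & .data$crit_hairpin &
             .data$crit_au & .data$crit_star & .data$crit_mfe)
}

#' Select the best passing window for one hit
#'
#' Among passing windows the one with minimal MFEI is retained; ties break
#' to the lower MFE, then to the leftmost window.
#'
#' @param windows A candidate tibble with `passed`, `mfei`, `mfe`,
#'   `window_start` columns.
#' @return At most one row of `windows`.
#' @export
select_best_window <- function(windows) {
  passing <- filter(windows, .data$passed)
  if (nrow(passing) == 0) return(passing)
  arrange(passing, .data$mfei, .data$mfe, .data$window_start) |> slice(1)
}

#' Predict and validate precursor candidates for a set of homology hits
#'
#' For every hit, extracts candidate windows, folds them, validates each
#' against the five criteria, and keeps the best passing window (minimal
#' MFEI, then minimal MFE, then leftmost). For minus-strand hits the mature
#' and its windows are taken as the reverse complement of the transcript
#' region, so precursors are always reported in hairpin (5'->3' duplex)
#' orientation.
#'
#' @param transcripts Transcript tibble.
#' @param hits Hit tibble from [scan_transcripts()].
#' @param mirnas Reference mature-miRNA tibble (for criterion (i) and family
#'   labels).
#' @param window,step,flank Window geometry (see [extract_windows()]).
#' @param provider Folding provider (see [fold_rna()]).
#' @param keep_all Return all scored windows instead of the best passing one
#'   per hit (default FALSE).
#' @param ... Criterion bounds passed to [validate_candidate()].
#' @return Candidate tibble: one row per selected precursor (or per window
#'   when `keep_all`), with source coordinates, structure, statistics and
#'   verdicts.
#' @export
predict_precursors <- function(transcripts, hits, mirnas, window = 100,
                               step = 20, flank = 80, provider = "auto",
                               keep_all = FALSE, ...) {
  provider <- resolve_provider(provider)
  if (nrow(hits) == 0) return(empty_candidates())
  tseq <- setNames(transcripts$seq, transcripts$id)
  tlen <- setNames(transcripts$length, transcripts$id)
  mir <- setNames(mirnas$seq, mirnas$name)
  fam <- setNames(mirnas$family, mirnas$name)
  out <- vector("list", nrow(hits))
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    seq <- tseq[[h$transcript_id]]
    wins <- extract_windows(seq, h$start, h$end, window, step, flank)
    if (nrow(wins) == 0) next
    if (h$strand == "-") {
      # orient windows so the mature reads 5'->3' inside the precursor
      L <- nchar(seq)
      wseq <- reverse_complement(wins$seq)
      mstart <- wins$window_end - h$end
    } else {
      wseq <- wins$seq
      mstart <- h$start - wins$window_start
    }
    mlen <- h$end - h$start
    mature <- if (h$strand == "-") reverse_complement(h$matched_seq) else h$matched_seq
    known <- mir[[h$mirna_name]]
    folded <- fold_rna(wseq, provider = provider)
    rows <- vector("list", nrow(wins))
    for (w in seq_len(nrow(wins))) {
      val <- validate_candidate(
        folded$seq[w], folded$structure[w], folded$mfe[w],
        mstart[w], mstart[w] + mlen, mature, known, ...
      )
      rows[[w]] <- dplyr::bind_cols(
        tibble(source_id = h$transcript_id,
               mirna_name = h$mirna_name,
               family = fam[[h$mirna_name]],
               source_length = unname(tlen[[h$transcript_id]]),
               strand = h$strand,
               window_start = wins$window_start[w],
               window_end = wins$window_end[w],
               precursor_seq = folded$seq[w],
               structure = folded$structure[w],
               mature_start = mstart[w],
               mature_end = mstart[w] + mlen,
               mature_seq = mature),
        val
      )
    }
    cand <- bind_rows(rows)
    out[[i]] <- if (keep_all) cand else select_best_window(cand)
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) empty_candidates() else res
}

empty_candidates <- function() {
  tibble(source_id = character(), mirna_name = character(),
         family = character(), source_length = integer(),
         strand = character(), window_start = integer(),
         window_end = integer(), precursor_seq = character(),
         structure = character(), mature_start = integer(),
         mature_end = integer(), mature_seq = character(),
         precursor_length = integer(), au_pct = numeric(),
         gc_pct = numeric(), n_a = integer(), n_c = integer(),
         n_g = integer(), n_u = integer(), mfe = numeric(),
         amfe = numeric(), mfei = numeric(), arm = character(),
         star_seq = character(), star_mismatches = numeric(),
         mature_mismatches = numeric(), crit_homology = logical(),
         crit_hairpin = logical(), crit_au = logical(),
         crit_star = logical(), crit_mfe = logical(), passed = logical())
}
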