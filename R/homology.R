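# Ungapped, mismatch-limited scanning of reference mature miRNAs against
# transcripts, on both strands. Exhaustive window comparison replaces a
# heuristic local aligner: at query lengths of 18-26 nt with <= 2 mismatches
# the exhaustive scan is exact and deterministic.

#' Count Hamming mismatches between two equal-length RNA strings
#'
#' @param a,b RNA strings over {A,C,G,U} of identical length.
#' @return Integer number of positions at which `a` and `b` differ.
#' @export
#' @examples
#' hamming_mismatches("AAAA", "AAAU") # 1
hamming_mismatches <- function(a, b) {
  if (nchar(a) != nchar(b)) abort("hamming_mismatches: unequal lengths")
  assert_unambiguous(c(a, b))
  sum(seq_chars(a) != seq_chars(b))
}

#' Scan transcripts for homologs of mature miRNAs
#'
#' Slides every reference miRNA along every transcript on both strands and
#' reports each gap-free alignment with at most `max_mismatch` mismatches.
#' Full-length alignments are preferred; terminal truncations (contiguous
#' prefixes or suffixes of the mature) are allowed down to `min_len`
#' nucleotides, emulating the local alignments a nucleotide BLAST would
#' report at these query lengths. Overlapping hits of the same miRNA on one
#' transcript are collapsed to a single best hit (longest match, then fewest
#' mismatches, then leftmost). Windows containing IUPAC ambiguity codes are
#' excluded from scoring.
#'
#' @param transcripts Tibble with columns `id`, `seq` (see
#'   [read_transcripts()]).
#' @param mirnas Tibble with columns `name`, `seq` (see
#'   [read_mature_mirnas()]).
#' @param max_mismatch Maximum mismatches per alignment (default 2).
#' @param min_len Minimum gap-free alignment length (default 18).
#' @return Tibble of hits with columns `transcript_id`, `mirna_name`,
#'   `start`, `end` (0-based half-open on the forward strand), `strand`,
#'   `match_len`, `mismatches`, `matched_seq` (the transcript window in
#'   forward orientation), sorted by (transcript_id, start, mirna_name).
#' @export
scan_transcripts <- function(transcripts, mirnas, max_mismatch = 2,
                             min_len = 18) {
  if (nrow(mirnas) == 0) abort("empty reference miRNA set")
  if (nrow(transcripts) == 0) return(empty_hits())
  hits <- vector("list", nrow(transcripts))
  frag_tbl <- mirna_fragments(mirnas, min_len)
  for (ti in seq_len(nrow(transcripts))) {
    hits[[ti]] <- scan_one_transcript(
      transcripts$id[ti], transcripts$seq[ti], frag_tbl, max_mismatch
    )
  }
  out <- bind_rows(hits)
  if (nrow(out) == 0) return(empty_hits())
  out <- collapse_overlaps(out)
  arrange(out, .data$transcript_id, .data$start, .data$mirna_name)
}

empty_hits <- function() {
  tibble(transcript_id = character(), mirna_name = character(),
         start = integer(), end = integer(), strand = character(),
         match_len = integer(), mismatches = integer(),
         matched_seq = character())
}

# Fragments compared against transcript windows: the full mature plus every
# contiguous prefix/suffix down to min_len, on both strands. The minus-strand
# comparison is performed as rc(fragment) against the forward transcript.
mirna_fragments <- function(mirnas, min_len) {
  rows <- list()
  for (i in seq_len(nrow(mirnas))) {
    m <- mirnas$seq[i]
    L <- nchar(m)
    lens <- if (L <= min_len) L else c(L, seq(L - 1L, min_len))
    for (l in lens) {
      frs <- if (l == L) substr(m, 1, L) else
        unique(c(substr(m, 1, l), substr(m, L - l + 1, L)))
      for (f in frs) {
        rows[[length(rows) + 1L]] <- tibble(
          mirna_name = mirnas$name[i], frag = f, match_len = l,
          strand = c("+", "-"),
          probe = c(f, reverse_complement(f))
        )
      }
    }
  }
  bind_rows(rows)
}

scan_one_transcript <- function(id, seq, frag_tbl, max_mismatch) {
  tv <- seq_chars(seq)
  n <- length(tv)
  valid <- tv %in% RNA_BASES
  cum_bad <- cumsum(!valid)
  out <- list()
  for (fi in seq_len(nrow(frag_tbl))) {
    probe <- seq_chars(frag_tbl$probe[fi])
    K <- length(probe)
    if (K > n) next
    nW <- n - K + 1L
    mism <- integer(nW)
    idx <- seq_len(nW)
    for (j in seq_len(K)) {
      mism <- mism + (tv[idx + j - 1L] != probe[j])
    }
    # windows touching an ambiguity code are not scored
    bad_in_win <- cum_bad[idx + K - 1L] - c(0L, cum_bad)[idx]
    ok <- which(mism <= max_mismatch & bad_in_win == 0L)
    if (length(ok) == 0) next
    out[[length(out) + 1L]] <- tibble(
      transcript_id = id,
      mirna_name = frag_tbl$mirna_name[fi],
      start = ok - 1L,
      end = ok - 1L + K,
      strand = frag_tbl$strand[fi],
      match_len = frag_tbl$match_len[fi],
      mismatches = mism[ok],
      matched_seq = substring(seq, ok, ok + K - 1L)
    )
  }
  bind_rows(out)
}

# Greedy non-overlap retention per (transcript, miRNA): longest match first,
# then fewest mismatches, then leftmost.
collapse_overlaps <- function(hits) {
  hits |>
    group_by(.data$transcript_id, .data$mirna_name) |>
    dplyr::group_modify(function(df, key) {
      df <- arrange(df, desc(.data$match_len), .data$mismatches, .data$start)
      kept <- integer(0)
      ks <- integer(0); ke <- integer(0)
      for (i in seq_len(nrow(df))) {
        s <- df$start[i]; e <- df$end[i]
        if (all(e <= ks | s >= ke)) {
          kept <- c(kept, i); ks <- c(ks, s); ke <- c(ke, e)
        }
      }
      df[sort(kept), ]
    }) |>
    ungroup()
}
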