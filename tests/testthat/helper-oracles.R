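# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's internal algorithms: naive enumeration and plain
# recursion only.

ref_mirnas <- function() {
  read_mature_mirnas(system.file("extdata", "musa_mature_mirnas.fasta",
                                 package = "mirquest"))
}

random_seq <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

naive_hamming <- function(a, b) {
  va <- chars(a); vb <- chars(b)
  n <- 0L
  for (i in seq_along(va)) if (va[i] != vb[i]) n <- n + 1L
  n
}

naive_revcomp <- function(s) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  paste(rev(unname(comp[chars(s)])), collapse = "")
}

# All-window scan for one transcript x one miRNA, reproducing the contract:
# full-length plus >=min_len prefix/suffix fragments, both strands, then
# greedy collapse by (match_len desc, mismatches asc, start asc).
naive_scan <- function(tid, tseq, mname, mseq, max_mm = 2, min_len = 18) {
  L <- nchar(mseq)
  frags <- list(list(f = mseq, len = L))
  if (L > min_len) {
    for (l in (L - 1):min_len) {
      frags <- c(frags, list(list(f = substr(mseq, 1, l), len = l)))
      sfx <- substr(mseq, L - l + 1, L)
      if (sfx != substr(mseq, 1, l)) {
        frags <- c(frags, list(list(f = sfx, len = l)))
      }
    }
  }
  raw <- list()
  n <- nchar(tseq)
  for (fr in frags) {
    K <- nchar(fr$f)
    if (K > n) next
    for (st in 0:(n - K)) {
      win <- substr(tseq, st + 1, st + K)
      if (grepl("[^ACGU]", win)) next
      for (strand in c("+", "-")) {
        probe <- if (strand == "+") fr$f else naive_revcomp(fr$f)
        mm <- naive_hamming(win, probe)
        if (mm <= max_mm) {
          raw[[length(raw) + 1]] <- data.frame(
            transcript_id = tid, mirna_name = mname, start = st,
            end = st + K, strand = strand, match_len = fr$len,
            mismatches = mm, matched_seq = win,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(raw) == 0) {
    return(data.frame(transcript_id = character(), mirna_name = character(),
                      start = integer(), end = integer(),
                      strand = character(), match_len = integer(),
                      mismatches = integer(), matched_seq = character()))
  }
  raw <- do.call(rbind, raw)
  raw <- raw[order(-raw$match_len, raw$mismatches, raw$start), ]
  keep <- integer(0)
  for (i in seq_len(nrow(raw))) {
    ov <- FALSE
    for (k in keep) {
      if (raw$start[i] < raw$end[k] && raw$end[i] > raw$start[k]) {
        ov <- TRUE; break
      }
    }
    if (!ov) keep <- c(keep, i)
  }
  out <- raw[sort(keep), ]
  out <- out[order(out$transcript_id, out$start, out$mirna_name), ]
  rownames(out) <- NULL
  out
}

# Plain memoized recursion for the maximum number of nested WC/GU pairs
# with a minimum loop of 3 (pair-count oracle for the built-in folder).
recursive_max_pairs <- function(seq, min_loop = 3) {
  v <- chars(seq)
  n <- length(v)
  pairable <- function(a, b) {
    (a == "A" && b == "U") || (a == "U" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G") ||
      (a == "G" && b == "U") || (a == "U" && b == "G")
  }
  memo <- new.env(hash = TRUE)
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    best <- rec(i, j - 1L)
    for (k in i:(j - min_loop - 1L)) {
      if (pairable(v[k], v[j])) {
        cand <- 1L + (if (k > i) rec(i, k - 1L) else 0L) + rec(k + 1L, j - 1L)
        if (cand > best) best <- cand
      }
    }
    memo[[key]] <- best
    best
  }
  rec(1L, n)
}

# Naive six-frame ORF walk (codon-by-codon state machine).
naive_has_orf <- function(seq, min_orf_aa) {
  for (s in c(seq, naive_revcomp(seq))) {
    for (off in 0:2) {
      body <- substring(s, off + 1)
      n <- nchar(body) %/% 3
      if (n == 0) next
      run <- -1L # codons since AUG, -1 = outside an ORF
      for (ci in seq_len(n)) {
        codon <- substr(body, 3 * ci - 2, 3 * ci)
        if (codon %in% c("UAA", "UAG", "UGA")) {
          if (run >= min_orf_aa) return(TRUE)
          run <- -1L
        } else if (codon == "AUG" && run < 0) {
          run <- 1L
        } else if (run >= 0) {
          run <- run + 1L
        }
      }
    }
  }
  FALSE
}

# All-window site scorer with independent penalty bookkeeping.
naive_find_sites <- function(mseq, sseq, cutoff, seed_lo = 2, seed_hi = 13) {
  L <- nchar(mseq)
  n <- nchar(sseq)
  if (n < L) return(data.frame(start = integer(), expectation = numeric()))
  mi <- chars(mseq)
  res <- list()
  for (st in 0:(n - L)) {
    win <- rev(chars(substr(sseq, st + 1, st + L)))
    e <- 0
    for (k in seq_len(L)) {
      a <- mi[k]; b <- win[k]
      wc <- paste0(a, b) %in% c("AU", "UA", "GC", "CG")
      gu <- paste0(a, b) %in% c("GU", "UG")
      p <- if (wc) 0 else if (gu) 0.5 else 1
      if (k >= seed_lo && k <= seed_hi) p <- 2 * p
      e <- e + p
    }
    if (e <= cutoff) res[[length(res) + 1]] <- data.frame(start = st, expectation = e)
  }
  if (length(res) == 0) return(data.frame(start = integer(), expectation = numeric()))
  raw <- do.call(rbind, res)
  raw <- raw[order(raw$expectation, raw$start), ]
  keep <- integer(0)
  for (i in seq_len(nrow(raw))) {
    if (all(abs(raw$start[i] - raw$start[keep]) >= L)) keep <- c(keep, i)
  }
  out <- raw[sort(keep), ]
  rownames(out) <- NULL
  out
}
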