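# RNA secondary-structure folding behind a provider contract. The default
# provider is ViennaRNA's RNAfold (minimum free energy, Turner parameters,
# folding temperature 37 C, linear RNA), invoked through its command-line
# interface. A built-in base-pair-maximization dynamic-programming folder
# (Nussinov-style: score -1 per Watson-Crick or G:U pair, minimum loop 3)
# is available so that every structural test can run with no external
# dependency; its "mfe" is the negated pair count, not a thermodynamic
# energy.

#' Is the ViennaRNA command-line folder available?
#' @return Logical scalar.
#' @export
vienna_available <- function() nzchar(Sys.which("RNAfold"))

#' Resolve the folding provider
#' @param provider `"auto"`, `"vienna"` or `"nussinov"`.
#' @return The resolved provider name.
#' @export
resolve_provider <- function(provider = "auto") {
  provider <- match.arg(provider, c("auto", "vienna", "nussinov"))
  if (provider == "auto") {
    if (vienna_available()) "vienna" else "nussinov"
  } else {
    if (provider == "vienna" && !vienna_available()) {
      abort("RNAfold not found on PATH; use provider = 'nussinov'")
    }
    provider
  }
}

#' Fold RNA sequences
#'
#' Deterministic minimum-free-energy folding. With the `vienna` provider the
#' structure and energy come from RNAfold at 37 C; with the `nussinov`
#' provider the structure maximizes the number of Watson-Crick/G:U pairs and
#' the reported `mfe` is minus that pair count.
#'
#' @param seqs Character vector of RNA sequences (no ambiguity codes; each
#'   at least 15 nt).
#' @param provider `"auto"` (vienna when available), `"vienna"` or
#'   `"nussinov"`.
#' @param temperature Folding temperature in degrees C (vienna only).
#' @return Tibble with columns `seq`, `structure` (dot-bracket), `mfe`,
#'   `provider`.
#' @export
#' @examples
#' fold_rna("GGGGAAAACCCCAAA", provider = "nussinov")
fold_rna <- function(seqs, provider = "auto", temperature = 37) {
  assert_unambiguous(seqs)
  if (any(nchar(seqs) < 15)) {
    abort("fold_rna: sequences shorter than 15 nt cannot form a credible hairpin")
  }
  provider <- resolve_provider(provider)
  if (provider == "vienna") {
    res <- vienna_fold(seqs, temperature)
  } else {
    res <- lapply(seqs, nussinov_fold)
    res <- tibble(structure = map_chr(res, "structure"),
                  mfe = map_dbl(res, "mfe"))
  }
  tibble(seq = seqs, structure = res$structure, mfe = res$mfe,
         provider = provider)
}

vienna_fold <- function(seqs, temperature = 37, constraints = NULL) {
  ids <- sprintf("s%06d", seq_along(seqs))
  if (is.null(constraints)) {
    input <- as.vector(rbind(paste0(">", ids), seqs))
    args <- c("--noPS", paste0("-T", temperature))
  } else {
    stopifnot(length(constraints) == length(seqs))
    input <- as.vector(rbind(paste0(">", ids), seqs, constraints))
    args <- c("--noPS", paste0("-T", temperature), "-C", "--enforceConstraint")
  }
  out <- suppressWarnings(
    system2("RNAfold", args = args, input = input, stdout = TRUE, stderr = FALSE)
  )
  struct_lines <- grep("\\(\\s*-?[0-9.]+\\s*\\)\\s*$", out, value = TRUE)
  if (length(struct_lines) != length(seqs)) {
    abort("RNAfold output could not be parsed")
  }
  m <- regmatches(struct_lines,
                  regexpr("\\(\\s*-?[0-9.]+\\s*\\)\\s*$", struct_lines))
  mfe <- as.numeric(gsub("[()\\s]", "", m, perl = TRUE))
  structure <- sub("\\s*\\(\\s*-?[0-9.]+\\s*\\)\\s*$", "", struct_lines)
  tibble(structure = structure, mfe = mfe)
}

#' Built-in base-pair-maximization folder
#'
#' Nussinov-style dynamic program over Watson-Crick and G:U pairs with a
#' minimum hairpin loop of 3 unpaired nucleotides. When several structures
#' tie on pair count, the traceback prefers pairing the rightmost base and,
#' among its admissible partners, the most distant one, which favors
#' long-range stems over scattered short helices.
#'
#' @param seq RNA string over {A,C,G,U}.
#' @param min_loop Minimum number of unpaired bases in a hairpin loop.
#' @return List with `structure` (dot-bracket), `mfe` (minus the pair
#'   count), `pairs` (pair count).
#' @export
nussinov_fold <- function(seq, min_loop = 3) {
  v <- seq_chars(seq)
  n <- length(v)
  can_pair <- PAIRABLE[v, v, drop = FALSE]
  F <- matrix(0L, n, n)
  spans <- if (n > min_loop + 1L) seq(min_loop + 1L, n - 1L) else integer(0)
  for (span in spans) {
    i <- seq_len(n - span)
    for (ii in i) {
      j <- ii + span
      best <- F[ii, j - 1L]
      ks <- ii:(j - min_loop - 1L)
      ks <- ks[can_pair[ks, j]]
      if (length(ks) > 0) {
        left <- integer(length(ks)) # F[ii, k-1], zero when k == ii
        sel <- ks > ii
        if (any(sel)) left[sel] <- F[cbind(ii, ks[sel] - 1L)]
        inner <- F[cbind(ks + 1L, j - 1L)]
        cand <- left + inner + 1L
        best <- max(best, max(cand))
      }
      F[ii, j] <- best
    }
  }
  # traceback (iterative, deterministic)
  partner <- rep(NA_integer_, n)
  stack <- list(c(1L, n))
  while (length(stack) > 0) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    while (j - i > min_loop) {
      fij <- F[i, j]
      ks <- i:(j - min_loop - 1L)
      ks <- ks[can_pair[ks, j]]
      paired_here <- FALSE
      if (length(ks) > 0) {
        for (k in ks) { # ascending: most distant admissible partner first
          left <- if (k > i) F[i, k - 1L] else 0L
          inner <- if (k + 1L <= j - 1L) F[k + 1L, j - 1L] else 0L
          if (left + inner + 1L == fij) {
            partner[k] <- j; partner[j] <- k
            if (k > i && F[i, k - 1L] > 0L) stack[[length(stack) + 1L]] <- c(i, k - 1L)
            i <- k + 1L; j <- j - 1L
            paired_here <- TRUE
            break
          }
        }
      }
      if (!paired_here) j <- j - 1L
    }
  }
  structure <- rep(".", n)
  structure[which(partner > seq_len(n))] <- "("
  structure[which(partner < seq_len(n))] <- ")"
  pairs <- sum(!is.na(partner)) / 2L
  list(structure = paste(structure, collapse = ""), mfe = -pairs,
       pairs = pairs)
}

#' Parse a dot-bracket structure into a partner table
#'
#' @param structure Dot-bracket string (Vienna notation, round brackets).
#' @return Integer vector: `pt[i]` is the 1-based partner of position `i`,
#'   `NA` if unpaired.
#' @export
dot_bracket_pairs <- function(structure) {
  v <- seq_chars(structure)
  pt <- rep(NA_integer_, length(v))
  stack <- integer(0)
  for (i in seq_along(v)) {
    if (v[i] == "(") {
      stack <- c(stack, i)
    } else if (v[i] == ")") {
      if (length(stack) == 0) abort("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    } else if (v[i] != ".") {
      abort(paste0("unexpected character in dot-bracket string: ", v[i]))
    }
  }
  if (length(stack) > 0) abort("unbalanced dot-bracket string")
  pt
}
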