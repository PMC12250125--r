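# Seeded generators for every input the pipeline consumes, with known
# ground truth: designed hairpin precursors planted in random transcripts,
# low-structure decoys, target mRNAs with sites of designed expectation, and
# Ct tables with known fold changes. Every generator is a pure function of
# its (mandatory) seed.

# A substitution that can pair with nothing the original partner offers:
# neither Watson-Crick nor G:U against the facing base.
nonpairing_base <- function(facing) {
  ifelse(facing %in% c("A", "U"), "C", "A")
}

#' Construct a designed hairpin precursor
#'
#' The precursor is mature + loop + reverse complement of the mature, with
#' `star_mismatches` star positions substituted so they can pair with
#' neither their facing mature base (no Watson-Crick, no G:U). The loop is
#' drawn from {A,C} only, so it cannot base-pair internally. The returned
#' `structure` is the designed duplex in dot-bracket form, with substituted
#' duplex positions unpaired.
#'
#' @param mature_seq Mature miRNA sequence (5' arm of the product).
#' @param star_mismatches Number of star positions to knock out (0-8).
#' @param loop_len Terminal loop length, >= 3 nt.
#' @param seed Mandatory RNG seed.
#' @return List with `precursor`, `structure`, `mature_start`, `mature_end`
#'   (0-based half-open; the mature is the 5p arm).
#' @export
make_hairpin <- function(mature_seq, star_mismatches = 0, loop_len = 8,
                         seed) {
  if (loop_len < 3) abort("loop_len must be >= 3")
  if (star_mismatches < 0 || star_mismatches > 8) {
    abort("star_mismatches must be between 0 and 8")
  }
  mature_seq <- normalize_rna(mature_seq)
  assert_unambiguous(mature_seq, "mature sequence")
  L <- nchar(mature_seq)
  with_seed(seed, {
    loop <- random_rna(loop_len, weights = c(A = 0.5, C = 0.5))
    star <- seq_chars(reverse_complement(mature_seq))
    # star position i faces mature position L - i + 1
    knocked <- integer(0)
    if (star_mismatches > 0) {
      knocked <- sort(sample(seq_len(L), star_mismatches))
      facing <- seq_chars(mature_seq)[L - knocked + 1L]
      star[knocked] <- nonpairing_base(facing)
    }
    struct <- c(rep("(", L), rep(".", loop_len), rep(")", L))
    if (length(knocked) > 0) {
      struct[L - knocked + 1L] <- "."          # mature side
      struct[L + loop_len + knocked] <- "."     # star side
    }
    list(
      precursor = paste0(mature_seq, loop, paste(star, collapse = "")),
      structure = paste(struct, collapse = ""),
      mature_start = 0L,
      mature_end = L
    )
  })
}

#' Plant precursors in a random background transcript
#'
#' Generates an i.i.d. background (optionally GC-biased) of `background_len`
#' nt and overwrites it with the given precursors at the given positions.
#'
#' @param precursors Character vector of precursor sequences.
#' @param positions Integer vector of 0-based start positions.
#' @param background_len Total transcript length.
#' @param seed Mandatory RNG seed.
#' @param gc_bias Background GC fraction (default 0.5).
#' @param id Transcript identifier.
#' @return List with `transcript` (a one-row tibble: id, seq, length) and
#'   `truth` (a tibble of planted spans).
#' @export
embed_precursors <- function(precursors, positions, background_len, seed,
                             gc_bias = 0.5, id = "synthetic_1") {
  stopifnot(length(precursors) == length(positions))
  lens <- nchar(precursors)
  if (any(positions < 0) || any(positions + lens > background_len)) {
    abort("planted precursor does not fit in the background")
  }
  o <- order(positions)
  if (length(positions) > 1) {
    p <- positions[o]; l <- lens[o]
    if (any(p[-1] < (p + l)[-length(p)])) abort("planted precursors overlap")
  }
  seq <- with_seed(seed, random_rna(background_len, gc_bias = gc_bias))
  v <- seq_chars(seq)
  for (i in seq_along(precursors)) {
    v[(positions[i] + 1L):(positions[i] + lens[i])] <- seq_chars(precursors[i])
  }
  seq <- paste(v, collapse = "")
  list(
    transcript = tibble(id = id, seq = seq, length = background_len),
    truth = tibble(id = id, precursor_start = as.integer(positions),
                   precursor_end = as.integer(positions + lens),
                   precursor = precursors)
  )
}

#' Generate a low-structure decoy sequence
#'
#' Rejection-samples A/C-biased sequences until the chosen folding provider
#' reports an MFE above `mfe_floor` (default -20), i.e. a sequence too
#' weakly self-complementary to satisfy the energetic precursor criterion.
#'
#' @param length Sequence length, nt.
#' @param seed Mandatory RNG seed.
#' @param provider Folding provider used for the acceptance check.
#' @param mfe_floor Decoys must fold above this MFE.
#' @param max_tries Sampling attempts before giving up.
#' @return Character scalar.
#' @export
make_decoy <- function(length, seed, provider = "auto", mfe_floor = -20,
                       max_tries = 50) {
  provider <- resolve_provider(provider)
  with_seed(seed, {
    for (i in seq_len(max_tries)) {
      s <- random_rna(length, weights = c(A = 0.49, C = 0.49, G = 0.01, U = 0.01))
      if (fold_rna(s, provider = provider)$mfe > mfe_floor) return(s)
    }
    abort("could not generate a decoy above the MFE floor")
  })
}

#' Generate an mRNA with one planted target site of designed expectation
#'
#' The site is the reverse complement of the miRNA with substitutions at
#' `mismatch_positions` (1-based from the miRNA 5' end), each chosen so the
#' duplex position is a clean mismatch (no accidental G:U). The designed
#' expectation is computed analytically from the scoring weights, not by
#' running the scorer.
#'
#' @param mirna_seq Mature miRNA sequence.
#' @param mismatch_positions Integer vector of miRNA positions to mismatch.
#' @param length mRNA length (>= miRNA length).
#' @param position 0-based site start on the mRNA; random if NULL.
#' @param seed Mandatory RNG seed.
#' @param weights Scoring weights (see [target_weights()]).
#' @param id mRNA identifier.
#' @return List with `mrna` (one-row tibble: id, seq, length) and `truth`
#'   (site span, designed expectation, designed inhibition class).
#' @export
make_target_mrna <- function(mirna_seq, mismatch_positions = integer(0),
                             length = 500, position = NULL, seed,
                             weights = target_weights(), id = "mrna_1") {
  mirna_seq <- normalize_rna(mirna_seq)
  L <- nchar(mirna_seq)
  if (length < L) abort("mRNA shorter than the site")
  if (any(mismatch_positions < 1 | mismatch_positions > L)) {
    abort("mismatch positions outside the miRNA")
  }
  n_mm <- base::length(mismatch_positions)
  with_seed(seed, {
    pos <- position %||% sample(0:(length - L), 1)
    site <- seq_chars(reverse_complement(mirna_seq))
    # miRNA position k faces site position L - k + 1
    if (n_mm > 0) {
      mi <- seq_chars(mirna_seq)[mismatch_positions]
      site[L - mismatch_positions + 1L] <- nonpairing_base(mi)
    }
    site <- paste(site, collapse = "")
    bg <- random_rna(length)
    v <- seq_chars(bg)
    v[(pos + 1L):(pos + L)] <- seq_chars(site)
    seq <- paste(v, collapse = "")
    k <- seq_len(L)
    in_seed <- k >= weights$seed_start & k <= weights$seed_end
    per_pos <- ifelse(k %in% mismatch_positions, weights$mismatch, 0) *
      ifelse(in_seed, weights$seed_multiplier, 1)
    expectation <- sum(per_pos)
    central <- any(mismatch_positions >= 9 & mismatch_positions <= 11)
    list(
      mrna = tibble(id = id, seq = seq, length = length),
      truth = tibble(id = id, site_start = as.integer(pos),
                     site_end = as.integer(pos + L),
                     designed_expectation = expectation,
                     designed_inhibition = ifelse(central, "translation",
                                                  "cleavage"))
    )
  })
}

#' Generate a replicated Ct table with known fold changes
#'
#' Control Ct for each gene is a constant baseline; stress Ct is the control
#' Ct minus log2 of the true fold change; Gaussian measurement noise of sd
#' `noise_sd` cycles is added independently to every reaction (both
#' conditions). Reference genes are emitted noise-free at a constant Ct so
#' the 2^-deltaCt normalization is exact.
#'
#' @param genes Tibble with `gene`, `class` (miRNA/mRNA), `fold_change`
#'   (> 0; stress/control).
#' @param seed Mandatory RNG seed.
#' @param groups,tissues Factor levels to emit (defaults: group "AAA",
#'   tissue "leaf").
#' @param n_bio,n_tech Biological and technical replicates (defaults 3, 3).
#' @param noise_sd Measurement noise, cycles.
#' @param base_ct Control-condition baseline Ct.
#' @param reference_genes Named vector mapping class to reference gene name.
#' @param ref_ct Reference-gene Ct.
#' @return List with `ct_table` (ready for [rel_expression_table()]) and
#'   `truth` (gene, true fold change).
#' @export
make_ct_table <- function(genes, seed, groups = "AAA", tissues = "leaf",
                          n_bio = 3, n_tech = 3, noise_sd = 0,
                          base_ct = 24,
                          reference_genes = c(miRNA = "MaU6", mRNA = "MaUBQ2"),
                          ref_ct = 18) {
  if (any(genes$fold_change <= 0)) abort("fold changes must be > 0")
  design <- tidyr::expand_grid(
    group = groups, tissue = tissues, condition = c("control", "stress"),
    bio = seq_len(n_bio), replicate = seq_len(n_tech)
  ) |>
    mutate(sample_id = paste(.data$group, .data$tissue, .data$condition,
                             .data$bio, sep = "_"))
  with_seed(seed, {
    rows <- pmap(genes[c("gene", "class", "fold_change")],
                 function(gene, class, fold_change) {
      d <- design
      d$gene <- gene
      d$class <- class
      d$ct <- base_ct -
        ifelse(d$condition == "stress", log2(fold_change), 0) +
        stats::rnorm(nrow(d), 0, noise_sd)
      d
    })
    refs <- map(unique(genes$class), function(cl) {
      d <- design
      d$gene <- unname(reference_genes[[cl]])
      d$class <- cl
      d$ct <- ref_ct
      d
    })
    ct <- bind_rows(c(rows, refs)) |>
      select("sample_id", "group", "tissue", "condition", "gene", "class",
             "replicate", "ct")
    list(ct_table = as_tibble(ct),
         truth = select(genes, "gene", "class", "fold_change"))
  })
}

#' Generate a planted-hairpin discovery corpus
#'
#' Builds `n_planted` transcripts each carrying one designed, criteria-
#' conforming hairpin for a reference miRNA (drawn round-robin), plus
#' `n_decoys` decoy transcripts with no planted signal and weak folding.
#'
#' @param mirnas Reference miRNA tibble (`name`, `seq`).
#' @param n_planted,n_decoys Corpus composition.
#' @param transcript_len Length of each transcript.
#' @param seed Mandatory RNG seed.
#' @param loop_len Hairpin loop length.
#' @param provider Folding provider used to certify decoys.
#' @return List with `transcripts`, `truth` (planted spans + miRNA name),
#'   and `decoy_ids`.
#' @export
make_discovery_corpus <- function(mirnas, n_planted = 30, n_decoys = 30,
                                  transcript_len = 300, seed,
                                  loop_len = 8, provider = "auto") {
  txs <- list(); truth <- list()
  for (i in seq_len(n_planted)) {
    mi <- ((i - 1L) %% nrow(mirnas)) + 1L
    hp <- make_hairpin(mirnas$seq[mi], star_mismatches = 0,
                       loop_len = loop_len, seed = seed + 7L * i)
    pos <- with_seed(seed + 7L * i + 1L,
                     sample(0:(transcript_len - nchar(hp$precursor)), 1))
    emb <- embed_precursors(hp$precursor, pos, transcript_len,
                            seed = seed + 7L * i + 2L,
                            id = sprintf("planted_%02d", i))
    txs[[length(txs) + 1L]] <- emb$transcript
    truth[[length(truth) + 1L]] <- mutate(emb$truth,
                                          mirna_name = mirnas$name[mi],
                                          mature_start = emb$truth$precursor_start,
                                          mature_end = emb$truth$precursor_start +
                                            nchar(mirnas$seq[mi]))
  }
  decoy_ids <- character(0)
  for (i in seq_len(n_decoys)) {
    id <- sprintf("decoy_%02d", i)
    txs[[length(txs) + 1L]] <- tibble(
      id = id,
      seq = make_decoy(transcript_len, seed = seed + 1000L + i,
                       provider = provider),
      length = transcript_len
    )
    decoy_ids <- c(decoy_ids, id)
  }
  list(transcripts = bind_rows(txs), truth = bind_rows(truth),
       decoy_ids = decoy_ids)
}
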