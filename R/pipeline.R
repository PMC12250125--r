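# End-to-end orchestration: dedup -> scan -> coding filter -> windows ->
# fold -> validate -> select, then (optionally) target prediction and
# expression analysis, with per-stage counts and reproducible reports.

#' Pipeline configuration
#'
#' All stage parameters with their conventional defaults: homology scan
#' (<= 2 mismatches, >= 18 nt gap-free), precursor windows (100 nt, step
#' 20, flank 80), hairpin criteria (AU% in [30, 70], star mismatches < 6,
#' MFE <= -20, <= 3 mature mismatches), target scoring (expectation <= 3.0,
#' UPE flag at 25), and the 1.5-fold direction threshold for expression
#' calls.
#'
#' @param max_mismatch,min_len Homology-scan filters.
#' @param window,step,flank Precursor window geometry, nt.
#' @param au_min,au_max,max_star_mismatch,max_mfe,max_mature_mismatch
#'   Hairpin criteria.
#' @param max_expectation,upe_flag Target-prediction cutoffs.
#' @param fold_threshold Expression direction threshold.
#' @param min_orf_aa Coding-filter ORF cutoff, codons.
#' @param provider Folding provider.
#' @param reference_genes Named class -> reference gene map for qPCR
#'   normalization.
#' @param seed Seed recorded with the run.
#' @return A `mirquest_config` list.
#' @export
mir_config <- function(max_mismatch = 2, min_len = 18,
                       window = 100, step = 20, flank = 80,
                       au_min = 30, au_max = 70,
                       max_star_mismatch = 6, max_mfe = -20,
                       max_mature_mismatch = 3,
                       max_expectation = 3.0, upe_flag = 25.0,
                       fold_threshold = 1.5, min_orf_aa = 100,
                       provider = "auto",
                       reference_genes = c(miRNA = "MaU6", mRNA = "MaUBQ2"),
                       seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "mirquest_config")
}

#' Run the discovery pipeline
#'
#' Deduplicates the reference miRNAs, scans the transcripts, drops hits on
#' coding transcripts, extracts/folds/validates precursor windows, and
#' selects the best passing window per hit. Per-stage input/output counts
#' are recorded and (at `verbose = TRUE`) logged.
#'
#' @param transcripts Transcript tibble (see [read_transcripts()]).
#' @param mirnas Reference miRNA tibble (see [read_mature_mirnas()]).
#' @param config A [mir_config()] list.
#' @param evidence Optional coding-evidence tibble.
#' @param verbose Log per-stage counts with `message()`.
#' @return A `mir_discovery` object: list with `candidates` (passing
#'   precursors), `hits`, `coding`, `family_summary`, `length_summary`,
#'   `stage_counts`, `config`.
#' @export
run_discovery <- function(transcripts, mirnas, config = mir_config(),
                          evidence = NULL, verbose = FALSE) {
  log_count <- function(stage, n_in, n_out) {
    if (verbose) message(sprintf("[%s] in=%d out=%d", stage, n_in, n_out))
    tibble(stage = stage, n_in = n_in, n_out = n_out)
  }
  counts <- list()
  mirnas_nr <- dedup_mirnas(mirnas)
  counts$dedup <- log_count("dedup_mirnas", nrow(mirnas), nrow(mirnas_nr))

  if (nrow(transcripts) == 0) {
    warn("no transcripts supplied; returning an empty discovery result")
    hits <- empty_hits()
  } else {
    hits <- scan_transcripts(transcripts, mirnas_nr,
                             max_mismatch = config$max_mismatch,
                             min_len = config$min_len)
  }
  counts$scan <- log_count("scan_transcripts", nrow(transcripts), nrow(hits))

  coding <- coding_verdicts(transcripts, evidence,
                            min_orf_aa = config$min_orf_aa)
  noncoding_ids <- coding$id[!coding$is_coding]
  hits_nc <- filter(hits, .data$transcript_id %in% noncoding_ids)
  counts$coding <- log_count("coding_filter", nrow(hits), nrow(hits_nc))

  candidates <- predict_precursors(
    transcripts, hits_nc, mirnas_nr,
    window = config$window, step = config$step, flank = config$flank,
    provider = config$provider,
    max_mature_mismatch = config$max_mature_mismatch,
    au_min = config$au_min, au_max = config$au_max,
    max_star_mismatch = config$max_star_mismatch,
    max_mfe = config$max_mfe
  )
  counts$validate <- log_count("predict_precursors", nrow(hits_nc),
                               nrow(candidates))

  fam <- candidates |>
    dplyr::count(.data$family, name = "members") |>
    arrange(desc(.data$members), .data$family)
  lens <- candidates |>
    mutate(mature_length = .data$mature_end - .data$mature_start) |>
    dplyr::count(.data$mature_length, name = "n_mirnas")

  structure(list(
    candidates = candidates,
    hits = hits,
    coding = select(coding, "id", "is_coding", "coding_source"),
    family_summary = fam,
    length_summary = lens,
    stage_counts = bind_rows(counts),
    config = config
  ), class = "mir_discovery")
}

#' @export
print.mir_discovery <- function(x, ...) {
  cat("<mir_discovery>\n")
  cat(sprintf("  %d passing precursor(s) from %d homology hit(s), %d famil%s\n",
              nrow(x$candidates), nrow(x$hits), nrow(x$family_summary),
              if (nrow(x$family_summary) == 1) "y" else "ies"))
  print(x$stage_counts)
  invisible(x)
}

#' Run discovery, target prediction and expression analysis together
#'
#' After discovery, the validated mature miRNAs are scored against the
#' supplied mRNAs, and (when a Ct table is given) the 2^-deltaCt expression
#' summary, stress/control directions and miRNA/target inverse-expression
#' flags are computed for every predicted miRNA:target pair present in the
#' Ct table.
#'
#' @inheritParams run_discovery
#' @param mrnas Tibble of candidate target mRNAs (`id`, `seq`).
#' @param ct_table Optional Ct table (see [read_ct_table()]).
#' @return A `mir_full` object: the `mir_discovery` fields plus `sites`,
#'   `expression_summary`, `directions`, `inverse_pairs`.
#' @export
run_full <- function(transcripts, mirnas, mrnas, ct_table = NULL,
                     config = mir_config(), evidence = NULL,
                     verbose = FALSE) {
  disc <- run_discovery(transcripts, mirnas, config, evidence, verbose)
  mature <- disc$candidates |>
    distinct(.data$mirna_name, .data$mature_seq) |>
    rename(name = "mirna_name", seq = "mature_seq")
  sites <- find_sites(mature, mrnas, max_expectation = config$max_expectation)
  if (verbose) message(sprintf("[find_sites] mirnas=%d sites=%d",
                               nrow(mature), nrow(sites)))
  summary <- directions <- inverse <- NULL
  if (!is.null(ct_table)) {
    rel <- rel_expression_table(ct_table,
                                reference_genes = config$reference_genes)
    summary <- summarize_expression(rel)
    directions <- expression_directions(summary,
                                        fold_threshold = config$fold_threshold)
    pairs <- sites |>
      distinct(mirna = .data$mirna_name, target = .data$mrna_id) |>
      filter(.data$mirna %in% ct_table$gene, .data$target %in% ct_table$gene)
    inverse <- flag_inverse(directions, pairs)
  }
  out <- unclass(disc)
  out$sites <- sites
  out$expression_summary <- summary
  out$directions <- directions
  out$inverse_pairs <- inverse
  structure(out, class = c("mir_full", "mir_discovery"))
}

#' Write the reports of a pipeline run
#'
#' Emits the candidate report, the hit table (TSV and GFF3), per-stage
#' counts, and a resolved copy of the configuration (JSON) so any run can be
#' reproduced from its output directory alone. Identical inputs, config and
#' seed produce byte-identical files.
#'
#' @param result A `mir_discovery` or `mir_full` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reports <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_candidate_report(result$candidates, file.path(dir, "candidates.tsv"))
  readr::write_tsv(result$hits, file.path(dir, "hits.tsv"), progress = FALSE)
  write_hits_gff3(result$hits, file.path(dir, "hits.gff3"))
  readr::write_tsv(result$stage_counts, file.path(dir, "stage_counts.tsv"),
                   progress = FALSE)
  readr::write_tsv(result$family_summary, file.path(dir, "families.tsv"),
                   progress = FALSE)
  cfg <- lapply(unclass(result$config), function(x) {
    if (is.null(names(x))) x else as.list(x)
  })
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(result$sites)) {
    readr::write_tsv(result$sites, file.path(dir, "sites.tsv"),
                     progress = FALSE)
  }
  if (!is.null(result$inverse_pairs)) {
    readr::write_tsv(result$inverse_pairs,
                     file.path(dir, "inverse_pairs.tsv"), progress = FALSE)
  }
  invisible(dir)
}
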