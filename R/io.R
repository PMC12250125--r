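# Reading and writing the external representations used by the pipeline:
# FASTA transcript collections, miRBase-dialect mature FASTA, coding-evidence
# tables, Ct tables, and the tab-delimited candidate report.

#' Read a transcript collection from FASTA
#'
#' Sequences are normalized to the internal RNA alphabet (uppercase, T -> U).
#' IUPAC ambiguity codes are kept in the record but any window containing one
#' is later excluded from homology scoring. Duplicate IDs are an error:
#' transcripts are the coordinate system for every downstream result.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `seq`, `length` (one row per record,
#'   in file order).
#' @export
read_transcripts <- function(path) {
  recs <- read_fasta_raw(path)
  dup <- unique(recs$id[duplicated(recs$id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate transcript ID(s): ", paste(dup, collapse = ", ")))
  }
  tibble(id = recs$id, seq = normalize_rna(recs$seq),
         length = nchar(recs$seq))
}

#' Read a reference set of mature miRNAs (miRBase mature-FASTA dialect)
#'
#' The record name is the first whitespace-delimited token of the header
#' (e.g. `osa-miR528-5p` from `>osa-miR528-5p MIMAT0003981 ...`). The family
#' is the `miR<number>` core of the name; the arm (5p/3p) is taken from the
#' name suffix when present. Reference entries must be 18-26 nt over
#' {A,C,G,U}.
#'
#' @param path Path to a mature-miRNA FASTA file.
#' @return A tibble with columns `name`, `family`, `seq`, `length`, `arm`,
#'   `strand`.
#' @export
read_mature_mirnas <- function(path) {
  recs <- read_fasta_raw(path)
  seqs <- normalize_rna(recs$seq)
  assert_unambiguous(seqs, "mature miRNA sequence")
  len <- nchar(seqs)
  if (any(len < 18 | len > 26)) {
    abort(paste0("mature miRNA length outside 18-26 nt: ",
                 paste(recs$id[len < 18 | len > 26], collapse = ", ")))
  }
  tibble(
    name = recs$id,
    family = mirna_family(recs$id),
    seq = seqs,
    length = len,
    arm = mirna_arm(recs$id),
    strand = "unknown"
  )
}

mirna_family <- function(name) {
  fam <- stringr::str_extract(name, "(?i)miR[0-9]+")
  fam <- ifelse(is.na(fam), name, sub("(?i)^mir", "miR", fam, perl = TRUE))
  fam
}

mirna_arm <- function(name) {
  dplyr::case_when(
    grepl("-5p$", name) ~ "5p",
    grepl("-3p$", name) ~ "3p",
    TRUE ~ "unknown"
  )
}

# Minimal shared FASTA reader built on Biostrings; headers are kept verbatim
# up to the first whitespace.
read_fasta_raw <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("malformed FASTA in ", path, ": ",
                                     conditionMessage(e)))
  )
  if (length(set) == 0) abort(paste0("no FASTA records in ", path))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  empty <- !nzchar(seqs) | !nzchar(ids)
  if (any(empty)) {
    abort(paste0("empty header or sequence at record ",
                 paste(which(empty), collapse = ", "), " in ", path))
  }
  list(id = unname(ids), seq = unname(seqs))
}

#' Write sequences to FASTA
#'
#' Output always uses the internal RNA alphabet (U, never T).
#'
#' @param x A tibble with an id-like first column (`id` or `name`) and a
#'   `seq` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  id_col <- if ("id" %in% names(x)) "id" else "name"
  set <- Biostrings::BStringSet(setNames(normalize_rna(x$seq), x[[id_col]]))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Deduplicate identical mature miRNA sequences
#'
#' Collapses the reference set so that each distinct sequence is represented
#' once (the first occurrence, order stable). This mirrors clustering the
#' reference miRNAs at a sequence-identity threshold of 1.0 before building
#' the search database.
#'
#' @param mirnas A mature-miRNA tibble (see [read_mature_mirnas()]).
#' @return The tibble restricted to the first record of each distinct
#'   sequence.
#' @export
dedup_mirnas <- function(mirnas) {
  distinct(mirnas, .data$seq, .keep_all = TRUE)
}

#' Read a coding-evidence table
#'
#' A two-column TSV/CSV (`transcript_id`, `coding` in {0,1}) summarizing
#' external evidence (typically a protein-database search run upstream).
#' Duplicate rows with conflicting verdicts for one transcript are an error.
#'
#' @param path Path to the table.
#' @return Tibble with columns `transcript_id`, `is_coding`.
#' @export
read_coding_evidence <- function(path) {
  tbl <- read_table_auto(path)
  if (!all(c("transcript_id", "coding") %in% names(tbl))) {
    abort("coding-evidence table needs columns 'transcript_id' and 'coding'")
  }
  tbl <- mutate(tbl, is_coding = as.logical(as.integer(.data$coding)))
  conflict <- tbl |>
    distinct(.data$transcript_id, .data$is_coding) |>
    dplyr::count(.data$transcript_id) |>
    filter(.data$n > 1)
  if (nrow(conflict) > 0) {
    abort(paste0("conflicting coding verdicts for: ",
                 paste(conflict$transcript_id, collapse = ", ")))
  }
  distinct(select(tbl, "transcript_id", "is_coding"), .data$transcript_id,
           .keep_all = TRUE)
}

#' Read a Ct table for expression analysis
#'
#' Headered CSV or TSV with columns `sample_id`, `group`, `tissue`,
#' `condition`, `gene`, `class` (miRNA or mRNA), `replicate`, `ct`.
#' Non-detected reactions are encoded as missing (`NA`), never as a ceiling
#' cycle number.
#'
#' @param path Path to the table.
#' @return Tibble with the columns above; `ct` numeric.
#' @export
read_ct_table <- function(path) {
  tbl <- read_table_auto(path)
  need <- c("sample_id", "group", "tissue", "condition", "gene",
            "class", "replicate", "ct")
  missing <- setdiff(need, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("Ct table missing column(s): ", paste(missing, collapse = ", ")))
  }
  tbl <- mutate(tbl, ct = as.numeric(.data$ct),
                replicate = as.integer(.data$replicate))
  if (any(!is.na(tbl$ct) & tbl$ct <= 0)) abort("Ct values must be > 0")
  as_tibble(tbl[need])
}

read_table_auto <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

#' Write the precursor-candidate report
#'
#' One row per candidate, tab-delimited, with AU%/GC% to 2 decimals, AMFE to
#' 3 decimals and MFEI to 2 decimals (the precision they are conventionally
#' reported at).
#'
#' @param candidates A candidate tibble (see [predict_precursors()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidate_report <- function(candidates, path) {
  cols <- c("source_id", "family", "source_length", "precursor_length",
            "au_pct", "gc_pct", "n_a", "n_c", "n_g", "n_u",
            "mfe", "amfe", "mfei")
  out <- candidates
  for (nm in setdiff(cols, names(out))) out[[nm]] <- NA
  out <- out[cols]
  fmt <- function(x, digits) ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "f"), x))
  out$au_pct <- fmt(out$au_pct, 2)
  out$gc_pct <- fmt(out$gc_pct, 2)
  out$amfe <- fmt(out$amfe, 3)
  out$mfei <- fmt(out$mfei, 2)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read back a candidate report written by [write_candidate_report()]
#' @param path Path to the TSV.
#' @return Tibble with numeric statistic columns.
#' @export
read_candidate_report <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         na = "NA")
  for (nm in c("au_pct", "gc_pct", "amfe", "mfei", "mfe")) {
    if (nm %in% names(tbl)) tbl[[nm]] <- as.numeric(tbl[[nm]])
  }
  tbl
}

#' Export homology hits as GFF3
#'
#' Coordinates are converted from the internal 0-based half-open convention
#' to GFF3's 1-based inclusive convention.
#'
#' @param hits A hit tibble from [scan_transcripts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_gff3 <- function(hits, path) {
  lines <- c("##gff-version 3")
  if (nrow(hits) > 0) {
    lines <- c(lines, sprintf(
      "%s\tmirquest\tmiRNA_homology_hit\t%d\t%d\t%d\t%s\t.\tID=hit%d;Name=%s;mismatches=%d",
      hits$transcript_id, hits$start + 1L, hits$end, hits$mismatches,
      hits$strand, seq_len(nrow(hits)), hits$mirna_name, hits$mismatches
    ))
  }
  writeLines(lines, path)
  invisible(path)
}
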