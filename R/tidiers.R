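# broom-style accessors for pipeline results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a discovery result into its candidate table
#'
#' @param x A `mir_discovery` object.
#' @param ... Unused.
#' @return The candidate tibble (one row per validated precursor).
#' @export
tidy.mir_discovery <- function(x, ...) {
  x$candidates
}

#' One-row summary of a discovery run
#'
#' @param x A `mir_discovery` object.
#' @param ... Unused.
#' @return One-row tibble with stage tallies.
#' @export
glance.mir_discovery <- function(x, ...) {
  sc <- x$stage_counts
  tibble(
    n_reference_mirnas = sc$n_in[sc$stage == "dedup_mirnas"],
    n_nonredundant_mirnas = sc$n_out[sc$stage == "dedup_mirnas"],
    n_transcripts = sc$n_in[sc$stage == "scan_transcripts"],
    n_hits = sc$n_out[sc$stage == "scan_transcripts"],
    n_noncoding_hits = sc$n_out[sc$stage == "coding_filter"],
    n_candidates = nrow(x$candidates),
    n_families = nrow(x$family_summary),
    provider = resolve_provider(x$config$provider)
  )
}
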