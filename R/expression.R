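# Relative-expression analysis of stem-loop RT-qPCR data: 2^-deltaCt per
# reaction against a class-specific endogenous reference gene, replicate
# summaries (mean over biological replicates of technical-replicate means,
# SEM across biological replicates), stress-vs-control direction calls and
# miRNA/target inverse-expression flags.

#' Relative expression by the 2^-deltaCt method
#'
#' @param ct_gene,ct_reference Ct values from the same sample (cycles, > 0).
#' @return `2^-(ct_gene - ct_reference)`; vectorized.
#' @export
#' @examples
#' relative_expression(25, 20) # 2^-5
relative_expression <- function(ct_gene, ct_reference) {
  2^-(ct_gene - ct_reference)
}

#' Per-reaction relative expression for a Ct table
#'
#' Each reaction is normalized against the mean Ct of the class-appropriate
#' reference gene in the same sample (conventionally a U6 snRNA for miRNAs
#' and a ubiquitin gene for mRNAs). Non-detected reactions (NA Ct)
#' propagate as NA.
#'
#' @param ct_table Tibble from [read_ct_table()].
#' @param reference_genes Named character vector mapping class to reference
#'   gene name, e.g. `c(miRNA = "MaU6", mRNA = "MaUBQ2")`.
#' @return The non-reference rows of `ct_table` with an added `rel_expr`
#'   column.
#' @export
rel_expression_table <- function(ct_table,
                                 reference_genes = c(miRNA = "MaU6",
                                                     mRNA = "MaUBQ2")) {
  refs <- ct_table |>
    filter(.data$gene %in% reference_genes) |>
    group_by(.data$sample_id, .data$class) |>
    summarise(ref_ct = mean(.data$ct, na.rm = TRUE), .groups = "drop")
  genes <- filter(ct_table, !(.data$gene %in% reference_genes))
  out <- left_join(genes, refs, by = c("sample_id", "class"))
  missing_ref <- unique(out$sample_id[is.na(out$ref_ct)])
  if (length(missing_ref) > 0) {
    abort(paste0("no reference-gene Ct for sample(s): ",
                 paste(missing_ref, collapse = ", ")))
  }
  out |>
    mutate(rel_expr = relative_expression(.data$ct, .data$ref_ct)) |>
    select(-"ref_ct")
}

#' Summarize relative expression over replicates
#'
#' Technical replicates are averaged within each biological sample first;
#' the reported mean and SEM (sd/sqrt(n)) are then taken across biological
#' samples. A single biological replicate yields SEM = NA.
#'
#' @param rel_table Output of [rel_expression_table()].
#' @return Tibble with `gene`, `class`, `group`, `tissue`, `condition`,
#'   `n` (biological replicates with any detection), `rel_expr` (mean),
#'   `sem`, and `detected` (FALSE when every reaction was non-detected).
#' @export
summarize_expression <- function(rel_table) {
  per_sample <- rel_table |>
    group_by(.data$gene, .data$class, .data$group, .data$tissue,
             .data$condition, .data$sample_id) |>
    summarise(rel_expr = mean(.data$rel_expr, na.rm = TRUE),
              .groups = "drop") |>
    filter(!is.nan(.data$rel_expr))
  rel_table |>
    distinct(.data$gene, .data$class, .data$group, .data$tissue,
             .data$condition) |>
    left_join(
      per_sample |>
        group_by(.data$gene, .data$class, .data$group, .data$tissue,
                 .data$condition) |>
        summarise(n = dplyr::n(),
                  sem = ifelse(dplyr::n() > 1,
                               sd(.data$rel_expr) / sqrt(dplyr::n()),
                               NA_real_),
                  rel_expr = mean(.data$rel_expr),
                  .groups = "drop"),
      by = c("gene", "class", "group", "tissue", "condition")
    ) |>
    mutate(detected = !is.na(.data$rel_expr),
           n = ifelse(is.na(.data$n), 0L, .data$n))
}

direction_call <- function(ratio, fold_threshold) {
  dplyr::case_when(
    is.na(ratio) ~ "flat",
    ratio >= fold_threshold ~ "up",
    ratio <= 1 / fold_threshold ~ "down",
    TRUE ~ "flat"
  )
}

#' Stress-vs-control direction and fold change per gene
#'
#' @param summary Output of [summarize_expression()].
#' @param fold_threshold Ratio above which a gene is called `up` (and below
#'   whose reciprocal it is called `down`); default 1.5.
#' @return Tibble with `gene`, `class`, `group`, `tissue`, `ratio`
#'   (stress/control), `log2_ratio`, `direction`, `not_detected` (TRUE when
#'   either condition lacked any detection; such genes are called `flat`).
#' @export
expression_directions <- function(summary, fold_threshold = 1.5) {
  wide <- summary |>
    select("gene", "class", "group", "tissue", "condition", "rel_expr") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "rel_expr")
  for (nm in c("control", "stress")) if (!nm %in% names(wide)) wide[[nm]] <- NA_real_
  wide |>
    mutate(
      ratio = .data$stress / .data$control,
      log2_ratio = log2(.data$ratio),
      not_detected = is.na(.data$stress) | is.na(.data$control),
      direction = direction_call(.data$ratio, fold_threshold)
    ) |>
    select("gene", "class", "group", "tissue", "ratio", "log2_ratio",
           "direction", "not_detected")
}

#' Flag miRNA/target pairs with inverse expression
#'
#' A pair is flagged inverse in a group x tissue cell when one molecule goes
#' up and the other goes down (strictly opposite directions at the fold
#' threshold). A molecule undetected in either condition is `flat` and can
#' never support an inverse call.
#'
#' @param directions Output of [expression_directions()].
#' @param pairs Tibble with columns `mirna`, `target` naming genes present
#'   in `directions`.
#' @return Tibble with one row per pair x group x tissue: the two direction
#'   calls and the logical `inverse`.
#' @export
flag_inverse <- function(directions, pairs) {
  md <- directions |>
    select(mirna = "gene", "group", "tissue",
           mirna_direction = "direction", mirna_nd = "not_detected")
  td <- directions |>
    select(target = "gene", "group", "tissue",
           target_direction = "direction", target_nd = "not_detected")
  pairs |>
    left_join(md, by = "mirna", relationship = "many-to-many") |>
    left_join(td, by = c("target", "group", "tissue")) |>
    mutate(inverse =
             (.data$mirna_direction == "up" & .data$target_direction == "down") |
             (.data$mirna_direction == "down" & .data$target_direction == "up")) |>
    mutate(inverse = ifelse(is.na(.data$inverse), FALSE, .data$inverse))
}

#' Log2 stress/control fold-change matrix
#'
#' One row per gene, one column per group x tissue cell; NA where either
#' condition was undetected. The layout mirrors the qRT-PCR heatmaps used to
#' compare miRNA responses across genomic groups and tissues.
#'
#' @param summary Output of [summarize_expression()].
#' @return A numeric matrix (genes x group:tissue).
#' @export
heatmap_matrix <- function(summary) {
  d <- expression_directions(summary) |>
    mutate(unit = paste(.data$group, .data$tissue, sep = ":"))
  wide <- tidyr::pivot_wider(
    select(d, "gene", "unit", "log2_ratio"),
    names_from = "unit", values_from = "log2_ratio"
  )
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$gene
  m
}

#' Condition-by-group ANOVA for one gene (routine companion statistics)
#'
#' Two-way ANOVA of relative expression on condition and group with
#' interaction, followed by Tukey's HSD, per tissue.
#'
#' @param rel_table Output of [rel_expression_table()].
#' @param gene Gene to test.
#' @param tissue Tissue to test.
#' @return List with the `aov` fit and the `TukeyHSD` table.
#' @export
expression_anova <- function(rel_table, gene, tissue) {
  d <- filter(rel_table, .data$gene == !!gene, .data$tissue == !!tissue,
              !is.na(.data$rel_expr))
  d$condition <- factor(d$condition)
  d$group <- factor(d$group)
  fit <- aov(rel_expr ~ condition * group, data = d)
  list(fit = fit, tukey = TukeyHSD(fit))
}
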