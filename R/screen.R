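#' Reads Per Kilobase of exon per Million mapped reads
#'
#' `count * 1e9 / (length_nt * total_mapped)`.  Vectorised; `NA` counts
#' ("not detectable") propagate to `NA` RPKM.
#'
#' @param count Non-negative read counts.
#' @param length_nt Transcript lengths in nucleotides (> 0).
#' @param total_mapped Library sizes in mapped reads (> 0).
#' @return RPKM values.
#' @examples
#' compute_rpkm(100, 1000, 1e6)  # 100
#' @export
compute_rpkm <- function(count, length_nt, total_mapped) {
  if (any(length_nt <= 0, na.rm = TRUE)) abort("`length_nt` must be > 0.")
  if (any(total_mapped <= 0, na.rm = TRUE)) abort("`total_mapped` must be > 0.")
  if (any(count < 0, na.rm = TRUE)) abort("`count` must be >= 0.")
  count * 1e9 / (length_nt * total_mapped)
}

#' Fold enrichment of a tissue over the control
#'
#' Expression that is below detection ("not detectable", represented as
#' `NA`) is an explicit state, never a zero: a not-detectable tissue gives
#' fold 0, and a not-detectable control is replaced by the small floor
#' `nd_epsilon` so that genes expressed in the tissue but silent in the
#' control still screen in.
#'
#' @param tissue,control RPKM vectors; `NA` means not detectable.
#' @param nd_epsilon Control floor (RPKM) used when the control is not
#'   detectable.  The default 0.1 means any tissue RPKM of at least 1
#'   passes a 10-fold screen.
#' @return Fold-enrichment values (may be `Inf` when the control is a
#'   measured zero).
#' @export
fold_enrichment <- function(tissue, control, nd_epsilon = 0.1) {
  if (nd_epsilon <= 0) abort("`nd_epsilon` must be > 0.")
  if (any(tissue < 0, na.rm = TRUE) || any(control < 0, na.rm = TRUE)) {
    abort("RPKM values must be >= 0.")
  }
  n <- max(length(tissue), length(control))
  tissue <- rep_len(as.numeric(tissue), n)
  control <- rep_len(as.numeric(control), n)
  dplyr::case_when(
    is.na(tissue) ~ 0,
    is.na(control) ~ tissue / nd_epsilon,
    tissue == 0 & control == 0 ~ 0,  # measured zeros: no enrichment
    TRUE ~ tissue / control
  )
}

#' Select candidate genes from an axillary-meristem expression table
#'
#' Reproduces the three-part candidate screen: (a) expression in the early
#' (EA) or very-early (VE) axillary-meristem zone at least `min_fold` times
#' the control, (b) assembled length strictly greater than
#' `min_length_nt`, and (c) an annotation class in `allowed_classes`.
#' A selected gene is assigned to the passing tissue with the larger RPKM
#' (ties go to EA).
#'
#' @param records Data frame with columns `gene_id`, `length_nt`, `ea`,
#'   `ve`, `control` (RPKM; `NA` = not detectable) and `annotation_class`.
#' @param min_fold Minimum fold enrichment (default 10).
#' @param min_length_nt Length threshold; the criterion is strict
#'   (`length_nt > min_length_nt`, default 200).
#' @param allowed_classes Annotation classes that pass criterion (c).
#' @param nd_epsilon Control floor for not-detectable controls, see
#'   [fold_enrichment()].
#' @return A tibble with one row per *selected* gene: `gene_id`,
#'   `assigned_tissue` (`"EA"`/`"VE"`), `fold_vs_control`, and logical
#'   columns `passed_a/b/c`.  Attribute `"screened"` holds the full
#'   per-gene criteria table.
#' @export
select_candidates <- function(records, min_fold = 10, min_length_nt = 200,
                              allowed_classes = c("transcription_factor", "unknown"),
                              nd_epsilon = 0.1) {
  needed <- c("gene_id", "length_nt", "ea", "ve", "control", "annotation_class")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    abort(paste0("`records` is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(records$gene_id)) {
    abort(sprintf("Duplicate gene_id: %s",
                  records$gene_id[duplicated(records$gene_id)][1]))
  }
  scr <- records |>
    as_tibble() |>
    dplyr::mutate(
      fold_ea = fold_enrichment(.data$ea, .data$control, nd_epsilon),
      fold_ve = fold_enrichment(.data$ve, .data$control, nd_epsilon),
      passed_a = pmax(.data$fold_ea, .data$fold_ve) >= min_fold,
      passed_b = .data$length_nt > min_length_nt,
      passed_c = .data$annotation_class %in% allowed_classes,
      selected = .data$passed_a & .data$passed_b & .data$passed_c
    )
  sel <- scr |>
    dplyr::filter(.data$selected) |>
    dplyr::mutate(
      assigned_tissue = assign_tissue(.data$ea, .data$ve, .data$fold_ea,
                                      .data$fold_ve, min_fold),
      fold_vs_control = pmax(.data$fold_ea, .data$fold_ve)
    ) |>
    dplyr::select("gene_id", "assigned_tissue", "fold_vs_control",
                  "passed_a", "passed_b", "passed_c")
  attr(sel, "screened") <- scr
  sel
}

#' Assign a selected gene to its expression tissue
#'
#' Among the tissues whose fold enrichment reaches `min_fold`, the tissue
#' with the larger RPKM wins; exact RPKM ties go to EA.  At least one
#' tissue must pass.
#'
#' @param ea,ve Tissue RPKM (`NA` = not detectable, treated as lowest).
#' @param fold_ea,fold_ve Fold enrichments from [fold_enrichment()].
#' @param min_fold Fold threshold.
#' @return Character vector of `"EA"` / `"VE"`.
#' @export
assign_tissue <- function(ea, ve, fold_ea, fold_ve, min_fold = 10) {
  if (any(fold_ea < min_fold & fold_ve < min_fold)) {
    abort("assign_tissue() requires at least one tissue passing min_fold.")
  }
  ea_val <- ifelse(is.na(ea), -Inf, ea)
  ve_val <- ifelse(is.na(ve), -Inf, ve)
  dplyr::case_when(
    fold_ea >= min_fold & fold_ve < min_fold ~ "EA",
    fold_ve >= min_fold & fold_ea < min_fold ~ "VE",
    ve_val > ea_val ~ "VE",
    TRUE ~ "EA"  # includes the exact-tie rule
  )
}

#' Read / write an expression table
#'
#' Tab-separated columns `gene_id`, `length_nt`, `ea`, `ve`, `control`,
#' `annotation_class` (plus any extra columns); the literal string `ND`
#' marks not-detectable cells and is read as `NA`.
#'
#' @param path File path.
#' @return A tibble ([read_expression_table()]) or `path` invisibly.
#' @export
read_expression_table <- function(path) {
  readr::read_tsv(path, na = c("ND", "NA"), show_col_types = FALSE,
                  progress = FALSE)
}

#' @rdname read_expression_table
#' @param records Data frame to write.
#' @export
write_expression_table <- function(records, path) {
  out <- dplyr::mutate(records, dplyr::across(
    dplyr::where(is.numeric), ~ ifelse(is.na(.x), NA, .x)
  ))
  readr::write_tsv(out, path, na = "ND", progress = FALSE)
  invisible(path)
}

#' Published axillary-meristem expression table
#'
#' RPKM values for the 12 candidate homolog constructs and the 24
#' screen-derived genes (11 EA, 13 VE) in the EA, VE and control
#' laser-microdissection zones, as published.  Not-detectable cells are
#' `NA`.
#'
#' @return A tibble with columns `gene_id`, `group` (`"homolog"` or
#'   `"screen"`), `ea`, `ve`, `control`.
#' @export
axillary_expression <- function() {
  path <- system.file("extdata", "axillary_expression.tsv",
                      package = "suckerscreen", mustWork = TRUE)
  readr::read_tsv(path, na = "ND", show_col_types = FALSE, progress = FALSE)
}

#' Plot fold enrichment of screened genes
#'
#' @param records Expression records as in [select_candidates()].
#' @param min_fold Fold threshold drawn as a dashed line.
#' @param nd_epsilon Control floor for not-detectable controls.
#' @return A ggplot object (log10 fold enrichment per tissue and gene).
#' @export
plot_enrichment <- function(records, min_fold = 10, nd_epsilon = 0.1) {
  df <- records |>
    dplyr::mutate(
      EA = fold_enrichment(.data$ea, .data$control, nd_epsilon),
      VE = fold_enrichment(.data$ve, .data$control, nd_epsilon)
    ) |>
    tidyr::pivot_longer(c("EA", "VE"), names_to = "tissue", values_to = "fold")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tissue, y = pmax(.data$fold, 0.01))) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = min_fold, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "Fold enrichment over control (log scale)")
}
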