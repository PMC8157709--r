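#' Per-line relative effects of constructs on shoot phenotypes
#'
#' For every construct, line and trait, the ratio of the transgenic plant
#' mean to the null-segregant plant mean within that line.  Null
#' segregants (progeny that lost the transgene) are the matched control,
#' so a ratio of 1 means no effect.  A line whose null mean is zero yields
#' a not-calculable ratio (`NA`) with a warning.
#'
#' @param phenotypes Long table with columns `construct_id`, `line_id`,
#'   `genotype` (`"transgenic"` / `"null_segregant"`), `plant_id`, `trait`,
#'   `value`.
#' @return A tibble: `construct_id`, `line_id`, `trait`, `ratio`.
#' @export
relative_effects <- function(phenotypes) {
  needed <- c("construct_id", "line_id", "genotype", "trait", "value")
  missing_cols <- setdiff(needed, names(phenotypes))
  if (length(missing_cols)) {
    abort(paste0("`phenotypes` is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  both <- phenotypes |>
    dplyr::distinct(.data$construct_id, .data$line_id, .data$genotype) |>
    dplyr::count(.data$construct_id, .data$line_id)
  if (any(both$n < 2)) {
    bad <- both[both$n < 2, ]
    abort(sprintf(
      "Construct %s line %s lacks one of the genotype classes.",
      bad$construct_id[1], bad$line_id[1]
    ))
  }
  out <- phenotypes |>
    dplyr::group_by(.data$construct_id, .data$line_id, .data$trait) |>
    dplyr::summarise(
      tg = mean(.data$value[.data$genotype == "transgenic"]),
      nu = mean(.data$value[.data$genotype == "null_segregant"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(ratio = ifelse(.data$nu > 0, .data$tg / .data$nu, NA_real_)) |>
    dplyr::select("construct_id", "line_id", "trait", "ratio")
  if (anyNA(out$ratio)) {
    warn("Some null-segregant means are zero; their ratios are not calculable (NA).")
  }
  out
}

#' Construct-level summaries of per-line relative effects
#'
#' Arithmetic mean and sample SD (n - 1 denominator) of the per-line
#' ratios, per construct and trait, mirroring the published
#' "effect relative to null segregants +/- SD" layout.  A single line
#' reports SD 0 with a warning.  Not-calculable lines are dropped.
#'
#' @param ratios Output of [relative_effects()].
#' @return A tibble: `construct_id`, `trait`, `mean`, `sd`, `n`.
#' @export
summarize_constructs <- function(ratios) {
  out <- ratios |>
    dplyr::filter(!is.na(.data$ratio)) |>
    dplyr::group_by(.data$construct_id, .data$trait) |>
    dplyr::summarise(
      mean = mean(.data$ratio),
      sd = ifelse(dplyr::n() > 1, stats::sd(.data$ratio), 0),
      n = dplyr::n(),
      .groups = "drop"
    )
  if (any(out$n == 1)) {
    warn("Constructs with a single usable line report sd = 0 by convention.")
  }
  out
}

one_sample_p <- function(mean, sd, n, mu = 1) {
  # Vectorised one-sample two-sided t against mu with the degenerate
  # zero-variance convention: sd = 0 gives p = 0 unless mean equals mu.
  se <- sd / sqrt(n)
  stat <- ifelse(sd == 0,
                 ifelse(mean == mu, 0, Inf * sign(mean - mu)),
                 (mean - mu) / se)
  p <- ifelse(sd == 0,
              ifelse(mean == mu, 1, 0),
              2 * pt(-abs((mean - mu) / se), df = n - 1))
  list(statistic = stat, df = n - 1, p_value = p)
}

#' One-sample t-test against a reference mean
#'
#' Two-sided Student t-test of per-line relative effects against `mu`
#' (1 = no effect), accepting either raw values or the published
#' mean/SD/n summary form.  A zero SD is the study's degenerate case
#' (e.g. every line fully suppressed): by the limit of the test statistic,
#' p is 0 when the mean differs from `mu` and 1 when it equals `mu`.
#'
#' @param x Raw values (optional if `mean`, `sd`, `n` are given).
#' @param mean,sd,n Summary-form inputs.
#' @param mu Reference mean (default 1).
#' @return An object of class `"shoot_ttest"`; see [tidy.shoot_ttest()].
#' @examples
#' t_test_one_sample(mean = 0.13, sd = 0.09, n = 3)  # strongly significant
#' @export
t_test_one_sample <- function(x = NULL, mean = NULL, sd = NULL, n = NULL, mu = 1) {
  if (!is.null(x)) {
    if (length(x) < 2) abort("Need at least 2 values for a one-sample t-test.")
    mean <- base::mean(x); sd <- stats::sd(x); n <- length(x)
  }
  if (is.null(mean) || is.null(sd) || is.null(n)) {
    abort("Provide either raw `x` or all of `mean`, `sd`, `n`.")
  }
  if (n < 2) abort("Need n >= 2.")
  r <- one_sample_p(mean, sd, n, mu)
  structure(
    list(statistic = r$statistic, df = r$df, p_value = r$p_value,
         estimate = mean, mu = mu, n = n, flavor = "one_sample"),
    class = "shoot_ttest"
  )
}

#' Two-sample t-test (Welch or pooled)
#'
#' Backed by [stats::t.test()]; two-sided.  When both groups are constant
#' the engine cannot run: equal constants give p = 1, unequal give p = 0
#' (the degenerate limit).
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#' @param flavor `"welch"` (default) or `"pooled"`.
#' @return An object of class `"shoot_ttest"`.
#' @export
t_test_two_sample <- function(a, b, flavor = c("welch", "pooled")) {
  flavor <- match.arg(flavor)
  if (length(a) < 2 || length(b) < 2) abort("Each group needs n >= 2.")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    res <- list(statistic = if (equal) 0 else Inf * sign(mean(a) - mean(b)),
                df = length(a) + length(b) - 2,
                p_value = if (equal) 1 else 0)
  } else {
    fit <- stats::t.test(a, b, var.equal = (flavor == "pooled"))
    res <- list(statistic = unname(fit$statistic),
                df = unname(fit$parameter),
                p_value = fit$p.value)
  }
  structure(
    list(statistic = res$statistic, df = res$df, p_value = res$p_value,
         estimate = mean(a) - mean(b), mu = 0, n = c(length(a), length(b)),
         flavor = paste0("two_sample_", flavor)),
    class = "shoot_ttest"
  )
}

#' @export
print.shoot_ttest <- function(x, ...) {
  cat(sprintf("%s t-test: t = %.3f, df = %.2f, p = %.4g\n",
              x$flavor, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Tidy a shoot t-test
#'
#' @param x A `"shoot_ttest"` object.
#' @param ... Ignored.
#' @return A one-row tibble with `estimate`, `statistic`, `df`, `p_value`,
#'   `mu` and `flavor`.
#' @export
tidy.shoot_ttest <- function(x, ...) {
  tibble(estimate = x$estimate, statistic = x$statistic, df = x$df,
         p_value = x$p_value, mu = x$mu, flavor = x$flavor)
}

#' @export
glance.shoot_ttest <- function(x, ...) tidy(x)

#' Test construct effects against the no-effect ratio
#'
#' Adds the one-sample two-sided t-test (against `mu = 1`) and the
#' significant-reduction flag to a construct/trait summary table.  A cell
#' is flagged only when it is significant *and* a reduction
#' (`mean < mu`): a significant increase is not suppression.
#'
#' @param summaries Table with `construct_id`, `trait`, `mean`, `sd`, `n`
#'   (raw-data route: [relative_effects()] then [summarize_constructs()]).
#' @param mu No-effect ratio (default 1).
#' @param alpha Significance level (default 0.01, the published level).
#' @return `summaries` with `statistic`, `df`, `p_value` and
#'   `significant_reduction` columns added.
#' @export
test_effects <- function(summaries, mu = 1, alpha = 0.01) {
  r <- one_sample_p(summaries$mean, summaries$sd, summaries$n, mu)
  dplyr::mutate(summaries,
    statistic = r$statistic, df = r$df, p_value = r$p_value,
    significant_reduction = .data$p_value < alpha & .data$mean < mu
  )
}

#' Call effective suppression genes
#'
#' A construct is effective when, for at least one of the requested
#' traits (by default secondary lateral-shoot number and weight), its mean
#' relative effect is significantly below 1 at level `alpha`.
#'
#' @param summaries Construct/trait summary table (`construct_id`, `trait`,
#'   `mean`, `sd`, `n`).
#' @param traits Traits a construct may qualify on.
#' @param alpha Significance level (default 0.01).
#' @param mu No-effect ratio (default 1).
#' @return Sorted character vector of effective construct ids.
#' @export
call_effective_genes <- function(summaries,
                                 traits = c("secondary_n", "secondary_wt"),
                                 alpha = 0.01, mu = 1) {
  have <- summaries |>
    dplyr::filter(.data$trait %in% traits) |>
    dplyr::count(.data$construct_id)
  all_constructs <- unique(summaries$construct_id)
  short <- setdiff(all_constructs, have$construct_id[have$n == length(traits)])
  if (length(short)) {
    abort(sprintf("Construct '%s' is missing rows for the requested traits.",
                  short[1]))
  }
  tested <- summaries |>
    dplyr::filter(.data$trait %in% traits) |>
    test_effects(mu = mu, alpha = alpha)
  sort(unique(tested$construct_id[tested$significant_reduction]))
}

#' Published RNAi effect summaries
#'
#' Construct-level mean +/- SD of the per-line effects relative to null
#' segregants for the 36 RNAi constructs (expression plus primary and
#' secondary lateral-shoot number and weight; three single-locus lines per
#' construct), together with the published significance marks.
#'
#' @return A tibble with columns `construct_id`, `trait`, `mean`, `sd`,
#'   `n`, `marked` (`TRUE` where the published table carries the 1%-level
#'   mark).
#' @export
rnai_effects <- function() {
  path <- system.file("extdata", "rnai_effects.tsv",
                      package = "suckerscreen", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Plot relative effects with significance marks
#'
#' @param tested Output of [test_effects()].
#' @return A ggplot object: mean +/- SD per construct and trait, flagged
#'   cells highlighted.
#' @export
plot_effects <- function(tested) {
  ggplot2::ggplot(tested, ggplot2::aes(
    x = .data$construct_id, y = .data$mean,
    colour = .data$significant_reduction
  )) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$trait), scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "Effect relative to null segregants",
                  colour = "Significant reduction") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
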