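#' Run the full synthetic screening pipeline
#'
#' Orchestrates simulate -> screen -> design -> offtarget -> phenostats on
#' one [sim_config()], writing every stage artifact (FASTA / TSV) plus an
#' md5 manifest and a human-readable report into `outdir`.  With a fixed
#' configuration the whole run is deterministic: a rerun reproduces
#' identical file digests.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @param stages Subset of
#'   `c("simulate", "screen", "design", "offtarget", "phenostats")`;
#'   later stages require the earlier ones in the same call.
#' @param trigger_length,min_st_identity,max_paralog_identity,step Trigger
#'   design parameters, see [design_triggers()].
#' @param k Off-target minimum exact match length (default 22).
#' @param alpha Significance level for effective-gene calling.
#' @return Invisibly, a list with the stage outputs (`transcriptome`,
#'   `expression`, `candidates`, `triggers`, `offtarget_hits`, `verdicts`,
#'   `effects`, `effective_genes`), the `manifest` tibble and the `report`
#'   lines.
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("simulate", "screen", "design",
                                    "offtarget", "phenostats"),
                         trigger_length = 430, min_st_identity = 90,
                         max_paralog_identity = 70, step = 5L,
                         k = 22L, alpha = 0.01) {
  stopifnot(inherits(config, "sim_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit_tsv <- function(df, name) {
    p <- file.path(outdir, name)
    readr::write_tsv(df, p, na = "ND", progress = FALSE)
    paths[[length(paths) + 1]] <<- p
    p
  }
  run <- list(config = config)
  stage_wrap <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  if ("simulate" %in% stages) {
    run$transcriptome <- stage_wrap("simulate", simulate_transcriptome(config))
    fa <- file.path(outdir, "transcripts.fasta")
    write_transcript_fasta(run$transcriptome$transcripts, fa)
    paths[[length(paths) + 1]] <- fa
    emit_tsv(run$transcriptome$families, "families.tsv")
    emit_tsv(run$transcriptome$paralogs, "paralogs.tsv")
    sim_expr <- stage_wrap("simulate", simulate_expression(run$transcriptome, config))
    run$expression <- sim_expr$expression
    emit_tsv(sim_expr$expression, "expression.tsv")
    emit_tsv(sim_expr$truth, "expression_truth.tsv")
    run$phenotypes <- stage_wrap("simulate", simulate_phenotypes(config))
    emit_tsv(run$phenotypes, "phenotypes.tsv")
  }
  if ("screen" %in% stages) {
    run$candidates <- stage_wrap("screen", select_candidates(run$expression))
    emit_tsv(run$candidates, "candidates.tsv")
  }
  if ("design" %in% stages) {
    run$triggers <- stage_wrap("design", design_triggers(
      run$transcriptome$transcripts, run$transcriptome$families,
      dplyr::select(run$transcriptome$paralogs, "family_id", "paralog_id"),
      trigger_length = trigger_length, min_st_identity = min_st_identity,
      max_paralog_identity = max_paralog_identity, step = step
    ))
    emit_tsv(dplyr::select(run$triggers, -"paralog_identity",
                           -"binding_constraints"),
             "triggers.tsv")
    ok <- dplyr::filter(run$triggers, .data$status == "ok")
    fa <- file.path(outdir, "triggers.fasta")
    write_transcript_fasta(
      tibble(id = ok$family_id, sequence = ok$sequence), fa
    )
    paths[[length(paths) + 1]] <- fa
  }
  if ("offtarget" %in% stages) {
    ok <- dplyr::filter(run$triggers, .data$status == "ok")
    exclusions <- dplyr::bind_rows(
      tibble(trigger_id = ok$family_id,
             transcript_id = ok$source_gene_id),
      tibble(trigger_id = ok$family_id,
             transcript_id = ok$partner_gene_id)
    )
    run$offtarget_hits <- stage_wrap("offtarget", scan_offtargets(
      dplyr::transmute(ok, trigger_id = .data$family_id, sequence = .data$sequence),
      run$transcriptome$transcripts, k = k, exclude = exclusions
    ))
    run$verdicts <- classify_triggers(
      dplyr::transmute(ok, trigger_id = .data$family_id, sequence = .data$sequence),
      run$offtarget_hits
    )
    emit_tsv(run$offtarget_hits, "offtarget_hits.tsv")
    emit_tsv(run$verdicts, "offtarget_verdicts.tsv")
  }
  if ("phenostats" %in% stages) {
    run$effects <- stage_wrap("phenostats", {
      relative_effects(run$phenotypes) |>
        summarize_constructs() |>
        test_effects(alpha = alpha)
    })
    run$effective_genes <- call_effective_genes(run$effects, alpha = alpha)
    emit_tsv(run$effects, "effects.tsv")
    emit_tsv(tibble(construct_id = run$effective_genes), "effective_genes.tsv")
  }

  run$manifest <- tibble(
    file = basename(unlist(paths)),
    md5 = unname(tools::md5sum(unlist(paths)))
  )
  emit_tsv(run$manifest, "manifest.tsv")
  run$report <- pipeline_report(outdir)
  writeLines(run$report, file.path(outdir, "report.txt"))
  invisible(run)
}

#' Summarise a pipeline run directory
#'
#' Recomputes every headline number from the stage files on disk (never
#' from in-memory caches), so the report cannot disagree with the
#' artifacts it describes.
#'
#' @param outdir A directory written by [run_pipeline()].
#' @return Character vector of report lines.
#' @export
pipeline_report <- function(outdir) {
  lines <- c("suckerscreen pipeline report", "===========================")
  grab <- function(name) {
    p <- file.path(outdir, name)
    if (file.exists(p)) readr::read_tsv(p, na = "ND", show_col_types = FALSE,
                                        progress = FALSE) else NULL
  }
  fam <- grab("families.tsv")
  if (!is.null(fam)) {
    lines <- c(lines, sprintf("Simulated homoeolog families: %d", nrow(fam)))
  }
  cand <- grab("candidates.tsv")
  if (!is.null(cand)) {
    lines <- c(lines, sprintf(
      "Screen: %d candidate genes selected (%d EA, %d VE)",
      nrow(cand), sum(cand$assigned_tissue == "EA"),
      sum(cand$assigned_tissue == "VE")
    ))
  }
  trig <- grab("triggers.tsv")
  if (!is.null(trig)) {
    ok <- trig[trig$status == "ok", ]
    lines <- c(lines, sprintf(
      "Triggers designed: %d of %d families (mean length %.1f nt, mean S/T identity %.1f%%)",
      nrow(ok), nrow(trig), mean(ok$length_nt), mean(ok$st_identity_pct)
    ))
  }
  verd <- grab("offtarget_verdicts.tsv")
  if (!is.null(verd)) {
    lines <- c(lines, sprintf(
      "Off-target scan: %d clean trigger(s), %d with off-target risk",
      sum(verd$verdict == "clean"), sum(verd$verdict == "off_target_risk")
    ))
  }
  eff <- grab("effective_genes.tsv")
  if (!is.null(eff)) {
    lines <- c(lines, sprintf(
      "Effective suppression constructs (%d): %s",
      nrow(eff), paste(eff$construct_id, collapse = ", ")
    ))
  }
  if (length(lines) == 2) lines <- c(lines, "(empty run)")
  lines
}
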