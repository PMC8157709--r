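#' Build an exact k-mer index over a transcriptome
#'
#' Every k-mer occurrence of every transcript is indexed; k-mers containing
#' `N` are skipped (N never matches anything) and transcripts shorter than
#' `k` contribute nothing.
#'
#' @param transcripts Transcript table with `id` and `sequence` columns.
#' @param k Word size; at least 8 (default 22, the published minimum match
#'   length for small-RNA off-target silencing).
#' @return A list of class `"kmer_index"` with the position table and `k`.
#' @export
kmer_index <- function(transcripts, k = 22L) {
  k <- as.integer(k)
  if (k < 8L) abort("`k` must be >= 8.")
  check_dna(transcripts$sequence)
  rows <- purrr::map2(transcripts$id, transcripts$sequence, function(id, s) {
    L <- nchar(s)
    if (L < k) return(NULL)
    pos <- seq_len(L - k + 1L)
    km <- substring(s, pos, pos + k - 1L)
    keep <- !grepl("N", km, fixed = TRUE)
    if (!any(keep)) return(NULL)
    tibble(kmer = km[keep], transcript_id = id, position = pos[keep])
  })
  structure(list(table = dplyr::bind_rows(rows), k = k), class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("k-mer index: k = %d, %d positions, %d transcripts\n",
              x$k, nrow(x$table), dplyr::n_distinct(x$table$transcript_id)))
  invisible(x)
}

# Collapse seed hits on one (transcript, strand) diagonal into maximal runs.
# A run of m consecutive seed starts on a diagonal is one maximal exact
# match of length k + m - 1 (every k-mer inside a shared substring seeds,
# so runs and maximal matches are in bijection).
chain_seeds <- function(trig_pos, tx_pos, k) {
  o <- order(trig_pos)
  trig_pos <- trig_pos[o]; tx_pos <- tx_pos[o]
  brk <- c(TRUE, diff(trig_pos) != 1L)
  run <- cumsum(brk)
  starts <- tapply(seq_along(trig_pos), run, function(ix) ix[1])
  lens <- tabulate(run)
  tibble(
    trigger_start = trig_pos[starts],
    transcript_start = tx_pos[starts],
    match_length_nt = k + lens - 1L
  )
}

#' Scan triggers for exact off-target matches of at least k nucleotides
#'
#' Finds every maximal exact match of at least `k` consecutive
#' nucleotides between each trigger and any transcript, on the sense
#' strand and (by default) the antisense strand — hairpin RNAi produces
#' small RNAs from both strands.  Matches inside the trigger's own target
#' genes are removed via `exclude`.  Every reported match is re-verified
#' character by character.
#'
#' @param triggers Data frame with `trigger_id` (or `family_id`) and
#'   `sequence` columns, or a named character vector of trigger sequences.
#' @param transcripts Transcript table (`id`, `sequence`).
#' @param k Minimum exact match length (default 22).
#' @param exclude Either a character vector of transcript ids excluded for
#'   every trigger, or a data frame with `trigger_id`, `transcript_id`
#'   pairs (per-trigger exclusions, e.g. each family's own S/T genes).
#' @param strands `"both"` (default) or `"sense"`.
#' @param index Optional pre-built [kmer_index()] over `transcripts`.
#' @return A tibble of maximal hits: `trigger_id`, `transcript_id`,
#'   `trigger_start`, `trigger_end`, `transcript_start`, `transcript_end`
#'   (1-based, inclusive), `strand` (`"sense"`/`"antisense"`) and
#'   `match_length_nt`.  Trigger coordinates always refer to the trigger's
#'   own (sense) orientation.
#' @export
scan_offtargets <- function(triggers, transcripts, k = 22L, exclude = NULL,
                            strands = c("both", "sense"), index = NULL) {
  strands <- match.arg(strands)
  k <- as.integer(k)
  if (is.character(triggers)) {
    triggers <- tibble(
      trigger_id = names(triggers) %||% paste0("trigger_", seq_along(triggers)),
      sequence = unname(triggers)
    )
  }
  if (!"trigger_id" %in% names(triggers)) {
    triggers <- dplyr::mutate(triggers, trigger_id = .data$family_id)
  }
  check_dna(triggers$sequence, "triggers$sequence")
  if (any(nchar(triggers$sequence) < k)) {
    abort(sprintf("All triggers must be at least k = %d nt long.", k))
  }
  index <- index %||% kmer_index(transcripts, k)
  if (index$k != k) abort("`index` was built with a different k.")
  seq_of <- setNames(transcripts$sequence, transcripts$id)

  scan_one <- function(trigger_id, trig_seq) {
    per_strand <- function(strand) {
      qseq <- if (strand == "sense") trig_seq else reverse_complement(trig_seq)
      L <- nchar(qseq)
      pos <- seq_len(L - k + 1L)
      km <- substring(qseq, pos, pos + k - 1L)
      q <- tibble(kmer = km, qpos = pos)
      q <- q[!grepl("N", q$kmer, fixed = TRUE), ]
      hits <- dplyr::inner_join(q, index$table, by = "kmer",
                                relationship = "many-to-many")
      if (nrow(hits) == 0) return(NULL)
      hits |>
        dplyr::mutate(diag = .data$position - .data$qpos) |>
        dplyr::group_by(.data$transcript_id, .data$diag) |>
        dplyr::reframe(chain_seeds(.data$qpos, .data$position, k)) |>
        dplyr::mutate(strand = strand) |>
        dplyr::select(-"diag")
    }
    res <- dplyr::bind_rows(
      per_strand("sense"),
      if (strands == "both") per_strand("antisense")
    )
    if (nrow(res) == 0) return(NULL)
    L <- nchar(trig_seq)
    res <- res |>
      dplyr::mutate(
        trigger_end = .data$trigger_start + .data$match_length_nt - 1L,
        transcript_end = .data$transcript_start + .data$match_length_nt - 1L
      )
    # map antisense coordinates back onto the trigger's own orientation
    anti <- res$strand == "antisense"
    if (any(anti)) {
      ts <- res$trigger_start[anti]; te <- res$trigger_end[anti]
      res$trigger_start[anti] <- L - te + 1L
      res$trigger_end[anti] <- L - ts + 1L
    }
    dplyr::mutate(res, trigger_id = trigger_id, .before = 1)
  }

  out <- purrr::pmap_dfr(
    list(triggers$trigger_id, triggers$sequence),
    function(id, s) scan_one(id, s) %||% tibble()
  )
  if (nrow(out) == 0) {
    out <- tibble(
      trigger_id = character(), transcript_id = character(),
      trigger_start = integer(), trigger_end = integer(),
      transcript_start = integer(), transcript_end = integer(),
      strand = character(), match_length_nt = integer()
    )
  } else {
    out <- dplyr::select(out, "trigger_id", "transcript_id",
                         "trigger_start", "trigger_end",
                         "transcript_start", "transcript_end",
                         "strand", "match_length_nt") |>
      dplyr::arrange(.data$trigger_id, .data$transcript_id,
                     .data$transcript_start)
  }
  if (!is.null(exclude)) {
    if (is.data.frame(exclude)) {
      out <- dplyr::anti_join(out, exclude,
                              by = c("trigger_id", "transcript_id"))
    } else {
      out <- dplyr::filter(out, !.data$transcript_id %in% exclude)
    }
  }
  # post-check: every reported substring must be literally identical
  if (nrow(out) > 0) {
    trig_of <- setNames(triggers$sequence, triggers$trigger_id)
    ok <- purrr::pmap_lgl(out, function(trigger_id, transcript_id,
                                        trigger_start, trigger_end,
                                        transcript_start, transcript_end,
                                        strand, match_length_nt) {
      t_sub <- substr(trig_of[[trigger_id]], trigger_start, trigger_end)
      x_sub <- substr(seq_of[[transcript_id]], transcript_start, transcript_end)
      if (strand == "antisense") t_sub <- reverse_complement(t_sub)
      identical(t_sub, x_sub)
    })
    if (!all(ok)) abort("Internal error: reported off-target hit failed re-verification.")
  }
  out
}

#' Classify triggers by off-target risk
#'
#' A trigger is `clean` when it has no exact match of at least k
#' consecutive nucleotides anywhere outside its own target genes, and
#' `off_target_risk` otherwise.
#'
#' @param triggers Trigger table (`trigger_id` or `family_id`, `sequence`).
#' @param hits Hit table from [scan_offtargets()] (already excluding the
#'   triggers' own targets).
#' @return A tibble: `trigger_id`, `n_hits`, `n_transcripts`, `verdict`.
#' @export
classify_triggers <- function(triggers, hits) {
  if (is.character(triggers)) {
    ids <- names(triggers) %||% paste0("trigger_", seq_along(triggers))
  } else {
    ids <- triggers$trigger_id %||% triggers$family_id
  }
  counts <- hits |>
    dplyr::group_by(.data$trigger_id) |>
    dplyr::summarise(n_hits = dplyr::n(),
                     n_transcripts = dplyr::n_distinct(.data$transcript_id))
  tibble(trigger_id = ids) |>
    dplyr::left_join(counts, by = "trigger_id") |>
    dplyr::mutate(
      n_hits = dplyr::coalesce(.data$n_hits, 0L),
      n_transcripts = dplyr::coalesce(.data$n_transcripts, 0L),
      verdict = ifelse(.data$n_hits > 0, "off_target_risk", "clean")
    )
}
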