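#' Homoeolog sliding-window identity profile
#'
#' Globally aligns the S- and T-subgenome copies of a target gene and
#' profiles the identity of every candidate trigger window, one entry per
#' window start on the (ungapped) S sequence.
#'
#' @param s_sequence,t_sequence DNA strings for the S and T homoeologs.
#' @param window_length Trigger window length in nt (default 430, the
#'   average trigger length used in the study design this emulates).
#' @param step Step between window starts (nt).
#' @param scoring Alignment scoring, see [align_scoring()].
#' @return An `"identity_profile"` tibble (`start`, `end`, `identity_pct`).
#' @export
homoeolog_window_profile <- function(s_sequence, t_sequence,
                                     window_length = 430, step = 1L,
                                     scoring = align_scoring()) {
  if (nchar(s_sequence) < window_length) {
    abort(sprintf(
      "Gene (%d nt) is shorter than the trigger window (%d nt); configure a shorter trigger_length.",
      nchar(s_sequence), window_length
    ))
  }
  aln <- align_pair(s_sequence, t_sequence, scoring)
  windowed_identity(aln, window_length, step)
}

design_trigger_pair <- function(family_id, s_id, t_id, s_sequence, t_sequence,
                                paralogs, trigger_length, min_st_identity,
                                max_paralog_identity, step, scoring) {
  profile <- homoeolog_window_profile(s_sequence, t_sequence,
                                      trigger_length, step, scoring)
  n_par <- nrow(paralogs)
  if (n_par > 0) {
    par_best <- matrix(NA_real_, nrow(profile), n_par)
    for (j in seq_len(n_par)) {
      v <- window_best_identity(s_sequence, paralogs$sequence[[j]],
                                trigger_length, both_strands = TRUE)
      par_best[, j] <- v[profile$start]
    }
    max_par <- apply(par_best, 1, max)
  } else {
    max_par <- rep(-Inf, nrow(profile))
  }
  ok_st <- profile$identity_pct >= min_st_identity
  ok_par <- max_par < max_paralog_identity
  valid <- ok_st & ok_par
  base <- tibble(
    family_id = family_id, source_gene_id = s_id, partner_gene_id = t_id,
    start = NA_integer_, end = NA_integer_, length_nt = NA_integer_,
    sequence = NA_character_, st_identity_pct = NA_real_,
    max_paralog_identity_pct = NA_real_, n_paralogs = n_par,
    status = "no_valid_trigger",
    paralog_identity = list(tibble(gene_id = character(), identity_pct = numeric())),
    binding_constraints = list(NULL)
  )
  if (!any(valid)) {
    # report which constraint binds where, so the failure is actionable
    base$binding_constraints <- list(tibble(
      start = profile$start,
      st_identity_pct = profile$identity_pct,
      max_paralog_identity_pct = ifelse(is.finite(max_par), max_par, NA_real_),
      fails = dplyr::case_when(
        !ok_st & !ok_par ~ "both",
        !ok_st ~ "st_identity",
        TRUE ~ "paralog_identity"
      )
    ))
    return(base)
  }
  best <- which(valid)[which.max(profile$identity_pct[valid])]
  # which.max returns the first (leftmost) index on ties
  best_start <- profile$start[best]
  pid <- if (n_par > 0) {
    tibble(gene_id = paralogs$id, identity_pct = par_best[best, ])
  } else {
    tibble(gene_id = character(), identity_pct = numeric())
  }
  dplyr::mutate(base,
    start = !!best_start,
    end = !!(best_start + trigger_length - 1L),
    length_nt = as.integer(trigger_length),
    sequence = substr(s_sequence, best_start, best_start + trigger_length - 1L),
    st_identity_pct = profile$identity_pct[best],
    max_paralog_identity_pct = ifelse(n_par > 0, max(pid$identity_pct), NA_real_),
    status = "ok",
    paralog_identity = list(pid)
  )
}

#' Design RNAi trigger windows for homoeolog pairs
#'
#' For every family, selects the trigger window on the S-subgenome copy
#' that maximises the S/T homoeolog identity (so a single hairpin knocks
#' down both copies), subject to a hard cap on the identity with every
#' same-family paralog (so the hairpin does not silence its relatives).
#' Ties are broken towards the leftmost window.  A family in which no
#' window satisfies both constraints is returned with
#' `status = "no_valid_trigger"` and a per-window breakdown of the binding
#' constraint in the `"binding_constraints"` attribute of that row's
#' design.
#'
#' @param transcripts Transcript table (as from [read_transcript_fasta()]
#'   or [simulate_transcriptome()]) holding all referenced sequences.
#' @param pairs Data frame with columns `family_id`, `s_id`, `t_id`.
#' @param paralogs Optional data frame with columns `family_id`,
#'   `paralog_id`: same-family genes the trigger must discriminate
#'   against.  Sequences are looked up in `transcripts`.
#' @param trigger_length Window length in nt (default 430).
#' @param min_st_identity Minimum S/T window identity (%, default 90).
#' @param max_paralog_identity Hard cap (%, exclusive) on the best sliding
#'   identity against any paralog, on either strand (default 70).
#' @param step Window-start step in nt (default 1, exhaustive).
#' @param scoring Alignment scoring, see [align_scoring()].
#' @return A tibble with one row per family: coordinates (1-based,
#'   inclusive) on the source gene, the trigger `sequence`,
#'   `st_identity_pct`, `max_paralog_identity_pct`, a `paralog_identity`
#'   list-column with the per-paralog breakdown, and `status`.
#' @export
design_triggers <- function(transcripts, pairs, paralogs = NULL,
                            trigger_length = 430, min_st_identity = 90,
                            max_paralog_identity = 70, step = 1L,
                            scoring = align_scoring()) {
  if (!(max_paralog_identity > 0 && max_paralog_identity < min_st_identity &&
        min_st_identity <= 100)) {
    abort("Require 0 < max_paralog_identity < min_st_identity <= 100.")
  }
  trigger_length <- as.integer(trigger_length)
  seq_of <- setNames(transcripts$sequence, transcripts$id)
  lookup <- function(id) {
    s <- unname(seq_of[id])
    if (is.na(s)) abort(sprintf("Transcript '%s' not found in `transcripts`.", id))
    s
  }
  paralogs <- paralogs %||% tibble(family_id = character(), paralog_id = character())
  out <- purrr::pmap_dfr(pairs, function(family_id, s_id, t_id, ...) {
    fam_par <- dplyr::filter(paralogs, .data$family_id == !!family_id)
    par_tbl <- tibble(id = fam_par$paralog_id,
                      sequence = purrr::map_chr(fam_par$paralog_id, lookup))
    design_trigger_pair(
      family_id, s_id, t_id, lookup(s_id), lookup(t_id), par_tbl,
      trigger_length, min_st_identity, max_paralog_identity, step, scoring
    )
  })
  class(out) <- c("trigger_design", class(out))
  out
}

#' Summary statistics of a trigger set
#'
#' @param triggers Design table from [design_triggers()] (rows with
#'   `status != "ok"` are dropped first).
#' @return A one-row tibble: `n`, `mean_length_nt`, `mean_st_identity_pct`.
#' @export
summarize_triggers <- function(triggers) {
  ok <- dplyr::filter(triggers, .data$status == "ok")
  if (nrow(ok) == 0) abort("No successfully designed triggers to summarize.")
  tibble(
    n = nrow(ok),
    mean_length_nt = mean(ok$length_nt),
    mean_st_identity_pct = mean(ok$st_identity_pct)
  )
}

#' @method glance trigger_design
#' @export
glance.trigger_design <- function(x, ...) summarize_triggers(x)
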