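# Ungapped diagonal match counting.
#
# For every window of length `w` on `source` and every ungapped placement of
# that window against `subject`, count matching bases; keep, per window
# start, the maximum over placements.  Placements that hang over the ends of
# `subject` simply contribute fewer comparable positions, so a subject
# shorter than the window is handled naturally.  `N` never matches.

int_seq <- function(x) {
  v <- utf8ToInt(x)
  v[v == utf8ToInt("N")] <- -1L  # sentinel: never equal across sequences
  v
}

diag_best_matches <- function(src_int, sub_int, w) {
  L1 <- length(src_int); L2 <- length(sub_int)
  nw <- max(L1 - w + 1L, 1L)
  ww <- min(w, L1)
  best <- integer(nw)
  sub_cmp <- sub_int
  sub_cmp[sub_cmp == -1L] <- -2L  # N in subject distinct from N in source
  s_idx <- seq_len(nw)
  for (d in seq.int(1L - L1, L2 - 1L)) {
    i1 <- max(1L, 1L - d); i2 <- min(L1, L2 - d)
    if (i2 < i1) next
    eq <- src_int[i1:i2] == sub_cmp[(i1:i2) + d]
    cs <- c(0L, cumsum(eq))
    a <- pmax(s_idx, i1)
    b <- pmin(s_idx + ww - 1L, i2)
    ok <- b >= a
    if (!any(ok)) next
    m <- integer(nw)
    m[ok] <- cs[b[ok] - i1 + 2L] - cs[a[ok] - i1 + 1L]
    best <- pmax(best, m)
  }
  best
}

# Per-window-start best ungapped identity (%) of windows of `source`
# against `subject`, optionally also against its reverse complement.
window_best_identity <- function(source, subject, window_length,
                                 both_strands = TRUE) {
  src <- int_seq(source)
  best <- diag_best_matches(src, int_seq(subject), window_length)
  if (both_strands) {
    rc <- reverse_complement(subject)
    best <- pmax(best, diag_best_matches(src, int_seq(rc), window_length))
  }
  100 * best / min(window_length, length(src))
}

#' Best sliding identity of a trigger window against paralogs
#'
#' For each paralog, the window sequence is slid without gaps over the
#' paralog (and, by default, over its reverse complement, since hairpin
#' RNAi silences through both strands); the best placement's identity is
#' reported.  The denominator is always the window length, so a paralog
#' shorter than the window cannot reach 100%.
#'
#' @param window_sequence A single DNA string (the candidate trigger).
#' @param paralogs A data frame with `id` and `sequence` columns, or a named
#'   character vector of sequences.  May be empty.
#' @param both_strands Also scan the paralog's reverse complement
#'   (default `TRUE`).
#' @return A tibble with columns `gene_id` and `identity_pct`, one row per
#'   paralog (zero rows for an empty paralog set).
#' @export
paralog_identity_scan <- function(window_sequence, paralogs,
                                  both_strands = TRUE) {
  check_dna(window_sequence, "window_sequence")
  if (is.character(paralogs)) {
    paralogs <- tibble(id = names(paralogs) %||% paste0("paralog_", seq_along(paralogs)),
                       sequence = unname(paralogs))
  }
  if (nrow(paralogs) == 0) {
    return(tibble(gene_id = character(), identity_pct = numeric()))
  }
  check_dna(paralogs$sequence, "paralogs$sequence")
  ident <- purrr::map_dbl(paralogs$sequence, function(p) {
    window_best_identity(window_sequence, p, nchar(window_sequence),
                         both_strands = both_strands)[1]
  })
  tibble(gene_id = paralogs$id, identity_pct = ident)
}
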