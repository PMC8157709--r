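#' Alignment scoring scheme
#'
#' Affine-gap scoring used for global alignment.  A gap run of length L
#' scores `gap_open + L * gap_extend` (both negative).  Defaults are
#' megablast-style weights; `N` scores as a mismatch against every base,
#' including another `N`.
#'
#' @param match Match score (positive).
#' @param mismatch Mismatch score (negative).
#' @param gap_open Penalty charged once per gap run (negative).
#' @param gap_extend Penalty charged per gapped position (negative).
#' @return A list of class `"align_scoring"`.
#' @export
align_scoring <- function(match = 2, mismatch = -3, gap_open = -5, gap_extend = -2) {
  if (match <= 0 || mismatch >= 0 || gap_open > 0 || gap_extend >= 0) {
    abort("Scoring must have match > 0, mismatch < 0, gap_open <= 0, gap_extend < 0.")
  }
  structure(
    list(match = match, mismatch = mismatch,
         gap_open = gap_open, gap_extend = gap_extend),
    class = "align_scoring"
  )
}

substitution_matrix <- function(scoring) {
  bases <- c("A", "C", "G", "T", "N")
  mat <- matrix(scoring$mismatch, 5, 5, dimnames = list(bases, bases))
  diag(mat) <- scoring$match
  mat["N", "N"] <- scoring$mismatch  # N never matches, not even N vs N
  mat
}

#' Optimal global alignment of two DNA sequences
#'
#' Needleman-Wunsch global alignment with affine gap costs (delegated to
#' the `Biostrings` alignment engine).  Deterministic: the same inputs
#' always give the same alignment.
#'
#' @param a,b Single DNA strings over `A`, `C`, `G`, `T`, `N`.
#' @param scoring An [align_scoring()] scheme.
#' @return An object of class `"pairwise_alignment"`: a list with gapped
#'   strings `aligned_a` / `aligned_b`, the optimal `score`, the default
#'   `identity_pct` (terminal gaps excluded, see [percent_identity()]) and
#'   `aligned_columns`.
#' @examples
#' aln <- align_pair("ACGTACGT", "ACGAACGT")
#' aln$identity_pct
#' @export
align_pair <- function(a, b, scoring = align_scoring()) {
  if (length(a) != 1 || length(b) != 1 || is.na(a) || is.na(b) ||
      nchar(a) == 0 || nchar(b) == 0) {
    abort("`a` and `b` must be single non-empty DNA strings.")
  }
  check_dna(a, "a"); check_dna(b, "b")
  fit <- Biostrings::pairwiseAlignment(
    a, b,
    substitutionMatrix = substitution_matrix(scoring),
    gapOpening = -scoring$gap_open,
    gapExtension = -scoring$gap_extend,
    type = "global"
  )
  aligned_a <- as.character(Biostrings::alignedPattern(fit))
  aligned_b <- as.character(Biostrings::alignedSubject(fit))
  out <- structure(
    list(
      aligned_a = unname(aligned_a),
      aligned_b = unname(aligned_b),
      score = Biostrings::score(fit),
      aligned_columns = nchar(aligned_a)[[1]],
      scoring = scoring
    ),
    class = "pairwise_alignment"
  )
  out$identity_pct <- percent_identity(out)
  out
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Global pairwise alignment\n")
  cat(sprintf("  score: %.1f  columns: %d  identity: %.1f%%\n",
              x$score, x$aligned_columns, x$identity_pct))
  wrap <- function(s) substr(s, 1, min(60, nchar(s)))
  cat("  ", wrap(x$aligned_a), if (nchar(x$aligned_a) > 60) "..." else "", "\n", sep = "")
  cat("  ", wrap(x$aligned_b), if (nchar(x$aligned_b) > 60) "..." else "", "\n", sep = "")
  invisible(x)
}

#' @method glance pairwise_alignment
#' @export
glance.pairwise_alignment <- function(x, ...) {
  tibble(score = x$score, identity_pct = x$identity_pct,
         aligned_columns = x$aligned_columns)
}

alignment_chars <- function(alignment) {
  list(
    a = strsplit(alignment$aligned_a, "", fixed = TRUE)[[1]],
    b = strsplit(alignment$aligned_b, "", fixed = TRUE)[[1]]
  )
}

column_matches <- function(ca, cb) {
  real <- ca != "-" & cb != "-" & ca != "N" & cb != "N"
  ca == cb & real
}

#' Percent identity of a pairwise alignment
#'
#' Identical columns divided by a mode-dependent denominator, times 100.
#' A column counts as identical only when both bases are real (no gap, no
#' `N`) and equal.
#'
#' @param alignment A `"pairwise_alignment"` from [align_pair()].
#' @param mode Denominator choice: `"exclude_terminal_gaps"` (default) drops
#'   leading/trailing gap columns before counting; `"all_columns"` uses the
#'   full alignment length; `"shorter_sequence"` divides by the shorter
#'   ungapped input length.
#' @return Percent identity in `[0, 100]`.
#' @export
percent_identity <- function(alignment,
                             mode = c("exclude_terminal_gaps", "all_columns",
                                      "shorter_sequence")) {
  mode <- match.arg(mode)
  stopifnot(inherits(alignment, "pairwise_alignment"))
  ch <- alignment_chars(alignment)
  m <- column_matches(ch$a, ch$b)
  n_col <- length(m)
  denom <- switch(mode,
    all_columns = n_col,
    shorter_sequence = min(sum(ch$a != "-"), sum(ch$b != "-")),
    exclude_terminal_gaps = {
      gap <- ch$a == "-" | ch$b == "-"
      keep <- rep(TRUE, n_col)
      i <- 1L
      while (i <= n_col && gap[i]) { keep[i] <- FALSE; i <- i + 1L }
      j <- n_col
      while (j >= 1L && gap[j]) { keep[j] <- FALSE; j <- j - 1L }
      m <- m & keep
      sum(keep)
    }
  )
  if (denom == 0) abort("Zero denominator for percent identity.")
  100 * sum(m) / denom
}

#' Sliding-window identity profile along an alignment
#'
#' For each window start on the ungapped first sequence (step `step`
#' apart), the identity over the alignment columns that the window spans.
#' With a gap-free alignment this is exactly matches / window_length.
#'
#' @param alignment A `"pairwise_alignment"` from [align_pair()].
#' @param window_length Window size in nucleotides on sequence `a`.
#' @param step Step between window starts (nt).
#' @return A tibble of class `"identity_profile"` with columns `start`,
#'   `end` (1-based, inclusive, on ungapped `a`) and `identity_pct`.
#' @export
windowed_identity <- function(alignment, window_length, step = 1L) {
  stopifnot(inherits(alignment, "pairwise_alignment"))
  window_length <- as.integer(window_length); step <- as.integer(step)
  if (window_length < 1 || step < 1) abort("window_length and step must be >= 1.")
  ch <- alignment_chars(alignment)
  colmap <- which(ch$a != "-")
  len_a <- length(colmap)
  if (window_length > len_a) {
    abort(sprintf("window_length (%d) exceeds ungapped sequence length (%d).",
                  window_length, len_a))
  }
  m <- column_matches(ch$a, ch$b)
  pre <- c(0, cumsum(m))
  starts <- seq.int(1L, len_a - window_length + 1L, by = step)
  c1 <- colmap[starts]
  c2 <- colmap[starts + window_length - 1L]
  ident <- 100 * (pre[c2 + 1L] - pre[c1]) / (c2 - c1 + 1L)
  out <- tibble(start = starts, end = starts + window_length - 1L,
                identity_pct = ident)
  class(out) <- c("identity_profile", class(out))
  attr(out, "window_length") <- window_length
  out
}

#' Plot an identity profile
#'
#' @param object An `"identity_profile"` from [windowed_identity()] or
#'   [homoeolog_window_profile()].
#' @param ... Ignored.
#' @return A ggplot object: window start versus percent identity.
#' @method autoplot identity_profile
#' @export
autoplot.identity_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$start, y = .data$identity_pct)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(
      x = "Window start (nt)", y = "Identity (%)",
      title = sprintf("Sliding-window identity (window = %s nt)",
                      attr(object, "window_length") %||% "?")
    ) +
    ggplot2::ylim(0, 100)
}
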