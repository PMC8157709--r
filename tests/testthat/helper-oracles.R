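# Independent reference implementations ("oracles") used to cross-check the
# package.  They are deliberately written in the most literal way possible
# (plain loops, character comparisons), trading speed for obviousness.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force global affine-gap alignment score (Gotoh three-state DP).
# A gap run of length L costs open + L * ext; N mismatches everything.
score_pair_dp <- function(a, b, match = 2, mismatch = -3, open = 5, ext = 2) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A)
  m <- length(B)
  sub <- function(x, y) if (x == y && x != "N") match else mismatch
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + ext * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + ext * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      M[i + 1, j + 1] <- sub(A[i], B[j]) + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                             X[i, j + 1] - ext,
                             Y[i, j + 1] - open - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                             Y[i + 1, j] - ext,
                             X[i + 1, j] - open - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Naive all-substrings off-target oracle: for every transcript, strand and
# ungapped offset, find maximal runs of matching characters of length >= k.
# Coordinates are 1-based inclusive, trigger coordinates in the trigger's
# own (sense) orientation, matching scan_offtargets().
naive_offtarget_scan <- function(trigger, transcripts, k, strands = "both") {
  strand_set <- if (strands == "both") c("sense", "antisense") else "sense"
  res <- list()
  for (r in seq_len(nrow(transcripts))) {
    tid <- transcripts$id[r]
    tc <- strsplit(transcripts$sequence[r], "", fixed = TRUE)[[1]]
    Lt <- length(tc)
    for (strand in strand_set) {
      q <- if (strand == "sense") trigger else reverse_complement(trigger)
      qc <- strsplit(q, "", fixed = TRUE)[[1]]
      Lq <- length(qc)
      for (d in (1L - Lq):(Lt - 1L)) {
        i1 <- max(1L, 1L - d)
        i2 <- min(Lq, Lt - d)
        if (i2 - i1 + 1L < k) next
        qi <- qc[i1:i2]
        ti <- tc[(i1:i2) + d]
        eq <- qi == ti & qi != "N" & ti != "N"
        rl <- rle(eq)
        ends <- cumsum(rl$lengths)
        starts <- ends - rl$lengths + 1L
        for (ri in which(rl$values & rl$lengths >= k)) {
          qs <- i1 + starts[ri] - 1L
          qe <- i1 + ends[ri] - 1L
          trig_s <- qs
          trig_e <- qe
          if (strand == "antisense") {
            trig_s <- Lq - qe + 1L
            trig_e <- Lq - qs + 1L
          }
          res[[length(res) + 1L]] <- tibble::tibble(
            transcript_id = tid,
            trigger_start = trig_s, trigger_end = trig_e,
            transcript_start = qs + d, transcript_end = qe + d,
            strand = strand, match_length_nt = qe - qs + 1L
          )
        }
      }
    }
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble::tibble(
      transcript_id = character(),
      trigger_start = integer(), trigger_end = integer(),
      transcript_start = integer(), transcript_end = integer(),
      strand = character(), match_length_nt = integer()
    ))
  }
  dplyr::arrange(out, transcript_id, transcript_start, strand, trigger_start)
}

# Naive best ungapped placement identity (%) of one window against a
# subject sequence, optionally also against its reverse complement.
# Denominator is min(window length, source length) as in the package.
naive_window_best <- function(window, subject, both_strands = TRUE) {
  wc <- strsplit(window, "", fixed = TRUE)[[1]]
  w <- length(wc)
  one_strand <- function(s) {
    sc <- strsplit(s, "", fixed = TRUE)[[1]]
    Ls <- length(sc)
    best <- 0L
    for (d in (1L - w):(Ls - 1L)) {
      i1 <- max(1L, 1L - d)
      i2 <- min(w, Ls - d)
      if (i2 < i1) next
      wi <- wc[i1:i2]
      si <- sc[(i1:i2) + d]
      best <- max(best, sum(wi == si & wi != "N" & si != "N"))
    }
    best
  }
  best <- one_strand(subject)
  if (both_strands) best <- max(best, one_strand(reverse_complement(subject)))
  100 * best / w
}

# Exhaustive trigger-window oracle for equal-length, substitution-only
# homoeolog pairs: window identity is plain positional agreement, the
# paralog constraint is checked with naive_window_best(), and the best
# valid window (max S/T identity, leftmost tie) is returned.
oracle_design <- function(s, t, paralog_seqs, window_length,
                          min_st_identity, max_paralog_identity) {
  stopifnot(nchar(s) == nchar(t))
  sc <- strsplit(s, "", fixed = TRUE)[[1]]
  tc <- strsplit(t, "", fixed = TRUE)[[1]]
  eq <- sc == tc & sc != "N" & tc != "N"
  n_starts <- length(sc) - window_length + 1L
  best_start <- NA_integer_
  best_ident <- -Inf
  for (p in seq_len(n_starts)) {
    ident <- 100 * sum(eq[p:(p + window_length - 1L)]) / window_length
    if (ident < min_st_identity) next
    win <- substr(s, p, p + window_length - 1L)
    par_ok <- all(vapply(
      paralog_seqs,
      function(ps) naive_window_best(win, ps) < max_paralog_identity,
      logical(1)
    ))
    if (!par_ok) next
    if (ident > best_ident) {
      best_ident <- ident
      best_start <- p
    }
  }
  list(start = best_start, identity_pct = best_ident)
}
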