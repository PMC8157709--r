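bg_table <- function(n, len, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    id = sprintf("bg_%03d", seq_len(n)),
    subgenome = "none", annotation_class = "other",
    length_nt = len,
    sequence = replicate(n, rand_dna(len))
  ))
}

test_that("kmer_index counts positions and skips N words", {
  tx <- tibble::tibble(id = "t1", sequence = strrep("A", 30))
  idx <- kmer_index(tx, k = 22)
  expect_equal(nrow(idx$table), 9)   # 30 - 22 + 1
  expect_equal(idx$table$position, 1:9)
  expect_equal(unique(idx$table$kmer), strrep("A", 22))

  tx_n <- tibble::tibble(id = "t1",
                         sequence = paste0(strrep("A", 10), "N", strrep("A", 10)))
  idx_n <- kmer_index(tx_n, k = 10)
  # every 10-mer covering the N is dropped: only positions 1 and 12 remain
  expect_equal(idx_n$table$position, c(1, 12))
  expect_error(kmer_index(tx, k = 7), ">= 8")
  expect_output(print(idx), "k-mer index")
})

test_that("a planted sense match is found with exact coordinates", {
  set.seed(31)
  tx <- bg_table(3, 200, seed = 131)
  trig <- rand_dna(60)
  planted <- plant_offtarget(tx, trig, match_length = 25, seed = 7,
                             strand = "sense", boundary_mismatch = TRUE)
  hits <- scan_offtargets(c(trig1 = trig), planted$transcripts, k = 22)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$transcript_id, planted$planting$transcript_id)
  expect_equal(hits$transcript_start, planted$planting$transcript_start)
  expect_equal(hits$transcript_end, planted$planting$transcript_end)
  expect_equal(hits$trigger_start, planted$planting$trigger_start)
  expect_equal(hits$trigger_end, planted$planting$trigger_end)
  expect_equal(hits$strand, "sense")
  expect_equal(hits$match_length_nt, 25L)
})

test_that("a planted antisense match is mapped back to trigger orientation", {
  set.seed(32)
  tx <- bg_table(3, 200, seed = 132)
  trig <- rand_dna(60)
  planted <- plant_offtarget(tx, trig, match_length = 24, seed = 9,
                             strand = "antisense", boundary_mismatch = TRUE)
  hits <- scan_offtargets(c(trig1 = trig), planted$transcripts, k = 22)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$strand, "antisense")
  expect_equal(hits$trigger_start, planted$planting$trigger_start)
  expect_equal(hits$trigger_end, planted$planting$trigger_end)
  expect_equal(hits$transcript_start, planted$planting$transcript_start)
  expect_equal(hits$match_length_nt, 24L)
  # the reported trigger substring reverse-complements onto the transcript
  t_sub <- substr(trig, hits$trigger_start, hits$trigger_end)
  x_sub <- substr(
    planted$transcripts$sequence[planted$transcripts$id == hits$transcript_id],
    hits$transcript_start, hits$transcript_end
  )
  expect_equal(reverse_complement(t_sub), x_sub)
})

test_that("21-nt plantings sit exactly below the k = 22 boundary", {
  set.seed(33)
  tx <- bg_table(3, 200, seed = 133)
  trig <- rand_dna(60)
  planted <- plant_offtarget(tx, trig, match_length = 21, seed = 11,
                             boundary_mismatch = TRUE)
  expect_equal(nrow(scan_offtargets(c(t1 = trig), planted$transcripts, k = 22)), 0)
  at21 <- scan_offtargets(c(t1 = trig), planted$transcripts, k = 21)
  expect_equal(nrow(at21), 1)
  expect_equal(at21$match_length_nt, 21L)
})

test_that("exclusions remove self-targets as vector or per-trigger pairs", {
  set.seed(34)
  tx <- bg_table(2, 150, seed = 134)
  trig <- substr(tx$sequence[1], 40, 80)  # exact 41-nt self match
  hits <- scan_offtargets(c(t1 = trig), tx, k = 22)
  expect_equal(hits$transcript_id, "bg_001")
  expect_equal(hits$match_length_nt, 41L)
  expect_equal(nrow(scan_offtargets(c(t1 = trig), tx, k = 22,
                                    exclude = "bg_001")), 0)
  excl <- tibble::tibble(trigger_id = "t1", transcript_id = "bg_001")
  expect_equal(nrow(scan_offtargets(c(t1 = trig), tx, k = 22, exclude = excl)), 0)
  # an exclusion for a different trigger does not apply
  excl2 <- tibble::tibble(trigger_id = "other", transcript_id = "bg_001")
  expect_equal(nrow(scan_offtargets(c(t1 = trig), tx, k = 22, exclude = excl2)), 1)
})

test_that("scanner agrees with the naive all-substrings oracle", {
  set.seed(35)
  for (i in 1:30) {
    tx <- tibble::tibble(
      id = c("x1", "x2"),
      sequence = c(rand_dna(150), rand_dna(150)),
      length_nt = 150
    )
    trig <- rand_dna(50)
    if (i %% 3 == 0) {
      # plant a match (sense or antisense, 20-40 nt) to exercise positives
      planted <- plant_offtarget(
        dplyr::mutate(tx, id = sub("x", "bg_00", id)), trig,
        match_length = sample(20:40, 1), seed = i
      )
      tx <- dplyr::mutate(planted$transcripts, id = sub("bg_00", "x", id))
    }
    got <- scan_offtargets(c(q = trig), tx, k = 22) |>
      dplyr::arrange(transcript_id, transcript_start, strand, trigger_start) |>
      dplyr::select(-trigger_id)
    want <- naive_offtarget_scan(trig, tx, k = 22)
    expect_equal(as.data.frame(got),
                 as.data.frame(want[, names(got)]),
                 info = paste("instance", i))
  }
})

test_that("scanning the reverse complement mirrors strands", {
  set.seed(36)
  tx <- bg_table(2, 150, seed = 136)
  trig <- substr(tx$sequence[2], 10, 45)
  fwd <- scan_offtargets(c(q = trig), tx, k = 22)
  rev <- scan_offtargets(c(q = reverse_complement(trig)), tx, k = 22)
  expect_equal(nrow(fwd), nrow(rev))
  expect_equal(sort(fwd$transcript_start), sort(rev$transcript_start))
  expect_equal(sum(fwd$strand == "sense"), sum(rev$strand == "antisense"))
})

test_that("scanner validates inputs and honours a prebuilt index", {
  tx <- bg_table(1, 100, seed = 137)
  expect_error(scan_offtargets(c(q = "ACGT"), tx, k = 22), "at least k")
  idx <- kmer_index(tx, k = 22)
  expect_error(scan_offtargets(c(q = rand_dna(30)), tx, k = 25, index = idx),
               "different k")
  trig <- substr(tx$sequence[1], 1, 30)
  with_idx <- scan_offtargets(c(q = trig), tx, k = 22, index = idx)
  without <- scan_offtargets(c(q = trig), tx, k = 22)
  expect_equal(with_idx, without)
})

test_that("classify_triggers splits clean from at-risk triggers", {
  set.seed(38)
  tx <- bg_table(4, 200, seed = 138)
  trigs <- setNames(replicate(5, rand_dna(60)), paste0("tr", 1:5))
  planted <- plant_offtarget(tx, trigs[["tr3"]], match_length = 30, seed = 3)
  hits <- scan_offtargets(trigs, planted$transcripts, k = 22)
  verd <- classify_triggers(trigs, hits)
  expect_equal(nrow(verd), 5)
  expect_equal(verd$verdict[verd$trigger_id == "tr3"], "off_target_risk")
  expect_equal(sum(verd$verdict == "clean"), 4)
  expect_equal(verd$n_hits[verd$trigger_id != "tr3"], rep(0L, 4))
  expect_equal(verd$n_transcripts[verd$trigger_id == "tr3"], 1L)
})
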