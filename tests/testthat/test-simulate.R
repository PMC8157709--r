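test_that("sim_config validates its knobs", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(st_identity_target = 0), "st_identity_target")
  expect_error(sim_config(st_identity_target = 1.2), "st_identity_target")
  expect_error(sim_config(paralog_identity_range = c(0.8, 0.5)), "ordered pair")
  expect_error(sim_config(transcript_length_range = c(0, 10)), "min >= 1")
  expect_error(sim_config(enriched_fraction = 1.5), "Fractions")
  expect_error(sim_config(n_lines_per_construct = 1), "at least 2 lines")
  bad_eff <- default_effect_table(4)
  bad_eff$secondary_mult[1] <- -0.1
  expect_error(sim_config(n_target_pairs = 4, effect_table = bad_eff), ">= 0")
  # a zero multiplier (complete suppression) is a legal effect
  zero_eff <- default_effect_table(4, n_effective = 1, effective_mult = 0)
  expect_s3_class(sim_config(n_target_pairs = 4, effect_table = zero_eff),
                  "sim_config")
})

test_that("simulation is deterministic in the seed", {
  cfg <- sim_config(seed = 99, n_target_pairs = 3, n_background = 8,
                    transcript_length_range = c(300, 500))
  a <- simulate_transcriptome(cfg)
  b <- simulate_transcriptome(cfg)
  expect_identical(a$transcripts, b$transcripts)
  expect_identical(simulate_expression(a), simulate_expression(b))
  expect_identical(simulate_phenotypes(cfg), simulate_phenotypes(cfg))
  other <- simulate_transcriptome(sim_config(seed = 100, n_target_pairs = 3,
                                             n_background = 8,
                                             transcript_length_range = c(300, 500)))
  expect_false(identical(a$transcripts$sequence, other$transcripts$sequence))
})

test_that("homoeolog divergence realizes the configured identity exactly", {
  cfg <- sim_config(seed = 3, n_target_pairs = 4, n_background = 0,
                    n_paralogs_per_family = 2,
                    transcript_length_range = c(400, 700))
  tx <- simulate_transcriptome(cfg)
  expect_equal(nrow(tx$families), 4)
  seq_of <- setNames(tx$transcripts$sequence, tx$transcripts$id)
  for (i in seq_len(nrow(tx$families))) {
    s <- seq_of[[tx$families$s_id[i]]]
    t <- seq_of[[tx$families$t_id[i]]]
    L <- nchar(s)
    expect_equal(nchar(t), L)
    mismatches <- sum(strsplit(s, "")[[1]] != strsplit(t, "")[[1]])
    expect_equal(mismatches, round((1 - cfg$st_identity_target) * L))
    expect_equal(tx$families$st_identity_realized[i], 1 - mismatches / L)
    # with substitutions only, alignment identity equals the recorded truth
    expect_equal(align_pair(s, t)$identity_pct,
                 100 * tx$families$st_identity_realized[i])
  }
  # paralog identities fall in the configured range (up to rounding of sites)
  for (i in seq_len(nrow(tx$paralogs))) {
    L <- nchar(seq_of[[tx$paralogs$paralog_id[i]]])
    expect_gte(tx$paralogs$identity_to_s[i],
               cfg$paralog_identity_range[1] - 1 / L)
    expect_lte(tx$paralogs$identity_to_s[i],
               cfg$paralog_identity_range[2] + 1 / L)
  }
  # identity 1 means byte-identical copies
  tx_id <- simulate_transcriptome(sim_config(seed = 3, n_target_pairs = 2,
                                             n_background = 0,
                                             st_identity_target = 1))
  seq_of2 <- setNames(tx_id$transcripts$sequence, tx_id$transcripts$id)
  expect_equal(seq_of2[[tx_id$families$s_id[1]]],
               seq_of2[[tx_id$families$t_id[1]]])
})

test_that("expression simulation is consistent with its own counts and truth", {
  cfg <- sim_config(seed = 8, n_target_pairs = 6, n_background = 30,
                    nd_probability = 0, contaminant_fraction = 0.1,
                    transcript_length_range = c(400, 800))
  sim <- simulate_expression(simulate_transcriptome(cfg), cfg)
  expr <- sim$expression
  # RPKM columns recompute exactly from counts and library sizes
  expect_equal(expr$ea, compute_rpkm(expr$ea_count, expr$length_nt, expr$ea_total))
  expect_equal(expr$ve, compute_rpkm(expr$ve_count, expr$length_nt, expr$ve_total))
  # planted genes clear a 10-fold screen by construction
  planted <- sim$truth[sim$truth$true_tissue != "none", ]
  expect_gt(nrow(planted), 0)
  rows <- expr[match(planted$gene_id, expr$gene_id), ]
  tis <- ifelse(planted$true_tissue == "EA", rows$ea, rows$ve)
  expect_true(all(fold_enrichment(tis, rows$control) >= 10))
  # contaminants exist and are all shorter than the 200-nt filter
  contam <- expr[grepl("^contam_", expr$gene_id), ]
  expect_gt(nrow(contam), 0)
  expect_true(all(contam$length_nt < 200))
  # nd_probability = 1 blanks every cell
  cfg_nd <- sim_config(seed = 8, n_target_pairs = 2, n_background = 5,
                       nd_probability = 1, contaminant_fraction = 0)
  expr_nd <- simulate_expression(simulate_transcriptome(cfg_nd), cfg_nd)$expression
  expect_true(all(is.na(expr_nd$ea) & is.na(expr_nd$ve) & is.na(expr_nd$control)))
})

test_that("noise generators honour their degenerate limits", {
  rnbinom2 <- suckerscreen:::rnbinom2
  rlnorm_cv <- suckerscreen:::rlnorm_cv
  set.seed(51)
  expect_equal(rnbinom2(5, rep(0, 5), 0.2), rep(0L, 5))
  expect_equal(rlnorm_cv(5, rep(0, 5), 0.2), rep(0, 5))
  expect_equal(rlnorm_cv(4, c(3, 7, 0, 1), 0), c(3, 7, 0, 1))
  # mean-preserving: sample mean approaches mu
  x <- rlnorm_cv(20000, rep(10, 20000), 0.3)
  expect_equal(mean(x), 10, tolerance = 0.05)
  y <- rnbinom2(20000, rep(10, 20000), 0.3)
  expect_equal(mean(y), 10, tolerance = 0.05)
  expect_equal(var(y), 10 + (0.3 * 10)^2, tolerance = 0.15)
})

test_that("phenotype simulation has the advertised shape and planted effects", {
  cfg <- sim_config(seed = 13, n_target_pairs = 6, n_background = 0,
                    effect_table = default_effect_table(6, n_effective = 2,
                                                        effective_mult = 0.1),
                    n_lines_per_construct = 3, n_plants_per_line = 10)
  ph <- simulate_phenotypes(cfg)
  expect_equal(nrow(ph), 6 * 3 * 2 * 10 * 6)  # constructs x lines x genotypes x plants x traits
  expect_named(ph, c("construct_id", "line_id", "genotype", "plant_id",
                     "trait", "value"))
  r <- summarize_constructs(relative_effects(ph))
  sec <- r[r$trait == "secondary_n", ]
  eff_ids <- cfg$effect_table$construct_id[cfg$effect_table$secondary_mult < 1]
  expect_true(all(sec$mean[sec$construct_id %in% eff_ids] < 0.3))
  expect_true(all(abs(sec$mean[!sec$construct_id %in% eff_ids] - 1) < 0.3))
  # a zero multiplier yields exactly zero transgenic secondary values
  cfg0 <- sim_config(seed = 13, n_target_pairs = 2, n_background = 0,
                     effect_table = default_effect_table(2, 1, 0))
  ph0 <- simulate_phenotypes(cfg0)
  z <- ph0[ph0$construct_id == "fam_01" & ph0$genotype == "transgenic" &
             grepl("^secondary", ph0$trait), ]
  expect_true(all(z$value == 0))
})

test_that("plant_offtarget inserts exactly the recorded substring", {
  set.seed(61)
  tx <- tibble::tibble(
    id = sprintf("bg_%03d", 1:4), subgenome = "none",
    annotation_class = "other", length_nt = 300,
    sequence = replicate(4, rand_dna(300))
  )
  trig <- rand_dna(80)
  for (strand in c("sense", "antisense")) {
    planted <- plant_offtarget(tx, trig, match_length = 30, seed = 2,
                               strand = strand)
    p <- planted$planting
    expect_equal(p$strand, strand)
    ins <- substr(trig, p$trigger_start, p$trigger_end)
    if (strand == "antisense") ins <- reverse_complement(ins)
    got <- substr(planted$transcripts$sequence[planted$transcripts$id == p$transcript_id],
                  p$transcript_start, p$transcript_end)
    expect_equal(got, ins)
  }
  expect_error(plant_offtarget(tx, trig, match_length = 81), "exceeds")
  short <- dplyr::mutate(tx, sequence = substr(sequence, 1, 20), length_nt = 20)
  expect_error(plant_offtarget(short, trig, match_length = 30),
               "No transcript long enough")
})
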