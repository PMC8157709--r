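#' Construct-effect table for phenotype simulation
#'
#' One row per RNAi construct with multiplicative effects on primary,
#' secondary and tertiary lateral shoots.  The default mirrors the study
#' outcome scale: five effective constructs whose secondary and tertiary
#' shoots are reduced to `effective_mult` of the control, and the rest
#' with no effect; primaries are never affected.
#'
#' @param n_constructs Number of constructs (default 36).
#' @param n_effective Number of effective constructs, taken from the head
#'   of the list (default 5).
#' @param effective_mult Multiplier applied to secondary/tertiary shoots of
#'   effective constructs (default 0.1).
#' @return A tibble: `construct_id`, `primary_mult`, `secondary_mult`,
#'   `tertiary_mult`.
#' @export
default_effect_table <- function(n_constructs = 36, n_effective = 5,
                                 effective_mult = 0.1) {
  eff <- seq_len(n_constructs) <= n_effective
  tibble(
    construct_id = sprintf("fam_%02d", seq_len(n_constructs)),
    primary_mult = 1,
    secondary_mult = ifelse(eff, effective_mult, 1),
    tertiary_mult = ifelse(eff, effective_mult, 1)
  )
}

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic allotetraploid study:
#' transcriptome structure, expression table and phenotype trial.  One
#' master `seed` drives everything; each stage derives its own sub-stream
#' (see Details), so stages are independently reproducible and the same
#' configuration always yields bit-identical output.
#'
#' @details Stage seeds are `(seed + 1009 * stage_index) mod (2^31 - 1)`
#'   with stage indices 1 (transcriptome), 2 (expression), 3 (phenotypes),
#'   4 (off-target planting).
#'
#' @param seed Master seed (integer).
#' @param n_target_pairs Number of homoeolog (S/T) target families.
#' @param n_background Number of unrelated background transcripts.
#' @param st_identity_target Intended S/T nucleotide identity, in (0, 1]
#'   (default 0.954, the study-scale average for trigger regions).
#' @param paralog_identity_range Identity range (fractions) for same-family
#'   paralogs, below the 0.70 discrimination cap by default.
#' @param n_paralogs_per_family Paralogs generated per family (default 2).
#' @param transcript_length_range Transcript length range in nt.
#' @param enriched_fraction Fraction of eligible genes planted as
#'   EA/VE-enriched in the expression table.
#' @param fold_distribution `list(mean, sd)` of the log fold for enriched
#'   genes; realized folds are floored at 10 so planted enrichment always
#'   clears a 10-fold screen.
#' @param nd_probability Per-cell probability of a "not detectable" entry.
#' @param contaminant_fraction Fraction of extra short-contig rows
#'   (< 200 nt) added to the expression table.
#' @param effect_table Construct effect table, see [default_effect_table()].
#' @param n_lines_per_construct Independent single-locus lines per
#'   construct (default 3, as in the emulated trial design).
#' @param n_plants_per_line Plants per line and genotype class.
#' @param noise_cv Coefficient of variation of phenotype noise: extra-
#'   Poisson dispersion for shoot counts, log-normal CV for weights.
#' @param indel_rate Per-site indel probability in homoeolog divergence
#'   (default 0: substitutions only, keeping identities exact).
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_target_pairs = 36L,
                       n_background = 100L,
                       st_identity_target = 0.954,
                       paralog_identity_range = c(0.50, 0.68),
                       n_paralogs_per_family = 2L,
                       transcript_length_range = c(500L, 2000L),
                       enriched_fraction = 0.1,
                       fold_distribution = list(mean = log(20), sd = 0.5),
                       nd_probability = 0.1,
                       contaminant_fraction = 0.05,
                       effect_table = default_effect_table(n_target_pairs),
                       n_lines_per_construct = 3L,
                       n_plants_per_line = 10L,
                       noise_cv = 0.1,
                       indel_rate = 0) {
  frac_ok <- function(x) all(x >= 0 & x <= 1)
  if (!frac_ok(st_identity_target) || st_identity_target <= 0) {
    abort("`st_identity_target` must be in (0, 1].")
  }
  if (length(paralog_identity_range) != 2 ||
      paralog_identity_range[1] > paralog_identity_range[2] ||
      !frac_ok(paralog_identity_range)) {
    abort("`paralog_identity_range` must be an ordered pair of fractions.")
  }
  if (length(transcript_length_range) != 2 ||
      transcript_length_range[1] > transcript_length_range[2] ||
      transcript_length_range[1] < 1) {
    abort("`transcript_length_range` must be an ordered pair with min >= 1.")
  }
  if (!frac_ok(c(enriched_fraction, nd_probability, contaminant_fraction))) {
    abort("Fractions must lie in [0, 1].")
  }
  if (any(c(effect_table$primary_mult, effect_table$secondary_mult,
            effect_table$tertiary_mult) < 0)) {
    abort("Effect multipliers must be >= 0.")
  }
  if (n_lines_per_construct < 2 || n_plants_per_line < 2) {
    abort("Need at least 2 lines per construct and 2 plants per line.")
  }
  structure(
    list(
      seed = as.integer(seed),
      n_target_pairs = as.integer(n_target_pairs),
      n_background = as.integer(n_background),
      st_identity_target = st_identity_target,
      paralog_identity_range = paralog_identity_range,
      n_paralogs_per_family = as.integer(n_paralogs_per_family),
      transcript_length_range = as.integer(transcript_length_range),
      enriched_fraction = enriched_fraction,
      fold_distribution = fold_distribution,
      nd_probability = nd_probability,
      contaminant_fraction = contaminant_fraction,
      effect_table = as_tibble(effect_table),
      n_lines_per_construct = as.integer(n_lines_per_construct),
      n_plants_per_line = as.integer(n_plants_per_line),
      noise_cv = noise_cv,
      indel_rate = indel_rate
    ),
    class = "sim_config"
  )
}

stage_seed <- function(config, stage) {
  idx <- match(stage, c("transcriptome", "expression", "phenotypes", "offtarget"))
  as.integer((as.numeric(config$seed) + 1009 * idx) %% 2147483647)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Substitute `n_sub` randomly chosen positions each to a uniformly chosen
# different base; returns the mutated string.
substitute_sites <- function(sequence, positions) {
  if (length(positions) == 0) return(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (p in positions) {
    chars[p] <- sample(setdiff(bases, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# Diverge an ancestor into two copies that differ at exactly
# round((1 - identity) * L) sites, each difference introduced on one
# branch at a distinct position, so the realized ungapped identity is
# controlled to within rounding.
diverge_pair <- function(ancestor, identity) {
  L <- nchar(ancestor)
  n_diff <- round((1 - identity) * L)
  pos <- sample.int(L, n_diff)
  branch <- sample(c(TRUE, FALSE), n_diff, replace = TRUE)
  list(
    a = substitute_sites(ancestor, pos[branch]),
    b = substitute_sites(ancestor, pos[!branch]),
    realized_identity = 1 - n_diff / L
  )
}

#' Simulate an allotetraploid transcriptome with known ground truth
#'
#' Generates, per target family, an ancestral sequence diverged into an
#' S-subgenome and a T-subgenome copy at the configured identity
#' (realized identity recorded exactly), plus same-family paralogs at
#' lower identity, plus unrelated background transcripts.  Mutations are
#' per-site substitutions, uniform over the three alternative bases, with
#' no indels by default, so recorded identities coincide with alignment
#' identities.
#'
#' @param config A [sim_config()].
#' @return A list of class `"sim_transcriptome"`: `transcripts` (tibble
#'   compatible with [write_transcript_fasta()]), `families` (`family_id`,
#'   `s_id`, `t_id`, `st_identity_realized`), `paralogs` (`family_id`,
#'   `paralog_id`, `identity_to_s`), and the `config`.
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(stage_seed(config, "transcriptome"), {
    lens <- config$transcript_length_range
    fam_ids <- sprintf("fam_%02d", seq_len(config$n_target_pairs))
    families <- vector("list", config$n_target_pairs)
    paralogs <- vector("list", config$n_target_pairs)
    tx <- list()
    for (i in seq_along(fam_ids)) {
      L <- sample(lens[1]:lens[2], 1)
      anc <- random_dna(L)
      pair <- diverge_pair(anc, config$st_identity_target)
      s_id <- paste0(fam_ids[i], "_S"); t_id <- paste0(fam_ids[i], "_T")
      tx[[length(tx) + 1]] <- tibble(
        id = c(s_id, t_id), subgenome = c("S", "T"),
        annotation_class = "transcription_factor",
        length_nt = nchar(c(pair$a, pair$b)), sequence = c(pair$a, pair$b)
      )
      families[[i]] <- tibble(
        family_id = fam_ids[i], s_id = s_id, t_id = t_id,
        st_identity_realized = pair$realized_identity
      )
      if (config$n_paralogs_per_family > 0) {
        par_rows <- purrr::map_dfr(seq_len(config$n_paralogs_per_family), function(j) {
          ident <- runif(1, config$paralog_identity_range[1],
                         config$paralog_identity_range[2])
          n_diff <- round((1 - ident) * L)
          p_seq <- substitute_sites(pair$a, sample.int(L, n_diff))
          p_id <- sprintf("%s_P%d", fam_ids[i], j)
          tx[[length(tx) + 1]] <<- tibble(
            id = p_id, subgenome = "none",
            annotation_class = "transcription_factor",
            length_nt = nchar(p_seq), sequence = p_seq
          )
          tibble(family_id = fam_ids[i], paralog_id = p_id,
                 identity_to_s = 1 - n_diff / L)
        })
        paralogs[[i]] <- par_rows
      }
    }
    bg_class <- sample(c("transcription_factor", "unknown", "other"),
                       config$n_background, replace = TRUE,
                       prob = c(0.1, 0.3, 0.6))
    for (i in seq_len(config$n_background)) {
      L <- sample(lens[1]:lens[2], 1)
      tx[[length(tx) + 1]] <- tibble(
        id = sprintf("bg_%03d", i), subgenome = "none",
        annotation_class = bg_class[i], length_nt = L, sequence = random_dna(L)
      )
    }
    structure(
      list(
        transcripts = dplyr::bind_rows(tx),
        families = dplyr::bind_rows(families),
        paralogs = {
          p <- dplyr::bind_rows(paralogs)
          if (nrow(p) == 0) {
            p <- tibble(family_id = character(), paralog_id = character(),
                        identity_to_s = numeric())
          }
          p
        },
        config = config
      ),
      class = "sim_transcriptome"
    )
  })
}

#' @export
print.sim_transcriptome <- function(x, ...) {
  cat(sprintf(
    "Synthetic transcriptome: %d families (S/T pairs), %d paralogs, %d background transcripts\n",
    nrow(x$families), nrow(x$paralogs), sum(grepl("^bg_", x$transcripts$id))
  ))
  invisible(x)
}

#' Simulate an axillary-meristem expression table with planted enrichment
#'
#' Assigns each transcript a control-zone RPKM, plants a configurable
#' fraction of eligible genes (length > 200 nt, transcription-factor or
#' unknown annotation) as EA- or VE-enriched with fold at least 10 *by
#' construction after count rounding*, adds short-contig contaminant rows,
#' and knocks individual cells to "not detectable" (`NA`) with the
#' configured probability.  Counts and library sizes are emitted so RPKM
#' can be recomputed exactly.
#'
#' @param transcriptome A `"sim_transcriptome"` from
#'   [simulate_transcriptome()].
#' @param config A [sim_config()]; defaults to the one inside
#'   `transcriptome`.
#' @return A list: `expression` (tibble with `gene_id`, `length_nt`,
#'   `annotation_class`, RPKM columns `ea`/`ve`/`control`, count columns
#'   and per-tissue totals) and `truth` (`gene_id`, `true_tissue`,
#'   `true_fold`).
#' @export
simulate_expression <- function(transcriptome, config = transcriptome$config) {
  stopifnot(inherits(transcriptome, "sim_transcriptome"))
  tx <- transcriptome$transcripts
  if (nrow(tx) == 0) abort("Empty transcriptome.")
  withr::with_seed(stage_seed(config, "expression"), {
    totals <- c(ea = 9e5, ve = 9e5, control = 9e5)  # study-scale library sizes
    n <- nrow(tx)
    eligible <- tx$length_nt > 200 &
      tx$annotation_class %in% c("transcription_factor", "unknown")
    n_enr <- round(config$enriched_fraction * n)
    enriched_ids <- if (n_enr > 0) {
      sample(tx$id[eligible], min(n_enr, sum(eligible)))
    } else character()
    tissue <- setNames(sample(c("EA", "VE"), length(enriched_ids), replace = TRUE),
                       enriched_ids)
    control_rpkm <- rlnorm(n, meanlog = log(5), sdlog = 1)
    bg_noise <- function() exp(rnorm(n, 0, 0.3))
    ea_rpkm <- control_rpkm * bg_noise()
    ve_rpkm <- control_rpkm * bg_noise()
    fold <- pmax(10, exp(rnorm(n, config$fold_distribution$mean,
                               config$fold_distribution$sd)))
    is_ea <- tx$id %in% enriched_ids[tissue[enriched_ids] == "EA"]
    is_ve <- tx$id %in% enriched_ids[tissue[enriched_ids] == "VE"]
    ea_rpkm[is_ea] <- control_rpkm[is_ea] * fold[is_ea]
    ve_rpkm[is_ve] <- control_rpkm[is_ve] * fold[is_ve]

    to_count <- function(rpkm, total) as.integer(round(rpkm * tx$length_nt * total / 1e9))
    ea_count <- to_count(ea_rpkm, totals["ea"])
    ve_count <- to_count(ve_rpkm, totals["ve"])
    control_count <- to_count(control_rpkm, totals["control"])
    # enforce the planted fold on the *recomputed* scale: tissue_count must
    # reach 10 x control_count x (tissue total / control total), and at
    # least 1 read so the gene is detectable
    need_ea <- pmax(1L, as.integer(ceiling(10 * control_count * totals["ea"] / totals["control"])))
    need_ve <- pmax(1L, as.integer(ceiling(10 * control_count * totals["ve"] / totals["control"])))
    ea_count[is_ea] <- pmax(ea_count[is_ea], need_ea[is_ea])
    ve_count[is_ve] <- pmax(ve_count[is_ve], need_ve[is_ve])

    expr <- tibble(
      gene_id = tx$id, length_nt = tx$length_nt,
      annotation_class = tx$annotation_class,
      ea_count = ea_count, ve_count = ve_count, control_count = control_count,
      ea_total = unname(totals["ea"]), ve_total = unname(totals["ve"]),
      control_total = unname(totals["control"])
    )

    # short-contig contaminants: strongly "enriched" assembly artifacts
    n_cont <- round(config$contaminant_fraction * n)
    if (n_cont > 0) {
      clen <- sample(50:199, n_cont, replace = TRUE)
      c_ctrl <- as.integer(round(rlnorm(n_cont, log(2), 0.5)))
      c_tis <- pmax(1L, as.integer(ceiling(20 * c_ctrl)))
      c_ea <- sample(c(TRUE, FALSE), n_cont, replace = TRUE)
      expr <- dplyr::bind_rows(expr, tibble(
        gene_id = sprintf("contam_%03d", seq_len(n_cont)),
        length_nt = clen, annotation_class = "unknown",
        ea_count = ifelse(c_ea, c_tis, c_ctrl),
        ve_count = ifelse(c_ea, c_ctrl, c_tis),
        control_count = c_ctrl,
        ea_total = unname(totals["ea"]), ve_total = unname(totals["ve"]),
        control_total = unname(totals["control"])
      ))
    }

    expr <- expr |>
      dplyr::mutate(
        ea = compute_rpkm(.data$ea_count, .data$length_nt, .data$ea_total),
        ve = compute_rpkm(.data$ve_count, .data$length_nt, .data$ve_total),
        control = compute_rpkm(.data$control_count, .data$length_nt,
                               .data$control_total)
      )
    if (config$nd_probability > 0) {
      for (col in c("ea", "ve", "control")) {
        nd <- runif(nrow(expr)) < config$nd_probability
        expr[[col]][nd] <- NA_real_
        expr[[paste0(col, "_count")]][nd] <- NA_integer_
      }
    }
    expr <- dplyr::relocate(expr, "gene_id", "length_nt", "annotation_class",
                            "ea", "ve", "control")
    truth <- tibble(gene_id = expr$gene_id) |>
      dplyr::mutate(
        true_tissue = dplyr::coalesce(unname(tissue[.data$gene_id]), "none"),
        true_fold = ifelse(.data$true_tissue == "none", 1,
                           fold[match(.data$gene_id, tx$id)])
      )
    list(expression = expr, truth = truth)
  })
}

rnbinom2 <- function(n, mu, cv) {
  # Counts with var = mu + (cv * mu)^2: negative binomial with extra-
  # Poisson dispersion cv; cv = 0 degenerates to Poisson.  mu = 0 gives 0.
  out <- integer(n)
  pos <- mu > 0
  if (any(pos)) {
    out[pos] <- if (cv > 0) {
      rnbinom(sum(pos), mu = mu[pos], size = 1 / cv^2)
    } else {
      rpois(sum(pos), mu[pos])
    }
  }
  out
}

rlnorm_cv <- function(n, mean, cv) {
  # Log-normal with expectation `mean` and coefficient of variation `cv`;
  # cv = 0 is deterministic and mean = 0 gives exactly 0.
  out <- numeric(n)
  pos <- mean > 0
  if (any(pos)) {
    if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      out[pos] <- rlnorm(sum(pos), log(mean[pos]) - sdlog^2 / 2, sdlog)
    } else {
      out[pos] <- mean[pos]
    }
  }
  out
}

phenotype_baselines <- function() {
  # Wild-type magnitudes on the scale of the emulated field trials:
  # ~20 primary shoots, ~10 secondary, a few tertiary; weights in grams.
  c(primary_n = 20, primary_wt = 35, secondary_n = 10, secondary_wt = 20,
    tertiary_n = 3, tertiary_wt = 5)
}

#' Simulate a greenhouse phenotype trial
#'
#' For every construct in the effect table, draws
#' `n_lines_per_construct` independent single-locus lines, each with
#' `n_plants_per_line` transgenic plants and as many null-segregant
#' plants.  Null segregants are drawn around wild-type baselines; the
#' transgenic plants around baseline times the construct's multiplier for
#' the shoot order.  Shoot counts are overdispersed integers
#' (negative-binomial with extra-Poisson CV `noise_cv`); weights are
#' log-normal with CV `noise_cv`.
#'
#' @param config A [sim_config()].
#' @return A long tibble: `construct_id`, `line_id`, `genotype`,
#'   `plant_id`, `trait`, `value`, directly consumable by
#'   [relative_effects()].
#' @export
simulate_phenotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  base <- phenotype_baselines()
  withr::with_seed(stage_seed(config, "phenotypes"), {
    grid <- tidyr::expand_grid(
      construct_id = config$effect_table$construct_id,
      line_id = sprintf("L%d", seq_len(config$n_lines_per_construct)),
      genotype = c("transgenic", "null_segregant"),
      plant_id = sprintf("p%02d", seq_len(config$n_plants_per_line)),
      trait = names(base)
    ) |>
      dplyr::left_join(config$effect_table, by = "construct_id") |>
      dplyr::mutate(
        mult = dplyr::case_when(
          .data$genotype == "null_segregant" ~ 1,
          grepl("^primary", .data$trait) ~ .data$primary_mult,
          grepl("^secondary", .data$trait) ~ .data$secondary_mult,
          TRUE ~ .data$tertiary_mult
        ),
        mu = base[.data$trait] * .data$mult
      )
    counts <- grepl("_n$", grid$trait)
    value <- numeric(nrow(grid))
    value[counts] <- rnbinom2(sum(counts), grid$mu[counts], config$noise_cv)
    value[!counts] <- rlnorm_cv(sum(!counts), grid$mu[!counts], config$noise_cv)
    grid |>
      dplyr::mutate(value = value) |>
      dplyr::select("construct_id", "line_id", "genotype", "plant_id",
                    "trait", "value")
  })
}

#' Plant an exact off-target match into a background transcript
#'
#' Copies a random `match_length`-nt substring of the trigger (sense, or
#' reverse-complemented for antisense) into a random background
#' transcript, recording exactly where — a known positive for the
#' off-target scanner.  With `boundary_mismatch = TRUE`, the transcript
#' bases flanking the planted copy are forced to differ from the
#' corresponding extended trigger bases, so the planted match cannot
#' lengthen by accident (used to build exact boundary cases at
#' `match_length = k - 1`).
#'
#' @param transcripts Transcript table (`id`, `sequence`).
#' @param trigger_sequence The trigger (DNA string).
#' @param match_length Length of the planted copy; at most the trigger
#'   length.
#' @param seed Integer seed for the planting.
#' @param strand `"sense"`, `"antisense"`, or `NULL` to pick at random.
#' @param boundary_mismatch Force mismatching flanks (default `FALSE`).
#' @return A list: `transcripts` (modified table) and `planting`, a
#'   one-row tibble with `transcript_id`, `transcript_start`,
#'   `transcript_end`, `trigger_start`, `trigger_end`, `strand`,
#'   `match_length_nt` (1-based inclusive coordinates).
#' @export
plant_offtarget <- function(transcripts, trigger_sequence, match_length,
                            seed = 1L, strand = NULL,
                            boundary_mismatch = FALSE) {
  match_length <- as.integer(match_length)
  if (match_length > nchar(trigger_sequence)) {
    abort("`match_length` exceeds the trigger length.")
  }
  bg <- transcripts[grepl("^bg_", transcripts$id) &
                      transcripts$length_nt >= match_length + 2L, ]
  if (nrow(bg) == 0) {
    bg <- transcripts[transcripts$length_nt >= match_length + 2L, ]
  }
  if (nrow(bg) == 0) abort("No transcript long enough to plant the match into.")
  withr::with_seed(as.integer(seed), {
    strand <- strand %||% sample(c("sense", "antisense"), 1)
    target_row <- bg[sample.int(nrow(bg), 1), ]
    trig_start <- sample.int(nchar(trigger_sequence) - match_length + 1L, 1)
    insert <- substr(trigger_sequence, trig_start, trig_start + match_length - 1L)
    if (strand == "antisense") insert <- reverse_complement(insert)
    # keep one base of flank available on each side
    tx_start <- sample.int(target_row$length_nt - match_length - 1L, 1) + 1L
    seq <- target_row$sequence
    substr(seq, tx_start, tx_start + match_length - 1L) <- insert
    if (boundary_mismatch) {
      flank <- function(trig_pos, tx_pos) {
        if (trig_pos < 1 || trig_pos > nchar(trigger_sequence)) return(NULL)
        tb <- substr(trigger_sequence, trig_pos, trig_pos)
        if (strand == "antisense") tb <- reverse_complement(tb)
        alt <- setdiff(c("A", "C", "G", "T"), tb)[1]
        substr(seq, tx_pos, tx_pos) <<- alt
        NULL
      }
      if (strand == "sense") {
        flank(trig_start - 1L, tx_start - 1L)
        flank(trig_start + match_length, tx_start + match_length)
      } else {
        flank(trig_start + match_length, tx_start - 1L)
        flank(trig_start - 1L, tx_start + match_length)
      }
    }
    transcripts$sequence[transcripts$id == target_row$id] <- seq
    list(
      transcripts = transcripts,
      planting = tibble(
        transcript_id = target_row$id,
        transcript_start = tx_start,
        transcript_end = tx_start + match_length - 1L,
        trigger_start = trig_start,
        trigger_end = trig_start + match_length - 1L,
        strand = strand, match_length_nt = match_length
      )
    )
  })
}
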