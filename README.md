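# suckerscreen

Tools for a tissue-specific gene-suppression screen in an allotetraploid
crop: from laser-microdissection expression tables, through RNAi hairpin
trigger design against homoeologous gene pairs, to off-target scanning
and the statistical calling of effective suppression constructs.

## The scientific problem

Topping a tobacco plant (removing the stem apex) releases axillary buds
from dormancy; the resulting lateral shoots ("suckers") must currently be
controlled by hand or with chemicals. A genetic route is to knock down
the genes that drive sucker outgrowth. That programme has four
computational stages, each implemented here as a data-frame-first R
module:

1. **Enrichment screen** (`select_candidates()`): from RPKM expression
   measured in early (EA) and very-early (VE) axillary-meristem zones
   versus a control zone, select genes that are (a) ≥ 10-fold enriched in
   EA or VE, (b) longer than 200 nt, and (c) annotated as transcription
   factors or unknowns. "Not detectable" (ND) is an explicit state: an ND
   tissue gives fold 0, an ND control is floored at RPKM 0.1. Selected
   genes are assigned to the passing tissue with the larger RPKM.
2. **Trigger design** (`design_triggers()`): tobacco is allotetraploid,
   so each target usually exists as an S-subgenome and a T-subgenome
   homoeolog. A single hairpin trigger should silence *both* copies but
   *no* same-family paralog. The designer slides a window (default
   430 nt) along the global alignment of the homoeologs, and picks the
   window maximising S/T identity subject to every paralog's best
   ungapped sliding identity (either strand) staying below 70%.
3. **Off-target scan** (`scan_offtargets()`): hairpin-derived small RNAs
   can silence any transcript sharing ≥ 22 consecutive nucleotides with
   the trigger, on either strand. A k-mer index plus seed-chaining finds
   every maximal exact match of length ≥ k (default 22) and
   `classify_triggers()` labels each trigger `clean` or
   `off_target_risk`.
4. **Effect calling** (`relative_effects()`, `test_effects()`,
   `call_effective_genes()`): for each construct, per-line phenotype
   ratios r (transgenic mean / null-segregant mean) are tested with a
   one-sample two-sided t-test of H0: E[r] = 1 on n = 3 lines at
   α = 0.01. A construct is *effective* when secondary lateral-shoot
   number and/or weight is significantly **reduced** (p < α and mean
   r < 1; a significant increase never counts).

A self-contained simulator (`sim_config()`, `simulate_transcriptome()`,
`simulate_expression()`, `simulate_phenotypes()`, `plant_offtarget()`)
generates allotetraploid transcriptomes, expression tables and greenhouse
trials with known ground truth, and `run_pipeline()` chains all stages
into a reproducible artifact directory with an md5 manifest.

## Worked example

```r
library(suckerscreen)

# 1. the bundled axillary-meristem screen (24 screen-derived genes)
tab <- axillary_expression()
screen <- tab[tab$group == "screen", ]
sel <- select_candidates(tibble::tibble(
  gene_id = screen$gene_id, length_nt = 1000,
  ea = screen$ea, ve = screen$ve, control = screen$control,
  annotation_class = "unknown"
))
table(sel$assigned_tissue)
#> EA VE
#> 11 13

# 2. effect testing: mean ratio 0.13 +/- 0.09 over 3 lines
t_test_one_sample(mean = 0.13, sd = 0.09, n = 3)
#> one_sample t-test: t = -16.743, df = 2.00, p = 0.003548
call_effective_genes(rnai_effects())
#> [1] "NtBl1" "NtLs"  "NtREV" "VE12"  "VE7"

# 3. trigger design on a simulated allotetraploid transcriptome
cfg <- sim_config(seed = 1, n_target_pairs = 4, n_background = 10,
                  transcript_length_range = c(600, 800))
tx <- simulate_transcriptome(cfg)
des <- design_triggers(tx$transcripts, tx$families,
                       tx$paralogs[, c("family_id", "paralog_id")],
                       trigger_length = 200, step = 5)
glance(des)
#> # A tibble: 1 × 3
#>       n mean_length_nt mean_st_identity_pct
#>   <int>          <dbl>                <dbl>
#> 1     4            200                 97.1
des[, c("family_id", "start", "st_identity_pct", "max_paralog_identity_pct", "status")]
#> # A tibble: 4 × 5
#>   family_id start st_identity_pct max_paralog_identity_pct status
#>   <chr>     <int>           <dbl>                    <dbl> <chr>
#> 1 fam_01        1            98                       52   ok
#> 2 fam_02      301            97.5                     60   ok
#> 3 fam_03      221            96                       68.5 ok
#> 4 fam_04      366            97                       61   ok
```

`plot_enrichment()`, `autoplot()` on identity profiles and
`plot_effects()` provide ggplot views of the screen, the designer's
identity landscape and the effect table; `tidy()`/`glance()` methods
give broom-style summaries.

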